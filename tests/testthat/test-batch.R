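small_cfg <- function(...) {
  sim_config(framework = 1, n_nodes = 40, ba_m = 3, renewal_rate = 0.05,
             alpha_a = 0.1, alpha_b = 0, gamma_a = 0, gamma_b = -1,
             produces_a = TRUE, produces_b = FALSE, cycle_limit = 200, ...)
}

test_that("the batch seed schedule is distinct and reproducible", {
  b <- run_batch(small_cfg(), n_graphs = 2, samples_per_graph = 3, base_seed = 10)
  s <- tidy(b)
  expect_equal(nrow(s), 6)
  expect_equal(s$seed, c(10 + 1 * 3 + 1:3, 10 + 2 * 3 + 1:3))
  expect_equal(anyDuplicated(s$seed), 0L)
  # re-running reproduces every record
  b2 <- run_batch(small_cfg(), n_graphs = 2, samples_per_graph = 3, base_seed = 10)
  expect_identical(tidy(b), tidy(b2))
  # any single sample can be re-run in isolation from its recorded seed
  g2 <- generate_ba_graph(40, 3, seed = 10 + 2)
  redo <- run_sample(g2, small_cfg(), seed = s$seed[6])
  expect_identical(redo, s[6, names(redo)])
})

test_that("summaries are an exact pure fold of the records", {
  samples <- tibble::tibble(
    outcome = c("FIXED_A", "FIXED_A", "FIXED_B", "UNDEFINED", "UNDEFINED"),
    cycles_elapsed = c(10L, 20L, 30L, 100L, 100L),
    final_count_a = c(40L, 40L, 0L, 30L, 10L),
    final_count_b = c(0L, 0L, 40L, 10L, 30L),
    final_ep_count = c(4L, 0L, 0L, 2L, 1L),
    final_ep_count_a = c(4L, 0L, 0L, 2L, 0L),
    final_ep_count_b = 0L
  )
  s <- summarise_samples(samples)
  expect_equal(s$frac_fixed_a, 0.4)
  expect_equal(s$frac_fixed_b, 0.2)
  expect_equal(s$frac_undefined, 0.4)
  expect_equal(s$frac_fixed_a + s$frac_fixed_b + s$frac_undefined, 1,
               tolerance = 1e-12)
  expect_equal(s$frac_undefined_a_majority, 0.5)
  expect_equal(s$mean_occupancy_a, mean(c(0.1, 0, 2 / 30, 0)))
})

test_that("batch summaries respect conservation and forced outcomes", {
  b <- run_batch(small_cfg(), n_graphs = 2, samples_per_graph = 10, base_seed = 3)
  s <- tidy(b); g <- glance(b)
  expect_true(all(s$final_count_a + s$final_count_b == 40L))
  expect_equal(g$frac_fixed_a + g$frac_fixed_b + g$frac_undefined, 1,
               tolerance = 1e-12)
  expect_equal(g$n_samples, 20)

  all_a <- run_batch(small_cfg(initial_count_a = 40), n_graphs = 1,
                     samples_per_graph = 5, base_seed = 1)
  expect_equal(glance(all_a)$frac_fixed_a, 1)
})

test_that("the alpha sweep covers the grid with offset seed schedules", {
  sw <- sweep_alpha(small_cfg(), alpha_values = seq(0, 0.15, by = 0.05),
                    n_graphs = 1, samples_per_graph = 4, base_seed = 5)
  tab <- tidy(sw)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$alpha, c(0, 0.05, 0.10, 0.15))
  expect_true(all(tab$n_samples == 4))
  # full default grid has 16 points
  expect_length(seq(0, 0.15, by = 0.01), 16)
})

test_that("batches and sweeps expose tidy, glance and autoplot methods", {
  b <- run_batch(small_cfg(), n_graphs = 1, samples_per_graph = 5, base_seed = 9)
  expect_s3_class(tidy(b), "tbl_df")
  expect_s3_class(glance(b), "tbl_df")
  expect_s3_class(autoplot(b), "ggplot")
  sw <- sweep_alpha(small_cfg(), alpha_values = c(0, 0.1), n_graphs = 1,
                    samples_per_graph = 3, base_seed = 2)
  expect_s3_class(tidy(sw), "tbl_df")
  expect_s3_class(autoplot(sw), "ggplot")
})

test_that("omega-ratio sweeps back-compute alpha_a and reject unreachable ratios", {
  cfg <- sim_config(framework = 2, n_nodes = 40, ba_m = 3, renewal_rate = 0.05,
                    beta_a = 0.03, beta_b = 0.03, gamma_a = 0.02,
                    gamma_b = 0.02, alpha_b = 0.04, cycle_limit = 100)
  sw <- sweep_omega_ratio(cfg, ratio_values = c(0.25, 1, 4), alpha_b = 0.04,
                          n_graphs = 1, samples_per_graph = 2, base_seed = 2)
  tab <- tidy(sw)
  expect_equal(nrow(tab), 3)
  # omega_b = 0.04 - 0.03 + 0.02 = 0.03; alpha_a = ratio*0.03 + 0.01
  expect_equal(tab$alpha_a, c(0.25, 1, 4) * 0.03 + 0.01, tolerance = 1e-12)
  expect_equal(tab$omega_a / tab$omega_b, c(0.25, 1, 4), tolerance = 1e-12)
  # at ratio 1 the populations are parameter-identical
  expect_equal(tab$alpha_a[2], 0.04, tolerance = 1e-12)
  expect_error(
    sweep_omega_ratio(cfg, ratio_values = c(1, 40), n_graphs = 1,
                      samples_per_graph = 2),
    class = "epmoran_invalid_grid")
  expect_error(
    sweep_omega_ratio(small_cfg(), ratio_values = 1, n_graphs = 1,
                      samples_per_graph = 2),
    class = "epmoran_invalid_grid")
})

test_that("equal-omega sweeps hold omega_a == omega_b in every cell", {
  cfg <- sim_config(framework = 2, n_nodes = 40, ba_m = 3, renewal_rate = 0.05,
                    cycle_limit = 100)
  sw <- sweep_equal_omega(cfg, pair_alpha_a = c(0.01, 0.08),
                          beta_values = c(0.01, 0.09),
                          n_graphs = 1, samples_per_graph = 2, base_seed = 4)
  tab <- tidy(sw)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$omega_a, tab$omega_b, tolerance = 1e-15)
  expect_equal(tab$omega_a, 0.09 - tab$beta, tolerance = 1e-12)
})
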