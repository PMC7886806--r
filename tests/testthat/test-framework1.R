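test_that("identical (graph, config, seed) triples reproduce byte-identical outcomes", {
  g <- generate_ba_graph(100, 4, seed = 3)
  cfg <- exp1_config(n_nodes = 100, cycle_limit = 400)
  r1 <- run_sample(g, cfg, seed = 11)
  r2 <- run_sample(g, cfg, seed = 11)
  r3 <- run_sample(g, cfg, seed = 12)
  expect_identical(r1, r2)
  expect_false(identical(r1, r3))
})

test_that("a newborn takes its parent's type", {
  # two nodes: the dying node's only neighbour is the other node, so after
  # one event both nodes must share a type
  g <- pair2()
  cfg <- sim_config(framework = 1, n_nodes = 2, ba_m = 1, renewal_rate = 0.5,
                    produces_a = FALSE, produces_b = FALSE,
                    birth_ep_chance = 0, cycle_limit = 1)
  for (seed in 1:20) {
    set.seed(seed)
    st <- sim_steps(g, cfg, manual_state(c(0L, 1L)), n_cycles = 1,
                    stop_on_fixation = FALSE)
    expect_true(sum(st$type == 0L) %in% c(0L, 2L))
  }
})

test_that("token timers carry over on reuse and expire on schedule", {
  # both nodes type A and reuse-capable: whoever dies, the single token
  # survives with its timer intact, so its fate is deterministic
  g <- pair2()
  cfg <- sim_config(framework = 1, n_nodes = 2, ba_m = 1, renewal_rate = 0.5,
                    gamma_a = 0, produces_a = FALSE, produces_b = FALSE,
                    birth_ep_chance = 0, cycle_limit = 100)
  start <- manual_state(c(0L, 0L), ep_time = c(10L, 0L))
  for (seed in c(1, 7, 42)) {
    set.seed(seed)
    st <- sim_steps(g, cfg, start, n_cycles = 9, stop_on_fixation = FALSE)
    expect_equal(sum(st$ep_time > 0), 1)       # still exactly one token
    expect_equal(max(st$ep_time), 1)           # 10 - 9 decrements
    set.seed(seed)
    st10 <- sim_steps(g, cfg, start, n_cycles = 10, stop_on_fixation = FALSE)
    expect_equal(sum(st10$ep_time), 0)         # expired
  }
})

test_that("tokens pass only to conspecifics and vanish otherwise", {
  # A - B - A path with the token on the middle B node; B cannot reuse
  # (gamma_b = -1) and reuse is conspecific-only, so the token must never
  # appear on nodes 0 or 2: it survives on node 1 or vanishes at B's death
  g <- path3()
  cfg <- sim_config(framework = 1, n_nodes = 3, ba_m = 1, renewal_rate = 1 / 3,
                    gamma_a = 0, gamma_b = -1,
                    produces_a = FALSE, produces_b = FALSE,
                    birth_ep_chance = 0, cycle_limit = 1)
  vanished <- 0L
  for (seed in 1:200) {
    set.seed(seed)
    st <- sim_steps(g, cfg, manual_state(c(0L, 1L, 0L), ep_time = c(0L, 30L, 0L)),
                    n_cycles = 1, stop_on_fixation = FALSE)
    expect_equal(st$ep_time[1], 0L)
    expect_equal(st$ep_time[3], 0L)
    if (st$ep_time[2] == 0L) vanished <- vanished + 1L
  }
  # the middle node dies (and the token vanishes) in about 1/3 of events
  expect_gt(vanished, 0L)
  expect_lt(abs(vanished / 200 - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / 200))
})

test_that("reuse picks uniformly among eligible neighbours", {
  # star: hub holds the token, three token-less conspecific leaves; when the
  # hub dies each leaf must receive the token with probability 1/3
  g <- star_graph(3)
  cfg <- sim_config(framework = 1, n_nodes = 4, ba_m = 1, renewal_rate = 0.25,
                    gamma_a = 0, produces_a = FALSE, produces_b = FALSE,
                    birth_ep_chance = 0, cycle_limit = 1)
  start <- manual_state(rep(0L, 4), ep_time = c(20L, 0L, 0L, 0L))
  recipients <- integer(0)
  for (seed in 1:4000) {
    set.seed(seed)
    st <- sim_steps(g, cfg, start, n_cycles = 1, stop_on_fixation = FALSE)
    holder <- which(st$ep_time > 0L)
    expect_length(holder, 1L)
    if (holder != 1L) recipients <- c(recipients, holder)
  }
  counts <- tabulate(factor(recipients, levels = 2:4), nbins = 3)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("a fresh birth token ends its first cycle one tick down", {
  g <- pair2()
  cfg <- sim_config(framework = 1, n_nodes = 2, ba_m = 1, renewal_rate = 0.5,
                    birth_ep_chance = 1, ep_lifetime = 5, cycle_limit = 1)
  set.seed(1)
  st <- sim_steps(g, cfg, manual_state(c(0L, 0L)), n_cycles = 1,
                  stop_on_fixation = FALSE)
  expect_setequal(st$ep_time, c(0L, 4L))
})

test_that("monomorphic starts and tight cycle limits classify as specified", {
  g <- generate_ba_graph(100, 4, seed = 5)
  all_a <- exp1_config(n_nodes = 100, initial_count_a = 100)
  r <- run_sample(g, all_a, seed = 1)
  expect_equal(r$outcome, "FIXED_A")
  expect_equal(r$cycles_elapsed, 0L)

  # one cycle of 4 events cannot fix a 50/50 start
  tight <- exp1_config(n_nodes = 100, cycle_limit = 1)
  r2 <- run_sample(g, tight, seed = 1)
  expect_equal(r2$outcome, "UNDEFINED")
  expect_lte(abs(r2$final_count_a - 50), 4)
  expect_equal(r2$final_count_a + r2$final_count_b, 100)
})

test_that("with no birth tokens the process goes token-free once initial tokens expire", {
  g <- generate_ba_graph(80, 4, seed = 6)
  cfg <- sim_config(framework = 1, n_nodes = 80, renewal_rate = 0.05,
                    alpha_a = 0.05, alpha_b = 0.05, gamma_a = 0, gamma_b = 0,
                    birth_ep_chance = 0, ep_lifetime = 15, cycle_limit = 5000)
  for (seed in 1:5) {
    set.seed(seed)
    start <- manual_state(rep(0:1, 40),
                          ep_time = rep(c(15L, 0L), 40))
    st14 <- sim_steps(g, cfg, start, n_cycles = 14, stop_on_fixation = FALSE)
    st15 <- sim_steps(g, cfg, start, n_cycles = 15, stop_on_fixation = FALSE)
    expect_gt(sum(st14$ep_time > 0), 0)   # initial tokens still circulating
    expect_equal(sum(st15$ep_time > 0), 0)  # all gone at the lifetime bound
  }
})

test_that("neutral symmetric dynamics fix both types equally often", {
  g <- generate_ba_graph(50, 4, seed = 8)
  cfg <- sim_config(framework = 1, n_nodes = 50, renewal_rate = 0.04,
                    alpha_a = 0, alpha_b = 0, gamma_a = 0, gamma_b = 0,
                    cycle_limit = 2000)
  out <- vapply(1:400, function(s) run_sample(g, cfg, seed = s)$outcome,
                character(1))
  pa <- mean(out == "FIXED_A"); pb <- mean(out == "FIXED_B")
  # FIXED_A and FIXED_B are mutually exclusive: var(1A - 1B) = pa + pb - (pa-pb)^2
  expect_lt(abs(pa - pb), 3 * sqrt((pa + pb) / 400))
  expect_lt(mean(out == "UNDEFINED"), 0.05)
})
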