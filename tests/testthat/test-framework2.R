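# The end-of-cycle sweep can be isolated by running zero death-birth events
# per cycle, which makes the behavioural state machine deterministic.

fw2_cfg <- function(...) {
  args <- list(framework = 2, n_nodes = 3, ba_m = 1, renewal_rate = 1 / 3,
               alpha_a = 0.04, alpha_b = 0.04, beta_a = 0.03, beta_b = 0.03,
               gamma_a = 0.06, gamma_b = 0.06, cycle_limit = 1000)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("an undisturbed node walks searching -> producing -> using own -> searching", {
  g <- path3()
  cfg <- fw2_cfg()
  start <- manual_state(c(0L, 1L, 0L))
  walk <- function(n_cycles) {
    set.seed(1)
    sim_steps(g, cfg, start, n_cycles = n_cycles, events_per_cycle = 0,
              stop_on_fixation = FALSE)
  }
  expect_true(all(walk(29)$state == 0L))             # still searching
  st30 <- walk(30)
  expect_true(all(st30$state == 1L))                 # producing
  expect_true(all(st30$ep_time == 0L))
  st60 <- walk(60)
  expect_true(all(st60$state == 2L))                 # using own, fresh token
  expect_true(all(st60$ep_time == 29L))              # one decrement applied
  st89 <- walk(89)
  expect_true(all(st89$state == 0L))                 # token expired at 30 cycles
  expect_true(all(st89$ep_time == 0L))
  expect_true(all(walk(88)$state == 2L))
})

test_that("beta = -1 pins a type in the searching state", {
  g <- path3()
  cfg <- fw2_cfg(beta_a = -1)
  set.seed(1)
  st <- sim_steps(g, cfg, manual_state(c(0L, 1L, 0L)), n_cycles = 60,
                  events_per_cycle = 0, stop_on_fixation = FALSE)
  expect_true(all(st$state[st$type == 0L] == 0L))   # A never leaves searching
  expect_true(all(st$state[st$type == 1L] == 2L))   # B is using its own token
})

test_that("a reused token returns its holder to searching when it expires", {
  g <- path3()
  cfg <- fw2_cfg()
  start <- manual_state(c(0L, 1L, 0L), ep_time = c(10L, 0L, 0L),
                        state = c(3L, 0L, 0L))   # USING_OTHER, 10 cycles left
  set.seed(1)
  st9 <- sim_steps(g, cfg, start, n_cycles = 9, events_per_cycle = 0,
                   stop_on_fixation = FALSE)
  expect_equal(st9$state[1], 3L)
  expect_equal(st9$ep_time[1], 1L)
  set.seed(1)
  st10 <- sim_steps(g, cfg, start, n_cycles = 10, events_per_cycle = 0,
                    stop_on_fixation = FALSE)
  expect_equal(st10$state[1], 0L)                  # searching again after 10, not 30
  expect_equal(st10$residence[1], 0L)
})

test_that("newborns always start searching without a token", {
  # both nodes using their own token: the survivor cannot reuse (not
  # searching), so the dead node's token is destroyed and the newborn is a
  # bare searcher
  g <- pair2()
  cfg <- sim_config(framework = 2, n_nodes = 2, ba_m = 1, renewal_rate = 0.5,
                    alpha_a = 0.04, beta_a = 0.03, gamma_a = 0.06,
                    alpha_b = 0.04, beta_b = 0.03, gamma_b = 0.06,
                    cycle_limit = 10)
  for (seed in 1:10) {
    set.seed(seed)
    st <- sim_steps(g, cfg, manual_state(c(0L, 0L), ep_time = c(30L, 30L),
                                         state = c(2L, 2L)),
                    n_cycles = 1, stop_on_fixation = FALSE)
    expect_setequal(st$state, c(0L, 2L))
    expect_equal(sum(st$ep_time > 0), 1L)
    expect_equal(st$ep_time[st$state == 2L], 29L)
    expect_equal(st$residence[st$state == 0L], 1L)  # one sweep since birth
  }
})

test_that("searching conspecifics inherit the dead's token as using-other", {
  g <- pair2()
  cfg <- sim_config(framework = 2, n_nodes = 2, ba_m = 1, renewal_rate = 0.5,
                    alpha_a = 0.04, beta_a = 0.03, gamma_a = 0.06,
                    alpha_b = 0.04, beta_b = 0.03, gamma_b = 0.06,
                    cycle_limit = 10)
  start <- manual_state(c(0L, 0L), ep_time = c(10L, 0L), state = c(2L, 0L))
  saw_reuse <- FALSE
  for (seed in 1:20) {
    set.seed(seed)
    st <- sim_steps(g, cfg, start, n_cycles = 1, stop_on_fixation = FALSE)
    holder <- which(st$ep_time > 0L)
    expect_length(holder, 1L)
    expect_equal(st$ep_time[holder], 9L)           # timer carried, then ticked
    expect_true(st$state[holder] %in% c(2L, 3L))
    if (st$state[holder] == 3L) saw_reuse <- TRUE
  }
  expect_true(saw_reuse)
})

test_that("behavioural state and token possession stay consistent through full runs", {
  g <- generate_ba_graph(60, 4, seed = 2)
  cfg <- sim_config(framework = 2, n_nodes = 60, alpha_a = 0.04, beta_a = 0.03,
                    gamma_a = 0.06, alpha_b = 0.05, beta_b = 0.03,
                    gamma_b = -1, cycle_limit = 300)
  for (seed in 1:10) {
    r <- run_sample(g, cfg, seed = seed, return_state = TRUE)
    st <- attr(r, "state")
    expect_true(all((st$state >= 2L) == (st$ep_time > 0L)))
    expect_equal(r$final_count_a + r$final_count_b, 60L)
    expect_equal(r$count_searching + r$count_producing +
                   r$count_using_own + r$count_using_other, 60L)
    # gamma_b = -1: type B can never be a token recipient
    expect_false(any(st$type == 1L & st$state == 3L))
  }
})

test_that("no token outlives its lifetime, counting across transfers", {
  g <- generate_ba_graph(60, 4, seed = 4)
  cfg <- sim_config(framework = 2, n_nodes = 60, alpha_a = 0.04, beta_a = 0.03,
                    gamma_a = 0.06, alpha_b = 0.04, beta_b = 0.03,
                    gamma_b = 0.06, ep_lifetime = 12, cycle_limit = 200)
  for (seed in 1:20) {
    r <- run_sample(g, cfg, seed = seed, log_eps = TRUE)
    log <- attr(r, "ep_log")
    done <- log[!is.na(log$removed), ]
    expect_true(all(done$removed - done$created <= cfg$ep_lifetime))
    expect_true(all(done$removed > done$created))
  }
})
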