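STATE_LEVELS <- c("SEARCHING", "PRODUCING", "USING_OWN", "USING_OTHER")

#' Initialise a population state
#'
#' Places types on the graph by a uniform random permutation
#' (`floor(N / 2)` type-A nodes by default, the remainder type B) and seeds
#' the extended phenotypes. In framework 1 each node of a producing type
#' independently starts with a token with probability `birth_ep_chance`
#' (or exactly the rounded expected number when `exact_initial_ep` is set);
#' in framework 2 nodes are distributed over the behavioural states
#' following the `init_*` percentages (largest-remainder rounding) and
#' token-holding states start with a token. Initial tokens carry a full
#' `initial_ep_lifetime` timer.
#'
#' Consumes the R random number stream; call `set.seed()` first for a
#' reproducible state (done automatically inside [run_sample()]).
#'
#' @param graph A [population_graph()] with `n` equal to `config$n_nodes`.
#' @param config A [sim_config()].
#' @return A `sim_state`: list with integer vectors `type` (0 = A, 1 = B),
#'   `ep_time` (0 = no token), `state`, `residence`, and the scalar `cycle`.
#' @export
init_population <- function(graph, config) {
  stopifnot(inherits(graph, "population_graph"), inherits(config, "sim_config"))
  n <- config$n_nodes
  if (graph$n != n) {
    abort(sprintf("graph has %d nodes but config expects %d.", graph$n, n),
          class = "epmoran_invalid_input")
  }
  count_a <- config$initial_count_a %||% (n %/% 2L)
  type <- rep.int(1L, n)
  type[sample.int(n, count_a)] <- 0L

  ep_time <- integer(n)
  state <- integer(n)      # SEARCHING
  residence <- integer(n)

  if (config$framework == 1L) {
    capable <- (type == 0L & config$produces_a) | (type == 1L & config$produces_b)
    idx <- which(capable)
    if (length(idx)) {
      if (config$exact_initial_ep) {
        k <- round_half_up(config$birth_ep_chance * length(idx))
        holders <- if (k > 0) sample(idx, k) else integer(0)
        ep_time[holders] <- config$initial_ep_lifetime
      } else {
        holders <- idx[runif(length(idx)) < config$birth_ep_chance]
        ep_time[holders] <- config$initial_ep_lifetime
      }
    }
  } else {
    pct <- c(config$init_searching, config$init_producing,
             config$init_using_own, config$init_using_other)
    counts <- largest_remainder(pct, n)
    state <- rep.int(0:3, counts)[sample.int(n)]
    ep_time[state >= 2L] <- config$initial_ep_lifetime
  }

  structure(list(type = type, ep_time = ep_time, state = state,
                 residence = residence, cycle = 0L),
            class = "sim_state")
}

largest_remainder <- function(pct, n) {
  raw <- pct * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Classify the outcome of a run
#'
#' A run is `FIXED_A` when every node is type A, `FIXED_B` when every node
#' is type B, and `UNDEFINED` when it reaches the cycle limit with both
#' types still present. Pure function of the final state.
#'
#' @param state A `sim_state` (see [init_population()]).
#' @param config A [sim_config()].
#' @return A one-row tibble: `outcome`, `cycles_elapsed`, `final_count_a`,
#'   `final_count_b`, `final_ep_count`.
#' @export
classify_outcome <- function(state, config) {
  stopifnot(inherits(state, "sim_state"), inherits(config, "sim_config"))
  n <- length(state$type)
  count_a <- sum(state$type == 0L)
  outcome <- if (count_a == n) "FIXED_A"
             else if (count_a == 0L) "FIXED_B"
             else "UNDEFINED"
  tibble::tibble(
    outcome = outcome,
    cycles_elapsed = as.integer(state$cycle),
    final_count_a = as.integer(count_a),
    final_count_b = as.integer(n - count_a),
    final_ep_count = as.integer(sum(state$ep_time > 0L))
  )
}

#' Low-level stepping interface
#'
#' Advances a population state by up to `n_cycles` cycles of the selected
#' engine. Each cycle executes `events_per_cycle` sequential death-birth
#' events (a uniformly chosen node dies; a neighbour reproduces into the
#' vacancy with probability proportional to relative fitness; the dead
#' node's extended phenotype is offered to conspecifics), then runs the
#' end-of-cycle sweep: framework-2 residence transitions followed by one
#' timer decrement for every token.
#'
#' `events_per_cycle = 0` runs only the end-of-cycle sweep, which isolates
#' the framework-2 state machine for inspection. `base_fitness` supplies a
#' per-type constant baseline (the classical Moran special case used by the
#' exact-oracle cross-check) and `parent_selection = "uniform"` is a
#' deliberate fitness-ignoring null engine used to verify that statistical
#' gates can detect a broken parent rule.
#'
#' @param graph A [population_graph()].
#' @param config A [sim_config()].
#' @param state A `sim_state` from [init_population()] (or hand-built).
#' @param n_cycles Maximum number of cycles to run.
#' @param events_per_cycle Death-birth events per cycle; defaults to
#'   `round(renewal_rate * n_nodes)` (half-up).
#' @param stop_on_fixation Stop at the first cycle boundary at which one
#'   type has fixed.
#' @param base_fitness Length-2 numeric baseline fitness for types A and B.
#' @param parent_selection `"fitness"` (default) or `"uniform"`.
#' @param log_eps Record an extended-phenotype event log (see Value).
#' @return The advanced `sim_state`, with attribute `"result"` (the raw
#'   engine summary) and, when `log_eps = TRUE`, attribute `"ep_log"`:
#'   a tibble with one row per token ever created (`created` and `removed`
#'   cycle, `removed = NA` if still alive, and the removal `reason`).
#' @export
sim_steps <- function(graph, config, state,
                      n_cycles = config$cycle_limit,
                      events_per_cycle = NULL,
                      stop_on_fixation = TRUE,
                      base_fitness = c(1, 1),
                      parent_selection = c("fitness", "uniform"),
                      log_eps = FALSE) {
  stopifnot(inherits(graph, "population_graph"), inherits(config, "sim_config"),
            inherits(state, "sim_state"))
  parent_selection <- match.arg(parent_selection)
  if (is.null(events_per_cycle)) {
    events_per_cycle <- round_half_up(config$renewal_rate * config$n_nodes)
  }
  res <- sim_run_cpp(
    graph$adj_ptr, graph$adj_idx,
    as.integer(state$type), as.integer(state$ep_time),
    as.integer(state$state), as.integer(state$residence),
    config$framework, as.integer(events_per_cycle), as.integer(n_cycles),
    stop_on_fixation,
    c(config$alpha_a, config$alpha_b),
    c(config$beta_a, config$beta_b),
    c(config$gamma_a, config$gamma_b),
    c(config$produces_a, config$produces_b),
    config$birth_ep_chance, config$ep_lifetime, config$state_time,
    as.numeric(base_fitness),
    parent_selection == "uniform", log_eps
  )
  out <- structure(list(type = res$type, ep_time = res$ep_time,
                        state = res$state, residence = res$residence,
                        cycle = state$cycle + res$cycles),
                   class = "sim_state")
  attr(out, "result") <- res[c("count_a", "count_b", "cycles", "ep_count",
                               "ep_count_a", "ep_count_b", "state_counts")]
  if (log_eps) {
    lg <- res$ep_log
    attr(out, "ep_log") <- tibble::tibble(
      ep = seq_along(lg$created),
      created = lg$created,
      removed = ifelse(lg$removed < 0L, NA_integer_, lg$removed),
      reason = c("alive", "expired", "destroyed")[lg$reason + 1L]
    )
  }
  out
}

#' Run one full simulation sample
#'
#' Initialises a population on `graph` from `seed` and runs the configured
#' engine until fixation of either type or the cycle limit. Fully
#' reproducible: identical `(graph, config, seed)` give identical results.
#'
#' @inheritParams sim_steps
#' @param seed Integer seed for this sample.
#' @return A one-row tibble: `seed`, `outcome` (`"FIXED_A"`, `"FIXED_B"` or
#'   `"UNDEFINED"`), `cycles_elapsed`, `final_count_a`, `final_count_b`,
#'   `final_ep_count`, `final_ep_count_a`, `final_ep_count_b` and, for
#'   framework 2, the final per-state counts `count_searching`,
#'   `count_producing`, `count_using_own`, `count_using_other`. When
#'   `log_eps = TRUE` the token event log is attached as attribute
#'   `"ep_log"`; with `return_state = TRUE` the final `sim_state` is
#'   attached as attribute `"state"`.
#' @export
#' @examples
#' g <- generate_ba_graph(60, 4, seed = 1)
#' cfg <- sim_config(n_nodes = 60, alpha_a = 0.1, gamma_a = 0, gamma_b = -1,
#'                   produces_b = FALSE, cycle_limit = 500)
#' run_sample(g, cfg, seed = 7)
run_sample <- function(graph, config, seed,
                       base_fitness = c(1, 1),
                       parent_selection = c("fitness", "uniform"),
                       log_eps = FALSE, return_state = FALSE) {
  parent_selection <- match.arg(parent_selection)
  set.seed(as.integer(seed))
  state0 <- init_population(graph, config)
  state <- sim_steps(graph, config, state0,
                     n_cycles = config$cycle_limit,
                     stop_on_fixation = TRUE,
                     base_fitness = base_fitness,
                     parent_selection = parent_selection,
                     log_eps = log_eps)
  res <- attr(state, "result")
  n <- config$n_nodes
  outcome <- if (res$count_a == n) "FIXED_A"
             else if (res$count_a == 0L) "FIXED_B"
             else "UNDEFINED"
  row <- tibble::tibble(
    seed = as.integer(seed),
    outcome = outcome,
    cycles_elapsed = as.integer(state$cycle),
    final_count_a = res$count_a,
    final_count_b = res$count_b,
    final_ep_count = res$ep_count,
    final_ep_count_a = res$ep_count_a,
    final_ep_count_b = res$ep_count_b
  )
  if (config$framework == 2L) {
    sc <- res$state_counts
    row$count_searching <- sc[1]
    row$count_producing <- sc[2]
    row$count_using_own <- sc[3]
    row$count_using_other <- sc[4]
  }
  if (log_eps) attr(row, "ep_log") <- attr(state, "ep_log")
  if (return_state) attr(row, "state") <- state
  row
}
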