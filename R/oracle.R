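as_type_vector <- function(initial_types, n) {
  if (is.character(initial_types)) {
    stopifnot(all(initial_types %in% c("A", "B")))
    initial_types <- as.integer(initial_types == "B")
  }
  initial_types <- as.integer(initial_types)
  stopifnot(length(initial_types) == n, all(initial_types %in% 0:1))
  initial_types
}

#' Exact transition matrix of the death-birth chain
#'
#' Enumerates all `2^n` type configurations of a small graph and builds the
#' one-event transition matrix of the death-birth process: a node dies
#' uniformly at random and a neighbour reproduces into the vacancy with
#' probability proportional to its (type-constant) fitness. State `s` is
#' the bitmask in which bit `i` set means node `i` is type A; the all-A and
#' all-B states are absorbing.
#'
#' @param graph A [population_graph()] with at most `max_nodes` nodes.
#' @param fitness_by_type Length-2 positive fitness for types A and B.
#' @param max_nodes State-space cap (default 12, i.e. 4096 states).
#' @return A sparse `2^n x 2^n` row-stochastic matrix
#'   ([Matrix::sparseMatrix]); rows/columns are states `0 .. 2^n - 1` in
#'   order (1-based index = state + 1).
#' @export
moran_transition_matrix <- function(graph, fitness_by_type = c(1, 1),
                                    max_nodes = 12L) {
  stopifnot(inherits(graph, "population_graph"),
            length(fitness_by_type) == 2L, all(fitness_by_type > 0))
  n <- graph$n
  if (n > max_nodes) {
    abort(sprintf("graph too large for exact solve (%d > %d nodes).",
                  n, max_nodes),
          class = "epmoran_size_error")
  }
  n_states <- 2L^n
  bits <- 2L^(seq_len(n) - 1L)
  nbrs <- lapply(seq_len(n), function(i) {
    graph$adj_idx[seq.int(graph$adj_ptr[i] + 1L, graph$adj_ptr[i + 1L])] + 1L
  })

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (s in 0:(n_states - 1L)) {
    is_a <- bitwAnd(s, bits) > 0L
    if (all(is_a) || all(!is_a)) {  # absorbing
      ii <- c(ii, s + 1L); jj <- c(jj, s + 1L); xx <- c(xx, 1)
      next
    }
    for (i in seq_len(n)) {
      w <- ifelse(is_a[nbrs[[i]]], fitness_by_type[1], fitness_by_type[2])
      p_a <- sum(w[is_a[nbrs[[i]]]]) / sum(w)
      s_a <- bitwOr(s, bits[i])                    # newborn type A
      s_b <- bitwAnd(s, bitwNot(bits[i]))          # newborn type B
      ii <- c(ii, s + 1L, s + 1L)
      jj <- c(jj, s_a + 1L, s_b + 1L)
      xx <- c(xx, p_a / n, (1 - p_a) / n)
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n_states, n_states))
}

#' Exact fixation probability on a small graph
#'
#' Solves the absorption linear system of the death-birth chain built by
#' [moran_transition_matrix()] for the probability that type A fixes,
#' starting from a given type assignment. Extended phenotypes must be
#' absent (they would blow up the state space); fitness is constant per
#' type, the classical Moran special case of the simulators.
#'
#' @inheritParams moran_transition_matrix
#' @param initial_types Type per node: integer vector (0 = A, 1 = B) or
#'   character vector of `"A"`/`"B"`.
#' @return Probability of type-A fixation (scalar). The full absorption
#'   vector over all states is attached as attribute `"all_states"`.
#' @export
#' @examples
#' g <- population_graph(2, rbind(c(0, 1)))
#' exact_fixation_probability(g, c("A", "B"))  # 0.5 by symmetry
exact_fixation_probability <- function(graph, initial_types,
                                       fitness_by_type = c(1, 1),
                                       max_nodes = 12L) {
  n <- graph$n
  types <- as_type_vector(initial_types, n)
  P <- moran_transition_matrix(graph, fitness_by_type, max_nodes)
  n_states <- nrow(P)
  all_a <- n_states - 1L  # state with every bit set, 0-based
  trans <- setdiff(0:(n_states - 1L), c(0L, all_a))

  h <- numeric(n_states)
  h[all_a + 1L] <- 1
  if (length(trans)) {
    Q <- P[trans + 1L, trans + 1L, drop = FALSE]
    b <- P[trans + 1L, all_a + 1L]
    h[trans + 1L] <- as.numeric(
      Matrix::solve(Matrix::Diagonal(length(trans)) - Q, b))
  }
  s0 <- sum(2^(which(types == 0L) - 1L))
  structure(h[s0 + 1L], all_states = h)
}

#' Monte-Carlo agreement with the exact oracle
#'
#' Runs the framework-1 simulator with extended phenotypes disabled (no
#' initial tokens, no birth tokens, one death-birth event per cycle,
#' type-constant baseline fitness) `n_samples` times and compares the
#' observed type-A fixation fraction against the exact absorbing-chain
#' probability. Agreement means the gap is within three binomial standard
#' errors. `parent_selection = "uniform"` swaps in the fitness-ignoring
#' mutant engine, which must break agreement under selection.
#'
#' @inheritParams exact_fixation_probability
#' @param n_samples Number of simulator runs.
#' @param seed Base seed (run `i` uses `seed + i`).
#' @param cycle_limit Cycle budget per run (one event per cycle); the
#'   default leaves the undefined fraction negligible on tiny graphs.
#' @param parent_selection `"fitness"` or the `"uniform"` mutant.
#' @return A list: `agree` (logical), `z`, `p_hat`, `p_exact`,
#'   `n_undefined`.
#' @export
monte_carlo_agrees_with_oracle <- function(graph, initial_types,
                                           fitness_by_type = c(1, 1),
                                           n_samples = 10000, seed = 1,
                                           cycle_limit = 100000L,
                                           parent_selection = c("fitness",
                                                                "uniform")) {
  parent_selection <- match.arg(parent_selection)
  n <- graph$n
  types <- as_type_vector(initial_types, n)
  p_exact <- as.numeric(
    exact_fixation_probability(graph, types, fitness_by_type))

  config <- sim_config(framework = 1, n_nodes = n, ba_m = 1L,
                       renewal_rate = 1 / n,
                       produces_a = FALSE, produces_b = FALSE,
                       birth_ep_chance = 0, cycle_limit = cycle_limit)
  state0 <- structure(list(type = types, ep_time = integer(n),
                           state = integer(n), residence = integer(n),
                           cycle = 0L),
                      class = "sim_state")
  n_fixed_a <- 0L; n_undefined <- 0L
  for (i in seq_len(n_samples)) {
    set.seed(as.integer(seed) + i)
    st <- sim_steps(graph, config, state0, n_cycles = cycle_limit,
                    events_per_cycle = 1L, stop_on_fixation = TRUE,
                    base_fitness = fitness_by_type,
                    parent_selection = parent_selection)
    res <- attr(st, "result")
    if (res$count_a == n) n_fixed_a <- n_fixed_a + 1L
    else if (res$count_a > 0L) n_undefined <- n_undefined + 1L
  }
  p_hat <- n_fixed_a / n_samples
  se <- sqrt(p_exact * (1 - p_exact) / n_samples)
  z <- if (se > 0) (p_hat - p_exact) / se else 0
  list(agree = abs(p_hat - p_exact) <= 3 * se, z = z,
       p_hat = p_hat, p_exact = p_exact, n_undefined = n_undefined)
}

#' Deterministic fixtures for validation
#'
#' Named graph + configuration pairs used throughout the validation suite:
#' `"tiny_path"` (3-node path, neutral, one event per cycle, tokens off),
#' `"triangle"` (3-node complete graph, same configuration),
#' `"ba_small"` (20-node BA graph with `m = 2`), and `"full_scale"`
#' (BA graph with `n = 500`, `m = 4`, 4% renewal, token lifetime 30,
#' birth-token chance 0.5 and a 250/250 type split).
#'
#' @param name Fixture name.
#' @param seed Seed for fixtures with a generated graph.
#' @return A list with elements `graph` and `config`.
#' @export
make_fixture <- function(name = c("tiny_path", "triangle", "ba_small",
                                  "full_scale"),
                         seed = 1) {
  name <- match.arg(name)
  tiny_cfg <- function(n) {
    sim_config(framework = 1, n_nodes = n, ba_m = 1L, renewal_rate = 1 / n,
               produces_a = FALSE, produces_b = FALSE, birth_ep_chance = 0,
               cycle_limit = 100000L)
  }
  switch(name,
    tiny_path = list(graph = population_graph(3, rbind(c(0, 1), c(1, 2))),
                     config = tiny_cfg(3)),
    triangle = list(graph = population_graph(3, rbind(c(0, 1), c(0, 2),
                                                      c(1, 2))),
                    config = tiny_cfg(3)),
    ba_small = list(graph = generate_ba_graph(20, 2, seed = seed),
                    config = sim_config(n_nodes = 20, ba_m = 2,
                                        renewal_rate = 0.05,
                                        cycle_limit = 2000L,
                                        gamma_a = 0, gamma_b = 0)),
    full_scale = list(graph = generate_ba_graph(500, 4, seed = seed),
                         config = sim_config(n_nodes = 500, ba_m = 4,
                                             renewal_rate = 0.04,
                                             gamma_a = 0, gamma_b = 0))
  )
}
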