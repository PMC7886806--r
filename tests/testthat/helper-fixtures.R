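# Graphs and configs used across the suite; everything is built in code.

path3 <- function() population_graph(3, rbind(c(0, 1), c(1, 2)))
triangle3 <- function() population_graph(3, rbind(c(0, 1), c(0, 2), c(1, 2)))
cycle4 <- function() {
  population_graph(4, rbind(c(0, 1), c(1, 2), c(2, 3), c(0, 3)))
}
pair2 <- function() population_graph(2, rbind(c(0, 1)))

# star: node 0 is the hub, nodes 1..k the leaves
star_graph <- function(k) {
  population_graph(k + 1L, cbind(0L, seq_len(k)))
}

# hand-built sim_state (bypasses init_population)
manual_state <- function(type, ep_time = integer(length(type)),
                         state = integer(length(type)),
                         residence = integer(length(type))) {
  structure(list(type = as.integer(type), ep_time = as.integer(ep_time),
                 state = as.integer(state), residence = as.integer(residence),
                 cycle = 0L),
            class = "sim_state")
}

# framework-1 experiment configs
exp1_config <- function(alpha_a = 0.05, n_nodes = 500, ...) {
  sim_config(framework = 1, alpha_a = alpha_a, alpha_b = 0,
             gamma_a = 0, gamma_b = -1,
             produces_a = TRUE, produces_b = FALSE,
             n_nodes = n_nodes, ba_m = min(4L, n_nodes - 1L), ...)
}
exp2_config <- function(alpha = 0.05, n_nodes = 500, ...) {
  sim_config(framework = 1, alpha_a = alpha, alpha_b = alpha,
             gamma_a = 0, gamma_b = -1,
             produces_a = TRUE, produces_b = TRUE,
             n_nodes = n_nodes, ba_m = min(4L, n_nodes - 1L), ...)
}

# independent brute-force absorption solve used as the oracle's oracle:
# enumerates type configurations directly from the death-birth definition
# with dense base-R linear algebra, written without reference to the
# package's sparse construction.
brute_force_fixation <- function(graph, initial_types, fitness_by_type) {
  n <- graph$n
  n_states <- 2^n
  nb <- lapply(seq_len(n), function(i) {
    unique(c(graph$edges[graph$edges[, 1] == i - 1L, 2],
             graph$edges[graph$edges[, 2] == i - 1L, 1])) + 1L
  })
  P <- matrix(0, n_states, n_states)
  for (s in seq_len(n_states) - 1L) {
    types <- as.integer(intToBits(s))[1:n]  # 1 = type A
    if (sum(types) %in% c(0L, n)) {
      P[s + 1, s + 1] <- 1
      next
    }
    for (i in seq_len(n)) {
      w <- ifelse(types[nb[[i]]] == 1L, fitness_by_type[1], fitness_by_type[2])
      pa <- sum(w[types[nb[[i]]] == 1L]) / sum(w)
      sa <- bitwOr(s, 2^(i - 1L))
      sb <- bitwAnd(s, bitwNot(2^(i - 1L)))
      P[s + 1, sa + 1] <- P[s + 1, sa + 1] + pa / n
      P[s + 1, sb + 1] <- P[s + 1, sb + 1] + (1 - pa) / n
    }
  }
  all_a <- n_states  # 1-based index of the all-A state
  trans <- setdiff(seq_len(n_states), c(1L, all_a))
  h <- numeric(n_states); h[all_a] <- 1
  h[trans] <- solve(diag(length(trans)) - P[trans, trans], P[trans, all_a])
  s0 <- sum(2^(which(initial_types == 0L) - 1L))
  h[s0 + 1]
}
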