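#' Per-node relative fitness
#'
#' Relative fitness is the reproductive weight a node contributes when it
#' competes to fill a vacancy next door. In framework 1 the baseline is 1
#' and holders of an extended phenotype gain their type's `alpha` bonus.
#' In framework 2 the weight is set by the behavioural state: searching is
#' the baseline 1, producing pays the cost `beta`, using an own token earns
#' `alpha` and using a token built by a dead conspecific earns `gamma`.
#'
#' @param node_type `"A"` or `"B"`.
#' @param config A [sim_config()].
#' @param has_ep Framework 1: does the node hold an extended phenotype?
#' @param state Framework 2: one of `"SEARCHING"`, `"PRODUCING"`,
#'   `"USING_OWN"`, `"USING_OTHER"`.
#' @return A positive scalar.
#' @export
#' @examples
#' cfg <- sim_config(framework = 1, alpha_a = 0.05)
#' relative_fitness("A", cfg, has_ep = TRUE)   # 1.05
#' relative_fitness("A", cfg, has_ep = FALSE)  # 1
relative_fitness <- function(node_type, config, has_ep = FALSE, state = NULL) {
  stopifnot(inherits(config, "sim_config"))
  node_type <- match.arg(toupper(node_type), c("A", "B"))
  suffix <- tolower(node_type)
  pick <- function(name) config[[paste0(name, "_", suffix)]]
  w <- if (config$framework == 1L) {
    1 + if (isTRUE(has_ep)) pick("alpha") else 0
  } else {
    state <- match.arg(toupper(state),
                       c("SEARCHING", "PRODUCING", "USING_OWN", "USING_OTHER"))
    switch(state,
      SEARCHING = 1,
      PRODUCING = {
        b <- pick("beta")
        if (b == -1) {
          abort("type cannot be PRODUCING: beta is the -1 sentinel.",
                class = "epmoran_invalid_configuration")
        }
        1 - b
      },
      USING_OWN = 1 + pick("alpha"),
      USING_OTHER = {
        g <- pick("gamma")
        if (g == -1) {
          abort("type cannot be USING_OTHER: gamma is the -1 sentinel.",
                class = "epmoran_invalid_configuration")
        }
        1 + g
      }
    )
  }
  if (w <= 0) {
    abort("configuration yields non-positive relative fitness.",
          class = "epmoran_invalid_configuration")
  }
  w
}

#' Parent-selection weights
#'
#' Converts the relative fitnesses of a dead node's neighbours into the
#' probability distribution from which the parent of the replacement is
#' drawn: probabilities proportional to fitness, summing to one.
#'
#' @param fitnesses Numeric vector of positive relative fitnesses, one per
#'   neighbour.
#' @return Numeric probability vector of the same length.
#' @export
#' @examples
#' selection_weights(c(1.05, 1))  # c(1.05, 1) / 2.05
selection_weights <- function(fitnesses) {
  if (length(fitnesses) == 0L) {
    abort("at least one neighbour fitness is required.",
          class = "epmoran_invalid_input")
  }
  if (anyNA(fitnesses) || any(fitnesses <= 0)) {
    abort("fitnesses must all be positive.", class = "epmoran_invalid_input")
  }
  fitnesses / sum(fitnesses)
}

#' Absolute population fitness omega
#'
#' The population-level fitness algebra: `omega = alpha - beta + gamma`,
#' combining the average own-use bonus, production cost and shared-use
#' bonus of a population. Sentinel `-1` values must be resolved to 0 by the
#' caller before use; `omega()` is pure arithmetic.
#'
#' @param alpha,beta,gamma Numeric vectors (recycled to a common length).
#' @return Numeric vector of absolute fitness values.
#' @export
#' @examples
#' omega(0.01, 0.01, 0.08)  # 0.08
#' omega(0.08, 0.09, 0.01)  # 0
omega <- function(alpha, beta, gamma) {
  alpha - beta + gamma
}

#' Is the shared use of extended phenotypes favoured?
#'
#' Sharing is favoured when the shared-use bonus outweighs the net cost of
#' producing and using your own token: `gamma / (alpha - beta) > 1`.
#'
#' @inheritParams omega
#' @return Logical vector.
#' @export
#' @examples
#' sharing_favored(0.04, 0.02, 0.05)  # TRUE  (ratio 2.5)
#' sharing_favored(0.05, 0.01, 0.01)  # FALSE (ratio 0.25)
sharing_favored <- function(alpha, beta, gamma) {
  d <- alpha - beta
  if (any(d == 0)) {
    abort("sharing condition undefined when alpha == beta (division by zero).",
          class = "epmoran_undefined_condition")
  }
  gamma / d > 1
}

#' Project phenotype abundance across generations
#'
#' Iterates the geometric recurrence `n(g + 1) = omega * n(g)`, a standalone
#' utility relating absolute fitness to phenotype abundance. Note the
#' multiplier is `omega` itself as defined by the fitness algebra, not
#' `1 + omega`; with typical omega values well below 1 the projected
#' abundance shrinks, so this is a bookkeeping identity rather than a
#' growth model, and the simulators do not use it.
#'
#' @param n0 Abundance at generation 0 (non-negative).
#' @param omega Absolute fitness multiplier.
#' @param generations Number of generations to project, `>= 0`.
#' @return A tibble with columns `generation` (0-based) and `abundance`.
#' @export
#' @examples
#' project_abundance(1, 2, 3)$abundance  # 1 2 4 8
project_abundance <- function(n0, omega, generations) {
  generations <- as.integer(generations)
  if (length(generations) != 1L || is.na(generations) || generations < 0L) {
    abort("`generations` must be a non-negative integer.",
          class = "epmoran_invalid_input")
  }
  if (n0 < 0) {
    abort("`n0` must be non-negative.", class = "epmoran_invalid_input")
  }
  g <- seq.int(0L, generations)
  tibble::tibble(generation = g, abundance = n0 * omega^g)
}

#' The equal-omega fitness table
#'
#' Enumerates the grid of alpha/gamma pairs used to compare two populations
#' at identical absolute fitness: type A takes `alpha_a = x, gamma_a = y`
#' and type B the mirrored `alpha_b = y, gamma_b = x`, with `x + y` held
#' constant, so `omega_a == omega_b == x + y - beta` in every cell.
#'
#' @param pair_alpha_a Values of `x` (`alpha_a`, equal to `gamma_b`).
#' @param pair_sum Constant value of `x + y` (default 0.09).
#' @param beta_values Production-cost column grid.
#' @return A tibble with one row per (pair, beta) cell: `alpha_a`,
#'   `gamma_b`, `alpha_b`, `gamma_a`, `beta`, `omega_a`, `omega_b`.
#' @export
#' @examples
#' fitness_table()
fitness_table <- function(pair_alpha_a = seq(0.01, 0.08, by = 0.01),
                          pair_sum = 0.09,
                          beta_values = seq(0.01, 0.09, by = 0.02)) {
  grid <- tidyr::expand_grid(alpha_a = pair_alpha_a, beta = beta_values)
  dplyr::mutate(
    grid,
    gamma_b = .data$alpha_a,
    alpha_b = pair_sum - .data$alpha_a,
    gamma_a = pair_sum - .data$alpha_a,
    omega_a = omega(.data$alpha_a, .data$beta, .data$gamma_a),
    omega_b = omega(.data$alpha_b, .data$beta, .data$gamma_b)
  )[, c("alpha_a", "gamma_b", "alpha_b", "gamma_a", "beta",
        "omega_a", "omega_b")]
}
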