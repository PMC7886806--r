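#' Run a batch of samples over freshly generated graphs
#'
#' Orchestrates `n_graphs` Barabasi-Albert graphs with
#' `samples_per_graph` independent runs on each. The seed schedule is
#' deterministic and order-independent: graph `g` (1-based) is generated
#' with seed `base_seed + g`, and sample `s` on graph `g` runs with seed
#' `base_seed + g * samples_per_graph + s`, so every sample can be re-run
#' in isolation from its recorded seed.
#'
#' @param config A [sim_config()].
#' @param n_graphs Number of independent graphs.
#' @param samples_per_graph Runs per graph.
#' @param base_seed Base of the seed schedule (default `config$base_seed`).
#' @return An `ep_batch` object: list with `samples` (per-run tibble with
#'   `graph_id`, `sample_id`, `seed`, outcome columns), `summary` (one-row
#'   tibble from [summarise_samples()]) and the batch metadata. [tidy()]
#'   returns the per-sample records, [glance()] the summary row.
#' @export
#' @examples
#' cfg <- sim_config(n_nodes = 60, alpha_a = 0.1, gamma_a = 0, gamma_b = -1,
#'                   produces_b = FALSE, cycle_limit = 300)
#' b <- run_batch(cfg, n_graphs = 2, samples_per_graph = 5, base_seed = 1)
#' glance(b)
run_batch <- function(config, n_graphs = 20, samples_per_graph = 100,
                      base_seed = config$base_seed) {
  stopifnot(inherits(config, "sim_config"), n_graphs >= 1,
            samples_per_graph >= 1)
  base_seed <- as.integer(base_seed)
  records <- vector("list", n_graphs)
  for (g in seq_len(n_graphs)) {
    graph <- generate_ba_graph(config$n_nodes, config$ba_m,
                               seed = base_seed + g)
    seeds <- base_seed + g * samples_per_graph + seq_len(samples_per_graph)
    rows <- purrr::map(seeds, function(s) run_sample(graph, config, seed = s))
    records[[g]] <- dplyr::bind_cols(
      tibble::tibble(graph_id = g,
                     sample_id = seq_len(samples_per_graph)),
      dplyr::bind_rows(rows)
    )
  }
  samples <- dplyr::bind_rows(records)
  structure(
    list(samples = samples, summary = summarise_samples(samples),
         config = config, n_graphs = as.integer(n_graphs),
         samples_per_graph = as.integer(samples_per_graph),
         base_seed = base_seed),
    class = "ep_batch"
  )
}

#' Aggregate per-sample records into a batch summary
#'
#' A pure fold over the per-sample tibble (so summaries can be recomputed
#' from saved TSV records): fixation fractions for each type, the fraction
#' of undefined runs, the share of undefined runs in which type A holds the
#' majority, and the mean terminal extended-phenotype occupancy among
#' type-A nodes (samples with surviving type-A individuals only).
#'
#' @param samples A tibble of [run_sample()] records.
#' @return A one-row tibble: `n_samples`, `frac_fixed_a`, `frac_fixed_b`,
#'   `frac_undefined`, `frac_undefined_a_majority`, `mean_occupancy_a`,
#'   `mean_cycles`.
#' @export
summarise_samples <- function(samples) {
  undefined <- samples$outcome == "UNDEFINED"
  occ <- samples$final_ep_count_a[samples$final_count_a > 0] /
    samples$final_count_a[samples$final_count_a > 0]
  tibble::tibble(
    n_samples = nrow(samples),
    frac_fixed_a = mean(samples$outcome == "FIXED_A"),
    frac_fixed_b = mean(samples$outcome == "FIXED_B"),
    frac_undefined = mean(undefined),
    frac_undefined_a_majority = if (any(undefined)) {
      mean(samples$final_count_a[undefined] > samples$final_count_b[undefined])
    } else NA_real_,
    mean_occupancy_a = if (length(occ)) mean(occ) else NA_real_,
    mean_cycles = mean(samples$cycles_elapsed)
  )
}

#' @method print ep_batch
#' @export
print.ep_batch <- function(x, ...) {
  cat(sprintf("<ep_batch> %d graphs x %d samples (base_seed %d)\n",
              x$n_graphs, x$samples_per_graph, x$base_seed))
  print(x$summary)
  invisible(x)
}

#' @method tidy ep_batch
#' @export
tidy.ep_batch <- function(x, ...) x$samples

#' @method glance ep_batch
#' @export
glance.ep_batch <- function(x, ...) x$summary

#' @method autoplot ep_batch
#' @export
autoplot.ep_batch <- function(object, ...) {
  counts <- dplyr::count(object$samples, .data$outcome)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$outcome, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "samples")
}

sweep_seed_stride <- function(n_graphs, samples_per_graph) {
  as.integer((n_graphs + 1L) * (samples_per_graph + 1L))
}

run_sweep <- function(configs, grid, n_graphs, samples_per_graph, base_seed,
                      keep_samples = FALSE) {
  stride <- sweep_seed_stride(n_graphs, samples_per_graph)
  out <- vector("list", length(configs))
  all_samples <- if (keep_samples) vector("list", length(configs)) else NULL
  for (i in seq_along(configs)) {
    b <- run_batch(configs[[i]], n_graphs = n_graphs,
                   samples_per_graph = samples_per_graph,
                   base_seed = base_seed + (i - 1L) * stride)
    out[[i]] <- dplyr::bind_cols(grid[i, , drop = FALSE], b$summary)
    if (keep_samples) {
      all_samples[[i]] <- dplyr::bind_cols(grid[i, , drop = FALSE], b$samples)
    }
  }
  structure(
    list(summaries = dplyr::bind_rows(out),
         samples = if (keep_samples) dplyr::bind_rows(all_samples) else NULL,
         grid_vars = names(grid)),
    class = "ep_sweep"
  )
}

#' @method print ep_sweep
#' @export
print.ep_sweep <- function(x, ...) {
  cat(sprintf("<ep_sweep> over %s (%d points)\n",
              paste(x$grid_vars, collapse = ", "), nrow(x$summaries)))
  print(x$summaries)
  invisible(x)
}

#' @method tidy ep_sweep
#' @export
tidy.ep_sweep <- function(x, ...) x$summaries

#' @method autoplot ep_sweep
#' @export
autoplot.ep_sweep <- function(object, ...) {
  xvar <- object$grid_vars[[1]]
  long <- tidyr::pivot_longer(
    object$summaries[, c(xvar, "frac_fixed_a", "frac_fixed_b",
                         "frac_undefined")],
    cols = -dplyr::all_of(xvar), names_to = "outcome", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[xvar]], y = .data$fraction,
                                     colour = .data$outcome)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(y = "fraction of samples")
}

#' Sweep the own-use bonus alpha
#'
#' One batch per alpha value on the grid (default 0 to 0.15 in steps of
#' 0.01). With `vary = "a_only"` only `alpha_a` moves and `alpha_b` stays
#' at its template value (the one-producer experiment); with
#' `vary = "both"` the two types share each alpha value (the
#' both-produce/one-reuses experiment).
#'
#' @param config Template [sim_config()].
#' @param alpha_values Alpha grid.
#' @param vary `"a_only"` or `"both"`.
#' @param n_graphs,samples_per_graph,base_seed Batch design per grid point;
#'   grid point `i` offsets the seed schedule by a fixed stride so all
#'   seeds are pairwise distinct.
#' @param keep_samples Keep the per-sample records of every point.
#' @return An `ep_sweep`: `summaries` tibble (one row per grid point, the
#'   grid column first) plus optional `samples`. [autoplot()] draws the
#'   fixation/undefined fractions against the grid.
#' @export
sweep_alpha <- function(config, alpha_values = seq(0, 0.15, by = 0.01),
                        vary = c("a_only", "both"),
                        n_graphs = 20, samples_per_graph = 100,
                        base_seed = config$base_seed, keep_samples = FALSE) {
  vary <- match.arg(vary)
  configs <- lapply(alpha_values, function(a) {
    cfg <- unclass(config)
    cfg$alpha_a <- a
    if (vary == "both") cfg$alpha_b <- a
    validate_sim_config(structure(cfg, class = "sim_config"))
  })
  run_sweep(configs, tibble::tibble(alpha = alpha_values),
            n_graphs, samples_per_graph, base_seed, keep_samples)
}

#' Sweep the omega ratio of the two populations
#'
#' Framework-2 sweep in which `beta` and `gamma` are fixed and equal for
#' both populations and `alpha_a` is back-computed so that
#' `omega_a / omega_b` takes each requested ratio:
#' `alpha_a = ratio * omega_b + beta - gamma` with
#' `omega_b = alpha_b - beta + gamma`.
#'
#' @param config Template [sim_config()] (framework 2).
#' @param ratio_values Target `omega_a / omega_b` grid (default 13
#'   log-spaced points from 0.25 to 4).
#' @param beta,gamma Shared cost and shared-use bonus for both types.
#' @param alpha_b Own-use bonus of the reference population B.
#' @inheritParams sweep_alpha
#' @return An `ep_sweep` with grid columns `ratio`, `alpha_a`, `omega_a`,
#'   `omega_b`.
#' @export
sweep_omega_ratio <- function(config,
                              ratio_values = exp(seq(log(0.25), log(4),
                                                     length.out = 13)),
                              beta = 0.03, gamma = 0.02, alpha_b = 0.04,
                              n_graphs = 20, samples_per_graph = 100,
                              base_seed = config$base_seed,
                              keep_samples = FALSE) {
  if (config$framework != 2L) {
    abort("sweep_omega_ratio requires a framework-2 config.",
          class = "epmoran_invalid_grid")
  }
  omega_b <- omega(alpha_b, beta, gamma)
  alpha_a <- ratio_values * omega_b + beta - gamma
  if (any(alpha_a < 0 | alpha_a > 1)) {
    abort("unreachable omega ratio: back-computed alpha_a outside [0, 1].",
          class = "epmoran_invalid_grid")
  }
  configs <- lapply(alpha_a, function(a) {
    cfg <- unclass(config)
    cfg$alpha_a <- a; cfg$alpha_b <- alpha_b
    cfg$beta_a <- beta; cfg$beta_b <- beta
    cfg$gamma_a <- gamma; cfg$gamma_b <- gamma
    validate_sim_config(structure(cfg, class = "sim_config"))
  })
  grid <- tibble::tibble(ratio = ratio_values, alpha_a = alpha_a,
                         omega_a = omega(alpha_a, beta, gamma),
                         omega_b = omega_b)
  run_sweep(configs, grid, n_graphs, samples_per_graph, base_seed,
            keep_samples)
}

#' Sweep mirrored alpha/gamma pairs at equal omega
#'
#' Framework-2 sweep over the equal-omega grid of [fitness_table()]: type A
#' takes `(alpha, gamma) = (x, y)` and type B the mirror `(y, x)` with
#' `x + y` constant, so both populations share the same absolute fitness in
#' every cell and only the split between own-use and shared-use bonus
#' differs.
#'
#' @param config Template [sim_config()] (framework 2).
#' @param pair_alpha_a Grid of `x` values (`alpha_a = gamma_b`).
#' @param pair_sum Constant `x + y` (default 0.09).
#' @param beta_values Production-cost grid applied to both types.
#' @inheritParams sweep_alpha
#' @return An `ep_sweep` with grid columns `alpha_a`, `gamma_a`, `beta`,
#'   `omega_a`, `omega_b`.
#' @export
sweep_equal_omega <- function(config,
                              pair_alpha_a = seq(0.01, 0.08, by = 0.01),
                              pair_sum = 0.09,
                              beta_values = seq(0.01, 0.09, by = 0.02),
                              n_graphs = 20, samples_per_graph = 100,
                              base_seed = config$base_seed,
                              keep_samples = FALSE) {
  if (config$framework != 2L) {
    abort("sweep_equal_omega requires a framework-2 config.",
          class = "epmoran_invalid_grid")
  }
  grid <- tidyr::expand_grid(alpha_a = pair_alpha_a, beta = beta_values)
  grid$gamma_a <- pair_sum - grid$alpha_a
  grid$omega_a <- omega(grid$alpha_a, grid$beta, grid$gamma_a)
  grid$omega_b <- omega(grid$gamma_a, grid$beta, grid$alpha_a)
  if (any(abs(grid$omega_a - grid$omega_b) > 1e-12)) {
    abort("grid violates omega_a == omega_b.", class = "epmoran_invalid_grid")
  }
  configs <- purrr::pmap(grid[, c("alpha_a", "gamma_a", "beta")],
    function(alpha_a, gamma_a, beta) {
      cfg <- unclass(config)
      cfg$alpha_a <- alpha_a; cfg$gamma_a <- gamma_a
      cfg$alpha_b <- gamma_a; cfg$gamma_b <- alpha_a
      cfg$beta_a <- beta; cfg$beta_b <- beta
      validate_sim_config(structure(cfg, class = "sim_config"))
    })
  run_sweep(configs,
            grid[, c("alpha_a", "gamma_a", "beta", "omega_a", "omega_b")],
            n_graphs, samples_per_graph, base_seed, keep_samples)
}
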