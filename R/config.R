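#' Simulation configuration
#'
#' Bundles every tunable run parameter of both simulation engines. All
#' bonuses are per-type: `alpha_*` is the own-use fitness bonus, `beta_*`
#' the production cost and `gamma_*` the shared-use bonus. `beta` and
#' `gamma` accept the sentinel `-1`, a behavioural switch rather than a
#' numeric value: `beta = -1` means the type never enters the producing
#' state (framework 2) and `gamma = -1` means the type never reuses an
#' abandoned extended phenotype. The sentinel never enters fitness
#' arithmetic.
#'
#' @param framework Simulation engine, `1` (extended phenotypes attached at
#'   birth, single bonus `alpha` for holders) or `2` (four behavioural
#'   states with timed transitions and `alpha`/`beta`/`gamma` bonuses).
#' @param n_nodes Population size `N` (default 500).
#' @param ba_m Preferential-attachment parameter used when graphs are
#'   generated internally (default 4).
#' @param renewal_rate Fraction of nodes replaced by death-birth events each
#'   cycle (default 0.04, i.e. 20 events per cycle at `N = 500`). Must give
#'   at least one event per cycle.
#' @param alpha_a,alpha_b Own-use fitness bonus per type, `>= 0`.
#' @param beta_a,beta_b Production cost per type, in `[0, 1)` or `-1`
#'   ("never produces"; the framework-1 experiments use `-1` for both types
#'   since no producing state exists there).
#' @param gamma_a,gamma_b Shared-use bonus per type, `>= 0` or `-1` ("never
#'   reuses").
#' @param produces_a,produces_b Framework 1 only: whether the type generates
#'   extended phenotypes (at initialisation and at birth).
#' @param ep_lifetime Cycles an extended phenotype lasts after creation
#'   (default 30). The timer keeps running across transfers to new holders.
#' @param state_time Framework 2: cycles spent in the searching and
#'   producing states before transitioning (default 30).
#' @param birth_ep_chance Framework 1: probability that a newborn of a
#'   producing type carries a fresh extended phenotype (default 0.5). Must
#'   be 0 in framework 2, where tokens arise only from the producing state.
#' @param initial_ep_lifetime Timer assigned to extended phenotypes present
#'   at initialisation (defaults to a full `ep_lifetime`).
#' @param init_searching,init_producing,init_using_own,init_using_other
#'   Framework 2: fractions of nodes initialised in each behavioural state;
#'   must sum to 1. The default starts everyone searching with no tokens,
#'   so state occupancies (and the fitness differences they carry) emerge
#'   from the dynamics instead of being injected by the initial condition;
#'   any other split seeds a transient selective advantage for whichever
#'   population profits more from the pre-assigned states.
#' @param initial_count_a Number of type-A nodes at initialisation; defaults
#'   to `floor(n_nodes / 2)` (the remaining nodes are type B).
#' @param exact_initial_ep Framework 1: if `TRUE`, exactly
#'   `round(birth_ep_chance * n)` of the eligible nodes start with a token
#'   instead of independent Bernoulli draws.
#' @param cycle_limit Cycle budget after which an unfixed run is classified
#'   `UNDEFINED` (default 5000).
#' @param samples Default number of runs per graph in batch helpers.
#' @param base_seed Default base seed for batch seed schedules.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [parse_config()] for the flat key=value file format.
#' @export
#' @examples
#' sim_config(framework = 1, alpha_a = 0.05, gamma_a = 0, gamma_b = -1,
#'            produces_b = FALSE)
sim_config <- function(framework = 1,
                       n_nodes = 500L,
                       ba_m = 4L,
                       renewal_rate = 0.04,
                       alpha_a = 0, alpha_b = 0,
                       beta_a = -1, beta_b = -1,
                       gamma_a = -1, gamma_b = -1,
                       produces_a = TRUE, produces_b = TRUE,
                       ep_lifetime = 30L,
                       state_time = 30L,
                       birth_ep_chance = if (framework == 1) 0.5 else 0,
                       initial_ep_lifetime = ep_lifetime,
                       init_searching = 1, init_producing = 0,
                       init_using_own = 0, init_using_other = 0,
                       initial_count_a = NULL,
                       exact_initial_ep = FALSE,
                       cycle_limit = 5000L,
                       samples = 100L,
                       base_seed = 1L) {
  cfg <- list(
    framework = as.integer(framework),
    n_nodes = as.integer(n_nodes),
    ba_m = as.integer(ba_m),
    renewal_rate = as.numeric(renewal_rate),
    alpha_a = as.numeric(alpha_a), alpha_b = as.numeric(alpha_b),
    beta_a = as.numeric(beta_a), beta_b = as.numeric(beta_b),
    gamma_a = as.numeric(gamma_a), gamma_b = as.numeric(gamma_b),
    produces_a = isTRUE(as.logical(produces_a)),
    produces_b = isTRUE(as.logical(produces_b)),
    ep_lifetime = as.integer(ep_lifetime),
    state_time = as.integer(state_time),
    birth_ep_chance = as.numeric(birth_ep_chance),
    initial_ep_lifetime = as.integer(initial_ep_lifetime),
    init_searching = as.numeric(init_searching),
    init_producing = as.numeric(init_producing),
    init_using_own = as.numeric(init_using_own),
    init_using_other = as.numeric(init_using_other),
    initial_count_a = if (is.null(initial_count_a)) NULL
                      else as.integer(initial_count_a),
    exact_initial_ep = isTRUE(as.logical(exact_initial_ep)),
    cycle_limit = as.integer(cycle_limit),
    samples = as.integer(samples),
    base_seed = as.integer(base_seed)
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  err <- function(key, msg) {
    abort(sprintf("invalid config: `%s` %s", key, msg),
          class = "epmoran_config_error")
  }
  if (!cfg$framework %in% c(1L, 2L)) err("framework", "must be 1 or 2")
  if (is.na(cfg$n_nodes) || cfg$n_nodes < 2L) err("n_nodes", "must be >= 2")
  if (is.na(cfg$ba_m) || cfg$ba_m < 1L || cfg$ba_m >= cfg$n_nodes) {
    err("ba_m", "must satisfy 1 <= ba_m < n_nodes")
  }
  if (is.na(cfg$renewal_rate) || cfg$renewal_rate <= 0 || cfg$renewal_rate > 1) {
    err("renewal_rate", "must lie in (0, 1]")
  }
  if (cfg$renewal_rate * cfg$n_nodes < 1) {
    err("renewal_rate", "must give at least one death-birth event per cycle")
  }
  for (key in c("alpha_a", "alpha_b")) {
    if (is.na(cfg[[key]]) || cfg[[key]] < 0) err(key, "must be >= 0")
  }
  for (key in c("beta_a", "beta_b")) {
    v <- cfg[[key]]
    if (is.na(v) || (v != -1 && (v < 0 || v >= 1))) {
      err(key, "must be in [0, 1) or the sentinel -1")
    }
  }
  for (key in c("gamma_a", "gamma_b")) {
    v <- cfg[[key]]
    if (is.na(v) || (v != -1 && v < 0)) {
      err(key, "must be >= 0 or the sentinel -1")
    }
  }
  if (is.na(cfg$birth_ep_chance) || cfg$birth_ep_chance < 0 ||
      cfg$birth_ep_chance > 1) {
    err("birth_ep_chance", "must lie in [0, 1]")
  }
  if (cfg$framework == 2L && cfg$birth_ep_chance != 0) {
    err("birth_ep_chance",
        "must be 0 in framework 2 (tokens arise from the producing state)")
  }
  for (key in c("ep_lifetime", "state_time", "initial_ep_lifetime",
                "cycle_limit", "samples")) {
    if (is.na(cfg[[key]]) || cfg[[key]] < 1L) err(key, "must be >= 1")
  }
  pct <- c(cfg$init_searching, cfg$init_producing,
           cfg$init_using_own, cfg$init_using_other)
  if (anyNA(pct) || any(pct < 0) || any(pct > 1)) {
    err("init_*", "state percentages must lie in [0, 1]")
  }
  if (abs(sum(pct) - 1) > 1e-9) {
    err("init_*", sprintf("state percentages must sum to 1 (got %g)", sum(pct)))
  }
  if (!is.null(cfg$initial_count_a) &&
      (cfg$initial_count_a < 0L || cfg$initial_count_a > cfg$n_nodes)) {
    err("initial_count_a", "must lie in 0 .. n_nodes")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> framework %d, N = %d, renewal %.3f (%d events/cycle)\n",
              x$framework, x$n_nodes, x$renewal_rate,
              round_half_up(x$renewal_rate * x$n_nodes)))
  cat(sprintf("  alpha (A,B) = (%g, %g); beta = (%g, %g); gamma = (%g, %g)\n",
              x$alpha_a, x$alpha_b, x$beta_a, x$beta_b, x$gamma_a, x$gamma_b))
  cat(sprintf("  ep_lifetime %d, state_time %d, birth_ep_chance %g, cycle_limit %d\n",
              x$ep_lifetime, x$state_time, x$birth_ep_chance, x$cycle_limit))
  invisible(x)
}

config_keys <- function() {
  setdiff(names(formals(sim_config)), character(0))
}

#' Parse a flat key=value configuration file
#'
#' The on-disk configuration format is flat text: one `key=value` pair per
#' line, `#` starts a comment, blank lines are ignored. Keys are exactly the
#' argument names of [sim_config()]; unknown keys are rejected with an error
#' naming the offending key, and all values pass the same validation as
#' [sim_config()]. Omitted keys take the documented defaults.
#'
#' @param path Path to a config file (ignored when `text` is given).
#' @param text Optional literal config text, for programmatic use.
#' @return A validated [sim_config()].
#' @export
#' @examples
#' parse_config(text = "framework=1\nalpha_a=0.05\ngamma_a=0\ngamma_b=-1")
parse_config <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) strsplit(text, "\n", fixed = TRUE)[[1]]
           else readLines(path)
  args <- list()
  known <- config_keys()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    line <- trimws(line)
    if (line == "") next
    if (!grepl("=", line, fixed = TRUE)) {
      abort(sprintf("config line %d: expected key=value, got '%s'.",
                    i, lines[[i]]),
            class = "epmoran_config_error")
    }
    key <- trimws(sub("=.*$", "", line))
    val <- trimws(sub("^[^=]*=", "", line))
    if (!key %in% known) {
      abort(sprintf("config line %d: unknown key `%s`.", i, key),
            class = "epmoran_config_error")
    }
    args[[key]] <- parse_config_value(key, val, i)
  }
  do.call(sim_config, args)
}

parse_config_value <- function(key, val, line_no) {
  logical_keys <- c("produces_a", "produces_b", "exact_initial_ep")
  if (key %in% logical_keys) {
    lv <- tolower(val)
    if (!lv %in% c("true", "false", "1", "0", "yes", "no")) {
      abort(sprintf("config line %d: `%s` must be a logical, got '%s'.",
                    line_no, key, val),
            class = "epmoran_config_error")
    }
    return(lv %in% c("true", "1", "yes"))
  }
  num <- suppressWarnings(as.numeric(val))
  if (is.na(num)) {
    abort(sprintf("config line %d: `%s` must be numeric, got '%s'.",
                  line_no, key, val),
          class = "epmoran_config_error")
  }
  num
}

#' Write a configuration to a flat key=value file
#'
#' @param config A [sim_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  vals <- config[!vapply(config, is.null, logical(1))]
  fmt <- function(v) {
    if (is.logical(v)) tolower(as.character(v)) else format(v, digits = 15)
  }
  writeLines(c("# epmoran config",
               sprintf("%s=%s", names(vals), vapply(vals, fmt, character(1)))),
             con = path)
  invisible(path)
}
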