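#' Population graphs
#'
#' A `population_graph` is the contact structure of the simulated population:
#' an undirected, connected, simple graph whose nodes are individuals. Nodes
#' are identified by the 0-based integers `0 .. n-1`; edges are stored as a
#' canonical `u < v` integer matrix, together with a compressed adjacency
#' index used by the simulation engine.
#'
#' @param n Number of nodes.
#' @param edges Two-column integer matrix of 0-based node ids, one row per
#'   undirected edge.
#' @param m Preferential-attachment parameter recorded as metadata (`NA` for
#'   graphs not built by [generate_ba_graph()]).
#'
#' @return An object of class `population_graph`: a list with elements `n`,
#'   `m`, `edges` (canonical `u < v`, ordered), `adj_ptr` and `adj_idx`
#'   (0-based compressed adjacency).
#' @export
#' @examples
#' g <- population_graph(3, rbind(c(0, 1), c(1, 2)))
#' degrees(g)
population_graph <- function(n, edges, m = NA_integer_) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    abort("`n` must be a single positive integer.", class = "epmoran_invalid_input")
  }
  edges <- as.matrix(edges)
  if (nrow(edges) == 0L) {
    abort("a population graph must have at least one edge.",
          class = "epmoran_invalid_input")
  }
  storage.mode(edges) <- "integer"
  if (ncol(edges) != 2L || anyNA(edges)) {
    abort("`edges` must be a two-column integer matrix without NAs.",
          class = "epmoran_invalid_input")
  }
  if (any(edges < 0L) || any(edges >= n)) {
    abort("edge endpoints must lie in 0 .. n-1.", class = "epmoran_invalid_input")
  }
  if (any(edges[, 1L] == edges[, 2L])) {
    abort("self-loops are not allowed.", class = "epmoran_invalid_input")
  }
  u <- pmin(edges[, 1L], edges[, 2L])
  v <- pmax(edges[, 1L], edges[, 2L])
  key <- as.double(u) * n + v
  if (anyDuplicated(key)) {
    abort("duplicate edges are not allowed.", class = "epmoran_invalid_input")
  }
  o <- order(u, v)
  edges <- cbind(u = u[o], v = v[o])

  # compressed adjacency (0-based, neighbours of i at adj_idx[(ptr[i]+1):ptr[i+1]])
  from <- c(edges[, 1L], edges[, 2L])
  to <- c(edges[, 2L], edges[, 1L])
  deg <- tabulate(from + 1L, nbins = n)
  ptr <- c(0L, cumsum(deg))
  idx <- to[order(from)]

  g <- structure(
    list(n = n, m = as.integer(m), edges = edges,
         adj_ptr = as.integer(ptr), adj_idx = as.integer(idx)),
    class = "population_graph"
  )
  if (!graph_is_connected(g)) {
    abort("the graph must be connected (every node reachable from node 0).",
          class = "epmoran_invalid_input")
  }
  g
}

graph_is_connected <- function(graph) {
  n <- graph$n
  if (n == 1L) return(TRUE)
  seen <- logical(n)
  queue <- integer(n)
  queue[1L] <- 0L
  seen[1L] <- TRUE
  lo <- 1L; hi <- 1L
  while (lo <= hi) {
    i <- queue[lo]; lo <- lo + 1L
    nb <- graph$adj_idx[seq.int(graph$adj_ptr[i + 1L] + 1L, graph$adj_ptr[i + 2L])]
    fresh <- nb[!seen[nb + 1L]]
    if (length(fresh)) {
      seen[fresh + 1L] <- TRUE
      queue[seq.int(hi + 1L, hi + length(fresh))] <- fresh
      hi <- hi + length(fresh)
    }
  }
  all(seen)
}

#' Node degrees of a population graph
#'
#' @param graph A [population_graph()].
#' @return Integer vector of degrees, one per node (0-based node order).
#' @export
degrees <- function(graph) {
  stopifnot(inherits(graph, "population_graph"))
  diff(graph$adj_ptr)
}

#' @export
print.population_graph <- function(x, ...) {
  cat(sprintf("<population_graph> %d nodes, %d edges (m = %s)\n",
              x$n, nrow(x$edges),
              if (is.na(x$m)) "?" else as.character(x$m)))
  invisible(x)
}

#' @export
format.population_graph <- function(x, ...) {
  sprintf("<population_graph: n=%d, edges=%d>", x$n, nrow(x$edges))
}

#' Generate a Barabasi-Albert scale-free population graph
#'
#' Grows a graph by preferential attachment: starting from `m` isolated seed
#' nodes, each of the `n - m` subsequently added nodes connects to `m`
#' distinct existing nodes chosen with probability proportional to their
#' current degree (the first added node necessarily links to all `m` seeds).
#' The construction uses the repeated-nodes urn method, so the resulting
#' graphs match the standard preferential-attachment generator used across
#' network libraries; the edge count is exactly `m * (n - m)`.
#'
#' Note that while every incrementally added node has degree at least `m`,
#' the initial seed nodes can end with smaller degree; `m` is therefore a
#' minimum degree for grown nodes only, not a global minimum.
#'
#' @param n Number of nodes (must exceed `m`).
#' @param m Edges attached per added node, `m >= 1`.
#' @param seed Optional integer seed; when supplied the construction is
#'   deterministic.
#' @return A [population_graph()] with `n` nodes and `m * (n - m)` edges.
#' @export
#' @examples
#' g <- generate_ba_graph(100, 4, seed = 1)
#' nrow(g$edges)  # 4 * 96
generate_ba_graph <- function(n, m, seed = NULL) {
  n <- as.integer(n); m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 1L) {
    abort("`m` must be a positive integer.", class = "epmoran_invalid_parameter")
  }
  if (length(n) != 1L || is.na(n) || n <= m) {
    abort("`n` must be an integer greater than `m`.",
          class = "epmoran_invalid_parameter")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  n_edges <- m * (n - m)
  eu <- integer(n_edges); ev <- integer(n_edges)
  urn <- integer(2L * n_edges)   # endpoint multiset; multiplicity = degree
  urn_len <- 0L
  e <- 0L
  for (v in seq.int(m, n - 1L)) {
    if (urn_len == 0L) {
      targets <- seq.int(0L, m - 1L)
    } else {
      targets <- integer(0L)
      while (length(targets) < m) {
        x <- urn[sample.int(urn_len, 1L)]
        if (!any(targets == x)) targets <- c(targets, x)
      }
    }
    ii <- seq.int(e + 1L, e + m)
    eu[ii] <- targets
    ev[ii] <- v
    e <- e + m
    urn[seq.int(urn_len + 1L, urn_len + 2L * m)] <- c(targets, rep.int(v, m))
    urn_len <- urn_len + 2L * m
  }
  population_graph(n, cbind(eu, ev), m = m)
}

#' Read and write plain-text edge lists
#'
#' Population graphs are exchanged as plain-text edge lists: one edge per
#' line as `"u v"` with `u < v` in ASCII decimal, preceded by `#`-prefixed
#' header lines carrying the node count and attachment parameter
#' (`# n 500`, `# m 4`). [read_edge_list()] validates the input (malformed
#' lines, self-loops and duplicate edges are reported with their line
#' number) and checks the graph invariants.
#'
#' @param graph A [population_graph()].
#' @param path Path of the text file to write or read.
#' @return [write_edge_list()] returns `path` invisibly; [read_edge_list()]
#'   returns a [population_graph()].
#' @export
#' @examples
#' f <- tempfile(fileext = ".edges")
#' g <- generate_ba_graph(30, 2, seed = 1)
#' write_edge_list(g, f)
#' identical(read_edge_list(f)$edges, g$edges)
write_edge_list <- function(graph, path) {
  if (!inherits(graph, "population_graph") || graph$n < 1L ||
      nrow(graph$edges) < 1L) {
    abort("`graph` must be a non-empty population_graph.",
          class = "epmoran_invalid_input")
  }
  header <- c("# epmoran edge list",
              sprintf("# n %d", graph$n),
              if (!is.na(graph$m)) sprintf("# m %d", graph$m))
  body <- sprintf("%d %d", graph$edges[, 1L], graph$edges[, 2L])
  writeLines(c(header, body), con = path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  n_meta <- NA_integer_; m_meta <- NA_integer_
  eu <- integer(0); ev <- integer(0)
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "") next
    if (startsWith(line, "#")) {
      toks <- strsplit(sub("^#\\s*", "", line), "\\s+")[[1]]
      if (length(toks) == 2L && toks[1] %in% c("n", "m")) {
        val <- suppressWarnings(as.integer(toks[2]))
        if (toks[1] == "n") n_meta <- val else m_meta <- val
      }
      next
    }
    toks <- strsplit(line, "\\s+")[[1]]
    pair <- suppressWarnings(as.integer(toks))
    if (length(pair) != 2L || anyNA(pair) || any(pair < 0L)) {
      abort(sprintf("line %d: malformed edge '%s'.", i, lines[[i]]),
            class = "epmoran_parse_error")
    }
    if (pair[1] == pair[2]) {
      abort(sprintf("line %d: self-loop '%s'.", i, lines[[i]]),
            class = "epmoran_parse_error")
    }
    eu <- c(eu, pair[1]); ev <- c(ev, pair[2])
  }
  if (length(eu) == 0L) {
    abort("no edges found in edge list.", class = "epmoran_parse_error")
  }
  key <- as.double(pmin(eu, ev)) * (max(eu, ev) + 1) + pmax(eu, ev)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    abort(sprintf("duplicate edge '%d %d' in edge list.", eu[dup], ev[dup]),
          class = "epmoran_parse_error")
  }
  n <- if (!is.na(n_meta)) n_meta else max(eu, ev) + 1L
  population_graph(n, cbind(eu, ev), m = m_meta)
}
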