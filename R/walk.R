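#' Configuration for the random walk with restart
#'
#' @param q restart probability per step, in `[0, 1]`.  The default 0.01
#'   keeps the walk mostly diffusive while guaranteeing ergodicity and a
#'   unique stationary distribution.
#' @param bias_restart if `TRUE` (default) the restart distribution is
#'   proportional to the data values, further biasing the walk towards the
#'   data; if `FALSE` restart is uniform over nodes.
#' @param tol convergence tolerance on the L1 change of the visitation
#'   vector between iterations.
#' @param max_iter iteration cap for the power iteration.
#' @param winsorize clip data to the 0.1st/99.9th percentile before the walk
#'   (see [winsorize()]).
#' @param reverse_tf flip directed TF_TARGET edges before the walk (see
#'   [reverse_tf_edges()]).
#' @param seed optional integer recorded for provenance; the solver itself
#'   is deterministic.
#' @return a `walk_config` list
#' @export
walk_config <- function(q = 0.01, bias_restart = TRUE, tol = 1e-12,
                        max_iter = 10000, winsorize = TRUE,
                        reverse_tf = TRUE, seed = NULL) {
  stopifnot(is.numeric(q), length(q) == 1, q >= 0, q <= 1,
            tol > 0, max_iter >= 1)
  structure(list(q = q, bias_restart = isTRUE(bias_restart), tol = tol,
                 max_iter = as.integer(max_iter),
                 winsorize = isTRUE(winsorize),
                 reverse_tf = isTRUE(reverse_tf), seed = seed),
            class = "walk_config")
}

# unique directed arc list of a network: undirected edges expand to two arcs
.arcs <- function(net) {
  e <- net$edges
  if (nrow(e) == 0)
    return(data.frame(from = character(), to = character()))
  from <- c(e$source, e$target[!e$directed])
  to <- c(e$target, e$source[!e$directed])
  a <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
  rownames(a) <- NULL
  a
}

#' Build the data-biased transition probability matrix
#'
#' For node i with downstream neighbour set N_i (undirected edges count in
#' both directions), the transition probability to j in N_i is
#' `p_ij = w_j / sum_{k in N_i} w_k`: the walker prefers neighbours with
#' high data values.  Nodes with no downstream neighbours (dangling nodes)
#' transition uniformly to all n nodes; those rows are kept implicit (a
#' logical `dangling` marker plus a rank-one correction at iteration time)
#' so the matrix stays sparse.
#'
#' @param net an [interaction_network] with at least one node
#' @param w a [data_vector] aligned to `net$nodes` (see [impute_missing()]),
#'   all values > 0
#' @return a `transition_matrix`: list with sparse `P` (zero rows at
#'   dangling nodes), logical `dangling`, and the node order `nodes`
#' @export
build_transition_matrix <- function(net, w) {
  if (length(net$nodes) == 0) stop("empty network")
  wv <- as.numeric(w[net$nodes])
  if (anyNA(wv)) stop("data vector does not cover all network nodes")
  if (any(wv <= 0)) stop("data values must be strictly positive")
  n <- length(net$nodes)
  arcs <- .arcs(net)
  if (nrow(arcs) > 0) {
    i <- match(arcs$from, net$nodes)
    j <- match(arcs$to, net$nodes)
    x <- wv[j]
    P <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
    rs <- Matrix::rowSums(P)
    dangling <- rs == 0
    scale <- ifelse(dangling, 1, rs)
    P <- Matrix::Diagonal(x = 1 / scale) %*% P
  } else {
    P <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n))
    dangling <- rep(TRUE, n)
  }
  structure(list(P = methods::as(P, "CsparseMatrix"),
                 dangling = as.vector(dangling), nodes = net$nodes),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("transition_matrix:", length(x$nodes), "nodes,",
      length(x$P@x), "stored transitions,", sum(x$dangling),
      "dangling node(s)\n")
  invisible(x)
}

#' Restart distribution of the walk
#'
#' With biased restart the walker returns to node i with probability
#' proportional to its data value, `r_i = w_i / sum_k w_k`; with uniform
#' restart `r_i = 1/n`.
#'
#' @param w a [data_vector] aligned to the node order, all values > 0
#' @param config a [walk_config]
#' @return numeric probability vector (sums to 1), named by gene
#' @export
restart_vector <- function(w, config = walk_config()) {
  wv <- as.numeric(w)
  if (any(is.na(wv)) || any(wv <= 0))
    stop("data values must be strictly positive")
  n <- length(wv)
  if (n == 0) stop("empty data vector")
  r <- if (config$bias_restart) wv / sum(wv) else rep(1 / n, n)
  setNames(r, names(w))
}

#' Stationary visitation distribution by power iteration
#'
#' Iterates `g <- (1 - q) * (g P) + q * r` from the uniform start
#' `g0 = 1/n`, with the dangling-node rank-one correction applied at each
#' step, until the L1 change drops below `config$tol`.  For `q > 0` the
#' update is a contraction with factor (1 - q), so the fixed point is unique
#' and the final error is at most `tol * (1 - q) / q`.  With `q = 0` on a
#' periodic or disconnected graph the limit may not be unique; a warning is
#' issued.
#'
#' @param tm a `transition_matrix` from [build_transition_matrix()]
#' @param r restart probability vector over the same node order
#' @param config a [walk_config]
#' @return named numeric vector `g` (sums to 1) with attributes
#'   `iterations` and `converged`
#' @export
stationary_distribution <- function(tm, r, config = walk_config()) {
  stopifnot(inherits(tm, "transition_matrix"))
  n <- length(tm$nodes)
  stopifnot(length(r) == n)
  q <- config$q
  if (q == 0)
    warning("q = 0: the stationary distribution may not be unique ",
            "on periodic or disconnected graphs")
  r <- as.numeric(r)
  g <- rep(1 / n, n)
  Pt <- Matrix::t(tm$P)  # column-oriented product: g P == t(P) %*% g
  dang <- tm$dangling
  converged <- FALSE
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    step <- as.numeric(Pt %*% g)
    if (any(dang)) step <- step + sum(g[dang]) / n
    g_new <- (1 - q) * step + q * r
    delta <- sum(abs(g_new - g))
    g <- g_new
    if (delta < config$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("power iteration did not converge in ", config$max_iter,
            " iterations")
  structure(setNames(g, tm$nodes), iterations = it, converged = converged)
}

#' Run the data-biased walk and its topology-only background
#'
#' Computes the data-biased visitation frequencies `g` (transition matrix
#' and restart both biased by `w`) and the background frequencies `g_r`
#' obtained by setting every data value to 1 with the same restart
#' probability q (biased restart under all-ones data is uniform).  The
#' relative visitation frequency `g_rel = g / g_r` corrects the data-driven
#' score for pure topological centrality (hub bias).
#'
#' @param net an [interaction_network]
#' @param w a [data_vector]; genes missing from it are imputed to 1
#' @param config a [walk_config].  Note: `run_walk()` does not winsorize or
#'   reverse TF edges; use [netwalk()] for the full pipeline.
#' @return a `visitation_result`: list with `nodes`, `w`, `g`, `g_r`,
#'   `g_rel`, iteration counts and convergence flags
#' @export
run_walk <- function(net, w, config = walk_config()) {
  w <- impute_missing(net, w, quiet = TRUE)
  tm <- build_transition_matrix(net, w)
  r <- restart_vector(w, config)
  g <- stationary_distribution(tm, r, config)

  ones <- data_vector(setNames(rep(1, length(net$nodes)), net$nodes),
                      condition = "background")
  tm_r <- build_transition_matrix(net, ones)
  r_r <- restart_vector(ones, config)  # uniform whether or not biased
  g_r <- stationary_distribution(tm_r, r_r, config)

  structure(list(
    nodes = net$nodes,
    w = as.numeric(w),
    g = as.numeric(g),
    g_r = as.numeric(g_r),
    g_rel = as.numeric(g) / as.numeric(g_r),
    iterations = attr(g, "iterations"),
    converged = attr(g, "converged"),
    iterations_bg = attr(g_r, "iterations"),
    converged_bg = attr(g_r, "converged"),
    tm = tm, tm_bg = tm_r,
    condition = condition_of(w)
  ), class = "visitation_result")
}

#' @export
print.visitation_result <- function(x, ...) {
  cat("visitation_result [", x$condition, "]: ", length(x$nodes),
      " nodes; converged = ", x$converged, " (", x$iterations,
      " iterations)\n", sep = "")
  invisible(x)
}
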