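#' Raw edge flux of a walk
#'
#' The flux through arc i->j at stationarity is `e_ij = g_i * p_ij`: the
#' probability mass flowing along the arc per step.  Each undirected edge
#' yields two arcs whose fluxes are kept separately (`e_fwd`, `e_rev`) and
#' also combined by summation (`e`) for per-interaction reporting; directed
#' edges have `e_rev = 0`.  Mass leaving dangling nodes corresponds to no
#' real interaction and is excluded from the table, but recorded in the
#' `dangling_mass` attribute so that total flux over unique arcs plus
#' dangling mass is exactly the total visitation mass, 1.
#'
#' @param g stationary visitation vector over `tm$nodes`
#' @param tm the `transition_matrix` the walk used
#' @param net the [interaction_network] the matrix was built from
#' @return data.frame with columns `source`, `target`, `directed`, `itype`,
#'   `e_fwd`, `e_rev`, `e`; attributes `dangling_mass` and
#'   `arc_flux_total` (flux over unique arcs + dangling mass)
#' @export
edge_flux <- function(g, tm, net) {
  stopifnot(inherits(tm, "transition_matrix"))
  if (length(g) != length(tm$nodes) ||
      !identical(tm$nodes, net$nodes))
    stop("g, transition matrix and network are not aligned")
  e <- net$edges
  g <- as.numeric(g)
  n <- length(tm$nodes)
  Tr <- methods::as(tm$P, "TsparseMatrix")
  # keyed lookup of stored entries: much faster than matrix subsetting
  stored_key <- (Tr@i + 1) + n * as.numeric(Tr@j)
  p_at <- function(i, j) {
    if (length(i) == 0) return(numeric())
    hit <- match(i + n * as.numeric(j - 1), stored_key)
    ifelse(is.na(hit), 0, Tr@x[hit])
  }
  i <- match(e$source, tm$nodes)
  j <- match(e$target, tm$nodes)
  e_fwd <- g[i] * p_at(i, j)
  e_rev <- ifelse(e$directed, 0, g[j] * p_at(j, i))
  out <- data.frame(source = e$source, target = e$target,
                    directed = e$directed, itype = e$itype,
                    e_fwd = e_fwd, e_rev = e_rev, e = e_fwd + e_rev,
                    stringsAsFactors = FALSE)
  dangling_mass <- sum(g[tm$dangling])
  arc_total <- sum(g[Tr@i + 1] * Tr@x) + dangling_mass
  attr(out, "dangling_mass") <- dangling_mass
  attr(out, "arc_flux_total") <- arc_total
  out
}

#' Normalized Edge Flux
#'
#' `s = log2(e / e_r)`: the data-biased flux of each interaction relative to
#' its flux under the topology-only background walk.  Values are centered at
#' 0; s > 0 means more probability mass flows through the interaction than
#' the network topology alone would produce (coherent high data values at
#' its endpoints), s < 0 means less (coherent low values).
#'
#' @param e data-biased flux values
#' @param e_r background flux values, indexed identically
#' @return numeric vector `s`; arcs with `e_r = 0` (impossible for q > 0)
#'   are `NA` with a warning
#' @export
normalized_edge_flux <- function(e, e_r) {
  stopifnot(length(e) == length(e_r))
  s <- rep(NA_real_, length(e))
  ok <- e_r > 0
  if (any(!ok))
    warning(sum(!ok), " interaction(s) with zero background flux excluded")
  s[ok] <- log2(e[ok] / e_r[ok])
  s
}

#' Full data-biased walk analysis of one condition
#'
#' The end-to-end pipeline: reverse directed TF->target edges, winsorize the
#' data at the 0.1st/99.9th percentiles, impute genes missing from the data
#' to 1, run the data-biased walk and the all-ones background walk with the
#' same restart probability, compute raw edge fluxes for both, and normalize
#' (`s = log2(e/e_r)` per interaction, combined over the two arcs of an
#' undirected edge before normalization).  Deterministic given its inputs.
#'
#' @param net an [interaction_network]
#' @param w a [data_vector]
#' @param config a [walk_config]
#' @return a `netwalk_result`: list with
#'   * `nodes`: data.frame (gene, w, g, g_r, g_rel),
#'   * `edges`: data.frame (source, target, directed, itype, e_fwd, e_rev,
#'     e, e_r_fwd, e_r_rev, e_r, s) sorted by decreasing s,
#'   * `vis`: the [run_walk()] result, `config`, `condition`.
#' @export
netwalk <- function(net, w, config = walk_config()) {
  stopifnot(inherits(net, "interaction_network"))
  if (!inherits(w, "data_vector")) w <- data_vector(w)
  if (config$reverse_tf) net <- reverse_tf_edges(net)
  if (config$winsorize) w <- winsorize(w)
  w <- impute_missing(net, w, quiet = TRUE)

  vis <- run_walk(net, w, config)
  ef <- edge_flux(vis$g, vis$tm, net)
  ef_bg <- edge_flux(vis$g_r, vis$tm_bg, net)

  edges <- ef
  edges$e_r_fwd <- ef_bg$e_fwd
  edges$e_r_rev <- ef_bg$e_rev
  edges$e_r <- ef_bg$e
  edges$s <- normalized_edge_flux(edges$e, edges$e_r)
  # deterministic ranking: by s descending, lexicographic tie-break
  ord <- order(-edges$s, edges$source, edges$target, edges$itype)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "dangling_mass") <- attr(ef, "dangling_mass")
  attr(edges, "dangling_mass_bg") <- attr(ef_bg, "dangling_mass")
  attr(edges, "arc_flux_total") <- attr(ef, "arc_flux_total")
  attr(edges, "arc_flux_total_bg") <- attr(ef_bg, "arc_flux_total")

  nodes <- data.frame(gene = vis$nodes, w = vis$w, g = vis$g, g_r = vis$g_r,
                      g_rel = vis$g_rel, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, vis = vis, config = config,
                 net = net, condition = condition_of(w)),
            class = "netwalk_result")
}

#' @export
print.netwalk_result <- function(x, ...) {
  cat("netwalk_result [", x$condition, "]: ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " interactions; s range [",
      sprintf("%.3f", min(x$edges$s)), ", ",
      sprintf("%.3f", max(x$edges$s)), "]\n", sep = "")
  invisible(x)
}

#' Write the node and edge tables of a walk analysis
#'
#' @param res a `netwalk_result`
#' @param node_path,edge_path output TSV paths (either may be `NULL`)
#' @return invisibly, the paths written
#' @export
write_netwalk_tables <- function(res, node_path = NULL, edge_path = NULL) {
  if (!is.null(node_path))
    utils::write.table(res$nodes, node_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(edge_path))
    utils::write.table(res$edges, edge_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(c(node_path, edge_path))
}
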