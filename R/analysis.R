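#' Extract a subnetwork from an edge-flux table
#'
#' Deterministic selection of interactions by normalized Edge Flux s:
#' `top_k` / `bottom_k` take the k highest / lowest scoring interactions
#' (ties at the boundary broken by lexicographic (source, target, itype)
#' order, with a message), `s_ge` / `s_le` take every interaction at or
#' above / below a score threshold.  Any s cutoff is valid: the scores form
#' a full distribution, so networks of any size can be read off it.
#'
#' @param ef edge table of a [netwalk()] result (must have an `s` column)
#' @param rule one of `"top_k"`, `"bottom_k"`, `"s_ge"`, `"s_le"`
#' @param value k (a count) for the k-rules, an s threshold otherwise
#' @return a `subnetwork`: list with `edges` (selected rows), `nodes`
#'   (induced node set) and `rule` (provenance record)
#' @export
extract_subnetwork <- function(ef, rule = c("top_k", "bottom_k", "s_ge",
                                            "s_le"), value) {
  rule <- match.arg(rule)
  stopifnot(nrow(ef) > 0, is.numeric(value), length(value) == 1)
  desc <- rule %in% c("top_k", "s_ge")
  ord <- order(if (desc) -ef$s else ef$s, ef$source, ef$target, ef$itype)
  ef_sorted <- ef[ord, , drop = FALSE]
  if (rule %in% c("top_k", "bottom_k")) {
    k <- as.integer(value)
    stopifnot(k >= 0)
    if (k > nrow(ef)) {
      warning("k = ", k, " exceeds the ", nrow(ef),
              " available interactions; returning all")
      k <- nrow(ef)
    }
    if (k > 0 && k < nrow(ef) &&
        isTRUE(all.equal(ef_sorted$s[k], ef_sorted$s[k + 1])))
      message("tie at the rank-", k,
              " boundary broken by lexicographic order")
    sel <- ef_sorted[seq_len(k), , drop = FALSE]
  } else {
    keep <- if (rule == "s_ge") ef_sorted$s >= value else ef_sorted$s <= value
    sel <- ef_sorted[keep, , drop = FALSE]
  }
  rownames(sel) <- NULL
  structure(list(edges = sel,
                 nodes = sort(unique(c(sel$source, sel$target))),
                 rule = list(rule = rule, value = value)),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("subnetwork (", x$rule$rule, " = ", x$rule$value, "): ",
      nrow(x$edges), " interactions, ", length(x$nodes), " nodes\n",
      sep = "")
  invisible(x)
}

#' Coherence summary of a subnetwork's node data values
#'
#' The boxplot statistics used to judge whether an extracted network is
#' composed of genes whose data values move together: median and quartiles
#' of the induced nodes' values plus the fraction above / below the
#' no-change ratio 1.  No judgement threshold is applied.
#'
#' @param sub a [extract_subnetwork()] result
#' @param w a [data_vector] covering the subnetwork's nodes
#' @return list with `n_nodes`, `median`, `q1`, `q3`, `frac_above_1`,
#'   `frac_below_1` (all `NA`/0 for an empty subnetwork)
#' @export
coherence_report <- function(sub, w) {
  genes <- intersect(sub$nodes, names(w))
  vals <- as.numeric(w[genes])
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0)
    return(list(n_nodes = 0L, median = NA_real_, q1 = NA_real_,
                q3 = NA_real_, frac_above_1 = NA_real_,
                frac_below_1 = NA_real_))
  qs <- quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
  list(n_nodes = length(vals), median = qs[2], q1 = qs[1], q3 = qs[3],
       frac_above_1 = mean(vals > 1), frac_below_1 = mean(vals < 1))
}

#' Stack per-condition edge-flux tables into a matrix
#'
#' @param runs named list of edge tables (or `netwalk_result`s), one per
#'   condition, all from the same network.  Names become condition labels.
#' @return an `ef_matrix`: numeric matrix of s values, rows keyed by
#'   `source|target|itype`, columns in the given condition order
#' @export
build_ef_matrix <- function(runs) {
  stopifnot(length(runs) >= 1)
  efs <- lapply(runs, function(r) {
    if (inherits(r, "netwalk_result")) r$edges else r
  })
  labels <- names(runs)
  if (is.null(labels)) labels <- paste0("condition", seq_along(runs))
  keys <- lapply(efs, function(ef) sort(edge_keys(ef)))
  for (k in seq_along(keys))
    if (!identical(keys[[k]], keys[[1]]))
      stop("edge sets differ between conditions; all runs must use ",
           "the same network")
  ref <- keys[[1]]
  mat <- vapply(efs, function(ef) {
    setNames(ef$s, edge_keys(ef))[ref]
  }, numeric(length(ref)))
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1)
  rownames(mat) <- ref
  colnames(mat) <- labels
  structure(mat, class = c("ef_matrix", "matrix"))
}

#' Ward clustering of multi-condition Edge Flux values
#'
#' Rows are the union, over conditions, of each condition's `k_select`
#' highest- and `k_select`-lowest-s interactions — the interactions whose
#' flux moves most in at least one condition.  Ward linkage (`"ward.D2"`,
#' Ward's minimum-variance method on Euclidean distances) is applied to the
#' selected raw s rows without standardization, and the dendrogram is cut
#' into `n_clusters` groups.  Unlike clustering of per-gene expression, a
#' gene may appear in several clusters through different interactions.
#'
#' @param efm an [build_ef_matrix()] matrix
#' @param k_select per-condition top/bottom count (rows selected =
#'   union over conditions)
#' @param n_clusters number of clusters to cut into
#' @return list with `hclust`, `clusters` (named integer vector over the
#'   selected edge keys), `selected` (keys) and the selected submatrix
#' @export
cluster_ef <- function(efm, k_select = 100, n_clusters = 2) {
  stopifnot(ncol(efm) >= 2)
  k <- as.integer(k_select)
  if (k > nrow(efm)) {
    warning("k_select exceeds the number of interactions; using all")
    k <- nrow(efm)
  }
  sel <- character()
  for (j in seq_len(ncol(efm))) {
    ord <- order(-efm[, j], rownames(efm))
    sel <- c(sel, rownames(efm)[ord[seq_len(k)]],
             rownames(efm)[rev(ord)[seq_len(k)]])
  }
  sel <- sort(unique(sel))
  if (length(sel) < 2) stop("need at least 2 selected interactions")
  sub <- efm[sel, , drop = FALSE]
  if (max(sub) - min(sub) < .Machine$double.eps * 100) {
    warning("all selected s values are equal; returning a single cluster")
    return(list(hclust = NULL,
                clusters = setNames(rep(1L, nrow(sub)), rownames(sub)),
                selected = rownames(sub), matrix = sub))
  }
  hc <- hclust(dist(sub), method = "ward.D2")
  cl <- cutree(hc, k = n_clusters)
  list(hclust = hc, clusters = cl, selected = rownames(sub), matrix = sub)
}

.spearman <- function(a, b) suppressWarnings(cor(a, b, method = "spearman"))

#' Data- and network-perturbation experiments
#'
#' Measures how strongly the walk output depends on the supplied data and
#' on the network connectivity by perturbing one of them and correlating
#' the perturbed relative visitation frequencies with the unperturbed run:
#'
#' * `data_deletion`: a fraction of genes have their data value reset to 1
#'   (equivalent to deleting the measurement under the missing-value rule);
#' * `node_deletion`: a fraction of nodes (and incident edges) removed;
#'   correlation computed over surviving nodes;
#' * `edge_deletion`: a fraction of edges removed;
#' * `edge_addition`: random node pairs added as undirected PPI edges, count
#'   = fraction of the current edge count;
#' * `expansion_factor`: the data are re-expanded as `f ^ log2(w)` (levels
#'   are factors f; `f = 2` is the identity) and the statistic is the
#'   fraction of shared nodes between the perturbed and unperturbed top-k
#'   interaction networks rather than a correlation.
#'
#' @param net an [interaction_network]
#' @param w a [data_vector]
#' @param config a [walk_config]
#' @param kind perturbation kind (see above)
#' @param levels perturbation levels: deleted/added fractions in `[0, 1]`,
#'   or expansion factors > 1
#' @param n_reps replicates per level (expansion_factor is deterministic;
#'   reps collapse to 1)
#' @param seed integer seed; every replicate draws from a deterministic
#'   sub-seed so the whole table is reproducible
#' @param top_k top-network size for the `expansion_factor` overlap
#' @return data.frame (kind, level, rep, statistic) where statistic is the
#'   Spearman correlation of g_rel with the unperturbed run, or the node
#'   overlap fraction for `expansion_factor`
#' @export
robustness_experiment <- function(net, w, config = walk_config(),
                                  kind = c("data_deletion", "node_deletion",
                                           "edge_deletion", "edge_addition",
                                           "expansion_factor"),
                                  levels, n_reps = 5, seed = 1,
                                  top_k = 100) {
  kind <- match.arg(kind)
  stopifnot(length(levels) >= 1)
  if (kind == "expansion_factor") {
    if (any(levels <= 1)) stop("expansion factors must be > 1")
    n_reps <- 1L
  } else if (any(levels < 0 | levels > 1)) {
    stop("deletion/addition fractions must lie in [0, 1]")
  }

  base <- netwalk(net, w, config)
  base_rel <- setNames(base$nodes$g_rel, base$nodes$gene)
  base_top <- extract_subnetwork(base$edges, "top_k", top_k)$nodes

  rows <- list()
  for (li in seq_along(levels)) {
    level <- levels[li]
    for (rep_i in seq_len(n_reps)) {
      stat <- if (kind == "expansion_factor") {
        pert <- netwalk(net, expansion_transform(w, level), config)
        top <- extract_subnetwork(pert$edges, "top_k", top_k)$nodes
        # shared-node fraction of the two top networks
        length(intersect(top, base_top)) / max(length(top), length(base_top))
      } else {
        # numeric arithmetic: keeps the derived seed inside integer range
        # without overflowing along the way
        sub_seed <- (as.numeric(seed) * 10007 + li * 101 + rep_i) %%
          2147483647
        set.seed(as.integer(sub_seed))
        if (kind == "data_deletion") {
          wp <- w
          idx <- sample(length(wp), round(level * length(wp)))
          wp[idx] <- 1
          pert <- netwalk(net, wp, config)
          prel <- setNames(pert$nodes$g_rel, pert$nodes$gene)
          .spearman(base_rel[names(prel)], prel)
        } else {
          netp <- .perturb_network(net, kind, level)
          pert <- netwalk(netp, w, config)
          prel <- setNames(pert$nodes$g_rel, pert$nodes$gene)
          common <- intersect(names(prel), names(base_rel))
          .spearman(base_rel[common], prel[common])
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        kind = kind, level = level, rep = rep_i, statistic = stat,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.perturb_network <- function(net, kind, level) {
  e <- net$edges
  if (kind == "node_deletion") {
    n_del <- round(level * length(net$nodes))
    if (n_del == 0) return(net)
    gone <- sample(net$nodes, n_del)
    keep <- !(e$source %in% gone | e$target %in% gone)
    interaction_network(e[keep, , drop = FALSE],
                        nodes = setdiff(net$nodes, gone), quiet = TRUE)
  } else if (kind == "edge_deletion") {
    n_del <- round(level * nrow(e))
    if (n_del == 0) return(net)
    gone <- sample(nrow(e), n_del)
    interaction_network(e[-gone, , drop = FALSE], nodes = net$nodes,
                        quiet = TRUE)
  } else {  # edge_addition
    n_add <- round(level * nrow(e))
    if (n_add == 0) return(net)
    src <- sample(net$nodes, n_add, replace = TRUE)
    tgt <- sample(net$nodes, n_add, replace = TRUE)
    ok <- src != tgt
    add <- data.frame(source = src[ok], target = tgt[ok], directed = FALSE,
                      itype = "PPI", stringsAsFactors = FALSE)
    interaction_network(rbind(e, add), nodes = net$nodes, quiet = TRUE)
  }
}
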