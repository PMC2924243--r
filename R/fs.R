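#' Significance of annotation overlap between two genes
#'
#' For genes i and j sharing the term set N, with `G_k` the set of genes
#' carrying term k and n the total number of genes, the overlap score is
#'
#'   s_ij = prod over k in N of  C(|G_k|, 2) / C(n, 2)
#'
#' i.e. the probability that a uniformly drawn gene pair co-carries every
#' term the pair shares.  Terms carried by many genes contribute factors
#' near 1 (uninformative); rare shared terms drive s_ij towards 0.  Smaller
#' s_ij means stronger, less-likely-by-chance functional overlap.  Genes
#' sharing no terms yield `NA` (no candidate edge).
#'
#' @param i,j gene identifiers
#' @param annotations an [annotation_table]
#' @return s_ij in (0, 1], or `NA` if the genes share no terms
#' @export
fs_significance <- function(i, j, annotations) {
  stopifnot(inherits(annotations, "annotation_table"))
  ti <- annotations$gene2terms[[i]]
  tj <- annotations$gene2terms[[j]]
  shared <- intersect(ti, tj)
  if (length(shared) == 0) return(NA_real_)
  n <- annotations$universe
  sizes <- vapply(shared, function(k) {
    sum(vapply(annotations$gene2terms, function(t) k %in% t, logical(1)))
  }, numeric(1))
  pair_total <- n * (n - 1) / 2
  prod(sizes * (sizes - 1) / 2 / pair_total)
}

# vectorized internals: term -> carrier genes index, shared via incidence
.term_carriers <- function(annotations) {
  g2t <- annotations$gene2terms
  terms <- unlist(g2t, use.names = FALSE)
  genes <- rep(names(g2t), lengths(g2t))
  split(genes, terms)
}

#' Build a functional-similarity network from annotations
#'
#' Emits an undirected FS edge for every gene pair whose annotation-overlap
#' significance [fs_significance()] falls below `threshold`, plus an FS edge
#' for every pair of genes co-annotated to the same metabolic pathway (each
#' m-gene pathway contributes the complete graph on its genes, C(m,2)
#' edges).  Signaling pathways must not be passed through `pathways`: they
#' are already represented as protein-protein/signaling interactions.  The
#' two edge sources are deduplicated against each other.
#'
#' @param annotations an [annotation_table] (may be empty)
#' @param pathways optional named list: metabolic pathway id -> character
#'   vector of member genes
#' @param threshold significance cutoff; an FS edge requires
#'   `s_ij < threshold` (default 0.001)
#' @return an [interaction_network] of undirected FS edges
#' @export
build_fs_network <- function(annotations = NULL, pathways = NULL,
                             threshold = 0.001) {
  edges <- list()
  if (!is.null(annotations) && length(annotations$gene2terms) > 0 &&
      threshold > 0) {
    carriers <- .term_carriers(annotations)
    sizes <- lengths(carriers)
    n <- annotations$universe
    pair_total <- n * (n - 1) / 2
    term_factor <- sizes * (sizes - 1) / 2 / pair_total
    # candidate pairs: only pairs sharing >= 1 term can score below 1
    cand <- new.env(parent = emptyenv())
    for (t in names(carriers)) {
      gs <- sort(carriers[[t]])
      if (length(gs) < 2) next
      pairs <- utils::combn(gs, 2)
      for (p in seq_len(ncol(pairs))) {
        key <- paste(pairs[1, p], pairs[2, p], sep = "\r")
        prev <- cand[[key]]
        cand[[key]] <- if (is.null(prev)) term_factor[[t]]
                       else prev * term_factor[[t]]
      }
    }
    keys <- ls(cand)
    if (length(keys) > 0) {
      sij <- vapply(keys, function(k) cand[[k]], numeric(1))
      hit <- keys[sij < threshold]
      if (length(hit) > 0) {
        parts <- strsplit(hit, "\r", fixed = TRUE)
        edges$go <- data.frame(
          source = vapply(parts, `[`, character(1), 1),
          target = vapply(parts, `[`, character(1), 2),
          directed = FALSE, itype = "FS", stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.null(pathways)) {
    pw_edges <- lapply(pathways, function(gs) {
      gs <- sort(unique(as.character(gs)))
      if (length(gs) < 2) return(NULL)
      pairs <- utils::combn(gs, 2)
      data.frame(source = pairs[1, ], target = pairs[2, ],
                 directed = FALSE, itype = "FS", stringsAsFactors = FALSE)
    })
    edges$pathway <- do.call(rbind, pw_edges)
  }
  all_edges <- do.call(rbind, edges)
  if (is.null(all_edges))
    all_edges <- data.frame(source = character(), target = character(),
                            directed = logical(), itype = character(),
                            stringsAsFactors = FALSE)
  interaction_network(all_edges, quiet = TRUE)
}
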