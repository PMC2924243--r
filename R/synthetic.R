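# The 12-node toy network used throughout the documentation and tests.
# G..L form a ring-shaped functional cluster; A bridges into it at G and L;
# B..F are background nodes wired as a clique and spoked to every cluster
# node.  Constraint: cluster-internal edges must be a minority (< 1/4) of
# all edges so that cluster-edge enrichment at the top of the s ranking is
# a meaningful statement.
.TOY_EDGES <- rbind(
  c("A", "G"), c("A", "L"),                                  # bridges
  cbind(c("G", "H", "I", "J", "K", "L"),
        c("H", "I", "J", "K", "L", "G")),                    # cluster ring
  t(utils::combn(c("B", "C", "D", "E", "F"), 2)),            # background K5
  as.matrix(expand.grid(c("B", "C", "D", "E", "F"),          # spokes
                        c("G", "H", "I", "J", "K", "L"),
                        stringsAsFactors = FALSE))
)

#' The 12-node toy walk example
#'
#' A hand-built illustration network of nodes A-L with data values chosen so
#' that node A (value 5) sits next to a coherent cluster G-L (value 2) while
#' the remaining nodes are unchanged (value 1).  Running [netwalk()] on it
#' shows the core behaviour: A and the G-L cluster receive the highest
#' relative visitation, and the cluster-internal interactions the highest
#' normalized Edge Flux.
#'
#' @return list with `net` (an [interaction_network], 48 undirected PPI
#'   edges) and `w` (a [data_vector]: A = 5, G..L = 2, rest = 1)
#' @export
make_toy_network <- function() {
  edges <- data.frame(source = .TOY_EDGES[, 1], target = .TOY_EDGES[, 2],
                      directed = FALSE, itype = "PPI",
                      stringsAsFactors = FALSE)
  net <- interaction_network(edges, quiet = TRUE)
  w <- setNames(rep(1, 12), LETTERS[1:12])
  w["A"] <- 5
  w[c("G", "H", "I", "J", "K", "L")] <- 2
  list(net = net, w = data_vector(w, condition = "toy"))
}

#' Gene identifiers of the cluster in the toy network
#' @return character vector G..L
#' @export
toy_cluster_nodes <- function() c("G", "H", "I", "J", "K", "L")

.gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Generate a planted-module benchmark fixture
#'
#' Builds a preferential-attachment (scale-free-ish, hub-rich) background
#' graph — the null that exercises topology-bias correction — and plants
#' two densely wired modules: a "high" module whose genes are up around
#' `high_mean` and a "low" module down around `low_mean`.  Per-gene log2
#' ratios are drawn Normal(log2 mean, `noise_sd`) inside active modules and
#' Normal(0, `noise_sd`) elsewhere, then exponentiated to positive ratios.
#' Multiple conditions with per-condition module activation patterns are
#' supported for clustering experiments.  Everything is a pure function of
#' the parameters and `seed`.
#'
#' @param n number of nodes
#' @param module_sizes integer vector of length 2: sizes of the high and
#'   low modules
#' @param high_mean,low_mean central ratio of the modules when active
#'   (defaults 4 and 0.25, i.e. +/- 2 on the log2 scale)
#' @param noise_sd standard deviation of the log2 ratios
#' @param n_conditions number of data vectors to draw
#' @param activation optional logical matrix (2 x n_conditions): is module
#'   1 / 2 active in each condition?  Default: always active.
#' @param pa_m edges per step of preferential attachment (mean degree ~
#'   2 * pa_m)
#' @param p_within wiring probability of each within-module gene pair
#' @param seed integer seed
#' @return a `planted_fixture`: list with `net`, `ws` (list of
#'   [data_vector]), `truth` (list with `high_nodes`, `low_nodes`,
#'   `high_edges`, `low_edges` — edge tables of module-internal edges),
#'   `activation` and `params`
#' @export
make_planted_fixture <- function(n = 1000, module_sizes = c(25, 25),
                                 high_mean = 4, low_mean = 0.25,
                                 noise_sd = 0.25, n_conditions = 1,
                                 activation = NULL, pa_m = 3,
                                 p_within = 0.35, seed = 42) {
  stopifnot(length(module_sizes) == 2, sum(module_sizes) < n,
            high_mean > 1, low_mean > 0, low_mean < 1, noise_sd >= 0)
  if (is.null(activation))
    activation <- matrix(TRUE, nrow = 2, ncol = n_conditions)
  stopifnot(nrow(activation) == 2, ncol(activation) == n_conditions)
  set.seed(seed)

  ids <- .gene_ids(n)
  gpa <- igraph::sample_pa(n, m = pa_m, directed = FALSE)
  el <- igraph::as_edgelist(gpa, names = FALSE)
  edges <- data.frame(source = ids[el[, 1]], target = ids[el[, 2]],
                      directed = FALSE, itype = "PPI",
                      stringsAsFactors = FALSE)

  picks <- sample(n, sum(module_sizes))
  high_nodes <- sort(ids[picks[seq_len(module_sizes[1])]])
  low_nodes <- sort(ids[picks[module_sizes[1] + seq_len(module_sizes[2])]])
  wire <- function(members) {
    pairs <- t(utils::combn(members, 2))
    keep <- runif(nrow(pairs)) < p_within
    data.frame(source = pairs[keep, 1], target = pairs[keep, 2],
               directed = FALSE, itype = "PPI", stringsAsFactors = FALSE)
  }
  net <- interaction_network(rbind(edges, wire(high_nodes),
                                   wire(low_nodes)),
                             nodes = ids, quiet = TRUE)

  module_edges <- function(members) {
    e <- net$edges
    e[e$source %in% members & e$target %in% members, , drop = FALSE]
  }
  truth <- list(high_nodes = high_nodes, low_nodes = low_nodes,
                high_edges = module_edges(high_nodes),
                low_edges = module_edges(low_nodes))

  ws <- lapply(seq_len(n_conditions), function(ci) {
    d <- rnorm(n, 0, noise_sd)
    if (activation[1, ci])
      d[match(high_nodes, ids)] <- rnorm(length(high_nodes),
                                         log2(high_mean), noise_sd)
    if (activation[2, ci])
      d[match(low_nodes, ids)] <- rnorm(length(low_nodes),
                                        log2(low_mean), noise_sd)
    data_vector(setNames(2 ^ d, ids),
                condition = sprintf("condition%02d", ci))
  })

  structure(list(net = net, ws = ws, truth = truth,
                 activation = activation,
                 params = list(n = n, module_sizes = module_sizes,
                               high_mean = high_mean, low_mean = low_mean,
                               noise_sd = noise_sd, pa_m = pa_m,
                               p_within = p_within, seed = seed)),
            class = "planted_fixture")
}

#' @export
print.planted_fixture <- function(x, ...) {
  cat("planted_fixture:", n_nodes(x$net), "nodes,", n_edges(x$net),
      "edges;", nrow(x$truth$high_edges), "high-module and",
      nrow(x$truth$low_edges), "low-module edges;",
      length(x$ws), "condition(s)\n")
  invisible(x)
}

#' Generate an annotation fixture with planted functional modules
#'
#' Genes inside a planted module share module-exclusive rare terms, so
#' their pairwise overlap is far stronger than chance; background genes
#' carry draws from a pool of common terms shared by many genes, which are
#' uninformative.  Used to exercise the functional-similarity edge rule.
#'
#' @param n_genes total genes (the universe)
#' @param n_common_terms size of the common-term pool
#' @param modules named list: module id -> character vector of member gene
#'   identifiers (default: none).  Each module receives
#'   `terms_per_module` exclusive terms carried by all members.
#' @param terms_per_module exclusive terms per module
#' @param common_per_gene common terms drawn per gene
#' @param seed integer seed
#' @return an [annotation_table] with a `modules` attribute
#' @export
make_annotation_fixture <- function(n_genes = 50, n_common_terms = 5,
                                    modules = list(),
                                    terms_per_module = 3,
                                    common_per_gene = 3, seed = 7) {
  set.seed(seed)
  ids <- .gene_ids(n_genes)
  common <- sprintf("COMMON%02d", seq_len(n_common_terms))
  g2t <- lapply(ids, function(g)
    sample(common, min(common_per_gene, n_common_terms)))
  names(g2t) <- ids
  for (m in names(modules)) {
    terms <- sprintf("%s_T%02d", m, seq_len(terms_per_module))
    for (g in modules[[m]]) {
      stopifnot(g %in% ids)
      g2t[[g]] <- c(g2t[[g]], terms)
    }
  }
  at <- annotation_table(g2t, universe = n_genes)
  attr(at, "modules") <- modules
  at
}
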