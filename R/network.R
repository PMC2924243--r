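#' @importFrom stats cor cutree dist hclust median quantile rbinom rnorm runif
#'   setNames cor.test
#' @importFrom utils read.table write.table combn
NULL

#' Recognised interaction types
#'
#' `PPI` (protein-protein interaction), `SIGNALING` (directed signaling
#' interaction), `TF_TARGET` (transcription factor to target gene) and `FS`
#' (functional similarity, i.e. indirect interaction inferred from shared
#' annotations or metabolic pathways).
#'
#' @export
INTERACTION_TYPES <- c("PPI", "SIGNALING", "TF_TARGET", "FS")

#' Construct a typed interaction network
#'
#' Builds a cleaned, deterministic network from an edge table.  Cleaning
#' drops self-loops, stores undirected edges once with lexicographically
#' ordered endpoints, and merges duplicate records of the same
#' (source, target, directedness, type); duplicate edges that differ only in
#' interaction type are kept as distinct records, because interactions are
#' scored per typed record.  Nodes are held in lexicographic order so matrix
#' indexing is reproducible across runs.
#'
#' @param edges data.frame with columns `source`, `target` (character) and
#'   optionally `directed` (logical, default `FALSE`) and `itype` (one of
#'   [INTERACTION_TYPES], default `"PPI"`).
#' @param nodes optional character vector of additional (possibly isolated)
#'   node identifiers to include.
#' @param quiet suppress messages about dropped/merged records.
#' @return An object of class `interaction_network`: a list with `nodes`
#'   (sorted character vector) and `edges` (data.frame with columns
#'   `source`, `target`, `directed`, `itype`).
#' @export
interaction_network <- function(edges = NULL, nodes = NULL, quiet = FALSE) {
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        directed = logical(), itype = character(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0 && !all(c("source", "target") %in% names(edges)))
    stop("edge table needs 'source' and 'target' columns")
  if (is.null(edges$directed)) edges$directed <- rep(FALSE, nrow(edges))
  if (is.null(edges$itype)) edges$itype <- rep("PPI", nrow(edges))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$directed <- as.logical(edges$directed)
  edges$itype <- as.character(edges$itype)
  bad <- !edges$itype %in% INTERACTION_TYPES
  if (any(bad))
    stop("unknown interaction type(s): ",
         paste(unique(edges$itype[bad]), collapse = ", "))

  loops <- edges$source == edges$target
  if (any(loops)) {
    if (!quiet) message("dropped ", sum(loops), " self-loop(s)")
    edges <- edges[!loops, , drop = FALSE]
  }
  # canonical orientation for undirected edges: (a,b) and (b,a) are the same
  flip <- !edges$directed & edges$source > edges$target
  if (any(flip)) {
    tmp <- edges$source[flip]
    edges$source[flip] <- edges$target[flip]
    edges$target[flip] <- tmp
  }
  key <- paste(edges$source, edges$target, edges$directed, edges$itype,
               sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    if (!quiet) message("merged ", sum(dup), " duplicate edge record(s)")
    edges <- edges[!dup, , drop = FALSE]
  }
  ord <- order(edges$source, edges$target, edges$itype, edges$directed)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL

  all_nodes <- sort(unique(c(edges$source, edges$target, as.character(nodes))))
  structure(list(nodes = all_nodes, edges = edges),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction_network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges) > 0) {
    tab <- table(x$edges$itype)
    cat("  types:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of edges / nodes of a network
#' @param net an `interaction_network`
#' @return integer count
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname n_edges
#' @export
n_nodes <- function(net) length(net$nodes)

#' Canonical per-edge keys
#'
#' A deterministic string key per edge record (`source|target|itype`), used
#' for aligning edge tables across runs and conditions.
#'
#' @param edges data.frame with `source`, `target`, `itype` columns (an
#'   `interaction_network$edges` table or an edge-flux table).
#' @return character vector of keys
#' @export
edge_keys <- function(edges) {
  paste(edges$source, edges$target, edges$itype, sep = "|")
}

# infer directedness from a SIF relation/type when no explicit flag exists
.default_directed <- function(itype) itype %in% c("SIGNALING", "TF_TARGET")

#' Read an interaction network from a file
#'
#' Two dialects are supported.  `"tsv"` (default) is a tab-separated table
#' with 2-4 columns: source, target, directed (0/1, optional, default 0) and
#' interaction type (optional, default PPI); a header row naming the columns
#' is recognised and skipped.  `"sif"` is the simple interaction format
#' `source<TAB>relation<TAB>target [target ...]`; the relation is used as the
#' interaction type and directedness defaults by type (TF_TARGET and
#' SIGNALING directed, PPI and FS undirected), since SIF carries no
#' directedness flag.
#'
#' @param path file path
#' @param dialect `"tsv"` or `"sif"`
#' @param quiet suppress cleaning messages
#' @return an [interaction_network]
#' @export
read_network <- function(path, dialect = c("tsv", "sif"), quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty network file: ", path)

  if (dialect == "tsv") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    start <- 1L
    f1 <- tolower(trimws(fields[[1]]))
    if (identical(f1[1:2], c("source", "target"))) start <- 2L
    if (start > length(lines)) {
      return(interaction_network(quiet = quiet))
    }
    rows <- lapply(seq(start, length(lines)), function(ln) {
      f <- trimws(fields[[ln]])
      if (length(f) < 2 || !nzchar(f[1]) || !nzchar(f[2]))
        stop("malformed network row at line ", ln, " of ", path)
      directed <- FALSE
      itype <- "PPI"
      if (length(f) >= 3 && nzchar(f[3])) {
        if (!f[3] %in% c("0", "1", "TRUE", "FALSE"))
          stop("bad directedness flag at line ", ln, " of ", path)
        directed <- f[3] %in% c("1", "TRUE")
      }
      if (length(f) >= 4 && nzchar(f[4])) itype <- f[4]
      data.frame(source = f[1], target = f[2], directed = directed,
                 itype = itype, stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, rows)
  } else {
    fields <- strsplit(lines, "[ \t]+")
    rows <- lapply(seq_along(fields), function(ln) {
      f <- fields[[ln]]
      f <- f[nzchar(f)]
      if (length(f) < 3)
        stop("malformed SIF row at line ", ln, " of ", path)
      itype <- f[2]
      data.frame(source = f[1], target = f[3:length(f)],
                 directed = .default_directed(itype), itype = itype,
                 stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, rows)
  }
  interaction_network(edges, quiet = quiet)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Write an interaction network to a file
#'
#' `"tsv"` round-trips losslessly through [read_network()].  `"sif"` writes
#' `source<TAB>itype<TAB>target` rows (directedness is implied by the
#' interaction type on re-read).  `"graphml"` writes a GraphML document with
#' per-edge `directed` attributes and an `itype` edge attribute, for network
#' viewers; GraphML is write-only here.
#'
#' @param net an [interaction_network]
#' @param path output path
#' @param dialect `"tsv"`, `"sif"` or `"graphml"`
#' @param edge_attr optional named list of extra numeric edge attribute
#'   vectors (length `n_edges(net)`), written to GraphML only.
#' @return `path`, invisibly
#' @export
write_network <- function(net, path, dialect = c("tsv", "sif", "graphml"),
                          edge_attr = NULL) {
  dialect <- match.arg(dialect)
  e <- net$edges
  if (dialect == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("source\ttarget\tdirected\titype", con)
    if (nrow(e) > 0)
      writeLines(paste(e$source, e$target, as.integer(e$directed), e$itype,
                       sep = "\t"), con)
  } else if (dialect == "sif") {
    con <- file(path, "w")
    on.exit(close(con))
    if (nrow(e) > 0)
      writeLines(paste(e$source, e$itype, e$target, sep = "\t"), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
      "  <key id=\"itype\" for=\"edge\" attr.name=\"itype\" attr.type=\"string\"/>"),
      con)
    if (!is.null(edge_attr)) {
      for (a in names(edge_attr))
        writeLines(sprintf(
          "  <key id=\"%s\" for=\"edge\" attr.name=\"%s\" attr.type=\"double\"/>",
          .xml_escape(a), .xml_escape(a)), con)
    }
    writeLines("  <graph edgedefault=\"undirected\">", con)
    writeLines(sprintf("    <node id=\"%s\"/>", .xml_escape(net$nodes)), con)
    if (nrow(e) > 0) {
      for (i in seq_len(nrow(e))) {
        extra <- ""
        if (!is.null(edge_attr)) {
          extra <- paste0(vapply(names(edge_attr), function(a) sprintf(
            "<data key=\"%s\">%.10g</data>", .xml_escape(a),
            edge_attr[[a]][i]), character(1)), collapse = "")
        }
        writeLines(sprintf(
          "    <edge source=\"%s\" target=\"%s\" directed=\"%s\"><data key=\"itype\">%s</data>%s</edge>",
          .xml_escape(e$source[i]), .xml_escape(e$target[i]),
          if (e$directed[i]) "true" else "false",
          .xml_escape(e$itype[i]), extra), con)
      }
    }
    writeLines(c("  </graph>", "</graphml>"), con)
  }
  invisible(path)
}

#' Reverse transcription factor to target edges
#'
#' Directed `TF_TARGET` edges are flipped from (tf -> target) to
#' (target -> tf) before the walk, so that the measured values of target
#' genes (e.g. mRNA changes) contribute to the visitation probability of the
#' transcription factor that regulates them, rather than the other way
#' around.  All other edges are untouched.  Apply exactly once per analysis:
#' a second application undoes the first.  [netwalk()] applies it for you.
#'
#' @param net an [interaction_network]
#' @return an [interaction_network] with flipped TF edges
#' @export
reverse_tf_edges <- function(net) {
  e <- net$edges
  flip <- e$directed & e$itype == "TF_TARGET"
  if (any(flip)) {
    tmp <- e$source[flip]
    e$source[flip] <- e$target[flip]
    e$target[flip] <- tmp
  }
  interaction_network(e, nodes = net$nodes, quiet = TRUE)
}

#' Merge several networks into one
#'
#' Union of node sets and typed edge sets, deduplicated under the standard
#' cleaning rules: records identical in endpoints, directedness and type are
#' merged; the same gene pair under different interaction types is kept once
#' per type.
#'
#' @param nets list of [interaction_network] objects
#' @return an [interaction_network]
#' @export
merge_networks <- function(nets) {
  stopifnot(length(nets) >= 1)
  edges <- do.call(rbind, lapply(nets, function(n) n$edges))
  nodes <- unique(unlist(lapply(nets, function(n) n$nodes)))
  interaction_network(edges, nodes = nodes, quiet = TRUE)
}
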