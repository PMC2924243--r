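#' Construct a per-gene data vector
#'
#' Holds one condition's worth of strictly positive ratio values (e.g.
#' treated/control expression ratios), keyed by gene identifier.  A value of
#' 1 means "no change"; missing genes are imputed to 1 when the vector is
#' aligned to a network (see [impute_missing()]).  `NA` entries are allowed
#' before imputation and are treated as missing.
#'
#' @param values named numeric vector, all values > 0 (or `NA`)
#' @param condition condition label
#' @return a `data_vector`: named numeric with a `condition` attribute
#' @export
data_vector <- function(values, condition = "condition") {
  if (is.null(names(values)) && length(values) > 0)
    stop("data values must be named by gene identifier")
  nm <- names(values)
  values <- as.numeric(values)
  if (!is.null(nm)) names(values) <- make.unique(nm)
  if (any(!is.na(values) & values <= 0))
    stop("data values must be strictly positive")
  structure(values, condition = condition, class = "data_vector")
}

#' @export
print.data_vector <- function(x, ...) {
  cat("data_vector [", attr(x, "condition"), "]: ", length(x), " genes\n",
      sep = "")
  invisible(x)
}

#' Condition label of a data vector
#' @param w a [data_vector]
#' @return character label
#' @export
condition_of <- function(w) attr(w, "condition") %||% "condition"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a genes-by-conditions data table
#'
#' First column: gene identifiers; each remaining column: one condition of
#' positive ratio values.  Tab- or comma-separated (chosen by file
#' extension, `.csv` meaning comma).  In strict mode (default) any
#' non-positive or non-numeric value is an error naming the offending gene
#' and condition, because the walk is only defined for positive values; with
#' `permissive = TRUE` such entries become missing (`NA`) and are later
#' imputed to 1 by [impute_missing()].
#'
#' @param path file path
#' @param permissive treat bad values as missing instead of erroring
#' @return list of [data_vector], one per condition column
#' @export
read_data_table <- function(path, permissive = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(tab) < 2) stop("data table needs a gene column plus >= 1 condition")
  genes <- trimws(tab[[1]])
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in data table")
  conds <- names(tab)[-1]
  lapply(seq_along(conds), function(j) {
    raw <- trimws(tab[[j + 1]])
    vals <- suppressWarnings(as.numeric(raw))
    missing <- !nzchar(raw) | toupper(raw) %in% c("NA", "NAN")
    bad <- (!missing & is.na(vals)) | (!is.na(vals) & vals <= 0)
    if (any(bad)) {
      if (!permissive)
        stop("non-positive or non-numeric value for gene '",
             genes[which(bad)[1]], "' in condition '", conds[j],
             "' (input values must be positive ratios)")
      vals[bad] <- NA_real_
    }
    vals[missing] <- NA_real_
    data_vector(setNames(vals, genes), condition = conds[j])
  })
}

#' Write a list of data vectors as a table
#'
#' @param ws list of [data_vector] sharing a gene universe
#' @param path output path (TSV)
#' @return `path`, invisibly
#' @export
write_data_table <- function(ws, path) {
  genes <- sort(unique(unlist(lapply(ws, names))))
  mat <- vapply(ws, function(w) as.numeric(w[genes]), numeric(length(genes)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(genes))
  colnames(mat) <- vapply(ws, condition_of, character(1))
  df <- data.frame(gene = genes, mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Winsorize a data vector at the 0.1st / 99.9th percentiles
#'
#' Values above the 99.9th percentile are set to that percentile, and values
#' below the 0.1st percentile to that percentile, so that extreme outliers
#' cannot dominate the transition probabilities.  Percentiles use linear
#' interpolation between order statistics (`quantile(type = 7)`) over the
#' supplied, non-missing values only — run before imputation so the imputed
#' 1s do not distort the tails.
#'
#' @param w a [data_vector]
#' @param lower,upper tail probabilities (defaults 0.001 and 0.999)
#' @return a winsorized [data_vector]
#' @export
winsorize <- function(w, lower = 0.001, upper = 0.999) {
  obs <- !is.na(w)
  if (sum(obs) < 2) {
    warning("fewer than 2 observed values; winsorization skipped")
    return(w)
  }
  ks <- quantile(as.numeric(w)[obs], probs = c(lower, upper), names = FALSE,
                 type = 7)
  out <- as.numeric(w)
  out[obs & out < ks[1]] <- ks[1]
  out[obs & out > ks[2]] <- ks[2]
  data_vector(setNames(out, names(w)), condition = condition_of(w))
}

#' Align a data vector to a network, imputing missing genes to 1
#'
#' Every network gene absent from (or `NA` in) the vector gets the value 1,
#' the "no change" ratio; genes in the vector that are not in the network
#' are dropped with a message.  The result is indexed exactly by
#' `net$nodes`.
#'
#' @param net an [interaction_network]
#' @param w a [data_vector]
#' @param quiet suppress the dropped-gene message
#' @return a [data_vector] over `net$nodes`, all values > 0
#' @export
impute_missing <- function(net, w, quiet = FALSE) {
  extra <- setdiff(names(w), net$nodes)
  if (length(extra) > 0 && !quiet)
    message("dropped ", length(extra), " gene(s) absent from the network")
  out <- setNames(rep(1, length(net$nodes)), net$nodes)
  keep <- intersect(names(w), net$nodes)
  vals <- as.numeric(w[keep])
  vals[is.na(vals)] <- 1
  out[keep] <- vals
  data_vector(out, condition = condition_of(w))
}

#' Expansion-factor transform of ratio values
#'
#' Maps each ratio `w_i` to `f ^ log2(w_i)`: re-expands the log2 ratios with
#' base `f` instead of 2.  `f = 2` is the identity; `f` between 1 and 2
#' compresses the data range, `f > 2` stretches it.  Used to probe how
#' robust the walk output is to the dynamic range of the input data.
#'
#' @param w a [data_vector]
#' @param f expansion factor, > 1
#' @return transformed [data_vector]
#' @export
expansion_transform <- function(w, f) {
  stopifnot(is.numeric(f), length(f) == 1, f > 1)
  out <- f ^ log2(as.numeric(w))
  data_vector(setNames(out, names(w)),
              condition = paste0(condition_of(w), "_f", f))
}

#' Construct an annotation table
#'
#' Flat gene-to-term annotations (GO-style), used to build
#' functional-similarity edges.  `universe` is the total number of genes n
#' against which annotation overlap is judged; it defaults to the number of
#' annotated genes but may be set larger when the annotation covers only
#' part of the genome.
#'
#' @param gene2terms named list: gene identifier -> character vector of term
#'   identifiers (deduplicated internally)
#' @param universe total gene count n (default: number of annotated genes)
#' @return an `annotation_table`
#' @export
annotation_table <- function(gene2terms, universe = NULL) {
  stopifnot(is.list(gene2terms))
  gene2terms <- lapply(gene2terms, function(t) sort(unique(as.character(t))))
  if (length(gene2terms) > 0)
    gene2terms <- gene2terms[order(names(gene2terms))]
  n <- if (is.null(universe)) length(gene2terms) else as.integer(universe)
  if (n < length(gene2terms))
    stop("universe size smaller than the number of annotated genes")
  structure(list(gene2terms = gene2terms, universe = n),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("annotation_table:", length(x$gene2terms), "annotated genes,",
      length(unique(unlist(x$gene2terms))), "terms, universe n =",
      x$universe, "\n")
  invisible(x)
}

#' Read a two-column gene-term annotation file
#'
#' @param path TSV with columns gene, term (header optional)
#' @param universe optional universe size n
#' @return an [annotation_table]
#' @export
read_annotations <- function(path, universe = NULL) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (ncol(tab) < 2) stop("annotation file needs gene and term columns")
  if (identical(tolower(trimws(tab[1, 1])), "gene"))
    tab <- tab[-1, , drop = FALSE]
  gene2terms <- split(as.character(tab[[2]]), as.character(tab[[1]]))
  annotation_table(gene2terms, universe = universe)
}
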