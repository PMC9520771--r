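#' Construct a cohort of expression profiles with cancer-type labels
#'
#' A cohort bundles a genes x samples expression matrix (nonnegative values
#' on the scale the upstream quantification produced, e.g. TPM or array
#' intensity -- the package never renormalizes) with a sample-to-cancer
#' label map. Every sample must carry exactly one label; gene symbols are
#' opaque, case-sensitive identifiers.
#'
#' @param expression numeric matrix (or coercible data.frame) with gene
#'   symbols as row names and sample identifiers as column names; values
#'   must be finite and >= 0, with no missing entries.
#' @param labels named character vector mapping sample identifier to
#'   cancer-type code; names must cover the expression columns exactly.
#' @param name cohort identifier string.
#' @return An object of class `dcsp_cohort`: a list with elements
#'   `expression`, `labels` (reordered to match columns) and `name`.
#' @examples
#' expr <- matrix(rexp(12), 3, 4,
#'                dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' co <- cohort(expr, setNames(rep(c("AML", "BRCA"), each = 2),
#'                             colnames(expr)))
#' @export
cohort <- function(expression, labels, name = "cohort") {
  if (is.data.frame(expression)) expression <- as.matrix(expression)
  if (!is.matrix(expression) || !is.numeric(expression)) {
    stop("`expression` must be a numeric matrix")
  }
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    stop("`expression` must have gene row names and sample column names")
  }
  if (anyDuplicated(rownames(expression))) {
    stop("duplicate gene symbols in expression matrix")
  }
  if (anyDuplicated(colnames(expression))) {
    stop("duplicate sample identifiers in expression matrix")
  }
  if (anyNA(expression) || any(!is.finite(expression))) {
    stop("expression values must be finite (no missing values allowed)")
  }
  if (any(expression < 0)) stop("expression values must be >= 0")
  labels <- unlist(labels)
  if (is.null(names(labels))) stop("`labels` must be named by sample")
  samples <- colnames(expression)
  if (!setequal(names(labels), samples) || length(labels) != length(samples)) {
    stop("`labels` must map every expression sample exactly once")
  }
  lab <- structure(as.character(labels[samples]), names = samples)
  if (anyNA(lab) || any(!nzchar(lab))) stop("missing cancer label for a sample")
  structure(
    list(expression = expression, labels = lab,
         name = as.character(name)[1]),
    class = "dcsp_cohort"
  )
}

#' @export
print.dcsp_cohort <- function(x, ...) {
  cat(sprintf(
    "<dcsp_cohort '%s'> %d genes x %d samples, %d cancer types\n",
    x$name, nrow(x$expression), ncol(x$expression),
    length(unique(x$labels))
  ))
  invisible(x)
}

#' Number of samples per cancer type in a cohort
#'
#' @param x a [cohort()] object.
#' @return Named integer vector of per-cancer sample counts.
#' @export
cancer_sizes <- function(x) {
  stopifnot(inherits(x, "dcsp_cohort"))
  tab <- table(x$labels)
  structure(as.integer(tab), names = names(tab))
}

#' Construct a pathway database
#'
#' @param sets named list mapping pathway name to a character vector of
#'   gene symbols; sets must be nonempty and names unique.
#' @return A named list of unique gene-symbol vectors, class `pathway_db`.
#' @export
pathway_db <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("`sets` must be a named list of gene vectors")
  }
  if (anyDuplicated(names(sets))) stop("duplicate pathway names")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) stop("empty pathway gene set")
  structure(sets, class = c("pathway_db", "list"))
}

#' Construct a drug-to-target-gene map
#'
#' @param targets named list mapping drug name to a nonempty character
#'   vector of target gene symbols.
#' @return Named list of target-gene vectors, class `drug_target_map`.
#' @export
drug_target_map <- function(targets) {
  if (!is.list(targets) || is.null(names(targets))) {
    stop("`targets` must be a named list")
  }
  if (anyDuplicated(names(targets))) stop("duplicate drug names")
  targets <- lapply(targets, function(g) unique(as.character(g)))
  if (any(lengths(targets) == 0L)) stop("drug with empty target set")
  structure(targets, class = c("drug_target_map", "list"))
}

#' Construct a per-cancer driver gene set
#'
#' Driver genes are the recurrent mutations and fusion partners retained by
#' the frequency filters; they anchor the connectivity weights.
#'
#' @param drivers named list mapping cancer-type code to a character vector
#'   of driver gene symbols (may be empty for a cancer).
#' @param cancers optional character vector of valid cancer codes (e.g. the
#'   label domain of a cohort); if supplied, every name must belong to it.
#' @return Named list of gene vectors, class `driver_set`.
#' @export
driver_set <- function(drivers, cancers = NULL) {
  if (!is.list(drivers) || is.null(names(drivers))) {
    stop("`drivers` must be a named list")
  }
  if (anyDuplicated(names(drivers))) stop("duplicate cancer codes")
  drivers <- lapply(drivers, function(g) {
    g <- unique(as.character(g))
    if (any(!nzchar(g))) stop("empty gene symbol in driver set")
    g
  })
  if (!is.null(cancers)) {
    bad <- setdiff(names(drivers), cancers)
    if (length(bad)) {
      stop("driver set names unknown cancer code(s): ",
           paste(bad, collapse = ", "))
    }
  }
  structure(drivers, class = c("driver_set", "list"))
}

#' Build a directed regulatory network from an edge list
#'
#' Self-loops and duplicate pairs are removed. The network is used only for
#' reachability when splitting pathway genes into upstream/downstream sets.
#'
#' @param edges two-column matrix or data.frame of (regulator, regulated)
#'   gene symbols; extra columns are ignored.
#' @return A directed, simplified `igraph` graph.
#' @export
directed_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop("`edges` needs at least two columns")
  df <- data.frame(from = as.character(edges[[1]]),
                   to = as.character(edges[[2]]),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df, directed = TRUE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Build an undirected functional gene network from an edge list
#'
#' The functional network carries the link counts of the network enrichment
#' analysis. Self-loops and duplicate (unordered) pairs are removed.
#'
#' @param edges two-column matrix or data.frame of gene symbols; an
#'   optional third (weight) column is ignored.
#' @return An undirected, simplified `igraph` graph.
#' @export
functional_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop("`edges` needs at least two columns")
  df <- data.frame(a = as.character(edges[[1]]),
                   b = as.character(edges[[2]]),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Construct a drug-response table
#'
#' @param records data.frame with columns `sample`, `drug`, `auc`
#'   (area under the dose-survival curve; smaller = stronger response).
#' @param unique_pairs require at most one record per (sample, drug)?
#'   Raw assay exports may violate this; see [dedupe_monotherapy()].
#' @return The validated data.frame, class `drug_response_table`.
#' @export
drug_response_table <- function(records, unique_pairs = TRUE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need_cols(records, c("sample", "drug", "auc"), "drug-response table")
  if (anyNA(records$auc) || any(!is.finite(records$auc))) {
    stop("AUC values must be finite")
  }
  if (any(records$auc < 0)) stop("AUC values must be >= 0")
  if (unique_pairs &&
      anyDuplicated(records[, c("sample", "drug")])) {
    stop("repeated (sample, drug) records; run dedupe_monotherapy() first")
  }
  class(records) <- c("drug_response_table", "data.frame")
  records
}
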