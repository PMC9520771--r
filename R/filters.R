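# Dataset-level filtering rules applied before PAS computation: removal of
# unexpressed genes, frequency filters for candidate driver mutations and
# fusions, and removal of replicated monotherapy profiles.

#' Drop genes that are unexpressed in most samples
#'
#' A gene is retained iff the proportion of samples in which its expression
#' is `<= threshold` is itself `<= fraction`. The defaults drop genes with
#' TPM at or below 0.01 in more than 90% of samples.
#'
#' @param x a [cohort()] object.
#' @param threshold expression value at or below which a sample counts as
#'   "unexpressed" (same scale as the matrix; default 1e-2).
#' @param fraction maximum tolerated proportion of unexpressed samples,
#'   in (0, 1] (default 0.90).
#' @return The filtered cohort. Errors if no gene survives.
#' @export
filter_unexpressed_genes <- function(x, threshold = 1e-2, fraction = 0.90) {
  stopifnot(inherits(x, "dcsp_cohort"),
            is.numeric(threshold), threshold >= 0,
            is.numeric(fraction), fraction > 0, fraction <= 1)
  prop_off <- rowMeans(x$expression <= threshold)
  keep <- prop_off <= fraction
  if (!any(keep)) stop("all genes removed by the unexpressed-gene filter")
  dcsp_log(sum(!keep), " unexpressed gene(s) removed")
  cohort(x$expression[keep, , drop = FALSE], x$labels, name = x$name)
}

#' Keep recurrently mutated genes as candidate drivers
#'
#' A gene passes iff it is mutated in at least `min_fraction` of the total
#' samples across all cancers (boundary inclusive). Passing genes become
#' drivers of every cancer in which at least one mutated sample lies.
#'
#' @param occurrences data.frame of mutation events with columns `gene`
#'   and `sample` (one row per event; repeated events in a sample count
#'   once).
#' @param x the [cohort()] whose samples define the denominator; rows
#'   naming samples outside the cohort are an error.
#' @param min_fraction minimum mutated-sample fraction in (0, 1);
#'   default 0.02 (use 0.01 for large patient cohorts).
#' @return A [driver_set()] keyed by cancer code (cancers without passing
#'   drivers are present with an empty set).
#' @export
filter_driver_mutations <- function(occurrences, x, min_fraction = 0.02) {
  stopifnot(inherits(x, "dcsp_cohort"),
            is.numeric(min_fraction), min_fraction > 0, min_fraction < 1)
  occurrences <- as.data.frame(occurrences, stringsAsFactors = FALSE)
  need_cols(occurrences, c("gene", "sample"), "mutation occurrence table")
  unknown <- setdiff(unique(occurrences$sample), names(x$labels))
  if (length(unknown)) {
    stop("mutation table names sample(s) outside the cohort: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  occ <- unique(occurrences[, c("gene", "sample")])
  n_total <- length(x$labels)
  counts <- table(occ$gene)
  kept_genes <- names(counts)[as.integer(counts) / n_total >= min_fraction]
  occ <- occ[occ$gene %in% kept_genes, , drop = FALSE]
  occ$cancer <- x$labels[occ$sample]
  out <- lapply(split(occ$gene, factor(occ$cancer, levels = unique(x$labels))),
                unique)
  driver_set(out, cancers = unique(x$labels))
}

#' Keep recurrent (whitelisted) fusions as candidate drivers
#'
#' A fusion passes iff it occurs in at least `min_count` distinct samples
#' and, when a whitelist is supplied, its identifier is on the whitelist
#' (standing in for intersection with a curated fusion database). Partner
#' genes of passing fusions become drivers of every cancer in which the
#' fusion occurs.
#'
#' @param fusions data.frame with columns `fusion` (identifier), `genes`
#'   (comma-separated partner gene symbols) and `sample`.
#' @param x the [cohort()] defining the sample universe.
#' @param min_count minimum number of distinct samples (default 2).
#' @param whitelist optional character vector of admissible fusion
#'   identifiers; `NULL` or empty means no whitelist restriction.
#' @return A [driver_set()] keyed by cancer code.
#' @export
filter_driver_fusions <- function(fusions, x, min_count = 2,
                                  whitelist = NULL) {
  stopifnot(inherits(x, "dcsp_cohort"), min_count >= 1)
  fusions <- as.data.frame(fusions, stringsAsFactors = FALSE)
  need_cols(fusions, c("fusion", "genes", "sample"), "fusion table")
  unknown <- setdiff(unique(fusions$sample), names(x$labels))
  if (length(unknown)) {
    stop("fusion table names sample(s) outside the cohort: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  ev <- unique(fusions[, c("fusion", "genes", "sample")])
  occ <- tapply(ev$sample, ev$fusion, function(s) length(unique(s)))
  kept <- names(occ)[occ >= min_count]
  if (!is.null(whitelist) && length(whitelist)) {
    kept <- intersect(kept, whitelist)
  }
  ev <- ev[ev$fusion %in% kept, , drop = FALSE]
  ev$cancer <- x$labels[ev$sample]
  split_genes <- function(g) unique(trimws(unlist(strsplit(g, ","))))
  out <- lapply(split(seq_len(nrow(ev)),
                      factor(ev$cancer, levels = unique(x$labels))),
                function(i) {
                  g <- split_genes(ev$genes[i])
                  g[nzchar(g)]
                })
  driver_set(out, cancers = unique(x$labels))
}

#' Merge driver sets (e.g. mutation- and fusion-derived)
#'
#' @param ... [driver_set()] objects.
#' @return A [driver_set()] with the per-cancer union.
#' @export
merge_driver_sets <- function(...) {
  sets <- list(...)
  cancers <- unique(unlist(lapply(sets, names)))
  out <- lapply(cancers, function(cz) {
    unique(unlist(lapply(sets, function(s) s[[cz]])))
  })
  names(out) <- cancers
  driver_set(out)
}

#' Remove replicated monotherapy profiles
#'
#' (sample, drug) pairs measured exactly once are retained; pairs with more
#' than one record are dropped entirely, matching the removal of
#' replicated profiles rather than averaging them.
#'
#' @param raw data.frame with columns `sample`, `drug`, `auc` (duplicates
#'   allowed).
#' @return A [drug_response_table()] with unique (sample, drug) pairs.
#' @export
dedupe_monotherapy <- function(raw) {
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  need_cols(raw, c("sample", "drug", "auc"), "raw drug-response table")
  key <- paste(raw$sample, raw$drug, sep = "\r")
  n_per <- table(key)
  keep <- key %in% names(n_per)[n_per == 1L]
  dcsp_log(sum(!keep), " replicated profile record(s) removed")
  drug_response_table(raw[keep, , drop = FALSE], unique_pairs = TRUE)
}
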