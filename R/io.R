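# Readers and writers for the standard text formats the pipeline consumes:
# GMT gene sets plus tab-separated tables (UTF-8, header row, no missing
# values in expression). All readers take explicit local paths.

#' Read a GMT gene-set file
#'
#' MSigDB dialect: one pathway per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description field is
#' discarded and duplicate genes within a line are deduplicated.
#'
#' @param path path to a GMT file.
#' @return A [pathway_db()] object (empty file gives an empty one).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), class = c("pathway_db", "list")))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop("malformed GMT line ", bad[1], " (fewer than 3 tab-separated fields)")
  }
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate pathway name in GMT: ", nm[duplicated(nm)][1])
  }
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  names(sets) <- nm
  pathway_db(sets)
}

#' Write a pathway database to GMT
#'
#' @param db a [pathway_db()] object.
#' @param path output path; the description field is written as `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db), function(nm) {
    paste(c(nm, "na", db[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

read_tsv_df <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

write_tsv_df <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' First column = gene symbol, remaining columns = samples.
#'
#' @param path path to a TSV file.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv_df(path, "expression")
  if (ncol(df) < 2) stop("expression TSV needs a gene column plus samples")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing values in expression TSV are forbidden")
  rownames(m) <- genes
  m
}

#' Write an expression matrix to TSV
#' @param expression genes x samples numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expression, path) {
  df <- data.frame(gene = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_df(df, path)
}

#' Read sample-to-cancer labels from TSV (columns `sample`, `cancer`)
#' @param path path to a TSV file.
#' @return Named character vector sample -> cancer code.
#' @export
read_labels_tsv <- function(path) {
  df <- need_cols(read_tsv_df(path, "labels"), c("sample", "cancer"), "labels TSV")
  structure(as.character(df$cancer), names = as.character(df$sample))
}

#' Write sample labels to TSV
#' @param labels named character vector sample -> cancer.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(labels, path) {
  write_tsv_df(data.frame(sample = names(labels), cancer = unname(labels)),
               path)
}

#' Read a cohort from expression and label TSVs
#' @param expression_path,labels_path input TSV paths.
#' @param name cohort identifier.
#' @return A [cohort()] object.
#' @export
read_cohort <- function(expression_path, labels_path, name = "cohort") {
  cohort(read_expression_tsv(expression_path),
         read_labels_tsv(labels_path), name = name)
}

#' Write a cohort to expression and label TSVs
#' @param x a [cohort()] object.
#' @param expression_path,labels_path output TSV paths.
#' @return `invisible(NULL)`.
#' @export
write_cohort <- function(x, expression_path, labels_path) {
  stopifnot(inherits(x, "dcsp_cohort"))
  write_expression_tsv(x$expression, expression_path)
  write_labels_tsv(x$labels, labels_path)
  invisible(NULL)
}

#' Read a drug-to-target map from TSV (columns `drug`, `target`)
#' @param path path to a TSV file, one row per drug-target pair.
#' @return A [drug_target_map()] object.
#' @export
read_drug_targets_tsv <- function(path) {
  df <- need_cols(read_tsv_df(path, "drug targets"), c("drug", "target"),
                  "drug-target TSV")
  drug_target_map(split(as.character(df$target), as.character(df$drug)))
}

#' Write a drug-to-target map to TSV
#' @param targets a [drug_target_map()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_drug_targets_tsv <- function(targets, path) {
  df <- data.frame(
    drug = rep(names(targets), lengths(targets)),
    target = unlist(targets, use.names = FALSE)
  )
  write_tsv_df(df, path)
}

#' Read per-cancer driver calls from TSV (columns `cancer`, `gene`)
#' @param path path to a TSV file, one row per cancer-driver pair.
#' @param cancers optional valid cancer codes (see [driver_set()]).
#' @return A [driver_set()] object.
#' @export
read_drivers_tsv <- function(path, cancers = NULL) {
  df <- need_cols(read_tsv_df(path, "drivers"), c("cancer", "gene"),
                  "driver TSV")
  driver_set(split(as.character(df$gene), as.character(df$cancer)), cancers)
}

#' Write a driver set to TSV
#' @param drivers a [driver_set()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_drivers_tsv <- function(drivers, path) {
  df <- data.frame(
    cancer = rep(names(drivers), lengths(drivers)),
    gene = unlist(drivers, use.names = FALSE)
  )
  write_tsv_df(df, path)
}

#' Read a network edge list from TSV
#'
#' The first two columns are the gene endpoints; any further columns
#' (e.g. a confidence weight) are ignored.
#'
#' @param path path to a TSV file.
#' @param directed build a directed regulatory network (`TRUE`) or an
#'   undirected functional network (`FALSE`).
#' @return An `igraph` graph (see [directed_network()],
#'   [functional_network()]).
#' @export
read_network_tsv <- function(path, directed = FALSE) {
  df <- read_tsv_df(path, "network")
  if (ncol(df) < 2) stop("network TSV needs two endpoint columns")
  if (directed) directed_network(df[, 1:2]) else functional_network(df[, 1:2])
}

#' Write a network edge list to TSV
#' @param g an `igraph` graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  df <- data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
  write_tsv_df(df, path)
}

#' Read a drug-response table from TSV (columns `sample`, `drug`, `auc`)
#' @param path path to a TSV file.
#' @param unique_pairs passed to [drug_response_table()]; set `FALSE` for
#'   raw exports that still contain replicated profiles.
#' @return A [drug_response_table()].
#' @export
read_response_tsv <- function(path, unique_pairs = TRUE) {
  df <- need_cols(read_tsv_df(path, "drug response"),
                  c("sample", "drug", "auc"), "drug-response TSV")
  df$auc <- as.numeric(df$auc)
  drug_response_table(df, unique_pairs = unique_pairs)
}

#' Write a drug-response table to TSV
#' @param x a [drug_response_table()] (or plain data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_response_tsv <- function(x, path) {
  write_tsv_df(as.data.frame(x)[, c("sample", "drug", "auc")], path)
}
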