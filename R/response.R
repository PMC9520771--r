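# Validation statistics relating PAS to drug response: rank-based normal
# scores, Pearson correlation on the transformed scales, rediscovery-rate
# curves, and a label-permutation specificity test.

#' Rank-based inverse normal (normal score) transformation
#'
#' Maps values to `qnorm(r_i / (n + 1))` with average ranks for ties
#' (van der Waerden scores). Order-preserving and invariant to any
#' strictly increasing transformation of the input; a constant vector maps
#' to all zeros (every value at the mid-rank).
#'
#' @param x numeric vector with at least 2 finite values.
#' @return Numeric vector of normal scores.
#' @export
normal_score_transform <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2 || any(!is.finite(x))) {
    stop("need >= 2 finite values")
  }
  stats::qnorm(rank(x, ties.method = "average") / (length(x) + 1))
}

# one-sided p for a Pearson correlation via the t transform
cor_p_one_sided <- function(r, n, lower.tail) {
  if (n < 3 || is.na(r)) return(NA_real_)
  r <- max(min(r, 1), -1)
  if (abs(r) == 1) return(if ((r < 0) == lower.tail) 0 else 1)
  t <- r * sqrt((n - 2) / (1 - r^2))
  stats::pt(t, df = n - 2, lower.tail = lower.tail)
}

#' Correlation between PAS and drug-response AUC
#'
#' For a single (drug, pathway, cancer) set of PAS records: restrict to
#' samples with positive activation (signed `PAS > 0` for the upstream
#' direction, `-PAS > 0` for the downstream variant) when
#' `positive_only = TRUE`, apply the normal score transformation to PAS
#' and AUC independently, and compute the Pearson correlation with a
#' two-sided p-value from the t transform with `n - 2` degrees of
#' freedom. A negative correlation means higher activation goes with
#' stronger drug response (smaller AUC).
#'
#' @param pas_records data.frame of PAS records for one drug and pathway
#'   (columns `sample`, `drug`, `pathway`, `pas`; typically one cancer).
#' @param response a [drug_response_table()] (or data.frame with columns
#'   `sample`, `drug`, `auc`).
#' @param direction `"upstream"` (default; activation = `PAS`) or
#'   `"downstream"` (activation = `-PAS`).
#' @param positive_only restrict to positively activated samples
#'   (default `TRUE`).
#' @return One-row data.frame: `drug`, `pathway`, `cancer`, `direction`,
#'   `n`, `r`, `p`, `ok` (`FALSE` with `NA` statistics when fewer than 3
#'   usable samples remain).
#' @export
pas_response_correlation <- function(pas_records, response,
                                     direction = c("upstream", "downstream"),
                                     positive_only = TRUE) {
  direction <- match.arg(direction)
  pas_records <- as.data.frame(pas_records)
  need_cols(pas_records, c("sample", "drug", "pathway", "pas"), "PAS records")
  response <- as.data.frame(response)
  need_cols(response, c("sample", "drug", "auc"), "response table")
  drug <- unique(pas_records$drug)
  pathway <- unique(pas_records$pathway)
  if (length(drug) != 1 || length(pathway) != 1) {
    stop("PAS records must cover exactly one (drug, pathway) pair")
  }
  cancer <- if ("cancer" %in% names(pas_records)) {
    paste(unique(pas_records$cancer), collapse = "+")
  } else {
    NA_character_
  }
  resp <- response[response$drug == drug, c("sample", "auc"), drop = FALSE]
  merged <- merge(pas_records[, c("sample", "pas")], resp, by = "sample")
  act <- if (direction == "upstream") merged$pas else -merged$pas
  if (positive_only) {
    merged <- merged[act > 0, , drop = FALSE]
    act <- act[act > 0]
  }
  empty <- data.frame(drug = drug, pathway = pathway, cancer = cancer,
                      direction = direction, n = nrow(merged),
                      r = NA_real_, p = NA_real_, ok = FALSE,
                      stringsAsFactors = FALSE)
  if (nrow(merged) < 3) {
    dcsp_log("correlation not computable: fewer than 3 usable samples")
    return(empty)
  }
  ps <- normal_score_transform(act)
  as_ <- normal_score_transform(merged$auc)
  if (stats::sd(ps) == 0 || stats::sd(as_) == 0) return(empty)
  r <- stats::cor(ps, as_)
  n <- length(ps)
  p <- if (abs(r) >= 1) {
    0
  } else {
    2 * stats::pt(abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2,
                  lower.tail = FALSE)
  }
  data.frame(drug = drug, pathway = pathway, cancer = cancer,
             direction = direction, n = n, r = r, p = p, ok = TRUE,
             stringsAsFactors = FALSE)
}

#' Rediscovery-rate curve across top fractions of ranked discoveries
#'
#' Discovery-set DCSPs are ranked by their discovery correlation (most
#' negative first for `sign = "negative"`, most positive first for
#' `"positive"`). For each fraction `f`, `RDR(f)` is the proportion of the
#' top `ceiling(f * m)` matched DCSPs whose validation correlation is
#' significant at `alpha` in a one-sided test in the discovery direction.
#' Under a null validation cohort the curve tracks `alpha` (the "target
#' line"); genuine coupling lifts the top fractions above it.
#'
#' @param discovery data.frame with columns `drug`, `pathway`, `r`
#'   (discovery correlations).
#' @param validation data.frame with columns `drug`, `pathway` and either
#'   `p_one` (precomputed one-sided validation p-values) or `r` and `n`
#'   from which they are derived.
#' @param alpha significance level (default 0.05).
#' @param sign `"negative"` (default) or `"positive"`: which discovery
#'   correlations form the ranked subset.
#' @param fractions top fractions to evaluate.
#' @return data.frame with `fraction`, `n_top`, `rdr`; `alpha` and `sign`
#'   attached as attributes.
#' @export
rdr_curve <- function(discovery, validation, alpha = 0.05,
                      sign = c("negative", "positive"),
                      fractions = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 1)) {
  sign <- match.arg(sign)
  stopifnot(alpha > 0, alpha < 1, all(fractions > 0), all(fractions <= 1))
  discovery <- as.data.frame(discovery)
  validation <- as.data.frame(validation)
  need_cols(discovery, c("drug", "pathway", "r"), "discovery records")
  need_cols(validation, c("drug", "pathway"), "validation records")
  if (!"p_one" %in% names(validation)) {
    need_cols(validation, c("r", "n"), "validation records")
    validation$p_one <- mapply(cor_p_one_sided, validation$r, validation$n,
                               MoreArgs = list(lower.tail = sign == "negative"))
  }
  m <- merge(discovery[, c("drug", "pathway", "r")],
             validation[, c("drug", "pathway", "p_one")],
             by = c("drug", "pathway"))
  m <- if (sign == "negative") {
    m[!is.na(m$r) & m$r < 0, , drop = FALSE]
  } else {
    m[!is.na(m$r) & m$r > 0, , drop = FALSE]
  }
  if (!nrow(m)) stop("no matched discovery records with the requested sign")
  ord <- order(m$r, decreasing = (sign == "positive"))
  m <- m[ord, , drop = FALSE]
  n_all <- nrow(m)
  fractions <- sort(fractions)
  n_top <- pmin(ceiling(fractions * n_all), n_all)
  rdr <- vapply(n_top, function(k) {
    mean(m$p_one[seq_len(k)] < alpha, na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(fraction = fractions, n_top = as.integer(n_top),
                    rdr = rdr)
  attr(out, "alpha") <- alpha
  attr(out, "sign") <- sign
  class(out) <- c("rdr_curve", "data.frame")
  out
}

pooled_t_stat <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0) return(0)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Permutation test for the specificity of a DCSP's activation
#'
#' Compares the PAS values of the focal (drug, pathway) group with one of
#' three comparison groups -- same pathway/other drugs, same drug/other
#' pathways, or other drugs/other pathways -- using the pooled-variance
#' two-sample t statistic. The null distribution is built by randomly
#' permuting the pooled record labels `n_perm` times; the one-sided
#' empirical p-value (focal group higher) is
#' `(1 + #(t* >= t_obs)) / (n_perm + 1)`, so it is never below
#' `1 / (n_perm + 1)`.
#'
#' @param pas_tbl PAS table (columns `drug`, `pathway`, `pas`) restricted
#'   to the cancer of interest.
#' @param drug,pathway the focal DCSP's drug and pathway.
#' @param comparison `"other_drugs_same_pathway"`,
#'   `"same_drug_other_pathways"` or `"other_drugs_other_pathways"`.
#' @param n_perm number of permutations (>= 1000; default 10000).
#' @param seed RNG seed for reproducibility.
#' @return Object of class `permutation_result`: list with `comparison`,
#'   `observed_t`, `n_perm`, `p_empirical`, `n_focal`, `n_comparison`.
#' @export
permutation_specificity_test <- function(pas_tbl, drug, pathway,
                                         comparison = c(
                                           "other_drugs_same_pathway",
                                           "same_drug_other_pathways",
                                           "other_drugs_other_pathways"),
                                         n_perm = 10000, seed = NULL) {
  comparison <- match.arg(comparison)
  if (n_perm < 1000) stop("n_perm must be >= 1000")
  pas_tbl <- as.data.frame(pas_tbl)
  need_cols(pas_tbl, c("drug", "pathway", "pas"), "PAS table")
  is_focal <- pas_tbl$drug == drug & pas_tbl$pathway == pathway
  is_comp <- switch(comparison,
    other_drugs_same_pathway =
      pas_tbl$drug != drug & pas_tbl$pathway == pathway,
    same_drug_other_pathways =
      pas_tbl$drug == drug & pas_tbl$pathway != pathway,
    other_drugs_other_pathways =
      pas_tbl$drug != drug & pas_tbl$pathway != pathway)
  a <- pas_tbl$pas[is_focal]
  b <- pas_tbl$pas[is_comp]
  if (length(a) < 2 || length(b) < 2) {
    stop("both the focal and the comparison group need >= 2 records")
  }
  x <- c(a, b)
  n1 <- length(a)
  n <- length(x)
  if (stats::sd(x) == 0) {
    dcsp_log("degenerate permutation test: all PAS values identical")
    return(structure(
      list(comparison = comparison, observed_t = 0,
           n_perm = as.integer(n_perm), p_empirical = 1,
           n_focal = n1, n_comparison = length(b)),
      class = "permutation_result"))
  }
  obs <- pooled_t_stat(a, b)
  sum_all <- sum(x)
  ss_all <- sum(x^2)
  n2 <- n - n1
  t_star <- with_seed(seed, {
    idx <- vapply(seq_len(n_perm), function(i) sample.int(n, n1),
                  integer(n1))
    xi <- matrix(x[idx], nrow = n1)
    s1 <- colSums(xi)
    ss1 <- colSums(xi^2)
    m1 <- s1 / n1
    m2 <- (sum_all - s1) / n2
    v1 <- (ss1 - n1 * m1^2) / (n1 - 1)
    v2 <- (ss_all - ss1 - n2 * m2^2) / (n2 - 1)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n - 2)
    ts <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    ts[!is.finite(ts)] <- 0
    ts
  })
  p <- (1 + sum(t_star >= obs)) / (n_perm + 1)
  structure(
    list(comparison = comparison, observed_t = obs,
         n_perm = as.integer(n_perm), p_empirical = p,
         n_focal = n1, n_comparison = length(b)),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %s: t = %.3f, p = %.4g (%d permutations)\n",
    x$comparison, x$observed_t, x$p_empirical, x$n_perm))
  invisible(x)
}
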