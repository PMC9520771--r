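# The two-statistic cancer-specificity screen: a robust one-vs-rest t
# statistic (T1) for overactivation of the target cancer and a chi-squared
# homogeneity statistic (T2) over the remaining cancers, combined with
# BH-FDR, a T2 first-quartile rule and sample-size conditions.

# trimmed mean, winsorized variance and effective size for one group
# (Yuen's components; trim = 0 reduces to mean/var/n)
yuen_group <- function(x, trim) {
  n <- length(x)
  g <- floor(trim * n)
  s <- sort(x)
  if (g > 0) {
    w <- c(rep(s[g + 1], g), s[(g + 1):(n - g)], rep(s[n - g], g))
    tm <- mean(s[(g + 1):(n - g)])
  } else {
    w <- s
    tm <- mean(s)
  }
  h <- n - 2 * g
  list(tm = tm, d = (n - 1) * stats::var(w) / (h * (h - 1)), h = h)
}

#' Robust one-vs-rest t statistic for overactivation
#'
#' Yuen-Welch unequal-variance t on symmetrically trimmed samples
#' (default 10% per tail in each group): the target cancer's PAS values
#' against the pooled values of the remaining cancers. Group variances are
#' winsorized at the trimming fraction and the degrees of freedom follow
#' Welch-Satterthwaite on the trimmed sample sizes; `trim = 0` reduces to
#' the plain Welch test. The p-value is one-sided for overactivation
#' (target mean above the rest).
#'
#' @param values_by_cancer named list of numeric PAS vectors, one per
#'   cancer.
#' @param target name of the target cancer (>= 2 samples; the pooled rest
#'   must also have >= 2).
#' @param trim trimming fraction per tail in `[0, 0.5)`.
#' @return List with `T1`, `p1`, `df`, and the trimmed group sizes
#'   `n_target`, `n_rest`.
#' @export
robust_t_one_vs_rest <- function(values_by_cancer, target, trim = 0.1) {
  stopifnot(is.list(values_by_cancer), target %in% names(values_by_cancer),
            trim >= 0, trim < 0.5)
  x <- as.numeric(values_by_cancer[[target]])
  y <- as.numeric(unlist(values_by_cancer[
    setdiff(names(values_by_cancer), target)
  ], use.names = FALSE))
  if (length(x) < 2 || length(y) < 2) {
    stop("both the target cancer and the pooled rest need >= 2 samples")
  }
  a <- yuen_group(x, trim)
  b <- yuen_group(y, trim)
  dm <- a$tm - b$tm
  se2 <- a$d + b$d
  if (se2 == 0) {
    if (dm == 0) {
      dcsp_log("degenerate one-vs-rest comparison (zero variance, equal means)")
      return(list(T1 = 0, p1 = 1, df = NA_real_,
                  n_target = a$h, n_rest = b$h))
    }
    return(list(T1 = sign(dm) * Inf, p1 = if (dm > 0) 0 else 1,
                df = NA_real_, n_target = a$h, n_rest = b$h))
  }
  t1 <- dm / sqrt(se2)
  df <- se2^2 / (a$d^2 / (a$h - 1) + b$d^2 / (b$h - 1))
  list(T1 = t1, p1 = stats::pt(t1, df, lower.tail = FALSE), df = df,
       n_target = a$h, n_rest = b$h)
}

#' Chi-squared homogeneity of the remaining cancers
#'
#' One-way heterogeneity statistic over the cancers other than the target:
#' `T2 = sum n_c * (m_c - m_bar)^2 / s2_pooled`, with per-cancer means
#' `m_c`, the sample-size-weighted grand mean `m_bar` and the pooled
#' within-cancer variance `s2_pooled`. Under homogeneity `T2` is
#' approximately chi-squared with (number of remaining cancers - 1)
#' degrees of freedom; the screen itself uses the empirical quartile rule,
#' the reference distribution is reported for interpretation only.
#'
#' @param values_by_cancer named list of numeric PAS vectors.
#' @param exclude name of the target cancer to leave out.
#' @return List with `T2` (>= 0, `Inf` when the pooled variance is 0 but
#'   the means differ), `df`, `n_groups`.
#' @export
chi2_homogeneity <- function(values_by_cancer, exclude) {
  stopifnot(is.list(values_by_cancer))
  g <- values_by_cancer[setdiff(names(values_by_cancer), exclude)]
  g <- g[vapply(g, length, 0L) >= 2L]
  if (length(g) < 2) {
    stop("need >= 2 remaining cancers with >= 2 samples each")
  }
  n <- lengths(g)
  m <- vapply(g, mean, numeric(1))
  v <- vapply(g, stats::var, numeric(1))
  s2 <- sum((n - 1) * v) / sum(n - 1)
  m_bar <- sum(n * m) / sum(n)
  t2 <- if (s2 == 0) {
    if (max(m) - min(m) == 0) 0 else Inf
  } else {
    sum(n * (m - m_bar)^2) / s2
  }
  list(T2 = t2, df = length(g) - 1L, n_groups = length(g))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Vector of BH-adjusted values.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Screen all (drug, pathway, cancer) triplets for cancer specificity
#'
#' For each target cancer, every (drug, pathway) pair is tested with
#' [robust_t_one_vs_rest()] (one-sided overactivation, BH-adjusted within
#' the per-cancer family by default) and [chi2_homogeneity()] over the
#' remaining cancers. Cancers with fewer than `min_samples` samples are
#' excluded from both the rest pool and the homogeneity statistic before
#' testing. A triplet is flagged `is_dcsp` when its FDR is below
#' `fdr_threshold`, its `T2` lies within the `t2_quartile` quantile of the
#' comparison set, the target cancer meets the sample-size rule and at
#' least `min_cancers` cancers enter the comparison.
#'
#' @param pas_tbl PAS table as returned by [pas_matrix()] (columns
#'   `sample`, `cancer`, `drug`, `pathway`, `pas`).
#' @param fdr_threshold FDR cutoff (default 0.01).
#' @param t2_quartile quantile of T2 that passing triplets must not exceed
#'   (default 0.25, the first quartile).
#' @param min_samples minimum samples per supporting cancer; the rule is
#'   strict "more than 5", i.e. the default 6 means `n >= 6`.
#' @param min_cancers minimum number of supporting cancers (default 3).
#' @param trim trimming fraction for the robust t (default 0.1).
#' @param family scope of the BH adjustment and T2 quantile:
#'   `"per_cancer"` (default; all drug-pathway pairs of one target cancer)
#'   or `"global"`.
#' @param t2_scope set over which the T2 quantile is taken:
#'   `"fdr_pass"` (default; among triplets already below the FDR cutoff)
#'   or `"family"` (all eligible triplets of the family).
#' @return data.frame with one row per (drug, pathway, cancer):
#'   `drug`, `pathway`, `cancer`, `n_target`, `n_rest_cancers`, `T1`,
#'   `p1`, `fdr`, `T2`, `t2_df`, `q_t2` (quantile rank of T2 within the
#'   family), `eligible`, `pass_fdr`, `pass_t2`, `is_dcsp`. Screen
#'   settings are attached as attribute `"config"`.
#' @export
dcsp_screen <- function(pas_tbl, fdr_threshold = 0.01, t2_quartile = 0.25,
                        min_samples = 6, min_cancers = 3, trim = 0.1,
                        family = c("per_cancer", "global"),
                        t2_scope = c("fdr_pass", "family")) {
  family <- match.arg(family)
  t2_scope <- match.arg(t2_scope)
  pas_tbl <- as.data.frame(pas_tbl)
  need_cols(pas_tbl, c("sample", "cancer", "drug", "pathway", "pas"),
            "PAS table")

  sc <- unique(pas_tbl[, c("sample", "cancer")])
  n_by_cancer <- table(sc$cancer)
  cancers <- sort(names(n_by_cancer))
  eligible_cancers <- cancers[as.integer(n_by_cancer[cancers]) >= min_samples]
  enough <- length(eligible_cancers) >= min_cancers

  pairs <- unique(pas_tbl[, c("drug", "pathway")])
  pairs <- pairs[order(pairs$drug, pairs$pathway), , drop = FALSE]

  # deterministic order regardless of input row order
  key <- paste(pas_tbl$drug, pas_tbl$pathway, sep = "\r")
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    pk <- paste(pairs$drug[i], pairs$pathway[i], sep = "\r")
    sub <- pas_tbl[key == pk, , drop = FALSE]
    sub <- sub[order(sub$cancer, sub$sample), , drop = FALSE]
    vals_all <- split(sub$pas, sub$cancer)
    vals <- vals_all[intersect(eligible_cancers, names(vals_all))]
    for (cz in cancers) {
      elig <- enough && cz %in% eligible_cancers &&
        length(intersect(eligible_cancers, names(vals_all))) >= min_cancers
      if (!elig) {
        rows[[length(rows) + 1L]] <- data.frame(
          drug = pairs$drug[i], pathway = pairs$pathway[i], cancer = cz,
          n_target = as.integer(n_by_cancer[cz]),
          n_rest_cancers = NA_integer_,
          T1 = NA_real_, p1 = NA_real_, T2 = NA_real_,
          t2_df = NA_integer_, eligible = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      rt <- robust_t_one_vs_rest(vals, cz, trim = trim)
      ch <- chi2_homogeneity(vals, cz)
      rows[[length(rows) + 1L]] <- data.frame(
        drug = pairs$drug[i], pathway = pairs$pathway[i], cancer = cz,
        n_target = as.integer(n_by_cancer[cz]),
        n_rest_cancers = ch$n_groups,
        T1 = rt$T1, p1 = rt$p1, T2 = ch$T2,
        t2_df = ch$df, eligible = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL

  fam_id <- if (family == "per_cancer") res$cancer else rep("all", nrow(res))
  res$fdr <- NA_real_
  res$q_t2 <- NA_real_
  res$pass_fdr <- FALSE
  res$pass_t2 <- FALSE
  for (f in unique(fam_id)) {
    idx <- which(fam_id == f & res$eligible)
    if (!length(idx)) next
    res$fdr[idx] <- bh_fdr(res$p1[idx])
    res$q_t2[idx] <- rank(res$T2[idx], ties.method = "average") / length(idx)
    res$pass_fdr[idx] <- res$fdr[idx] < fdr_threshold
    ref <- if (t2_scope == "fdr_pass") {
      idx[res$pass_fdr[idx]]
    } else {
      idx
    }
    if (length(ref)) {
      t2_ref <- res$T2[ref][is.finite(res$T2[ref])]
      if (length(t2_ref)) {
        qcut <- stats::quantile(t2_ref, probs = t2_quartile, names = FALSE,
                                type = 7)
        res$pass_t2[idx] <- is.finite(res$T2[idx]) & res$T2[idx] <= qcut
      }
    }
  }
  res$is_dcsp <- res$eligible & res$pass_fdr & res$pass_t2
  attr(res, "config") <- list(
    fdr_threshold = fdr_threshold, t2_quartile = t2_quartile,
    min_samples = min_samples, min_cancers = min_cancers, trim = trim,
    family = family, t2_scope = t2_scope,
    eligible_cancers = eligible_cancers
  )
  res
}
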