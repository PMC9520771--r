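test_that("robust one-vs-rest t handles degenerate and textbook cases", {
  vals <- list(A = rep(2, 10), B = rep(2, 10), C = rep(2, 10))
  r <- robust_t_one_vs_rest(vals, "A")
  expect_equal(r$T1, 0)
  expect_equal(r$p1, 1)

  # with trimming off, matches the standard Welch test exactly
  withr::local_seed(4)
  vals2 <- list(A = rnorm(15, 1), B = rnorm(20), C = rnorm(25))
  r2 <- robust_t_one_vs_rest(vals2, "A", trim = 0)
  ref <- t.test(vals2$A, c(vals2$B, vals2$C), alternative = "greater",
                var.equal = FALSE)
  expect_equal(r2$T1, unname(ref$statistic))
  expect_equal(r2$p1, ref$p.value)
  expect_equal(r2$df, unname(ref$parameter))

  # strong shift gives a tiny one-sided p
  shifted <- list(A = rnorm(20, 10, 1), B = rnorm(50, 0, 1),
                  C = rnorm(50, 0, 1))
  expect_lt(robust_t_one_vs_rest(shifted, "A")$p1, 1e-6)

  # swapping target and rest flips the sign
  two <- list(A = rnorm(12, 1), B = rnorm(12))
  expect_equal(robust_t_one_vs_rest(two, "A", trim = 0)$T1,
               -robust_t_one_vs_rest(two, "B", trim = 0)$T1)
})

test_that("chi2 homogeneity statistic matches its definition", {
  same <- list(T = rnorm(5), A = rep(3, 4), B = rep(3, 6), C = rep(3, 3))
  expect_equal(chi2_homogeneity(same, "T")$T2, 0)

  degen <- list(T = rnorm(5), A = c(0, 0), B = c(1, 1))
  expect_equal(chi2_homogeneity(degen, "T")$T2, Inf)

  withr::local_seed(8)
  g <- list(T = rnorm(5), A = rnorm(7, 1), B = rnorm(9, 2), C = rnorm(8, 3))
  got <- chi2_homogeneity(g, "T")
  # manual recomputation
  gg <- g[c("A", "B", "C")]
  n <- lengths(gg); m <- vapply(gg, mean, 0); v <- vapply(gg, var, 0)
  s2 <- sum((n - 1) * v) / sum(n - 1)
  mb <- sum(n * m) / sum(n)
  expect_equal(got$T2, sum(n * (m - mb)^2) / s2)
  expect_equal(got$df, 2L)

  expect_error(chi2_homogeneity(list(T = rnorm(5), A = rnorm(3)), "T"),
               ">= 2 remaining")
})

test_that("chi2 statistic follows its chi-squared reference under the null", {
  withr::local_seed(19)
  n_sim <- 2000
  t2 <- vapply(seq_len(n_sim), function(i) {
    g <- split(rnorm(250), rep(1:5, each = 50))
    names(g) <- c("T", "A", "B", "C", "D")
    chi2_homogeneity(g, "T")$T2
  }, numeric(1))
  ks <- suppressWarnings(ks.test(t2, function(q) pchisq(q, df = 3)))
  expect_gt(ks$p.value, 0.01)
})

test_that("bh_fdr agrees with the step-up oracle and validates input", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::local_seed(10)
  for (m in c(3, 17, 200)) {
    p <- runif(m)^2
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
})

# build a PAS-like table from per-cancer values replicated over pairs
pas_table_from <- function(values_by_cancer, n_pairs = 4) {
  rows <- do.call(rbind, lapply(names(values_by_cancer), function(cz) {
    v <- values_by_cancer[[cz]]
    data.frame(sample = sprintf("%s_s%02d", cz, seq_along(v)),
               cancer = cz, pas = v, stringsAsFactors = FALSE)
  }))
  do.call(rbind, lapply(seq_len(n_pairs), function(k) {
    out <- rows
    out$drug <- paste0("D", (k - 1) %/% 2 + 1)
    out$pathway <- paste0("PW", (k - 1) %% 2 + 1)
    # decouple pairs so the family is not perfectly duplicated
    out$pas <- out$pas + stats::rnorm(nrow(out), sd = 1e-6)
    out
  }))
}

test_that("screen enforces the strict >5-sample and >=3-cancer rules", {
  withr::local_seed(12)
  vals <- list(A = rnorm(12), B = rnorm(12), C = rnorm(12), E = rnorm(5))
  tab <- pas_table_from(vals)
  scr <- dcsp_screen(tab)
  # the 5-sample cancer is never eligible as a target
  expect_true(all(!scr$eligible[scr$cancer == "E"]))
  # and never enters the rest pool: n_rest_cancers excludes it
  expect_true(all(scr$n_rest_cancers[scr$eligible] == 2))

  # with only 2 eligible cancers nothing is tested
  vals2 <- list(A = rnorm(12), B = rnorm(12), E = rnorm(5))
  scr2 <- dcsp_screen(pas_table_from(vals2))
  expect_true(all(!scr2$eligible))
  expect_true(all(!scr2$is_dcsp))
})

test_that("screen output is invariant to row order and PAS location shift", {
  withr::local_seed(14)
  vals <- list(A = rnorm(12), B = rnorm(12), C = rnorm(12), D = rnorm(12))
  tab <- pas_table_from(vals)
  scr1 <- dcsp_screen(tab)
  scr2 <- dcsp_screen(tab[sample(nrow(tab)), ])
  expect_equal(scr1, scr2, ignore_attr = TRUE)

  shifted <- tab
  shifted$pas <- shifted$pas + 1000
  scr3 <- dcsp_screen(shifted)
  expect_equal(scr1$T1, scr3$T1, tolerance = 1e-8)
  expect_equal(scr1$T2, scr3$T2, tolerance = 1e-6)
  expect_equal(scr1$is_dcsp, scr3$is_dcsp)
})

test_that("fdr is monotone in p1 within each family", {
  withr::local_seed(15)
  vals <- list(A = rnorm(12), B = rnorm(12), C = rnorm(12), D = rnorm(12))
  scr <- dcsp_screen(pas_table_from(vals, n_pairs = 6))
  for (cz in unique(scr$cancer)) {
    sub <- scr[scr$cancer == cz & scr$eligible, ]
    ord <- order(sub$p1)
    expect_true(all(diff(sub$fdr[ord]) >= -1e-12))
  }
})
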