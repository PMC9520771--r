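test_that("normal score transform maps ranks to normal quantiles", {
  got <- normal_score_transform(c(5, 1, 9))
  expect_equal(got, c(0, qnorm(0.25), qnorm(0.75)))
  expect_equal(got[2], -0.6745, tolerance = 1e-4)

  # invariance under strictly increasing recoding
  withr::local_seed(6)
  x <- rnorm(25)
  expect_equal(normal_score_transform(exp(x) + 3),
               normal_score_transform(x))

  # two-step oracle at n = 7
  y <- runif(7)
  expect_equal(normal_score_transform(y),
               qnorm(rank(y) / 8))

  # constant input -> all mid-rank zeros; short input errors
  expect_equal(normal_score_transform(rep(4, 6)), rep(0, 6))
  expect_error(normal_score_transform(3), ">= 2")

  # symmetric about zero with exact zero mean for odd n without ties
  z <- normal_score_transform(rnorm(11))
  expect_lt(abs(mean(z)), 1e-9)
  expect_equal(sort(z), sort(-z))
})

make_pas_records <- function(pas, drug = "D1", pathway = "PW1",
                             cancer = "C1") {
  data.frame(sample = sprintf("s%03d", seq_along(pas)),
             cancer = cancer, drug = drug, pathway = pathway,
             pas = pas, stringsAsFactors = FALSE)
}

test_that("PAS-response correlation is rank-based with the stated guards", {
  withr::local_seed(16)
  pas <- rlnorm(30)
  rec <- make_pas_records(pas)
  # AUC strictly increasing in PAS -> r = 1 on normal scores
  resp <- data.frame(sample = rec$sample, drug = "D1", auc = pas^2 + 1)
  out <- pas_response_correlation(rec, resp)
  expect_true(out$ok)
  expect_equal(out$r, 1)
  expect_equal(out$p, 0)

  # negating AUC flips the sign exactly
  resp2 <- resp
  resp2$auc <- max(resp$auc) + 1 - resp$auc
  out2 <- pas_response_correlation(rec, resp2)
  expect_equal(out2$r, -out$r)

  # invariance under monotone transforms of either variable
  resp3 <- resp
  resp3$auc <- log(resp$auc)
  expect_equal(pas_response_correlation(rec, resp3)$r, out$r)

  # positivity restriction: non-positive PAS samples are excluded
  rec_mix <- make_pas_records(c(-1, -2, rlnorm(10)))
  resp_mix <- data.frame(sample = rec_mix$sample, drug = "D1",
                         auc = runif(12, 1, 5))
  got <- pas_response_correlation(rec_mix, resp_mix)
  expect_equal(got$n, 10)
  # downstream direction uses -PAS as activation
  down <- pas_response_correlation(rec_mix, resp_mix,
                                   direction = "downstream")
  expect_equal(down$n, 2)
  expect_false(down$ok)   # fewer than 3 usable samples

  # fewer than 3 overlapping samples -> flagged not computable
  tiny <- pas_response_correlation(make_pas_records(c(1, 2)),
                                   data.frame(sample = c("s001", "s002"),
                                              drug = "D1", auc = c(1, 2)))
  expect_false(tiny$ok)
  expect_true(is.na(tiny$r))
})

test_that("rdr_curve counts top-fraction rediscoveries", {
  disc <- data.frame(drug = paste0("D", 1:10), pathway = "PW",
                     r = seq(-0.9, -0.1, length.out = 10))
  val <- data.frame(drug = paste0("D", 1:10), pathway = "PW",
                    p_one = c(0.001, 0.002, rep(0.5, 8)))
  cur <- rdr_curve(disc, val, alpha = 0.05, sign = "negative",
                   fractions = c(0.2, 1))
  expect_equal(cur$rdr, c(1, 0.2))
  expect_equal(cur$n_top, c(2L, 10L))

  # all significant -> RDR identically 1
  val2 <- val
  val2$p_one <- 1e-4
  cur2 <- rdr_curve(disc, val2)
  expect_true(all(cur2$rdr == 1))

  # positive sign selects positive discovery correlations
  disc3 <- rbind(disc, data.frame(drug = "D11", pathway = "PW", r = 0.5))
  val3 <- rbind(val, data.frame(drug = "D11", pathway = "PW", p_one = 0.01))
  cur3 <- rdr_curve(disc3, val3, sign = "positive", fractions = 1)
  expect_equal(cur3$n_top, 1L)
  expect_equal(cur3$rdr, 1)

  expect_error(rdr_curve(disc[0, ], val), "no matched")
})

test_that("permutation specificity test honors its floor and seed", {
  withr::local_seed(17)
  tab <- data.frame(
    drug = rep(c("D1", "D2"), each = 20),
    pathway = rep(c("PWa", "PWb"), 20),
    pas = c(rnorm(20, 50, 1), rnorm(20, 0, 1)))
  focal <- tab$drug == "D1" & tab$pathway == "PWa"
  # maximal separation: no permuted t reaches the observed one
  r <- permutation_specificity_test(tab, "D1", "PWa",
                                    "other_drugs_other_pathways",
                                    n_perm = 1000, seed = 3)
  expect_equal(r$p_empirical, 1 / 1001)
  expect_gt(r$observed_t, 0)

  # reproducible under the same seed
  r2 <- permutation_specificity_test(tab, "D1", "PWa",
                                     "other_drugs_other_pathways",
                                     n_perm = 1000, seed = 3)
  expect_identical(r$p_empirical, r2$p_empirical)

  # degenerate input: identical values -> p = 1
  flat <- tab
  flat$pas <- 7
  rf <- permutation_specificity_test(flat, "D1", "PWa",
                                     "other_drugs_other_pathways",
                                     n_perm = 1000, seed = 1)
  expect_equal(rf$p_empirical, 1)
  expect_equal(rf$observed_t, 0)

  # comparison group selection
  ra <- permutation_specificity_test(tab, "D1", "PWa",
                                     "other_drugs_same_pathway",
                                     n_perm = 1000, seed = 1)
  expect_equal(ra$n_comparison, sum(tab$drug != "D1" &
                                      tab$pathway == "PWa"))
  expect_error(permutation_specificity_test(tab, "D1", "PWa",
                                            n_perm = 10),
               ">= 1000")
})
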