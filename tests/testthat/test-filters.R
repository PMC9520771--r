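test_that("unexpressed-gene filter applies the threshold/fraction rule", {
  genes <- sprintf("g%03d", 1:100)
  samples <- sprintf("s%02d", 1:20)
  withr::local_seed(1)
  m <- matrix(rexp(2000) + 0.5, 100, 20, dimnames = list(genes, samples))
  # zero out 20 genes in 19/20 = 95% of samples
  m[1:20, 1:19] <- 0
  co <- make_cohort(m, genes, samples)
  kept <- filter_unexpressed_genes(co, threshold = 1e-2, fraction = 0.9)
  # independent recount: proportion at/below threshold per gene
  expect_identical(rownames(kept$expression),
                   genes[rowMeans(m <= 1e-2) <= 0.9])
  expect_equal(nrow(kept$expression), 80)

  # gene zero everywhere is removed, gene always expressed is retained
  co2 <- make_cohort(c(rep(0, 10), rep(5, 10)), c("off", "on"),
                     sprintf("t%02d", 1:10))
  # column-major fill puts alternating values; build explicitly instead
  m2 <- rbind(off = rep(0, 10), on = rep(5, 10))
  colnames(m2) <- sprintf("t%02d", 1:10)
  co2 <- cohort(m2, stats::setNames(rep("CA", 10), colnames(m2)))
  f2 <- filter_unexpressed_genes(co2)
  expect_identical(rownames(f2$expression), "on")

  # idempotence
  again <- filter_unexpressed_genes(kept)
  expect_identical(rownames(again$expression), rownames(kept$expression))

  expect_error(filter_unexpressed_genes(
    cohort(m2["off", , drop = FALSE] ,
           stats::setNames(rep("CA", 10), colnames(m2)))),
    "all genes removed")
})

test_that("driver mutation filter keeps genes at the inclusive boundary", {
  samples <- sprintf("s%03d", 1:100)
  labels <- stats::setNames(rep(c("A", "B"), each = 50), samples)
  co <- make_cohort(rep(1, 200), c("g1", "g2"), samples, labels)

  occ <- data.frame(gene = c("hit2", "hit2", "hit1"),
                    sample = c("s001", "s060", "s002"))
  ds <- filter_driver_mutations(occ, co, min_fraction = 0.02)
  expect_setequal(ds$A, "hit2")   # 2/100 kept, assigned to both cancers
  expect_setequal(ds$B, "hit2")
  expect_false("hit1" %in% unlist(ds))   # 1/100 dropped

  expect_error(
    filter_driver_mutations(data.frame(gene = "g", sample = "nope"), co),
    "outside the cohort")
})

test_that("driver mutation filter matches a brute-force recount and is monotone", {
  withr::local_seed(7)
  samples <- sprintf("s%03d", 1:80)
  labels <- stats::setNames(sample(c("A", "B", "C"), 80, TRUE), samples)
  co <- make_cohort(rep(1, 80), "g0", samples, labels)
  genes <- sprintf("mut%02d", 1:50)
  occ <- do.call(rbind, lapply(genes, function(g) {
    hit <- samples[stats::rbinom(80, 1, 0.03) == 1]
    if (!length(hit)) return(NULL)
    data.frame(gene = g, sample = hit)
  }))
  ds <- filter_driver_mutations(occ, co, min_fraction = 0.02)
  # oracle: direct per-gene distinct-sample count
  cnt <- tapply(occ$sample, occ$gene, function(s) length(unique(s)))
  oracle <- names(cnt)[cnt / 80 >= 0.02]
  expect_setequal(unique(unlist(ds)), oracle)

  stricter <- filter_driver_mutations(occ, co, min_fraction = 0.05)
  expect_true(all(unlist(stricter) %in% unlist(ds)))
})

test_that("fusion filter combines occurrence count and whitelist", {
  samples <- sprintf("s%02d", 1:10)
  labels <- stats::setNames(rep(c("A", "B"), each = 5), samples)
  co <- make_cohort(rep(1, 10), "g0", samples, labels)
  fus <- data.frame(
    fusion = c("F1", "F1", "F2", "F3", "F3", "F4"),
    genes = c("X,Y", "X,Y", "P,Q", "U,V", "U,V", "W,Z"),
    sample = c("s01", "s06", "s02", "s03", "s04", "s05"))

  once <- filter_driver_fusions(fus[fus$fusion == "F2", ], co)
  expect_length(unlist(once), 0)     # single occurrence dropped

  no_wl <- filter_driver_fusions(fus, co)
  expect_setequal(unique(unlist(no_wl)), c("X", "Y", "U", "V"))

  wl <- filter_driver_fusions(fus, co, whitelist = c("F1", "F4"))
  # manual set algebra: occurrence>=2 gives {F1,F3}; intersect -> {F1}
  expect_setequal(unique(unlist(wl)), c("X", "Y"))
  expect_setequal(wl$A, c("X", "Y"))
  expect_length(wl$B, 2)   # F1 occurs in s06 (cancer B) too
})

test_that("monotherapy dedup drops replicated profiles entirely", {
  raw <- data.frame(sample = c("s1", "s2", "s2"),
                    drug = c("d1", "d1", "d1"),
                    auc = c(1, 2, 3))
  kept <- dedupe_monotherapy(raw)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$sample, "s1")

  clean <- data.frame(sample = c("s1", "s2"), drug = "d1", auc = c(1, 2))
  expect_equal(nrow(dedupe_monotherapy(clean)), 2)

  withr::local_seed(3)
  big <- data.frame(
    sample = sample(sprintf("s%02d", 1:15), 60, TRUE),
    drug = sample(c("d1", "d2", "d3"), 60, TRUE),
    auc = runif(60))
  got <- dedupe_monotherapy(big)
  key <- paste(big$sample, big$drug)
  expect_equal(nrow(got), sum(table(key) == 1))
  # idempotent
  expect_equal(nrow(dedupe_monotherapy(got)), nrow(got))
})
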