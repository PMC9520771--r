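test_that("partition splits a chain around the target", {
  dn <- chain_directed(c("A", "B", "C", "D"))
  p <- partition_pathway(c("A", "B", "C", "D"), "C", dn)
  expect_setequal(p$g_u, c("A", "B", "C"))
  expect_setequal(p$g_d, "D")
  expect_false(p$disconnected)

  # a target that is a pathway member always lands in G_u
  p2 <- partition_pathway(c("HSP90", "AKT1"), "HSP90",
                          chain_directed(c("HSP90", "AKT1")))
  expect_true("HSP90" %in% p2$g_u)
})

test_that("unreached genes follow the policy and disconnection errors", {
  dn <- chain_directed(c("A", "B"))
  p_down <- partition_pathway(c("A", "B", "orphan"), "B", dn,
                              unreached_policy = "downstream")
  expect_true("orphan" %in% p_down$g_d)
  p_excl <- partition_pathway(c("A", "B", "orphan"), "B", dn,
                              unreached_policy = "exclude")
  expect_false("orphan" %in% c(p_excl$g_u, p_excl$g_d))
  expect_true("orphan" %in% p_excl$unreached)

  expect_error(
    partition_pathway(c("X", "Y"), "B", dn),
    "disconnected")
})

test_that("cycles resolve with target-side precedence", {
  dn <- directed_network(data.frame(from = c("A", "B", "C"),
                                    to = c("B", "C", "A")))
  p <- partition_pathway(c("A", "B", "C"), "B", dn)
  # every gene both reaches and is reachable from the target
  expect_setequal(p$g_u, c("A", "B", "C"))
  expect_length(p$g_d, 0)
})

test_that("partition equals the transitive-closure oracle on random DAGs", {
  withr::local_seed(21)
  for (rep in 1:15) {
    adj <- random_dag_adj(15, 0.15)
    genes <- rownames(adj)
    targets <- sample(genes, 2)
    dn <- adj_to_directed(adj)
    want <- partition_oracle(adj, genes, targets)
    if (!length(want$g_u)) {
      expect_error(partition_pathway(genes, targets, dn), "disconnected")
      next
    }
    got <- partition_pathway(genes, targets, dn)
    expect_identical(sort(got$g_u), want$g_u)
    expect_identical(sort(got$g_d), want$g_d)
  }
})

test_that("expression_sum adds the requested rows only", {
  co <- make_cohort(c(2, 3, 7, 1, 4, 9), c("A", "B", "C"),
                    c("s1", "s2"))
  expect_equal(expression_sum(co, "s1", c("A", "B")), 5)
  expect_equal(expression_sum(co, "s1", character(0)), 0)
  expect_equal(expression_sum(co, "s2", c("A", "missing")), 1)
  expect_error(expression_sum(co, "nope", "A"), "unknown sample")

  withr::local_seed(2)
  genes <- sprintf("g%03d", 1:80)
  co2 <- make_cohort(rexp(160), genes, c("x1", "x2"))
  pick <- sample(genes, 50)
  expect_equal(expression_sum(co2, "x2", pick),
               sum(co2$expression[pick, "x2"]))
})

test_that("compute_pas follows the weighted-sum algebra exactly", {
  co <- make_cohort(c(5, 2, 0, 1, 1, 3), c("u1", "d1", "n1"),
                    c("s1", "s2"))
  dn <- chain_directed(c("u1", "d1"))
  part <- partition_pathway(c("u1", "d1"), "u1", dn)
  w0 <- weights_from_z(-50, -50, -50)   # w ~ 0
  r0 <- compute_pas(co, part, w0)
  expect_equal(r0$pas_u[1], 5, tolerance = 1e-6)
  expect_equal(r0$pas_d[1], 2, tolerance = 1e-6)
  expect_equal(r0$pas[1], 3, tolerance = 1e-6)

  w1 <- weights_from_z(50, 50, 50)      # w ~ 1
  r1 <- compute_pas(co, part, w1)
  expect_equal(r1$pas_u[1], 20, tolerance = 1e-4)
  expect_equal(r1$pas_u, r1$s_u * 4, tolerance = 1e-4)

  # PAS_u stays within [S_u, 4 S_u] for any weights
  wmid <- weights_from_z(0.3, -1, 2)
  rmid <- compute_pas(co, part, wmid)
  expect_true(all(rmid$pas_u >= rmid$s_u - 1e-12))
  expect_true(all(rmid$pas_u <= 4 * rmid$s_u + 1e-12))

  # antisymmetry under G_u/G_d swap
  swapped <- part
  tmp <- swapped$g_u; swapped$g_u <- swapped$g_d; swapped$g_d <- tmp
  rs <- compute_pas(co, swapped, wmid)
  expect_equal(rs$pas, -rmid$pas)

  # linearity in expression
  co3 <- cohort(co$expression * 3.5, co$labels)
  r3 <- compute_pas(co3, part, wmid)
  expect_equal(r3$pas, 3.5 * rmid$pas)
})

test_that("pas_matrix composes partition, weights and sums per cancer", {
  sim <- simulate_cohort(sim_config(
    n_cancers = 3, samples_per_cancer = 10, n_genes = 120,
    n_pathways = 3, pathway_size = 6, n_drugs = 2, seed = 31))
  tab <- pas_matrix(sim$cohort, sim$pathways, sim$drug_targets,
                    sim$drivers, sim$directed, sim$functional, seed = 31)
  expect_equal(nrow(tab), 2 * 3 * 30)
  expect_equal(nrow(attr(tab, "skipped")), 0)

  # stepwise recomposition for one (drug, pathway, cancer)
  d <- "D2"; pj <- "PW3"; cz <- "C2"
  part <- partition_pathway(sim$pathways[[pj]], sim$drug_targets[[d]],
                            sim$directed)
  w <- connectivity_weights(sim$functional, sim$drug_targets[[d]],
                            sim$drivers[[cz]], sim$pathways[[pj]],
                            mode = "analytic")
  samples <- names(sim$cohort$labels)[sim$cohort$labels == cz]
  manual <- compute_pas(sim$cohort, part, w, samples = samples,
                        drug = d, pathway = pj)
  got <- tab[tab$drug == d & tab$pathway == pj & tab$cancer == cz, ]
  rownames(got) <- NULL
  attr(got, "skipped") <- NULL
  expect_equal(got, manual)

  # weight factor is sample-independent within a (drug, pathway, cancer)
  ratio <- got$pas_u / got$s_u
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-12)
})

test_that("pas_matrix records skipped pairs instead of failing", {
  genes <- c("A", "B", "X", "Y")
  co <- make_cohort(rep(1, 8), genes, c("s1", "s2"))
  pw <- pathway_db(list(PW1 = c("A", "B"), PW2 = c("X", "Y")))
  tg <- drug_target_map(list(D1 = "A"))
  dn <- chain_directed(c("A", "B"))      # PW2 unreachable from the target
  fn <- path_network(genes)
  ds <- driver_set(list(CA = "X"), "CA")
  tab <- pas_matrix(co, pw, tg, ds, dn, fn)
  expect_equal(sort(unique(tab$pathway)), "PW1")
  sk <- attr(tab, "skipped")
  expect_equal(sk$pathway, "PW2")
  expect_match(sk$reason, "disconnected")

  # nothing computable at all -> error
  expect_error(
    pas_matrix(co, pathway_db(list(PW2 = c("X", "Y"))), tg, ds, dn, fn),
    "no \\(drug, pathway\\) pair")
})
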