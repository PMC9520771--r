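# Programmatic fixtures and independent oracles used across the suite.

# small cohort with known values; genes x samples filled column-major
make_cohort <- function(values, genes, samples, labels = NULL,
                        name = "fixture") {
  m <- matrix(values, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  if (is.null(labels)) {
    labels <- stats::setNames(rep("CA", length(samples)), samples)
  }
  cohort(m, labels, name = name)
}

# undirected path graph over the given node names
path_network <- function(nodes) {
  functional_network(data.frame(a = nodes[-length(nodes)], b = nodes[-1]))
}

# complete undirected graph over the given node names
complete_network <- function(nodes) {
  pr <- t(utils::combn(nodes, 2))
  functional_network(data.frame(a = pr[, 1], b = pr[, 2]))
}

# directed chain a -> b -> c ...
chain_directed <- function(nodes) {
  directed_network(data.frame(from = nodes[-length(nodes)], to = nodes[-1]))
}

# random DAG adjacency matrix (upper triangular) over n named genes
random_dag_adj <- function(n, p, genes = sprintf("g%02d", seq_len(n))) {
  adj <- matrix(0L, n, n, dimnames = list(genes, genes))
  adj[upper.tri(adj)] <- stats::rbinom(sum(upper.tri(adj)), 1, p)
  adj
}

adj_to_directed <- function(adj) {
  idx <- which(adj == 1L, arr.ind = TRUE)
  if (!nrow(idx)) {
    # igraph needs at least one edge to carry the vertex set; add a
    # self-contained two-node edge outside the gene universe
    return(directed_network(data.frame(from = "..a", to = "..b")))
  }
  directed_network(data.frame(from = rownames(adj)[idx[, 1]],
                              to = colnames(adj)[idx[, 2]]))
}

# boolean transitive closure by repeated matrix multiplication
closure_oracle <- function(adj) {
  n <- nrow(adj)
  reach <- adj > 0
  repeat {
    nxt <- ((reach %*% reach) > 0) | reach
    if (all(nxt == reach)) break
    reach <- nxt
  }
  reach
}

# partition oracle on a DAG adjacency: mirrors the G_u/G_d definitions
# using the closure matrix instead of graph traversal
partition_oracle <- function(adj, pathway, targets,
                             unreached_policy = "downstream") {
  reach <- closure_oracle(adj)
  genes <- rownames(adj)
  t_in <- intersect(targets, genes)
  up <- genes[rowSums(reach[, t_in, drop = FALSE]) > 0]
  down <- genes[colSums(reach[t_in, , drop = FALSE]) > 0]
  g_u <- union(intersect(targets, pathway), intersect(pathway, up))
  g_d <- setdiff(intersect(pathway, down), g_u)
  unreached <- setdiff(pathway, union(g_u, g_d))
  if (unreached_policy == "downstream") g_d <- union(g_d, unreached)
  list(g_u = sort(g_u), g_d = sort(g_d))
}

# exhaustive enumeration of all simple graphs on the same nodes with the
# same per-node degree vector; returns the count_links statistic over
# every such graph (uniform enumeration oracle for the rewiring null)
enumerate_link_counts <- function(n_nodes, edges_idx, ags_idx, fgs_idx) {
  all_pairs <- t(utils::combn(n_nodes, 2))
  deg_target <- tabulate(c(edges_idx), n_nodes)
  cmb <- utils::combn(nrow(all_pairs), nrow(edges_idx))
  vals <- numeric(0)
  for (j in seq_len(ncol(cmb))) {
    e <- all_pairs[cmb[, j], , drop = FALSE]
    if (!all(tabulate(c(e), n_nodes) == deg_target)) next
    hit <- (e[, 1] %in% ags_idx & e[, 2] %in% fgs_idx) |
      (e[, 1] %in% fgs_idx & e[, 2] %in% ags_idx)
    vals <- c(vals, sum(hit))
  }
  vals
}

# step-up BH oracle written from the adjustment formula directly
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- prev
  }
  pmin(adj, 1)
}

# one run of the screen on a simulated cohort (shared by calibration and
# recovery checks)
run_screen_once <- function(seed, planted = NULL, ...) {
  sim <- simulate_cohort(sim_config(seed = seed, planted = planted, ...))
  tab <- pas_matrix(sim$cohort, sim$pathways, sim$drug_targets,
                    sim$drivers, sim$directed, sim$functional, seed = seed)
  dcsp_screen(tab)
}
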