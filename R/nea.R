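# Network enrichment analysis (NEA): the link-count z-score between two
# gene sets in an undirected functional network, and its conversion into
# the probability weights that enter the pathway activation score.

# Restrict a gene set to network nodes, dropping (and logging) the rest.
restrict_to_network <- function(network, genes, what) {
  vn <- igraph::V(network)$name
  g <- intersect(unique(as.character(genes)), vn)
  dropped <- length(unique(genes)) - length(g)
  if (dropped > 0) dcsp_log(dropped, " ", what, " gene(s) not in network dropped")
  g
}

#' Count functional links between two gene sets
#'
#' Counts each undirected edge `{a, f}` with one endpoint in `ags` and the
#' other in `fgs` exactly once, including edges whose endpoints both lie in
#' the intersection of the two sets. Genes absent from the network are
#' dropped before counting.
#'
#' @param network undirected `igraph` graph (see [functional_network()]).
#' @param ags,fgs character vectors of gene symbols (the altered and
#'   functional gene sets; the statistic is symmetric in the two).
#' @return Integer link count `d_AF`.
#' @export
count_links <- function(network, ags, fgs) {
  stopifnot(igraph::is_igraph(network), !igraph::is_directed(network))
  a <- restrict_to_network(network, ags, "AGS")
  f <- restrict_to_network(network, fgs, "FGS")
  if (!length(a) && !length(f)) {
    stop("neither gene set has any member in the functional network")
  }
  if (!length(a) || !length(f)) return(0L)
  el <- igraph::as_edgelist(network, names = TRUE)
  in_a1 <- el[, 1] %in% a
  in_a2 <- el[, 2] %in% a
  in_f1 <- el[, 1] %in% f
  in_f2 <- el[, 2] %in% f
  sum((in_a1 & in_f2) | (in_f1 & in_a2))
}

#' Null mean and standard deviation of the link count
#'
#' Two null models for the number of links between `ags` and `fgs` in a
#' randomized network:
#' * `"permute_network"`: `n_perm` independent degree-preserving
#'   randomizations of the network (double-edge swaps, `10 * |E|` swap
#'   attempts each), returning the Monte-Carlo mean and SD of the link
#'   count.
#' * `"analytic"`: a closed-form approximation to the permutation null,
#'   `mean = sum k_a * k_f / (2E)` over unordered qualifying pairs with
#'   `k` the node degrees and `E` the edge count, and a Poisson-style
#'   `sd = sqrt(mean)`.
#'
#' @param network undirected `igraph` graph with at least 2 edges.
#' @param ags,fgs gene sets.
#' @param mode `"analytic"` (default) or `"permute_network"`.
#' @param n_perm number of randomized networks (>= 100) for
#'   `"permute_network"`.
#' @param seed RNG seed for reproducible permutation nulls.
#' @return List with `null_mean`, `null_sd`, `mode`, and for the
#'   permutation mode `n_perm` and the vector of null `draws`.
#' @export
null_link_distribution <- function(network, ags, fgs,
                                   mode = c("analytic", "permute_network"),
                                   n_perm = 1000, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(igraph::is_igraph(network))
  n_edges <- igraph::ecount(network)
  if (n_edges < 2) stop("network must have at least 2 edges")
  a <- restrict_to_network(network, ags, "AGS")
  f <- restrict_to_network(network, fgs, "FGS")
  if (mode == "analytic") {
    if (!length(a) || !length(f)) {
      return(list(null_mean = 0, null_sd = 0, mode = mode))
    }
    deg <- igraph::degree(network)
    pairs <- expand.grid(a = a, f = f, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$f, , drop = FALSE]
    if (nrow(pairs)) {
      key <- paste(pmin(pairs$a, pairs$f), pmax(pairs$a, pairs$f), sep = "\r")
      pairs <- pairs[!duplicated(key), , drop = FALSE]
    }
    mu <- if (nrow(pairs)) {
      sum(deg[pairs$a] * deg[pairs$f]) / (2 * n_edges)
    } else 0
    list(null_mean = mu, null_sd = sqrt(mu), mode = mode)
  } else {
    if (n_perm < 100) stop("n_perm must be >= 100 for permute_network")
    draws <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        r <- igraph::rewire(
          network,
          igraph::keeping_degseq(loops = FALSE, niter = 10 * n_edges)
        )
        as.numeric(count_links(r, a, f))
      }, numeric(1))
    })
    list(null_mean = mean(draws), null_sd = stats::sd(draws),
         mode = mode, n_perm = as.integer(n_perm), draws = draws)
  }
}

#' Network enrichment z-score between two gene sets
#'
#' `z = (d_AF - null_mean) / null_sd`, with `z = 0` when the null SD is 0
#' (degenerate null, e.g. isolated gene sets) so downstream scores remain
#' computable.
#'
#' @inheritParams null_link_distribution
#' @return An object of class `nea_result`: list with `d_AF`, `null_mean`,
#'   `null_sd`, `z`, `mode`.
#' @export
nea_z <- function(network, ags, fgs,
                  mode = c("analytic", "permute_network"),
                  n_perm = 1000, seed = NULL) {
  mode <- match.arg(mode)
  d <- count_links(network, ags, fgs)
  nl <- null_link_distribution(network, ags, fgs, mode = mode,
                               n_perm = n_perm, seed = seed)
  z <- if (is.na(nl$null_sd) || nl$null_sd == 0) {
    0
  } else {
    (d - nl$null_mean) / nl$null_sd
  }
  structure(
    list(d_AF = as.integer(d), null_mean = nl$null_mean,
         null_sd = if (is.na(nl$null_sd)) 0 else nl$null_sd,
         z = z, mode = mode),
    class = "nea_result"
  )
}

#' @export
print.nea_result <- function(x, ...) {
  cat(sprintf("<nea_result> d_AF = %d, null = %.3f +/- %.3f, z = %.3f (%s)\n",
              x$d_AF, x$null_mean, x$null_sd, x$z, x$mode))
  invisible(x)
}

#' Convert NEA z-scores into connectivity weights
#'
#' Each weight is the standard normal probability `w = pnorm(z)`: 0 means
#' little or no functional interaction, 1 high interaction, 0.5 the neutral
#' value at `z = 0`. The three z-scores correspond to the gene-set pairs
#' (drug targets vs driver genes), (driver genes vs pathway) and
#' (drug targets vs pathway).
#'
#' @param z1,z2,z3 finite NEA z-scores.
#' @return Object of class `connectivity_weights`: list with `z1..z3`,
#'   `w1..w3` and the PAS multiplier `factor = 1 + w1 + w2 + w3`.
#' @export
weights_from_z <- function(z1, z2, z3) {
  z <- c(z1 = z1, z2 = z2, z3 = z3)
  if (any(!is.finite(z))) stop("z-scores must be finite")
  w <- stats::pnorm(z)
  structure(
    list(z1 = z[["z1"]], z2 = z[["z2"]], z3 = z[["z3"]],
         w1 = w[["z1"]], w2 = w[["z2"]], w3 = w[["z3"]],
         factor = 1 + sum(w)),
    class = "connectivity_weights"
  )
}

#' @export
print.connectivity_weights <- function(x, ...) {
  cat(sprintf(
    "<connectivity_weights> w1 = %.3f, w2 = %.3f, w3 = %.3f (factor %.3f)\n",
    x$w1, x$w2, x$w3, x$factor))
  invisible(x)
}

#' Connectivity weights for a (drug, pathway, cancer) context
#'
#' Computes the three NEA z-scores -- targets vs drivers (`z1`), drivers vs
#' pathway (`z2`), targets vs pathway (`z3`) -- on the functional network
#' and converts them with [weights_from_z()]. An empty driver set yields
#' `z = 0` and the neutral weight 0.5 for the pairs involving drivers.
#'
#' @param network undirected functional `igraph` network.
#' @param targets drug target genes.
#' @param drivers driver genes of the cancer (may be empty).
#' @param pathway_genes pathway member genes.
#' @inheritParams null_link_distribution
#' @return A `connectivity_weights` object.
#' @export
connectivity_weights <- function(network, targets, drivers, pathway_genes,
                                 mode = c("analytic", "permute_network"),
                                 n_perm = 1000, seed = NULL) {
  mode <- match.arg(mode)
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else as.list(seed + 0:2)
  z1 <- nea_z(network, targets, drivers, mode, n_perm, seeds[[1]])$z
  z2 <- nea_z(network, drivers, pathway_genes, mode, n_perm, seeds[[2]])$z
  z3 <- nea_z(network, targets, pathway_genes, mode, n_perm, seeds[[3]])$z
  weights_from_z(z1, z2, z3)
}
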