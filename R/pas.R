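# Pathway activation score (PAS): partition the pathway genes around the
# drug's targets using directed-network reachability, sum expression over
# each side, and weight by the connectivity factor 1 + w1 + w2 + w3.

#' Split pathway genes into upstream and downstream sets
#'
#' `G_u` contains the drug targets that are pathway members plus every
#' pathway gene with a directed path into some target (unbounded depth);
#' `G_d` contains the pathway genes reachable from some target that are not
#' already in `G_u` (so on cycles the target side takes precedence).
#' Pathway genes reachable in neither direction (including genes absent
#' from the directed network) are assigned per `unreached_policy`.
#'
#' @param pathway_genes character vector of pathway member genes.
#' @param targets character vector of drug target genes (need not be
#'   pathway members; out-of-pathway targets still anchor reachability).
#' @param directed directed `igraph` regulatory network
#'   (see [directed_network()]).
#' @param unreached_policy `"downstream"` (default: unreachable genes join
#'   `G_d`, the conservative choice since they cannot be argued to feed the
#'   targets) or `"exclude"`.
#' @param max_depth maximum path length considered (default `Inf`,
#'   i.e. full transitive closure).
#' @return Object of class `pathway_partition`: list with `g_u`, `g_d`,
#'   `targets`, `unreached` (the genes the policy acted on) and a
#'   `disconnected` flag. Errors if the partition would leave `G_u` empty
#'   (no target in the pathway and no pathway gene upstream of a target).
#' @export
partition_pathway <- function(pathway_genes, targets, directed,
                              unreached_policy = c("downstream", "exclude"),
                              max_depth = Inf) {
  unreached_policy <- match.arg(unreached_policy)
  pathway_genes <- unique(as.character(pathway_genes))
  targets <- unique(as.character(targets))
  if (!length(pathway_genes)) stop("empty pathway gene set")
  if (!length(targets)) stop("empty drug target set")
  stopifnot(igraph::is_igraph(directed), igraph::is_directed(directed))

  vn <- igraph::V(directed)$name
  t_in_net <- intersect(targets, vn)
  anc <- desc <- character(0)
  if (length(t_in_net)) {
    order <- if (is.finite(max_depth)) max_depth else igraph::vcount(directed)
    nb_in <- igraph::ego(directed, order = order, nodes = t_in_net,
                         mode = "in")
    nb_out <- igraph::ego(directed, order = order, nodes = t_in_net,
                          mode = "out")
    anc <- unique(unlist(lapply(nb_in, names)))
    desc <- unique(unlist(lapply(nb_out, names)))
  }
  g_u <- union(intersect(targets, pathway_genes),
               intersect(pathway_genes, anc))
  g_d <- setdiff(intersect(pathway_genes, desc), g_u)
  unreached <- setdiff(pathway_genes, union(g_u, g_d))
  disconnected <- length(g_u) == 0L
  if (disconnected) {
    stop("pathway is disconnected from the drug targets: ",
         "no target is a pathway member and no pathway gene reaches a target")
  }
  if (unreached_policy == "downstream") {
    g_d <- union(g_d, unreached)
  }
  structure(
    list(g_u = g_u, g_d = g_d, targets = targets, unreached = unreached,
         unreached_policy = unreached_policy, disconnected = disconnected),
    class = "pathway_partition"
  )
}

#' @export
print.pathway_partition <- function(x, ...) {
  cat(sprintf(
    "<pathway_partition> |G_u| = %d, |G_d| = %d (%d unreached -> %s)\n",
    length(x$g_u), length(x$g_d), length(x$unreached), x$unreached_policy))
  invisible(x)
}

#' Sum expression of a gene set in one sample
#'
#' Genes missing from the cohort's expression rows are dropped (logged);
#' the empty set sums to 0.
#'
#' @param x a [cohort()] object.
#' @param sample sample identifier present in the cohort.
#' @param genes character vector of gene symbols.
#' @return Nonnegative scalar sum.
#' @export
expression_sum <- function(x, sample, genes) {
  stopifnot(inherits(x, "dcsp_cohort"))
  if (!sample %in% colnames(x$expression)) {
    stop("unknown sample: ", sample)
  }
  g <- intersect(unique(as.character(genes)), rownames(x$expression))
  if (length(g) < length(unique(genes))) {
    dcsp_log(length(unique(genes)) - length(g),
             " gene(s) not in expression matrix dropped from sum")
  }
  if (!length(g)) return(0)
  sum(x$expression[g, sample])
}

#' Per-sample PAS records for one drug-pathway partition
#'
#' For each sample, `S_u` and `S_d` are the expression sums over `G_u` and
#' `G_d`; `PAS_u = S_u * (1 + w1 + w2 + w3)`, `PAS_d` likewise, and the
#' signed score is `PAS = PAS_u - PAS_d` (its negation is the
#' downstream-activation variant).
#'
#' @param x a [cohort()] object.
#' @param partition a [partition_pathway()] result.
#' @param weights a [weights_from_z()] / [connectivity_weights()] result.
#' @param samples samples to score (default: all cohort samples).
#' @param drug,pathway identifier strings carried into the output.
#' @return data.frame with one row per sample: `sample`, `cancer`, `drug`,
#'   `pathway`, `s_u`, `s_d`, `pas_u`, `pas_d`, `pas`.
#' @export
compute_pas <- function(x, partition, weights,
                        samples = colnames(x$expression),
                        drug = NA_character_, pathway = NA_character_) {
  stopifnot(inherits(x, "dcsp_cohort"),
            inherits(partition, "pathway_partition"),
            inherits(weights, "connectivity_weights"))
  ws <- c(weights$w1, weights$w2, weights$w3)
  if (any(ws < 0 | ws > 1)) stop("weights must lie in [0, 1]")
  unknown <- setdiff(samples, colnames(x$expression))
  if (length(unknown)) stop("unknown sample: ", unknown[1])
  expr <- x$expression
  gu <- intersect(partition$g_u, rownames(expr))
  gd <- intersect(partition$g_d, rownames(expr))
  if (!length(gu) && !length(gd)) {
    stop("neither G_u nor G_d has genes in the expression matrix")
  }
  s_u <- if (length(gu)) {
    colSums(expr[gu, samples, drop = FALSE])
  } else {
    structure(numeric(length(samples)), names = samples)
  }
  s_d <- if (length(gd)) {
    colSums(expr[gd, samples, drop = FALSE])
  } else {
    structure(numeric(length(samples)), names = samples)
  }
  fac <- weights$factor
  data.frame(
    sample = samples,
    cancer = unname(x$labels[samples]),
    drug = drug,
    pathway = pathway,
    s_u = unname(s_u),
    s_d = unname(s_d),
    pas_u = unname(s_u * fac),
    pas_d = unname(s_d * fac),
    pas = unname((s_u - s_d) * fac),
    stringsAsFactors = FALSE
  )
}

#' PAS table over all samples, drugs and pathways
#'
#' For each (drug, pathway) pair: one pathway partition; for each cancer,
#' one set of connectivity weights computed against that cancer's driver
#' genes (z-scores are cached across pairs sharing a gene-set pair); PAS
#' records for all samples of that cancer. Pairs whose partition or
#' scoring fails are skipped and recorded, not fatal.
#'
#' @param x a [cohort()] object.
#' @param pathways a [pathway_db()].
#' @param drug_targets a [drug_target_map()].
#' @param drivers a [driver_set()] keyed by cancer code.
#' @param directed directed regulatory `igraph` network.
#' @param functional undirected functional `igraph` network.
#' @param nea_mode,n_perm,seed NEA null model options
#'   (see [null_link_distribution()]); with the permutation null, `seed`
#'   makes the whole table deterministic.
#' @param unreached_policy passed to [partition_pathway()].
#' @return data.frame of PAS records (columns as in [compute_pas()]) with
#'   attribute `"skipped"`: a data.frame of skipped (drug, pathway) pairs
#'   and reasons.
#' @export
pas_matrix <- function(x, pathways, drug_targets, drivers,
                       directed, functional,
                       nea_mode = c("analytic", "permute_network"),
                       n_perm = 1000, seed = NULL,
                       unreached_policy = "downstream") {
  nea_mode <- match.arg(nea_mode)
  stopifnot(inherits(x, "dcsp_cohort"))
  cancers <- unique(x$labels)
  samples_by_cancer <- split(names(x$labels), x$labels)

  z_cache <- new.env(parent = emptyenv())
  n_nea <- 0L
  cached_z <- function(key, set_a, set_b) {
    if (!is.null(z_cache[[key]])) return(z_cache[[key]])
    n_nea <<- n_nea + 1L
    s <- if (is.null(seed)) NULL else seed + n_nea
    z <- nea_z(functional, set_a, set_b, mode = nea_mode,
               n_perm = n_perm, seed = s)$z
    z_cache[[key]] <- z
    z
  }

  out <- list()
  skipped <- list()
  for (di in names(drug_targets)) {
    tg <- drug_targets[[di]]
    for (pj in names(pathways)) {
      pg <- pathways[[pj]]
      part <- tryCatch(
        partition_pathway(pg, tg, directed,
                          unreached_policy = unreached_policy),
        error = function(e) e
      )
      if (inherits(part, "error")) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(drug = di, pathway = pj,
                     reason = conditionMessage(part),
                     stringsAsFactors = FALSE)
        next
      }
      for (cz in cancers) {
        dz <- drivers[[cz]] %||% character(0)
        res <- tryCatch({
          z1 <- cached_z(paste0("z1\r", di, "\r", cz), tg, dz)
          z2 <- cached_z(paste0("z2\r", cz, "\r", pj), dz, pg)
          z3 <- cached_z(paste0("z3\r", di, "\r", pj), tg, pg)
          w <- weights_from_z(z1, z2, z3)
          compute_pas(x, part, w, samples = samples_by_cancer[[cz]],
                      drug = di, pathway = pj)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          skipped[[length(skipped) + 1L]] <-
            data.frame(drug = di, pathway = pj,
                       reason = paste0(cz, ": ", conditionMessage(res)),
                       stringsAsFactors = FALSE)
        } else {
          out[[length(out) + 1L]] <- res
        }
      }
    }
  }
  if (!length(out)) stop("no (drug, pathway) pair could be scored")
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  skipped <- if (length(skipped)) {
    do.call(rbind, skipped)
  } else {
    data.frame(drug = character(0), pathway = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  }
  if (nrow(skipped)) {
    dcsp_log(nrow(skipped), " (drug, pathway[, cancer]) combination(s) skipped")
  }
  attr(tab, "skipped") <- skipped
  tab
}
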