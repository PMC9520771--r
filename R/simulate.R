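# Synthetic cohort generator. Emulates the structure the method assumes:
# several cancer groups of modest size, log-normal (TPM-like) expression
# with a planted upstream-pathway upshift in one cancer, directed chains
# placing drug targets mid-pathway, a functional network with enriched
# driver-target-pathway connectivity for planted triplets, and AUC
# linearly coupled (negatively) to the planted activation.

#' One planted (drug, pathway, cancer) activation signal
#'
#' @param drug,pathway,cancer identifiers (must exist in the simulated
#'   universe, e.g. `"D1"`, `"PW1"`, `"C1"`).
#' @param delta upshift of the upstream pathway genes in the planted
#'   cancer, in within-cancer SD units of log-expression.
#' @return One-row data.frame suitable for the `planted` field of
#'   [sim_config()].
#' @export
planted_triplet <- function(drug = "D1", pathway = "PW1", cancer = "C1",
                            delta = 3) {
  data.frame(drug = drug, pathway = pathway, cancer = cancer,
             delta = delta, stringsAsFactors = FALSE)
}

#' Configuration for the synthetic cohort simulator
#'
#' Defaults describe the compact study conditions used throughout the
#' package's tests: 6 cancers of 12 samples each (within the 6-64 range of
#' real pan-cancer drug panels), 4 drugs x 5 pathways = 20 drug-pathway
#' pairs, disjoint 10-gene pathways inside a 400-gene genome, log-normal
#' baseline expression, and an Erdos-Renyi functional network.
#'
#' @param n_cancers number of cancer groups (>= 3).
#' @param samples_per_cancer scalar or length-`n_cancers` vector.
#' @param n_genes total genes (>= `n_pathways * pathway_size`).
#' @param n_pathways,pathway_size pathway count and size
#'   (`pathway_size >= 3` so both pathway halves are nonempty).
#' @param n_drugs,targets_per_drug drug count and targets per drug.
#' @param n_drivers_per_cancer driver genes per cancer.
#' @param planted data.frame of planted signals (see [planted_triplet()]),
#'   or `NULL` for a pure-null cohort.
#' @param response_slope coupling `beta >= 0` between standardized planted
#'   activation and AUC (`AUC = baseline - beta * z(S_u) + noise` for the
#'   planted drug in the planted cancer); 0 decouples response from PAS.
#' @param noise_sd SD of the AUC noise.
#' @param auc_baseline mean AUC away from planted signals.
#' @param baseline_meanlog,meanlog_sd,baseline_sdlog log-normal expression
#'   parameters: per-gene log-means are drawn from
#'   `N(baseline_meanlog, meanlog_sd)` and log-expression has within-group
#'   SD `baseline_sdlog`.
#' @param network_density edge probability of the background functional
#'   network.
#' @param seed RNG seed; a fixed seed makes the full output deterministic.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_cancers = 6, samples_per_cancer = 12,
                       n_genes = 400, n_pathways = 5, pathway_size = 10,
                       n_drugs = 4, targets_per_drug = 1,
                       n_drivers_per_cancer = 3,
                       planted = NULL,
                       response_slope = 1, noise_sd = 1, auc_baseline = 10,
                       baseline_meanlog = 2, meanlog_sd = 0.5,
                       baseline_sdlog = 0.5,
                       network_density = 0.02, seed = 1) {
  cfg <- list(
    n_cancers = as.integer(n_cancers),
    samples_per_cancer = as.integer(samples_per_cancer),
    n_genes = as.integer(n_genes),
    n_pathways = as.integer(n_pathways),
    pathway_size = as.integer(pathway_size),
    n_drugs = as.integer(n_drugs),
    targets_per_drug = as.integer(targets_per_drug),
    n_drivers_per_cancer = as.integer(n_drivers_per_cancer),
    planted = planted,
    response_slope = response_slope, noise_sd = noise_sd,
    auc_baseline = auc_baseline,
    baseline_meanlog = baseline_meanlog, meanlog_sd = meanlog_sd,
    baseline_sdlog = baseline_sdlog,
    network_density = network_density,
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_cancers < 3) stop("need at least 3 cancers")
    if (pathway_size < 3) stop("pathway_size must be >= 3")
    if (n_pathways * pathway_size > n_genes) {
      stop("n_genes too small for the requested pathways")
    }
    if (!length(samples_per_cancer) %in% c(1L, n_cancers) ||
        any(samples_per_cancer < 2)) {
      stop("samples_per_cancer must be a positive scalar or per-cancer vector")
    }
    if (any(c(n_drugs, targets_per_drug, n_drivers_per_cancer) < 1)) {
      stop("counts must be positive")
    }
    if (response_slope < 0 || noise_sd < 0) {
      stop("response_slope and noise_sd must be >= 0")
    }
    if (network_density <= 0 || network_density >= 1) {
      stop("network_density must lie in (0, 1)")
    }
  })
  if (!is.null(cfg$planted)) {
    cfg$planted <- as.data.frame(cfg$planted, stringsAsFactors = FALSE)
    need_cols(cfg$planted, c("drug", "pathway", "cancer", "delta"),
              "planted table")
    ids <- list(
      drug = paste0("D", seq_len(cfg$n_drugs)),
      pathway = paste0("PW", seq_len(cfg$n_pathways)),
      cancer = paste0("C", seq_len(cfg$n_cancers))
    )
    for (f in names(ids)) {
      bad <- setdiff(cfg$planted[[f]], ids[[f]])
      if (length(bad)) {
        stop("planted ", f, " not in the simulated universe: ",
             paste(bad, collapse = ", "))
      }
    }
    if (anyDuplicated(cfg$planted$drug)) {
      stop("at most one planted signal per drug")
    }
    if (!all(is.finite(cfg$planted$delta))) stop("planted deltas must be finite")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a full synthetic study
#'
#' Generates every input the pipeline needs -- cohort, pathway database,
#' drug targets, per-cancer drivers, directed and functional networks,
#' drug-response table -- plus a truth table of the planted signals.
#'
#' Construction:
#' * Expression: per gene `g`, `log(x) ~ N(mu_g, sdlog)` i.i.d. across
#'   samples; for each planted triplet the upstream genes of the planted
#'   pathway gain `delta * sdlog` on the log scale in the planted cancer
#'   only.
#' * Directed network: each pathway's genes form a chain
#'   `p1 -> ... -> pS`; every drug's primary target is tapped into every
#'   pathway at a drug-specific anchor depth `a`
#'   (`p(a) -> target -> p(a+1)`), so all drug-pathway partitions have
#'   nonempty `G_u` and `G_d`. A planted drug anchors mid-pathway
#'   (`a = floor(S/2)`) and its primary target is the next pathway gene
#'   `p(a+1)` itself; other drugs anchor at half that depth, which places
#'   the planted upshift evenly across their `G_u`/`G_d` split and leaves
#'   their triplets mean-null.
#' * Functional network: Erdos-Renyi background; for planted triplets the
#'   driver-target, driver-pathway and target-pathway links are added
#'   explicitly so all three connectivity weights exceed 0.5.
#' * Response: `AUC = baseline + noise` everywhere, except the planted
#'   drug in the planted cancer where
#'   `AUC = baseline - response_slope * z(S(G_u)) + noise`.
#'
#' @param config a [sim_config()].
#' @return List of class `dcsp_simulation` with elements `cohort`,
#'   `pathways`, `drug_targets`, `drivers`, `directed`, `functional`,
#'   `response`, `truth` (data.frame of planted facts, zero rows for a
#'   null cohort) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    cancers <- paste0("C", seq_len(cfg$n_cancers))
    sizes <- rep(cfg$samples_per_cancer, length.out = cfg$n_cancers)
    samples <- unlist(lapply(seq_len(cfg$n_cancers), function(i) {
      sprintf("%s_S%02d", cancers[i], seq_len(sizes[i]))
    }))
    labels <- structure(rep(cancers, sizes), names = samples)
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))

    pw_names <- paste0("PW", seq_len(cfg$n_pathways))
    pw <- lapply(seq_len(cfg$n_pathways), function(k) {
      genes[((k - 1) * cfg$pathway_size + 1):(k * cfg$pathway_size)]
    })
    names(pw) <- pw_names
    pathway_genes <- unlist(pw, use.names = FALSE)
    background <- setdiff(genes, pathway_genes)
    h <- floor(cfg$pathway_size / 2)

    drugs <- paste0("D", seq_len(cfg$n_drugs))
    planted <- cfg$planted
    targets <- vector("list", cfg$n_drugs)
    names(targets) <- drugs
    pool <- sample(background)
    pool_i <- 1L
    take_background <- function(k) {
      if (pool_i + k - 1L > length(pool)) stop("not enough background genes")
      g <- pool[pool_i:(pool_i + k - 1L)]
      pool_i <<- pool_i + k
      g
    }
    for (d in drugs) {
      prow <- if (!is.null(planted)) planted[planted$drug == d, ] else NULL
      if (!is.null(prow) && nrow(prow)) {
        primary <- pw[[prow$pathway[1]]][h + 1]
        extra <- if (cfg$targets_per_drug > 1) {
          take_background(cfg$targets_per_drug - 1L)
        } else character(0)
        targets[[d]] <- c(primary, extra)
      } else {
        targets[[d]] <- take_background(cfg$targets_per_drug)
      }
    }

    # directed regulatory network: full intra-pathway chains plus
    # drug-specific anchor taps p[a] -> target -> p[a+1]
    planted_drugs <- if (!is.null(planted)) planted$drug else character(0)
    anchor_of <- function(d) {
      if (d %in% planted_drugs) h else max(1L, floor((h + 1) / 2))
    }
    from <- to <- character(0)
    for (pj in pw_names) {
      p <- pw[[pj]]
      s <- length(p)
      from <- c(from, p[1:(s - 1)])
      to <- c(to, p[2:s])
      for (d in drugs) {
        a <- anchor_of(d)
        t1 <- targets[[d]][1]
        if (t1 != p[a]) {
          from <- c(from, p[a]); to <- c(to, t1)
        }
        if (a + 1 <= s && t1 != p[a + 1]) {
          from <- c(from, t1); to <- c(to, p[a + 1])
        }
      }
    }
    directed <- directed_network(data.frame(from = from, to = to,
                                            stringsAsFactors = FALSE))

    # expression: log-normal baseline, planted upshift on the log scale.
    # Genes within a pathway share one baseline abundance (a co-regulated
    # module expresses at a comparable level); background genes vary
    # gene by gene. This keeps the up/downstream halves of a pathway
    # exchangeable, so a planted upshift creates a signal only for the
    # planted drug's partition.
    mu <- stats::rnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$meanlog_sd)
    names(mu) <- genes
    mu_pw <- stats::rnorm(cfg$n_pathways, cfg$baseline_meanlog,
                          cfg$meanlog_sd)
    for (k in seq_len(cfg$n_pathways)) mu[pw[[k]]] <- mu_pw[k]
    logx <- matrix(
      stats::rnorm(cfg$n_genes * length(samples), mean = mu,
                   sd = cfg$baseline_sdlog),
      nrow = cfg$n_genes, ncol = length(samples),
      dimnames = list(genes, samples)
    )
    truth_rows <- list()
    if (!is.null(planted) && nrow(planted)) {
      for (i in seq_len(nrow(planted))) {
        pj <- planted$pathway[i]
        cz <- planted$cancer[i]
        d <- planted$drug[i]
        delta <- planted$delta[i]
        gu <- c(pw[[pj]][seq_len(h)], targets[[d]][1])
        gu <- intersect(unique(gu), genes)
        cz_samples <- samples[labels == cz]
        logx[gu, cz_samples] <- logx[gu, cz_samples] +
          delta * cfg$baseline_sdlog
        truth_rows[[i]] <- data.frame(
          drug = d, pathway = pj, cancer = cz, delta = delta,
          target = targets[[d]][1],
          shifted_genes = paste(gu, collapse = ","),
          response_slope = cfg$response_slope,
          stringsAsFactors = FALSE)
      }
    }
    expr <- exp(logx)
    co <- cohort(expr, labels, name = "simulated")

    # drivers: background genes, disjoint from target pool
    drivers <- lapply(cancers, function(cz) take_background(
      cfg$n_drivers_per_cancer))
    names(drivers) <- cancers

    # functional network: ER background + planted connectivity
    g_bg <- igraph::sample_gnp(cfg$n_genes, cfg$network_density,
                               directed = FALSE)
    igraph::V(g_bg)$name <- genes
    el <- igraph::as_edgelist(g_bg, names = TRUE)
    fa <- el[, 1]; fb <- el[, 2]
    if (!is.null(planted) && nrow(planted)) {
      for (i in seq_len(nrow(planted))) {
        dz <- drivers[[planted$cancer[i]]]
        tg <- targets[[planted$drug[i]]][1]
        pg <- pw[[planted$pathway[i]]]
        fa <- c(fa, rep(dz, each = 1 + length(pg)), rep(tg, length(pg)))
        fb <- c(fb, as.vector(vapply(dz, function(z) c(tg, pg),
                                     character(1 + length(pg)))), pg)
        # balance driver degrees: the enrichment raises the planted
        # cancer's driver degrees, which would depress its NEA z-scores
        # against every *other* pathway (the degree-based null grows);
        # give the remaining cancers' drivers the same number of extra
        # links to background genes so degrees stay comparable
        n_extra <- 1 + length(pg)
        decoy_pool <- setdiff(background, unlist(drivers))
        for (cz in setdiff(cancers, planted$cancer[i])) {
          for (z in drivers[[cz]]) {
            fa <- c(fa, rep(z, n_extra))
            fb <- c(fb, sample(setdiff(decoy_pool, z), n_extra))
          }
        }
      }
    }
    functional <- functional_network(data.frame(a = fa, b = fb,
                                                stringsAsFactors = FALSE))

    # drug response
    resp <- expand.grid(sample = samples, drug = drugs,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    resp$auc <- cfg$auc_baseline +
      stats::rnorm(nrow(resp), 0, cfg$noise_sd)
    if (!is.null(planted) && nrow(planted) && cfg$response_slope > 0) {
      for (i in seq_len(nrow(planted))) {
        cz <- planted$cancer[i]
        d <- planted$drug[i]
        gu <- strsplit(truth_rows[[i]]$shifted_genes, ",")[[1]]
        cz_samples <- samples[labels == cz]
        su <- colSums(expr[gu, cz_samples, drop = FALSE])
        zs <- if (stats::sd(su) > 0) (su - mean(su)) / stats::sd(su) else su * 0
        sel <- resp$drug == d & resp$sample %in% cz_samples
        resp$auc[sel] <- resp$auc[sel] -
          cfg$response_slope * zs[resp$sample[sel]]
      }
    }
    resp$auc <- pmax(resp$auc, 0)

    structure(
      list(
        cohort = co,
        pathways = pathway_db(pw),
        drug_targets = drug_target_map(targets),
        drivers = driver_set(drivers, cancers),
        directed = directed,
        functional = functional,
        response = drug_response_table(resp),
        truth = if (length(truth_rows)) {
          do.call(rbind, truth_rows)
        } else {
          data.frame(drug = character(0), pathway = character(0),
                     cancer = character(0), delta = numeric(0),
                     target = character(0), shifted_genes = character(0),
                     response_slope = numeric(0), stringsAsFactors = FALSE)
        },
        config = cfg
      ),
      class = "dcsp_simulation"
    )
  })
}

#' @export
print.dcsp_simulation <- function(x, ...) {
  cat(sprintf(
    "<dcsp_simulation> %d cancers, %d samples, %d genes, %d drugs x %d pathways, %d planted signal(s)\n",
    x$config$n_cancers, ncol(x$cohort$expression),
    nrow(x$cohort$expression), x$config$n_drugs, x$config$n_pathways,
    nrow(x$truth)))
  invisible(x)
}

#' Write all simulated inputs as the pipeline's text formats
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of written file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "dcsp_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.tsv"),
    pathways = file.path(dir, "pathways.gmt"),
    targets = file.path(dir, "drug_targets.tsv"),
    drivers = file.path(dir, "drivers.tsv"),
    directed = file.path(dir, "directed_network.tsv"),
    functional = file.path(dir, "functional_network.tsv"),
    response = file.path(dir, "drug_response.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_cohort(sim$cohort, paths["expression"], paths["labels"])
  write_gmt(sim$pathways, paths["pathways"])
  write_drug_targets_tsv(sim$drug_targets, paths["targets"])
  write_drivers_tsv(sim$drivers, paths["drivers"])
  write_network_tsv(sim$directed, paths["directed"])
  write_network_tsv(sim$functional, paths["functional"])
  write_response_tsv(sim$response, paths["response"])
  write_tsv_df(sim$truth, paths["truth"])
  invisible(paths)
}
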