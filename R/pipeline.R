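# Pipeline orchestration: run simulate -> pas -> screen -> correlate ->
# permtest from a single structured config, writing stage TSVs and a run
# manifest with digests so identical configs reproduce identical outputs.

default_pipeline_config <- function() {
  list(
    seed = 1,
    pas = list(nea_mode = "analytic", n_perm = 1000,
               unreached_policy = "downstream"),
    screen = list(fdr = 0.01, t2_quartile = 0.25, min_samples = 6,
                  min_cancers = 3, trim = 0.1, family = "per_cancer",
                  t2_scope = "fdr_pass"),
    correlate = list(direction = "upstream", positive_only = TRUE),
    permtest = list(enabled = TRUE, n_perm = 10000)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]] %||% NULL)) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Validate a pipeline configuration
#'
#' A config must provide either a `simulate` block (arguments for
#' [sim_config()]) or an `inputs` block with paths `expression`, `labels`,
#' `pathways`, `targets`, `drivers`, `directed`, `functional`
#' (`response` optional). Unknown stage options fall back to defaults.
#'
#' @param config named list, or path to a YAML file.
#' @return The merged, validated config list.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  cfg <- merge_config(default_pipeline_config(), config)
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    stop("config field missing: provide either `simulate` or `inputs` ",
         "(with `inputs.expression` etc.)")
  }
  if (!is.null(cfg$inputs)) {
    required <- c("expression", "labels", "pathways", "targets",
                  "drivers", "directed", "functional")
    miss <- setdiff(required, names(cfg$inputs))
    if (length(miss)) {
      stop("config field missing: inputs.", miss[1])
    }
  }
  if (is.null(cfg$seed)) stop("config field missing: seed")
  cfg
}

load_pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (!is.null(sim_args$planted)) {
      sim_args$planted <- as.data.frame(
        do.call(rbind, lapply(sim_args$planted, function(p) {
          if (is.list(p)) as.data.frame(p, stringsAsFactors = FALSE) else p
        })), stringsAsFactors = FALSE)
    }
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    sim <- simulate_cohort(do.call(sim_config, sim_args))
    list(cohort = sim$cohort, pathways = sim$pathways,
         drug_targets = sim$drug_targets, drivers = sim$drivers,
         directed = sim$directed, functional = sim$functional,
         response = sim$response, truth = sim$truth, files = NULL)
  } else {
    ip <- cfg$inputs
    co <- read_cohort(ip$expression, ip$labels)
    list(
      cohort = co,
      pathways = read_gmt(ip$pathways),
      drug_targets = read_drug_targets_tsv(ip$targets),
      drivers = read_drivers_tsv(ip$drivers, unique(co$labels)),
      directed = read_network_tsv(ip$directed, directed = TRUE),
      functional = read_network_tsv(ip$functional, directed = FALSE),
      response = if (!is.null(ip$response)) {
        read_response_tsv(ip$response)
      },
      truth = NULL,
      files = unlist(ip)
    )
  }
}

#' Run the full DCSP pipeline
#'
#' Executes simulate (or load) -> PAS -> screen -> correlate -> permtest,
#' writing `pas.tsv`, `dcsp.tsv`, `correlations.tsv`, `permtest.tsv` and
#' `manifest.json` into `out_dir`. Stages after a failure are skipped but
#' completed stage outputs are kept; the manifest records the failure.
#'
#' @param config named list or YAML path (see
#'   [validate_pipeline_config()]).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the stage results (`pas`, `screen`,
#'   `correlations`, `permtest`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- load_pipeline_inputs(cfg)
  results <- list()
  failure <- NULL

  run_stage <- function(name, fun) {
    if (!is.null(failure)) return(NULL)
    out <- tryCatch(fun(), error = function(e) e)
    if (inherits(out, "error")) {
      failure <<- paste0(name, ": ", conditionMessage(out))
      dcsp_log("stage ", name, " failed: ", conditionMessage(out))
      NULL
    } else {
      out
    }
  }

  results$pas <- run_stage("pas", function() {
    tab <- pas_matrix(
      inputs$cohort, inputs$pathways, inputs$drug_targets, inputs$drivers,
      inputs$directed, inputs$functional,
      nea_mode = cfg$pas$nea_mode, n_perm = cfg$pas$n_perm,
      seed = cfg$seed, unreached_policy = cfg$pas$unreached_policy)
    write_tsv_df(tab, file.path(out_dir, "pas.tsv"))
    tab
  })

  results$screen <- run_stage("screen", function() {
    scr <- dcsp_screen(
      results$pas, fdr_threshold = cfg$screen$fdr,
      t2_quartile = cfg$screen$t2_quartile,
      min_samples = cfg$screen$min_samples,
      min_cancers = cfg$screen$min_cancers, trim = cfg$screen$trim,
      family = cfg$screen$family, t2_scope = cfg$screen$t2_scope)
    write_tsv_df(scr, file.path(out_dir, "dcsp.tsv"))
    scr
  })

  if (!is.null(inputs$response)) {
    results$correlations <- run_stage("correlate", function() {
      scr <- results$screen
      elig <- scr[scr$eligible, , drop = FALSE]
      rows <- lapply(seq_len(nrow(elig)), function(i) {
        rec <- results$pas[
          results$pas$drug == elig$drug[i] &
            results$pas$pathway == elig$pathway[i] &
            results$pas$cancer == elig$cancer[i], , drop = FALSE]
        out <- pas_response_correlation(
          rec, inputs$response,
          direction = cfg$correlate$direction,
          positive_only = cfg$correlate$positive_only)
        out$is_dcsp <- elig$is_dcsp[i]
        out
      })
      tab <- do.call(rbind, rows)
      write_tsv_df(tab, file.path(out_dir, "correlations.tsv"))
      tab
    })

    results$permtest <- run_stage("permtest", function() {
      if (!isTRUE(cfg$permtest$enabled)) return(NULL)
      scr <- results$screen
      hits <- scr[scr$is_dcsp, , drop = FALSE]
      if (!nrow(hits)) {
        hits <- scr[scr$eligible, , drop = FALSE]
        if (!nrow(hits)) return(NULL)
      }
      top <- hits[order(-hits$T1), , drop = FALSE][1, ]
      ptab <- results$pas[results$pas$cancer == top$cancer, , drop = FALSE]
      comps <- c("other_drugs_same_pathway", "same_drug_other_pathways",
                 "other_drugs_other_pathways")
      rows <- lapply(seq_along(comps), function(k) {
        pr <- permutation_specificity_test(
          ptab, top$drug, top$pathway, comparison = comps[k],
          n_perm = cfg$permtest$n_perm, seed = cfg$seed + k)
        data.frame(drug = top$drug, pathway = top$pathway,
                   cancer = top$cancer, comparison = pr$comparison,
                   observed_t = pr$observed_t, n_perm = pr$n_perm,
                   p_empirical = pr$p_empirical, stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      write_tsv_df(tab, file.path(out_dir, "permtest.tsv"))
      tab
    })
  }

  manifest <- list(
    tool = "dcsp",
    version = as.character(utils::packageVersion("dcsp")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "inputs")],
    input_files = if (!is.null(inputs$files)) {
      as.list(tools::md5sum(inputs$files))
    },
    outputs = {
      fs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
      as.list(tools::md5sum(fs))
    },
    record_counts = lapply(
      Filter(is.data.frame, results), nrow),
    failure = failure
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  results$manifest <- manifest
  if (!is.null(failure)) warning("pipeline stage failed: ", failure)
  invisible(results)
}
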