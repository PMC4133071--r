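# Orchestration: one reproducible run from simulated (or supplied) data
# through QC, stability, efficiency, normalization and robustness, with a
# machine-readable manifest. Each output table mirrors the shape of the
# standard reporting tables for this kind of study (descriptive stats,
# stability rankings, group variation, normalization-factor SDs,
# robustness percentages, per-gene efficiencies, method correlations, and
# group summaries of normalized targets).

#' Build a pipeline run configuration
#'
#' @param seed integer seed governing every stochastic stage.
#' @param output_dir directory for all outputs.
#' @param design a [study_design()] (its seed is overridden by `seed`).
#' @param truth a [cq_truth()] or NULL for [default_cq_truth()].
#' @param qc_max_delta replicate-range QC threshold (cycles).
#' @param stability_methods,efficiency_methods method name vectors.
#' @param reference_combos list of reference-gene combinations compared as
#'   normalization factors.
#' @param norm_combos list of combos used for the normalized target
#'   tables.
#' @param norm_efficiency_methods efficiency methods used for the
#'   normalized target tables (one dataset per combo x method).
#' @param curves_per_gene simulated amplification reactions per gene.
#' @param gene_E0 named per-gene true amplification factors for curve
#'   simulation; NULL draws them uniformly in [1.82, 1.98].
#' @param robustness_per_group,robustness_n_subsets subsampling strata and
#'   subsets per stratum.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       output_dir = tempfile("qpcr_run_"),
                       design = study_design(),
                       truth = NULL,
                       qc_max_delta = 1.0,
                       stability_methods = c("deltact", "bestkeeper",
                                             "normfinder", "genorm"),
                       efficiency_methods = c("linreg", "dart",
                                              "miner", "lre"),
                       reference_combos = NULL,
                       norm_combos = NULL,
                       norm_efficiency_methods = c("linreg", "miner"),
                       curves_per_gene = 4L,
                       gene_E0 = NULL,
                       robustness_per_group = c(3L, 2L),
                       robustness_n_subsets = 25L) {
  design$seed <- as.integer(seed)
  rg <- design$reference_genes
  if (is.null(reference_combos)) {
    reference_combos <- list(rg[1], rg[2], rg[1:2], rg[1:3])
  }
  if (is.null(norm_combos)) {
    norm_combos <- list(rg[1:2], rg[length(rg)])
  }
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 design = design, truth = truth,
                 qc_max_delta = qc_max_delta,
                 stability_methods = stability_methods,
                 efficiency_methods = efficiency_methods,
                 reference_combos = reference_combos,
                 norm_combos = norm_combos,
                 norm_efficiency_methods = norm_efficiency_methods,
                 curves_per_gene = as.integer(curves_per_gene),
                 gene_E0 = gene_E0,
                 robustness_per_group = as.integer(robustness_per_group),
                 robustness_n_subsets = as.integer(robustness_n_subsets)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates a replicate-level Cq dataset and per-gene amplification
#' curves under the configured design, then runs interplate calibration,
#' replicate QC and duplicate averaging; the four stability methods and
#' the normalization-factor comparison; the four efficiency estimators
#' with per-gene aggregation; efficiency-corrected normalization of the
#' target genes with per-temperature and per-sex summaries; and the
#' subsampling robustness evaluation. All tables are written as CSV under
#' `config$output_dir` together with a JSON manifest and the serialized
#' configuration.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with every stage result plus `manifest`
#'   (named file paths).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list()
  out_csv <- function(df, name) {
    p <- file.path(config$output_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    manifest[[name]] <<- p
    p
  }
  design <- config$design
  truth <- config$truth %||% default_cq_truth(design)

  say("simulating Cq dataset (%d samples, %d genes)",
      nrow(design$groups) * design$samples_per_cell,
      length(c(design$reference_genes, design$target_genes)))
  sim <- simulate_cq_dataset(design, truth, seed = config$seed)
  out_csv(sim$records, "cq_records.csv")
  out_csv(sim$metadata, "sample_metadata.csv")

  say("preprocessing: calibration, replicate QC (max delta %.2f), averaging",
      config$qc_max_delta)
  prep <- preprocess_cq(sim$records, sim$metadata,
                        max_delta = config$qc_max_delta)
  out_csv(prep$removed, "qc_removed.csv")
  refs <- design$reference_genes
  tgts <- design$target_genes
  ref_mat <- subset_cq(prep$matrix, genes = refs)
  desc <- describe_cq(ref_mat)
  out_csv(desc, "descriptive_reference.csv")        # Table-1 shape
  if (length(tgts)) {
    out_csv(describe_cq(subset_cq(prep$matrix, genes = tgts)),
            "descriptive_target.csv")               # Table-2 shape
  }

  say("stability: %s", paste(config$stability_methods, collapse = ", "))
  stab <- stability_suite(ref_mat, methods = config$stability_methods)
  out_csv(stab$ranking_table, "stability_rankings.csv")   # Table-3 shape
  if (!is.null(stab$normfinder)) {
    out_csv(stab$normfinder$group_variation, "group_variation.csv") # T4
  }
  if (!is.null(stab$bestkeeper)) {
    r <- stab$bestkeeper$correlation$r
    out_csv(data.frame(gene = rownames(r), round(r, 3)),
            "gene_correlations.csv")
  }
  nf_tab <- compare_normalization_factors(
    subset_cq(prep$matrix, genes = refs),
    targets = if (length(tgts)) subset_cq(prep$matrix, genes = tgts)
              else NULL,
    combos = config$reference_combos,
    target_genes = if (length(tgts)) tgts else NULL)
  out_csv(nf_tab, "normalization_factor_sd.csv")    # Table-5 shape

  genes_eff <- c(refs, tgts)
  eff_by_method <- list()
  agg <- NULL
  est <- NULL
  gene_E0 <- NULL
  if (length(config$efficiency_methods) == 0) {
    warning("no efficiency methods configured; normalization uses E = 2")
    say("efficiency stage skipped: normalization falls back to E = 2")
  } else {
  say("efficiency: simulating %d curves/gene and estimating with %s",
      config$curves_per_gene,
      paste(config$efficiency_methods, collapse = ", "))
  gene_E0 <- config$gene_E0
  if (is.null(gene_E0)) {
    gene_E0 <- with_seed(config$seed + 1L, stats::setNames(
      stats::runif(length(genes_eff), 1.82, 1.98), genes_eff))
  }
  curves <- list()
  for (gi in seq_along(genes_eff)) {
    g <- genes_eff[gi]
    df <- simulate_amp_curves(config$curves_per_gene,
                              curve_truth(E0 = gene_E0[[g]]),
                              gene = g, sample_prefix = paste0(g, "_R"),
                              seed = config$seed + 100L + gi)
    df$well <- paste0(g, "_", df$well)
    curves[[g]] <- df
  }
  curves <- do.call(rbind, curves)
  out_csv(curves, "amplification_curves.csv")
  est <- estimate_curves(curves, methods = config$efficiency_methods)
  est$true_E <- gene_E0[est$gene]
  out_csv(est, "efficiency_estimates.csv")
  agg <- aggregate_gene_efficiency(est)
  gm <- data.frame(gene = rownames(agg$gene_means),
                   round(100 * (agg$gene_means - 1), 2))
  names(gm)[-1] <- paste0(colnames(agg$gene_means), "_pct")
  out_csv(gm, "gene_efficiency.csv")                # Table-7 shape
  rr <- agg$method_correlation$r
  pp <- agg$method_correlation$p
  out_csv(data.frame(method = rownames(rr), round(rr, 3),
                     p = apply(round(pp, 4), 1, paste, collapse = "/")),
          "efficiency_method_correlation.csv")      # Table-8 shape
  mean_E <- stats::setNames(rep(2, length(genes_eff)), genes_eff)
  for (m in colnames(agg$gene_means)) {
    v <- mean_E
    hit <- intersect(names(v), rownames(agg$gene_means))
    v[hit] <- pmin(2, pmax(1.0001, agg$gene_means[hit, m]))
    eff_by_method[[m]] <- v
  }
  }

  if (length(eff_by_method) == 0) {
    eff_by_method <- list(none = stats::setNames(rep(2, length(genes_eff)),
                                                 genes_eff))
  }
  if (length(tgts)) {
    say("normalizing targets by %d combo x method datasets",
        length(config$norm_combos) * length(config$norm_efficiency_methods))
    gs_temp <- list()
    gs_sex <- list()
    norm_methods <- intersect(config$norm_efficiency_methods,
                              names(eff_by_method))
    if (length(norm_methods) == 0) norm_methods <- names(eff_by_method)
    for (combo in config$norm_combos) {
      for (m in norm_methods) {
        nrm <- normalize_targets(subset_cq(prep$matrix, genes = refs),
                                 targets = subset_cq(prep$matrix,
                                                     genes = tgts),
                                 combo = combo,
                                 efficiencies = eff_by_method[[m]],
                                 target_genes = tgts)
        tag <- sprintf("%s (%s)", paste(combo, collapse = "+"), m)
        a <- group_summary(nrm, "temperature")
        a$dataset <- tag
        gs_temp[[tag]] <- a
        b <- group_summary(nrm, "sex")
        b$dataset <- tag
        gs_sex[[tag]] <- b
      }
    }
    out_csv(do.call(rbind, gs_temp), "normalized_by_temperature.csv") # T9
    out_csv(do.call(rbind, gs_sex), "normalized_by_sex.csv")          # T10
  }

  say("robustness: %s samples/group x %d subsets",
      paste(config$robustness_per_group, collapse = "/"),
      config$robustness_n_subsets)
  rob <- robustness_summary(ref_mat,
                            methods = config$stability_methods,
                            per_group = config$robustness_per_group,
                            n_subsets = config$robustness_n_subsets,
                            seed = config$seed + 500L)
  out_csv(rob$counts, "robustness_counts.csv")
  out_csv(data.frame(method = rownames(rob$percent),
                     round(rob$percent, 1)),
          "robustness_percent.csv")                 # Table-6 shape

  cfg_path <- file.path(config$output_dir, "run_config.yaml")
  yaml::write_yaml(serialize_config(config), cfg_path)
  manifest[["run_config.yaml"]] <- cfg_path
  man_path <- file.path(config$output_dir, "manifest.json")
  manifest[["manifest.json"]] <- man_path
  jsonlite::write_json(
    list(seed = config$seed,
         dialect = list(
           ks_variant = "lilliefors",
           calibration = "per gene, replicate-level, before QC",
           genorm_ties = "remove gene later in input order",
           genorm_comparison = "final pair first (input order), then reverse exclusion",
           normfinder_input = "Cq scale, sample means removed",
           efficiency_scale = "amplification factor (1-2)"),
         files = manifest),
    man_path, auto_unbox = TRUE, pretty = TRUE)
  say("done: %d files in %s", length(manifest), config$output_dir)
  invisible(list(sim = sim, preprocess = prep, descriptive = desc,
                 stability = stab, normalization_factors = nf_tab,
                 efficiency = list(estimates = est, aggregated = agg,
                                   true_E0 = gene_E0),
                 robustness = rob, manifest = manifest, config = config))
}

# Flatten a run_config into YAML-serializable values.
serialize_config <- function(config) {
  d <- config$design
  list(seed = config$seed,
       output_dir = config$output_dir,
       design = list(ages = d$ages, temperatures = d$temperatures,
                     samples_per_cell = d$samples_per_cell,
                     reference_genes = d$reference_genes,
                     target_genes = d$target_genes,
                     replicates_per_reaction = d$replicates_per_reaction,
                     plates = d$plates, calibrators = d$calibrators),
       qc_max_delta = config$qc_max_delta,
       stability_methods = config$stability_methods,
       efficiency_methods = config$efficiency_methods,
       reference_combos = lapply(config$reference_combos, identity),
       curves_per_gene = config$curves_per_gene,
       robustness = list(per_group = config$robustness_per_group,
                         n_subsets = config$robustness_n_subsets))
}

#' One-command seeded demo run
#'
#' Simulates the default study design and runs every stage with settings
#' sized to finish in a few minutes on one CPU.
#'
#' @param seed integer seed.
#' @param output_dir output directory.
#' @param quiet suppress progress messages.
#' @return The [run_pipeline()] result, invisibly.
#' @export
run_demo <- function(seed = 1L, output_dir = tempfile("qpcr_demo_"),
                     quiet = FALSE) {
  cfg <- run_config(seed = seed, output_dir = output_dir,
                    curves_per_gene = 3L)
  run_pipeline(cfg, quiet = quiet)
}
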