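# Synthetic qPCR data: Cq datasets with a known variance structure and raw
# amplification curves with a known per-cycle efficiency model.

#' Describe a qPCR study design
#'
#' A study design records the experimental layout: the age x temperature
#' grid, how many fish are sampled per cell, the gene panels, replication,
#' and the plate/calibrator structure. The defaults reproduce a turbot
#' gonad-development layout: 8 ages (30-135 days post fertilization) x 3
#' rearing temperatures x 10 fish = 240 samples, six candidate reference
#' genes and six sex-differentiation target genes, duplicate reactions, and
#' three interplate calibrator samples run in triplicate on every plate.
#'
#' @param ages integer vector of sampling ages in days post fertilization.
#' @param temperatures character vector of rearing-temperature labels.
#' @param samples_per_cell number of fish per age x temperature cell (>= 2).
#' @param reference_genes,target_genes character vectors of gene names.
#' @param replicates_per_reaction technical replicates per sample reaction.
#' @param plates number of plates each gene's reactions are spread over.
#' @param calibrators number of interplate calibrator samples run on every
#'   plate.
#' @param calibrator_replicates replicates for each calibrator reaction.
#' @param seed integer seed used by [simulate_cq_dataset()].
#'
#' @return An object of class `study_design` (a list of the above fields
#'   plus the derived `groups` data frame with one row per age x
#'   temperature cell).
#' @export
#' @examples
#' d <- study_design()
#' nrow(d$groups)   # 24 experimental groups
study_design <- function(ages = c(30L, 45L, 60L, 75L, 90L, 105L, 120L, 135L),
                         temperatures = c("Low", "Normal", "High"),
                         samples_per_cell = 10L,
                         reference_genes = c("RPS4", "RPL17", "GAPDH",
                                             "ACTB", "UBQ", "B2M"),
                         target_genes = c("CYP19a", "AMH", "SOX9",
                                          "SOX19", "SOX17", "VASA"),
                         replicates_per_reaction = 2L,
                         plates = 6L,
                         calibrators = 3L,
                         calibrator_replicates = 3L,
                         seed = 1L) {
  if (length(ages) == 0L || length(temperatures) == 0L) {
    fail("'ages' and 'temperatures' must be non-empty")
  }
  check_number(samples_per_cell, "samples_per_cell", lower = 2)
  if (length(reference_genes) == 0L) fail("'reference_genes' must be non-empty")
  if (anyDuplicated(c(reference_genes, target_genes))) {
    fail("gene names must be unique across panels")
  }
  check_number(replicates_per_reaction, "replicates_per_reaction",
               lower = 1, upper = 3)
  check_number(plates, "plates", lower = 1)
  check_number(calibrators, "calibrators", lower = 0)
  groups <- expand.grid(age_dpf = as.integer(ages),
                        temperature = temperatures,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  groups$group <- paste(groups$age_dpf, groups$temperature, sep = "_")
  structure(list(
    ages = as.integer(ages),
    temperatures = as.character(temperatures),
    samples_per_cell = as.integer(samples_per_cell),
    reference_genes = as.character(reference_genes),
    target_genes = as.character(target_genes),
    replicates_per_reaction = as.integer(replicates_per_reaction),
    plates = as.integer(plates),
    calibrators = as.integer(calibrators),
    calibrator_replicates = as.integer(calibrator_replicates),
    seed = as.integer(seed),
    groups = groups
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "qPCR study design: %d ages x %d temperatures x %d fish = %d samples\n",
    length(x$ages), length(x$temperatures), x$samples_per_cell,
    nrow(x$groups) * x$samples_per_cell))
  cat(sprintf("  reference genes: %s\n",
              paste(x$reference_genes, collapse = ", ")))
  cat(sprintf("  target genes:    %s\n",
              paste(x$target_genes, collapse = ", ")))
  cat(sprintf("  %d replicates/reaction, %d plates, %d calibrators (x%d)\n",
              x$replicates_per_reaction, x$plates, x$calibrators,
              x$calibrator_replicates))
  invisible(x)
}

#' Ground-truth variance structure for a simulated Cq dataset
#'
#' Encodes the generative model behind [simulate_cq_dataset()]. Every Cq
#' record is built additively on the cycle (log2-quantity) scale:
#'
#'   Cq = baseline(gene) + loading(sample) + sample_effect(gene, sample)
#'        + regulation(gene, group) + sex_effect(gene, sex)
#'        + coregulation latents + plate_offset(gene, plate)
#'        + technical noise
#'
#' `loading` is shared by every gene in a sample (RNA input / RT yield
#' differences -- exactly the noise normalization is meant to remove),
#' `sample_effect` is gene-specific biological scatter, `regulation` is a
#' fixed per-group offset (a regulated gene), and technical noise is drawn
#' independently per replicate.
#'
#' @param design a [study_design()].
#' @param baseline named numeric vector, per-gene baseline Cq (cycles).
#' @param tech_sd named or scalar, per-gene technical (replicate) SD.
#' @param sample_sd named or scalar, per-gene biological sample-level SD.
#' @param loading_sd scalar SD of the shared per-sample loading effect.
#' @param plate_sd scalar SD of per-gene-per-plate offsets.
#' @param group_offsets NULL, or a gene x group numeric matrix of fixed
#'   regulation offsets (cycles); genes/groups not named default to 0.
#' @param sex_offsets NULL, or a named list `gene -> c(F = dF, M = dM)` of
#'   sex-specific offsets (cycles).
#' @param coreg NULL, or a data frame with columns `gene1`, `gene2`, `sd`:
#'   each row adds one latent N(0, sd) per-sample effect shared by the two
#'   genes (co-regulation).
#' @param fail_rate per-replicate probability of a failed reaction: half
#'   of failures are missing Cqs, half are gross outliers (1.2-3 cycle
#'   shifts). These are the records the replicate QC filter is meant to
#'   catch. Default 0 (clean data).
#'
#' @return An object of class `cq_truth`.
#' @seealso [default_cq_truth()] for turbot-gonad-like defaults.
#' @export
cq_truth <- function(design,
                     baseline,
                     tech_sd = 0.15,
                     sample_sd = 0.5,
                     loading_sd = 0.9,
                     plate_sd = 0.15,
                     group_offsets = NULL,
                     sex_offsets = NULL,
                     coreg = NULL,
                     fail_rate = 0) {
  genes <- c(design$reference_genes, design$target_genes)
  expand_gene <- function(x, name) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- stats::setNames(rep(as.numeric(x), length(genes)), genes)
    } else {
      miss <- setdiff(genes, names(x))
      if (length(miss)) fail("'%s' missing genes: %s", name,
                             paste(miss, collapse = ", "))
      x <- x[genes]
    }
    if (any(!is.finite(x))) fail("'%s' must be finite", name)
    x
  }
  baseline <- expand_gene(baseline, "baseline")
  tech_sd <- expand_gene(tech_sd, "tech_sd")
  sample_sd <- expand_gene(sample_sd, "sample_sd")
  if (any(tech_sd < 0) || any(sample_sd < 0)) fail("SDs must be >= 0")
  check_number(loading_sd, "loading_sd", lower = 0)
  check_number(plate_sd, "plate_sd", lower = 0)

  grp <- design$groups$group
  off <- matrix(0, nrow = length(genes), ncol = length(grp),
                dimnames = list(genes, grp))
  if (!is.null(group_offsets)) {
    if (is.null(rownames(group_offsets)) || is.null(colnames(group_offsets))) {
      fail("'group_offsets' needs gene rownames and group colnames")
    }
    bad <- setdiff(rownames(group_offsets), genes)
    if (length(bad)) fail("unknown genes in group_offsets: %s",
                          paste(bad, collapse = ", "))
    bad <- setdiff(colnames(group_offsets), grp)
    if (length(bad)) fail("unknown groups in group_offsets: %s",
                          paste(bad, collapse = ", "))
    off[rownames(group_offsets), colnames(group_offsets)] <- group_offsets
  }
  sx <- matrix(0, nrow = length(genes), ncol = 2,
               dimnames = list(genes, c("F", "M")))
  if (!is.null(sex_offsets)) {
    for (g in names(sex_offsets)) {
      if (!g %in% genes) fail("unknown gene in sex_offsets: %s", g)
      v <- sex_offsets[[g]]
      sx[g, names(v)] <- v
    }
  }
  if (!is.null(coreg)) {
    need <- c("gene1", "gene2", "sd")
    if (!all(need %in% names(coreg))) {
      fail("'coreg' must have columns gene1, gene2, sd")
    }
    bad <- setdiff(c(coreg$gene1, coreg$gene2), genes)
    if (length(bad)) fail("unknown genes in coreg: %s",
                          paste(unique(bad), collapse = ", "))
    if (any(coreg$sd < 0)) fail("SDs must be >= 0")
  }
  check_number(fail_rate, "fail_rate", lower = 0, upper = 1)
  structure(list(baseline = baseline, tech_sd = tech_sd,
                 sample_sd = sample_sd, loading_sd = loading_sd,
                 plate_sd = plate_sd, group_offsets = off,
                 sex_offsets = sx, coreg = coreg, fail_rate = fail_rate),
            class = "cq_truth")
}

#' Default ground truth emulating a turbot gonad dataset
#'
#' Baseline Cqs and gene-level scatter are set to the scale observed in
#' gonad panels of this kind (reference genes with mean Cq 15-22 and SD
#' 1.1-1.7; sex-differentiation targets with mean Cq 25-32 and much larger,
#' partly sex-driven variation). B2M carries temperature-linked regulation
#' offsets (the "unstable reference" of the panel), RPS4/UBQ/GAPDH/RPL17
#' share a co-regulation latent on top of the common loading effect, and
#' the targets carry strong sex offsets (CYP19a high in females) plus
#' temperature regulation. VASA shares a latent with B2M so that
#' normalizing VASA by B2M artificially shrinks its spread.
#'
#' @param design a [study_design()].
#' @return A [cq_truth()] object.
#' @export
default_cq_truth <- function(design) {
  ref_base <- c(RPS4 = 21.2, RPL17 = 18.4, GAPDH = 20.2,
                ACTB = 15.9, UBQ = 18.3, B2M = 19.5)
  tgt_base <- c(CYP19a = 31.9, AMH = 26.3, SOX9 = 24.8,
                SOX19 = 26.6, SOX17 = 29.4, VASA = 26.2)
  genes <- c(design$reference_genes, design$target_genes)
  baseline <- stats::setNames(rep(20, length(genes)), genes)
  known <- c(ref_base, tgt_base)
  hit <- intersect(genes, names(known))
  baseline[hit] <- known[hit]

  sample_sd <- stats::setNames(rep(0.6, length(genes)), genes)
  ref_ssd <- c(RPS4 = 0.55, RPL17 = 0.75, GAPDH = 0.95,
               ACTB = 0.75, UBQ = 0.45, B2M = 1.05)
  tgt_ssd <- c(CYP19a = 2.0, AMH = 1.6, SOX9 = 1.0,
               SOX19 = 1.8, SOX17 = 1.5, VASA = 1.9)
  known <- c(ref_ssd, tgt_ssd)
  hit <- intersect(genes, names(known))
  sample_sd[hit] <- known[hit]

  grp <- design$groups
  off <- NULL
  sexo <- NULL
  cor_pairs <- NULL
  if ("B2M" %in% genes) {
    # temperature-regulated reference: monotone offset across temperatures
    b2m <- stats::setNames(rep(0, nrow(grp)), grp$group)
    temp_eff <- c(Low = -0.6, Normal = 0, High = 0.6)
    present <- grp$temperature %in% names(temp_eff)
    b2m[present] <- temp_eff[grp$temperature[present]]
    off <- matrix(b2m, nrow = 1, dimnames = list("B2M", grp$group))
  }
  tgt_temp <- c(CYP19a = 1.2, AMH = -1.0, SOX9 = 0.5,
                SOX19 = 0.8, SOX17 = 0.6, VASA = 0.7)
  for (g in intersect(names(tgt_temp), genes)) {
    v <- stats::setNames(rep(0, nrow(grp)), grp$group)
    temp_eff <- c(Low = -1, Normal = 0, High = 1) * tgt_temp[[g]]
    present <- grp$temperature %in% names(temp_eff)
    v[present] <- temp_eff[grp$temperature[present]]
    off <- rbind(off, matrix(v, nrow = 1, dimnames = list(g, grp$group)))
  }
  tgt_sex <- list(CYP19a = c(F = -3.5, M = 3.5), AMH = c(F = 1.0, M = -1.0),
                  SOX9 = c(F = 0.9, M = -0.9), SOX19 = c(F = -2.8, M = 2.8),
                  SOX17 = c(F = -1.2, M = 1.2), VASA = c(F = -0.3, M = 0.3))
  sexo <- tgt_sex[intersect(names(tgt_sex), genes)]
  if (length(sexo) == 0L) sexo <- NULL

  pairs <- list(c("RPS4", "UBQ", 0.6), c("RPS4", "GAPDH", 0.5),
                c("RPS4", "RPL17", 0.4), c("VASA", "B2M", 0.8))
  keep <- vapply(pairs, function(p) all(p[1:2] %in% genes), logical(1))
  if (any(keep)) {
    cor_pairs <- do.call(rbind, lapply(pairs[keep], function(p) {
      data.frame(gene1 = p[1], gene2 = p[2], sd = as.numeric(p[3]),
                 stringsAsFactors = FALSE)
    }))
  }
  cq_truth(design, baseline = baseline, tech_sd = 0.15,
           sample_sd = sample_sd, loading_sd = 0.9, plate_sd = 0.15,
           group_offsets = off, sex_offsets = sexo, coreg = cor_pairs,
           fail_rate = 0.005)
}

#' Simulate a replicate-level Cq dataset
#'
#' Draws one Cq record per sample x gene x replicate under the additive
#' model of [cq_truth()], assigns samples to plates gene-wise in blocks
#' ("sample maximization": plates are filled in sample order), and runs
#' every calibrator sample on every plate with the same latent values, so
#' that interplate calibration can be exercised downstream.
#'
#' @param design a [study_design()].
#' @param truth a [cq_truth()]; defaults to [default_cq_truth()].
#' @param seed integer; defaults to `design$seed`.
#'
#' @return A list of class `cq_sim` with elements
#'   \describe{
#'     \item{records}{data frame `sample, gene, replicate, plate, cq,
#'       is_calibrator` (replicate-level, uncalibrated).}
#'     \item{metadata}{data frame `sample, age_dpf, temperature, sex, group`
#'       for the study samples.}
#'     \item{truth}{the `cq_truth` used, plus realized latent tables:
#'       `latent` (per-sample loading and gene effects), `plate_offsets`
#'       (gene x plate), and `expected` (noise-free expected Cq per sample
#'       x gene).}
#'   }
#' @export
#' @examples
#' d <- study_design(ages = c(30, 60), temperatures = c("Low", "High"),
#'                   samples_per_cell = 3, plates = 2)
#' sim <- simulate_cq_dataset(d)
#' head(sim$records)
simulate_cq_dataset <- function(design, truth = default_cq_truth(design),
                                seed = design$seed) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "cq_truth"))
  genes <- c(design$reference_genes, design$target_genes)
  grp <- design$groups
  n_s <- nrow(grp) * design$samples_per_cell
  with_seed(seed, {
    meta <- grp[rep(seq_len(nrow(grp)), each = design$samples_per_cell), ]
    meta$sample <- sprintf("S%03d", seq_len(n_s))
    meta$sex <- sample(c("F", "M"), n_s, replace = TRUE)
    rownames(meta) <- NULL
    meta <- meta[, c("sample", "age_dpf", "temperature", "sex", "group")]

    cal_ids <- if (design$calibrators > 0) {
      sprintf("CAL%02d", seq_len(design$calibrators))
    } else character(0)
    all_samples <- c(meta$sample, cal_ids)

    # latent per-sample effects (calibrators get them too, groupless)
    loading <- stats::rnorm(length(all_samples), 0, truth$loading_sd)
    names(loading) <- all_samples
    sample_eff <- sapply(genes, function(g) {
      stats::rnorm(length(all_samples), 0, truth$sample_sd[[g]])
    })
    rownames(sample_eff) <- all_samples
    coreg_eff <- matrix(0, nrow = length(all_samples), ncol = length(genes),
                        dimnames = list(all_samples, genes))
    if (!is.null(truth$coreg)) {
      for (i in seq_len(nrow(truth$coreg))) {
        z <- stats::rnorm(length(all_samples), 0, truth$coreg$sd[i])
        coreg_eff[, truth$coreg$gene1[i]] <-
          coreg_eff[, truth$coreg$gene1[i]] + z
        coreg_eff[, truth$coreg$gene2[i]] <-
          coreg_eff[, truth$coreg$gene2[i]] + z
      }
    }
    plate_off <- matrix(stats::rnorm(length(genes) * design$plates,
                                     0, truth$plate_sd),
                        nrow = length(genes),
                        dimnames = list(genes, seq_len(design$plates)))

    # noise-free expected Cq for every sample x gene (plate excluded)
    group_of <- c(stats::setNames(meta$group, meta$sample),
                  stats::setNames(rep(NA_character_, length(cal_ids)),
                                  cal_ids))
    sex_of <- c(stats::setNames(meta$sex, meta$sample),
                stats::setNames(rep(NA_character_, length(cal_ids)), cal_ids))
    expected <- matrix(NA_real_, nrow = length(all_samples),
                       ncol = length(genes),
                       dimnames = list(all_samples, genes))
    for (g in genes) {
      e <- truth$baseline[[g]] + loading + sample_eff[, g] + coreg_eff[, g]
      gidx <- !is.na(group_of)
      e[gidx] <- e[gidx] + truth$group_offsets[g, group_of[gidx]]
      sidx <- !is.na(sex_of)
      e[sidx] <- e[sidx] + truth$sex_offsets[g, sex_of[sidx]]
      expected[, g] <- e
    }

    # plate assignment: per gene, study samples fill plates in order
    per_plate <- ceiling(n_s / design$plates)
    plate_of_sample <- pmin(design$plates,
                            (seq_len(n_s) - 1L) %/% per_plate + 1L)
    rec <- list()
    for (g in genes) {
      study <- data.frame(
        sample = rep(meta$sample, each = design$replicates_per_reaction),
        gene = g,
        replicate = rep(seq_len(design$replicates_per_reaction), times = n_s),
        plate = rep(plate_of_sample, each = design$replicates_per_reaction),
        is_calibrator = FALSE, stringsAsFactors = FALSE)
      if (length(cal_ids)) {
        cal <- expand.grid(replicate = seq_len(design$calibrator_replicates),
                           sample = cal_ids,
                           plate = seq_len(design$plates),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        cal$gene <- g
        cal$is_calibrator <- TRUE
        study <- rbind(study,
                       cal[, c("sample", "gene", "replicate", "plate",
                               "is_calibrator")])
      }
      study$cq <- expected[study$sample, g] +
        plate_off[g, study$plate] +
        stats::rnorm(nrow(study), 0, truth$tech_sd[[g]])
      rec[[g]] <- study
    }
    records <- do.call(rbind, rec)
    rownames(records) <- NULL
    records <- records[, c("sample", "gene", "replicate", "plate", "cq",
                           "is_calibrator")]
    if (truth$fail_rate > 0) {
      study_rows <- which(!records$is_calibrator)
      failed <- study_rows[stats::runif(length(study_rows)) <
                             truth$fail_rate]
      if (length(failed)) {
        half <- stats::runif(length(failed)) < 0.5
        records$cq[failed[half]] <- NA_real_
        n_out <- sum(!half)
        records$cq[failed[!half]] <- records$cq[failed[!half]] +
          sample(c(-1, 1), n_out, replace = TRUE) *
          stats::runif(n_out, 1.2, 3)
      }
    }
    truth$latent <- data.frame(sample = all_samples, loading = loading,
                               stringsAsFactors = FALSE, row.names = NULL)
    truth$plate_offsets <- plate_off
    truth$sample_effects <- sample_eff + coreg_eff
    truth$expected <- expected
    structure(list(records = records, metadata = meta, truth = truth,
                   design = design),
              class = "cq_sim")
  })
}

#' Ground truth for one simulated amplification curve
#'
#' @param E0 amplification factor at vanishing product, in (1, 2]
#'   (2 = perfect doubling; efficiency% = 100 * (E0 - 1)).
#' @param F0 initial target signal at cycle 0, in fluorescence units (> 0).
#' @param Fmax plateau signal (fluorescence units, > F0).
#' @param baseline baseline fluorescence intercept (units).
#' @param drift per-cycle linear baseline drift (units/cycle).
#' @param noise_sd SD of additive Gaussian read noise (units).
#' @param cycles number of amplification cycles (>= 25).
#'
#' @return An object of class `curve_truth`.
#' @export
curve_truth <- function(E0 = 1.9, F0 = 0.02, Fmax = 30000,
                        baseline = 3000, drift = 2, noise_sd = 30,
                        cycles = 40L) {
  check_number(E0, "E0", lower = 1, upper = 2, strict_lower = TRUE)
  check_number(F0, "F0", lower = 0, strict_lower = TRUE)
  check_number(Fmax, "Fmax", lower = F0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(cycles, "cycles", lower = 25)
  structure(list(E0 = E0, F0 = F0, Fmax = Fmax, baseline = baseline,
                 drift = drift, noise_sd = noise_sd,
                 cycles = as.integer(cycles)),
            class = "curve_truth")
}

#' Simulate one raw amplification curve
#'
#' Product amount follows the recursion `N_c = N_{c-1} * E_c` with
#' per-cycle efficiency `E_c = 1 + (E0 - 1) * (1 - N_{c-1} / Fmax)`: the
#' reaction amplifies geometrically at factor E0 while far from the
#' plateau and the efficiency decays linearly in product amount as
#' reagents (dye, primers) deplete. Observed fluorescence is
#' `F_c = N_c + baseline + drift * c + noise`, i.e. raw, un-baselined
#' instrument output.
#'
#' @param truth a [curve_truth()].
#' @param sample,gene,well optional metadata labels stored on the curve.
#' @param seed optional integer seed (RNG state is restored afterwards).
#'
#' @return An object of class `amp_curve`: a list with `cycle` (1-based
#'   integer vector), `fluorescence`, metadata fields, and the generating
#'   `truth`.
#' @export
#' @examples
#' cv <- simulate_amp_curve(curve_truth(E0 = 2, noise_sd = 0), seed = 1)
#' plot(cv$cycle, cv$fluorescence, type = "l")
simulate_amp_curve <- function(truth, sample = NA_character_,
                               gene = NA_character_, well = NA_character_,
                               seed = NULL) {
  stopifnot(inherits(truth, "curve_truth"))
  with_seed(seed, {
    n <- truth$cycles
    N <- numeric(n)
    prev <- truth$F0
    for (c in seq_len(n)) {
      Ec <- 1 + (truth$E0 - 1) * max(0, 1 - prev / truth$Fmax)
      prev <- prev * Ec
      N[c] <- prev
    }
    cyc <- seq_len(n)
    f <- N + truth$baseline + truth$drift * cyc
    if (truth$noise_sd > 0) f <- f + stats::rnorm(n, 0, truth$noise_sd)
    structure(list(cycle = cyc, fluorescence = f, sample = sample,
                   gene = gene, well = well, truth = truth),
              class = "amp_curve")
  })
}

#' Simulate a set of amplification curves as a long table
#'
#' @param n number of curves.
#' @param truth a [curve_truth()] shared by all curves.
#' @param gene,sample_prefix labels for the generated reactions.
#' @param seed integer seed.
#' @return data frame `well, sample, gene, cycle, fluorescence`.
#' @export
simulate_amp_curves <- function(n, truth, gene = "GENE",
                                sample_prefix = "S", seed = 1L) {
  with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      cv <- simulate_amp_curve(truth,
                               sample = sprintf("%s%03d", sample_prefix, i),
                               gene = gene, well = sprintf("W%03d", i))
      out[[i]] <- data.frame(well = cv$well, sample = cv$sample,
                             gene = cv$gene, cycle = cv$cycle,
                             fluorescence = cv$fluorescence,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Split a long curve table into `amp_curve` objects
#'
#' @param df data frame `well, sample, gene, cycle, fluorescence`.
#' @return list of `amp_curve` objects, one per well.
#' @export
split_amp_curves <- function(df) {
  need <- c("well", "sample", "gene", "cycle", "fluorescence")
  if (!all(need %in% names(df))) {
    fail("curve table must have columns %s", paste(need, collapse = ", "))
  }
  lapply(split(df, df$well), function(d) {
    d <- d[order(d$cycle), ]
    structure(list(cycle = as.integer(d$cycle),
                   fluorescence = d$fluorescence,
                   sample = d$sample[1], gene = d$gene[1], well = d$well[1],
                   truth = NULL),
              class = "amp_curve")
  })
}

#' Write a deterministic suite of small CSV fixtures
#'
#' Generates the toy datasets used by the test suite: a small complete Cq
#' study (`cq_toy_*`), a six-gene panel in which exactly one gene carries
#' group-regulation offsets (`stable5_shifted1_*`), and a set of 300
#' amplification curves (100 per E0 in 1.80/1.90/2.00,
#' `curves_recovery.csv`). Identical seeds produce byte-identical files.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @return Invisibly, a named character vector of the written file paths.
#' @export
make_fixture_suite <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths[[name]] <<- p
    p
  }

  d1 <- study_design(ages = c(30L, 60L), temperatures = c("Low", "High"),
                     samples_per_cell = 5L,
                     reference_genes = c("G1", "G2", "G3", "G4"),
                     target_genes = c("T1", "T2"),
                     plates = 2L, calibrators = 2L, seed = seed)
  t1 <- cq_truth(d1, baseline = c(G1 = 18, G2 = 20, G3 = 22, G4 = 19,
                                  T1 = 26, T2 = 28),
                 tech_sd = 0.15, sample_sd = 0.4, loading_sd = 0.8,
                 plate_sd = 0.2)
  s1 <- simulate_cq_dataset(d1, t1)
  put(s1$records, "cq_toy_records.csv")
  put(s1$metadata, "cq_toy_metadata.csv")

  d2 <- study_design(ages = c(30L, 60L, 90L, 120L),
                     temperatures = c("Low", "High"),
                     samples_per_cell = 6L,
                     reference_genes = paste0("G", 1:6),
                     target_genes = character(0),
                     plates = 2L, calibrators = 2L, seed = seed + 1L)
  off <- matrix(0, nrow = 1, ncol = nrow(d2$groups),
                dimnames = list("G6", d2$groups$group))
  off["G6", d2$groups$group[d2$groups$temperature == "High"]] <- 1.5
  t2 <- cq_truth(d2, baseline = stats::setNames(seq(18, 23, by = 1),
                                                paste0("G", 1:6)),
                 tech_sd = 0.15, sample_sd = 0.3, loading_sd = 0.8,
                 plate_sd = 0, group_offsets = off)
  s2 <- simulate_cq_dataset(d2, t2)
  put(s2$records, "stable5_shifted1_records.csv")
  put(s2$metadata, "stable5_shifted1_metadata.csv")
  off_long <- data.frame(gene = rep(rownames(t2$group_offsets),
                                    times = ncol(t2$group_offsets)),
                         group = rep(colnames(t2$group_offsets),
                                     each = nrow(t2$group_offsets)),
                         offset = as.vector(t2$group_offsets),
                         stringsAsFactors = FALSE)
  put(off_long, "stable5_shifted1_truth.csv")

  e0s <- c(1.80, 1.90, 2.00)
  curves <- do.call(rbind, lapply(seq_along(e0s), function(i) {
    df <- simulate_amp_curves(100L, curve_truth(E0 = e0s[i]),
                              gene = "G", seed = seed + 10L + i)
    df$gene <- sprintf("E0_%.2f", e0s[i])
    df$well <- paste0(df$gene, "_", df$well)
    df
  }))
  put(curves, "curves_recovery.csv")

  cfg <- list(seed = as.integer(seed), qc_max_delta = 1.0,
              stability_methods = c("deltact", "bestkeeper",
                                    "normfinder", "genorm"),
              efficiency_methods = c("linreg", "dart", "miner", "lre"))
  p <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, p)
  paths[["config.yaml"]] <- p
  invisible(paths)
}
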