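# Replicate QC, interplate calibration, duplicate averaging and
# descriptive statistics for replicate-level Cq records.

check_records <- function(records) {
  need <- c("sample", "gene", "replicate", "plate", "cq")
  miss <- setdiff(need, names(records))
  if (length(miss)) fail("records missing columns: %s",
                         paste(miss, collapse = ", "))
  if (!"is_calibrator" %in% names(records)) records$is_calibrator <- FALSE
  key <- paste(records$sample, records$gene, records$replicate,
               records$plate, sep = "\r")
  if (anyDuplicated(key)) {
    fail("duplicate (sample, gene, replicate) records present")
  }
  records
}

#' Replicate consistency filter
#'
#' Removes whole samples whose technical replicates disagree. A sample is
#' dropped from the dataset (for every gene) if, for any gene in the
#' panel, one of its replicate Cqs is missing or the within-reaction Cq
#' range exceeds `max_delta` cycles. Calibrator reactions are not subject
#' to the filter.
#'
#' @param records replicate-level data frame
#'   (`sample, gene, replicate, plate, cq[, is_calibrator]`).
#' @param max_delta maximum tolerated Cq range within a reaction (cycles).
#' @return list with `records` (kept rows) and `removed`, a data frame
#'   `sample, gene, reason` with one row per offending reaction.
#' @export
filter_replicates <- function(records, max_delta = 1.0) {
  records <- check_records(records)
  check_number(max_delta, "max_delta", lower = 0)
  study <- records[!records$is_calibrator, ]
  sk <- interaction(study$sample, study$gene, drop = TRUE)
  bad <- list()
  for (d in split(study, sk)) {
    if (anyNA(d$cq)) {
      bad[[length(bad) + 1L]] <- data.frame(sample = d$sample[1],
                                            gene = d$gene[1],
                                            reason = "missing Cq",
                                            stringsAsFactors = FALSE)
    } else if (diff(range(d$cq)) > max_delta) {
      bad[[length(bad) + 1L]] <- data.frame(
        sample = d$sample[1], gene = d$gene[1],
        reason = sprintf("replicate range %.3f > %.3f",
                         diff(range(d$cq)), max_delta),
        stringsAsFactors = FALSE)
    }
  }
  removed <- if (length(bad)) do.call(rbind, bad) else
    data.frame(sample = character(0), gene = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  drop <- unique(removed$sample)
  keep <- records$is_calibrator | !(records$sample %in% drop)
  list(records = records[keep, , drop = FALSE], removed = removed)
}

#' Interplate calibration
#'
#' Removes plate-to-plate offsets using calibrator samples run on every
#' plate: for each plate and gene, the offset is the difference between
#' the mean calibrator Cq on that plate and the overall mean calibrator Cq
#' for that gene; the offset is subtracted from every Cq on the plate.
#' After calibration, per-gene calibrator means are identical across
#' plates, and the operation is idempotent.
#'
#' @param records replicate-level data frame; calibrator rows are
#'   identified by `is_calibrator` or by `calibrator_ids`.
#' @param calibrator_ids optional character vector of sample ids to treat
#'   as calibrators (overrides the `is_calibrator` column).
#' @return The records with calibrated `cq` and an added `plate_offset`
#'   column (the per-row offset that was subtracted).
#' @export
interplate_calibrate <- function(records, calibrator_ids = NULL) {
  records <- check_records(records)
  if (!is.null(calibrator_ids)) {
    records$is_calibrator <- records$sample %in% calibrator_ids
  }
  if (!any(records$is_calibrator)) fail("no calibrator records found")
  records$plate_offset <- 0
  for (g in unique(records$gene)) {
    gi <- records$gene == g
    plates <- unique(records$plate[gi])
    cal <- records[gi & records$is_calibrator & !is.na(records$cq), ]
    miss <- setdiff(plates, unique(cal$plate))
    if (length(miss)) {
      fail("plate(s) %s missing calibrators for gene %s",
           paste(miss, collapse = ", "), g)
    }
    overall <- mean(cal$cq)
    pm <- tapply(cal$cq, cal$plate, mean)
    off <- pm[as.character(records$plate[gi])] - overall
    records$plate_offset[gi] <- off
    records$cq[gi] <- records$cq[gi] - off
  }
  records
}

#' Average replicates into a samples x genes Cq matrix
#'
#' @param records QC-passed replicate-level records.
#' @param metadata data frame `sample, age_dpf, temperature[, sex]`; every
#'   non-calibrator sample must appear.
#' @param drop_calibrators drop calibrator samples from the matrix
#'   (default TRUE; they carry no group metadata).
#' @return An object of class `cq_matrix`: list with `cq` (numeric
#'   samples x genes matrix of replicate-averaged Cq) and `meta` (one row
#'   per sample, with a `group` = age x temperature key).
#' @export
average_replicates <- function(records, metadata, drop_calibrators = TRUE) {
  records <- check_records(records)
  if (drop_calibrators) records <- records[!records$is_calibrator, ]
  if (anyNA(records$cq)) fail("records contain missing Cq; run QC first")
  need <- c("sample", "age_dpf", "temperature")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) fail("metadata missing columns: %s",
                         paste(miss, collapse = ", "))
  nometa <- setdiff(unique(records$sample), metadata$sample)
  if (length(nometa)) fail("samples lacking metadata: %s",
                           paste(utils::head(nometa, 5), collapse = ", "))
  m <- tapply(records$cq, list(records$sample, records$gene), mean)
  meta <- metadata[match(rownames(m), metadata$sample), , drop = FALSE]
  if (!"group" %in% names(meta)) {
    meta$group <- paste(meta$age_dpf, meta$temperature, sep = "_")
  }
  if (!"sex" %in% names(meta)) meta$sex <- NA_character_
  rownames(meta) <- NULL
  structure(list(cq = m, meta = meta), class = "cq_matrix")
}

#' Construct a `cq_matrix` directly
#'
#' Convenience constructor used by tests and by code that already has an
#' averaged matrix.
#'
#' @param cq numeric samples x genes matrix with dimnames.
#' @param meta data frame with a `sample` column matching `rownames(cq)`;
#'   optional `group`, `sex` columns.
#' @return A `cq_matrix`.
#' @export
cq_matrix <- function(cq, meta = NULL) {
  if (is.null(rownames(cq))) rownames(cq) <- paste0("S", seq_len(nrow(cq)))
  if (is.null(colnames(cq))) colnames(cq) <- paste0("G", seq_len(ncol(cq)))
  if (is.null(meta)) {
    meta <- data.frame(sample = rownames(cq), group = "all",
                       sex = NA_character_, stringsAsFactors = FALSE)
  }
  if (!"group" %in% names(meta)) meta$group <- "all"
  if (!"sex" %in% names(meta)) meta$sex <- NA_character_
  meta <- meta[match(rownames(cq), meta$sample), , drop = FALSE]
  if (anyNA(meta$sample)) fail("meta must cover every row of 'cq'")
  rownames(meta) <- NULL
  structure(list(cq = cq, meta = meta), class = "cq_matrix")
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat(sprintf("cq_matrix: %d samples x %d genes, %d groups\n",
              nrow(x$cq), ncol(x$cq), length(unique(x$meta$group))))
  invisible(x)
}

#' Subset a `cq_matrix` by sample and/or gene
#' @param x a `cq_matrix`.
#' @param samples,genes row/column selectors (names or indices).
#' @return A `cq_matrix`.
#' @export
subset_cq <- function(x, samples = NULL, genes = NULL) {
  stopifnot(inherits(x, "cq_matrix"))
  m <- x$cq
  meta <- x$meta
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, rownames(m)) else samples
    m <- m[idx, , drop = FALSE]
    meta <- meta[idx, , drop = FALSE]
    rownames(meta) <- NULL
  }
  if (!is.null(genes)) m <- m[, genes, drop = FALSE]
  structure(list(cq = m, meta = meta), class = "cq_matrix")
}

#' Per-gene descriptive statistics
#'
#' Computes, per gene, N, mean, sample SD, minimum and maximum Cq, and a
#' Lilliefors-corrected one-sample Kolmogorov-Smirnov test of normality
#' (mean and SD estimated from the data; the classical KS test would be
#' anti-conservative with estimated parameters). Constant columns get an
#' NA p-value rather than an error.
#'
#' @param x a `cq_matrix` (>= 3 samples).
#' @return data frame `gene, n, mean, sd, min, max, ks_p` with attribute
#'   `ks_variant = "lilliefors"`.
#' @export
describe_cq <- function(x) {
  stopifnot(inherits(x, "cq_matrix"))
  if (nrow(x$cq) < 3) fail("need at least 3 samples")
  out <- data.frame(
    gene = colnames(x$cq),
    n = nrow(x$cq),
    mean = apply(x$cq, 2, mean),
    sd = apply(x$cq, 2, stats::sd),
    min = apply(x$cq, 2, min),
    max = apply(x$cq, 2, max),
    ks_p = vapply(seq_len(ncol(x$cq)), function(j) {
      v <- x$cq[, j]
      if (stats::sd(v) < .Machine$double.eps^0.5 || length(v) < 4) {
        return(NA_real_)
      }
      nortest::lillie.test(v)$p.value
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "ks_variant") <- "lilliefors"
  out
}

#' Full preprocessing: calibrate, QC, average
#'
#' Applies the stages in the order calibration -> replicate filter ->
#' duplicate averaging (calibrating first so that plate offsets cannot
#' inflate replicate deltas measured across plates).
#'
#' @param records replicate-level records (with calibrators).
#' @param metadata sample metadata.
#' @param max_delta replicate-range QC threshold (cycles).
#' @param calibrate apply interplate calibration (requires calibrators).
#' @return list with `matrix` (a `cq_matrix`), `removed` (QC report) and
#'   `n_removed` (number of samples dropped).
#' @export
preprocess_cq <- function(records, metadata, max_delta = 1.0,
                          calibrate = TRUE) {
  if (calibrate) records <- interplate_calibrate(records)
  qc <- filter_replicates(records, max_delta = max_delta)
  mat <- average_replicates(qc$records, metadata)
  list(matrix = mat, removed = qc$removed,
       n_removed = length(unique(qc$removed$sample)))
}
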