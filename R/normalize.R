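# Efficiency correction of Cq values and normalization of target genes by
# reference-gene combinations.

#' Efficiency-correct a Cq value
#'
#' Rescales a quantification cycle measured under amplification factor E
#' onto the perfect-doubling (E = 2) scale:
#' `corrected Cq = Cq * log(E) / log(2)`. With E = 2 the correction is the
#' identity; lower efficiencies shrink the Cq proportionally.
#'
#' @param cq numeric vector of Cq values (cycles, > 0).
#' @param E amplification factor in (1, 2].
#' @return corrected Cq values (cycles).
#' @export
#' @examples
#' efficiency_correct(20, 2)     # 20
#' efficiency_correct(20, 1.9)   # 20 * log(1.9)/log(2) = 18.52
efficiency_correct <- function(cq, E) {
  check_number(E, "E", lower = 1, upper = 2, strict_lower = TRUE)
  if (any(cq <= 0, na.rm = TRUE)) fail("Cq values must be > 0")
  cq * log(E) / log(2)
}

#' Normalize target genes by a reference combination
#'
#' Every Cq (reference and target) is first efficiency-corrected with its
#' gene's amplification factor; each target's corrected Cq is then
#' normalized by the arithmetic mean of the combination's corrected Cqs
#' (the Cq-scale equivalent of dividing by the geometric mean of
#' reference quantities), and finally each target is mean-centered across
#' samples.
#'
#' @param x a `cq_matrix` containing the reference genes (and metadata).
#' @param targets a `cq_matrix` with the target genes (same samples), or
#'   NULL if targets are columns of `x`.
#' @param combo character vector of reference gene names (non-empty).
#' @param efficiencies named per-gene amplification factors covering every
#'   gene involved; NULL means E = 2 for all genes (classic delta-Cq).
#' @param target_genes target gene names (default: all columns of
#'   `targets` not in `x`).
#' @param center mean-center each target across samples (default TRUE).
#' @return An object of class `normalized_expression`: list with `dcq`
#'   (samples x targets matrix of centered delta-Cq, log2 scale), `meta`,
#'   and `provenance` (combo, efficiency source, centering).
#' @export
normalize_targets <- function(x, targets = NULL, combo,
                              efficiencies = NULL, target_genes = NULL,
                              center = TRUE) {
  x <- as_cqm(x)
  tg <- if (is.null(targets)) x else as_cqm(targets)
  if (length(combo) == 0) fail("empty reference combo")
  miss <- setdiff(combo, colnames(x$cq))
  if (length(miss)) fail("unknown reference gene(s): %s",
                         paste(miss, collapse = ", "))
  target_genes <- target_genes %||% setdiff(colnames(tg$cq), colnames(x$cq))
  if (length(target_genes) == 0) fail("no target genes")
  all_genes <- c(combo, target_genes)
  if (is.null(efficiencies)) {
    efficiencies <- stats::setNames(rep(2, length(all_genes)), all_genes)
    esrc <- "none (E = 2)"
  } else {
    miss <- setdiff(all_genes, names(efficiencies))
    if (length(miss)) fail("missing efficiency for gene(s): %s",
                           paste(miss, collapse = ", "))
    esrc <- "per-gene mean E"
  }
  corr <- function(mat, genes) {
    out <- mat[, genes, drop = FALSE]
    for (g in genes) out[, g] <- efficiency_correct(out[, g],
                                                    efficiencies[[g]])
    out
  }
  rmat <- corr(x$cq, unique(combo))
  nf <- rowMeans(rmat[, combo, drop = FALSE])
  dcq <- corr(tg$cq, target_genes) - nf
  if (center) dcq <- scale(dcq, center = TRUE, scale = FALSE)
  structure(list(dcq = dcq[, , drop = FALSE], meta = x$meta,
                 provenance = list(combo = combo,
                                   efficiency_source = esrc,
                                   efficiencies = efficiencies[all_genes],
                                   centered = center)),
            class = "normalized_expression")
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat(sprintf(
    "normalized expression: %d samples x %d targets, refs %s (%s)%s\n",
    nrow(x$dcq), ncol(x$dcq),
    paste(x$provenance$combo, collapse = "+"),
    x$provenance$efficiency_source,
    if (x$provenance$centered) ", mean-centered" else ""))
  invisible(x)
}

#' Per-group means and SDs of normalized expression
#'
#' @param norm a `normalized_expression`.
#' @param grouping metadata column to group by (e.g. `"temperature"`,
#'   `"sex"`, `"group"`), or a vector of labels per sample.
#' @return data frame `gene, group, n, mean, sd` (SD is NA for groups of
#'   one sample).
#' @export
group_summary <- function(norm, grouping = "group") {
  stopifnot(inherits(norm, "normalized_expression"))
  g <- if (length(grouping) == 1L && is.character(grouping)) {
    if (!grouping %in% names(norm$meta)) {
      fail("grouping column '%s' not in metadata", grouping)
    }
    norm$meta[[grouping]]
  } else grouping
  if (length(g) != nrow(norm$dcq)) fail("grouping length mismatch")
  keep <- !is.na(g)
  rows <- list()
  for (gene in colnames(norm$dcq)) {
    v <- norm$dcq[keep, gene]
    gg <- g[keep]
    for (lev in unique(gg)) {
      vi <- v[gg == lev]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, group = lev, n = length(vi), mean = mean(vi),
        sd = if (length(vi) >= 2) stats::sd(vi) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
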