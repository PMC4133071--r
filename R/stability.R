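# Reference-gene stability methods: comparative delta-Ct, BestKeeper,
# NormFinder-style model-based decomposition, and stepwise-exclusion
# M-values (GeNorm tradition). All operate on the calibrated,
# replicate-averaged Cq matrix; lower values mean more stable genes.

stability_result <- function(method, values, extras = list()) {
  values <- sort(values)  # ascending: most stable first
  structure(c(list(method = method, values = values,
                   ranking = names(values)), extras),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Stability ranking (%s), most stable first:\n", x$method))
  for (i in seq_along(x$values)) {
    cat(sprintf("  %d. %s (%.3f)\n", i, names(x$values)[i], x$values[i]))
  }
  invisible(x)
}

as_cqm <- function(x) {
  if (inherits(x, "cq_matrix")) return(x)
  if (is.matrix(x)) return(cq_matrix(x))
  fail("expected a cq_matrix or a numeric matrix")
}

#' Comparative delta-Ct stability
#'
#' For each gene g, forms the within-sample Cq difference with every other
#' gene h and computes the sample SD of each difference series; the
#' stability value of g is the mean of those pairwise SDs. Lower values
#' indicate genes whose expression tracks the rest of the panel.
#'
#' @param x a `cq_matrix` (or samples x genes matrix) with >= 3 genes and
#'   >= 3 samples, no missing cells.
#' @return A `stability_result` with per-gene values and ranking.
#' @export
delta_ct_stability <- function(x) {
  x <- as_cqm(x)
  m <- x$cq
  if (ncol(m) < 3) fail("need at least 3 genes for pairwise stability")
  if (nrow(m) < 3) fail("need at least 3 samples")
  if (anyNA(m)) fail("matrix contains missing Cq values")
  vals <- mean_pairwise_sd(m)
  stability_result("deltact", vals)
}

# Mean pairwise SD of Cq differences for each gene over a gene set.
mean_pairwise_sd <- function(m) {
  g <- colnames(m)
  k <- length(g)
  sdmat <- matrix(0, k, k, dimnames = list(g, g))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s <- stats::sd(m[, i] - m[, j])
      sdmat[i, j] <- s
      sdmat[j, i] <- s
    }
  }
  stats::setNames(rowSums(sdmat) / (k - 1), g)
}

#' BestKeeper-style descriptive stability
#'
#' Ranks genes by the raw sample SD of their Cq values; also reports the
#' coefficient of variation (CV% = 100 * SD / mean) and all-pairs Pearson
#' correlations between genes (two-sided t-based p-values). Genes whose SD
#' exceeds `sd_cutoff` (conventionally 1 cycle) are flagged as too
#' variable for use as references.
#'
#' @param x a `cq_matrix` with >= 2 genes and >= 3 samples.
#' @param sd_cutoff flag threshold on the Cq SD, in cycles.
#' @return A `stability_result` (values = SD; ranking by SD) with extras:
#'   `cv` (named CV% vector), `cv_ranking`, `flagged` (genes with SD >
#'   cutoff), `correlation` (list with `r` and `p` gene x gene matrices).
#' @export
bestkeeper <- function(x, sd_cutoff = 1.0) {
  x <- as_cqm(x)
  m <- x$cq
  if (ncol(m) < 2) fail("need at least 2 genes")
  if (nrow(m) < 3) fail("need at least 3 samples")
  if (anyNA(m)) fail("matrix contains missing Cq values")
  mu <- colMeans(m)
  if (any(abs(mu) < .Machine$double.eps)) {
    fail("zero-mean Cq column: CV undefined")
  }
  sds <- apply(m, 2, stats::sd)
  cv <- 100 * sds / mu
  r <- stats::cor(m)
  n <- nrow(m)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  stability_result("bestkeeper", sds, extras = list(
    cv = cv,
    cv_ranking = names(sort(cv)),
    flagged = names(sds)[sds > sd_cutoff],
    sd_cutoff = sd_cutoff,
    correlation = list(r = r, p = p)))
}

#' Model-based (NormFinder-style) stability
#'
#' Decomposes Cq variation into intra-group and inter-group components.
#' Per-sample means across genes are removed first (this absorbs the
#' common loading effect), then for each gene g and group j the group
#' deviation `d_gj` (group mean minus overall gene mean of the
#' sample-centered values) and the within-group SD `s_gj` are estimated.
#' Group deviations are shrunken towards zero in proportion to their
#' sampling noise: `d~_gj = d_gj * gamma2 / (gamma2 + s_gj^2 / n_j)` where
#' `gamma2` is the variance of `d_gj` across groups. The stability value
#' combines systematic between-group regulation and within-group scatter:
#'
#'   rho_g = mean_j ( |d~_gj| + s_gj / sqrt(n_j) )
#'
#' The best two-gene combination minimizes the analogous quantity with
#' pair deviation `(d~_g + d~_h)/2` and pair variance `(s_g^2 + s_h^2)/4`.
#'
#' @param x a `cq_matrix` with >= 3 genes.
#' @param groups optional character vector of group labels per sample;
#'   defaults to `x$meta$group`. Every group needs >= 2 samples.
#' @return A `stability_result` with extras: `intra` / `inter` (named
#'   per-gene mean intra-group and inter-group variation, cycles),
#'   `group_variation` (data frame, Table-style), `best_gene`,
#'   `best_pair`, `best_pair_value`.
#' @export
normfinder <- function(x, groups = NULL) {
  x <- as_cqm(x)
  m <- x$cq
  if (ncol(m) < 3) fail("need at least 3 genes")
  if (anyNA(m)) fail("matrix contains missing Cq values")
  groups <- groups %||% x$meta$group
  if (length(groups) != nrow(m)) fail("'groups' must match sample count")
  tab <- table(groups)
  if (length(tab) < 2) fail("need at least 2 groups")
  if (any(tab < 2)) {
    fail("group(s) with < 2 samples: %s",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  glev <- names(tab)
  genes <- colnames(m)
  y <- m - rowMeans(m)            # remove per-sample loading
  gene_mean <- colMeans(y)
  k <- length(glev)
  d <- s <- matrix(0, nrow = length(genes), ncol = k,
                   dimnames = list(genes, glev))
  nj <- as.numeric(tab)[match(glev, names(tab))]
  for (j in seq_along(glev)) {
    yj <- y[groups == glev[j], , drop = FALSE]
    d[, j] <- colMeans(yj) - gene_mean
    s[, j] <- apply(yj, 2, stats::sd)
  }
  # shrink group deviations by their estimation noise
  dt <- d
  for (g in seq_along(genes)) {
    gamma2 <- if (k > 1) stats::var(d[g, ]) else 0
    denom <- gamma2 + s[g, ]^2 / nj
    w <- ifelse(denom > 0, gamma2 / denom, 0)
    dt[g, ] <- d[g, ] * w
  }
  intra <- rowMeans(s)
  inter <- rowMeans(abs(dt))
  rho <- rowMeans(abs(dt) + sweep(s, 2, sqrt(nj), "/"))
  names(rho) <- genes

  pair_stab <- function(g, h) {
    pd <- (dt[g, ] + dt[h, ]) / 2
    pv <- (s[g, ]^2 + s[h, ]^2) / 4
    mean(abs(pd) + sqrt(pv) / sqrt(nj))
  }
  best_pair <- NULL
  best_pv <- Inf
  if (length(genes) >= 2) {
    cmb <- utils::combn(genes, 2)
    for (i in seq_len(ncol(cmb))) {
      v <- pair_stab(cmb[1, i], cmb[2, i])
      if (v < best_pv) {
        best_pv <- v
        best_pair <- cmb[, i]
      }
    }
  }
  gv <- data.frame(gene = genes, intra_group = intra, inter_group = inter,
                   stringsAsFactors = FALSE, row.names = NULL)
  stability_result("normfinder", rho, extras = list(
    intra = intra, inter = inter, group_variation = gv,
    best_gene = names(which.min(rho)),
    best_pair = best_pair, best_pair_value = best_pv,
    groups = glev, n_per_group = stats::setNames(nj, glev)))
}

#' Stepwise-exclusion M-value stability (GeNorm tradition)
#'
#' The M-value of a gene is its mean pairwise SD of Cq differences with
#' every other gene in the current set (identical to the comparative
#' delta-Ct value in the first round). The gene with the highest M is
#' excluded and M-values recomputed, repeating until two genes remain;
#' those two share the final M. Ties for highest M are broken by removing
#' the gene appearing later in column order (logged in `ties`).
#'
#' @param x a `cq_matrix` with >= 3 genes, no missing cells.
#' @param cutoff acceptability threshold on the final-pair M (convention:
#'   1.5; lower is acceptable).
#' @return A `stability_result`. Values are the M-value each gene had in
#'   the round it was excluded (the final pair shares the last M), so the
#'   ranking equals the reverse exclusion order with the final pair first.
#'   Extras: `exclusion_order`, `final_pair`, `final_m`, `acceptable`,
#'   `rounds` (per-round M tables), `initial_m`, `ties`.
#' @export
genorm <- function(x, cutoff = 1.5) {
  x <- as_cqm(x)
  m <- x$cq
  if (ncol(m) < 3) fail("need at least 3 genes")
  if (anyNA(m)) fail("matrix contains missing Cq values")
  cur <- colnames(m)
  excl <- character(0)
  vals <- numeric(0)
  rounds <- list()
  ties <- character(0)
  initial <- NULL
  while (length(cur) > 2) {
    mv <- mean_pairwise_sd(m[, cur, drop = FALSE])
    if (is.null(initial)) initial <- mv
    rounds[[length(rounds) + 1L]] <- mv
    worst_val <- max(mv)
    cand <- names(mv)[mv >= worst_val - 1e-12]
    if (length(cand) > 1) {
      ties <- c(ties, paste(cand, collapse = "/"))
      # remove the candidate later in input (column) order
      cand <- cand[which.max(match(cand, colnames(m)))]
    }
    vals[cand] <- mv[[cand]]
    excl <- c(excl, cand)
    cur <- setdiff(cur, cand)
  }
  final_m <- mean_pairwise_sd(m[, cur, drop = FALSE])[1]
  rounds[[length(rounds) + 1L]] <- stats::setNames(rep(final_m, 2), cur)
  vals[cur] <- final_m
  # order final pair by input order; ranking = reverse exclusion order
  cur <- cur[order(match(cur, colnames(m)))]
  ranking <- c(cur, rev(excl))
  values <- vals[ranking]
  structure(list(method = "genorm", values = values, ranking = ranking,
                 exclusion_order = excl, final_pair = cur,
                 final_m = unname(final_m),
                 acceptable = unname(final_m) < cutoff, cutoff = cutoff,
                 rounds = rounds, initial_m = initial, ties = ties),
            class = "stability_result")
}

#' Mean M-value of a candidate reference-gene set
#'
#' The set-wise analogue reported when comparing normalization factors
#' (e.g. the M of a 3-gene set vs the best pair): the mean over the set's
#' genes of their pairwise-SD M computed within the set.
#'
#' @param x a `cq_matrix`.
#' @param combo character vector of >= 2 gene names.
#' @return single numeric M.
#' @export
set_m_value <- function(x, combo) {
  x <- as_cqm(x)
  if (length(combo) < 2) fail("need at least 2 genes in the set")
  mean(mean_pairwise_sd(x$cq[, combo, drop = FALSE]))
}

#' Run all four stability methods
#'
#' @param x a `cq_matrix`.
#' @param groups optional group labels for the model-based method.
#' @param methods subset of `c("deltact", "bestkeeper", "normfinder",
#'   "genorm")`.
#' @return Named list of `stability_result`s plus a `ranking_table` data
#'   frame with one column per method (Table-style: rank in rows).
#' @export
stability_suite <- function(x, groups = NULL,
                            methods = c("deltact", "bestkeeper",
                                        "normfinder", "genorm")) {
  x <- as_cqm(x)
  res <- list()
  for (meth in methods) {
    res[[meth]] <- switch(meth,
      deltact = delta_ct_stability(x),
      bestkeeper = bestkeeper(x),
      normfinder = normfinder(x, groups = groups),
      genorm = genorm(x),
      fail("unknown stability method '%s'", meth))
  }
  cols <- list(rank = seq_len(ncol(x$cq)))
  for (meth in names(res)) {
    r <- res[[meth]]
    cols[[meth]] <- sprintf("%s (%.3f)", r$ranking,
                            r$values[r$ranking])
    if (meth == "bestkeeper") {
      cols[["bestkeeper_cv"]] <- sprintf("%s (%.2f)", r$cv_ranking,
                                         r$cv[r$cv_ranking])
    }
  }
  res$ranking_table <- as.data.frame(cols, stringsAsFactors = FALSE)
  res
}

#' Effect of different normalization factors on target-gene spread
#'
#' For each candidate reference combination, normalizes every target gene
#' by the arithmetic mean of the combination's (optionally
#' efficiency-corrected) Cqs -- the Cq-scale equivalent of dividing by the
#' geometric mean of reference quantities -- and summarizes the spread of
#' the normalized values: average within-group SD, SD of group means
#' (inter-group), and within-sex SDs, each averaged over target genes.
#'
#' @param x a `cq_matrix` holding the reference genes (and metadata).
#' @param targets a `cq_matrix` (same samples) holding target genes, or
#'   NULL if target columns live in `x`.
#' @param combos list of character vectors of reference-gene names.
#' @param target_genes target gene names (default: all columns of
#'   `targets`).
#' @param efficiencies optional named per-gene amplification factors used
#'   to efficiency-correct Cqs before normalizing (see
#'   [efficiency_correct()]).
#' @return data frame with one row per combo: `combo, intragroup_sd,
#'   intergroup_sd, <sex>_sd...` (Table-style).
#' @export
compare_normalization_factors <- function(x, targets = NULL, combos,
                                          target_genes = NULL,
                                          efficiencies = NULL) {
  x <- as_cqm(x)
  tg <- if (is.null(targets)) x else as_cqm(targets)
  target_genes <- target_genes %||% setdiff(colnames(tg$cq), colnames(x$cq))
  if (length(target_genes) == 0) fail("no target genes")
  if (!is.list(combos)) combos <- list(combos)
  ec <- function(mat, genes) {
    out <- mat[, genes, drop = FALSE]
    if (!is.null(efficiencies)) {
      miss <- setdiff(genes, names(efficiencies))
      if (length(miss)) fail("missing efficiency for gene(s): %s",
                             paste(miss, collapse = ", "))
      for (g in genes) out[, g] <- efficiency_correct(out[, g],
                                                      efficiencies[[g]])
    }
    out
  }
  tmat <- ec(tg$cq, target_genes)
  groups <- x$meta$group
  sexes <- unique(x$meta$sex[!is.na(x$meta$sex)])
  rows <- lapply(combos, function(combo) {
    if (length(combo) == 0) fail("empty reference combo")
    miss <- setdiff(combo, colnames(x$cq))
    if (length(miss)) fail("unknown reference gene(s): %s",
                           paste(miss, collapse = ", "))
    rmat <- ec(x$cq, combo)
    nf <- rowMeans(rmat)
    dcq <- tmat - nf
    intra <- mean(vapply(target_genes, function(g) {
      mean(tapply(dcq[, g], groups, sd0))
    }, numeric(1)))
    inter <- mean(vapply(target_genes, function(g) {
      sd0(tapply(dcq[, g], groups, mean))
    }, numeric(1)))
    row <- data.frame(combo = paste(combo, collapse = "+"),
                      intragroup_sd = intra, intergroup_sd = inter,
                      stringsAsFactors = FALSE)
    for (sx in sexes) {
      sel <- !is.na(x$meta$sex) & x$meta$sex == sx
      row[[paste0(tolower(sx), "_sd")]] <- mean(vapply(
        target_genes, function(g) sd0(dcq[sel, g]), numeric(1)))
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
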