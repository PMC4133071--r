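# Stratified-subsampling evaluation of stability-ranking robustness: how
# often does a method's gene ranking survive when only a few samples per
# experimental group are assayed?

#' Draw stratified sample subsets
#'
#' Samples `per_group` samples without replacement within every
#' experimental group, independently for each of `n_subsets` subsets.
#'
#' @param x a `cq_matrix`.
#' @param per_group samples drawn per group.
#' @param n_subsets number of subsets.
#' @param seed integer seed (RNG state restored afterwards).
#' @return list of character vectors of sample ids.
#' @export
draw_subsets <- function(x, per_group, n_subsets, seed = 1L) {
  x <- as_cqm(x)
  check_number(per_group, "per_group", lower = 1)
  check_number(n_subsets, "n_subsets", lower = 1)
  tab <- table(x$meta$group)
  small <- names(tab)[tab < per_group]
  if (length(small)) fail("group(s) smaller than per_group = %d: %s",
                          per_group, paste(small, collapse = ", "))
  by_group <- split(x$meta$sample, x$meta$group)
  with_seed(seed, {
    lapply(seq_len(n_subsets), function(i) {
      unlist(lapply(by_group, function(s) {
        if (length(s) == per_group) s else sample(s, per_group)
      }), use.names = FALSE)
    })
  })
}

#' Classify a subset ranking against the full-data ranking
#'
#' Three mutually exclusive classes: `"identical"` when the ordered
#' rankings coincide; `"top3_reordered"` when they differ but the sets of
#' the first three genes coincide; `"different"` otherwise.
#'
#' @param full,sub character vectors (most stable first) over the same
#'   gene set.
#' @return one of `"identical"`, `"top3_reordered"`, `"different"`.
#' @export
classify_ranking <- function(full, sub) {
  if (length(full) != length(sub) || !setequal(full, sub)) {
    fail("rankings must cover the same gene set")
  }
  if (identical(as.character(full), as.character(sub))) return("identical")
  if (setequal(utils::head(full, 3), utils::head(sub, 3))) {
    return("top3_reordered")
  }
  "different"
}

# Ranking used for robustness comparison, per method convention:
# stepwise-exclusion output already places the final pair first (in input
# order) followed by the reverse exclusion order; the model-based method
# uses its single-gene ranking.
comparison_ranking <- function(res, method) {
  res$ranking
}

#' Robustness of stability rankings under subsampling
#'
#' Recomputes each stability method on stratified subsets and classifies
#' every subset ranking against the full-data ranking, tabulating counts
#' and percentages per subset-size stratum and pooled.
#'
#' @param x a `cq_matrix`.
#' @param methods stability method names (see [stability_suite()]).
#' @param per_group integer vector of samples-per-group strata
#'   (default `c(3, 2)`).
#' @param n_subsets subsets per stratum (default 25).
#' @param seed integer seed.
#' @param groups optional group labels for the model-based method.
#' @return An object of class `subset_evaluation`: list with
#'   `per_subset` (data frame `stratum, subset, method, class`), `counts`
#'   (data frame of class counts per stratum and method), `percent`
#'   (pooled percentage table, methods x classes), `full_rankings`, and
#'   `failures` (subset/method combinations that errored, excluded from
#'   percentages).
#' @export
robustness_summary <- function(x, methods = c("deltact", "bestkeeper",
                                              "normfinder", "genorm"),
                               per_group = c(3L, 2L), n_subsets = 25L,
                               seed = 1L, groups = NULL) {
  x <- as_cqm(x)
  run_method <- function(mat, meth, grp) {
    res <- switch(meth,
      deltact = delta_ct_stability(mat),
      bestkeeper = bestkeeper(mat),
      normfinder = normfinder(mat, groups = grp),
      genorm = genorm(mat),
      fail("unknown stability method '%s'", meth))
    comparison_ranking(res, meth)
  }
  grp_all <- groups %||% x$meta$group
  full <- lapply(methods, function(m) run_method(x, m, grp_all))
  names(full) <- methods
  per_subset <- list()
  failures <- list()
  for (si in seq_along(per_group)) {
    pg <- per_group[si]
    subsets <- draw_subsets(x, pg, n_subsets, seed = seed + si - 1L)
    for (k in seq_along(subsets)) {
      xs <- subset_cq(x, samples = subsets[[k]])
      for (m in methods) {
        cls <- tryCatch(
          classify_ranking(full[[m]],
                           run_method(xs, m, xs$meta$group)),
          error = function(e) NA_character_)
        if (is.na(cls)) {
          failures[[length(failures) + 1L]] <- data.frame(
            stratum = pg, subset = k, method = m, stringsAsFactors = FALSE)
          next
        }
        per_subset[[length(per_subset) + 1L]] <- data.frame(
          stratum = pg, subset = k, method = m, class = cls,
          stringsAsFactors = FALSE)
      }
    }
  }
  per_subset <- do.call(rbind, per_subset)
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(stratum = integer(0), subset = integer(0),
               method = character(0), stringsAsFactors = FALSE)
  if (nrow(failures)) {
    warning(sprintf("%d subset/method runs failed and were excluded",
                    nrow(failures)))
  }
  classes <- c("identical", "top3_reordered", "different")
  counts <- as.data.frame(table(
    stratum = per_subset$stratum,
    method = factor(per_subset$method, levels = methods),
    class = factor(per_subset$class, levels = classes)),
    stringsAsFactors = FALSE)
  names(counts)[4] <- "count"
  counts$stratum <- as.integer(as.character(counts$stratum))
  pooled <- tapply(rep(1, nrow(per_subset)),
                   list(factor(per_subset$method, levels = methods),
                        factor(per_subset$class, levels = classes)),
                   sum, default = 0)
  percent <- 100 * pooled / rowSums(pooled)
  structure(list(per_subset = per_subset, counts = counts,
                 percent = percent, full_rankings = full,
                 failures = failures,
                 per_group = per_group, n_subsets = n_subsets,
                 seed = seed),
            class = "subset_evaluation")
}

#' @export
print.subset_evaluation <- function(x, ...) {
  cat(sprintf("Ranking robustness over %d x %d stratified subsets\n",
              length(x$per_group), x$n_subsets))
  print(round(x$percent, 1))
  invisible(x)
}
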