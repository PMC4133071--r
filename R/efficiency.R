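# Single-reaction amplification-efficiency estimation from raw
# fluorescence curves. Four estimator families are provided, named after
# the algorithmic traditions they follow:
#   linreg - iterative baseline + best 4-6 cycle window-of-linearity fit
#   dart   - saturation-function baseline + regression over a 10-fold
#            signal range around the exponential-phase midpoint
#   miner  - four-parameter logistic fit defining the exponential phase,
#            then a three-parameter exponential fit on that phase
#   lre    - early-cycle baseline, per-cycle efficiency ratios regressed
#            on fluorescence, efficiency extrapolated to zero product
# E is reported as an amplification factor (1 = no amplification,
# 2 = perfect doubling); efficiency% = 100 * (E - 1).

efficiency_estimate <- function(method, E = NA_real_, window = c(NA, NA),
                                r2 = NA_real_, baseline = NA_real_,
                                valid = TRUE, reason = NA_character_,
                                flags = character(0), curve = NULL) {
  if (is.finite(E)) {
    if (E <= 1) {
      valid <- FALSE
      reason <- reason %||% "estimated E <= 1 (no amplification)"
      if (is.na(reason)) reason <- "estimated E <= 1 (no amplification)"
    } else if (E > 2) {
      flags <- union(flags, "E_above_2")
    }
  } else {
    valid <- FALSE
  }
  structure(list(method = method, E = E,
                 efficiency_pct = 100 * (E - 1),
                 window = window, r2 = r2, baseline = baseline,
                 valid = valid, reason = reason, flags = flags,
                 sample = curve$sample %||% NA_character_,
                 gene = curve$gene %||% NA_character_,
                 well = curve$well %||% NA_character_),
            class = "efficiency_estimate")
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("E = %.4f (%.1f%%) by %s, window %s-%s, R2 = %.4f%s\n",
                x$E, x$efficiency_pct, x$method, x$window[1], x$window[2],
                x$r2,
                if (length(x$flags)) paste0(" [", paste(x$flags,
                                                        collapse = ","), "]")
                else ""))
  } else {
    cat(sprintf("invalid %s estimate: %s\n", x$method, x$reason))
  }
  invisible(x)
}

check_curve <- function(curve) {
  if (is.data.frame(curve)) {
    curve <- structure(list(cycle = as.integer(curve$cycle),
                            fluorescence = curve$fluorescence,
                            sample = NA_character_, gene = NA_character_,
                            well = NA_character_, truth = NULL),
                       class = "amp_curve")
  }
  stopifnot(inherits(curve, "amp_curve"))
  if (length(curve$cycle) < 25) fail("curve needs >= 25 cycles")
  if (any(!is.finite(curve$fluorescence))) fail("non-finite fluorescence")
  curve
}

# Spread of the early (pre-amplification) cycles after removing a linear
# drift: a noise-scale estimate that is 0 for noiseless drifting input.
early_noise <- function(f, n_early = 8L) {
  idx <- seq_len(min(n_early, length(f)))
  fit <- lsfit1(idx, f[idx])
  stats::sd(f[idx] - (fit$intercept + fit$slope * idx))
}

# Does the curve show an exponential phase at all?
has_amplification <- function(f, k = 10) {
  spread <- early_noise(f)
  rise <- max(f) - stats::median(f[seq_len(min(8, length(f)))])
  rise > max(k * spread, 10 * .Machine$double.eps * max(abs(f), 1))
}

# Early-cycle baseline model: a linear drift fitted to the cycles before
# lift-off (where fluorescence first exceeds the early trend by 10 noise
# SDs). Returns the per-cycle baseline prediction and the noise scale.
early_baseline <- function(cyc, f) {
  idx <- seq_len(min(6L, length(f)))
  fit <- lsfit1(cyc[idx], f[idx])
  noise <- stats::sd(f[idx] - (fit$intercept + fit$slope * cyc[idx]))
  pred <- fit$intercept + fit$slope * cyc
  thr <- 10 * max(noise, 1e-9 * max(abs(f), 1))
  lift <- which(f - pred > thr)[1]
  n_early <- if (is.na(lift)) length(f) else max(5L, lift - 2L)
  idx <- seq_len(min(n_early, length(f)))
  fit <- lsfit1(cyc[idx], f[idx])
  list(pred = fit$intercept + fit$slope * cyc,
       noise = stats::sd(f[idx] - (fit$intercept + fit$slope * cyc[idx])),
       n_early = length(idx))
}

# Best 4-6 cycle log-linear window for given baseline-subtracted signal.
# Returns NULL when no usable window exists.
best_window_fit <- function(cyc, fs, noise, lo_mult = 3,
                            hi_frac = 0.25, win_sizes = 4:6) {
  ok <- fs > max(lo_mult * noise, 0) & fs < hi_frac * max(fs)
  if (sum(ok) < min(win_sizes)) return(NULL)
  lf <- suppressWarnings(log(fs))
  best <- NULL
  idx <- which(ok)
  for (w in win_sizes) {
    if (length(idx) < w) next
    for (s in seq_len(length(idx) - w + 1L)) {
      sel <- idx[s:(s + w - 1L)]
      if (sel[w] - sel[1] != w - 1L) next   # require consecutive cycles
      fit <- lsfit1(cyc[sel], lf[sel])
      if (!is.finite(fit$r2)) next
      if (is.null(best) || fit$r2 > best$r2 ||
          (fit$r2 == best$r2 && w > best$w)) {
        best <- list(r2 = fit$r2, slope = fit$slope, w = w,
                     from = cyc[sel[1]], to = cyc[sel[w]])
      }
    }
  }
  best
}

#' Window-of-linearity efficiency estimate (iterative baseline)
#'
#' The baseline (including any linear drift) is first estimated from the
#' pre-lift-off cycles, then iterated: a grid of constant offsets around
#' the early-cycle estimate (within +/- 5 noise SDs) is scanned and, for
#' each candidate baseline, the 4-6 consecutive-cycle window of
#' log(F - baseline) vs cycle with the best linear fit is found,
#' restricted to the rising part of the curve (above the noise floor,
#' below a quarter of the maximum baseline-subtracted signal). The
#' offset is refined by golden-section search on the best-window
#' R-squared; E = exp(slope of the winning window). Anchoring the
#' iteration to the early cycles avoids the degenerate solution in which
#' an under-subtracted baseline makes the log-curve flat-but-straight.
#'
#' @param curve an `amp_curve` (or data frame with `cycle`,
#'   `fluorescence`).
#' @param grid_points number of baseline-offset grid values.
#' @return An `efficiency_estimate`.
#' @export
estimate_linreg <- function(curve, grid_points = 21L) {
  curve <- check_curve(curve)
  f <- curve$fluorescence
  cyc <- curve$cycle
  if (!has_amplification(f)) {
    return(efficiency_estimate("linreg", valid = FALSE,
                               reason = "no exponential phase",
                               curve = curve))
  }
  eb <- early_baseline(cyc, f)
  noise <- eb$noise
  half_range <- 5 * max(noise, 1e-9 * max(abs(f), 1))
  score <- function(delta) {
    w <- best_window_fit(cyc, f - eb$pred - delta, noise)
    if (is.null(w)) -Inf else w$r2
  }
  grid <- seq(-half_range, half_range, length.out = grid_points)
  r2s <- vapply(grid, score, numeric(1))
  if (!any(is.finite(r2s))) {
    return(efficiency_estimate("linreg", valid = FALSE,
                               reason = "no usable log-linear window",
                               curve = curve))
  }
  i <- which.max(r2s)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  d <- if (hi > lo) {
    stats::optimize(score, c(lo, hi), maximum = TRUE, tol = 1e-8)$maximum
  } else lo
  if (score(d) < r2s[i]) d <- grid[i]   # keep the grid optimum
  w <- best_window_fit(cyc, f - eb$pred - d, noise)
  efficiency_estimate("linreg", E = exp(w$slope),
                      window = c(w$from, w$to), r2 = w$r2,
                      baseline = mean(eb$pred) + d, curve = curve)
}

#' Saturation-baseline efficiency estimate (10-fold midpoint window)
#'
#' The baseline trend is estimated by fitting a saturation function
#' `F = a * c / (b + c) + d` to cycles 2-10 (falling back to the mean of
#' those cycles when the fit diverges). After subtraction, the
#' exponential-phase midpoint is the first cycle whose signal exceeds the
#' early-cycle mean plus 10 early-cycle SDs (with a small floor relative
#' to the curve maximum so noiseless input is handled); the efficiency is
#' the slope of log signal vs cycle over the cycles spanning a 10-fold
#' signal range centred on that midpoint.
#'
#' @param curve an `amp_curve`.
#' @return An `efficiency_estimate`. The `flags` field carries
#'   `"baseline_fallback"` when the saturation fit failed.
#' @export
estimate_dart <- function(curve) {
  curve <- check_curve(curve)
  f <- curve$fluorescence
  cyc <- curve$cycle
  if (!has_amplification(f)) {
    return(efficiency_estimate("dart", valid = FALSE,
                               reason = "no exponential phase",
                               curve = curve))
  }
  flags <- character(0)
  idx <- which(cyc >= 2 & cyc <= 10)
  dat <- data.frame(c = cyc[idx], y = f[idx])
  base_fun <- NULL
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * c / (b + c) + d, data = dat,
                      start = list(a = max(dat$y) - min(dat$y) + 1e-6,
                                   b = 5, d = min(dat$y)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    base_fun <- function(c) cf[["a"]] * c / (cf[["b"]] + c) + cf[["d"]]
    # reject a "baseline" that swallowed the amplification signal
    if (any(!is.finite(base_fun(cyc))) ||
        max(base_fun(cyc)) > min(f) + 0.5 * (max(f) - min(f))) {
      base_fun <- NULL
    }
  }
  if (is.null(base_fun)) {
    flags <- c(flags, "baseline_fallback")
    bmean <- mean(dat$y)
    base_fun <- function(c) rep(bmean, length(c))
  }
  fs <- f - base_fun(cyc)
  em <- mean(fs[cyc <= 10])
  esd <- stats::sd(fs[cyc <= 10])
  # floor keeps the window above the region where residual baseline-fit
  # error dominates the signal (matters only for near-noiseless input)
  thr <- max(em + 10 * esd, 1e-2 * max(fs))
  cm <- which(fs > thr)[1]
  if (is.na(cm)) {
    return(efficiency_estimate("dart", valid = FALSE,
                               reason = "no cycle above midpoint threshold",
                               flags = flags, curve = curve))
  }
  fmid <- fs[cm]
  sel <- which(fs >= fmid / sqrt(10) & fs <= fmid * sqrt(10) & fs > 0)
  sel <- sel[sel >= cm - 10 & sel <= cm + 10]
  if (length(sel) < 3) {
    return(efficiency_estimate("dart", valid = FALSE,
                               reason = "fewer than 3 window cycles",
                               flags = flags, curve = curve))
  }
  fitw <- lsfit1(cyc[sel], log(fs[sel]))
  efficiency_estimate("dart", E = exp(fitw$slope),
                      window = range(cyc[sel]), r2 = fitw$r2,
                      baseline = mean(base_fun(cyc[sel])),
                      flags = flags, curve = curve)
}

# Four-parameter logistic fit with deterministic multi-start.
fit_logistic4 <- function(cyc, f) {
  d1 <- diff(f)
  chalf0 <- cyc[which.max(d1)]
  amp <- max(f) - min(f)
  starts <- list(
    list(fb = min(f), fm = amp, ch = chalf0, k = 2),
    list(fb = min(f), fm = amp, ch = chalf0 + 2, k = 1),
    list(fb = stats::median(f[seq_len(8)]), fm = amp, ch = chalf0 - 2,
         k = 3))
  dat <- data.frame(c = cyc, y = f)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ fb + fm / (1 + exp(-(c - ch) / k)), data = dat,
                        start = s,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 300, ftol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  best
}

#' Logistic-then-exponential efficiency estimate
#'
#' Fits a four-parameter logistic `F = Fb + Fmax / (1 + exp(-(c - c½)/k))`
#' to the whole curve by nonlinear least squares (three deterministic
#' starts). The exponential phase is taken as the cycles where the fitted
#' curve lies between 0.5% and 5% of the plateau amplitude -- below the
#' bend of the sigmoid, where amplification is still close to geometric
#' (windows ending at the fitted midpoint systematically underestimate E
#' because the least-squares exponential fit is dominated by the cycles
#' where the efficiency has already decayed). A three-parameter
#' exponential `F = Fb' + F0 * E^c` is then fitted to the raw
#' fluorescence on that phase; E is reported. When the logistic cannot be
#' fitted (e.g. a curve with no plateau) the exponential model is fitted
#' to the rising cycles directly and the estimate is flagged
#' `"no_logistic"`.
#'
#' @param curve an `amp_curve`.
#' @return An `efficiency_estimate`.
#' @export
estimate_miner <- function(curve) {
  curve <- check_curve(curve)
  f <- curve$fluorescence
  cyc <- curve$cycle
  if (!has_amplification(f)) {
    return(efficiency_estimate("miner", valid = FALSE,
                               reason = "no exponential phase",
                               curve = curve))
  }
  flags <- character(0)
  lg <- fit_logistic4(cyc, f)
  phase <- NULL
  if (!is.null(lg)) {
    cf <- stats::coef(lg$fit)
    sane <- is.finite(cf[["k"]]) && cf[["k"]] > 0 &&
      cf[["ch"]] > min(cyc) && cf[["ch"]] < max(cyc) + 10
    if (sane) {
      at_frac <- function(p) cf[["ch"]] - cf[["k"]] * log(1 / p - 1)
      lo <- ceiling(at_frac(0.005))
      hi <- floor(at_frac(0.05))
      lo <- min(max(lo, min(cyc)), max(cyc) - 3L)
      hi <- max(min(hi, max(cyc)), min(cyc) + 3L)
      if (hi - lo + 1 < 4) lo <- max(min(cyc), hi - 3L)
      if (hi - lo + 1 >= 4) phase <- which(cyc >= lo & cyc <= hi)
    }
  }
  if (is.null(phase)) {
    flags <- c(flags, "no_logistic")
    fs <- f - min(f)
    phase <- which(fs > 0.001 * max(fs))
    if (length(phase) < 4) {
      return(efficiency_estimate("miner", valid = FALSE,
                                 reason = "logistic fit failed and no rising phase",
                                 flags = flags, curve = curve))
    }
  }
  # fit y = fb + A * E^(c - c0) with c0 at the window centre: the raw
  # f0 * E^c parameterization has a Jacobian spanning many decades and
  # goes numerically singular on long windows
  c0 <- mean(cyc[phase])
  yscale <- max(abs(f[phase]))
  dat <- data.frame(cs = cyc[phase] - c0, y = f[phase] / yscale)
  b0 <- min(f[seq_len(min(8, length(f)))]) / yscale
  ys <- pmax(dat$y - b0, .Machine$double.eps)
  lf <- lsfit1(dat$cs, log(ys))
  E0 <- exp(lf$slope)
  if (!is.finite(E0) || E0 <= 1) E0 <- 1.8
  E0 <- min(E0, 1.99)
  A0 <- exp(lf$intercept)
  # starts deliberately offset from the log-linear solution: nls's model
  # construction rejects a start that already fits the data exactly
  starts <- list(list(fb = b0 + 0.01 * A0, A = 0.95 * A0, E = 0.98 * E0),
                 list(fb = b0, A = A0, E = min(2, E0 + 0.07)),
                 list(fb = 0, A = 1.05 * A0, E = max(1.01, E0 - 0.07)))
  best <- NULL
  for (s in starts) {
    if (!all(vapply(s, is.finite, logical(1)))) next
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ fb + A * E^cs, data = dat, start = s,
                        lower = c(fb = -Inf, A = 1e-300, E = 1.0001),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 300, ftol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(efficiency_estimate("miner", valid = FALSE,
                               reason = "exponential fit did not converge",
                               flags = flags, curve = curve))
  }
  cf <- stats::coef(best$fit)
  tss <- sum((dat$y - mean(dat$y))^2)
  r2 <- if (tss > 0) 1 - best$rss / tss else 1
  efficiency_estimate("miner", E = unname(cf[["E"]]),
                      window = range(cyc[phase]), r2 = r2,
                      baseline = unname(cf[["fb"]]) * yscale,
                      flags = flags, curve = curve)
}

#' Per-cycle efficiency regression estimate (zero-product extrapolation)
#'
#' Baseline is the mean fluorescence of cycles 6-12. Per-cycle
#' efficiencies `E_c = F_c / F_{c-1}` (baseline-subtracted) decline
#' approximately linearly in fluorescence as the reaction approaches the
#' plateau; a window of cycles is grown outward from the mid-rise point
#' while the linear regression of `E_c` on `F_c` keeps R-squared >= 0.99,
#' and the maximum efficiency is the regression intercept -- the
#' efficiency extrapolated to zero product.
#'
#' @param curve an `amp_curve`.
#' @param min_r2 window-growth R-squared threshold.
#' @return An `efficiency_estimate`.
#' @export
estimate_lre <- function(curve, min_r2 = 0.99) {
  curve <- check_curve(curve)
  f <- curve$fluorescence
  cyc <- curve$cycle
  if (!has_amplification(f)) {
    return(efficiency_estimate("lre", valid = FALSE,
                               reason = "no exponential phase",
                               curve = curve))
  }
  b <- mean(f[cyc >= 6 & cyc <= 12])
  fs <- f - b
  noise <- early_noise(f)
  usable <- fs > max(5 * noise, 0.02 * max(fs))
  usable[1] <- FALSE
  usable <- usable & c(FALSE, fs[-length(fs)] >
                         max(5 * noise, 0.02 * max(fs)))
  idx <- which(usable)
  if (length(idx) < 4) {
    return(efficiency_estimate("lre", valid = FALSE,
                               reason = "fewer than 4 usable window cycles",
                               curve = curve))
  }
  Ec <- fs[idx] / fs[idx - 1]
  # start from the cycle nearest half-maximal signal and grow outward
  start <- which.min(abs(fs[idx] - 0.5 * max(fs)))
  lo <- hi <- start
  repeat {
    grown <- FALSE
    for (side in c(-1L, 1L)) {
      cand_lo <- if (side < 0) lo - 1L else lo
      cand_hi <- if (side > 0) hi + 1L else hi
      if (cand_lo < 1L || cand_hi > length(idx)) next
      if (cand_hi - cand_lo + 1L < 2L) next
      sel <- cand_lo:cand_hi
      fit <- lsfit1(fs[idx[sel]], Ec[sel])
      if (is.finite(fit$r2) && fit$r2 >= min_r2) {
        lo <- cand_lo
        hi <- cand_hi
        grown <- TRUE
      }
    }
    if (!grown) break
  }
  if (hi - lo + 1L < 4L) {
    # tolerate a short window only if it can be padded without breaking R2
    while (hi - lo + 1L < 4L && (lo > 1L || hi < length(idx))) {
      if (lo > 1L) lo <- lo - 1L else hi <- hi + 1L
    }
  }
  if (hi - lo + 1L < 4L) {
    return(efficiency_estimate("lre", valid = FALSE,
                               reason = "fewer than 4 usable window cycles",
                               curve = curve))
  }
  sel <- lo:hi
  fit <- lsfit1(fs[idx[sel]], Ec[sel])
  efficiency_estimate("lre", E = fit$intercept,
                      window = range(cyc[idx[sel]]), r2 = fit$r2,
                      baseline = b, curve = curve)
}

#' Estimate efficiency with one or several methods
#'
#' @param curve an `amp_curve`.
#' @param methods subset of `c("linreg", "dart", "miner", "lre")`.
#' @return A named list of `efficiency_estimate`s (single estimate if one
#'   method requested).
#' @export
estimate_efficiency <- function(curve, methods = c("linreg", "dart",
                                                   "miner", "lre")) {
  out <- lapply(methods, function(meth) switch(meth,
    linreg = estimate_linreg(curve),
    dart = estimate_dart(curve),
    miner = estimate_miner(curve),
    lre = estimate_lre(curve),
    fail("unknown efficiency method '%s'", meth)))
  names(out) <- methods
  if (length(out) == 1L) out[[1L]] else out
}

#' Estimate efficiencies for a table of curves
#'
#' @param curves long data frame `well, sample, gene, cycle, fluorescence`
#'   or a list of `amp_curve`s.
#' @param methods estimator names.
#' @return data frame with one row per curve x method: `well, sample,
#'   gene, method, E, efficiency_pct, window_from, window_to, r2,
#'   baseline, valid, reason, flags, true_E` (`true_E` populated for
#'   simulated curves carrying ground truth).
#' @export
estimate_curves <- function(curves, methods = c("linreg", "dart",
                                                "miner", "lre")) {
  if (is.data.frame(curves)) curves <- split_amp_curves(curves)
  rows <- list()
  for (cv in curves) {
    for (meth in methods) {
      e <- estimate_efficiency(cv, meth)
      rows[[length(rows) + 1L]] <- data.frame(
        well = e$well, sample = e$sample, gene = e$gene, method = meth,
        E = e$E, efficiency_pct = e$efficiency_pct,
        window_from = e$window[1], window_to = e$window[2], r2 = e$r2,
        baseline = e$baseline, valid = e$valid,
        reason = e$reason %||% NA_character_,
        flags = paste(e$flags, collapse = ";"),
        true_E = if (!is.null(cv$truth)) cv$truth$E0 else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-gene mean efficiencies and cross-method correlation
#'
#' Invalid estimates are excluded (and counted); the remaining estimates
#' are averaged arithmetically per gene and method, and the per-gene mean
#' efficiencies of each method pair are correlated (Pearson, two-sided
#' t-based p).
#'
#' @param estimates data frame from [estimate_curves()].
#' @return list with `gene_means` (genes x methods matrix of mean E),
#'   `n_invalid` (per method), `excluded_genes`, and `method_correlation`
#'   (list of `r` and `p` matrices across methods).
#' @export
aggregate_gene_efficiency <- function(estimates) {
  need <- c("gene", "method", "E", "valid")
  miss <- setdiff(need, names(estimates))
  if (length(miss)) fail("estimates missing columns: %s",
                         paste(miss, collapse = ", "))
  methods <- unique(estimates$method)
  genes <- unique(estimates$gene)
  if (length(genes) < 2 || length(methods) < 2) {
    fail("need >= 2 genes and >= 2 methods to aggregate")
  }
  ok <- estimates[estimates$valid & is.finite(estimates$E), ]
  gm <- tapply(ok$E, list(ok$gene, ok$method), mean)
  gm <- gm[genes[genes %in% rownames(gm)], methods, drop = FALSE]
  excluded <- genes[!genes %in% rownames(gm) |
                      apply(is.na(gm[match(genes, rownames(gm)), ,
                                     drop = FALSE]), 1, any)]
  excluded <- excluded[!is.na(excluded)]
  if (length(excluded)) {
    warning(sprintf("gene(s) without valid estimates in every method: %s",
                    paste(excluded, collapse = ", ")))
    gm <- gm[!rownames(gm) %in% excluded, , drop = FALSE]
  }
  n_invalid <- tapply(!estimates$valid, estimates$method, sum)[methods]
  r <- stats::cor(gm)
  n <- nrow(gm)
  tt <- r * sqrt(pmax(n - 2, 1) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = max(n - 2, 1), lower.tail = FALSE)
  diag(p) <- NA_real_
  list(gene_means = gm, n_invalid = n_invalid,
       excluded_genes = excluded,
       method_correlation = list(r = r, p = p))
}
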