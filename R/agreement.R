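# Reliability and agreement statistics: ICC, Bland-Altman, percent
# agreement, rating scales, and the combined reliability report.

#' Intraclass correlation coefficient (two-way, single rater)
#'
#' Two-way ANOVA-based ICC in the McGraw-Wong formulation.  With subjects
#' as rows and raters/rounds as columns, the mean squares are MSR (rows),
#' MSC (columns) and MSE (error); the single-rater estimates are
#'
#' absolute agreement: (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)
#'
#' consistency:        (MSR - MSE) / (MSR + (k-1) MSE)
#'
#' The two-way random and mixed models share these point estimates; the
#' model choice is a reporting label (random for interchangeable raters,
#' mixed when the raters are the only ones of interest, e.g. two fixed
#' observers or manual vs automated methods).  95% confidence intervals use
#' the exact F-based construction for the chosen form.  Rows containing any
#' missing value are dropped (listwise deletion) and the dropped count is
#' reported.
#'
#' @param x numeric matrix or data.frame, n subjects x k raters; may
#'   contain NA.
#' @param model `"two-way-random"` or `"two-way-mixed"` (label only).
#' @param type `"absolute-agreement"` or `"consistency"`.
#' @param conf_level confidence level for the interval.
#' @return an object of class `icc_result`: `estimate`, `ci95 = c(lo, hi)`,
#'   `model`, `type`, `rating` (see [rate_icc()]), `n_used`, `n_dropped`,
#'   `k`, and the mean squares in `ms`.  With zero total variance the
#'   estimate is NA with a `reason`.
#' @export
icc <- function(x, model = c("two-way-random", "two-way-mixed"),
                type = c("absolute-agreement", "consistency"),
                conf_level = 0.95) {
  model <- match.arg(model)
  type <- match.arg(type)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  complete <- stats::complete.cases(x)
  n_dropped <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L)
    hm_error(sprintf(
      "ICC needs at least 2 subjects and 2 raters after listwise deletion (have %d x %d)",
      n, k), "hipmorph_insufficient_data")
  grand <- mean(x)
  rm_ <- rowMeans(x); cm_ <- colMeans(x)
  SSR <- k * sum((rm_ - grand)^2)
  SSC <- n * sum((cm_ - grand)^2)
  SST <- sum((x - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSE < 0 && MSE > -1e-12) MSE <- 0

  out <- list(model = model, type = type, n_used = n, n_dropped = n_dropped,
              k = k, conf_level = conf_level,
              ms = list(MSR = MSR, MSC = MSC, MSE = MSE))
  if (SST <= .Machine$double.eps * max(1, abs(grand))^2 * n * k) {
    out$estimate <- NA_real_
    out$ci95 <- c(NA_real_, NA_real_)
    out$rating <- NA_character_
    out$reason <- "zero total variance: ICC undefined"
    class(out) <- "icc_result"
    return(out)
  }

  alpha <- 1 - conf_level
  if (type == "consistency") {
    est <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    if (MSE == 0) {
      ci <- c(1, 1)
    } else {
      Fobs <- MSR / MSE
      FL <- Fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      FU <- Fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
    }
  } else {
    est <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    if (MSE == 0 && MSC == 0) {
      # limit of the F interval as the error and rater variance vanish
      ci <- c(1, 1)
    } else {
      a <- k * est / (n * (1 - est))
      b <- 1 + k * est * (n - 1) / (n * (1 - est))
      v <- (a * MSC + b * MSE)^2 /
        ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
      F1 <- stats::qf(1 - alpha / 2, n - 1, v)
      F2 <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (MSR - F1 * MSE) /
        (F1 * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
      hi <- n * (F2 * MSR - MSE) /
        (k * MSC + (k * n - k - n) * MSE + n * F2 * MSR)
      ci <- c(lo, hi)
    }
  }
  out$estimate <- est
  out$ci95 <- pmin(1, pmax(-1, ci))
  out$rating <- rate_icc(est)
  class(out) <- "icc_result"
  out
}

#' @export
print.icc_result <- function(x, ...) {
  if (is.na(x$estimate))
    cat(sprintf("<icc: undefined (%s)>\n", x$reason %||% "missing"))
  else
    cat(sprintf("<icc %s, %s, single rater: %.3f (95%% CI %.3f-%.3f), %s; n=%d, k=%d%s>\n",
                x$model, x$type, x$estimate, x$ci95[1L], x$ci95[2L], x$rating,
                x$n_used, x$k,
                if (x$n_dropped > 0) sprintf(", %d dropped", x$n_dropped) else ""))
  invisible(x)
}

#' Qualitative rating of an ICC estimate
#'
#' Bands: poor below 0.50, moderate 0.50-0.75, good above 0.75 up to 0.90,
#' excellent above 0.90 (the printed 0.75/0.76 band gap is assigned to the
#' higher band).
#'
#' @param estimate finite ICC estimate.
#' @return `"poor"`, `"moderate"`, `"good"` or `"excellent"`.
#' @export
rate_icc <- function(estimate) {
  if (is.na(estimate)) return(NA_character_)
  stopifnot(is_number(estimate))
  if (estimate < 0.50) "poor"
  else if (estimate <= 0.75) "moderate"
  else if (estimate <= 0.90) "good"
  else "excellent"
}

#' Bland-Altman agreement analysis
#'
#' Paired-difference analysis of two measurement series: bias (mean of
#' d = x - y), limits of agreement bias +/- 1.96 sd(d), and a
#' systematic-error flag.  A mean difference larger than 2.5 degrees counts
#' as systematic error for angle measurements (mAI, AA, WCEA, LCEA, NSA); a
#' mean difference larger than 1% of the measurement (here: of the grand
#' mean of the pairwise averages, in absolute value) counts for the ratio
#' measurements (ADR, EI, TIR).
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped and at
#'   least 3 complete pairs are required.
#' @param kind `"angle"` or `"ratio"`; selects the systematic-error rule.
#' @param loa_multiplier multiplier on sd(d) for the limits of agreement.
#' @param angle_threshold degrees of bias tolerated for angle measurements.
#' @param ratio_fraction fraction of the measurement tolerated as bias for
#'   ratio measurements.
#' @return an object of class `bland_altman`: `bias`, `loa = c(lo, hi)`,
#'   `sd_diff`, `systematic_error`, `n`, plus the retained per-pair
#'   `differences` and `means`.
#' @export
bland_altman <- function(x, y, kind = c("angle", "ratio"),
                         loa_multiplier = 1.96, angle_threshold = 2.5,
                         ratio_fraction = 0.01) {
  kind <- match.arg(kind)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    hm_error("Bland-Altman needs at least 3 complete pairs",
             "hipmorph_insufficient_data")
  d <- x - y
  bias <- mean(d)
  sdd <- stats::sd(d)
  loa <- bias + c(-1, 1) * loa_multiplier * sdd
  sys <- if (kind == "angle") abs(bias) > angle_threshold
  else abs(bias) > ratio_fraction * abs(mean((x + y) / 2))
  structure(list(bias = bias, loa = loa, sd_diff = sdd,
                 systematic_error = sys, kind = kind, n = length(x),
                 differences = d, means = (x + y) / 2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman (%s): bias %.3f, LoA (%.3f, %.3f), n=%d%s>\n",
              x$kind, x$bias, x$loa[1L], x$loa[2L], x$n,
              if (x$systematic_error) ", systematic error" else ""))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ..., main = "Bland-Altman",
                              xlab = "Mean of pair", ylab = "Difference") {
  graphics::plot(x$means, x$differences, main = main, xlab = xlab,
                 ylab = ylab, pch = 19, ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = x$loa, lty = 2)
  invisible(x)
}

#' Percent agreement between two categorical series
#'
#' 100 * matches / comparable pairs, where a pair is comparable when both
#' entries are non-missing.  Rated poor below 50%, moderate 50-70%, good
#' above 70% up to 90%, excellent above 90% (the printed 70/71 gap is
#' assigned to the higher band).
#'
#' @param a,b aligned vectors (logical, factor or character).
#' @return list with `percent`, `rating`, `n_comparable`, `n_matches`.
#' @export
percent_agreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  comp <- !is.na(a) & !is.na(b)
  if (sum(comp) == 0L)
    hm_error("no comparable pairs for percent agreement",
             "hipmorph_insufficient_data")
  matches <- sum(a[comp] == b[comp])
  pct <- 100 * matches / sum(comp)
  rating <- if (pct < 50) "poor" else if (pct <= 70) "moderate"
  else if (pct <= 90) "good" else "excellent"
  list(percent = pct, rating = rating, n_comparable = sum(comp),
       n_matches = matches)
}

#' Minimum sample size for an ICC reliability study
#'
#' Walter-Eliasziw-Donner asymptotic sample size for testing H0: ICC =
#' `rho0` against the alternative `rho1` with `k` replicates per subject:
#'
#' n = 1 + 2 (z_a + z_b)^2 k / ((ln C0)^2 (k - 1)),
#' C0 = (1 + k rho0 / (1 - rho0)) / (1 + k rho1 / (1 - rho1))
#'
#' rounded up to the next integer.
#'
#' @param rho0 minimally acceptable reliability under H0 (0 < rho0 < rho1).
#' @param rho1 expected reliability.
#' @param k replications per subject (raters or rounds), k >= 2.
#' @param alpha type I error (one-sided by default).
#' @param beta type II error.
#' @param two_sided use alpha/2 in the normal quantile.
#' @return minimum number of subjects (integer).
#' @examples
#' icc_sample_size(0.75, 0.90, k = 2)   # 26
#' @export
icc_sample_size <- function(rho0, rho1, k = 2L, alpha = 0.05, beta = 0.20,
                            two_sided = FALSE) {
  stopifnot(is_number(rho0), is_number(rho1), is_number(alpha), is_number(beta))
  if (!(rho0 > 0 && rho0 < 1) || !(rho1 > 0 && rho1 < 1))
    hm_error("rho0 and rho1 must lie in (0, 1)", "hipmorph_config")
  if (rho1 <= rho0)
    hm_error("expected reliability rho1 must exceed rho0", "hipmorph_config")
  if (k < 2L) hm_error("need at least 2 replications", "hipmorph_config")
  za <- stats::qnorm(1 - alpha / if (two_sided) 2 else 1)
  zb <- stats::qnorm(1 - beta)
  C0 <- (1 + k * rho0 / (1 - rho0)) / (1 + k * rho1 / (1 - rho1))
  n <- 1 + 2 * (za + zb)^2 * k / (log(C0)^2 * (k - 1))
  as.integer(ceiling(n))
}

# measurement kind for the systematic-error rule
MEASUREMENT_KIND <- c(adr = "ratio", mai_deg = "angle", alpha_deg = "angle",
                      wcea_deg = "angle", lcea_deg = "angle", ei_pct = "ratio",
                      nsa_deg = "angle", tir = "ratio")

#' Reliability report across measurement sources
#'
#' Builds the machine-readable analogue of a validation study's report
#' tables from two or more aligned measurement batches (e.g. observers,
#' rounds, or methods): per-measurement ICC across all sources, pairwise
#' Bland-Altman bias and limits of agreement with systematic-error flags,
#' and pairwise diagnostic percent agreement with prevalences.  Hips with a
#' missing value for a measurement in any source are dropped for that
#' measurement's row (listwise), and the per-row `n_used` records the
#' reduced n.
#'
#' @param batches named list (>= 2) of measurement data.frames from
#'   [measure_batch()], aligned by hip: identical `image_id`/`side`
#'   sequences.
#' @param t [thresholds()] used for the diagnostic-agreement table.
#' @param icc_model ICC model label, see [icc()].
#' @return an object of class `reliability_report`: data.frames `icc`
#'   (measurement, estimate, ci, rating, n_used, n_dropped),
#'   `bland_altman` (per measurement and source pair) and `diagnosis`
#'   (per flag and source pair).
#' @export
reliability_report <- function(batches, t = thresholds(),
                               icc_model = "two-way-random") {
  stopifnot(is.list(batches))
  if (length(batches) < 2L || is.null(names(batches)) || any(!nzchar(names(batches))))
    hm_error("need >= 2 named measurement batches", "hipmorph_config")
  ids <- lapply(batches, function(b) paste(b$image_id, b$side))
  for (j in seq_along(ids)[-1L]) {
    if (!identical(ids[[1L]], ids[[j]])) {
      bad <- union(setdiff(ids[[1L]], ids[[j]]), setdiff(ids[[j]], ids[[1L]]))
      hm_error(sprintf("batches are misaligned; unmatched hips: %s",
                       paste(unique(c(bad, "(ordering differs)")), collapse = ", ")),
               "hipmorph_config")
    }
  }
  n_hips <- nrow(batches[[1L]])
  if (n_hips < 2L)
    hm_error(sprintf("reliability statistics need at least 2 hips (have %d)", n_hips),
             "hipmorph_insufficient_data")
  src <- names(batches)

  icc_rows <- lapply(MEASUREMENT_NAMES, function(nm) {
    m <- sapply(batches, function(b) b[[nm]])
    res <- tryCatch(icc(m, model = icc_model, type = "absolute-agreement"),
                    hipmorph_error = function(e) NULL)
    data.frame(measurement = nm,
               icc = if (is.null(res)) NA_real_ else res$estimate,
               ci_lo = if (is.null(res)) NA_real_ else res$ci95[1L],
               ci_hi = if (is.null(res)) NA_real_ else res$ci95[2L],
               rating = if (is.null(res)) NA_character_ else res$rating,
               n_used = if (is.null(res)) 0L else res$n_used,
               n_dropped = if (is.null(res)) n_hips else res$n_dropped)
  })

  pairs <- utils::combn(src, 2L, simplify = FALSE)
  ba_rows <- list()
  for (p in pairs) {
    for (nm in MEASUREMENT_NAMES) {
      res <- tryCatch(
        bland_altman(batches[[p[1L]]][[nm]], batches[[p[2L]]][[nm]],
                     kind = MEASUREMENT_KIND[[nm]]),
        hipmorph_error = function(e) NULL)
      ba_rows[[length(ba_rows) + 1L]] <- data.frame(
        measurement = nm, source_a = p[1L], source_b = p[2L],
        bias = if (is.null(res)) NA_real_ else res$bias,
        loa_lo = if (is.null(res)) NA_real_ else res$loa[1L],
        loa_hi = if (is.null(res)) NA_real_ else res$loa[2L],
        systematic_error = if (is.null(res)) NA else res$systematic_error,
        n_used = if (is.null(res)) 0L else res$n)
    }
  }

  flags <- lapply(batches, classify_batch, t = t)
  dg_rows <- list()
  for (p in pairs) {
    da <- diagnostic_agreement(flags[[p[1L]]], flags[[p[2L]]])
    da$source_a <- p[1L]; da$source_b <- p[2L]
    dg_rows[[length(dg_rows) + 1L]] <- da
  }

  structure(list(icc = do.call(rbind, icc_rows),
                 bland_altman = do.call(rbind, ba_rows),
                 diagnosis = do.call(rbind, dg_rows),
                 n_hips = n_hips, sources = src, thresholds = t),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report: %d hips, sources: %s>\n",
              x$n_hips, paste(x$sources, collapse = ", ")))
  cat("\nICC (single rater, absolute agreement):\n")
  print(x$icc, row.names = FALSE, digits = 3)
  cat("\nBland-Altman:\n")
  print(x$bland_altman, row.names = FALSE, digits = 3)
  cat("\nDiagnostic agreement:\n")
  print(x$diagnosis, row.names = FALSE, digits = 3)
  invisible(x)
}
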