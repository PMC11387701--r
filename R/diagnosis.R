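# Radiographic morphological diagnosis from measurement thresholds.

FLAG_NAMES <- c("dysplasia_adr", "dysplasia_mai", "overcoverage_mai",
                "dysplasia_wcea", "dysplasia_ei", "pincer_lcea",
                "cam_aa", "coxa_valga", "coxa_vara", "dysplasia_any")

# measurement feeding each per-measurement flag
FLAG_SOURCE <- c(dysplasia_adr = "adr", dysplasia_mai = "mai_deg",
                 overcoverage_mai = "mai_deg", dysplasia_wcea = "wcea_deg",
                 dysplasia_ei = "ei_pct", pincer_lcea = "lcea_deg",
                 cam_aa = "alpha_deg", coxa_valga = "nsa_deg",
                 coxa_vara = "nsa_deg")

#' Diagnostic thresholds
#'
#' Literature thresholds for radiographic morphological diagnosis.
#' Defaults: acetabular dysplasia at ADR <= 250, mAI >= 13 deg,
#' WCEA <= 25 deg or EI >= 25%; acetabular overcoverage at mAI <= 3 deg;
#' pincer morphology at LCEA >= 40 deg; cam morphology at alpha angle
#' >= 60 deg; coxa valga at NSA > 140 deg and coxa vara at NSA < 120 deg.
#' Comparator inclusivity follows the printed symbols: `<=`/`>=` inclusive,
#' NSA bounds strict.  All values are overridable.
#'
#' @param adr_max,mai_dysplasia_min,mai_overcoverage_max,wcea_max,lcea_min
#'   per-measurement cutoffs.
#' @param ei_min,aa_min,nsa_valga_exclusive_min,nsa_vara_exclusive_max
#'   per-measurement cutoffs.
#' @return an object of class `hip_thresholds`.
#' @export
thresholds <- function(adr_max = 250, mai_dysplasia_min = 13,
                       mai_overcoverage_max = 3, wcea_max = 25,
                       lcea_min = 40, ei_min = 25, aa_min = 60,
                       nsa_valga_exclusive_min = 140,
                       nsa_vara_exclusive_max = 120) {
  t <- list(adr_max = adr_max, mai_dysplasia_min = mai_dysplasia_min,
            mai_overcoverage_max = mai_overcoverage_max, wcea_max = wcea_max,
            lcea_min = lcea_min, ei_min = ei_min, aa_min = aa_min,
            nsa_valga_exclusive_min = nsa_valga_exclusive_min,
            nsa_vara_exclusive_max = nsa_vara_exclusive_max)
  for (nm in names(t)) if (!is_number(t[[nm]]))
    hm_error(sprintf("threshold %s must be a finite number", nm), "hipmorph_config")
  if (t$nsa_vara_exclusive_max >= t$nsa_valga_exclusive_min)
    hm_error("vara cutoff must be below valga cutoff", "hipmorph_config")
  structure(t, class = "hip_thresholds")
}

#' Classify radiographic morphological diagnoses
#'
#' Applies the per-measurement thresholds to one hip's measurements.
#' Missing measurements yield missing (`NA`) flags.  Besides the
#' per-measurement flags, a convenience `dysplasia_any` flag combines the
#' four dysplasia measurements (ADR, mAI, WCEA, EI): `TRUE` when any of the
#' present measurements is positive, `NA` when none is positive but at
#' least one is missing.
#'
#' @param m a `hip_measurements` object, a named numeric vector, or a
#'   one-row data.frame with the measurement columns.
#' @param t a [thresholds()] object.
#' @return named logical vector over the diagnosis flags.
#' @examples
#' classify(c(alpha_deg = 60), thresholds())["cam_aa"]   # TRUE (inclusive)
#' @export
classify <- function(m, t = thresholds()) {
  v <- if (inherits(m, "hip_measurements")) m$values
  else if (is.data.frame(m)) {
    stopifnot(nrow(m) == 1L)
    stats::setNames(vapply(MEASUREMENT_NAMES, function(nm)
      if (nm %in% names(m)) as.numeric(m[[nm]]) else NA_real_, 0), MEASUREMENT_NAMES)
  } else {
    full <- stats::setNames(rep(NA_real_, length(MEASUREMENT_NAMES)),
                            MEASUREMENT_NAMES)
    full[intersect(names(m), MEASUREMENT_NAMES)] <-
      m[intersect(names(m), MEASUREMENT_NAMES)]
    full
  }
  stopifnot(inherits(t, "hip_thresholds"))
  f <- c(
    dysplasia_adr    = unname(v[["adr"]] <= t$adr_max),
    dysplasia_mai    = unname(v[["mai_deg"]] >= t$mai_dysplasia_min),
    overcoverage_mai = unname(v[["mai_deg"]] <= t$mai_overcoverage_max),
    dysplasia_wcea   = unname(v[["wcea_deg"]] <= t$wcea_max),
    dysplasia_ei     = unname(v[["ei_pct"]] >= t$ei_min),
    pincer_lcea      = unname(v[["lcea_deg"]] >= t$lcea_min),
    cam_aa           = unname(v[["alpha_deg"]] >= t$aa_min),
    coxa_valga       = unname(v[["nsa_deg"]] > t$nsa_valga_exclusive_min),
    coxa_vara        = unname(v[["nsa_deg"]] < t$nsa_vara_exclusive_max)
  )
  dys <- f[c("dysplasia_adr", "dysplasia_mai", "dysplasia_wcea", "dysplasia_ei")]
  f[["dysplasia_any"]] <- if (any(dys, na.rm = TRUE)) TRUE
  else if (anyNA(dys)) NA else FALSE
  f[FLAG_NAMES]
}

#' @rdname classify
#' @param df measurement data.frame from [measure_batch()].
#' @return `classify_batch()` returns a data.frame with `image_id`, `side`
#'   and one logical column per flag.
#' @export
classify_batch <- function(df, t = thresholds()) {
  stopifnot(is.data.frame(df))
  flags <- t(vapply(seq_len(nrow(df)), function(i)
    classify(df[i, , drop = FALSE], t), logical(length(FLAG_NAMES))))
  colnames(flags) <- FLAG_NAMES
  cbind(df[, intersect(c("image_id", "side"), names(df)), drop = FALSE],
        as.data.frame(flags))
}

#' Percent agreement between two sets of diagnosis flags
#'
#' For each flag, the percentage of hips on which the two sources agree
#' (over pairs where both are non-missing) and the prevalence of the
#' positive diagnosis in each source.
#'
#' @param a,b aligned data.frames from [classify_batch()] (equal length,
#'   same hips in the same order).
#' @return data.frame with one row per flag: `flag`, `n_comparable`,
#'   `percent_agreement`, `prevalence_a`, `prevalence_b` (percentages; NA
#'   with zero comparable pairs).
#' @export
diagnostic_agreement <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b))
  if (nrow(a) != nrow(b))
    hm_error("flag lists must be of equal length and aligned by hip",
             "hipmorph_config")
  rows <- lapply(FLAG_NAMES, function(fl) {
    fa <- a[[fl]]; fb <- b[[fl]]
    comp <- !is.na(fa) & !is.na(fb)
    data.frame(flag = fl, n_comparable = sum(comp),
               percent_agreement = if (sum(comp) == 0L) NA_real_
               else 100 * mean(fa[comp] == fb[comp]),
               prevalence_a = if (all(is.na(fa))) NA_real_
               else 100 * mean(fa, na.rm = TRUE),
               prevalence_b = if (all(is.na(fb))) NA_real_
               else 100 * mean(fb, na.rm = TRUE))
  })
  do.call(rbind, rows)
}
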