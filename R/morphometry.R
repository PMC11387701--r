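# The eight radiographic hip-morphology measurements.
#
# All geometry happens in the canonical frame (+x lateral, +y superior);
# measurement functions canonicalize their input and transform the pelvic
# reference axis into that frame, so callers can pass raw image-frame sets.

MEASUREMENT_NAMES <- c("adr", "mai_deg", "alpha_deg", "wcea_deg",
                       "lcea_deg", "ei_pct", "nsa_deg", "tir")

#' Measurement options
#'
#' @param alpha_epsilon relative departure tolerance for the alpha point:
#'   the head-neck contour is considered to have left the best-fitting head
#'   circle at the first landmark whose distance from the center exceeds
#'   `radius * (1 + alpha_epsilon)`.
#' @param tir_orientation report the triangular index ratio as the contour
#'   distance at the 0.5r station over the head radius (`"d_over_r"`,
#'   aspherical heads give values > 1) or its reciprocal (`"r_over_d"`).
#' @return a list of options for [measure_all()].
#' @export
measure_options <- function(alpha_epsilon = 0.01,
                            tir_orientation = c("d_over_r", "r_over_d")) {
  stopifnot(is_number(alpha_epsilon), alpha_epsilon >= 0)
  list(alpha_epsilon = alpha_epsilon,
       tir_orientation = match.arg(tir_orientation))
}

# Shared per-hip geometry: canonical set plus the (lateral, superior)
# orthonormal basis derived from the reference axis.  Orientation is
# resolved anatomically so results do not depend on how the radiograph is
# rotated: lateral points from the teardrop toward the acetabular edge,
# superior from the neck toward the femoral head.
hip_frame <- function(set, ref = NULL) {
  set <- canonicalize(set)
  cref <- canonical_ref(ref, set$side)
  e_lat <- cref$direction
  med_lat <- role_xy(set, "ACETAB_LATERAL_EDGE")[1L, ] -
    role_xy(set, "TEARDROP_CAUDAL")[1L, ]
  if (sum(e_lat * med_lat) < 0) e_lat <- -e_lat
  e_sup <- perp2(e_lat)
  inf_sup <- colMeans(role_xy(set, "HEAD_CONTOUR")) -
    colMeans(role_xy(set, "NECK_LATERAL"))
  if (sum(e_sup * inf_sup) < 0) e_sup <- -e_sup
  list(set = set, e_lat = e_lat, e_sup = e_sup)
}

#' Acetabular depth-width ratio (ADR)
#'
#' The acetabular width B runs from the lateral bony edge of the acetabulum
#' to the caudal point of the teardrop; the depth A is the perpendicular
#' distance from the medial point of the acetabular sourcil to the width
#' line.  ADR = A / B * 1000.  Values at or below 250 indicate acetabular
#' dysplasia.
#'
#' @param set a `landmark_set`.
#' @param ref pelvic reference axis (unused by ADR, accepted for interface
#'   uniformity).
#' @return dimensionless ratio (x 1000).
#' @export
measure_adr <- function(set, ref = NULL) {
  set <- canonicalize(set)
  E <- role_xy(set, "ACETAB_LATERAL_EDGE")[1L, ]
  Tt <- role_xy(set, "TEARDROP_CAUDAL")[1L, ]
  S <- role_xy(set, "SOURCIL_MEDIAL")[1L, ]
  B <- vnorm(E - Tt)
  if (B == 0)
    hm_error("acetabular width is zero; ADR undefined", "hipmorph_degenerate")
  A <- abs(cross2(E - Tt, S - Tt)) / B
  unname(A / B * 1000)
}

#' Modified acetabular index (mAI)
#'
#' The inclination of the acetabular roof: the signed angle between the
#' pelvic horizontal reference line and the line from the medial sourcil
#' point to the lateral bony edge of the acetabulum.  Positive when the
#' lateral edge lies superior to the medial sourcil (up-sloping roof).
#' Dysplasia at >= 13 deg, acetabular overcoverage at <= 3 deg.
#'
#' @inheritParams measure_adr
#' @return degrees (signed).
#' @export
measure_mai <- function(set, ref = NULL) {
  fr <- hip_frame(set, ref)
  S <- role_xy(fr$set, "SOURCIL_MEDIAL")[1L, ]
  E <- role_xy(fr$set, "ACETAB_LATERAL_EDGE")[1L, ]
  v <- E - S
  if (vnorm(v) == 0)
    hm_error("sourcil and acetabular edge coincide; mAI undefined",
             "hipmorph_degenerate")
  a <- angle_deg(fr$e_lat, v, signed = TRUE)
  if (a > 90) a <- a - 180 else if (a < -90) a <- a + 180
  a
}

# superior-side contour candidates relative to the neck axis:
# polar angle theta from the neck direction, distance from the center
superior_contour <- function(set, head, neck) {
  ctr <- as.numeric(head$center)
  u <- neck$direction
  idx_head <- set$schema$roles$HEAD_CONTOUR + 1L
  idx_junc <- set$schema$roles$HEADNECK_SUPERIOR_CONTOUR + 1L
  pts <- set$points[c(idx_head, idx_junc), , drop = FALSE]
  src <- c(rep("head", length(idx_head)), rep("junction", length(idx_junc)))
  d <- sweep(pts, 2L, ctr)
  cr <- u[1L] * d[, 2L] - u[2L] * d[, 1L]
  keep <- cr > 0  # superior-lateral side of the neck axis
  pts <- pts[keep, , drop = FALSE]
  d <- d[keep, , drop = FALSE]
  theta <- rad2deg(atan2(abs(u[1L] * d[, 2L] - u[2L] * d[, 1L]),
                         d %*% u))
  list(points = pts, dist = sqrt(rowSums(d^2)), theta = as.numeric(theta),
       t = as.numeric(d %*% u), source = src[keep],
       center = ctr, u = u, radius = head$radius,
       last_junction = set$points[idx_junc[length(idx_junc)], ])
}

#' Alpha angle (AA)
#'
#' Quantifies sphericity of the femoral head-neck junction: the angle
#' between the femoral head-neck axis and the line from the femoral head
#' center to the alpha point, where the contour of the head-neck junction
#' leaves the best-fitting circle around the femoral head.  The contour is
#' traversed on the superior-lateral side from the point farthest from the
#' neck toward the neck; the alpha point is the first landmark whose
#' distance from the center exceeds `radius * (1 + alpha_epsilon)`.  If no
#' landmark leaves the circle the last superior-contour landmark is used.
#' Values at or above 60 deg indicate cam morphology.
#'
#' @inheritParams measure_adr
#' @param head optional precomputed `hip_circle`.
#' @param neck optional precomputed neck `hip_axis`.
#' @param options see [measure_options()].
#' @return list with `alpha_deg` and `alpha_point` (canonical frame).
#' @export
measure_alpha <- function(set, head = NULL, neck = NULL,
                          options = measure_options()) {
  set <- canonicalize(set)
  if (is.null(head)) head <- fit_circle(role_xy(set, "HEAD_CONTOUR"))
  if (is.null(neck)) neck <- neck_axis(set, head)
  sc <- superior_contour(set, head, neck)
  thresh <- sc$radius * (1 + options$alpha_epsilon)
  ord <- order(sc$theta, decreasing = TRUE)
  # Departure detection runs on a 3-point running median of the radial
  # profile along the contour: noiseless contours are untouched (the
  # median never leaks the junction bump onto its spherical neighbour, nor
  # a single noisy landmark onto the head), while isolated annotation
  # outliers are suppressed.  The reported alpha point is a raw landmark.
  dist_s <- sc$dist[ord]
  n_c <- length(dist_s)
  if (n_c >= 3L) {
    sm <- dist_s
    for (i in 2:(n_c - 1L))
      sm[i] <- sort(dist_s[(i - 1L):(i + 1L)])[2L]
    dist_s <- sm
  }
  outside <- dist_s > thresh
  # The alpha point is where the contour durably leaves the circle: the
  # first landmark of the last run of consecutive outside landmarks (the
  # run reaching the neck).  On noiseless contours this is exactly the
  # first landmark exceeding the tolerance; isolated excursions of noisy
  # head-contour landmarks near the apex do not trigger it.
  ap <- NULL
  if (any(outside)) {
    runs <- rle(outside)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    k <- max(which(runs$values))
    ap <- sc$points[ord[starts[k]], ]
  }
  if (is.null(ap)) ap <- sc$last_junction
  v <- ap - sc$center
  list(alpha_deg = angle_deg(sc$u, v), alpha_point = as.numeric(ap))
}

# shared CEA geometry
cea <- function(set, ref, head, role) {
  fr <- hip_frame(set, ref)
  if (is.null(head)) head <- fit_circle(role_xy(fr$set, "HEAD_CONTOUR"))
  P <- role_xy(fr$set, role)[1L, ]
  v <- P - as.numeric(head$center)
  if (vnorm(v) == 0)
    hm_error("edge point coincides with femoral head center", "hipmorph_degenerate")
  unname(rad2deg(atan2(sum(v * fr$e_lat), sum(v * fr$e_sup))))
}

#' Wiberg and lateral center-edge angles (WCEA, LCEA)
#'
#' Angle between the vertical through the femoral head center
#' (perpendicular to the pelvic horizontal) and the line from the head
#' center to the lateral point of the acetabular sourcil (WCEA, weight-
#' bearing coverage) or the lateral bony edge of the acetabulum (LCEA,
#' bony coverage).  Signed: negative when the edge point lies medial to the
#' vertical, as in dysplastic hips.  WCEA <= 25 deg indicates dysplasia;
#' LCEA >= 40 deg indicates pincer morphology.
#'
#' @inheritParams measure_alpha
#' @return degrees (signed).
#' @export
measure_wcea <- function(set, ref = NULL, head = NULL)
  cea(set, ref, head, "SOURCIL_LATERAL")

#' @rdname measure_wcea
#' @export
measure_lcea <- function(set, ref = NULL, head = NULL)
  cea(set, ref, head, "ACETAB_LATERAL_EDGE")

#' Extrusion index (EI)
#'
#' Percentage of the femoral head width lying lateral to (uncovered by) the
#' lateral bony edge of the acetabulum, measured along the pelvic
#' horizontal.  The medial and lateral head extremes are taken from the
#' fitted head circle, which is robust to contour sampling density.
#' EI >= 25% indicates acetabular dysplasia.
#'
#' @inheritParams measure_alpha
#' @return percent in [0, 100].
#' @export
measure_ei <- function(set, ref = NULL, head = NULL) {
  fr <- hip_frame(set, ref)
  if (is.null(head)) head <- fit_circle(role_xy(fr$set, "HEAD_CONTOUR"))
  E <- role_xy(fr$set, "ACETAB_LATERAL_EDGE")[1L, ]
  xc <- sum(as.numeric(head$center) * fr$e_lat)
  xe <- sum(E * fr$e_lat)
  A <- max(0, (xc + head$radius) - xe)  # uncovered lateral head
  B <- max(0, xe - (xc - head$radius))  # covered head width
  if (A + B <= 0)
    hm_error("degenerate geometry: femoral head has zero width along the reference",
             "hipmorph_degenerate")
  unname(A / (A + B) * 100)
}

#' Neck-shaft angle (NSA)
#'
#' The angle between the femoral head-neck axis (oriented from the neck
#' toward the head center) and the distally oriented longitudinal axis of
#' the femoral shaft.  Typical anatomy yields 110-150 deg; NSA > 140 deg
#' defines coxa valga and NSA < 120 deg coxa vara.  When fewer than two
#' shaft landmark pairs are depicted the measurement is reported missing.
#'
#' @inheritParams measure_alpha
#' @param shaft optional precomputed shaft `hip_axis`.
#' @return degrees.
#' @export
measure_nsa <- function(set, head = NULL, neck = NULL, shaft = NULL) {
  set <- canonicalize(set)
  if (is.null(neck)) {
    if (is.null(head)) head <- fit_circle(role_xy(set, "HEAD_CONTOUR"))
    neck <- neck_axis(set, head)
  }
  if (is.null(shaft)) shaft <- shaft_axis(set)
  angle_deg(-neck$direction, shaft$direction)
}

#' Triangular index ratio (TIR)
#'
#' Asphericity of the femoral head at a fixed station: the superior
#' head-neck contour (piecewise linear between landmarks) is intersected
#' with the line perpendicular to the head-neck axis at 0.5r along the axis
#' from the head center; `d` is the distance from the center to that
#' intersection S.  Reported as d/r by default, so TIR > 1 means the
#' contour lies outside the best-fitting head circle at the station,
#' indicating an aspherical (cam) head.
#'
#' @inheritParams measure_alpha
#' @return dimensionless ratio.
#' @export
measure_tir <- function(set, head = NULL, neck = NULL,
                        options = measure_options()) {
  set <- canonicalize(set)
  if (is.null(head)) head <- fit_circle(role_xy(set, "HEAD_CONTOUR"))
  if (is.null(neck)) neck <- neck_axis(set, head)
  sc <- superior_contour(set, head, neck)
  if (nrow(sc$points) < 2L)
    hm_error("superior contour too short; TIR undefined", "hipmorph_missing_value")
  tstar <- 0.5 * sc$radius
  if (tstar < min(sc$t) || tstar > max(sc$t))
    hm_error("contour does not reach the 0.5r station; TIR unavailable",
             "hipmorph_missing_value")
  # local linear fit of contour distance vs axial station around 0.5r:
  # equivalent to intersecting the piecewise-linear contour on noiseless
  # data, but averages landmark noise instead of relying on one chord
  near <- order(abs(sc$t - tstar))[seq_len(min(4L, length(sc$t)))]
  tt <- sc$t[near]; dd <- sc$dist[near]
  d <- if (max(tt) - min(tt) < 1e-9) mean(dd) else {
    cf <- stats::coef(stats::lm(dd ~ tt))
    unname(cf[1L] + cf[2L] * tstar)
  }
  if (options$tir_orientation == "d_over_r") d / sc$radius else sc$radius / d
}

#' Compute all eight measurements for one hip
#'
#' Runs the full measurement battery on one landmark set.  Individual
#' failures (missing shaft, degenerate geometry) become missing values with
#' a reason and never abort the remaining measurements.
#'
#' @param set a `landmark_set` (image or canonical frame).
#' @param ref pelvic reference axis from [pelvic_reference_axis()]; `NULL`
#'   assumes the image horizontal.
#' @param options see [measure_options()].
#' @return an object of class `hip_measurements`: named `values` (NA when
#'   missing), `missing` reasons, the fitted `head` circle, the
#'   `alpha_point`, and the hip's `image_id`/`side`.
#' @export
measure_all <- function(set, ref = NULL, options = measure_options()) {
  set <- canonicalize(set)
  values <- stats::setNames(rep(NA_real_, length(MEASUREMENT_NAMES)),
                            MEASUREMENT_NAMES)
  missing <- character(0)
  alpha_point <- NULL

  grab <- function(name, expr) {
    res <- tryCatch(expr, hipmorph_error = function(e) {
      missing[[name]] <<- conditionMessage(e)
      NA_real_
    })
    values[[name]] <<- if (is.numeric(res)) res else NA_real_
    invisible(res)
  }

  head <- tryCatch(fit_circle(role_xy(set, "HEAD_CONTOUR")),
                   hipmorph_error = function(e) e)
  if (inherits(head, "condition")) {
    for (nm in c("alpha_deg", "wcea_deg", "lcea_deg", "ei_pct", "nsa_deg", "tir"))
      missing[[nm]] <- conditionMessage(head)
    head <- NULL
  }
  neck <- if (!is.null(head))
    tryCatch(neck_axis(set, head), hipmorph_error = function(e) e) else NULL
  if (inherits(neck, "condition")) {
    for (nm in c("alpha_deg", "nsa_deg", "tir"))
      missing[[nm]] <- conditionMessage(neck)
    neck <- NULL
  }

  grab("adr", measure_adr(set))
  grab("mai_deg", measure_mai(set, ref))
  if (!is.null(head)) {
    grab("wcea_deg", measure_wcea(set, ref, head))
    grab("lcea_deg", measure_lcea(set, ref, head))
    grab("ei_pct", measure_ei(set, ref, head))
    if (!is.null(neck)) {
      a <- tryCatch(measure_alpha(set, head, neck, options),
                    hipmorph_error = function(e) {
                      missing[["alpha_deg"]] <<- conditionMessage(e); NULL
                    })
      if (!is.null(a)) { values[["alpha_deg"]] <- a$alpha_deg; alpha_point <- a$alpha_point }
      grab("nsa_deg", measure_nsa(set, head, neck))
      grab("tir", measure_tir(set, head, neck, options))
    }
  }

  structure(list(values = values, missing = unlist(missing) %||% character(0),
                 head = head, alpha_point = alpha_point,
                 image_id = set$image_id, side = set$side),
            class = "hip_measurements")
}

#' @export
print.hip_measurements <- function(x, ...) {
  cat(sprintf("<hip_measurements: image %s, %s hip>\n", x$image_id, x$side))
  for (nm in names(x$values)) {
    if (is.na(x$values[[nm]]))
      cat(sprintf("  %-10s missing (%s)\n", nm, x$missing[[nm]] %||% "unknown"))
    else cat(sprintf("  %-10s %.2f\n", nm, x$values[[nm]]))
  }
  invisible(x)
}

#' Measure a batch of hips
#'
#' @param sets list of `landmark_set`s.
#' @param refs a single reference `hip_axis`, a list of per-hip axes, or
#'   `NULL` (image horizontal).
#' @param options see [measure_options()].
#' @return data.frame with one row per hip: `image_id`, `side`, the eight
#'   measurement columns, `head_rms` (circle-fit residual) and
#'   `missing_reasons` (semicolon-separated `name: reason` entries).
#' @export
measure_batch <- function(sets, refs = NULL, options = measure_options()) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  per_hip <- is.list(refs) && !inherits(refs, "hip_axis")
  rows <- lapply(seq_along(sets), function(i) {
    ref <- if (per_hip) refs[[i]] else refs
    m <- measure_all(sets[[i]], ref = ref, options = options)
    as.data.frame(m)
  })
  do.call(rbind, rows)
}

#' @export
as.data.frame.hip_measurements <- function(x, ...) {
  df <- as.data.frame(as.list(x$values))
  cbind(data.frame(image_id = x$image_id, side = x$side),
        df,
        data.frame(head_rms = if (is.null(x$head)) NA_real_ else x$head$rms,
                   missing_reasons = if (length(x$missing) == 0L) ""
                   else paste(sprintf("%s: %s", names(x$missing), x$missing),
                              collapse = "; ")))
}

#' Read and write measurement CSV files
#'
#' Measurement tables are written as UTF-8 CSV with `#`-prefixed header
#' metadata lines and measurement values rounded to two decimals (internal
#' computations keep full precision).
#'
#' @param df data.frame from [measure_batch()].
#' @param path output path.
#' @param meta named character vector echoed as `# key: value` lines.
#' @export
write_measurements_csv <- function(df, path, meta = character(0)) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  out <- df
  for (nm in intersect(MEASUREMENT_NAMES, names(out)))
    out[[nm]] <- round(out[[nm]], 2)
  utils::write.csv(out, con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  if (!file.exists(path))
    hm_error(sprintf("measurements CSV not found: %s", path), "hipmorph_io")
  utils::read.csv(path, comment.char = "#")
}
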