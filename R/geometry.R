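# Geometric primitives: circle fit, angles, reference axes.

#' Least-squares circle fit
#'
#' Fits a circle to 2-D points by least squares: an algebraic (Kasa)
#' solution of the linearized system initializes a Gauss-Newton refinement
#' of the geometric (orthogonal-distance) objective, iterated until the
#' parameter change falls below 1e-9 px.  Exact on points lying on a true
#' circle.  Used for the best-fitting circle around the femoral head.
#'
#' @param points numeric m x 2 matrix, m >= 3, not all collinear.
#' @param tol convergence tolerance on the parameter step, in px.
#' @param max_iter iteration cap for the geometric refinement.
#' @return an object of class `hip_circle`: list with `center` (x, y),
#'   `radius`, `rms` (root-mean-square orthogonal residual) and `n`.
#' @examples
#' fit_circle(rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)))
#' @export
fit_circle <- function(points, tol = 1e-9, max_iter = 100L) {
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    hm_error("circle fit needs at least 3 points", "hipmorph_degenerate")
  x <- points[, 1L]; y <- points[, 2L]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  # collinearity check on the normal equations
  AtA <- crossprod(A)
  if (kappa(AtA, exact = TRUE) > 1e12)
    hm_error("circle fit is degenerate (collinear points)", "hipmorph_degenerate")
  sol <- solve(AtA, crossprod(A, b))
  cx <- sol[1L]; cy <- sol[2L]
  r <- sqrt(sol[3L] + cx^2 + cy^2)
  # Gauss-Newton on residuals r_i = ||p_i - c|| - r
  par <- c(cx, cy, r)
  for (it in seq_len(max_iter)) {
    dx <- x - par[1L]; dy <- y - par[2L]
    di <- sqrt(dx^2 + dy^2)
    di[di == 0] <- .Machine$double.eps
    res <- di - par[3L]
    J <- cbind(-dx / di, -dy / di, -1)
    step <- tryCatch(solve(crossprod(J), -crossprod(J, res)),
                     error = function(e) rep(0, 3))
    par <- par + as.numeric(step)
    if (max(abs(step)) <= tol) break
  }
  dx <- x - par[1L]; dy <- y - par[2L]
  res <- sqrt(dx^2 + dy^2) - par[3L]
  if (!is.finite(par[3L]) || par[3L] <= 0)
    hm_error("circle fit produced a non-positive radius", "hipmorph_degenerate")
  structure(list(center = c(x = par[1L], y = par[2L]), radius = par[3L],
                 rms = sqrt(mean(res^2)), n = nrow(points)),
            class = "hip_circle")
}

#' @export
print.hip_circle <- function(x, ...) {
  cat(sprintf("<hip_circle: center (%.3f, %.3f), r %.3f, rms %.2g, n %d>\n",
              x$center[1L], x$center[2L], x$radius, x$rms, x$n))
  invisible(x)
}

#' Angle between two vectors, in degrees
#'
#' @param u,v non-zero 2-vectors.
#' @param signed when `TRUE`, returns the rotation from `u` to `v` in
#'   (-180, 180], positive counter-clockwise; otherwise the unsigned angle
#'   in [0, 180].
#' @return degrees.
#' @examples
#' angle_deg(c(1, 0), c(0, 1))          # 90
#' angle_deg(c(1, 0), c(1, -1), TRUE)   # -45
#' @export
angle_deg <- function(u, v, signed = FALSE) {
  if (vnorm(u) == 0 || vnorm(v) == 0)
    hm_error("angle of a zero vector is undefined", "hipmorph_degenerate")
  a <- unname(rad2deg(atan2(cross2(u, v), sum(u * v))))
  if (signed) a else abs(a)
}

#' Reference and anatomical axes
#'
#' An axis is a point plus a unit direction with a semantic label
#' (`"pelvic_horizontal"`, `"neck"` for the femoral head-neck axis, or
#' `"shaft"` for the longitudinal femoral shaft axis) and a coordinate
#' `frame` attribute (`"image"` or `"canonical"`).
#'
#' @param point 2-vector on the axis.
#' @param direction 2-vector; normalized internally.
#' @param label axis label.
#' @param frame coordinate frame the axis lives in.
#' @return an object of class `hip_axis`.
#' @export
hip_axis <- function(point, direction,
                     label = c("pelvic_horizontal", "neck", "shaft"),
                     frame = c("image", "canonical")) {
  label <- match.arg(label)
  frame <- match.arg(frame)
  structure(list(point = as.numeric(point), direction = unit(as.numeric(direction)),
                 label = label, frame = frame),
            class = "hip_axis")
}

#' @export
print.hip_axis <- function(x, ...) {
  cat(sprintf("<hip_axis %s (%s frame): point (%.2f, %.2f), direction (%.4f, %.4f)>\n",
              x$label, x$frame, x$point[1L], x$point[2L],
              x$direction[1L], x$direction[2L]))
  invisible(x)
}

#' Horizontal reference line of the pelvis
#'
#' The pelvic horizontal runs through the caudal teardrop landmarks of the
#' left and right hips of one radiograph, direction normalized from the
#' left-side set's teardrop to the right-side set's.  With a single hip no
#' reference can be built; the caller may supply an explicit fallback
#' (typically the image horizontal), which is returned unchanged.
#'
#' @param pair a [hip_pair()]; may be `NULL` when `fallback` is given.
#' @param fallback an image-frame `hip_axis` used when no pair is available.
#' @return an image-frame `hip_axis` labelled `"pelvic_horizontal"`.
#' @export
pelvic_reference_axis <- function(pair, fallback = NULL) {
  if (is.null(pair) || !inherits(pair, "hip_pair")) {
    if (!is.null(fallback)) return(fallback)
    hm_error("reference line unavailable: need both hips or an explicit fallback axis",
             "hipmorph_missing_reference")
  }
  tl <- role_xy(pair$left, "TEARDROP_CAUDAL")[1L, ]
  tr <- role_xy(pair$right, "TEARDROP_CAUDAL")[1L, ]
  if (all(tl == tr))
    hm_error("teardrop landmarks coincide; reference line undefined",
             "hipmorph_degenerate")
  hip_axis(point = tl, direction = tr - tl, label = "pelvic_horizontal",
           frame = "image")
}

# Express a reference axis in the canonical frame of `side`, oriented so the
# lateral direction is +x.  Canonical-frame axes pass through unchanged
# (up to orientation).
canonical_ref <- function(ref, side) {
  if (is.null(ref))
    return(hip_axis(c(0, 0), c(1, 0), "pelvic_horizontal", frame = "canonical"))
  d <- ref$direction
  if (identical(ref$frame, "image")) {
    d[2L] <- -d[2L]
    if (side == "right") d[1L] <- -d[1L]
  }
  if (d[1L] < 0) d <- -d
  hip_axis(c(0, 0), d, ref$label, frame = "canonical")
}

#' Femoral head-neck axis
#'
#' The axis from the fitted femoral head center through the middle of the
#' femoral neck.  Neck cross-sections pair the i-th lateral with the i-th
#' medial neck landmark; the middle of the neck is taken as the midpoint of
#' the narrowest cross-section (minimum pair distance).  The direction
#' points from the head center toward the neck.
#'
#' @param set a canonicalized `landmark_set` with neck segments.
#' @param head a `hip_circle` for the femoral head; fitted from the head
#'   contour when `NULL`.
#' @return a canonical-frame `hip_axis` labelled `"neck"`.
#' @export
neck_axis <- function(set, head = NULL) {
  set <- canonicalize(set)
  if (!role_present(set, "NECK_LATERAL") || !role_present(set, "NECK_MEDIAL"))
    hm_error("neck landmarks absent; head-neck axis unavailable",
             "hipmorph_missing_axis")
  if (is.null(head)) head <- fit_circle(role_xy(set, "HEAD_CONTOUR"))
  lat <- role_xy(set, "NECK_LATERAL")
  med <- role_xy(set, "NECK_MEDIAL")
  m <- min(nrow(lat), nrow(med))
  if (m < 1L)
    hm_error("empty neck segments; head-neck axis unavailable",
             "hipmorph_missing_axis")
  lat <- lat[seq_len(m), , drop = FALSE]
  med <- med[seq_len(m), , drop = FALSE]
  w <- sqrt(rowSums((lat - med)^2))
  j <- which.min(w)
  mid <- (lat[j, ] + med[j, ]) / 2
  ctr <- as.numeric(head$center)
  if (all(mid == ctr))
    hm_error("neck midpoint coincides with head center", "hipmorph_degenerate")
  hip_axis(point = ctr, direction = mid - ctr, label = "neck",
           frame = "canonical")
}

#' Longitudinal axis of the femoral shaft
#'
#' Least-squares line through the midpoints of paired (lateral, medial)
#' shaft landmarks, oriented distally (away from the femoral head).  At
#' least two pairs are required; with fewer the shaft is considered not
#' depicted and the neck-shaft angle must be reported missing.
#'
#' @param set a canonicalized `landmark_set`.
#' @return a canonical-frame `hip_axis` labelled `"shaft"`.
#' @export
shaft_axis <- function(set) {
  set <- canonicalize(set)
  if (!role_present(set, "SHAFT_LATERAL") || !role_present(set, "SHAFT_MEDIAL"))
    hm_error("insufficient femoral shaft depicted; shaft axis unavailable",
             "hipmorph_missing_shaft")
  lat <- role_xy(set, "SHAFT_LATERAL")
  med <- role_xy(set, "SHAFT_MEDIAL")
  m <- min(nrow(lat), nrow(med))
  if (m < 2L)
    hm_error("insufficient femoral shaft depicted; shaft axis unavailable",
             "hipmorph_missing_shaft")
  mids <- (lat[seq_len(m), , drop = FALSE] + med[seq_len(m), , drop = FALSE]) / 2
  ctrd <- colMeans(mids)
  cen <- sweep(mids, 2L, ctrd)
  if (max(abs(cen)) < 1e-12)
    hm_error("shaft midpoints coincide; shaft axis undefined", "hipmorph_degenerate")
  sv <- svd(cen)
  d <- sv$v[, 1L]
  # orient distally: away from the femoral head region
  head_ctrd <- colMeans(role_xy(set, "HEAD_CONTOUR"))
  if (sum(d * (ctrd - head_ctrd)) < 0) d <- -d
  hip_axis(point = ctrd, direction = d, label = "shaft", frame = "canonical")
}
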