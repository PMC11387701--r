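# Parametric synthetic hip generator: builds landmark sets with prescribed
# ground-truth morphology, plus observer-noise simulation, so the whole
# pipeline is testable without radiographs.
#
# Construction happens in the canonical frame (+x lateral, +y superior),
# femoral head center at the origin:
#   - head contour on a circle of radius r, spanning from the infero-medial
#     head across the apex down to `gap` degrees above the target alpha
#     angle (polar angles measured from the neck axis);
#   - superior head-neck junction contour leaving the circle at the target
#     alpha angle via a radial bump that grows linearly past the alpha
#     station (amplitude scaled by cam_bump_scale; at scale >= 1 the
#     departure-tolerance rule triggers at the first junction landmark, so
#     the alpha-angle ground truth is exact);
#   - neck border pairs whose narrowest cross-section midpoint lies exactly
#     on the neck axis; shaft border pairs whose midpoints realize the
#     target neck-shaft angle exactly;
#   - acetabular anchor points placed to realize the target LCEA, WCEA,
#     mAI and ADR exactly (teardrop position solved from the ADR);
#   - teardrops of the two hips at equal image height, so the pelvic
#     reference line is exactly horizontal;
#   - the contralateral hip is the exact mirror image.
# The extrusion index and triangular index ratio are emergent: their ground
# truths are derived analytically from the construction, not prescribed.

#' Specification of one synthetic hip
#'
#' @param head_radius femoral head radius in px.
#' @param target_alpha_deg alpha angle at which the head-neck contour
#'   leaves the head circle, in (40, 100).
#' @param target_lcea_deg,target_wcea_deg lateral and Wiberg center-edge
#'   angles in (-10, 60); the bony edge must not be medial to the sourcil
#'   edge (`lcea >= wcea`).
#' @param target_mai_deg acetabular roof inclination.
#' @param target_adr acetabular depth-width ratio (x 1000).
#' @param target_nsa_deg neck-shaft angle in (100, 160).
#' @param neck_axis_tilt_deg tilt of the head-neck axis from vertical.
#' @param include_shaft generate femoral-shaft landmarks; when `FALSE` the
#'   schema omits the shaft segments and the NSA ground truth is missing.
#' @param contour_spacing_deg landmark spacing of the junction contour near
#'   the alpha station; bounds the alpha-angle quantization error.
#' @param cam_bump_scale scales the radial cam bump beyond the alpha
#'   station (>= 1 keeps the alpha ground truth exact).
#' @param alpha_epsilon departure tolerance the bump is calibrated against;
#'   must match the measurement option of the same name.
#' @return an object of class `hip_spec`.
#' @export
hip_spec <- function(head_radius = 100, target_alpha_deg = 55,
                     target_lcea_deg = 30, target_wcea_deg = 25,
                     target_mai_deg = 5, target_adr = 300,
                     target_nsa_deg = 130, neck_axis_tilt_deg = 45,
                     include_shaft = TRUE, contour_spacing_deg = 2,
                     cam_bump_scale = 1, alpha_epsilon = 0.01) {
  chk <- function(x, lo, hi, nm) {
    if (!is_number(x) || x < lo || x > hi)
      hm_error(sprintf("%s must be in [%g, %g]", nm, lo, hi), "hipmorph_infeasible")
  }
  chk(head_radius, 1, Inf, "head_radius")
  chk(target_alpha_deg, 40, 100, "target_alpha_deg")
  chk(target_lcea_deg, -10, 60, "target_lcea_deg")
  chk(target_wcea_deg, -10, 60, "target_wcea_deg")
  chk(target_mai_deg, -10, 25, "target_mai_deg")
  chk(target_adr, 100, 450, "target_adr")
  chk(target_nsa_deg, 100, 160, "target_nsa_deg")
  chk(neck_axis_tilt_deg, 20, 70, "neck_axis_tilt_deg")
  chk(contour_spacing_deg, 0.5, 5, "contour_spacing_deg")
  chk(cam_bump_scale, 0, 20, "cam_bump_scale")
  if (target_lcea_deg < target_wcea_deg)
    hm_error("infeasible targets: lateral bony edge would be medial to the sourcil edge (lcea < wcea)",
             "hipmorph_infeasible")
  structure(list(head_radius = head_radius,
                 target_alpha_deg = target_alpha_deg,
                 target_lcea_deg = target_lcea_deg,
                 target_wcea_deg = target_wcea_deg,
                 target_mai_deg = target_mai_deg,
                 target_adr = target_adr,
                 target_nsa_deg = target_nsa_deg,
                 neck_axis_tilt_deg = neck_axis_tilt_deg,
                 include_shaft = isTRUE(include_shaft),
                 contour_spacing_deg = contour_spacing_deg,
                 cam_bump_scale = cam_bump_scale,
                 alpha_epsilon = alpha_epsilon),
            class = "hip_spec")
}

# geometric constants of the construction, relative to the head radius
RIM_RADIUS <- 1.15     # lateral bony acetabular edge distance from center
SOURCIL_RADIUS <- 1.08 # lateral sourcil distance from center
ACETAB_WIDTH <- 2.2    # teardrop-to-edge width
HEAD_GAP_DEG <- 4      # gap between head arc end and junction arc start

# radial cam-bump profile (relative inflation) at polar angle theta (deg
# from the neck axis), for theta <= alpha
cam_bump <- function(theta, spec) {
  spec$cam_bump_scale * spec$alpha_epsilon *
    (1.5 + 0.3 * (spec$target_alpha_deg - theta) / spec$contour_spacing_deg)
}

# junction polar-angle grid: fine near the alpha station, then widening
junction_grid <- function(spec) {
  a <- spec$target_alpha_deg; s <- spec$contour_spacing_deg
  fine <- a - s * (0:5)
  end <- min(25, a - 8 * s)
  c(fine, seq(a - 6 * s, end, length.out = 4L))
}

#' Generate a synthetic hip pair with known ground truth
#'
#' Builds the landmark sets of both hips of one synthetic pelvic image from
#' a [hip_spec()], together with the analytically known values of all eight
#' measurements.  The generated coordinates are noiseless; add observer
#' noise with [jitter_landmarks()].
#'
#' @param spec a [hip_spec()].
#' @param image_id identifier recorded on both sets.
#' @return list with `pair` (a [hip_pair()]) and `truth` (one-row
#'   data.frame of the eight ground-truth measurement values; `nsa_deg` is
#'   NA when the shaft is not generated).
#' @export
generate_hip <- function(spec, image_id = "synthetic") {
  stopifnot(inherits(spec, "hip_spec"))
  r <- spec$head_radius
  tau <- spec$neck_axis_tilt_deg
  alpha <- spec$target_alpha_deg
  u_neck <- c(sin(deg2rad(tau)), -cos(deg2rad(tau)))
  dir_at <- function(theta) rot2(u_neck, theta)  # CCW sweeps lateral->superior

  pts <- matrix(NA_real_, 80L, 2L)

  # femoral head contour (indices 12-41), apex (theta = 180) at index 26
  s_head <- (180 - alpha - HEAD_GAP_DEG) / 15
  theta_head <- (180 + 14 * s_head) - s_head * (0:29)
  for (j in seq_along(theta_head))
    pts[12L + j, ] <- r * dir_at(theta_head[j])

  # superior head-neck junction contour (42-51), ordered head -> neck
  theta_junc <- junction_grid(spec)
  rho_junc <- r * (1 + cam_bump(theta_junc, spec))
  for (j in seq_along(theta_junc))
    pts[42L + j, ] <- rho_junc[j] * dir_at(theta_junc[j])

  # neck border pairs (lateral 52-59, medial 60-67); narrowest pair midpoint
  # lies exactly on the neck axis, at pair index 4
  n_perp <- rot2(u_neck, 90)  # supero-lateral side
  for (i in 0:7) {
    ctr_i <- r * (1.15 + 0.09 * i) * u_neck
    w_i <- r * (0.75 + 0.02 * (i - 3)^2)
    pts[52L + i + 1L, ] <- ctr_i + (w_i / 2) * n_perp
    pts[60L + i + 1L, ] <- ctr_i - (w_i / 2) * n_perp
  }

  # shaft border pairs (lateral 68-73, medial 74-79), proximal -> distal
  u_shaft <- rot2(-u_neck, spec$target_nsa_deg)
  if (spec$include_shaft) {
    n_s <- rot2(u_shaft, 90)
    if (n_s[1L] < 0) n_s <- -n_s  # lateral side is +x
    p0 <- 2.0 * r * u_neck
    for (i in 0:5) {
      ctr_i <- p0 + (0.35 * r * i) * u_shaft
      pts[68L + i + 1L, ] <- ctr_i + 0.45 * r * n_s
      pts[74L + i + 1L, ] <- ctr_i - 0.45 * r * n_s
    }
  }

  # acetabulum (0-11): anchors realize LCEA, WCEA, mAI, ADR exactly
  E <- RIM_RADIUS * r * c(sin(deg2rad(spec$target_lcea_deg)),
                          cos(deg2rad(spec$target_lcea_deg)))
  S_lat <- SOURCIL_RADIUS * r * c(sin(deg2rad(spec$target_wcea_deg)),
                                  cos(deg2rad(spec$target_wcea_deg)))
  mai <- deg2rad(spec$target_mai_deg)
  roof_len <- (E[1L] + 0.5 * r) / cos(mai)
  S_med <- E - roof_len * c(cos(mai), sin(mai))
  B_len <- ACETAB_WIDTH * r
  v <- S_med - E
  A_len <- B_len * spec$target_adr / 1000
  if (A_len >= 0.999 * vnorm(v))
    hm_error("infeasible targets: requested acetabular depth exceeds the roof span",
             "hipmorph_infeasible")
  phi <- rad2deg(asin(A_len / vnorm(v)))
  Tt <- E + B_len * rot2(unit(v), phi)
  pts[1L, ] <- Tt
  pts[5L, ] <- S_med
  pts[9L, ] <- S_lat
  pts[12L, ] <- E
  for (j in 1:3) pts[1L + j, ] <- Tt + (j / 4) * (S_med - Tt)
  for (j in 1:3) pts[5L + j, ] <- S_med + (j / 4) * (S_lat - S_med)
  for (j in 1:2) pts[9L + j, ] <- S_lat + (j / 3) * (E - S_lat)

  schema <- hip_schema(n_points = if (spec$include_shaft) 80L else 68L,
                       roles = default_roles(include_shaft = spec$include_shaft))
  if (!spec$include_shaft) pts <- pts[1:68, , drop = FALSE]

  # canonical -> image: y flips; patient right hip sits on the image left
  left_img <- cbind(1400 + pts[, 1L], 800 - pts[, 2L])
  right_img <- cbind(600 - pts[, 1L], 800 - pts[, 2L])
  pair <- hip_pair(
    landmark_set(left_img, side = "left", image_id = image_id, schema = schema),
    landmark_set(right_img, side = "right", image_id = image_id, schema = schema))

  # emergent ground truths
  xe <- E[1L]
  A_ei <- max(0, r - xe)
  B_ei <- max(0, xe + r)
  ei <- 100 * A_ei / (A_ei + B_ei)
  tir <- tir_truth(spec)

  truth <- data.frame(image_id = image_id,
                      adr = spec$target_adr,
                      mai_deg = spec$target_mai_deg,
                      alpha_deg = alpha,
                      wcea_deg = spec$target_wcea_deg,
                      lcea_deg = spec$target_lcea_deg,
                      ei_pct = ei,
                      nsa_deg = if (spec$include_shaft) spec$target_nsa_deg else NA_real_,
                      tir = tir)
  list(pair = pair, truth = truth)
}

# analytic TIR ground truth: intersect the continuous contour profile with
# the perpendicular station at 0.5r along the neck axis
tir_truth <- function(spec) {
  r <- spec$head_radius
  alpha <- spec$target_alpha_deg
  theta_min <- min(junction_grid(spec))
  theta <- seq(179, theta_min, by = -0.005)
  rho <- ifelse(theta >= alpha, r, r * (1 + cam_bump(theta, spec)))
  t <- rho * cos(deg2rad(theta))
  tstar <- 0.5 * r
  k <- which(t[-length(t)] <= tstar & t[-1L] >= tstar)
  if (length(k) == 0L) return(NA_real_)
  k <- k[1L]
  w <- (tstar - t[k]) / (t[k + 1L] - t[k])
  d <- (1 - w) * rho[k] + w * rho[k + 1L]
  d / r
}

#' Add observer noise to a landmark set
#'
#' Adds isotropic Gaussian displacement (standard deviation `sd` px) to
#' every landmark.  Deterministic given `seed`, and the underlying standard
#' normal draws depend only on the seed, so the same seed with a different
#' `sd` rescales the same displacement field.  The caller's RNG state is
#' untouched.
#'
#' @param set a `landmark_set`.
#' @param sd displacement standard deviation in px (0 = identity).
#' @param seed integer seed.
#' @return the jittered `landmark_set`.
#' @export
jitter_landmarks <- function(set, sd, seed) {
  stopifnot(inherits(set, "landmark_set"), is_number(sd), sd >= 0)
  if (sd == 0) return(set)
  n <- nrow(set$points)
  disp <- with_seed(seed, matrix(stats::rnorm(2L * n), n, 2L))
  set$points <- set$points + sd * disp
  set
}

#' Specification of a simulated reliability study
#'
#' Emulates the design of a landmark-based validation study: `n_hips`
#' random hips, each annotated by every observer in every round, with
#' per-observer landmark jitter standing in for annotation variability.
#'
#' @param n_hips number of hips (radiographs), >= 1.
#' @param observer_sds numeric vector of per-observer jitter standard
#'   deviations in px; its length is the number of observers.
#' @param rounds measurement rounds per observer.
#' @param seed master seed; every random draw in the study derives from it.
#' @param sampler function(n) returning a list of `n` [hip_spec()]s; the
#'   default draws morphology targets uniformly over representative adult
#'   ranges (alpha 45-75 deg, LCEA 18-45 deg, WCEA 3-10 deg below LCEA,
#'   mAI 0-12 deg, ADR 230-330, NSA 115-145 deg, cam bump amplitude scale
#'   1-6 so head asphericity varies independently of the alpha angle).
#' @return an object of class `study_spec`.
#' @export
study_spec <- function(n_hips = 30L, observer_sds = c(1, 1), rounds = 2L,
                       seed = 1L, sampler = NULL) {
  stopifnot(n_hips >= 1L, length(observer_sds) >= 1L, all(observer_sds >= 0),
            rounds >= 1L)
  structure(list(n_hips = as.integer(n_hips),
                 observer_sds = as.numeric(observer_sds),
                 rounds = as.integer(rounds), seed = as.integer(seed),
                 sampler = sampler),
            class = "study_spec")
}

default_hip_sampler <- function(n) {
  lapply(seq_len(n), function(i) {
    lcea <- stats::runif(1, 18, 45)
    hip_spec(target_alpha_deg = stats::runif(1, 45, 75),
             target_lcea_deg = lcea,
             target_wcea_deg = lcea - stats::runif(1, 3, 10),
             target_mai_deg = stats::runif(1, 0, 12),
             target_adr = stats::runif(1, 230, 330),
             target_nsa_deg = stats::runif(1, 115, 145),
             neck_axis_tilt_deg = stats::runif(1, 38, 52),
             cam_bump_scale = stats::runif(1, 1, 6))
  })
}

#' Simulate a full reliability study
#'
#' Generates `n_hips` synthetic hips, applies independent observer/round
#' jitter to each annotation, measures every hip in every batch, and
#' returns the batches ready for [reliability_report()].  The measurement
#' of each hip uses the pelvic reference line of its own (jittered) pair,
#' as a real pipeline would.
#'
#' @param spec a [study_spec()].
#' @param options see [measure_options()].
#' @return an object of class `hip_study`: `truth` (ground-truth
#'   data.frame), `batches` (named list of measurement data.frames,
#'   `obs<o>_round<r>`), `hip_specs` and `spec`.
#' @export
simulate_study <- function(spec, options = measure_options()) {
  stopifnot(inherits(spec, "study_spec"))
  sampler <- spec$sampler %||% default_hip_sampler
  hip_specs <- with_seed(spec$seed, sampler(spec$n_hips))
  hips <- lapply(seq_along(hip_specs), function(i)
    generate_hip(hip_specs[[i]], image_id = sprintf("hip%03d", i)))
  truth <- do.call(rbind, lapply(hips, `[[`, "truth"))

  base <- (spec$seed %% 10000L) * 100000L
  batches <- list()
  for (o in seq_along(spec$observer_sds)) {
    for (rd in seq_len(spec$rounds)) {
      rows <- lapply(seq_along(hips), function(i) {
        s <- base + o * 10000L + rd * 1000L + i
        left <- jitter_landmarks(hips[[i]]$pair$left, spec$observer_sds[o], s)
        right <- jitter_landmarks(hips[[i]]$pair$right, spec$observer_sds[o], s + 500L)
        ref <- pelvic_reference_axis(hip_pair(left, right))
        as.data.frame(measure_all(left, ref = ref, options = options))
      })
      batches[[sprintf("obs%d_round%d", o, rd)]] <- do.call(rbind, rows)
    }
  }
  structure(list(truth = truth, batches = batches, hip_specs = hip_specs,
                 spec = spec),
            class = "hip_study")
}

#' @export
print.hip_study <- function(x, ...) {
  cat(sprintf("<hip_study: %d hips, %d observers x %d rounds (jitter sd: %s px)>\n",
              x$spec$n_hips, length(x$spec$observer_sds), x$spec$rounds,
              paste(x$spec$observer_sds, collapse = ", ")))
  invisible(x)
}

#' Interobserver ratings matrix from a simulated study
#'
#' Collapses each observer's rounds to their mean (the usual interobserver
#' convention) and returns the n_hips x n_observers matrix for one
#' measurement, ready for [icc()].
#'
#' @param study a `hip_study`.
#' @param measurement one of the eight measurement column names.
#' @return numeric matrix, hips x observers.
#' @export
observer_means <- function(study, measurement) {
  stopifnot(inherits(study, "hip_study"),
            measurement %in% MEASUREMENT_NAMES)
  n_obs <- length(study$spec$observer_sds)
  sapply(seq_len(n_obs), function(o) {
    cols <- sapply(seq_len(study$spec$rounds), function(rd)
      study$batches[[sprintf("obs%d_round%d", o, rd)]][[measurement]])
    rowMeans(as.matrix(cols))
  })
}

#' Write a study to disk as plain-text fixtures
#'
#' Writes per-hip `.pts` files (`<id>_left.pts`, `<id>_right.pts`, from the
#' noiseless generated landmarks), the schema, and a `ground_truth.csv`
#' manifest into a directory.
#'
#' @param study a `hip_study` (or the `hips` list from [generate_hip()]).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "hip_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hips <- lapply(seq_along(study$hip_specs), function(i)
    generate_hip(study$hip_specs[[i]], image_id = sprintf("hip%03d", i)))
  for (h in hips) {
    write_pts(h$pair$left, file.path(dir, paste0(h$truth$image_id, "_left.pts")))
    write_pts(h$pair$right, file.path(dir, paste0(h$truth$image_id, "_right.pts")))
  }
  write_schema(hips[[1L]]$pair$left$schema, file.path(dir, "schema.yaml"))
  utils::write.csv(study$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
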