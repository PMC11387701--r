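# The eight measurements: hand-constructed cases, parameter recovery,
# invariance and monotonicity properties.

# helper: landmark set with selected acetabular anchors replaced, so the
# hand-arithmetic examples run through the real measurement path
patched_set <- function(edits, spec = hip_spec()) {
  set <- canonicalize(generate_hip(spec)$pair$left)
  for (role in names(edits))
    set$points[set$schema$roles[[role]] + 1L, ] <- edits[[role]]
  set
}

test_that("ADR matches hand arithmetic and degenerates safely", {
  set <- patched_set(list(ACETAB_LATERAL_EDGE = c(100, 0),
                          TEARDROP_CAUDAL = c(0, 0),
                          SOURCIL_MEDIAL = c(30, 25)))
  expect_equal(measure_adr(set), 250)   # 25/100 * 1000
  set$points[set$schema$roles$SOURCIL_MEDIAL + 1L, ] <- c(40, 0)  # on the line
  expect_equal(measure_adr(set), 0)
  set$points[set$schema$roles$TEARDROP_CAUDAL + 1L, ] <- c(100, 0)  # B = 0
  expect_error(measure_adr(set), class = "hipmorph_degenerate")
})

test_that("mAI sign convention follows roof inclination", {
  up <- patched_set(list(SOURCIL_MEDIAL = c(0, 0),
                         ACETAB_LATERAL_EDGE = c(40, 10)))
  expect_equal(measure_mai(up), atan(10 / 40) * 180 / pi, tolerance = 1e-9)
  flat <- patched_set(list(SOURCIL_MEDIAL = c(0, 5),
                           ACETAB_LATERAL_EDGE = c(40, 5)))
  expect_equal(measure_mai(flat), 0)
  down <- patched_set(list(SOURCIL_MEDIAL = c(0, 10),
                           ACETAB_LATERAL_EDGE = c(40, 0)))
  expect_equal(measure_mai(down), -atan(10 / 40) * 180 / pi, tolerance = 1e-9)
})

test_that("center-edge angles match constructed geometry and sign", {
  set <- canonicalize(generate_hip(hip_spec())$pair$left)
  head <- fit_circle(set$points[set$schema$roles$HEAD_CONTOUR + 1L, ])
  ctr <- as.numeric(head$center)
  # lateral sourcil at 30 deg from the vertical through the center
  set$points[set$schema$roles$SOURCIL_LATERAL + 1L, ] <-
    ctr + 50 * c(sin(pi / 6), cos(pi / 6))
  expect_equal(measure_wcea(set, head = head), 30, tolerance = 1e-9)
  # edge straight above the center: LCEA 0
  set$points[set$schema$roles$ACETAB_LATERAL_EDGE + 1L, ] <- ctr + c(0, 60)
  expect_equal(measure_lcea(set, head = head), 0, tolerance = 1e-9)
  # edge 10 deg medial of the vertical: negative
  set$points[set$schema$roles$ACETAB_LATERAL_EDGE + 1L, ] <-
    ctr + 60 * c(-sin(pi / 18), cos(pi / 18))
  expect_equal(measure_lcea(set, head = head), -10, tolerance = 1e-9)
  set$points[set$schema$roles$ACETAB_LATERAL_EDGE + 1L, ] <- ctr
  expect_error(measure_lcea(set, head = head), class = "hipmorph_degenerate")
})

test_that("extrusion index matches the covered/uncovered split", {
  set <- canonicalize(generate_hip(hip_spec())$pair$left)
  head <- fit_circle(set$points[set$schema$roles$HEAD_CONTOUR + 1L, ])
  ctr <- as.numeric(head$center); r <- head$radius
  place_edge <- function(dx) {
    set$points[set$schema$roles$ACETAB_LATERAL_EDGE + 1L, ] <<- ctr + c(dx, 1.1 * r)
  }
  place_edge(0.4 * r)           # A = 0.6r, B = 1.4r -> 30%
  expect_equal(measure_ei(set, head = head), 30, tolerance = 1e-9)
  place_edge(1.2 * r)           # edge lateral to the head: fully covered
  expect_equal(measure_ei(set, head = head), 0)
  place_edge(0)                 # edge over the center: half uncovered
  expect_equal(measure_ei(set, head = head), 50, tolerance = 1e-9)
})

test_that("EI decreases strictly as the acetabular edge moves laterally", {
  eis <- sapply(c(20, 26, 32, 38, 44), function(lcea)
    measure_values(generate_hip(hip_spec(target_lcea_deg = lcea,
                                         target_wcea_deg = 15))$pair)[["ei_pct"]])
  expect_true(all(diff(eis) < 0))
})

test_that("alpha angle: recovery, fallback, and monotonicity", {
  # target recovery within one contour spacing, no noise
  for (aa in c(48, 60, 70, 85)) {
    v <- measure_values(generate_hip(hip_spec(target_alpha_deg = aa))$pair)
    expect_equal(v[["alpha_deg"]], aa, tolerance = 2)
  }
  # spherical head (zero bump): no departure, falls back to the last
  # superior-contour landmark
  sph <- generate_hip(hip_spec(target_alpha_deg = 55, cam_bump_scale = 0))$pair
  set <- canonicalize(sph$left)
  m <- measure_alpha(set)
  junc <- set$points[set$schema$roles$HEADNECK_SUPERIOR_CONTOUR + 1L, ]
  expect_equal(as.numeric(m$alpha_point), as.numeric(junc[nrow(junc), ]))
  # monotone in the prescribed angle, same hip otherwise
  a55 <- measure_values(generate_hip(hip_spec(target_alpha_deg = 55))$pair)[["alpha_deg"]]
  a75 <- measure_values(generate_hip(hip_spec(target_alpha_deg = 75))$pair)[["alpha_deg"]]
  expect_gt(a75, a55)
})

test_that("NSA: construction recovery, perpendicular case, missing shaft", {
  for (nsa in c(115, 125, 145))
    expect_equal(measure_values(generate_hip(hip_spec(target_nsa_deg = nsa))$pair)[["nsa_deg"]],
                 nsa, tolerance = 1e-6)
  # axes at 90 degrees exactly
  set <- canonicalize(generate_hip(hip_spec())$pair$left)
  neck <- hip_axis(c(0, 0), c(1, 0), "neck", frame = "canonical")
  shaft <- hip_axis(c(0, -100), c(0, -1), "shaft", frame = "canonical")
  expect_equal(measure_nsa(set, neck = neck, shaft = shaft), 90)
  # missing shaft -> missing value with reason, others present
  m <- measure_all(generate_hip(hip_spec(include_shaft = FALSE))$pair$left)
  expect_true(is.na(m$values[["nsa_deg"]]))
  expect_match(m$missing[["nsa_deg"]], "shaft")
  expect_false(anyNA(m$values[setdiff(names(m$values), "nsa_deg")]))
})

test_that("TIR: unity on spherical heads, d/r reading, bump monotonicity", {
  # spherical head at the station -> TIR 1
  v <- measure_values(generate_hip(hip_spec(target_alpha_deg = 50,
                                            cam_bump_scale = 0))$pair)
  expect_equal(v[["tir"]], 1, tolerance = 5e-3)
  # growing cam bump -> non-decreasing TIR
  tirs <- sapply(c(0, 1, 3, 6), function(s)
    measure_values(generate_hip(hip_spec(target_alpha_deg = 70,
                                         cam_bump_scale = s))$pair)[["tir"]])
  expect_true(all(diff(tirs) >= 0))
  expect_gt(tirs[4], 1)
  # reciprocal orientation
  opt <- measure_options(tir_orientation = "r_over_d")
  pair <- generate_hip(hip_spec(target_alpha_deg = 70, cam_bump_scale = 4))$pair
  ref <- pelvic_reference_axis(pair)
  v1 <- measure_all(pair$left, ref = ref)$values[["tir"]]
  v2 <- measure_all(pair$left, ref = ref, options = opt)$values[["tir"]]
  expect_equal(v2, 1 / v1, tolerance = 1e-12)
})

test_that("noiseless generator hips recover every prescribed target", {
  specs <- with_seed_local(7, lapply(1:20, function(i)
    hip_spec(target_alpha_deg = runif(1, 42, 95),
             target_lcea_deg = runif(1, 18, 50),
             target_wcea_deg = runif(1, 0, 12),
             target_mai_deg = runif(1, -5, 20),
             target_adr = runif(1, 200, 360),
             target_nsa_deg = runif(1, 105, 155),
             neck_axis_tilt_deg = runif(1, 30, 60),
             cam_bump_scale = runif(1, 1, 8))))
  for (sp in specs) {
    gh <- generate_hip(sp)
    v <- measure_values(gh$pair)
    tr <- gh$truth
    expect_equal(v[["mai_deg"]], tr$mai_deg, tolerance = 0.1)
    expect_equal(v[["wcea_deg"]], tr$wcea_deg, tolerance = 0.1)
    expect_equal(v[["lcea_deg"]], tr$lcea_deg, tolerance = 0.1)
    expect_equal(v[["nsa_deg"]], tr$nsa_deg, tolerance = 0.1)
    expect_equal(v[["alpha_deg"]], tr$alpha_deg,
                 tolerance = sp$contour_spacing_deg)
    expect_equal(v[["adr"]], tr$adr, tolerance = 0.5)
    expect_equal(v[["ei_pct"]], tr$ei_pct, tolerance = 0.5)
  }
})

test_that("all eight measurements are invariant under similarity transforms", {
  pair <- generate_hip(hip_spec(target_alpha_deg = 68))$pair
  v0 <- measure_values(pair)
  trs <- with_seed_local(3, replicate(10, list(angle = runif(1, -180, 180),
                                               scale = runif(1, 0.3, 3),
                                               shift = runif(2, -500, 500)),
                         simplify = FALSE))
  for (tr in trs) {
    v1 <- measure_values(transform_pair(pair, tr$angle, tr$scale, tr$shift))
    expect_equal(v1, v0, tolerance = 1e-9)
  }
})

test_that("left and right hips of a mirrored pair measure identically", {
  for (sp in list(hip_spec(), hip_spec(target_alpha_deg = 75, target_lcea_deg = 45))) {
    pair <- generate_hip(sp)$pair
    vl <- measure_values(pair, "left")
    vr <- measure_values(pair, "right")
    expect_equal(vl, vr, tolerance = 1e-9)
  }
})

test_that("measure_batch preserves order and reports per-hip failures", {
  hips <- lapply(1:5, function(i)
    generate_hip(hip_spec(target_alpha_deg = 50 + 5 * i),
                 image_id = sprintf("h%d", i)))
  sets <- lapply(hips, function(h) h$pair$left)
  sets[[3]] <- generate_hip(hip_spec(include_shaft = FALSE), image_id = "h3")$pair$left
  df <- measure_batch(sets)
  expect_identical(df$image_id, sprintf("h%d", 1:5))
  expect_true(is.na(df$nsa_deg[3]))
  expect_match(df$missing_reasons[3], "nsa_deg")
  expect_false(anyNA(df$nsa_deg[-3]))
})

test_that("measurement CSVs round-trip with metadata and 2-decimal values", {
  df <- measure_batch(list(generate_hip(hip_spec())$pair$left))
  p <- withr::local_tempfile(fileext = ".csv")
  write_measurements_csv(df, p, meta = c(tool = "test"))
  expect_match(readLines(p, n = 1), "^# tool: test")
  back <- read_measurements_csv(p)
  expect_equal(back$alpha_deg, round(df$alpha_deg, 2))
})
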