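# Anatomical landmark schema: maps semantic roles to 0-based landmark indices.

POINT_ROLES <- c("TEARDROP_CAUDAL", "ACETAB_LATERAL_EDGE", "SOURCIL_MEDIAL",
                 "SOURCIL_LATERAL", "FEMORAL_HEAD_APEX")
SEGMENT_ROLES <- c("HEAD_CONTOUR", "HEADNECK_SUPERIOR_CONTOUR",
                   "NECK_MEDIAL", "NECK_LATERAL",
                   "SHAFT_MEDIAL", "SHAFT_LATERAL")

#' Hip landmark schema
#'
#' A schema declares how many landmarks describe one hip and which landmark
#' indices play which anatomical role.  Point roles (teardrop, sourcil edges,
#' acetabular rim, head apex) resolve to a single index; segment roles (head
#' contour, superior head-neck contour, neck and shaft borders) resolve to a
#' contiguous index range.  Indices are 0-based throughout, matching the
#' convention of shape-model point files.
#'
#' The default schema describes an 80-point hip outline: indices 0-11 the
#' acetabulum (0 = caudal teardrop, 4 = medial sourcil, 8 = lateral sourcil,
#' 11 = lateral bony acetabular edge), 12-41 the femoral head contour (26 =
#' head apex), 42-51 the superior head-neck junction contour ordered head to
#' neck, 52-59 the lateral and 60-67 the medial neck border, 68-73 the
#' lateral and 74-79 the medial femoral shaft border ordered proximal to
#' distal.  Annotation protocols differ between groups, so the schema is an
#' editable configuration (see [read_schema()]) rather than a constant.
#'
#' @param n_points total number of landmarks per hip.
#' @param roles named list mapping each role to a 0-based index (point
#'   roles) or an integer vector of 0-based indices (segment roles).  Shaft
#'   segments may be omitted; the neck-shaft angle is then reported missing.
#' @return an object of class `hip_schema`.
#' @examples
#' sch <- hip_schema()
#' sch$roles$FEMORAL_HEAD_APEX   # 26
#' @export
hip_schema <- function(n_points = 80L, roles = default_roles(include_shaft = TRUE)) {
  n_points <- as.integer(n_points)
  if (!is_number(n_points) || n_points < 1L)
    hm_error("n_points must be a positive integer", "hipmorph_schema")
  for (r in POINT_ROLES) {
    if (is.null(roles[[r]]))
      hm_error(sprintf("schema is missing point role %s", r), "hipmorph_schema")
    roles[[r]] <- as.integer(roles[[r]])
    if (length(roles[[r]]) != 1L || roles[[r]] < 0L || roles[[r]] >= n_points)
      hm_error(sprintf("role %s must be one index in [0, %d)", r, n_points),
               "hipmorph_schema")
  }
  for (r in SEGMENT_ROLES) {
    idx <- roles[[r]]
    if (is.null(idx) || length(idx) == 0L) {
      if (r %in% c("SHAFT_MEDIAL", "SHAFT_LATERAL")) {
        roles[r] <- list(integer(0))
        next
      }
      hm_error(sprintf("schema segment role %s must be non-empty", r),
               "hipmorph_schema")
    }
    idx <- as.integer(idx)
    if (any(idx < 0L) || any(idx >= n_points))
      hm_error(sprintf("role %s has indices outside [0, %d)", r, n_points),
               "hipmorph_schema")
    if (length(idx) > 1L && !all(diff(idx) == 1L))
      hm_error(sprintf("segment role %s must be a contiguous index range", r),
               "hipmorph_schema")
    roles[[r]] <- idx
  }
  if (length(roles$HEAD_CONTOUR) < 5L)
    hm_error("HEAD_CONTOUR needs at least 5 landmarks for a circle fit",
             "hipmorph_schema")
  structure(list(n_points = n_points, roles = roles[c(POINT_ROLES, SEGMENT_ROLES)]),
            class = "hip_schema")
}

#' @rdname hip_schema
#' @param include_shaft omit the femoral-shaft segments when `FALSE` (e.g.
#'   radiographs where too little of the shaft is depicted).
#' @export
default_roles <- function(include_shaft = TRUE) {
  roles <- list(
    TEARDROP_CAUDAL = 0L,
    SOURCIL_MEDIAL = 4L,
    SOURCIL_LATERAL = 8L,
    ACETAB_LATERAL_EDGE = 11L,
    FEMORAL_HEAD_APEX = 26L,
    HEAD_CONTOUR = 12:41,
    HEADNECK_SUPERIOR_CONTOUR = 42:51,
    NECK_LATERAL = 52:59,
    NECK_MEDIAL = 60:67,
    SHAFT_LATERAL = 68:73,
    SHAFT_MEDIAL = 74:79
  )
  if (!include_shaft) {
    roles$SHAFT_LATERAL <- integer(0)
    roles$SHAFT_MEDIAL <- integer(0)
  }
  roles
}

#' @export
print.hip_schema <- function(x, ...) {
  cat(sprintf("<hip_schema: %d landmarks>\n", x$n_points))
  for (r in names(x$roles)) {
    idx <- x$roles[[r]]
    if (length(idx) == 0L) cat(sprintf("  %-26s (absent)\n", r))
    else if (length(idx) == 1L) cat(sprintf("  %-26s %d\n", r, idx))
    else cat(sprintf("  %-26s %d-%d (%d points)\n", r, idx[1L],
                     idx[length(idx)], length(idx)))
  }
  invisible(x)
}

#' Read or write a landmark schema configuration
#'
#' Schemas are stored as YAML or JSON (chosen by file extension) with fields
#' `n_points` and `roles`; segment roles are written as `[first, last]`
#' 0-based inclusive ranges.  The packaged default lives at
#' `system.file("extdata", "hip80_schema.yaml", package = "hipmorph")`.
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_schema()` returns a `hip_schema`; `write_schema()` returns
#'   `path` invisibly.
#' @export
read_schema <- function(path) {
  if (!file.exists(path))
    hm_error(sprintf("schema file not found: %s", path), "hipmorph_io")
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  roles <- raw$roles
  for (r in SEGMENT_ROLES) {
    rng <- roles[[r]]
    if (is.null(rng) || length(rng) == 0L) next
    rng <- as.integer(unlist(rng))
    roles[[r]] <- if (length(rng) == 2L) rng[1L]:rng[2L] else rng
  }
  hip_schema(n_points = raw$n_points, roles = roles)
}

#' @rdname read_schema
#' @param schema a `hip_schema` object.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "hip_schema"))
  roles <- schema$roles
  out <- list(n_points = schema$n_points, roles = list())
  for (r in POINT_ROLES) out$roles[[r]] <- roles[[r]]
  for (r in SEGMENT_ROLES) {
    idx <- roles[[r]]
    out$roles[[r]] <- if (length(idx) == 0L) integer(0)
    else c(idx[1L], idx[length(idx)])
  }
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  else yaml::write_yaml(out, path)
  invisible(path)
}
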