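# Landmark data model and point-set file I/O.

#' Landmark set for one hip
#'
#' The atomic input of the pipeline: an ordered set of 2-D landmark
#' coordinates outlining the proximal femur and acetabulum of one hip on an
#' AP pelvic radiograph, together with the side of the body and the schema
#' describing which landmark plays which anatomical role.
#'
#' Coordinates are in image pixels with x increasing to the right and y
#' increasing downwards (the raster convention of point files).  All
#' measurements are angles or ratios, so `pixel_spacing` is carried for
#' provenance but never used.
#'
#' @param points numeric n x 2 matrix (or data.frame) of (x, y) coordinates,
#'   in schema order.
#' @param side `"left"` or `"right"`.
#' @param image_id identifier of the source radiograph.
#' @param schema a [hip_schema()]; its `n_points` must match `nrow(points)`.
#' @param pixel_spacing optional mm/pixel, informational only.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(points, side, image_id = "unknown",
                         schema = hip_schema(), pixel_spacing = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L)
    hm_error("points must have two columns (x, y)", "hipmorph_schema")
  if (!all(is.finite(points)))
    hm_error("all landmark coordinates must be finite", "hipmorph_schema")
  side <- match.arg(side, c("left", "right"))
  if (nrow(points) != schema$n_points)
    hm_error(sprintf("expected %d landmarks per schema, got %d",
                     schema$n_points, nrow(points)), "hipmorph_schema")
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(points = points, side = side, image_id = as.character(image_id),
                 schema = schema, pixel_spacing = pixel_spacing,
                 canonical = FALSE),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set: %s hip, %d points, image %s%s>\n", x$side,
              nrow(x$points), x$image_id,
              if (isTRUE(x$canonical)) ", canonical frame" else ""))
  invisible(x)
}

# coordinates of a role (1 x 2 for point roles, m x 2 for segments)
role_xy <- function(set, role) {
  idx <- set$schema$roles[[role]]
  if (is.null(idx) || length(idx) == 0L)
    hm_error(sprintf("role %s absent from schema", role), "hipmorph_missing_role")
  set$points[idx + 1L, , drop = FALSE]
}

role_present <- function(set, role) {
  idx <- set$schema$roles[[role]]
  !is.null(idx) && length(idx) > 0L
}

#' Pair of left and right hips from one radiograph
#'
#' Both sides of one pelvic image.  The pair exists to build the horizontal
#' reference line of the pelvis, which runs through the caudal teardrop
#' landmarks of the two hips.
#'
#' @param left,right `landmark_set`s sharing `image_id`, one per side.
#' @return an object of class `hip_pair`.
#' @export
hip_pair <- function(left, right) {
  stopifnot(inherits(left, "landmark_set"), inherits(right, "landmark_set"))
  if (left$side != "left" || right$side != "right")
    hm_error("hip_pair expects a left-side and a right-side landmark_set",
             "hipmorph_schema")
  if (left$image_id != right$image_id)
    hm_error("both hips of a pair must share image_id", "hipmorph_schema")
  structure(list(left = left, right = right), class = "hip_pair")
}

#' Canonicalize a landmark set
#'
#' Transforms a landmark set from image coordinates (y down) into the
#' internal canonical frame in which +y points superior (up) and +x points
#' lateral for either side: the y axis is flipped, and right-side hips are
#' additionally mirrored about a vertical axis.  All downstream geometry
#' assumes this frame; measurement functions canonicalize automatically, so
#' calling this directly is only needed when building geometry by hand.
#' The operation is idempotent.
#'
#' @param set a `landmark_set`.
#' @return the set in the canonical frame (`$canonical` is `TRUE`).
#' @export
canonicalize <- function(set) {
  stopifnot(inherits(set, "landmark_set"))
  if (isTRUE(set$canonical)) return(set)
  p <- set$points
  p[, 2L] <- -p[, 2L]
  if (set$side == "right") p[, 1L] <- -p[, 1L]
  set$points <- p
  set$canonical <- TRUE
  set
}

# --- BoneFinder-style .pts dialect ------------------------------------------
# version: 1
# n_points: 80
# {
# x y
# ...
# }

#' Read and write point files
#'
#' `read_pts()` parses the plain-text points dialect used by shape-model
#' annotation tools: a `version:` line, an `n_points:` line, then the
#' coordinate pairs wrapped in `{` ... `}`.  `write_pts()` writes the same
#' dialect with six decimal places, so a read/write round trip preserves
#' coordinates to 1e-6 px.
#'
#' @param path file path.
#' @param schema a [hip_schema()]; the declared point count must match.
#' @param side `"left"` or `"right"` (point files carry no side metadata).
#' @param image_id identifier recorded on the returned set; defaults to the
#'   file name without extension.
#' @return `read_pts()` returns a `landmark_set`; `write_pts()` returns
#'   `path` invisibly.
#' @export
read_pts <- function(path, schema = hip_schema(), side, image_id = NULL) {
  if (!file.exists(path))
    hm_error(sprintf("points file not found: %s", path), "hipmorph_io")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  nonblank <- which(nzchar(lines))
  if (length(nonblank) < 4L)
    hm_error(sprintf("%s: truncated points file", path), "hipmorph_parse")
  i <- nonblank[1L]
  if (!grepl("^version:", lines[i]))
    hm_error(sprintf("%s:%d: expected 'version:' header", path, i), "hipmorph_parse")
  i <- nonblank[2L]
  if (!grepl("^n_points:", lines[i]))
    hm_error(sprintf("%s:%d: expected 'n_points:' header", path, i), "hipmorph_parse")
  n_declared <- suppressWarnings(as.integer(sub("^n_points:\\s*", "", lines[i])))
  if (is.na(n_declared))
    hm_error(sprintf("%s:%d: non-numeric n_points", path, i), "hipmorph_parse")
  if (n_declared != schema$n_points)
    hm_error(sprintf("%s: declared n_points %d does not match schema (%d)",
                     path, n_declared, schema$n_points), "hipmorph_parse")
  open <- nonblank[3L]
  if (lines[open] != "{")
    hm_error(sprintf("%s:%d: expected '{'", path, open), "hipmorph_parse")
  close <- nonblank[length(nonblank)]
  if (lines[close] != "}")
    hm_error(sprintf("%s:%d: expected closing '}'", path, close), "hipmorph_parse")
  body <- setdiff(nonblank, c(nonblank[1:3], close))
  if (length(body) != n_declared)
    hm_error(sprintf("%s: expected %d coordinate pairs, found %d",
                     path, n_declared, length(body)), "hipmorph_parse")
  pts <- matrix(NA_real_, length(body), 2L)
  for (j in seq_along(body)) {
    tok <- strsplit(lines[body[j]], "\\s+")[[1L]]
    val <- suppressWarnings(as.numeric(tok))
    if (length(val) != 2L || anyNA(val))
      hm_error(sprintf("%s:%d: expected two numeric tokens, got '%s'",
                       path, body[j], lines[body[j]]), "hipmorph_parse")
    pts[j, ] <- val
  }
  landmark_set(pts, side = side, schema = schema,
               image_id = image_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_pts
#' @param set a `landmark_set`.
#' @export
write_pts <- function(set, path) {
  stopifnot(inherits(set, "landmark_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("version: 1",
               sprintf("n_points: %d", nrow(set$points)),
               "{",
               sprintf("%.6f %.6f", set$points[, 1L], set$points[, 2L]),
               "}"), con)
  invisible(path)
}

#' Read and write landmark CSV files
#'
#' The CSV dialect has columns `index` (0-based, each index exactly once),
#' `x` and `y`.  Round trips are stable to six decimal places.
#'
#' @inheritParams read_pts
#' @return `read_landmarks_csv()` returns a `landmark_set`;
#'   `write_landmarks_csv()` returns `path` invisibly.
#' @export
read_landmarks_csv <- function(path, schema = hip_schema(), side, image_id = NULL) {
  if (!file.exists(path))
    hm_error(sprintf("landmark CSV not found: %s", path), "hipmorph_io")
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("index", "x", "y")
  if (!all(need %in% names(df)))
    hm_error(sprintf("%s: landmark CSV needs columns index, x, y", path),
             "hipmorph_schema")
  if (nrow(df) != schema$n_points ||
      !setequal(df$index, 0:(schema$n_points - 1L)) ||
      anyDuplicated(df$index))
    hm_error(sprintf(
      "%s: indices must be 0..%d each exactly once (got %d rows)",
      path, schema$n_points - 1L, nrow(df)), "hipmorph_schema")
  df <- df[order(df$index), ]
  landmark_set(cbind(df$x, df$y), side = side, schema = schema,
               image_id = image_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_landmarks_csv
#' @param set a `landmark_set`.
#' @export
write_landmarks_csv <- function(set, path) {
  stopifnot(inherits(set, "landmark_set"))
  df <- data.frame(index = 0:(nrow(set$points) - 1L),
                   x = sprintf("%.6f", set$points[, 1L]),
                   y = sprintf("%.6f", set$points[, 2L]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
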