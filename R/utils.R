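# Internal helpers shared across the package.  Nothing here is exported.

hm_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "hipmorph_error")))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) hm_error("cannot normalize a zero vector", "hipmorph_degenerate")
  v / n
}

cross2 <- function(u, v) u[1L] * v[2L] - u[2L] * v[1L]

# counter-clockwise rotation of a 2-vector (or n x 2 matrix rows) by `deg`
rot2 <- function(p, deg) {
  th <- deg2rad(deg)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  if (is.matrix(p)) p %*% t(R) else as.numeric(R %*% p)
}

# perpendicular (CCW) of a 2-vector
perp2 <- function(v) c(-v[2L], v[1L])

# Run `code` with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
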