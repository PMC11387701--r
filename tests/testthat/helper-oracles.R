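# Independent oracles and small fixture builders used across the suite.

# Brute-force circle fit: dense grid around a center guess plus local
# refinement, minimizing the orthogonal rms residual.  Slow and simple, so
# it stays independent of the package's algebraic + Gauss-Newton path.
oracle_circle <- function(points, center_guess, r_guess, span = 1, steps = 41L) {
  obj <- function(cx, cy) {
    d <- sqrt((points[, 1] - cx)^2 + (points[, 2] - cy)^2)
    r <- mean(d)
    list(rss = sum((d - r)^2), r = r)
  }
  best <- list(rss = Inf)
  for (pass in 1:4) {
    cx <- seq(center_guess[1] - span, center_guess[1] + span, length.out = steps)
    cy <- seq(center_guess[2] - span, center_guess[2] + span, length.out = steps)
    for (i in seq_along(cx)) for (j in seq_along(cy)) {
      o <- obj(cx[i], cy[j])
      if (o$rss < best$rss) best <- list(rss = o$rss, cx = cx[i], cy = cy[j], r = o$r)
    }
    center_guess <- c(best$cx, best$cy)
    span <- span * 2.5 / steps
  }
  list(center = c(best$cx, best$cy), radius = best$r)
}

# Direct ANOVA-summation ICC oracle: explicit double loops over the cell
# deviations, no matrix shortcuts shared with the implementation.
oracle_icc <- function(x, type = c("absolute", "consistency")) {
  type <- match.arg(type)
  n <- nrow(x); k <- ncol(x)
  grand <- sum(x) / (n * k)
  ssr <- 0; ssc <- 0; sse <- 0
  rmean <- numeric(n); cmean <- numeric(k)
  for (i in 1:n) rmean[i] <- sum(x[i, ]) / k
  for (j in 1:k) cmean[j] <- sum(x[, j]) / n
  for (i in 1:n) ssr <- ssr + k * (rmean[i] - grand)^2
  for (j in 1:k) ssc <- ssc + n * (cmean[j] - grand)^2
  for (i in 1:n) for (j in 1:k)
    sse <- sse + (x[i, j] - rmean[i] - cmean[j] + grand)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  if (type == "consistency") (msr - mse) / (msr + (k - 1) * mse)
  else (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

with_seed_local <- function(seed, code) withr::with_seed(seed, code)

vnorm_test <- function(v) sqrt(sum(v^2))

# a small valid landmark set built from the generator, for I/O tests
demo_set <- function(...) {
  generate_hip(hip_spec(...), image_id = "demo")$pair$left
}

# rigid/similarity transform of a hip pair in the image frame
transform_pair <- function(pair, angle = 0, scale = 1, shift = c(0, 0)) {
  th <- angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tp <- function(set) {
    set$points <- sweep(scale * set$points %*% t(R), 2, shift, `+`)
    set
  }
  hip_pair(tp(pair$left), tp(pair$right))
}

measure_values <- function(pair, side = "left", ...) {
  ref <- pelvic_reference_axis(pair)
  measure_all(pair[[side]], ref = ref, ...)$values
}
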