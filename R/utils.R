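#' Wrap angles to (-180, 180]
#'
#' Azimuth convention used throughout the package: degrees, 0 = straight
#' ahead, positive = leftward (counterclockwise seen from above).
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

#' Shortest signed angular difference a - b in degrees
#' @param a,b numeric vectors of angles in degrees.
#' @return wrapped difference in (-180, 180].
#' @export
ang_diff <- function(a, b) wrap_angle(a - b)

deg2rad <- function(x) x * pi / 180

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded generation does not
#' disturb the caller's RNG stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# centered moving average, edges handled by the caller
moving_average <- function(x, n) {
  if (n <= 1) return(x)
  as.numeric(stats::filter(x, rep(1 / n, n), sides = 2))
}

# moving average with linear-extrapolation padding so the result covers the
# full support of x; centered window (left-heavy by one sample when n is even)
moving_average_padded <- function(x, n) {
  n <- as.integer(n)
  if (n <= 1) return(x)
  left <- n %/% 2
  right <- n - left - 1L
  nfit <- max(2L, min(length(x), n %/% 2))
  i <- seq_len(nfit)
  fit1 <- stats::lm.fit(cbind(1, i), x[i])$coefficients
  j <- seq(length(x) - nfit + 1L, length(x))
  fit2 <- stats::lm.fit(cbind(1, j), x[j])$coefficients
  pre <- if (left > 0) fit1[1] + fit1[2] * seq(1L - left, 0L) else numeric(0)
  post <- if (right > 0) fit2[1] + fit2[2] * seq(length(x) + 1L, length(x) + right) else numeric(0)
  padded <- c(pre, x, post)
  s <- cumsum(c(0, padded))
  # window for x[i]: padded[(i) .. (i + n - 1)] == x[(i - left) .. (i + right)]
  idx <- seq_along(x)
  (s[idx + n] - s[idx]) / n
}

# smoothed central-difference angular velocity (deg/s); the single velocity
# estimator shared by saccade detection and the speed measures
angular_velocity <- function(x, fs, smooth_dur = 0.05) {
  n_sm <- max(1L, round(smooth_dur * fs))
  xs <- moving_average_padded(x, n_sm)
  v <- numeric(length(xs))
  if (length(xs) >= 3) {
    v[2:(length(xs) - 1)] <- ang_diff(xs[3:length(xs)], xs[1:(length(xs) - 2)]) * fs / 2
  }
  if (length(xs) >= 2) {
    v[1] <- ang_diff(xs[2], xs[1]) * fs
    v[length(xs)] <- ang_diff(xs[length(xs)], xs[length(xs) - 1]) * fs
  }
  v
}
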