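#' Evaluate code with a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a user-visible `seed` argument makes the result
#' reproducible without clobbering the session's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Draw from a truncated normal distribution
#'
#' Inverse-CDF sampling: exact (no rejection), vectorised, and well behaved
#' for the mild truncations used by the cohort generator (e.g. passing rates
#' capped at 100).
#'
#' @param n number of draws.
#' @param mean,sd moments of the parent normal; `sd = 0` returns `mean`
#'   (checked against the bounds).
#' @param lower,upper truncation bounds.
#' @return numeric vector of length `n`.
#' @export
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(n >= 0, sd >= 0, lower < upper)
  if (n == 0) return(numeric(0))
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("degenerate distribution (sd = 0) with mean outside [lower, upper]",
           call. = FALSE)
    }
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo <= 0) {
    stop("truncation interval has vanishing probability mass", call. = FALSE)
  }
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

#' Moments of a truncated normal distribution
#'
#' Closed-form mean and standard deviation of a normal distribution with
#' parameters `mean`, `sd` truncated to `[lower, upper]`. Used as the
#' population oracle when checking that control limits estimated from
#' simulated in-control passing rates converge to their true values.
#'
#' @inheritParams rtruncnorm
#' @return list with elements `mean` and `sd`.
#' @export
truncnorm_moments <- function(mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper)
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  phi_a <- stats::dnorm(a)
  phi_b <- stats::dnorm(b)
  # a*dnorm(a) -> 0 as a -> -Inf; guard the 0 * Inf cases explicitly
  a_phi_a <- if (is.finite(a)) a * phi_a else 0
  b_phi_b <- if (is.finite(b)) b * phi_b else 0
  m <- mean + sd * (phi_a - phi_b) / Z
  v <- sd^2 * (1 + (a_phi_a - b_phi_b) / Z - ((phi_a - phi_b) / Z)^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

#' Parent parameters of a truncated normal with given realized moments
#'
#' Solves for the parameters `(mean, sd)` of the parent normal such that its
#' truncation to `[lower, upper]` has the requested mean and standard
#' deviation. Used to calibrate generators so that simulated series realize
#' stated moments exactly (truncation otherwise shifts them).
#'
#' @param mean_t,sd_t target moments of the truncated distribution.
#' @param lower,upper truncation bounds; `upper` must be finite (the passing
#'   rate cap is the use case) and is the binding side: `sd_t` must be
#'   smaller than `upper - mean_t`, the exponential-tail limit.
#' @return list with elements `mean` and `sd` of the parent normal.
#' @export
truncnorm_parent <- function(mean_t, sd_t, lower = 0, upper = 100) {
  stopifnot(sd_t > 0, mean_t > lower, mean_t < upper, is.finite(upper))
  if (sd_t >= upper - mean_t) {
    stop("infeasible moments: an upper-truncated normal always has ",
         "sd < upper - mean", call. = FALSE)
  }
  # nested solve: for a trial parent mean mu, find the parent sd that
  # realizes the target truncated mean, then move mu until the truncated sd
  # matches too (the sd grows monotonically with mu along that curve)
  sigma_for <- function(mu) {
    g <- function(s) truncnorm_moments(mu, s, lower, upper)$mean - mean_t
    lo <- max(sd_t * 1e-4, (mu - upper) / 7)
    hi <- max(sd_t * 50, (mu - upper) * 3 + sd_t)
    if (g(lo) < 0) return(NA_real_)   # even a point mass at mu is too low
    stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  }
  h <- function(mu) {
    s <- sigma_for(mu)
    if (is.na(s)) return(NA_real_)
    truncnorm_moments(mu, s, lower, upper)$sd - sd_t
  }
  mus <- mean_t + (upper - mean_t) * c(1e-4, 0.25, 0.5, 0.75, 1, 1.5, 2, 3,
                                       5, 8, 13, 21, 34, 55)
  hs <- vapply(mus, h, 1.0)
  ok <- which(!is.na(hs))
  mus <- mus[ok]; hs <- hs[ok]
  i <- which(hs[-1] * hs[-length(hs)] <= 0)[1]
  if (is.na(i)) {
    stop("no parent normal realizes the requested truncated moments", call. = FALSE)
  }
  mu <- stats::uniroot(h, c(mus[i], mus[i + 1]), tol = 1e-10)$root
  list(mean = mu, sd = sigma_for(mu))
}

# Bilinear interpolation on a regular 2D grid (rows = y axis, cols = x axis).
# Returns NA for query points outside the grid extent.
interp_bilinear <- function(values, spacing_mm, origin_mm, y, x) {
  ny <- nrow(values); nx <- ncol(values)
  gy <- (y - origin_mm[1]) / spacing_mm[1]
  gx <- (x - origin_mm[2]) / spacing_mm[2]
  ok <- gy >= 0 & gy <= ny - 1 & gx >= 0 & gx <= nx - 1
  out <- rep(NA_real_, length(y))
  if (!any(ok)) return(out)
  gy <- gy[ok]; gx <- gx[ok]
  iy <- pmin(floor(gy), ny - 2); ix <- pmin(floor(gx), nx - 2)
  ty <- gy - iy; tx <- gx - ix
  i00 <- iy + 1L + ny * ix          # column-major linear index of (iy, ix)
  v00 <- values[i00];        v01 <- values[i00 + ny]
  v10 <- values[i00 + 1L];   v11 <- values[i00 + ny + 1L]
  out[ok] <- (1 - ty) * ((1 - tx) * v00 + tx * v01) +
    ty * ((1 - tx) * v10 + tx * v11)
  out
}

# Trilinear interpolation on a regular 3D grid (axis order z, y, x).
interp_trilinear <- function(values, spacing_mm, origin_mm, z, y, x) {
  d <- dim(values); nz <- d[1]; ny <- d[2]; nx <- d[3]
  gz <- (z - origin_mm[1]) / spacing_mm[1]
  gy <- (y - origin_mm[2]) / spacing_mm[2]
  gx <- (x - origin_mm[3]) / spacing_mm[3]
  ok <- gz >= 0 & gz <= nz - 1 & gy >= 0 & gy <= ny - 1 & gx >= 0 & gx <= nx - 1
  out <- rep(NA_real_, length(z))
  if (!any(ok)) return(out)
  gz <- gz[ok]; gy <- gy[ok]; gx <- gx[ok]
  iz <- pmin(floor(gz), nz - 2)
  iy <- pmin(floor(gy), ny - 2)
  ix <- pmin(floor(gx), nx - 2)
  tz <- gz - iz; ty <- gy - iy; tx <- gx - ix
  base <- iz + 1L + nz * (iy + ny * ix)
  dzy <- nz; dzx <- nz * ny
  c000 <- values[base];                 c100 <- values[base + 1L]
  c010 <- values[base + dzy];           c110 <- values[base + 1L + dzy]
  c001 <- values[base + dzx];           c101 <- values[base + 1L + dzx]
  c011 <- values[base + dzy + dzx];     c111 <- values[base + 1L + dzy + dzx]
  c00 <- (1 - tz) * c000 + tz * c100
  c10 <- (1 - tz) * c010 + tz * c110
  c01 <- (1 - tz) * c001 + tz * c101
  c11 <- (1 - tz) * c011 + tz * c111
  c0 <- (1 - ty) * c00 + ty * c10
  c1 <- (1 - ty) * c01 + ty * c11
  out[ok] <- (1 - tx) * c0 + tx * c1
  out
}
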