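#' WHAM unbiasing of umbrella-sampling windows into a radial PMF
#'
#' Combines the biased COM-distance histograms of all windows with the
#' standard self-consistent weighted-histogram iteration (tolerance on the
#' per-window free-energy shifts), then applies the radial Jacobian
#' correction: with `P(r)` the unbiased distance distribution,
#' `F(r) = -kB T ln(P(r) / r^2) + C`, and `C` is fixed so that `F` vanishes
#' at the largest well-sampled distance `b`.
#'
#' The bias convention is `w_i(r) = k_u (r - d0_i)^2` (no 1/2 prefactor),
#' matching [run_umbrella()].
#'
#' @param umbrella A `cg_umbrella` from [run_umbrella()], or a list of numeric
#'   COM-distance series (then `centers`, `k_u`, `temperature` must be given).
#' @param centers,k_u,temperature Window centres (A), spring constant
#'   (kcal/(mol A^2)) and temperature (K); taken from `umbrella` when it is a
#'   `cg_umbrella`.
#' @param breaks Histogram bin edges (A); default 100 bins spanning the data.
#' @param tol Convergence tolerance on free-energy shifts (kcal/mol).
#' @param maxit Maximum iterations.
#' @param min_count Minimum total histogram count for a bin to count as
#'   well-sampled (defines `b` and the support of the profile).
#' @return Object of class `cg_pmf`: data frame `profile` with columns `r`
#'   (bin centres), `F` (kcal/mol) and `count`; plus `b` (A), `temperature`,
#'   `f_shifts`, `iterations`.
#' @export
wham_pmf <- function(umbrella, centers = NULL, k_u = NULL, temperature = NULL,
                     breaks = NULL, tol = 1e-7, maxit = 10000, min_count = 10) {
  if (inherits(umbrella, "cg_umbrella")) {
    series <- umbrella$series
    centers <- umbrella$centers
    k_u <- umbrella$k_u
    temperature <- umbrella$temperature
  } else {
    series <- umbrella
    if (is.null(centers) || is.null(k_u) || is.null(temperature)) {
      stop("centers, k_u and temperature are required with raw series input")
    }
  }
  W <- length(series)
  if (W < 1) stop("no umbrella windows")
  stopifnot(length(centers) == W)
  all_r <- unlist(series)
  if (is.null(breaks)) {
    breaks <- seq(min(all_r) - 1e-9, max(all_r) + 1e-9, length.out = 101)
  }
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  nb <- length(mids)
  H <- vapply(series, function(x)
    graphics::hist(x, breaks = breaks, plot = FALSE,
                   warn.unused = FALSE)$counts, numeric(nb))
  H <- matrix(H, nrow = nb)
  N <- colSums(H)
  beta <- 1 / (cg_constants$kB * temperature)
  bias <- vapply(centers, function(c0) k_u * (mids - c0)^2, numeric(nb))  # nb x W
  expb <- exp(-beta * bias)

  # window overlap diagnostic: adjacent windows must share support
  if (W >= 2) {
    occ <- H > 0
    for (w in seq_len(W - 1)) {
      if (!any(occ[, w] & occ[, w + 1])) {
        stop(sprintf("umbrella windows %d (d0 = %.2f) and %d (d0 = %.2f) do not overlap",
                     w, centers[w], w + 1, centers[w + 1]))
      }
    }
  }

  f <- rep(0, W)   # per-window free-energy shifts (kcal/mol)
  hsum <- rowSums(H)
  it <- 0
  repeat {
    it <- it + 1
    denom <- as.vector(expb %*% (N * exp(beta * f)))
    P <- ifelse(denom > 0, hsum / denom, 0)
    fnew <- -log(colSums(P * expb)) / beta
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - f)) < tol || it >= maxit) { f <- fnew; break }
    f <- fnew
  }
  P <- P / sum(P)
  well <- hsum >= min_count & P > 0
  if (!any(well)) stop("no well-sampled bins")
  Fr <- rep(NA_real_, nb)
  Fr[well] <- -log(P[well] / mids[well]^2) / beta
  b <- max(mids[well])
  Fr <- Fr - Fr[which(well)[which.max(mids[well])]]
  out <- list(profile = data.frame(r = mids, F = Fr, count = hsum),
              b = b, temperature = temperature, f_shifts = f, iterations = it)
  class(out) <- "cg_pmf"
  out
}

#' Molar dissociation constant from a radial PMF
#'
#' Integrates the bound volume under the PMF:
#' `1 / Kd = N_A * integral_0^b 4 pi r^2 exp(-beta F(r)) dr` (volume converted
#' from A^3 to litres), with `b` the distance where the PMF reaches its
#' limiting value of zero. Trapezoidal quadrature on the profile grid.
#'
#' @param profile A `cg_pmf`, or a data frame with columns `r` and `F`
#'   (then `b` defaults to the largest finite r).
#' @param temperature Temperature in K (default: the profile's).
#' @param b Integration limit (A); default the profile's `b`.
#' @return Dissociation constant in mol/L.
#' @export
#' @examples
#' flat <- data.frame(r = seq(0.1, 50, length.out = 200), F = 0)
#' kd_from_pmf(flat, temperature = 300, b = 50)  # ~3.2e-3 M
kd_from_pmf <- function(profile, temperature = NULL, b = NULL) {
  if (inherits(profile, "cg_pmf")) {
    if (is.null(temperature)) temperature <- profile$temperature
    if (is.null(b)) b <- profile$b
    profile <- profile$profile
  }
  if (is.null(temperature)) stop("temperature required")
  ok <- is.finite(profile$F) & is.finite(profile$r)
  r <- profile$r[ok]; Fv <- profile$F[ok]
  if (is.null(b)) b <- max(r)
  keep <- r <= b + 1e-9
  r <- r[keep]; Fv <- Fv[keep]
  if (length(r) < 2) stop("PMF profile has too few points inside b")
  # extend to r = 0 with the innermost value so the sphere volume is complete
  if (min(r) > 1e-6) { r <- c(0, r); Fv <- c(Fv[1], Fv) }
  beta <- 1 / (cg_constants$kB * temperature)
  integrand <- 4 * pi * r^2 * exp(-beta * Fv)
  I <- sum(diff(r) * (head(integrand, -1) + tail(integrand, -1)) / 2)  # A^3
  vol_L <- I * cg_constants$A3_to_L
  if (vol_L <= 0 || !is.finite(vol_L)) return(Inf)
  1 / (cg_constants$avogadro * vol_L)
}
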