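#' SAXS curve container
#'
#' @param q momentum transfer grid in 1/Angstrom, strictly increasing, >= 0.
#' @param I intensity (arbitrary units).
#' @param sigma optional per-point uncertainty (> 0 where present).
#' @return An object of class `saxs_curve`.
#' @export
saxs_curve <- function(q, I, sigma = NULL) {
  q <- as.numeric(q); I <- as.numeric(I)
  if (length(q) != length(I)) stop("saxs_curve: q and I lengths differ")
  if (!length(q)) stop("saxs_curve: empty curve")
  if (any(diff(q) <= 0)) stop("saxs_curve: q must be strictly increasing")
  if (any(q < 0)) stop("saxs_curve: q must be non-negative")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("saxs_curve: sigma length mismatch")
    if (any(sigma <= 0)) stop("saxs_curve: sigma must be positive")
  }
  out <- list(q = q, I = I, sigma = sigma)
  class(out) <- "saxs_curve"
  out
}

#' @export
print.saxs_curve <- function(x, ...) {
  cat(sprintf("saxs_curve: %d points, q in [%.4g, %.4g] 1/A%s\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "" else ", with uncertainties"))
  invisible(x)
}

#' Read a SAXS curve from 3-column text
#'
#' Whitespace-separated columns `q I sigma` (sigma optional), `#` comments,
#' q in 1/Angstrom.
#'
#' @param path text file path.
#' @return A [saxs_curve()].
#' @export
read_saxs <- function(path) {
  if (!file.exists(path)) stop("read_saxs: file not found: ", path)
  tab <- utils::read.table(path, comment.char = "#")
  if (ncol(tab) < 2) stop("read_saxs: need at least 2 columns (q, I)")
  saxs_curve(tab[[1]], tab[[2]], if (ncol(tab) >= 3) tab[[3]] else NULL)
}

#' Write a SAXS curve as 3-column text
#' @param curve a `saxs_curve`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_saxs <- function(curve, path) {
  sig <- if (is.null(curve$sigma)) rep(NA_real_, length(curve$q)) else curve$sigma
  lines <- c("# q I sigma",
             sprintf("%.8g %.8g %.8g", curve$q, curve$I, sig))
  writeLines(lines, path)
  invisible(path)
}

#' Theoretical SAXS profile by the Debye formula
#'
#' Coarse-grained one-bead-per-residue evaluation at the Calpha positions
#' with a uniform form factor:
#' `I(q) = sum_ij f^2 sin(q r_ij) / (q r_ij)`, with the sinc limit at q = 0.
#' The default method accumulates the double sum over a pair-distance
#' histogram (bin width `bin`); `method = "exact"` is the O(N^2) reference
#' sum.
#'
#' @param structure an `xl_structure` (>= 1 Calpha bead).
#' @param q_grid momentum transfer grid, 1/Angstrom.
#' @param form_factor uniform per-bead form factor f (default 1).
#' @param method "hist" (default) or "exact".
#' @param bin histogram bin width in Angstrom.
#' @return A [saxs_curve()] without uncertainties.
#' @export
debye_profile <- function(structure, q_grid, form_factor = 1,
                          method = c("hist", "exact"), bin = 0.1) {
  method <- match.arg(method)
  xyz <- ca_coords(structure)$xyz
  n <- nrow(xyz)
  if (!n) stop("debye_profile: structure has no Calpha beads")
  q <- as.numeric(q_grid)
  if (any(diff(q) <= 0) || any(q < 0)) stop("debye_profile: invalid q grid")
  f2 <- form_factor^2
  if (n == 1L) return(saxs_curve(q, rep(f2, length(q))))
  dvec <- as.numeric(stats::dist(xyz))
  if (method == "exact") {
    I <- vapply(q, function(qk) {
      if (qk == 0) return(f2 * (n + 2 * length(dvec)))
      x <- qk * dvec
      f2 * (n + 2 * sum(sin(x) / x))
    }, numeric(1))
  } else {
    h <- as.integer(dvec / bin) + 1L
    cnt <- tabulate(h)
    r <- (seq_along(cnt) - 0.5) * bin
    keep <- cnt > 0
    cnt <- cnt[keep]; r <- r[keep]
    I <- vapply(q, function(qk) {
      if (qk == 0) return(f2 * (n + 2 * length(dvec)))
      x <- qk * r
      f2 * (n + 2 * sum(cnt * sin(x) / x))
    }, numeric(1))
  }
  saxs_curve(q, I)
}

#' Fit a model profile to an experimental curve
#'
#' Linearly interpolates the model onto the experimental q grid
#' (extrapolation is forbidden), finds the analytic least-squares scale
#' `c = sum(I_e I_m / s^2) / sum(I_m^2 / s^2)`, and reports the reduced
#' discrepancy `chi2 = (1/N) sum(((I_e - c I_m) / s)^2)` (divide-by-N
#' convention; `n_minus_one = TRUE` switches to N - 1).
#'
#' @param model a `saxs_curve` (theoretical; sigma ignored).
#' @param experiment a `saxs_curve` with positive sigma.
#' @param n_minus_one divide chi2 by N - 1 instead of N.
#' @return List of class `saxs_fit`: `scale`, `chi2`, `n_points`.
#' @export
fit_scale_chi2 <- function(model, experiment, n_minus_one = FALSE) {
  stopifnot(inherits(model, "saxs_curve"), inherits(experiment, "saxs_curve"))
  if (is.null(experiment$sigma))
    stop("fit_scale_chi2: experimental curve lacks uncertainties")
  if (min(experiment$q) < min(model$q) - 1e-12 ||
      max(experiment$q) > max(model$q) + 1e-12)
    stop("fit_scale_chi2: experimental q range [", min(experiment$q), ", ",
         max(experiment$q), "] not covered by the model grid (no extrapolation)")
  Im <- stats::approx(model$q, model$I, xout = experiment$q)$y
  Ie <- experiment$I; s2 <- experiment$sigma^2
  cc <- sum(Ie * Im / s2) / sum(Im^2 / s2)
  n <- length(Ie)
  chi2 <- sum(((Ie - cc * Im) / experiment$sigma)^2) /
    (if (n_minus_one) n - 1L else n)
  out <- list(scale = cc, chi2 = chi2, n_points = n)
  class(out) <- "saxs_fit"
  out
}

#' @export
print.saxs_fit <- function(x, ...) {
  cat(sprintf("saxs_fit: scale %.4g, chi2 %.4g over %d points\n",
              x$scale, x$chi2, x$n_points))
  invisible(x)
}

#' Guinier analysis: radius of gyration from the low-q regime
#'
#' Iteratively fits `ln I` versus `q^2` on the window `q <= qmax_rg / Rg`
#' until the window stabilises; `Rg = sqrt(-3 slope)`.
#'
#' @param curve a `saxs_curve` with positive intensities at low q.
#' @param qmax_rg Guinier validity bound on `q * Rg` (default 1.3).
#' @param min_points minimum window size (default 5).
#' @return List of class `guinier_fit`: `Rg` (Angstrom), `I0`, `q_window`
#'   (range used), `n_points`.
#' @export
guinier_rg <- function(curve, qmax_rg = 1.3, min_points = 5L) {
  stopifnot(inherits(curve, "saxs_curve"))
  use <- curve$q > 0 & curve$I > 0
  q <- curve$q[use]; I <- curve$I[use]
  if (length(q) < min_points) stop("guinier_rg: fewer than ", min_points,
                                   " usable points")
  fit_window <- function(n) {
    co <- stats::coef(stats::lm(log(I[1:n]) ~ I(q[1:n]^2)))
    list(I0 = exp(co[[1]]), slope = co[[2]])
  }
  n <- max(min_points, min(10L, length(q)))
  rg <- NA_real_
  for (iter in 1:25) {
    fw <- fit_window(n)
    if (fw$slope >= 0)
      stop("guinier_rg: non-decreasing intensity in the fit window (no Guinier decay)")
    rg <- sqrt(-3 * fw$slope)
    n_new <- max(min_points, sum(q * rg <= qmax_rg))
    if (n_new < min_points)
      stop("guinier_rg: fewer than ", min_points, " points satisfy q*Rg <= ",
           qmax_rg)
    if (n_new == n) break
    n <- n_new
  }
  fw <- fit_window(n)
  if (fw$slope >= 0) stop("guinier_rg: no Guinier decay in final window")
  out <- list(Rg = sqrt(-3 * fw$slope), I0 = fw$I0,
              q_window = c(q[1], q[n]), n_points = n)
  class(out) <- "guinier_fit"
  out
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("guinier_fit: Rg %.2f A, I0 %.4g, window q [%.4g, %.4g] (%d pts)\n",
              x$Rg, x$I0, x$q_window[1], x$q_window[2], x$n_points))
  invisible(x)
}
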