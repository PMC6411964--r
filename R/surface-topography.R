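#' Radially averaged power spectrum of a height map
#'
#' Removes the best-fit plane, applies a 2-D Hann taper normalized to unit
#' mean square power, computes the 2-D periodogram and averages it over
#' logarithmically spaced annuli in spatial frequency.  Parseval's identity
#' is preserved exactly against the tapered field (`total_power` equals
#' `tapered_var`); the detrended raw variance is kept in `height_var` --
#' with a taper the two agree closely only for spectra that are not
#' strongly red.
#'
#' @param map a [height_map()], at least 32 x 32 pixels.
#' @param n_bins number of logarithmic q bins (>= 16).
#' @return A list of class `power_spectrum` with fields `q` (1/nm,
#'   increasing), `Q` (annulus-mean power density), `n_modes` (modes per
#'   bin), `window`, `total_power`, `height_var` and logical `degenerate`
#'   (all-zero spectrum, e.g. a constant map).
#' @export
radial_power_spectrum <- function(map, n_bins = 24) {
  stopifnot(inherits(map, "height_map"), n_bins >= 16)
  z <- map$heights
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 32 || nc < 32) stop("radial_power_spectrum: map must be >= 32x32")

  # detrend: subtract best-fit plane
  xs <- (seq_len(nc) - (nc + 1) / 2)
  ys <- (seq_len(nr) - (nr + 1) / 2)
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)
  bx <- sum(X * z) / sum(X * X)
  by <- sum(Y * z) / sum(Y * Y)
  z <- z - mean(z) - bx * X - by * Y
  hv <- mean(z^2)

  # Hann taper, normalized to unit mean square so total power is preserved
  wx <- 0.5 * (1 - cos(2 * pi * (seq_len(nc) - 1) / (nc - 1)))
  wy <- 0.5 * (1 - cos(2 * pi * (seq_len(nr) - 1) / (nr - 1)))
  w <- outer(wy, wx)
  w <- w / sqrt(mean(w^2))
  zw <- z * w
  zf <- fft(zw)
  per <- Mod(zf)^2 / (nr * nc)^2          # sum(per) == mean((z*w)^2)
  tv <- mean(zw^2)

  kx <- c(0:(nc %/% 2), -((nc - (nc %/% 2 + 1)):1)) / (nc * map$pixel_size)
  ky <- c(0:(nr %/% 2), -((nr - (nr %/% 2 + 1)):1)) / (nr * map$pixel_size)
  qq <- sqrt(outer(ky^2, kx^2, `+`))
  keep <- qq > 0
  qv <- qq[keep]; pv <- per[keep]

  q_lo <- min(qv); q_hi <- max(qv)
  edges <- exp(seq(log(q_lo * 0.999), log(q_hi * 1.001), length.out = n_bins + 1))
  bin <- findInterval(qv, edges, rightmost.closed = TRUE)
  Qm <- tapply(pv, bin, mean)
  qm <- tapply(qv, bin, function(x) exp(mean(log(x))))
  nm <- tapply(pv, bin, length)
  ord <- order(qm)
  structure(list(q = as.numeric(qm[ord]), Q = as.numeric(Qm[ord]),
                 n_modes = as.integer(nm[ord]), window = "hann",
                 total_power = sum(per), tapered_var = tv, height_var = hv,
                 degenerate = all(pv == 0)),
            class = "power_spectrum")
}

default_fit_range <- function(ps) {
  # drop the lowest 2 bins (finite size) and the top 25% of bins (pixel noise)
  nb <- length(ps$q)
  lo <- ps$q[min(3, nb)]
  hi <- ps$q[max(1, floor(nb * 0.75))]
  c(lo, hi)
}

#' Fractal dimension from a power spectrum
#'
#' Fits log Q against log q by least squares over `fit_range`; the negative
#' slope is the spectral exponent beta and the fractal dimension follows as
#' \eqn{D_f = (8 - \beta)/2} (2 for a flat Euclidean surface up to 3 for an
#' extremely rough one).  Values outside \[2, 3\] are reported unclamped with
#' `out_of_range = TRUE`.
#'
#' @param ps a `power_spectrum` (see [radial_power_spectrum()]).
#' @param fit_range `c(q_lo, q_hi)`; default drops the 2 lowest bins and the
#'   top 25% of bins.
#' @return list with `D_f`, `beta`, `fit_r2`, `fit_range`, `out_of_range`.
#' @export
fractal_dimension <- function(ps, fit_range = NULL) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (isTRUE(ps$degenerate)) stop("fractal_dimension: degenerate (zero) spectrum")
  if (is.null(fit_range)) fit_range <- default_fit_range(ps)
  sel <- ps$q >= fit_range[1] & ps$q <= fit_range[2] & ps$Q > 0
  if (sum(sel) < 5)
    stop("fractal_dimension: fewer than 5 positive spectrum points in fit range")
  # weight bins by their mode counts: sparse low-q annuli carry large
  # sampling variance on the log scale and would otherwise tilt the fit
  w <- if (!is.null(ps$n_modes)) ps$n_modes[sel] else rep(1, sum(sel))
  fit <- lm(log(ps$Q[sel]) ~ log(ps$q[sel]), weights = w)
  beta <- -unname(coef(fit)[2])
  y <- log(ps$Q[sel])
  r2 <- 1 - sum(w * resid(fit)^2) /
    sum(w * (y - sum(w * y) / sum(w))^2)
  D_f <- (8 - beta) / 2
  list(D_f = D_f, beta = beta, fit_r2 = r2, fit_range = fit_range,
       out_of_range = (D_f < 2 || D_f > 3))
}

#' Average roughness Ra
#'
#' Mean absolute deviation of heights from the map mean, the standard
#' areal average-roughness parameter.
#'
#' @param map a [height_map()].
#' @return Ra in nm.
#' @export
average_roughness <- function(map) {
  stopifnot(inherits(map, "height_map"))
  mean(abs(map$heights - mean(map$heights)))
}

#' Abbott-Firestone (bearing area) curve
#'
#' Fraction of surface points at or above each of `n_levels` height
#' thresholds spanning the observed height range.
#'
#' @param map a [height_map()].
#' @param n_levels number of thresholds (>= 2).
#' @return list of class `abbott_curve` with `z` (nm, increasing) and `f`
#'   (fraction >= z, non-increasing).
#' @export
abbott_firestone <- function(map, n_levels = 100) {
  stopifnot(inherits(map, "height_map"), n_levels >= 2)
  h <- as.vector(map$heights)
  z <- seq(min(h), max(h), length.out = n_levels)
  f <- vapply(z, function(zz) mean(h >= zz), numeric(1))
  structure(list(z = z, f = f), class = "abbott_curve")
}

#' Solid fraction of a nanowire structure
#'
#' Fraction of pixels occupied by material.  For a [binary_image()] this is
#' the solid-pixel count over the total; for a [height_map()] the map is
#' first binarized at `cutoff` (default: midpoint of the height range),
#' counting pixels at or above the cutoff as solid.
#'
#' @param input a [binary_image()] or [height_map()].
#' @param cutoff height threshold in nm (height-map path only).
#' @return solid fraction in \[0, 1\].
#' @export
solid_fraction <- function(input, cutoff = NULL) {
  if (inherits(input, "binary_image")) return(mean(input$mask))
  if (inherits(input, "height_map")) {
    h <- input$heights
    if (is.null(cutoff)) cutoff <- min(h) + 0.5 * (max(h) - min(h))
    if (cutoff < min(h) || cutoff > max(h))
      stop("solid_fraction: cutoff outside height range")
    return(mean(h >= cutoff))
  }
  stop("solid_fraction: input must be a binary_image or height_map")
}

#' Full surface characterization report
#'
#' Convenience wrapper: power spectrum, spectral slope and fractal
#' dimension, average roughness, and (when a top view or cutoff is
#' available) solid fraction.
#'
#' @param map a [height_map()].
#' @param topview optional [binary_image()] used for the solid fraction.
#' @param fit_range optional `c(q_lo, q_hi)` for the slope fit.
#' @param n_bins number of radial q bins.
#' @return list of class `surface_report` with `D_f`, `beta`, `Ra`, `sf`,
#'   `fit_range`, `fit_r2`, `out_of_range`.
#' @export
surface_report <- function(map, topview = NULL, fit_range = NULL,
                           n_bins = 24) {
  ps <- radial_power_spectrum(map, n_bins = n_bins)
  fd <- fractal_dimension(ps, fit_range)
  sf <- if (!is.null(topview)) solid_fraction(topview) else
    solid_fraction(map)
  structure(list(D_f = fd$D_f, beta = fd$beta, Ra = average_roughness(map),
                 sf = sf, fit_range = fd$fit_range, fit_r2 = fd$fit_r2,
                 out_of_range = fd$out_of_range),
            class = "surface_report")
}

#' @export
print.surface_report <- function(x, ...) {
  cat(sprintf("<surface_report> D_f = %.3f (beta = %.3f, r2 = %.3f%s), Ra = %.3g nm, sf = %.3f\n",
              x$D_f, x$beta, x$fit_r2,
              if (x$out_of_range) ", OUT OF [2,3]" else "", x$Ra, x$sf))
  invisible(x)
}
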