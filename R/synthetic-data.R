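#' Synthesize a self-affine surface with a prescribed spectral slope
#'
#' Builds a square height map whose radially averaged power spectral density
#' falls off as \eqn{Q(q) \propto q^{-\beta}} with \eqn{\beta} =
#' `spectral_slope`, using Fourier-domain filtering of seeded white noise
#' (Hermitian symmetry is inherited from the real-space noise, amplitudes are
#' shaped as \eqn{q^{-\beta/2}}, the zero mode is removed so the surface has
#' zero mean).  The height field is rescaled so its root-mean-square
#' deviation equals `rms` exactly.
#'
#' Under the spectral relation \eqn{D_f = (8 - \beta)/2}, `spectral_slope = 4`
#' corresponds to a smooth (Euclidean) surface with \eqn{D_f = 2} and
#' `spectral_slope = 2` to an extremely rough surface with \eqn{D_f = 3}.
#'
#' @param size_px grid side in pixels (>= 32).
#' @param pixel_size lateral spacing, nm per pixel.
#' @param spectral_slope target log-log PSD slope beta, in (1, 8).
#' @param rms target root-mean-square height deviation (nm, >= 0).
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @return A [height_map()].
#' @export
gen_self_affine_surface <- function(size_px = 512, pixel_size = 10,
                                    spectral_slope = 3, rms = 50,
                                    seed = 1) {
  stopifnot(size_px >= 32, spectral_slope > 1, spectral_slope < 8)
  if (rms < 0) stop("gen_self_affine_surface: rms must be >= 0")
  n <- as.integer(size_px)
  # a decade of usable frequencies needs at least ~20 modes below Nyquist
  if (n / 2 < 10)
    stop("gen_self_affine_surface: grid too small to span a decade of q")
  if (rms == 0) {
    return(height_map(matrix(0, n, n), pixel_size,
                      name = sprintf("self-affine beta=%g rms=0", spectral_slope)))
  }
  k <- c(0:(n %/% 2), -((n - (n %/% 2 + 1)):1)) / n  # cycles per pixel
  kx <- matrix(k, n, n)
  ky <- t(kx)
  q <- sqrt(kx^2 + ky^2)
  amp <- q
  amp[1, 1] <- 1
  amp <- amp^(-spectral_slope / 2)
  amp[1, 1] <- 0                       # zero mean
  noise <- with_seed(seed, matrix(rnorm(n * n), n, n))
  z <- Re(fft(fft(noise) * amp, inverse = TRUE)) / (n * n)
  z <- z - mean(z)
  z <- z * (rms / sqrt(mean(z^2)))
  height_map(z, pixel_size,
             name = sprintf("self-affine beta=%g", spectral_slope))
}

#' Synthesize a nanowire-array top view as a binary disc image
#'
#' Emulates a segmented top-view electron micrograph of a vertical nanowire
#' array: discs of radius `wire_radius_px` are stamped at seeded random
#' positions until the solid (pixel-count) fraction is within 0.02 of
#' `target_sf` or no further progress is possible.
#'
#' @param size_px image side in pixels.
#' @param target_sf target solid fraction in \[0, 1\].
#' @param wire_radius_px disc radius in pixels (>= 1).
#' @param seed integer RNG seed.
#' @param pixel_size lateral nm per pixel (metadata only).
#' @return A [binary_image()] with attribute `achieved_sf`.
#' @export
gen_nanowire_topview <- function(size_px = 256, target_sf = 0.5,
                                 wire_radius_px = 4, seed = 1,
                                 pixel_size = 10) {
  stopifnot(target_sf >= 0, target_sf <= 1, wire_radius_px >= 1, size_px >= 8)
  n <- as.integer(size_px)
  mask <- matrix(FALSE, n, n)
  if (target_sf >= 1) {
    img <- binary_image(matrix(TRUE, n, n), pixel_size)
    attr(img, "achieved_sf") <- 1
    return(img)
  }
  if (target_sf > 0) {
    r <- wire_radius_px
    offs <- expand.grid(dx = -r:r, dy = -r:r)
    offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, ]
    disc_px <- nrow(offs)
    max_iter <- ceiling(5 * n * n / disc_px) + 1000
    with_seed(seed, {
      it <- 0; stalled <- 0
      while (it < max_iter) {
        it <- it + 1
        cx <- sample.int(n, 1); cy <- sample.int(n, 1)
        ix <- ((cx + offs$dx - 1) %% n) + 1   # periodic stamping
        iy <- ((cy + offs$dy - 1) %% n) + 1
        idx <- cbind(ix, iy)
        before <- sum(mask[idx])
        mask[idx] <- TRUE
        if (before == disc_px) stalled <- stalled + 1 else stalled <- 0
        frac <- sum(mask) / (n * n)
        if (frac >= target_sf - 0.02) break
        if (stalled > 200) break
      }
    })
    frac <- sum(mask) / (n * n)
    if (abs(frac - target_sf) > 0.02)
      warning(sprintf("gen_nanowire_topview: target sf %.3f unreachable; achieved %.3f",
                      target_sf, frac))
  }
  img <- binary_image(mask, pixel_size)
  attr(img, "achieved_sf") <- sum(mask) / (n * n)
  img
}

#' Generate a synthetic cell field (uniform or clustered)
#'
#' With `planted_cluster_size = 1` this draws a homogeneous (binomial
#' approximation of Poisson) point process.  With `planted_cluster_size = n
#' > 1` it draws a Thomas-type process: `ceiling(N / n)` parent centres are
#' placed uniformly in the ROI and each receives `n` offspring scattered with
#' an isotropic Gaussian of standard deviation `cluster_sigma`, resampled
#' until inside the ROI so the planted total count is kept.  The default
#' density of 2000 cells/mm^2 over a 1 mm-square ROI matches the cell
#' seeding regime the downstream analyses assume.
#'
#' @param roi numeric length-2 ROI `c(width, height)` in um.
#' @param density target density in cells per mm^2 (> 0).
#' @param planted_cluster_size cells per planted cluster (>= 1).
#' @param cluster_sigma Gaussian scatter of offspring around parents (um).
#' @param seed integer RNG seed.
#' @return A [point_field()] with attribute `parents` (the planted centres)
#'   when clustered.
#' @export
gen_cell_field <- function(roi = c(1000, 1000), density = 2000,
                           planted_cluster_size = 1, cluster_sigma = 40,
                           seed = 1) {
  stopifnot(density > 0, planted_cluster_size >= 1)
  if (planted_cluster_size > 1) stopifnot(cluster_sigma > 0)
  area_mm2 <- prod(roi) / 1e6
  n_total <- round(density * area_mm2)
  if (n_total < 1) {
    warning("gen_cell_field: ROI area x density < 1; returning empty field")
    return(point_field(matrix(numeric(0), 0, 2), roi))
  }
  n <- as.integer(planted_cluster_size)
  with_seed(seed, {
    if (n == 1) {
      pts <- cbind(runif(n_total, 0, roi[1]), runif(n_total, 0, roi[2]))
      parents <- NULL
    } else {
      n_par <- ceiling(n_total / n)
      parents <- cbind(runif(n_par, 0, roi[1]), runif(n_par, 0, roi[2]))
      counts <- rep(n, n_par)
      counts[n_par] <- n_total - n * (n_par - 1)
      pts <- matrix(NA_real_, n_total, 2)
      row <- 1
      for (p in seq_len(n_par)) {
        need <- counts[p]
        got <- 0
        while (got < need) {
          m <- (need - got) * 2 + 8
          cand <- cbind(rnorm(m, parents[p, 1], cluster_sigma),
                        rnorm(m, parents[p, 2], cluster_sigma))
          ok <- cand[, 1] >= 0 & cand[, 1] <= roi[1] &
                cand[, 2] >= 0 & cand[, 2] <= roi[2]
          cand <- cand[ok, , drop = FALSE]
          take <- min(nrow(cand), need - got)
          if (take > 0) {
            pts[row:(row + take - 1), ] <- cand[seq_len(take), ]
            row <- row + take
            got <- got + take
          }
        }
      }
    }
  })
  field <- point_field(pts, roi)
  if (!is.null(parents)) attr(field, "parents") <- parents
  field
}

#' Render a synthetic nuclei image from a point field
#'
#' One Gaussian spot (unit peak amplitude) per cell, plus seeded additive
#' Gaussian noise; emulates a DAPI-stained nuclei micrograph for testing
#' blob detection.
#'
#' @param field a [point_field()].
#' @param pixel_size um per pixel of the rendered image.
#' @param psf_sigma Gaussian spot standard deviation (um, > 0).
#' @param noise_sd additive noise standard deviation (fraction of peak).
#' @param seed integer RNG seed.
#' @return numeric matrix (rows = y, cols = x) with attributes
#'   `pixel_size` (um/px) and `roi`.
#' @export
gen_nuclei_image <- function(field, pixel_size = 2, psf_sigma = 4,
                             noise_sd = 0, seed = 1) {
  stopifnot(inherits(field, "point_field"), psf_sigma > 0)
  if (pixel_size > psf_sigma)
    warning("gen_nuclei_image: pixel_size exceeds psf_sigma (undersampled spots)")
  nx <- max(2L, ceiling(field$roi[1] / pixel_size))
  ny <- max(2L, ceiling(field$roi[2] / pixel_size))
  img <- matrix(0, ny, nx)
  xc <- (seq_len(nx) - 0.5) * pixel_size
  yc <- (seq_len(ny) - 0.5) * pixel_size
  s <- psf_sigma
  halo <- ceiling(4 * s / pixel_size)
  for (i in seq_len(n_points(field))) {
    px <- field$points[i, 1]; py <- field$points[i, 2]
    jx <- max(1, floor(px / pixel_size) - halo):min(nx, ceiling(px / pixel_size) + halo)
    jy <- max(1, floor(py / pixel_size) - halo):min(ny, ceiling(py / pixel_size) + halo)
    gx <- exp(-(xc[jx] - px)^2 / (2 * s^2))
    gy <- exp(-(yc[jy] - py)^2 / (2 * s^2))
    img[jy, jx] <- img[jy, jx] + outer(gy, gx)
  }
  if (noise_sd > 0)
    img <- img + with_seed(seed, matrix(rnorm(length(img), 0, noise_sd), ny, nx))
  attr(img, "pixel_size") <- pixel_size
  attr(img, "roi") <- field$roi
  img
}

#' Generate synthetic calcium-fluorescence traces with planted spikes
#'
#' Spike onsets are drawn from a homogeneous Poisson process at `rate`
#' spikes/s per neuron, thinned so successive onsets are at least
#' `min_interval` apart (calcium events have effective inter-event
#' refractoriness, and sub-interval doublets would be unresolvable in the
#' fluorescence by construction); each planted spike adds an
#' instantaneous-rise, single-exponential-decay transient of peak
#' `amplitude` (dF/F units) on a constant baseline, plus seeded Gaussian
#' noise.  The planted onset times are stored so detection can be scored
#' against ground truth.
#'
#' @param n_neurons number of neurons (rows).
#' @param duration recording length (s); must be >= 10 frame intervals.
#' @param frame_interval frame spacing (s).
#' @param rate planted spike rate (spikes/s, >= 0).
#' @param amplitude transient peak in dF/F units.
#' @param decay_tau transient decay time constant (s, > frame_interval).
#' @param noise_sd additive noise sd in dF/F units.
#' @param baseline constant fluorescence baseline (arbitrary units, > 0).
#' @param min_interval minimal spacing between planted onsets (s).
#' @param seed integer RNG seed.
#' @return A [trace_set()] with `planted_onsets` filled.
#' @export
gen_calcium_traces <- function(n_neurons = 30, duration = 40,
                               frame_interval = 0.1, rate = 0.5,
                               amplitude = 1, decay_tau = 1,
                               noise_sd = 0.05, baseline = 100,
                               min_interval = 1, seed = 1) {
  stopifnot(duration >= 10 * frame_interval, decay_tau > frame_interval,
            rate >= 0, baseline > 0)
  if (rate * decay_tau > 5)
    warning("gen_calcium_traces: rate x decay_tau > 5; transients merge heavily")
  n_frames <- floor(duration / frame_interval)
  tt <- (seq_len(n_frames) - 1) * frame_interval
  with_seed(seed, {
    onsets <- vector("list", n_neurons)
    dff <- matrix(0, n_neurons, n_frames)
    for (i in seq_len(n_neurons)) {
      k <- rpois(1, rate * duration)
      on <- sort(runif(k, 0, duration - frame_interval))
      # snap to frame times so the sampled peak equals the nominal amplitude
      on <- unique(tt[floor(on / frame_interval) + 1])
      # thin to the minimal inter-event interval
      if (length(on) > 1) {
        keep <- c(TRUE, diff(on) >= min_interval)
        while (!all(keep)) {
          on <- on[keep]
          keep <- c(TRUE, diff(on) >= min_interval)
        }
      }
      onsets[[i]] <- on
      for (t0 in on) {
        active <- tt >= t0
        dff[i, active] <- dff[i, active] +
          amplitude * exp(-(tt[active] - t0) / decay_tau)
      }
    }
    if (noise_sd > 0)
      dff <- dff + matrix(rnorm(length(dff), 0, noise_sd), nrow(dff))
  })
  traces <- baseline * (1 + dff)
  traces[traces < 0] <- 0
  trace_set(traces, frame_interval, planted_onsets = onsets)
}
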