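#' @useDynLib neurowire, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft lm coef median mad quantile sd runif rnorm rpois
#'   rgeom optimize optim nls resid fitted setNames dist var predict
#'   dnorm pnorm
#' @importFrom utils head tail read.csv write.csv
NULL

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Gridded surface height map
#'
#' Container for an AFM-like topography: a rectangular grid of surface
#' heights in nanometres with a fixed lateral pixel size.
#'
#' @param heights numeric matrix of heights (nm); finite, non-empty.
#' @param pixel_size lateral spacing in nm per pixel (> 0).
#' @param name free-text label.
#' @return An object of class `height_map`.
#' @export
height_map <- function(heights, pixel_size, name = "") {
  heights <- as.matrix(heights)
  stopifnot(is.numeric(heights), length(heights) > 0,
            all(is.finite(heights)),
            is.numeric(pixel_size), length(pixel_size) == 1, pixel_size > 0)
  structure(list(heights = heights, pixel_size = pixel_size,
                 name = as.character(name)[1]),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %dx%d px, %.3g nm/px%s\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size,
              if (nzchar(x$name)) paste0(" [", x$name, "]") else ""))
  cat(sprintf("  height range: [%.3g, %.3g] nm, rms %.3g nm\n",
              min(x$heights), max(x$heights),
              sqrt(mean((x$heights - mean(x$heights))^2))))
  invisible(x)
}

#' Two-level (solid/void) image
#'
#' @param mask logical (or 0/1) matrix; `TRUE`/1 marks solid material.
#' @param pixel_size lateral spacing in nm per pixel.
#' @return An object of class `binary_image`.
#' @export
binary_image <- function(mask, pixel_size = 1) {
  mask <- as.matrix(mask)
  stopifnot(length(mask) > 0, pixel_size > 0)
  u <- unique(as.vector(mask))
  if (!all(u %in% c(0, 1, TRUE, FALSE)))
    stop("binary_image: mask must be strictly two-level (0/1)")
  structure(list(mask = matrix(as.logical(mask), nrow(mask), ncol(mask)),
                 pixel_size = pixel_size),
            class = "binary_image")
}

#' Planar field of cell positions
#'
#' Positions of cell nuclei (micrometres) inside a rectangular region of
#' interest with its origin at (0, 0).
#'
#' @param points two-column matrix or data frame of (x, y) positions in um.
#' @param roi numeric length-2 vector `c(width, height)` of the ROI in um.
#' @return An object of class `point_field`.
#' @export
point_field <- function(points, roi) {
  pts <- as.matrix(points)
  if (length(pts) == 0) pts <- matrix(numeric(0), 0, 2)
  stopifnot(ncol(pts) == 2, is.numeric(roi), length(roi) == 2, all(roi > 0))
  colnames(pts) <- c("x", "y")
  if (nrow(pts) > 0) {
    stopifnot(all(is.finite(pts)))
    tol <- 1e-9
    if (any(pts[, 1] < -tol | pts[, 1] > roi[1] + tol |
            pts[, 2] < -tol | pts[, 2] > roi[2] + tol))
      stop("point_field: points outside ROI")
    if (anyDuplicated(round(pts / 1e-9)))
      stop("point_field: duplicate coordinates (within 1e-9 um)")
  }
  structure(list(points = pts, roi = as.numeric(roi)), class = "point_field")
}

#' @export
print.point_field <- function(x, ...) {
  cat(sprintf("<point_field> %d points in %g x %g um ROI\n",
              nrow(x$points), x$roi[1], x$roi[2]))
  invisible(x)
}

n_points <- function(field) nrow(field$points)

#' Fluorescence trace set
#'
#' Raw fluorescence time series, one row per neuron, with optional
#' ground-truth spike onsets planted by the generator.
#'
#' @param traces numeric matrix, neurons x frames, all values >= 0.
#' @param frame_interval frame spacing in seconds (> 0).
#' @param planted_onsets optional list of per-neuron onset times (s).
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(traces, frame_interval, planted_onsets = NULL) {
  traces <- as.matrix(traces)
  stopifnot(all(is.finite(traces)), all(traces >= 0), frame_interval > 0)
  dur <- ncol(traces) * frame_interval
  if (!is.null(planted_onsets)) {
    stopifnot(is.list(planted_onsets), length(planted_onsets) == nrow(traces))
    if (any(unlist(planted_onsets, use.names = FALSE) > dur))
      stop("trace_set: planted onsets outside recording duration")
  }
  structure(list(traces = traces, frame_interval = frame_interval,
                 planted_onsets = planted_onsets),
            class = "trace_set")
}

#' Spike raster
#'
#' Per-neuron sorted spike-time lists over a common time window.
#'
#' @param spike_times list of numeric vectors of spike times.
#' @param t_max end of the window (same units as the times).
#' @param stimulus_id optional label of the driving stimulus.
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(spike_times, t_max, stimulus_id = NA) {
  stopifnot(is.list(spike_times), t_max >= 0)
  spike_times <- lapply(spike_times, function(v) sort(as.numeric(v)))
  if (length(spike_times) &&
      any(unlist(spike_times, use.names = FALSE) < 0 |
          unlist(spike_times, use.names = FALSE) > t_max + 1e-9))
    stop("spike_raster: times outside [0, t_max]")
  structure(list(spike_times = spike_times,
                 n_neurons = length(spike_times),
                 t_max = t_max, stimulus_id = stimulus_id),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d neurons, %d spikes, window [0, %g]\n",
              x$n_neurons, sum(lengths(x$spike_times)), x$t_max))
  invisible(x)
}

euclid_dist_matrix <- function(pts) as.matrix(dist(pts))
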