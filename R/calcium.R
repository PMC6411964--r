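#' Normalized fluorescence change dF/F
#'
#' Per neuron, \eqn{\Delta F/F = (F_t - F_0)/F_0} where the baseline F_0
#' is either a global percentile of the neuron's whole trace
#' (`global_min_percentile`, default) or a rolling percentile over a
#' sliding window (`rolling_percentile`).
#'
#' @param t a [trace_set()].
#' @param baseline baseline method.
#' @param pct baseline percentile (0-100).
#' @param window rolling window length in frames (rolling method).
#' @return list of class `dff_traces` with `dff` (neurons x frames),
#'   `frame_interval`, `baseline_method`.
#' @export
delta_f_over_f <- function(t, baseline = c("global_min_percentile",
                                           "rolling_percentile"),
                           pct = 10, window = 101) {
  stopifnot(inherits(t, "trace_set"))
  baseline <- match.arg(baseline)
  tr <- t$traces
  dff <- matrix(NA_real_, nrow(tr), ncol(tr))
  for (i in seq_len(nrow(tr))) {
    if (baseline == "global_min_percentile") {
      f0 <- quantile(tr[i, ], pct / 100, names = FALSE)
      if (f0 <= 0)
        stop(sprintf("delta_f_over_f: non-positive baseline for neuron %d", i))
      dff[i, ] <- (tr[i, ] - f0) / f0
    } else {
      half <- floor(window / 2)
      nfr <- ncol(tr)
      f0 <- vapply(seq_len(nfr), function(j) {
        lo <- max(1, j - half); hi <- min(nfr, j + half)
        quantile(tr[i, lo:hi], pct / 100, names = FALSE)
      }, numeric(1))
      if (any(f0 <= 0))
        stop(sprintf("delta_f_over_f: non-positive baseline for neuron %d", i))
      dff[i, ] <- (tr[i, ] - f0) / f0
    }
  }
  structure(list(dff = dff, frame_interval = t$frame_interval,
                 baseline_method = baseline),
            class = "dff_traces")
}

#' Detect calcium-transient onsets as spike timings
#'
#' Spike timings are the onsets of individual calcium transients: the
#' first frame of each upward crossing of the per-neuron threshold
#' `median + k_sigma * robust sd`, with successive onsets at least
#' `min_separation` frames apart.  The robust sd is the
#' difference-based noise estimator `1.4826 * mad(diff(dff)) / sqrt(2)`:
#' unlike the plain MAD of the trace it is insensitive to how much of the
#' recording the (slowly decaying) transients occupy, which is what makes
#' a fixed multiple of it a usable transient threshold.
#'
#' Crossings are debounced: a crossing only counts as a transient onset if
#' the trace stays above threshold for `sustain` consecutive frames
#' (single-frame noise excursions are not calcium transients, whose decay
#' time spans many frames).
#'
#' @param d a `dff_traces` with >= 20 frames.
#' @param k_sigma threshold multiplier.
#' @param min_separation minimal onset spacing in frames.
#' @param sustain frames the crossing must persist (>= 1).
#' @return a [spike_raster()] with times in seconds.
#' @export
detect_onsets <- function(d, k_sigma = 3, min_separation = 10,
                          sustain = 2) {
  stopifnot(inherits(d, "dff_traces"), ncol(d$dff) >= 20, sustain >= 1)
  nfr <- ncol(d$dff)
  onsets <- lapply(seq_len(nrow(d$dff)), function(i) {
    x <- d$dff[i, ]
    thr <- median(x) + k_sigma * mad(diff(x)) / sqrt(2)
    above <- x > thr
    if (!any(above)) return(numeric(0))
    sus <- above
    if (sustain > 1) {
      for (s in seq_len(sustain - 1))
        sus <- sus & c(above[-seq_len(s)], rep(FALSE, s))
    }
    cross <- which(sus & !c(FALSE, above[-nfr]))
    keep <- numeric(0)
    last <- -Inf
    for (f in cross) {
      if (f - last >= min_separation) { keep <- c(keep, f); last <- f }
    }
    (keep - 1) * d$frame_interval
  })
  spike_raster(onsets, t_max = nfr * d$frame_interval)
}

#' Per-neuron spike counts and mean activity
#'
#' @param r a [spike_raster()].
#' @return list with `counts` (spikes per neuron) and
#'   `mean_spikes_per_neuron`.
#' @export
raster_summary <- function(r) {
  stopifnot(inherits(r, "spike_raster"))
  counts <- lengths(r$spike_times)
  list(counts = counts,
       mean_spikes_per_neuron = if (length(counts)) mean(counts) else 0)
}
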