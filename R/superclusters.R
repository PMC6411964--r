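#' Cutoff-distance heuristic for density-peak clustering
#'
#' Chooses `d_c` as the quantile of the pairwise-distance distribution such
#' that the mean local density rho is about `frac` of N (the 1-2% rule of
#' the original density-peak method).
#'
#' @param field a [point_field()].
#' @param frac target mean rho / N (default 0.02).
#' @return d_c in um.
#' @export
dc_heuristic <- function(field, frac = 0.02) {
  stopifnot(inherits(field, "point_field"), n_points(field) >= 2)
  as.numeric(quantile(as.vector(dist(field$points)), frac))
}

#' Density-peak decision graph (rho, delta)
#'
#' For every point, `rho` counts the neighbours strictly within `d_c`
#' (cutoff kernel, self excluded) and `delta` is the distance to the
#' nearest point of higher density; equal densities are ordered by point
#' index, and the globally densest point receives the maximum pairwise
#' distance.  Cluster centres reveal themselves as points where both rho
#' and delta (hence gamma = rho * delta) are anomalously large.
#'
#' @param field a [point_field()] with >= 2 points.
#' @param d_c cutoff distance in um; default from [dc_heuristic()].
#' @return list of class `decision_graph` with `rho`, `delta`, `gamma`,
#'   `nearest_higher` (NA for the densest point), `d_c`, `order` (indices
#'   in decreasing-density order).
#' @export
density_peak_decision <- function(field, d_c = NULL) {
  stopifnot(inherits(field, "point_field"))
  n <- n_points(field)
  stopifnot(n >= 2, is.null(d_c) || d_c > 0)
  if (is.null(d_c)) d_c <- dc_heuristic(field)
  D <- euclid_dist_matrix(field$points)
  if (d_c >= sqrt(sum(field$roi^2)))
    warning("density_peak_decision: d_c exceeds the ROI diagonal; all rho equal")
  rho <- rowSums(D < d_c) - 1L
  ord <- order(-rho, seq_len(n))          # density-decreasing, ties by index
  delta <- numeric(n)
  nh <- rep(NA_integer_, n)
  delta[ord[1]] <- max(D)
  for (k in 2:n) {
    i <- ord[k]
    prev <- ord[seq_len(k - 1)]
    j <- prev[which.min(D[i, prev])]
    delta[i] <- D[i, j]
    nh[i] <- j
  }
  structure(list(rho = as.numeric(rho), delta = delta, gamma = rho * delta,
                 nearest_higher = nh, d_c = d_c, order = ord),
            class = "decision_graph")
}

#' Select cluster centres from a decision graph
#'
#' `gamma_gap` (default): rank points by gamma = rho * delta (the globally
#' densest point, whose delta is by construction the maximum pairwise
#' distance, is re-ranked with the largest of the other deltas so its
#' forced delta cannot dwarf the real centres), keep the top
#' \eqn{3\sqrt N} candidates and split their log-gamma values into an
#' outlier group and a bulk at the threshold maximizing the between-group
#' variance (Otsu's criterion); the outliers are the centres.  When the
#' two groups are not well separated (between/within separation below
#' `min_separation`, as happens on uniform fields where the decision graph
#' carries no reliable gap) a single centre is returned flagged
#' `low_confidence`.  `threshold`: centres are all points with `rho >
#' rho_min` and `delta > delta_min`, mirroring manual decision-graph
#' inspection.
#'
#' @param dg a `decision_graph`.
#' @param method `"gamma_gap"` or `"threshold"`.
#' @param min_separation minimal Otsu between/within separation of the
#'   outlier group (in within-group standard deviations of log gamma)
#'   accepted as evidence of real cluster structure.
#' @param rho_min,delta_min thresholds (threshold method).
#' @return integer vector of centre indices with attributes
#'   `low_confidence` and `separation`.
#' @export
select_centers <- function(dg, method = c("gamma_gap", "threshold"),
                           min_separation = 7, rho_min = NULL,
                           delta_min = NULL) {
  stopifnot(inherits(dg, "decision_graph"))
  method <- match.arg(method)
  n <- length(dg$rho)
  if (method == "threshold") {
    stopifnot(!is.null(rho_min), !is.null(delta_min))
    ctr <- which(dg$rho > rho_min & dg$delta > delta_min)
    if (length(ctr) == 0) ctr <- which.max(dg$gamma)
    attr(ctr, "low_confidence") <- FALSE
    return(ctr)
  }
  # corrected ranking gamma (see above)
  gam <- dg$gamma
  top <- dg$order[1]
  gam[top] <- dg$rho[top] * max(dg$delta[-top])
  ord <- order(-gam, seq_len(n))
  K <- min(n, max(3L, ceiling(3 * sqrt(n))))
  g <- log10(pmax(gam[ord[seq_len(K)]], 0) + 1)
  sp <- otsu_split(g)
  low_conf <- !is.finite(sp["sep"]) || sp["sep"] < min_separation
  k_star <- if (low_conf) 1L else as.integer(sp["k_above"])
  ctr <- sort(ord[seq_len(k_star)])
  attr(ctr, "low_confidence") <- low_conf
  attr(ctr, "separation") <- unname(sp["sep"])
  ctr
}

## Otsu threshold on a numeric vector (descending-sorted or not); returns
## the count above the cut and the between/within separation statistic.
otsu_split <- function(v) {
  v <- sort(unname(v))
  n <- length(v)
  if (n < 3) return(c(k_above = 1, sep = Inf))
  cs <- cumsum(v); tot <- cs[n]
  ks <- seq_len(n - 1)
  m1 <- cs[ks] / ks
  m2 <- (tot - cs[ks]) / (n - ks)
  bc <- (ks / n) * (1 - ks / n) * (m1 - m2)^2
  k <- which.max(bc)
  s1 <- if (k > 1) var(v[1:k]) else 0
  s2 <- if (k < n - 1) var(v[(k + 1):n]) else 0
  sw <- sqrt(((k - 1) * s1 + (n - k - 1) * s2) / (n - 2))
  c(k_above = n - k, sep = unname(m2[k] - m1[k]) / max(sw, 1e-12))
}

#' Assign every point to a cluster centre
#'
#' Standard density-peak assignment: in decreasing-density order each
#' non-centre point inherits the label of its nearest point of higher
#' density, so labels propagate outward from the centres and every point
#' is labeled.
#'
#' @param field a [point_field()].
#' @param dg the matching `decision_graph`.
#' @param centers integer vector of centre indices (>= 1).
#' @return list of class `cluster_labeling` with `labels` (1..K per
#'   point), `centers`, `n_clusters`, `cells_per_cluster`.
#' @export
assign_clusters <- function(field, dg, centers) {
  stopifnot(inherits(field, "point_field"), inherits(dg, "decision_graph"),
            length(centers) >= 1)
  n <- n_points(field)
  labels <- rep(NA_integer_, n)
  labels[centers] <- seq_along(centers)
  for (i in dg$order) {
    if (is.na(labels[i])) labels[i] <- labels[dg$nearest_higher[i]]
  }
  structure(list(labels = labels, centers = as.integer(centers),
                 n_clusters = length(centers),
                 cells_per_cluster = n / length(centers)),
            class = "cluster_labeling")
}

#' Mean number of cells per cluster
#'
#' @param labeling a `cluster_labeling`.
#' @param total_points total cell count (defaults to the labeled count).
#' @return n = total cells / number of clusters.
#' @export
cells_per_cluster <- function(labeling, total_points = length(labeling$labels)) {
  stopifnot(inherits(labeling, "cluster_labeling"))
  if (labeling$n_clusters < 1) stop("cells_per_cluster: zero clusters")
  total_points / labeling$n_clusters
}

#' End-to-end supercluster detection
#'
#' Convenience wrapper: decision graph, gamma-gap centre selection and
#' assignment.
#'
#' @param field a [point_field()].
#' @param d_c cutoff distance; default from [dc_heuristic()].
#' @param ... passed to [select_centers()].
#' @return a `cluster_labeling` with attribute `decision_graph`.
#' @export
find_superclusters <- function(field, d_c = NULL, ...) {
  dg <- density_peak_decision(field, d_c)
  ctr <- select_centers(dg, ...)
  lab <- assign_clusters(field, dg, ctr)
  attr(lab, "decision_graph") <- dg
  attr(lab, "low_confidence") <- attr(ctr, "low_confidence")
  lab
}

#' Fit the bounded-exponential cluster-size trend
#'
#' Nonlinear least squares of \eqn{n(x) = C + A (1 - B e^{-(x - o)})} with
#' multi-start initialization.  Note the family is over-parameterized: the
#' curve depends on the four parameters only through the plateau
#' \eqn{\theta_1 = C + A} and the amplitude \eqn{\theta_2 = A B e^{o}}
#' (\eqn{n(x) = \theta_1 - \theta_2 e^{-x}}), so many 4-tuples reproduce
#' the same data exactly.  The identifiable pair is returned alongside the
#' 4-tuple (`theta1`, `theta2`) and should be preferred for comparisons;
#' fixing `B` and `o` makes the remaining two parameters identifiable.
#'
#' @param x sample index (or coordinate) vector, >= 4 values.
#' @param n_values observed cells-per-cluster at each x.
#' @param B,o optionally fix these parameters (NULL = fit them).
#' @param starts number of random multi-start perturbations.
#' @param seed RNG seed for the multi-start jitter.
#' @return list of class `cluster_trend_fit` with `C`, `A`, `B`, `o`,
#'   `theta1`, `theta2`, `r2`, `fitted`, `degenerate_flag`.
#' @export
fit_cluster_size_trend <- function(x, n_values, B = NULL, o = NULL,
                                   starts = 20, seed = 1) {
  stopifnot(length(x) == length(n_values), length(x) >= 4)
  x <- as.numeric(x); y <- as.numeric(n_values)
  # identifiable reparameterization is linear: y = theta1 - theta2 * exp(-x)
  ex <- exp(-x)
  lf <- lm(y ~ ex)
  theta1 <- unname(coef(lf)[1])
  theta2 <- -unname(coef(lf)[2])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid(lf)^2) / ss_tot else NA_real_
  degenerate <- abs(theta2) < 1e-8 * max(abs(y), 1)
  fixB <- !is.null(B); fixo <- !is.null(o)
  model <- function(p, xx) {
    Bv <- if (fixB) B else p["B"]; ov <- if (fixo) o else p["o"]
    p["C"] + p["A"] * (1 - Bv * exp(-(xx - ov)))
  }
  obj <- function(p) sum((y - model(p, x))^2)
  # data-driven start on the zero-residual manifold, then jittered restarts
  o0 <- if (fixo) o else min(x)
  B0 <- if (fixB) B else 1
  A0 <- theta2 / (B0 * exp(o0)); C0 <- theta1 - A0
  p0 <- c(C = C0, A = A0)
  if (!fixB) p0 <- c(p0, B = B0)
  if (!fixo) p0 <- c(p0, o = o0)
  best <- stats::optim(p0, obj, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-14))
  with_seed(seed, {
    for (s in seq_len(starts)) {
      ps <- p0 * (1 + rnorm(length(p0), 0, 0.3))
      cand <- tryCatch(stats::optim(ps, obj, method = "BFGS",
                                    control = list(maxit = 500, reltol = 1e-14)),
                       error = function(e) NULL)
      if (!is.null(cand) && cand$value < best$value) best <- cand
    }
  })
  p <- best$par
  Bv <- if (fixB) B else unname(p["B"])
  ov <- if (fixo) o else unname(p["o"])
  fitted_y <- unname(p["C"]) + unname(p["A"]) * (1 - Bv * exp(-(x - ov)))
  ss_res <- sum((y - fitted_y)^2)
  r2_nls <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  if (!is.finite(best$value))
    stop("fit_cluster_size_trend: optimization failed to converge")
  r2_best <- if (all(is.na(c(r2, r2_nls)))) NA_real_
             else max(r2, r2_nls, na.rm = TRUE)
  structure(list(C = unname(p["C"]), A = unname(p["A"]), B = Bv, o = ov,
                 theta1 = theta1, theta2 = theta2,
                 r2 = r2_best, fitted = fitted_y,
                 degenerate_flag = degenerate),
            class = "cluster_trend_fit")
}
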