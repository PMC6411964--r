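## FFT-based periodic Gaussian blur (adequate for interior blobs)
gaussian_blur <- function(img, sigma_px) {
  nr <- nrow(img); nc <- ncol(img)
  gy <- dnorm(c(0:(nr %/% 2), -((nr - (nr %/% 2 + 1)):1)), sd = sigma_px)
  gx <- dnorm(c(0:(nc %/% 2), -((nc - (nc %/% 2 + 1)):1)), sd = sigma_px)
  k <- outer(gy / sum(gy), gx / sum(gx))
  Re(fft(fft(img) * fft(k), inverse = TRUE)) / (nr * nc)
}

local_maxima <- function(R) {
  nr <- nrow(R); nc <- ncol(R)
  out <- matrix(TRUE, nr, nc)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- R
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- out & (R >= pad[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)])
  }
  out
}

#' Detect cell nuclei in a grayscale image
#'
#' Multi-scale difference-of-Gaussians blob detector (a standard
#' approximation of the scale-normalized Laplacian of Gaussian).  Bright
#' blobs with radii between roughly `min_sigma` and `max_sigma` are
#' returned as a [point_field()]; detections closer than `min_sigma` are
#' merged keeping the stronger response.
#'
#' @param image numeric matrix (rows = y) with a `pixel_size` attribute in
#'   um/px (or pass `pixel_size`).
#' @param min_sigma,max_sigma blob scale range in um (`min_sigma <
#'   max_sigma`).
#' @param threshold detection threshold as a fraction of the maximum
#'   blob response.
#' @param n_scales number of scales between the two sigmas.
#' @param pixel_size um per pixel, overriding the image attribute.
#' @return A [point_field()] of detected centroids (um).
#' @export
detect_nuclei <- function(image, min_sigma = 2, max_sigma = 8,
                          threshold = 0.2, n_scales = 5,
                          pixel_size = attr(image, "pixel_size")) {
  stopifnot(is.matrix(image), min_sigma < max_sigma, !is.null(pixel_size))
  roi <- attr(image, "roi")
  if (is.null(roi)) roi <- c(ncol(image), nrow(image)) * pixel_size
  sig_px <- exp(seq(log(min_sigma), log(max_sigma), length.out = n_scales)) /
    pixel_size
  k <- 1.6
  resp <- array(0, c(nrow(image), ncol(image), n_scales))
  for (s in seq_len(n_scales)) {
    # DoG, scale-normalized; positive at centres of bright blobs
    resp[, , s] <- (gaussian_blur(image, sig_px[s]) -
                    gaussian_blur(image, sig_px[s] * k)) * sig_px[s]^2
  }
  rmax <- max(resp)
  if (!is.finite(rmax) || rmax <= 0)
    return(point_field(matrix(numeric(0), 0, 2), roi))
  thr <- threshold * rmax
  det <- NULL
  for (s in seq_len(n_scales)) {
    # per-plane maxima only: cross-scale suppression would let the merged
    # coarse-scale response of a close (but resolvable) pair veto the
    # fine-scale peaks; duplicates across scales are merged below instead
    R <- resp[, , s]
    pk <- local_maxima(R) & (R > thr)
    idx <- which(pk, arr.ind = TRUE)
    if (nrow(idx)) {
      det <- rbind(det, cbind(x = (idx[, 2] - 0.5) * pixel_size,
                              y = (idx[, 1] - 0.5) * pixel_size,
                              r = R[idx], s = sig_px[s] * pixel_size))
    }
  }
  if (is.null(det) || nrow(det) == 0)
    return(point_field(matrix(numeric(0), 0, 2), roi))
  # strongest detection wins; weaker ones overlapping it (closer than the
  # sum of the two blob scales, at least min_sigma) are duplicates
  det <- det[order(-det[, "r"]), , drop = FALSE]
  keep <- rep(TRUE, nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!keep[i]) next
    if (i < nrow(det)) {
      j <- (i + 1):nrow(det)
      d2 <- (det[j, 1] - det[i, 1])^2 + (det[j, 2] - det[i, 2])^2
      rad <- pmax(min_sigma, det[i, "s"] + det[j, "s"])
      keep[j][d2 < rad^2] <- FALSE
    }
  }
  pts <- det[keep, c("x", "y"), drop = FALSE]
  pts[, 1] <- pmin(pmax(pts[, 1], 0), roi[1])
  pts[, 2] <- pmin(pmax(pts[, 2], 0), roi[2])
  point_field(pts, roi)
}

#' Wire a cell field with the Waxman random spatial graph model
#'
#' Each unordered pair of nodes (i, j) is connected independently with
#' probability \eqn{P(i,j) = \beta \exp(-d_{ij} / (\alpha L))}, where
#' \eqn{d_{ij}} is the Euclidean distance.  `alpha` acts as a temperature
#' setting the connection range, `beta` scales the node degree.  `L` is
#' the wiring length scale: by default a fixed 75 um, of order the reach
#' of neurite arbors.  Local wiring at this scale makes clustered
#' 2000 cells/mm^2 fields form connected graphs with small-world
#' character while uniform fields of equal density fragment into small
#' components.  `L = NULL` selects the classical normalization by
#' the realized maximum pairwise distance; note that on millimetre-scale
#' fields that choice makes edge probability almost distance-blind (the
#' graph degenerates to Erdos-Renyi and all small-world structure is
#' lost).  Pairs are visited in lexicographic index order drawing one
#' uniform variate each, so a fixed seed yields an identical edge set.
#'
#' @param field a [point_field()] with >= 2 points.
#' @param alpha range parameter (> 0).
#' @param beta degree parameter in \[0, 1\].
#' @param seed integer RNG seed.
#' @param L wiring length scale in um, or `NULL` for the maximum pairwise
#'   distance.
#' @return An object of class `spatial_graph`: list with `field`, `edges`
#'   (m x 2 index matrix, i < j), `lengths` (um), and `params`.
#' @export
waxman_graph <- function(field, alpha = 1, beta = 0.025, seed = 1,
                         L = 75) {
  stopifnot(inherits(field, "point_field"), n_points(field) >= 2,
            alpha > 0, beta >= 0, beta <= 1)
  n <- n_points(field)
  dvec <- as.vector(dist(field$points))   # lexicographic pair order (i<j)
  if (is.null(L)) L <- max(dvec)
  if (L == 0) {
    warning("waxman_graph: all points coincident; P = beta for every pair")
    p <- rep(beta, length(dvec))
  } else {
    p <- beta * exp(-dvec / (alpha * L))
  }
  u <- with_seed(seed, runif(length(dvec)))
  hit <- which(u < p)
  ij <- pair_index_to_ij(hit, n)
  structure(list(field = field,
                 edges = ij,
                 lengths = dvec[hit],
                 params = list(alpha = alpha, beta = beta, seed = seed,
                               L = L),
                 expected_edges = sum(p)),
            class = "spatial_graph")
}

## dist() vector position -> (i, j) with i < j, lexicographic by i
pair_index_to_ij <- function(k, n) {
  if (length(k) == 0) return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  k <- as.numeric(k)
  # pairs for row i occupy positions after cum_i = (i-1)*(n - i/2)
  i <- ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * k))
  base <- (i - 1) * n - i * (i - 1) / 2
  j <- k - base + i
  cbind(i = as.integer(i), j = as.integer(j))
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> %d nodes, %d edges (alpha=%g, beta=%g, seed=%s)\n",
              n_points(x$field), nrow(x$edges), x$params$alpha,
              x$params$beta, as.character(x$params$seed)))
  invisible(x)
}

#' Convert a spatial graph to an igraph object
#'
#' @param g a `spatial_graph`.
#' @return an undirected [igraph::graph] with vertex attributes `x`, `y`
#'   and edge attribute `length_um`.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "spatial_graph"))
  ig <- igraph::make_empty_graph(n = n_points(g$field), directed = FALSE)
  if (nrow(g$edges))
    ig <- igraph::add_edges(ig, t(g$edges))
  igraph::V(ig)$x <- g$field$points[, 1]
  igraph::V(ig)$y <- g$field$points[, 2]
  if (nrow(g$edges)) igraph::E(ig)$length_um <- g$lengths
  ig
}

#' Distribution of nodal (pairwise) distances
#'
#' Histogram over all N(N-1)/2 pairwise Euclidean distances of a field,
#' normalized to a probability distribution.  Uniform fields give a
#' unimodal distribution; clustered fields develop a second, inter-cluster
#' mode.
#'
#' @param field a [point_field()] with >= 2 points.
#' @param n_bins number of histogram bins.
#' @return list of class `distance_histogram` with `bin_edges` (um) and
#'   `density` (probability per bin, sums to 1).
#' @export
nodal_distance_distribution <- function(field, n_bins = 50) {
  stopifnot(inherits(field, "point_field"), n_points(field) >= 2,
            n_bins >= 1)
  d <- as.vector(dist(field$points))
  edges <- seq(0, max(d) * (1 + 1e-9), length.out = n_bins + 1)
  cts <- tabulate(findInterval(d, edges, rightmost.closed = TRUE), n_bins)
  structure(list(bin_edges = edges, density = cts / sum(cts)),
            class = "distance_histogram")
}

#' Degree distribution of a spatial graph
#'
#' @param g a `spatial_graph`.
#' @return list with `degrees` (per node), `histogram` (named counts) and
#'   `kappa_mean` = 2|E|/N.
#' @export
degree_distribution <- function(g) {
  stopifnot(inherits(g, "spatial_graph"))
  n <- n_points(g$field)
  deg <- tabulate(as.vector(g$edges), nbins = n)
  list(degrees = deg,
       histogram = table(factor(deg, levels = 0:max(deg))),
       kappa_mean = 2 * nrow(g$edges) / n)
}
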