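# Independent brute-force oracles, kept deliberately naive and separate
# from the package's implementation paths.

# mean local clustering coefficient by direct neighbourhood enumeration
oracle_cc <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) { cc[i] <- 0; next }
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (adj[nb[a], nb[b]] > 0) links <- links + 1
    cc[i] <- 2 * links / (k * (k - 1))
  }
  mean(cc)
}

# characteristic path length by Floyd-Warshall on the largest component
oracle_cpl <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[adj > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  # largest component = largest set of mutually reachable nodes
  comp <- rep(NA_integer_, n); cid <- 0
  for (i in seq_len(n)) if (is.na(comp[i])) {
    cid <- cid + 1
    comp[is.finite(D[i, ])] <- cid
  }
  big <- which(comp == which.max(tabulate(comp)))
  Db <- D[big, big]
  mean(Db[upper.tri(Db)])
}

# density-peak rho/delta by direct O(N^2) enumeration
oracle_rho_delta <- function(pts, d_c) {
  n <- nrow(pts)
  D <- as.matrix(dist(pts))
  rho <- sapply(seq_len(n), function(i) sum(D[i, -i] < d_c))
  ord <- order(-rho, seq_len(n))
  delta <- numeric(n)
  delta[ord[1]] <- max(D)
  for (k in 2:n) {
    i <- ord[k]
    delta[i] <- min(D[i, ord[seq_len(k - 1)]])
  }
  list(rho = rho, delta = delta)
}

# greedy matching of detections to ground truth within a tolerance
oracle_match <- function(truth, det, tol) {
  if (nrow(det) == 0 || nrow(truth) == 0) return(0L)
  D <- as.matrix(dist(rbind(truth, det)))[seq_len(nrow(truth)),
                                          -(seq_len(nrow(truth))),
                                          drop = FALSE]
  matched <- 0L
  used <- rep(FALSE, ncol(D))
  for (i in order(apply(D, 1, min))) {
    j <- which.min(ifelse(used, Inf, D[i, ]))
    if (is.finite(D[i, j]) && D[i, j] <= tol) {
      matched <- matched + 1L
      used[j] <- TRUE
    }
  }
  matched
}

# independent spectral-slope estimate from the raw 2-D periodogram
# (no detrending, no taper, no radial binning)
oracle_periodogram_slope <- function(z, pixel_size) {
  n <- nrow(z)
  z <- z - mean(z)
  per <- Mod(fft(z))^2 / length(z)^2
  k <- c(0:(n %/% 2), -((n - (n %/% 2 + 1)):1)) / (n * pixel_size)
  q <- sqrt(outer(k^2, k^2, `+`))
  sel <- q > 0 & per > 0
  # restrict to a central band clear of the zero mode and Nyquist corner
  qlim <- range(q[q > 0])
  sel <- sel & q > qlim[1] * 4 & q < qlim[2] * 0.5
  unname(-coef(lm(log(per[sel]) ~ log(q[sel])))[2])
}

# uniform random points with a hard-core minimum separation
hardcore_field <- function(n, roi, min_sep, seed) {
  set.seed(seed)
  pts <- matrix(numeric(0), 0, 2)
  while (nrow(pts) < n) {
    cand <- cbind(runif(200, min_sep / 2, roi[1] - min_sep / 2),
                  runif(200, min_sep / 2, roi[2] - min_sep / 2))
    for (k in seq_len(nrow(cand))) {
      if (nrow(pts) == 0 ||
          min((pts[, 1] - cand[k, 1])^2 + (pts[, 2] - cand[k, 2])^2) >
            min_sep^2) {
        pts <- rbind(pts, cand[k, ])
        if (nrow(pts) >= n) break
      }
    }
  }
  point_field(pts, roi)
}

# spatial_graph built from an explicit edge list (test fixture helper);
# shifts points into the positive quadrant (metrics are translation
# invariant)
graph_from_edges <- function(pts, edges, roi = NULL) {
  pts[, 1] <- pts[, 1] - min(0, min(pts[, 1]))
  pts[, 2] <- pts[, 2] - min(0, min(pts[, 2]))
  if (is.null(roi)) roi <- c(max(pts[, 1]) + 1, max(pts[, 2]) + 1)
  fld <- point_field(pts, roi)
  edges <- matrix(as.integer(edges), ncol = 2)
  lens <- sqrt(rowSums((pts[edges[, 1], , drop = FALSE] -
                        pts[edges[, 2], , drop = FALSE])^2))
  structure(list(field = fld, edges = edges, lengths = lens,
                 params = list(alpha = NA, beta = NA, seed = NA, L = NA),
                 expected_edges = nrow(edges)),
            class = "spatial_graph")
}

# adjacency matrix of a spatial_graph / igraph interop for oracles
adj_of <- function(g) {
  n <- nrow(g$field$points)
  A <- matrix(0L, n, n)
  if (nrow(g$edges)) {
    A[g$edges] <- 1L
    A[g$edges[, c(2, 1), drop = FALSE]] <- 1L
  }
  A
}

# discrete power-law sampler (Clauset et al. approximation)
rpowerlaw_discrete <- function(n, alpha, xmin = 1, seed = 1) {
  set.seed(seed)
  u <- runif(n)
  floor((xmin - 0.5) * (1 - u)^(-1 / (alpha - 1)) + 0.5)
}
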