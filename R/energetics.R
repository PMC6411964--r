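#' Pair-potential parameters for the ghost-cell energy model
#'
#' The probe (ghost) cell interacts with each cell of the configuration
#' through a short-range attraction with a hard core:
#' \eqn{u(r) = -\epsilon e^{-r/\lambda_a}} for \eqn{r \ge r_{core}}, and a
#' large flagged penalty inside the core.  A position-independent
#' substrate-adhesion term `w_sub` is carried as a constant offset (it
#' cancels in barriers).  With energies in attojoules and distances in
#' micrometres, forces come out in aJ/um = pN.
#'
#' Defaults are calibrated once against two anchors of the cluster-
#' stability phenomenology at 2000 cells/mm^2: the escape barrier flattens
#' in the several-hundred-cells regime, and the peak escape force of a
#' 200-cell cluster (the observed maximum supercluster size) is about
#' 2000 pN, the scale of measured neuronal migration forces.  `lambda_a`
#' is of order a cell radius: adhesion is a contact interaction.
#'
#' @param epsilon pair binding energy scale (aJ, > 0).
#' @param lambda_a attraction decay length (um, > 0).
#' @param r_core hard-core radius (um, >= 0).
#' @param w_sub substrate adhesion energy per cell (aJ).
#' @param core_penalty energy charged per core overlap (aJ).
#' @return list of class `potential_params`.
#' @export
potential_params <- function(epsilon = 25000, lambda_a = 5, r_core = 2,
                             w_sub = 0, core_penalty = 1000 * epsilon) {
  stopifnot(epsilon > 0, lambda_a > 0, r_core >= 0)
  structure(list(epsilon = epsilon, lambda_a = lambda_a, r_core = r_core,
                 w_sub = w_sub, core_penalty = core_penalty),
            class = "potential_params")
}

#' Build a clustered cell configuration at fixed global density
#'
#' Clusters of exactly `n` cells are centred on a regular lattice whose
#' spacing keeps the global density at `density`; cells scatter around
#' their centre with an isotropic Gaussian of standard deviation
#' \eqn{\sigma(n) = \sigma_1 n^{\gamma}}.  With the default exponent
#' \eqn{\gamma = 0.75 > 1/2} the peak intra-cluster density *dilutes* as
#' clusters grow (\eqn{\propto n^{1-2\gamma}}), reaching the global
#' density -- i.e. an effectively uniform field with a flat energy
#' landscape -- at \eqn{n \approx (2\pi\sigma_1^2\rho_g)^{-2}}; the
#' default \eqn{\sigma_1 = 1.8} um places that flattening point near
#' n = 600 cells/cluster at 2000 cells/mm^2.  (A \eqn{\sqrt n} scaling,
#' i.e. constant intra-cluster density, makes the configuration geometry
#' scale-invariant and the escape barrier *non-decreasing* in n, which
#' contradicts the cluster-stability phenomenology this module exists to
#' reproduce; see the methods vignette.)  Offspring are resampled until
#' inside the domain.
#'
#' @param n cells per cluster (1..1000).
#' @param density global density, cells per mm^2.
#' @param domain `c(width, height)` in um.
#' @param cluster_sigma per-cell scatter scale sigma_1 (um).
#' @param sigma_exponent growth exponent gamma of the cluster scatter.
#' @param seed integer RNG seed.
#' @return A [point_field()] with attributes `parents`, `sigma_n`,
#'   `n_per_cluster`.
#' @export
build_cluster_configuration <- function(n, density = 2000,
                                        domain = c(3000, 3000),
                                        cluster_sigma = 1.8,
                                        sigma_exponent = 0.75, seed = 1) {
  stopifnot(n >= 1, n <= 1000, density > 0, cluster_sigma > 0,
            sigma_exponent > 0)
  area_mm2 <- prod(domain) / 1e6
  n_clusters <- round(area_mm2 * density / n)
  if (n_clusters < 1)
    stop("build_cluster_configuration: domain too small for one cluster")
  sigma_n <- cluster_sigma * n^sigma_exponent
  # near-square lattice of parents covering the domain
  nx <- max(1L, round(sqrt(n_clusters * domain[1] / domain[2])))
  ny <- ceiling(n_clusters / nx)
  gx <- (seq_len(nx) - 0.5) * domain[1] / nx
  gy <- (seq_len(ny) - 0.5) * domain[2] / ny
  parents <- as.matrix(expand.grid(x = gx, y = gy))[seq_len(n_clusters), ,
                                                    drop = FALSE]
  with_seed(seed, {
    pts <- matrix(NA_real_, n_clusters * n, 2)
    row <- 1
    for (p in seq_len(n_clusters)) {
      got <- 0
      while (got < n) {
        m <- (n - got) * 2 + 8
        cand <- cbind(rnorm(m, parents[p, 1], sigma_n),
                      rnorm(m, parents[p, 2], sigma_n))
        ok <- cand[, 1] >= 0 & cand[, 1] <= domain[1] &
              cand[, 2] >= 0 & cand[, 2] <= domain[2]
        cand <- cand[ok, , drop = FALSE]
        take <- min(nrow(cand), n - got)
        if (take > 0) {
          pts[row:(row + take - 1), ] <- cand[seq_len(take), ]
          row <- row + take; got <- got + take
        }
      }
    }
  })
  field <- point_field(pts, domain)
  attr(field, "parents") <- parents
  attr(field, "sigma_n") <- sigma_n
  attr(field, "n_per_cluster") <- n
  field
}

#' Potential energy felt by a ghost cell at a position
#'
#' Sums the pair potential over every cell of the configuration and adds
#' the substrate term.  Positions inside a cell's hard core incur
#' `core_penalty` each; the result then carries attribute
#' `core_overlaps > 0`.
#'
#' @param probe numeric `c(x, y)` in um, inside the domain.
#' @param field a [point_field()].
#' @param p a [potential_params()].
#' @return energy e (aJ) with attribute `core_overlaps`.
#' @export
energy_at <- function(probe, field, p = potential_params()) {
  stopifnot(length(probe) == 2, inherits(field, "point_field"),
            inherits(p, "potential_params"))
  if (probe[1] < 0 || probe[1] > field$roi[1] ||
      probe[2] < 0 || probe[2] > field$roi[2])
    stop("energy_at: probe outside domain")
  if (n_points(field) == 0) {
    e <- p$w_sub
    attr(e, "core_overlaps") <- 0L
    return(e)
  }
  r <- sqrt((field$points[, 1] - probe[1])^2 +
            (field$points[, 2] - probe[2])^2)
  core <- r < p$r_core
  e <- p$w_sub + sum(-p$epsilon * exp(-r[!core] / p$lambda_a)) +
    sum(core) * p$core_penalty
  attr(e, "core_overlaps") <- sum(core)
  e
}

#' Radial energy landscape around a cluster centre
#'
#' Samples the ghost-cell energy along a ray from `center` in `direction`,
#' returning the profile, the barrier `delta_e = e(border) - e(center)`
#' and the escape-force profile `f_e = de/drho` by centred finite
#' differences.
#'
#' @param field a [point_field()].
#' @param center `c(x, y)` ray origin (um).
#' @param direction length-2 vector (normalized internally).
#' @param r_max ray length (um).
#' @param n_steps number of samples along the ray (>= 10).
#' @param p a [potential_params()].
#' @param border_radius radius defining the cluster border for the
#'   barrier; conventionally twice the cluster's radial standard
#'   deviation.  Default `r_max / 2`.
#' @return list of class `energy_landscape` with `rho`, `e`, `f_e`,
#'   `delta_e`, `border_radius`, `truncated`, `core_overlaps`.
#' @export
energy_landscape <- function(field, center, direction = c(1, 0),
                             r_max = 200, n_steps = 81,
                             p = potential_params(),
                             border_radius = r_max / 2) {
  stopifnot(n_steps >= 10, r_max > 0, border_radius <= r_max)
  u <- direction / sqrt(sum(direction^2))
  rho <- seq(0, r_max, length.out = n_steps)
  xs <- center[1] + rho * u[1]
  ys <- center[2] + rho * u[2]
  inside <- xs >= 0 & xs <= field$roi[1] & ys >= 0 & ys <= field$roi[2]
  truncated <- !all(inside)
  rho <- rho[inside]; xs <- xs[inside]; ys <- ys[inside]
  if (length(rho) < 2) stop("energy_landscape: ray immediately exits domain")
  ov <- 0L
  e <- vapply(seq_along(rho), function(i) {
    ei <- energy_at(c(xs[i], ys[i]), field, p)
    ov <<- ov + attr(ei, "core_overlaps")
    as.numeric(ei)
  }, numeric(1))
  h <- rho[2] - rho[1]
  f_e <- c((e[2] - e[1]) / h,
           (e[-(1:2)] - e[-((length(e) - 1):length(e))]) / (2 * h),
           (e[length(e)] - e[length(e) - 1]) / h)
  ib <- which.min(abs(rho - border_radius))
  structure(list(rho = rho, e = e, f_e = f_e,
                 delta_e = e[ib] - e[1], border_radius = rho[ib],
                 truncated = truncated, core_overlaps = ov),
            class = "energy_landscape")
}

#' Cluster-size stability scan
#'
#' For each cluster size `n`, builds seeded configurations at fixed global
#' density, probes the energy landscape of the most central cluster along
#' four axis-aligned rays, and reports the mean barrier
#' \eqn{\Delta e} (border at twice the cluster scatter) and the mean
#' maximal escape force inside the border.  `n_star` is the smallest
#' scanned n whose mean barrier falls below `tol * epsilon` (the
#' "flat landscape" threshold beyond which binding further cells is
#' unstable).
#'
#' @param n_values cluster sizes to scan (>= 3 values).
#' @param density global density (cells/mm^2).
#' @param p a [potential_params()].
#' @param seeds integer vector of seeds averaged per n.
#' @param domain `c(width, height)` um.
#' @param cluster_sigma per-cell scatter scale (um), as in
#'   [build_cluster_configuration()].
#' @param tol flatness tolerance in units of `epsilon`.
#' @return data.frame of class `stability_scan` with columns `n`,
#'   `delta_e`, `max_f_e`; attributes `n_star`, `tol`.
#' @export
stability_scan <- function(n_values, density = 2000,
                           p = potential_params(), seeds = 1:5,
                           domain = c(3000, 3000), cluster_sigma = 1.8,
                           sigma_exponent = 0.75, tol = 0.1) {
  stopifnot(length(n_values) >= 3)
  n_values <- sort(n_values)
  dirs <- lapply(seq(0, 2 * pi, length.out = 9)[-9],
                 function(a) c(cos(a), sin(a)))
  rows <- lapply(n_values, function(n) {
    de <- fe <- numeric(0)
    for (s in seeds) {
      field <- build_cluster_configuration(n, density, domain,
                                           cluster_sigma, sigma_exponent,
                                           seed = s)
      parents <- attr(field, "parents")
      sigma_n <- attr(field, "sigma_n")
      ctr_i <- which.min((parents[, 1] - domain[1] / 2)^2 +
                         (parents[, 2] - domain[2] / 2)^2)
      ctr <- parents[ctr_i, ]
      border <- 2 * sigma_n
      n_steps <- max(21, min(81, ceiling(border)))
      # azimuthally aggregate the landscape pointwise (median over rays:
      # robust against hard-core spikes on single rays), then measure
      prof <- vapply(dirs, function(dir) {
        energy_landscape(field, ctr, dir, r_max = border,
                         n_steps = n_steps, p = p,
                         border_radius = border)$e
      }, numeric(n_steps))
      e_med <- apply(prof, 1, median)
      h <- border / (n_steps - 1)
      g <- diff(e_med) / h
      de <- c(de, e_med[n_steps] - e_med[1])
      fe <- c(fe, max(g))
    }
    c(n = n, delta_e = median(de), max_f_e = median(fe))
  })
  out <- as.data.frame(do.call(rbind, rows))
  flat <- which(out$delta_e < tol * p$epsilon)
  attr(out, "n_star") <- if (length(flat)) out$n[min(flat)] else NA_real_
  attr(out, "tol") <- tol
  class(out) <- c("stability_scan", "data.frame")
  out
}

#' Maximum stable cluster size under a migration force
#'
#' A migrating cell exerting force `f_m` escapes wherever `f_m` exceeds
#' the peak escape force; the maximum cluster size is the largest scanned
#' n whose mean peak escape force still reaches `f_m`.  The inverse query
#' (`invert = TRUE`) returns the escape force at a given cluster size,
#' i.e. the migration force implied by an observed maximum cluster size.
#'
#' @param scan a `stability_scan` table.
#' @param f_m migration force (aJ/um = pN) or, when `invert = TRUE`, the
#'   observed maximum cluster size.
#' @param invert return the implied migration force instead.
#' @return n_max (or implied f_m) with attribute `boundary` when the query
#'   saturates the scanned range.
#' @export
migration_force_balance <- function(scan, f_m, invert = FALSE) {
  stopifnot(inherits(scan, "stability_scan"))
  if (invert) {
    i <- which(scan$n == f_m)
    if (length(i) != 1)
      stop("migration_force_balance: cluster size not in scan (extrapolation refused)")
    return(scan$max_f_e[i])
  }
  if (f_m < 0) stop("migration_force_balance: negative force")
  ok <- which(scan$max_f_e >= f_m)
  if (length(ok) == 0) {
    res <- min(scan$n)
    attr(res, "boundary") <- TRUE
    return(res)
  }
  res <- max(scan$n[ok])
  attr(res, "boundary") <- (res == max(scan$n) && f_m <= min(scan$max_f_e))
  res
}
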