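as_metric_graph <- function(g) {
  if (inherits(g, "spatial_graph")) as_igraph(g)
  else if (igraph::is_igraph(g)) g
  else stop("expected a spatial_graph or igraph object")
}

#' Mean local clustering coefficient
#'
#' Watts-Strogatz clustering: per node, the fraction of realized links
#' among its neighbours, averaged over all nodes; nodes of degree < 2
#' contribute 0.
#'
#' @param g a `spatial_graph` or igraph object with >= 3 nodes.
#' @return cc in \[0, 1\].
#' @export
clustering_coefficient <- function(g) {
  ig <- as_metric_graph(g)
  stopifnot(igraph::vcount(ig) >= 3)
  cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  mean(cc)
}

#' Characteristic path length
#'
#' Mean unweighted shortest-path hop count over all connected pairs within
#' the largest connected component.  The fraction of nodes covered by that
#' component is attached as attribute `coverage` so the restriction is
#' auditable.
#'
#' @param g a `spatial_graph` or igraph object with >= 2 nodes.
#' @return cpl (hops) with attribute `coverage`.
#' @export
characteristic_path_length <- function(g) {
  ig <- as_metric_graph(g)
  n <- igraph::vcount(ig)
  stopifnot(n >= 2)
  if (igraph::ecount(ig) == 0)
    stop("characteristic_path_length: graph has no edges")
  comp <- igraph::components(ig)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(ig, which(comp$membership == big))
  D <- igraph::distances(sub, weights = NA)
  cpl <- mean(D[upper.tri(D)])
  attr(cpl, "coverage") <- comp$csize[big] / n
  cpl
}

#' Small-world-ness coefficient
#'
#' Humphries-Gurney small-world-ness
#' \eqn{S_w = (cc/cc_{rand}) / (cpl/cpl_{rand})}, where the baselines are
#' averaged over `n_random` Erdos-Renyi G(n, m) graphs matched in node and
#' edge count (path lengths on their largest components).  Values above 1
#' indicate a small-world architecture.
#'
#' @param g a `spatial_graph` or igraph object whose largest component has
#'   >= 10 nodes.
#' @param n_random number of random baseline graphs (>= 10).
#' @param seed integer RNG seed for the baselines.
#' @return Sw with attributes `cc`, `cpl`, `cc_rand`, `cpl_rand`,
#'   `smoothed` (TRUE if the zero-clustering guard was applied).
#' @export
small_world_ness <- function(g, n_random = 50, seed = 1) {
  ig <- as_metric_graph(g)
  stopifnot(n_random >= 10)
  comp <- igraph::components(ig)
  if (max(comp$csize) < 10)
    stop("small_world_ness: largest component has fewer than 10 nodes")
  n <- igraph::vcount(ig); m <- igraph::ecount(ig)
  cc <- clustering_coefficient(ig)
  cpl <- as.numeric(characteristic_path_length(ig))
  sims <- with_seed(seed, {
    vapply(seq_len(n_random), function(k) {
      r <- igraph::sample_gnm(n, m)
      c(clustering_coefficient(r),
        as.numeric(characteristic_path_length(r)))
    }, numeric(2))
  })
  cc_rand <- mean(sims[1, ])
  cpl_rand <- mean(sims[2, ])
  smoothed <- FALSE
  if (cc_rand == 0) {
    # add-one smoothing on triangle counts: one triangle among all triples
    cc_rand <- 1 / choose(n, 3)
    smoothed <- TRUE
  }
  sw <- (cc / cc_rand) / (cpl / cpl_rand)
  attr(sw, "cc") <- cc; attr(sw, "cpl") <- cpl
  attr(sw, "cc_rand") <- cc_rand; attr(sw, "cpl_rand") <- cpl_rand
  attr(sw, "smoothed") <- smoothed
  sw
}

## Hurwitz zeta via direct summation plus Euler-Maclaurin tail
hurwitz_zeta <- function(a, xmin, n_direct = 2000) {
  N <- xmin + n_direct
  s <- sum((xmin:(N - 1))^(-a))
  s + N^(1 - a) / (a - 1) + N^(-a) / 2 + a * N^(-a - 1) / 12
}

#' Exponential-vs-power-law degree-tail test
#'
#' Fits a discrete power law (zeta distribution) and a geometric
#' (exponential-tail) model to degrees at or above `kappa_min` by maximum
#' likelihood, then applies a Vuong-style normalized log-likelihood-ratio
#' test.  The sign of the ratio decides the verdict; `inconclusive` when
#' the two-sided p-value exceeds 0.1 or the data are degenerate.
#'
#' @param degrees integer vector of node degrees.
#' @param kappa_min lower cutoff; default: mode of the degree histogram.
#' @return list of class `tail_test` with `verdict` (one of
#'   `"exponential"`, `"power_law"`, `"inconclusive"`), `llr`, `p_value`,
#'   `kappa_min`, `n_tail` and the two fitted parameters.
#' @export
degree_tail_test <- function(degrees, kappa_min = NULL) {
  degrees <- as.integer(degrees)
  if (is.null(kappa_min)) {
    tb <- table(degrees[degrees > 0])
    kappa_min <- if (length(tb)) as.integer(names(tb)[which.max(tb)]) else 1L
    kappa_min <- max(kappa_min, 1L)
  }
  x <- degrees[degrees >= kappa_min]
  out <- function(verdict, llr = NA, p = NA, par_pl = NA, par_geom = NA)
    structure(list(verdict = verdict, llr = llr, p_value = p,
                   kappa_min = kappa_min, n_tail = length(x),
                   alpha_power_law = par_pl, p_geometric = par_geom),
              class = "tail_test")
  if (length(x) < 20) return(out("inconclusive"))
  if (length(unique(x)) == 1) return(out("inconclusive"))
  # geometric on x - kappa_min: MLE p = 1 / (mean excess + 1)
  p_hat <- 1 / (mean(x - kappa_min) + 1)
  ll_geom <- (x - kappa_min) * log(1 - p_hat) + log(p_hat)
  # discrete power law with cutoff: ML over the zeta exponent
  nll_pl <- function(a) sum(a * log(x)) + length(x) * log(hurwitz_zeta(a, kappa_min))
  a_hat <- optimize(nll_pl, c(1.05, 8))$minimum
  ll_pl <- -a_hat * log(x) - log(hurwitz_zeta(a_hat, kappa_min))
  d <- ll_geom - ll_pl
  llr <- sum(d)
  sdd <- sd(d)
  if (sdd == 0) return(out("inconclusive", llr, NA, a_hat, p_hat))
  z <- llr / (sqrt(length(d)) * sdd)
  p_val <- 2 * pnorm(-abs(z))
  verdict <- if (p_val > 0.1) "inconclusive"
             else if (llr > 0) "exponential" else "power_law"
  out(verdict, llr, p_val, a_hat, p_hat)
}

#' Full topological metrics report
#'
#' @param g a `spatial_graph`.
#' @param n_random random baselines for [small_world_ness()].
#' @param seed RNG seed for the baselines.
#' @return list of class `metrics_report` with `cc`, `cpl`, `sw`,
#'   `kappa_mean`, `n_nodes`, `n_edges`, `n_random`, `coverage`,
#'   `tail_verdict`.
#' @export
network_metrics <- function(g, n_random = 50, seed = 1) {
  stopifnot(inherits(g, "spatial_graph"))
  deg <- degree_distribution(g)
  cpl <- characteristic_path_length(g)
  sw <- small_world_ness(g, n_random = n_random, seed = seed)
  structure(list(cc = attr(sw, "cc"), cpl = as.numeric(cpl),
                 sw = as.numeric(sw), kappa_mean = deg$kappa_mean,
                 n_nodes = n_points(g$field), n_edges = nrow(g$edges),
                 n_random = n_random, coverage = attr(cpl, "coverage"),
                 tail_verdict = degree_tail_test(deg$degrees)$verdict),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> N=%d E=%d cc=%.3f cpl=%.3f Sw=%.3f kappa=%.2f tail=%s\n",
              x$n_nodes, x$n_edges, x$cc, x$cpl, x$sw, x$kappa_mean,
              x$tail_verdict))
  invisible(x)
}
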