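test_that("decision graph: two-point and hand-computed configurations", {
  two <- point_field(rbind(c(0, 0), c(60, 0)), c(100, 100))
  dg <- density_peak_decision(two, d_c = 10)
  expect_equal(dg$rho, c(0, 0))
  expect_equal(dg$delta, c(60, 60))

  # 5 points on a line; d_c = 3 -> rho = (1,2,1,0,0) by hand
  pts <- cbind(c(0, 2, 4, 20, 30), rep(1, 5))
  fld <- point_field(pts, c(40, 10))
  dg5 <- density_peak_decision(fld, d_c = 3)
  expect_equal(dg5$rho, c(1, 2, 1, 0, 0))
  # densest is point 2: delta = max pairwise distance (point1 -> point5)
  expect_equal(dg5$delta[2], 30)
  expect_equal(dg5$delta[1], 2)   # to point 2
  expect_equal(dg5$delta[3], 2)   # to point 2
  expect_equal(dg5$delta[4], 16)  # nearest higher-density: point 3
  # equal densities are ordered by index, so point 5 looks to point 4
  expect_equal(dg5$delta[5], 10)
  expect_warning(density_peak_decision(two, d_c = 1000), "diagonal")
})

test_that("rho/delta equal brute-force enumeration on random fields (N <= 500)", {
  for (s in 1:5) {
    fld <- gen_cell_field(c(300, 300), 2000, ifelse(s %% 2, 1, 60),
                          cluster_sigma = 20, seed = s)
    stopifnot(nrow(fld$points) <= 500)
    d_c <- dc_heuristic(fld)
    dg <- density_peak_decision(fld, d_c)
    or <- oracle_rho_delta(fld$points, d_c)
    expect_equal(dg$rho, or$rho, ignore_attr = TRUE)
    expect_equal(dg$delta, or$delta, tolerance = 1e-12)
  }
})

test_that("a single tight blob yields exactly one outlier-gamma centre", {
  set.seed(8)
  pts <- cbind(rnorm(50, 100, 5), rnorm(50, 100, 5))
  fld <- point_field(pts, c(200, 200))
  dg <- density_peak_decision(fld, d_c = 15)  # 3 sigma
  ctr <- select_centers(dg)
  expect_length(ctr, 1)
  lab <- assign_clusters(fld, dg, ctr)
  expect_true(all(lab$labels == 1))
})

test_that("two well-separated blobs: 2 centres, assignment matches planting", {
  set.seed(3)
  a <- cbind(rnorm(100, 60, 8), rnorm(100, 60, 8))
  b <- cbind(rnorm(100, 240, 8), rnorm(100, 240, 8))
  fld <- point_field(rbind(a, b), c(300, 300))
  lab <- find_superclusters(fld)
  expect_equal(lab$n_clusters, 2)
  truth <- rep(1:2, each = 100)
  # agreement up to label permutation
  agree <- max(mean(lab$labels == truth), mean(lab$labels == 3 - truth))
  expect_gte(agree, 0.98)
  expect_equal(cells_per_cluster(lab), 100)
})

test_that("uniform fields return one low-confidence centre", {
  flags <- vapply(1:20, function(s) {
    fld <- gen_cell_field(c(1000, 1000), 2000, 1, seed = s)
    lab <- find_superclusters(fld)
    lab$n_clusters == 1 && isTRUE(attr(lab, "low_confidence"))
  }, logical(1))
  expect_true(all(flags))
})

test_that("10 planted well-separated blobs are recovered in >= 90% of seeds", {
  hits <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    centers <- as.matrix(expand.grid(x = seq(100, 900, length.out = 5)[c(1, 3, 5)],
                                     y = seq(150, 850, length.out = 4)))[1:10, ]
    centers <- centers + matrix(runif(20, -30, 30), 10, 2)
    pts <- do.call(rbind, lapply(seq_len(10), function(k) {
      p <- cbind(rnorm(200, centers[k, 1], 35), rnorm(200, centers[k, 2], 35))
      p[pmin(p[, 1], p[, 2]) > 0 & pmax(p[, 1], p[, 2]) < 1000, , drop = FALSE]
    }))
    fld <- point_field(pts, c(1000, 1000))
    find_superclusters(fld)$n_clusters == 10
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("monotone-density chain inherits the densest point's label", {
  # crowding increases toward x = 0, so rho decreases along the chain
  x <- c(0, 1.2, 2.6, 4.4, 6.8, 10, 14.5, 20)
  fld <- point_field(cbind(x, rep(1, 8)), c(25, 5))
  dg <- density_peak_decision(fld, d_c = 3)
  expect_true(which.max(dg$rho) %in% 1:3)  # crowded end of the chain
  lab <- assign_clusters(fld, dg, select_centers(dg))
  expect_equal(length(unique(lab$labels)), 1)
})

test_that("labels are invariant under point reordering", {
  set.seed(14)
  a <- cbind(rnorm(80, 60, 8), rnorm(80, 60, 8))
  b <- cbind(rnorm(80, 240, 8), rnorm(80, 240, 8))
  pts <- rbind(a, b)
  perm <- sample(nrow(pts))
  l1 <- find_superclusters(point_field(pts, c(300, 300)))
  l2 <- find_superclusters(point_field(pts[perm, ], c(300, 300)))
  # compare partitions via pairwise co-membership, undoing the permutation
  inv <- match(seq_along(perm), perm)
  co <- function(l) outer(l, l, "==")
  expect_identical(co(l1$labels), co(l2$labels[inv]))
})

test_that("cells_per_cluster arithmetic and error case", {
  lab <- structure(list(labels = rep(1:10, each = 200), centers = 1:10,
                        n_clusters = 10, cells_per_cluster = 200),
                   class = "cluster_labeling")
  expect_equal(cells_per_cluster(lab, 2000), 200)
  lab1 <- structure(list(labels = rep(1, 100), centers = 1L,
                         n_clusters = 1, cells_per_cluster = 100),
                    class = "cluster_labeling")
  expect_equal(cells_per_cluster(lab1), 100)
  lab0 <- structure(list(labels = integer(0), centers = integer(0),
                         n_clusters = 0), class = "cluster_labeling")
  expect_error(cells_per_cluster(lab0, 10))
})

test_that("end-to-end size recovery for planted n in {100, 200, 400}", {
  rho_g <- 0.002  # cells per um^2
  for (n in c(100, 200, 400)) {
    sig <- sqrt(n / rho_g) / 10  # clusters separated ~10 sigma: resolvable
    est <- vapply(1:20, function(s) {
      fld <- gen_cell_field(c(1000, 1000), 2000, n, sig, seed = s)
      cells_per_cluster(find_superclusters(fld))
    }, numeric(1))
    expect_lt(abs(median(est) - n) / n, 0.2)
  }
})

test_that("bounded-exponential fit: exact curve recovery and identifiable parameters", {
  x <- 2:6
  y <- 50 + 180 * (1 - 2 * exp(-(x - 1.4)))
  fit <- fit_cluster_size_trend(x, y)
  expect_lt(abs(fit$r2 - 1), 1e-9)
  expect_lt(max(abs(fit$fitted - y)), 1e-6 * max(abs(y)))
  expect_lt(abs(fit$theta1 - 230), 1e-6)
  expect_lt(abs(fit$theta2 - 360 * exp(1.4)), 1e-3)
  # fixing the degenerate directions identifies C and A exactly
  fit2 <- fit_cluster_size_trend(x, y, B = 2, o = 1.4)
  expect_lt(abs(fit2$C - 50), 1e-5)
  expect_lt(abs(fit2$A - 180), 1e-5)

  flat <- fit_cluster_size_trend(1:5, rep(100, 5))
  expect_true(flat$degenerate_flag)
})

test_that("trend fit is robust to 5% noise (identifiable parameters)", {
  x <- 2:6
  y0 <- 50 + 180 * (1 - 2 * exp(-(x - 1.4)))
  set.seed(21)
  th1 <- th2 <- numeric(100)
  for (r in 1:100) {
    y <- y0 * (1 + rnorm(5, 0, 0.05))
    f <- fit_cluster_size_trend(x, y, starts = 0)
    th1[r] <- f$theta1; th2[r] <- f$theta2
  }
  expect_lt(abs(median(th1) - 230) / 230, 0.1)
  expect_lt(abs(median(th2) - 360 * exp(1.4)) / (360 * exp(1.4)), 0.1)
})
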