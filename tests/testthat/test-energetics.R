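test_that("cluster configurations keep global density and cluster counts", {
  f1 <- build_cluster_configuration(1, 2000, c(1000, 1000), seed = 1)
  expect_equal(nrow(f1$points), 2000)
  f18 <- build_cluster_configuration(1000, 2000, c(3000, 3000), seed = 1)
  expect_equal(nrow(attr(f18, "parents")), 18)  # area * density / n
  for (n in c(10, 100, 1000)) {
    f <- build_cluster_configuration(n, 2000, c(3000, 3000), seed = 2)
    realized <- nrow(f$points) / 9  # cells per mm^2
    expect_lt(abs(realized - 2000) / 2000, 0.05)
  }
  expect_error(build_cluster_configuration(1000, 2000, c(100, 100), seed = 1))
})

test_that("ghost-cell energy matches closed forms and hand summation", {
  p <- potential_params(epsilon = 2, lambda_a = 30, r_core = 1, w_sub = 5)
  empty <- point_field(matrix(numeric(0), 0, 2), c(100, 100))
  expect_equal(as.numeric(energy_at(c(50, 50), empty, p)), 5)

  one <- point_field(matrix(c(50 + 30, 50), 1, 2), c(100, 100))
  e1 <- energy_at(c(50, 50), one, p)
  expect_equal(as.numeric(e1), 5 - 2 / exp(1), tolerance = 1e-12)

  tri <- point_field(rbind(c(10, 0) + 50, c(-10, 0) + 50, c(0, 15) + 50),
                     c(100, 100))
  et <- energy_at(c(50, 50), tri, p)
  hand <- 5 - 2 * (exp(-10 / 30) + exp(-10 / 30) + exp(-15 / 30))
  expect_equal(as.numeric(et), hand, tolerance = 1e-12)
  expect_equal(attr(et, "core_overlaps"), 0L)

  ov <- energy_at(c(80.5, 50), one, p)  # 0.5 um from the cell
  expect_equal(attr(ov, "core_overlaps"), 1L)
  expect_gt(as.numeric(ov), 100)
  expect_error(energy_at(c(-1, 50), one, p))
})

test_that("energy is extensive under symmetric duplication", {
  p <- potential_params(epsilon = 1, lambda_a = 20, r_core = 0.1, w_sub = 0)
  single <- point_field(matrix(c(70, 50), 1, 2), c(100, 100))
  mirrored <- point_field(rbind(c(70, 50), c(30, 50)), c(100, 100))
  e1 <- as.numeric(energy_at(c(50, 50), single, p))
  e2 <- as.numeric(energy_at(c(50, 50), mirrored, p))
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
})

test_that("energy landscapes: monotone single well, symmetry, force oracle", {
  p <- potential_params(epsilon = 1, lambda_a = 20, r_core = 0.5, w_sub = 0)
  one <- point_field(matrix(c(100, 100), 1, 2), c(400, 400))
  ls <- energy_landscape(one, c(100, 100), c(1, 0), r_max = 100,
                         n_steps = 51, p = p, border_radius = 80)
  expect_true(all(diff(ls$e[-1]) > 0))  # beyond the core: monotone rise
  expect_false(ls$truncated)

  # mirror-symmetric pair: opposite rays along the symmetry axis agree
  sym <- point_field(rbind(c(130, 100), c(70, 100),
                           c(100, 130), c(100, 70)), c(200, 200))
  la <- energy_landscape(sym, c(100, 100), c(1, 0), 40, 41, p, 30)
  lb <- energy_landscape(sym, c(100, 100), c(-1, 0), 40, 41, p, 30)
  expect_equal(la$e, lb$e, tolerance = 1e-9)

  # f_e equals the analytic radial derivative on a 3-cell configuration
  tri <- point_field(rbind(c(300, 100), c(300, 140), c(340, 120)),
                     c(600, 300))
  n_steps <- 2001  # h = 0.01 um: centred differences at O(h^2) accuracy
  lt <- energy_landscape(tri, c(200, 120), c(1, 0), 20, n_steps, p, 10)
  analytic <- vapply(seq_along(lt$rho), function(i) {
    x <- 200 + lt$rho[i]
    sum(vapply(seq_len(3), function(j) {
      dx <- x - tri$points[j, 1]; dy <- 120 - tri$points[j, 2]
      r <- sqrt(dx^2 + dy^2)
      (p$epsilon / p$lambda_a) * exp(-r / p$lambda_a) * dx / r
    }, numeric(1)))
  }, numeric(1))
  interior <- 2:(n_steps - 1)
  expect_lt(max(abs(lt$f_e[interior] - analytic[interior])),
            1e-6 * p$epsilon)

  trunc <- energy_landscape(one, c(390, 100), c(1, 0), 50, 21, p, 20)
  expect_true(trunc$truncated)
})

test_that("stability scan: barrier decreases with cluster size and flattens", {
  sc <- stability_scan(c(10, 50, 200), seeds = 1:10)
  expect_true(all(diff(sc$delta_e) < 0))       # strictly decreasing
  expect_true(all(diff(sc$max_f_e) < 0))
  # tol -> large: n* is the smallest n scanned
  sc2 <- sc
  attr(sc2, "n_star") <- NULL
  flat <- which(sc$delta_e < 1e9 * potential_params()$epsilon)
  expect_equal(sc$n[min(flat)], 10)
})

test_that("without the fixed-density tiling the barrier saturates instead of vanishing", {
  p <- potential_params()
  # isolated single cluster with the same sigma(n) scaling, no neighbours
  iso_barrier <- function(n, seeds = 1:5) {
    sigma_n <- 1.8 * n^0.75
    border <- 2 * sigma_n
    ctr <- c(4000, 4000)
    median(vapply(seeds, function(s) {
      set.seed(s)
      pts <- cbind(rnorm(n, ctr[1], sigma_n), rnorm(n, ctr[2], sigma_n))
      fld <- point_field(pts, c(8000, 8000))
      prof <- vapply(list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                          c(1, 1) / sqrt(2), c(-1, -1) / sqrt(2)),
                     function(d) energy_landscape(fld, ctr, d, border, 41,
                                                  p, border)$e,
                     numeric(41))
      e_med <- apply(prof, 1, median)
      e_med[41] - e_med[1]
    }, numeric(1)))
  }
  tiled <- stability_scan(c(10, 50, 600), seeds = 1:5)
  de_t <- tiled$delta_e[tiled$n %in% c(50, 600)]
  de_i <- c(iso_barrier(50), iso_barrier(600))
  # the tiled barrier collapses by n = 600 (background fills in); the
  # isolated cluster's barrier only decays slowly with the diluting
  # intra-cluster density (~ n^-1/2), staying an order of magnitude up
  expect_lt(de_t[2] / de_t[1], 0.1)
  expect_gt(de_i[2] / de_i[1], 5 * de_t[2] / de_t[1])
  expect_gt(de_i[2], 5 * de_t[2])
})

test_that("migration force balance: crossings, boundaries and inverse query", {
  scan <- structure(data.frame(n = c(10, 50, 200, 600),
                               delta_e = c(8, 5, 2, 0.3),
                               max_f_e = c(4000, 3000, 2100, 900)),
                    class = c("stability_scan", "data.frame"))
  expect_equal(as.numeric(migration_force_balance(scan, 2000)), 200)
  expect_equal(as.numeric(migration_force_balance(scan, 0)), 600)
  hi <- migration_force_balance(scan, 1e6)
  expect_equal(as.numeric(hi), 10)
  expect_true(attr(hi, "boundary"))
  expect_equal(migration_force_balance(scan, 200, invert = TRUE), 2100)
  expect_error(migration_force_balance(scan, 123, invert = TRUE))
})
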