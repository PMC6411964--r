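isolated_pair <- function(d = 900) {
  fld <- point_field(rbind(c(0, 0), c(d, d)), c(1000, 1000))
  waxman_graph(fld, beta = 0, seed = 1)  # no edges
}

relay_pair <- function(d, roi = c(1000, 1000)) {
  pts <- rbind(c(0, 0), c(d, 0))
  graph_from_edges(pts, rbind(c(1, 2)), roi = roi)
}

test_that("no stimulus produces an empty raster", {
  r <- simulate_lif(isolated_pair(), 1, numeric(0))
  expect_equal(sum(lengths(r$spike_times)), 0)
})

test_that("constant-current firing matches the closed-form LIF period", {
  p <- lif_params(dt = 0.25, T = 4000)
  r <- simulate_lif(isolated_pair(), 1, numeric(0), p, i_const = 30)
  isi_sim <- mean(diff(r$spike_times[[1]]))
  isi_theory <- p$t_ref + p$tau_m *
    log((30 - (p$v_reset - p$v_rest)) / (30 - (p$v_th - p$v_rest)))
  expect_lt(abs(isi_sim - isi_theory) / isi_theory, 0.03)

  # halving dt changes the spike count by < 2%
  n1 <- length(simulate_lif(isolated_pair(), 1, numeric(0),
                            lif_params(dt = 0.5, T = 2000),
                            i_const = 30)$spike_times[[1]])
  n2 <- length(simulate_lif(isolated_pair(), 1, numeric(0),
                            lif_params(dt = 0.25, T = 2000),
                            i_const = 30)$spike_times[[1]])
  expect_lt(abs(n1 - n2) / n2, 0.02)
})

test_that("sub- and suprathreshold kicks gate 1:1 relay", {
  p <- lif_params(J = 25, lambda_s = 80)
  # zeta(d) J > 15 mV iff d < 80 * ln(25/15) ~ 40.9 um
  sub <- simulate_lif(relay_pair(60), 1, c(10, 50, 100), p)
  expect_equal(length(sub$spike_times[[1]]), 3)
  expect_equal(length(sub$spike_times[[2]]), 0)
  supra <- simulate_lif(relay_pair(30), 1, c(10, 50, 100), p)
  expect_equal(length(supra$spike_times[[2]]), 3)
  # relayed spikes arrive one integration step later
  expect_equal(supra$spike_times[[2]], supra$spike_times[[1]] + p$dt)
})

test_that("fixed seed gives identical rasters; noise breaks determinism", {
  p <- lif_params(noise_sd = 1)
  g <- relay_pair(30)
  r1 <- simulate_lif(g, 1, c(10, 60), p, seed = 3)
  r2 <- simulate_lif(g, 1, c(10, 60), p, seed = 3)
  expect_identical(r1$spike_times, r2$spike_times)
  r3 <- simulate_lif(g, 1, c(10, 60), p, seed = 4)
  expect_false(identical(r1$spike_times, r3$spike_times))
})

test_that("word distributions match hand counts", {
  # T = 24 ms, bin 3, word_len 8 -> one 8-bit word per response
  mk <- function(times) spike_raster(list(times), t_max = 24)
  rs <- list(mk(numeric(0)), mk(numeric(0)), mk(c(1)), mk(c(1, 4)))
  P <- word_distribution(rs, 1, bin = 3, word_len = 8)
  # words: 0, 0, 10000000b = 128, 11000000b = 192
  expect_equal(sort(names(P)), sort(c("0", "128", "192")))
  expect_equal(unname(P[c("0", "128", "192")]), c(0.5, 0.25, 0.25))

  silent <- word_distribution(list(mk(numeric(0))), 1, 3, 8)
  expect_equal(shannon_entropy(silent), 0)

  eight <- lapply(0:7, function(k) mk(3 * k + 1.5))
  P8 <- word_distribution(eight, 1, 3, 8)
  expect_equal(shannon_entropy(P8), 3)  # uniform over 8 distinct words
})

test_that("shannon entropy closed forms and input validation", {
  expect_equal(shannon_entropy(c(1)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannon_entropy(c(0.5, 0.2)))
})

test_that("noise-free relay: N = 0 and I equals the response entropy", {
  g <- relay_pair(30)
  ens <- make_stimulus_ensemble(12, T = 192, bin = 3, seed = 5)
  p <- lif_params(noise_sd = 0)
  I2 <- node_information(g, 2, 1, ens, n_repeats = 10, p = p, seed = 1)
  expect_equal(attr(I2, "N"), 0)
  expect_equal(as.numeric(I2), attr(I2, "H"))
  expect_gt(as.numeric(I2), 1)  # relayed stimulus words carry entropy

  # a node disconnected from the stimulus carries no information
  pts <- rbind(c(0, 0), c(30, 0), c(500, 500))
  g3 <- graph_from_edges(pts, rbind(c(1, 2)), roi = c(1000, 1000))
  I3 <- node_information(g3, 3, 1, ens, n_repeats = 10, p = p, seed = 1)
  expect_equal(as.numeric(I3), 0)
})

test_that("a faithful relay chain delivers the stimulus word entropy", {
  # 10-node chain, 30 um spacing: every link is suprathreshold
  pts <- cbind(seq(0, 270, by = 30), rep(0, 10))
  g <- graph_from_edges(pts, cbind(1:9, 2:10), roi = c(1000, 1000))
  ens <- make_stimulus_ensemble(16, T = 192, bin = 3, seed = 9)
  p <- lif_params(noise_sd = 0)
  I_end <- node_information(g, 10, 1, ens, n_repeats = 10, p = p, seed = 2)
  # stimulus word entropy, computed directly from the stimulus trains
  stim_words <- unlist(lapply(ens, function(tt)
    neurowire:::response_words(tt, 192, 3, 8)))
  tb <- table(stim_words)
  H_stim <- shannon_entropy(as.numeric(tb) / sum(tb))
  expect_lt(abs(as.numeric(I_end) - H_stim) / H_stim, 0.15)
})

test_that("grid information: silence, additivity over disconnected copies", {
  g <- relay_pair(30)
  p0 <- lif_params(noise_sd = 0)
  # all-silent stimulation: every node stays at the zero word
  ens0 <- lapply(1:10, function(i) numeric(0))
  im0 <- neurowire:::information_map(g, 1, ens0, 10, p0, seed = 1)
  expect_equal(sum(im0$I), 0)

  # two disconnected copies, stimulated one at a time, sum to twice one copy
  ptsA <- cbind(c(0, 30), c(0, 0))
  single <- graph_from_edges(ptsA, rbind(c(1, 2)), roi = c(1000, 1000))
  double <- graph_from_edges(rbind(ptsA, ptsA + 500),
                             rbind(c(1, 2), c(3, 4)), roi = c(1000, 1000))
  I1 <- grid_information(single, 1, n_stimuli = 10, n_repeats = 10,
                         p = p0, seed = 3)
  IA <- grid_information(double, 1, n_stimuli = 10, n_repeats = 10,
                         p = p0, seed = 3)
  IB <- grid_information(double, 3, n_stimuli = 10, n_repeats = 10,
                         p = p0, seed = 3)
  expect_equal(as.numeric(IA) + as.numeric(IB), 2 * as.numeric(I1),
               tolerance = 1e-9)
})

test_that("enhancement factor arithmetic", {
  expect_equal(enhancement_factor(5, 5), 1)
  expect_equal(enhancement_factor(9.1, 1.8), 9.1 / 1.8)
  expect_lt(abs(enhancement_factor(9.1, 1.8) - 5.06), 0.01)
  expect_lt(enhancement_factor(3, 1e6), 1e-5)
  expect_error(enhancement_factor(1, 0))
})

test_that("saturation flag trips under runaway drive", {
  p <- lif_params(t_ref = 2, T = 500)
  r <- simulate_lif(isolated_pair(), 1, numeric(0), p, i_const = 1000)
  expect_true(isTRUE(attr(r, "saturated")))
})
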