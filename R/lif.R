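#' Parameters of the leaky integrate-and-fire network model
#'
#' Membrane potential follows
#' \eqn{dV/dt = (-(V - v_{rest}) + RI_0)/\tau_m}; every presynaptic spike
#' of a neighbour at distance d delivers an instantaneous voltage kick
#' \eqn{\zeta(d) J} with the damping \eqn{\zeta(d) = e^{-d/\lambda_s}}
#' (signals degrade over long distances); crossing `v_th` emits a spike,
#' resets to `v_reset` and enforces the refractory period.  Synaptic
#' weights are otherwise unitary: propagation quality depends on network
#' architecture, not on per-edge strengths, and there is no plasticity.
#'
#' @param tau_m membrane time constant (ms).
#' @param v_rest,v_reset,v_th resting, reset and threshold potentials
#'   (mV); `v_reset < v_th`.
#' @param t_ref absolute refractory period (ms).
#' @param J characteristic synaptic kick amplitude (mV per spike).
#' @param lambda_s damping length of the distance term zeta (um).
#' @param dt Euler step (ms); must satisfy `dt < tau_m / 5`.
#' @param T simulation window (ms).
#' @param noise_sd membrane noise standard deviation (mV / sqrt(ms)).
#' @return list of class `lif_params`.
#' @export
lif_params <- function(tau_m = 20, v_rest = -65, v_reset = -65,
                       v_th = -50, t_ref = 2, J = 25, lambda_s = 80,
                       dt = 0.5, T = 192, noise_sd = 0) {
  stopifnot(v_reset < v_th, dt < tau_m / 5, tau_m > 0, t_ref >= 0,
            dt > 0, T > 0, lambda_s > 0)
  structure(list(tau_m = tau_m, v_rest = v_rest, v_reset = v_reset,
                 v_th = v_th, t_ref = t_ref, J = J, lambda_s = lambda_s,
                 dt = dt, T = T, noise_sd = noise_sd),
            class = "lif_params")
}

#' Simulate spike propagation on a spatial graph
#'
#' Drives `stim_node` with the spike train `stim_train` (the stimulated
#' node is a spike generator, subject to its own refractoriness) and
#' integrates the LIF dynamics of every neuron.  Deterministic for a
#' fixed seed; membrane noise (if `p$noise_sd > 0`) is seeded.
#'
#' @param g a `spatial_graph`.
#' @param stim_node index of the stimulated neuron (1-based).
#' @param stim_train numeric vector of stimulus spike times (ms) in
#'   `[0, T]`.
#' @param p a [lif_params()].
#' @param seed integer RNG seed.
#' @param i_const constant suprathreshold drive R*I0 (mV) applied to all
#'   neurons (0 in network use; handy for single-neuron calibration).
#' @return a [spike_raster()] (times in ms) with attribute `saturated` if
#'   any neuron approaches its refractory-limited maximal rate.
#' @export
simulate_lif <- function(g, stim_node, stim_train = numeric(0),
                         p = lif_params(), seed = 1, i_const = 0) {
  stopifnot(inherits(g, "spatial_graph"), inherits(p, "lif_params"))
  n <- n_points(g$field)
  stopifnot(stim_node >= 1, stim_node <= n)
  stim_train <- sort(as.numeric(stim_train))
  if (length(stim_train) && (min(stim_train) < 0 || max(stim_train) > p$T))
    stop("simulate_lif: stimulus spikes outside [0, T]")
  w <- p$J * exp(-g$lengths / p$lambda_s)
  res <- with_seed(seed,
    lif_core(n, as.integer(g$edges[, 1] - 1L), as.integer(g$edges[, 2] - 1L),
             as.numeric(w), as.integer(stim_node - 1L), stim_train,
             p$tau_m, p$v_rest, p$v_reset, p$v_th, p$t_ref, p$dt, p$T,
             i_const, p$noise_sd))
  st <- split(res$t, factor(res$neuron, levels = seq_len(n)))
  raster <- spike_raster(st, t_max = p$T)
  # refractory + one integration step is the attainable period ceiling
  max_rate <- p$T / (p$t_ref + p$dt)
  attr(raster, "saturated") <- any(lengths(st) > 0.95 * max_rate)
  raster
}

#' Word (spike-pattern) distribution at a node
#'
#' Discretizes each response into `bin`-ms spike/no-spike bins, slices
#' the bin sequence into consecutive words of `word_len` bins, and pools
#' word counts over all responses and word positions into a probability
#' table.
#'
#' @param raster_set list of [spike_raster()] responses.
#' @param node neuron index.
#' @param bin bin width (ms).
#' @param word_len bins per word.
#' @return named numeric vector of word probabilities (names are the
#'   word bit patterns as integers), summing to 1.
#' @export
word_distribution <- function(raster_set, node, bin = 3, word_len = 8) {
  stopifnot(length(raster_set) > 0, bin > 0, word_len >= 1)
  tmax <- raster_set[[1]]$t_max
  if (word_len * bin > tmax)
    stop("word_distribution: word longer than the simulation window")
  counts <- integer(0)
  for (r in raster_set) {
    w <- response_words(r$spike_times[[node]], tmax, bin, word_len)
    counts <- c(counts, w)
  }
  tab <- table(counts)
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  p
}

## spike times -> integer words (big-endian bit order within each word)
response_words <- function(times, tmax, bin, word_len) {
  n_bins <- floor(tmax / bin)
  n_words <- n_bins %/% word_len
  if (n_words == 0) return(integer(0))
  occ <- integer(n_bins)
  if (length(times)) {
    b <- pmin(floor(times / bin) + 1L, n_bins)
    occ[unique(b)] <- 1L
  }
  occ <- occ[seq_len(n_words * word_len)]
  m <- matrix(occ, nrow = word_len)
  as.integer(2^((word_len - 1):0) %*% m)
}

#' Shannon entropy of a probability table
#'
#' \eqn{H = -\sum_s P(s) \log_2 P(s)} in bits, with the convention
#' \eqn{0 \log 0 = 0}.
#'
#' @param P numeric vector of probabilities summing to 1 (within 1e-9).
#' @return entropy in bits.
#' @export
shannon_entropy <- function(P) {
  stopifnot(all(P >= 0))
  if (abs(sum(P) - 1) > 1e-9)
    stop("shannon_entropy: probabilities must sum to 1")
  P <- P[P > 0]
  -sum(P * log2(P))
}

#' Random binary stimulus ensemble
#'
#' Each stimulus is a binary spike train on the word grid: every `bin`-ms
#' slot fires independently with probability `p_fire`.
#'
#' @param n_stimuli number of distinct stimuli.
#' @param T window (ms).
#' @param bin slot width (ms).
#' @param p_fire per-slot firing probability.
#' @param seed integer RNG seed.
#' @return list of spike-time vectors (ms).
#' @export
make_stimulus_ensemble <- function(n_stimuli = 32, T = 192, bin = 3,
                                   p_fire = 0.5, seed = 1) {
  n_slots <- floor(T / bin)
  with_seed(seed, {
    lapply(seq_len(n_stimuli), function(i) {
      on <- runif(n_slots) < p_fire
      (which(on) - 0.5) * bin
    })
  })
}

## Shared engine: simulate the whole ensemble x repeats once, then
## compute per-node H, N and I from the pooled rasters.
information_map <- function(g, stim_node, stimulus_ensemble, n_repeats,
                            p = lif_params(noise_sd = 0.5), seed = 1,
                            bin = 3, word_len = 8) {
  stopifnot(length(stimulus_ensemble) >= 1, n_repeats >= 1)
  n <- n_points(g$field)
  n_stim <- length(stimulus_ensemble)
  n_words_per <- (floor(p$T / bin) %/% word_len)
  # words[node] -> list over (stimulus) of pooled word integers
  rasters <- vector("list", n_stim * n_repeats)
  idx <- 0
  for (s in seq_len(n_stim)) {
    for (r in seq_len(n_repeats)) {
      idx <- idx + 1
      sub_seed <- (as.numeric(seed) * 100003 + idx) %% 2147483647
      rasters[[idx]] <- simulate_lif(g, stim_node, stimulus_ensemble[[s]],
                                     p, seed = sub_seed)
    }
  }
  stim_of <- rep(seq_len(n_stim), each = n_repeats)
  H <- N <- I <- numeric(n)
  n_samples <- length(rasters) * n_words_per
  undersampled <- FALSE
  for (v in seq_len(n)) {
    # words: matrix [response, position]
    words <- t(vapply(rasters, function(r)
      response_words(r$spike_times[[v]], r$t_max, bin, word_len),
      integer(n_words_per)))
    tab <- table(as.vector(words))
    # total entropy: word distribution pooled over positions and stimuli
    H[v] <- shannon_entropy(as.numeric(tab) / sum(tab))
    if (length(tab) > 0.1 * n_samples && length(tab) > 2)
      undersampled <- TRUE
    # noise entropy: variability across repeats at fixed stimulus and
    # fixed word position, averaged over positions and stimuli
    Ns <- vapply(seq_len(n_stim), function(s) {
      ws <- words[stim_of == s, , drop = FALSE]
      mean(vapply(seq_len(ncol(ws)), function(pos) {
        tb <- table(ws[, pos])
        shannon_entropy(as.numeric(tb) / sum(tb))
      }, numeric(1)))
    }, numeric(1))
    N[v] <- mean(Ns)
    I[v] <- max(H[v] - N[v], 0)
  }
  if (undersampled)
    warning("information_map: word space undersampled at some nodes")
  list(H = H, N = N, I = I, bias_floored = any(H - N < 0))
}

#' Information transmitted to one node
#'
#' Direct-method information: the total entropy H of the node's word
#' distribution across a stimulus ensemble minus the noise entropy N
#' across repeats of each stimulus, \eqn{I = H - N}, floored at 0 (with a
#' bias flag).
#'
#' @param g a `spatial_graph`.
#' @param node node at which information is read out.
#' @param stim_node stimulated node.
#' @param stimulus_ensemble list of >= 10 distinct stimulus trains (see
#'   [make_stimulus_ensemble()]).
#' @param n_repeats repeats per stimulus (>= 10).
#' @param p a [lif_params()]; give it `noise_sd > 0` so repeats are not
#'   trivially identical.
#' @param seed integer RNG seed.
#' @param bin,word_len word coding parameters (ms, bins).
#' @return information in bits, with attributes `H` and `N`.
#' @export
node_information <- function(g, node, stim_node, stimulus_ensemble,
                             n_repeats = 20, p = lif_params(noise_sd = 0.5),
                             seed = 1, bin = 3, word_len = 8) {
  stopifnot(length(stimulus_ensemble) >= 10, n_repeats >= 10)
  im <- information_map(g, stim_node, stimulus_ensemble, n_repeats, p,
                        seed, bin, word_len)
  out <- im$I[node]
  attr(out, "H") <- im$H[node]
  attr(out, "N") <- im$N[node]
  out
}

#' Total information delivered over the whole grid
#'
#' Sum over all nodes of the per-node information under a common
#' stimulation protocol (one set of simulations serves every node).
#'
#' @param g a `spatial_graph`.
#' @param stim_node stimulated node.
#' @param n_stimuli size of the random stimulus ensemble.
#' @param n_repeats repeats per stimulus.
#' @param p a [lif_params()].
#' @param seed integer RNG seed.
#' @param bin,word_len word coding parameters.
#' @return total information (bits) with attribute `per_node`.
#' @export
grid_information <- function(g, stim_node = 1, n_stimuli = 16,
                             n_repeats = 10, p = lif_params(noise_sd = 0.5),
                             seed = 1, bin = 3, word_len = 8) {
  ens <- make_stimulus_ensemble(n_stimuli, T = p$T, bin = bin,
                                seed = seed)
  im <- information_map(g, stim_node, ens, n_repeats, p, seed, bin,
                        word_len)
  out <- sum(im$I)
  attr(out, "per_node") <- im$I
  out
}

#' Information enhancement factor between two conditions
#'
#' @param I_a,I_b total information (bits) in the two conditions;
#'   `I_b > 0`.
#' @return Q_E = I_a / I_b.
#' @export
enhancement_factor <- function(I_a, I_b) {
  if (I_b <= 0) stop("enhancement_factor: denominator must be positive")
  as.numeric(I_a) / as.numeric(I_b)
}
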