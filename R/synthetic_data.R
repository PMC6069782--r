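#' Simulation parameters for synthetic replicate Hi-C pairs
#'
#' The generator emulates the qualitative structure the method relies on:
#' a power-law decay of interaction frequency with distance, overdispersed
#' counts, an optional global depth imbalance, an optional distance-dependent
#' multiplicative bias on dataset 2, optional zero inflation, and an
#' optional plaid A/B-compartment pattern.
#'
#' For every upper-triangular bin pair at unit distance D the expected count
#' is `mu(D) = decay_scale * (1 + D)^(-decay_exponent)` (floored at 1e-6),
#' optionally modulated by `(1 + ab_strength * s_i * s_j)` where `s` is a
#' +/-1 block label alternating every `ab_block_size` bins. IF1 is drawn
#' NB(mu, size = dispersion); IF2 is drawn
#' NB(mu * depth_ratio * bias_fn(D), size = dispersion). Each entry is then
#' independently zeroed with probability `zero_inflation`. The ground-truth
#' log2 bias recoverable from the pair is `log2(depth_ratio * bias_fn(D))`.
#'
#' Defaults describe a deeply sequenced 1-Mb chromosome map (near-diagonal
#' IFs ~1e5, ~2.5e8 total contacts over 500 bins, replicate log-ratio
#' spread sigma_M ~ 0.3): `n_bins = 500`, `resolution = 1e6`,
#' `decay_scale = 1e5`, `decay_exponent = 1`, `dispersion = 50`,
#' `depth_ratio = 1`, flat bias, `zero_inflation = 0`, no compartments.
#'
#' @param n_bins number of genomic bins (>= 2)
#' @param resolution bin size in bp
#' @param decay_scale expected count at distance 0
#' @param decay_exponent power-law decay exponent (> 0)
#' @param dispersion negative-binomial size parameter (> 0); smaller means
#'   more overdispersed
#' @param bias_fn function D -> multiplicative bias on dataset 2; see
#'   [default_bias_library()]
#' @param depth_ratio global library-size multiplier for dataset 2
#' @param zero_inflation probability in [0, 1) of zeroing an entry
#' @param ab_strength plaid compartment contrast in [0, 1); 0 disables
#' @param ab_block_size compartment block width in bins
#' @return a `sim_params` list
#' @export
sim_params <- function(n_bins = 500, resolution = 1e6,
                       decay_scale = 1e5, decay_exponent = 1,
                       dispersion = 50, bias_fn = NULL, depth_ratio = 1,
                       zero_inflation = 0, ab_strength = 0,
                       ab_block_size = 50) {
  stopifnot(n_bins >= 2, resolution > 0, decay_scale > 0, decay_exponent > 0,
            dispersion > 0, depth_ratio > 0,
            zero_inflation >= 0, zero_inflation < 1,
            ab_strength >= 0, ab_strength < 1, ab_block_size >= 1)
  if (is.null(bias_fn)) bias_fn <- default_bias_library()$flat
  stopifnot(is.function(bias_fn))
  structure(list(n_bins = as.integer(n_bins), resolution = resolution,
                 decay_scale = decay_scale, decay_exponent = decay_exponent,
                 dispersion = dispersion, bias_fn = bias_fn,
                 depth_ratio = depth_ratio, zero_inflation = zero_inflation,
                 ab_strength = ab_strength,
                 ab_block_size = as.integer(ab_block_size)),
            class = "sim_params")
}

#' Library of preset between-dataset bias shapes
#'
#' Each preset returns a multiplicative bias function of D to pass as
#' `bias_fn` in [sim_params()]; the recoverable ground truth is the log2 of
#' the returned value:
#' \describe{
#'   \item{`flat`}{1 everywhere; log2 form f(D) = 0.}
#'   \item{`global_shift(k)`}{constant `2^k`; f(D) = k. Mimics a pure
#'     library-depth imbalance.}
#'   \item{`linear_in_logD(intercept, slope)`}{`2^(intercept + slope *
#'     log2(1 + D))`; f(D) = intercept + slope * log2(1 + D).}
#'   \item{`sinusoidal(amplitude, period)`}{`2^(amplitude * sin(2 pi D /
#'     period))`; f(D) = amplitude * sin(2 pi D / period). A smooth curved
#'     trend of the kind joint normalization is designed to remove.}
#' }
#'
#' @return named list: `flat` (a function) and three preset factories.
#' @export
default_bias_library <- function() {
  list(
    flat = function(D) rep(1, length(D)),
    global_shift = function(k = 1) {
      force(k); function(D) rep(2^k, length(D))
    },
    linear_in_logD = function(intercept = 0.5, slope = 0.25) {
      force(intercept); force(slope)
      function(D) 2^(intercept + slope * log2(1 + D))
    },
    sinusoidal = function(amplitude = 1, period = 500) {
      force(amplitude); force(period)
      function(D) 2^(amplitude * sin(2 * pi * D / period))
    })
}

#' Simulate a replicate-like pair of Hi-C contact tables
#'
#' @param params a [sim_params()]
#' @param seed integer seed; the same seed reproduces bit-identical tables
#' @param chrom chromosome name for the generated tables
#' @return list with `t1`, `t2` ([contact_table()]s; zero draws are dropped,
#'   sparse semantics) and `true_bias`, the function
#'   `D -> log2(depth_ratio * bias_fn(D))`.
#' @examples
#' pair <- simulate_replicate_pair(sim_params(n_bins = 50), seed = 1)
#' pair$t1
#' @export
simulate_replicate_pair <- function(params = sim_params(), seed = 1,
                                    chrom = "chrS") {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_bins
  ij <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  i <- ij[, 1L]; j <- ij[, 2L]
  D <- j - i
  mu <- pmax(params$decay_scale * (1 + D)^(-params$decay_exponent), 1e-6)
  if (params$ab_strength > 0) {
    s <- rep_len(rep(c(1, -1), each = params$ab_block_size), n)
    mu <- mu * (1 + params$ab_strength * s[i] * s[j])
  }
  bias <- params$bias_fn(D) * params$depth_ratio
  out <- with_seed(seed, {
    IF1 <- stats::rnbinom(length(mu), mu = mu, size = params$dispersion)
    IF2 <- stats::rnbinom(length(mu), mu = mu * bias, size = params$dispersion)
    if (params$zero_inflation > 0) {
      IF1[stats::runif(length(IF1)) < params$zero_inflation] <- 0L
      IF2[stats::runif(length(IF2)) < params$zero_inflation] <- 0L
    }
    list(IF1 = IF1, IF2 = IF2)
  })
  res <- params$resolution
  mk <- function(v) {
    keep <- v > 0
    contact_table(data.table::data.table(start1 = (i[keep] - 1) * res,
                                         start2 = (j[keep] - 1) * res,
                                         IF = as.numeric(v[keep])),
                  chrom = chrom, resolution = res)
  }
  bias_fn <- params$bias_fn
  depth_ratio <- params$depth_ratio
  list(t1 = mk(out$IF1), t2 = mk(out$IF2),
       true_bias = function(D) log2(depth_ratio * bias_fn(D)))
}
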