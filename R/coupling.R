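#' Per-neuron afferent coupling strengths
#'
#' Builds the distribution of afferent scaling factors `K_i` around a mean
#' `k_mean` with maximal distance `delta_k`. The default `"equidistant"`
#' scheme places the `K_i` on a regular grid,
#' `K_i = k_mean - delta_k + 2 delta_k (i - 1)/(n - 1)`, so that neuron index
#' orders coupling strength; `"flat_random"` draws them uniformly from
#' `[k_mean - delta_k, k_mean + delta_k]` and sorts them ascending so the
#' relative rank `i/n` remains a coupling rank in both schemes. For large
#' networks the two schemes are statistically indistinguishable.
#'
#' @param n Number of neurons (>= 2).
#' @param k_mean Mean afferent scaling, dimensionless, > 0.
#' @param delta_k Maximal distance to the mean; `0 <= delta_k <= k_mean` so
#'   that all couplings stay nonnegative.
#' @param scheme `"equidistant"` or `"flat_random"`.
#' @param seed RNG seed for the `"flat_random"` scheme.
#' @return A tibble with one row per neuron: `neuron_id`, `k` (the coupling
#'   `K_i`), `k_offset` (the normalized position `(k - k_mean)/delta_k` in
#'   `[-1, 1]`, used by scheduled simulations) and `k_rank` (`i/n`).
#' @examples
#' coupling_strengths(3, k_mean = 2, delta_k = 1)
#' @export
coupling_strengths <- function(n, k_mean, delta_k = 0,
                               scheme = c("equidistant", "flat_random"),
                               seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(
    "n must be >= 2" = n >= 2,
    "k_mean must be > 0" = k_mean > 0,
    "delta_k must be >= 0" = delta_k >= 0
  )
  if (delta_k > k_mean) {
    stop("delta_k (", delta_k, ") must not exceed k_mean (", k_mean,
         "): couplings would become negative")
  }
  n <- as.integer(n)
  offset <- if (scheme == "equidistant") {
    -1 + 2 * (seq_len(n) - 1) / (n - 1)
  } else {
    draw <- function() sort(stats::runif(n, -1, 1))
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  out <- tibble::tibble(
    neuron_id = seq_len(n),
    k = k_mean + delta_k * offset,
    k_offset = offset,
    k_rank = seq_len(n) / n
  )
  attr(out, "k_mean") <- k_mean
  attr(out, "delta_k") <- delta_k
  out
}

#' Synaptic weight matrix
#'
#' The baseline connectivity is all-to-all and uniform without self-coupling:
#' `w_ij = 1` for `i != j`, `w_ii = 0`, so each neuron couples to the network
#' mean field. With `jitter_width > 0` each off-diagonal weight becomes
#' `1 + eta` with `eta` drawn from a flat distribution of zero mean and
#' half-width `jitter_width`, modelling structural variability of the
#' connectivity while keeping row sums near `n - 1` in expectation.
#'
#' @param n Number of neurons.
#' @param jitter_width Half-width of the flat weight jitter, in `[0, 1)`.
#' @param seed RNG seed for the jitter draw.
#' @param renormalize If `TRUE`, rescale each row so its off-diagonal mean is
#'   exactly 1 (the jitter is zero-mean, so this holds in expectation anyway;
#'   default off).
#' @return An `n x n` numeric matrix with zero diagonal.
#' @examples
#' weight_matrix(4)                        # uniform mean-field coupling
#' weight_matrix(4, jitter_width = 0.5, seed = 1)
#' @export
weight_matrix <- function(n, jitter_width = 0, seed = NULL,
                          renormalize = FALSE) {
  stopifnot("n must be >= 2" = n >= 2)
  if (jitter_width < 0 || jitter_width >= 1) {
    stop("jitter_width must lie in [0, 1): larger values allow negative weights")
  }
  n <- as.integer(n)
  w <- matrix(1, n, n)
  diag(w) <- 0
  if (jitter_width > 0) {
    draw <- function() stats::runif(n * n, -jitter_width, jitter_width)
    eta <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    w <- w * (1 + matrix(eta, n, n))
    diag(w) <- 0
    if (renormalize) {
      w <- w * (n - 1) / rowSums(w)
    }
  }
  w
}
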