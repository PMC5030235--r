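#' Per-neuron firing rates from a spike record
#'
#' Counts spikes in a measurement window that starts after a settling
#' transient and converts to Hz. Rates are reported against each neuron's
#' coupling rank `k_rank = i/n` so profiles from different network sizes can
#' be overlaid.
#'
#' @param record A `spike_record`.
#' @param t_transient Settling time discarded at the start of the record, ms.
#' @param t_measure Length of the measurement window, ms; default everything
#'   after the transient.
#' @param coupling Optional coupling tibble; defaults to the one stored in
#'   the record.
#' @return A `rate_profile` tibble: `neuron_id`, `k` (if known), `k_rank`,
#'   `n_spikes`, `rate_hz`.
#' @export
spike_rates <- function(record, t_transient = 2000, t_measure = NULL,
                        coupling = NULL) {
  n <- attr(record, "n_neurons")
  if (is.null(n)) stop("record does not carry its network size")
  t0 <- attr(record, "t0") %||% 0
  duration <- attr(record, "duration") %||% max(record$time_ms, 0)
  if (is.null(t_measure)) t_measure <- duration - t_transient
  if (t_measure <= 0 || t_transient + t_measure > duration + 1e-9) {
    stop("empty measurement window: need t_transient + t_measure <= duration")
  }
  lo <- t0 + t_transient
  hi <- lo + t_measure
  sel <- record$time_ms > lo & record$time_ms <= hi
  counts <- tabulate(record$neuron_id[sel], nbins = n)
  coupling <- coupling %||% attr(record, "coupling")
  out <- tibble::tibble(
    neuron_id = seq_len(n),
    k = if (!is.null(coupling)) coupling$k else NA_real_,
    k_rank = if (!is.null(coupling) && !is.null(coupling$k_rank))
      coupling$k_rank else seq_len(n) / n,
    n_spikes = counts,
    rate_hz = counts / t_measure * 1000
  )
  attr(out, "t_measure") <- t_measure
  attr(out, "params") <- attr(record, "params")
  class(out) <- c("rate_profile", class(out))
  out
}

#' Interspike intervals
#'
#' @param record A `spike_record`.
#' @param neurons Optional neuron ids to restrict to.
#' @param t_transient Settling time discarded before collecting intervals, ms.
#' @return A tibble `neuron_id`, `n` (interval index), `isi_ms`.
#' @export
isi_intervals <- function(record, neurons = NULL, t_transient = 0) {
  t0 <- attr(record, "t0") %||% 0
  x <- record[record$time_ms >= t0 + t_transient, c("neuron_id", "time_ms")]
  if (!is.null(neurons)) x <- x[x$neuron_id %in% neurons, ]
  x |>
    dplyr::arrange(.data$neuron_id, .data$time_ms) |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(isi_ms = list(diff(.data$time_ms)), .groups = "drop") |>
    tidyr::unnest_longer("isi_ms") |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::mutate(n = dplyr::row_number(), .before = "isi_ms") |>
    dplyr::ungroup()
}

#' Interspike-interval statistics and coefficient of variation
#'
#' Per neuron: mean interval `T`, standard deviation `sigma`, and the
#' coefficient of variation `CV = sigma / T`. `CV = 0` signals perfectly
#' periodic firing (as in fully drifting or fully synchronized states);
#' drifting neurons that coexist with a synchronized cluster fire
#' irregularly and show markedly larger CVs. Neurons with fewer than two
#' spikes are excluded (their ids are kept in the `excluded` attribute).
#'
#' @inheritParams isi_intervals
#' @return A tibble `neuron_id`, `n_isi`, `mean_isi_ms`, `sd_isi_ms`, `cv`.
#' @export
isi_stats <- function(record, neurons = NULL, t_transient = 0) {
  iv <- isi_intervals(record, neurons, t_transient)
  out <- iv |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::summarise(
      n_isi = dplyr::n(),
      mean_isi_ms = mean(.data$isi_ms),
      sd_isi_ms = sqrt(mean((.data$isi_ms - mean(.data$isi_ms))^2)),
      .groups = "drop"
    ) |>
    dplyr::mutate(cv = .data$sd_isi_ms / .data$mean_isi_ms)
  all_ids <- if (!is.null(neurons)) neurons else
    unique(record$neuron_id)
  attr(out, "excluded") <- setdiff(all_ids, out$neuron_id)
  out
}

#' Network-averaged normalized ISI histogram
#'
#' Each neuron's intervals are normalized by its own mean interval `T_i`;
#' per-neuron densities over `s/T` are then averaged with equal weight per
#' neuron, so fast and slow neurons contribute equally. A single sharp bin
#' at `s/T = 1` signals fully periodic firing.
#'
#' @inheritParams isi_intervals
#' @param bins Number of bins.
#' @param s_max Upper edge of the normalized interval axis.
#' @return A tibble `s_over_t` (bin midpoint), `density`.
#' @export
isi_histogram <- function(record, neurons = NULL, t_transient = 0,
                          bins = 100, s_max = 3) {
  iv <- isi_intervals(record, neurons, t_transient)
  if (nrow(iv) == 0) stop("no intervals to histogram")
  edges <- seq(0, s_max, length.out = bins + 1)
  bw <- edges[2] - edges[1]
  dens <- iv |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::mutate(s_norm = .data$isi_ms / mean(.data$isi_ms)) |>
    dplyr::summarise(
      d = list(tabulate(findInterval(.data$s_norm, edges,
                                     rightmost.closed = TRUE),
                        nbins = bins) / (dplyr::n() * bw)),
      .groups = "drop"
    )
  mat <- do.call(rbind, dens$d)
  tibble::tibble(s_over_t = (edges[-1] + edges[-(bins + 1)]) / 2,
                 density = colMeans(mat))
}

#' Classify the self-organized dynamical state
#'
#' Splits the neurons of a settled rate profile into inactive, drifting and
#' synchronized groups and assembles the state label:
#' \describe{
#'   \item{I}{inactive (everything below `rate_floor`)}
#'   \item{I+D}{partially inactive and drifting}
#'   \item{D}{fully drifting: a continuum of distinct rates}
#'   \item{D+S}{mixed: a drifting continuum plus a synchronized plateau}
#'   \item{S}{fully synchronized: one rate plateau spanning all neurons}
#' }
#' Synchrony is diagnosed operationally from rate equality: the largest run
#' of consecutive-rank active neurons whose rates all agree within `rel_tol`
#' (relative spread) forms a synchronized cluster if it has at least
#' `min_cluster` members. A set of numerically identical rates is never
#' split. The tolerance is a convention (exposed here) since rate equality
#' on a plateau is only exact in infinite measurement windows.
#'
#' @param profile A `rate_profile` from [spike_rates()] (any data frame with
#'   `neuron_id` and `rate_hz`, ordered by coupling rank, works).
#' @param rate_floor Rates below this (Hz) count as inactive.
#' @param rel_tol Maximal relative spread `(max-min)/max` within a plateau.
#' @param min_cluster Minimal plateau size; default `max(3, ceiling(0.05 n))`.
#' @return A `phase_label`: list with `label`, `fractions` (named inactive /
#'   drifting / synchronized proportions summing to 1), `cluster` (neuron ids
#'   of the plateau) and `n`. Has `print()` and [generics::tidy()] methods.
#' @export
classify_state <- function(profile, rate_floor = 1, rel_tol = 0.005,
                           min_cluster = NULL) {
  n <- nrow(profile)
  if (is.null(min_cluster)) min_cluster <- max(3, ceiling(0.05 * n))
  rate <- profile$rate_hz
  active <- which(rate >= rate_floor)
  cluster <- integer(0)
  if (length(active) >= min_cluster) {
    r <- rate[active]
    best_len <- 0L; best <- c(0L, 0L)
    i <- 1L
    for (i in seq_along(r)) {
      rmin <- r[i]; rmax <- r[i]
      j <- i
      while (j < length(r)) {
        rmin2 <- min(rmin, r[j + 1]); rmax2 <- max(rmax, r[j + 1])
        if ((rmax2 - rmin2) > rel_tol * rmax2) break
        rmin <- rmin2; rmax <- rmax2; j <- j + 1L
      }
      if (j - i + 1L > best_len) {
        best_len <- j - i + 1L; best <- c(i, j)
      }
    }
    if (best_len >= min_cluster) cluster <- active[best[1]:best[2]]
  }
  n_inact <- n - length(active)
  n_sync <- length(cluster)
  n_drift <- length(active) - n_sync
  fractions <- c(inactive = n_inact, drifting = n_drift,
                 synchronized = n_sync) / n
  parts <- c("I", "D", "S")[c(n_inact > 0, n_drift > 0, n_sync > 0)]
  label <- if (length(parts) == 0) "I" else paste(parts, collapse = "+")
  structure(
    list(label = label, fractions = fractions,
         cluster = profile$neuron_id[cluster], n = n),
    class = "phase_label"
  )
}

#' @export
print.phase_label <- function(x, ...) {
  cat(sprintf("<phase_label> %s  (inactive %.0f%%, drifting %.0f%%, synchronized %.0f%%)\n",
              x$label, 100 * x$fractions[1], 100 * x$fractions[2],
              100 * x$fractions[3]))
  invisible(x)
}

#' @rdname classify_state
#' @param x A `phase_label`.
#' @param ... Unused.
#' @export
tidy.phase_label <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    frac_inactive = unname(x$fractions["inactive"]),
    frac_drifting = unname(x$fractions["drifting"]),
    frac_synchronized = unname(x$fractions["synchronized"]),
    cluster_size = length(x$cluster),
    n = x$n
  )
}
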