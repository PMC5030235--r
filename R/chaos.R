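#' Consecutive-ISI return-map embedding
#'
#' Embeds a neuron's spike train in the plane of consecutive interspike
#' intervals: each point is a pair `(s(n), s(n+1))`. For regular firing
#' (pure drifting or fully synchronized states) all points collapse onto a
#' single point `(T, T)`; a drifting neuron coexisting with a synchronized
#' cluster traces out a structured, non-repeating set. This two-dimensional
#' projection is a minimal delay embedding of the spike-time dynamics: a
#' non-integer box-counting dimension of the resulting set indicates chaos.
#'
#' @param x A `spike_record` (with `neuron` given) or a numeric vector of
#'   interspike intervals in ms.
#' @param neuron Neuron id to embed when `x` is a spike record.
#' @param t_transient Settling time discarded first, ms.
#' @return An `isi_embedding` tibble: `n`, `s_n`, `s_np1` (ms).
#' @examples
#' emb <- isi_pairs(c(8, 9, 8.5, 9.2))
#' emb
#' @export
isi_pairs <- function(x, neuron = NULL, t_transient = 0) {
  if (inherits(x, "spike_record") || is.data.frame(x)) {
    if (is.null(neuron)) stop("give `neuron` to embed a spike record")
    iv <- isi_intervals(x, neurons = neuron, t_transient = t_transient)
    s <- iv$isi_ms
  } else {
    s <- as.numeric(x)
  }
  if (length(s) < 2) stop("need at least 2 interspike intervals to embed")
  out <- tibble::tibble(
    n = seq_len(length(s) - 1),
    s_n = s[-length(s)],
    s_np1 = s[-1]
  )
  attr(out, "neuron") <- neuron
  class(out) <- c("isi_embedding", class(out))
  out
}

#' Count occupied boxes at one or more grid refinements
#'
#' Lays a `2^r x 2^r` grid of equal squares over the tight bounding square
#' of the point set (the square centred on the data whose side is the larger
#' of the two coordinate extents) and counts cells containing at least one
#' point.
#'
#' @param embedding An `isi_embedding`, or any data frame whose first two
#'   numeric columns are point coordinates.
#' @param r Integer grid exponent(s), >= 0.
#' @return A tibble `r`, `n_box`.
#' @export
box_count <- function(embedding, r) {
  stopifnot(all(r >= 0), all(r == floor(r)))
  x <- embedding[[if ("s_n" %in% names(embedding)) "s_n" else 1]]
  y <- embedding[[if ("s_np1" %in% names(embedding)) "s_np1" else 2]]
  if (length(x) < 1) stop("need at least one point")
  side <- max(max(x) - min(x), max(y) - min(y))
  n_box <- if (side == 0) {
    rep(1L, length(r))
  } else {
    x0 <- (min(x) + max(x)) / 2 - side / 2
    y0 <- (min(y) + max(y)) / 2 - side / 2
    vapply(r, function(ri) {
      m <- 2^ri
      ix <- pmin(floor((x - x0) / side * m), m - 1)
      iy <- pmin(floor((y - y0) / side * m), m - 1)
      length(unique(ix * m + iy))
    }, numeric(1))
  }
  tibble::tibble(r = as.integer(r), n_box = n_box)
}

#' Box-counting (Minkowski) fractal dimension
#'
#' Estimates the fractal dimension of a planar point set as the
#' least-squares slope of `log2(n_box)` against the grid exponent `r`
#' (i.e. against `log2` of the inverse box size). A limit cycle gives
#' `D_F = 1`, a filled region 2; a strange attractor yields a fractional
#' value. `log2(n_box)` saturates at `log2` of the number of points, so the
#' fit range must stay below saturation: by default `r = 2..7` with at least
#' `1e5` points, `r = 2..5` with at least `2e4`, `r = 2..4` otherwise, and
#' the range is additionally capped where `n_box` exceeds half the number of
#' points. Longer spike trains extend the usable linear range.
#'
#' @inheritParams box_count
#' @param fit_range Integer vector of grid exponents to fit over; `NULL`
#'   picks the default for the available number of points.
#' @param r_max Largest exponent evaluated for the reported curve.
#' @return A `boxcount_fit`: list with `d_f`, the `curve` tibble
#'   (`r`, `n_box`, `log2_n_box`, `in_fit`), `fit_range`, `residual_se`,
#'   `n_points` and a `saturated` flag set when the fit range touches the
#'   saturation plateau. Supports `tidy()`, `glance()` and `autoplot()`.
#' @examples
#' pts <- tibble::tibble(s_n = runif(1e4), s_np1 = runif(1e4))
#' fractal_dimension(pts)$d_f # ~2 for a filled square
#' @export
fractal_dimension <- function(embedding, fit_range = NULL, r_max = NULL) {
  npts <- nrow(embedding)
  if (is.null(fit_range)) {
    fit_range <- if (npts >= 1e5) 2:7 else if (npts >= 2e4) 2:5 else 2:4
  }
  fit_range <- as.integer(fit_range)
  if (is.null(r_max)) r_max <- max(fit_range) + 2L
  curve <- box_count(embedding, 0:r_max)
  # keep the fit below the saturation plateau
  ok <- curve$n_box[match(fit_range, curve$r)] <= 0.5 * npts
  saturated <- any(!ok)
  fit_range <- fit_range[ok]
  if (length(fit_range) < 2) {
    stop("fewer than two usable grid refinements below saturation; ",
         "supply more points or a smaller fit_range")
  }
  curve$log2_n_box <- log2(curve$n_box)
  curve$in_fit <- curve$r %in% fit_range
  fit <- stats::lm(log2_n_box ~ r, data = curve[curve$in_fit, ])
  # residual se computed directly: an exact power law has zero residuals
  rse <- sqrt(sum(stats::resid(fit)^2) / max(stats::df.residual(fit), 1))
  structure(
    list(d_f = unname(stats::coef(fit)[2]) + 0, # + 0 normalizes signed zero
         curve = curve,
         fit_range = range(fit_range),
         residual_se = rse,
         n_points = npts,
         saturated = saturated),
    class = "boxcount_fit"
  )
}

#' @export
print.boxcount_fit <- function(x, ...) {
  cat(sprintf("<boxcount_fit> D_F = %.3f (fit r = %d..%d over %d points%s)\n",
              x$d_f, x$fit_range[1], x$fit_range[2], x$n_points,
              if (x$saturated) "; fit range was capped at saturation" else ""))
  invisible(x)
}

#' @rdname fractal_dimension
#' @param x A `boxcount_fit`.
#' @param ... Unused.
#' @export
tidy.boxcount_fit <- function(x, ...) x$curve

#' @rdname fractal_dimension
#' @export
glance.boxcount_fit <- function(x, ...) {
  tibble::tibble(
    d_f = x$d_f,
    r_lo = x$fit_range[1],
    r_hi = x$fit_range[2],
    residual_se = x$residual_se,
    n_points = x$n_points,
    saturated = x$saturated
  )
}
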