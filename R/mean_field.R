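#' Firing condition bound on K * r
#'
#' A neuron driven by a stationary mean field `r_bar` reaches threshold only
#' if its steady drive is strong enough: the membrane fixed point must lie
#' above `v_theta`, which requires
#' `K * r_bar > (v_theta - v_rest) / (tau_ex * (e_ex - v_theta))`.
#' At the default constants the bound is `(1/5) * (10/50) = 0.04` per ms.
#'
#' @param params [neuron_params()].
#' @return The bound on the product `K * r_bar`, in 1/ms.
#' @export
firing_bound <- function(params = neuron_params()) {
  params <- as_neuron_params(params)
  (params$v_theta - params$v_rest) /
    (params$tau_ex * (params$e_ex - params$v_theta))
}

#' Steady-state conductance under a stationary mean field
#'
#' With the network firing at a constant mean rate `r_bar`, the conductance
#' of a neuron with coupling `k` relaxes to `g* = tau_ex * k * r_bar`.
#'
#' @param k Coupling strength(s) `K_i`, nonnegative.
#' @param r_bar Stationary mean field, spikes per ms, nonnegative.
#' @param params [neuron_params()].
#' @return Steady conductance(s), dimensionless.
#' @export
steady_conductance <- function(k, r_bar, params = neuron_params()) {
  params <- as_neuron_params(params)
  if (any(k < 0) || any(r_bar < 0)) stop("k and r_bar must be nonnegative")
  params$tau_ex * k * r_bar
}

#' Time to threshold under a stationary mean field
#'
#' Closed-form integration of the membrane equation with the conductance
#' frozen at its steady value `g* = tau_ex * k * r_bar`: starting from
#' `v_rest`, the time to reach `v_theta` is
#' `t* = -(1/B) log((B v_theta - A) / (B v_rest - A))` with
#' `A = (v_rest + g* e_ex)/tau` and `B = (1 + g*)/tau`. When the drive does
#' not satisfy [firing_bound()] the threshold is never reached and `t* = Inf`.
#'
#' @inheritParams steady_conductance
#' @return Time(s) to threshold in ms (`Inf` for non-firing neurons).
#' @export
time_to_threshold <- function(k, r_bar, params = neuron_params()) {
  params <- as_neuron_params(params)
  if (any(k < 0) || any(r_bar < 0)) stop("k and r_bar must be nonnegative")
  gs <- params$tau_ex * k * r_bar
  a <- (params$v_rest + gs * params$e_ex) / params$tau
  b <- (1 + gs) / params$tau
  fires <- k * r_bar > firing_bound(params)
  ts <- rep(Inf, length(gs))
  ts[fires] <- -(1 / b[fires]) *
    log((b[fires] * params$v_theta - a[fires]) /
          (b[fires] * params$v_rest - a[fires]))
  ts
}

#' Predicted stationary firing rate of a single neuron
#'
#' `1 / (t* + t_ref)` in spikes per ms for neurons satisfying the firing
#' condition, 0 otherwise.
#'
#' @inheritParams steady_conductance
#' @return Rate(s) in spikes per ms.
#' @export
smf_rate <- function(k, r_bar, params = neuron_params()) {
  ts <- time_to_threshold(k, r_bar, params)
  params <- as_neuron_params(params)
  ifelse(is.finite(ts), 1 / (ts + params$t_ref), 0)
}

#' Stationary mean-field self-consistency map
#'
#' Maps a trial mean field `r_bar` to the network-average predicted rate
#' `mean_i 1/(t*_i(r_bar) + t_ref)`, with non-firing neurons counted as zero.
#' The average runs over all neurons (silent ones included), which is what
#' makes partially inactive states self-consistent. The map is nondecreasing
#' in `r_bar` and bounded by `1/t_ref`, so its largest fixed point can be
#' found by bisection from the top.
#'
#' @param r_bar Trial mean field, spikes per ms.
#' @param k Vector of coupling strengths `K_i`.
#' @param params [neuron_params()].
#' @return The updated mean field, spikes per ms.
#' @export
smf_map <- function(r_bar, k, params = neuron_params()) {
  vapply(r_bar, function(r) mean(smf_rate(k, r, params)), numeric(1))
}

#' Solve the stationary mean-field self-consistency
#'
#' Finds the fixed points of [smf_map()] on `[0, 1/t_ref]` by scanning a
#' grid for sign changes of `smf_map(r) - r` and bisecting each bracket to
#' `tol`. The trivial fixed point `r = 0` (silent network) always exists;
#' the returned solution is the **largest** fixed point, which describes the
#' active branch. All bracketed roots are kept for diagnostics. The theory
#' describes asynchronous drifting states (it becomes exact in the
#' thermodynamic limit) and does not hold once synchronized clusters form.
#'
#' @param coupling Coupling tibble from [coupling_strengths()], or a plain
#'   numeric vector of `K_i`.
#' @param params [neuron_params()]; requires `t_ref > 0`.
#' @param grid_n Number of grid cells scanned for sign changes.
#' @param tol Bisection tolerance on `r_bar`, spikes per ms.
#' @return An `smf_solution`: list with the self-consistent `r_bar` (1/ms),
#'   `r_bar_hz`, a per-neuron tibble `neurons` (`neuron_id`, `k`, `k_rank`,
#'   `g_star`, `t_star_ms`, `rate_hz`, `fires`), all fixed points `roots`,
#'   the fixed-point `residual`, and the inputs. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' cpl <- coupling_strengths(100, k_mean = 2, delta_k = 1.2)
#' sol <- solve_smf(cpl)
#' sol$r_bar_hz
#' @export
solve_smf <- function(coupling, params = neuron_params(), grid_n = 400,
                      tol = 1e-10) {
  params <- as_neuron_params(params)
  if (params$t_ref <= 0) {
    stop("solve_smf requires t_ref > 0: without a refractory period the ",
         "map is unbounded and no stationary finite-rate state exists")
  }
  if (is.data.frame(coupling)) {
    k <- coupling$k
  } else {
    k <- as.numeric(coupling)
    coupling <- tibble::tibble(neuron_id = seq_along(k), k = k,
                               k_rank = seq_along(k) / length(k))
  }
  if (any(k < 0)) stop("coupling strengths must be nonnegative")

  sol <- find_fixed_points(function(r) mean(smf_rate(k, r, params)),
                           1 / params$t_ref, grid_n, tol)
  roots <- sol$roots
  r_bar <- sol$r_bar

  ts <- time_to_threshold(k, r_bar, params)
  neurons <- tibble::tibble(
    neuron_id = coupling$neuron_id,
    k = k,
    k_rank = coupling$k_rank %||% (seq_along(k) / length(k)),
    g_star = steady_conductance(k, r_bar, params),
    t_star_ms = ts,
    rate_hz = 1000 * smf_rate(k, r_bar, params),
    fires = is.finite(ts)
  )
  structure(
    list(r_bar = r_bar, r_bar_hz = 1000 * r_bar, neurons = neurons,
         roots = roots, residual = smf_map(r_bar, k, params) - r_bar,
         params = params, k = k),
    class = "smf_solution"
  )
}

#' @export
print.smf_solution <- function(x, ...) {
  cat("<smf_solution>\n")
  cat(sprintf("  r_bar = %.6g Hz (%d fixed point%s found; residual %.2e)\n",
              x$r_bar_hz, length(x$roots), ifelse(length(x$roots) > 1, "s", ""),
              x$residual))
  cat(sprintf("  %d / %d neurons predicted active\n",
              sum(x$neurons$fires), nrow(x$neurons)))
  invisible(x)
}

#' @rdname solve_smf
#' @param x An `smf_solution`.
#' @param ... Unused.
#' @export
tidy.smf_solution <- function(x, ...) x$neurons

#' @rdname solve_smf
#' @export
glance.smf_solution <- function(x, ...) {
  tibble::tibble(
    r_bar_hz = x$r_bar_hz,
    n_neurons = nrow(x$neurons),
    n_active = sum(x$neurons$fires),
    n_roots = length(x$roots),
    residual = x$residual
  )
}

#' Stationary mean field in the thermodynamic limit
#'
#' Solves the same self-consistency as [solve_smf()] but with the average
#' over neurons replaced by an integral over the flat coupling distribution
#' on `[k_mean - delta_k, k_mean + delta_k]`, evaluated by Gauss-Legendre
#' quadrature. This is the `N -> infinity` limit in which the theory is
#' exact for drifting states; finite-`N` solutions converge to it.
#'
#' @param k_mean,delta_k Coupling distribution parameters.
#' @param params [neuron_params()]; requires `t_ref > 0`.
#' @param nodes Number of quadrature nodes.
#' @param grid_n,tol As in [solve_smf()].
#' @return An `smf_solution` whose `neurons` tibble holds the quadrature
#'   nodes (with `k_rank` the cumulative probability of each node).
#' @export
solve_smf_limit <- function(k_mean, delta_k, params = neuron_params(),
                            nodes = 256, grid_n = 400, tol = 1e-10) {
  params <- as_neuron_params(params)
  if (params$t_ref <= 0) stop("solve_smf_limit requires t_ref > 0")
  stopifnot(k_mean > 0, delta_k >= 0, delta_k <= k_mean)
  gl <- if (delta_k == 0) list(x = k_mean, w = 1) else
    pracma::gaussLegendre(nodes, k_mean - delta_k, k_mean + delta_k)
  wts <- gl$w / sum(gl$w) # quadrature of the flat (uniform) K density
  map_fn <- function(r) sum(wts * smf_rate(gl$x, r, params))
  sol <- find_fixed_points(map_fn, 1 / params$t_ref, grid_n, tol)
  r_bar <- sol$r_bar
  ts <- time_to_threshold(gl$x, r_bar, params)
  neurons <- tibble::tibble(
    neuron_id = seq_along(gl$x),
    k = gl$x,
    k_rank = if (delta_k == 0) 1 else (gl$x - (k_mean - delta_k)) / (2 * delta_k),
    g_star = steady_conductance(gl$x, r_bar, params),
    t_star_ms = ts,
    rate_hz = 1000 * smf_rate(gl$x, r_bar, params),
    fires = is.finite(ts)
  )
  structure(
    list(r_bar = r_bar, r_bar_hz = 1000 * r_bar, neurons = neurons,
         roots = sol$roots, residual = map_fn(r_bar) - r_bar,
         params = params, k = gl$x),
    class = "smf_solution"
  )
}

# Largest fixed point of a nondecreasing map on [0, r_max] by grid scan and
# bracketed bisection; 0 is always a fixed point for the maps used here.
find_fixed_points <- function(map_fn, r_max, grid_n, tol) {
  rs <- seq(0, r_max, length.out = grid_n + 1)
  f <- vapply(rs, map_fn, numeric(1)) - rs
  roots <- 0
  for (i in seq_len(grid_n)) {
    flo <- f[i]; fhi <- f[i + 1]
    if ((flo > 0 && fhi <= 0) || (flo < 0 && fhi >= 0)) {
      roots <- c(roots, stats::uniroot(function(r) map_fn(r) - r,
                                       c(rs[i], rs[i + 1]), f.lower = flo,
                                       f.upper = fhi, tol = tol)$root)
    }
  }
  roots <- sort(unique(roots))
  list(r_bar = max(roots), roots = roots)
}

#' Analytic phase boundaries of the stationary mean field
#'
#' For each coupling spread `delta_k`, locates two critical mean couplings by
#' bisection: `k_onset`, where a positive fixed point of [smf_map()] first
#' exists (transition from the fully inactive state to a partially active
#' one), and `k_all_active`, where the weakest neuron's drive
#' `min(K_i) * r_bar` reaches [firing_bound()] so every neuron fires
#' (transition from partially inactive to fully drifting). For `delta_k = 0`
#' the two coincide.
#'
#' @param delta_k Vector of coupling spreads: absolute `delta_k` values when
#'   `spread = "absolute"` (bisection at fixed `delta_k`; the valid domain is
#'   `k_mean >= delta_k`, and `NA` is returned when the boundary lies outside
#'   it), or relative spreads `delta_k / k_mean` in `[0, 1]` when
#'   `spread = "relative"` (bisection along rays of constant ratio, matching
#'   the phase-diagram axes).
#' @param params [neuron_params()].
#' @param n Network size used for the discrete coupling grid.
#' @param spread Interpretation of `delta_k` (see above).
#' @param k_max Upper end of the search bracket for `k_mean`.
#' @param tol Bisection tolerance on `k_mean`.
#' @return A tibble with columns `delta_k`, `k_onset`, `k_all_active`
#'   (`NA` when the bracket does not contain the boundary).
#' @export
smf_boundaries <- function(delta_k, params = neuron_params(), n = 100,
                           spread = c("absolute", "relative"),
                           k_max = 30, tol = 1e-4) {
  params <- as_neuron_params(params)
  spread <- match.arg(spread)
  one <- function(dk) {
    klo <- if (spread == "absolute") max(dk, 1e-6) else 1e-3
    dk_at <- function(km) if (spread == "absolute") dk else dk * km
    active_r <- function(km) {
      d <- dk_at(km)
      cpl <- if (d > 0) coupling_strengths(n, km, d) else
        tibble::tibble(neuron_id = seq_len(n), k = rep(km, n),
                       k_rank = seq_len(n) / n)
      solve_smf(cpl, params)$r_bar
    }
    bisect <- function(pred, lo, hi) {
      if (pred(lo) || !pred(hi)) return(NA_real_)
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (pred(mid)) hi <- mid else lo <- mid
      }
      (lo + hi) / 2
    }
    k_on <- bisect(function(km) active_r(km) > 1e-9, klo, k_max)
    bound <- firing_bound(params)
    k_all <- bisect(function(km) {
      r <- active_r(km)
      r > 1e-9 && (km - dk_at(km)) * r > bound
    }, klo, k_max)
    tibble::tibble(delta_k = dk, k_onset = k_on, k_all_active = k_all)
  }
  purrr::map_dfr(delta_k, one)
}
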