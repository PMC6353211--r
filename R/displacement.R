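# Single-step displacement analysis: Rayleigh-mixture fitting of the
# frame-to-frame displacement histogram, bound fraction, and the
# pseudo-first-order association rate.

#' Single-step displacements from fast-acquisition tracks
#'
#' Euclidean distances between consecutive-frame detections of each track.
#' Pairs spanning a blink gap (frame difference > 1) are excluded, so every
#' displacement corresponds to exactly one camera cycle `dt`.
#'
#' @param tracks data.frame with `track_id`, `frame`, `x_um`, `y_um`.
#' @param dt frame interval of the fast acquisition, s (default 0.02).
#' @return An object of class `ssd_set` with fields `dt` and
#'   `displacements` (um).
#' @export
single_step_displacements <- function(tracks, dt = 0.02) {
  .check_number(dt, "dt", lower = 1e-12)
  stopifnot(all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)))
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  same <- diff(tracks$track_id) == 0L & diff(tracks$frame) == 1L
  r <- sqrt(diff(tracks$x_um)^2 + diff(tracks$y_um)^2)[same]
  structure(list(dt = dt, displacements = as.numeric(r)), class = "ssd_set")
}

# Rayleigh-mixture displacement density:
# p(r) = sum_i f_i * r/(2 D_i dt) * exp(-r^2 / (4 D_i dt))
#' @keywords internal
.ssd_density <- function(r, fractions, diffusivities, dt) {
  out <- numeric(length(r))
  for (i in seq_along(fractions)) {
    s <- 2 * diffusivities[i] * dt
    out <- out + fractions[i] * r / s * exp(-r^2 / (2 * s))
  }
  out
}

# log-spaced diffusivity k-tuples for multistart
#' @keywords internal
.diffusivity_starts <- function(k, n_grid = 6) {
  g <- 10 ^ seq(-2.2, 1.2, length.out = n_grid)
  if (k == 1L) return(lapply(g, function(d) d))
  m <- t(utils::combn(g, k))
  lapply(seq_len(nrow(m)), function(i) m[i, ])
}

#' Fit an n-component diffusion mixture to a displacement histogram
#'
#' Least-squares fit of the mixture density
#' \deqn{p(r) = r \sum_i \frac{f_i}{2 D_i \Delta t}
#'   e^{-r^2/(4 D_i \Delta t)}, \qquad \sum_i f_i = 1}
#' to the normalized single-step displacement histogram (default bin width
#' 0.02 um, range to the 99.5th percentile). The unit-sum constraint on the
#' fractions is enforced by a softmax reparameterization; diffusivities are
#' optimized on the log scale from a deterministic multistart grid.
#' Components are reported by ascending diffusivity.
#'
#' @param ssd an `ssd_set` from [single_step_displacements()].
#' @param n_components number of diffusive components (default 3).
#' @param bin_width histogram bin width, um (default 0.02).
#' @return An object of class `diffusion_fit` with fields `fractions`
#'   (summing to 1), `diffusivities` (um^2/s, ascending), `objective`
#'   (residual sum of squares on the density scale), `n_components`,
#'   `n_displacements`, and the histogram used (`breaks`, `density`).
#' @export
fit_diffusion_components <- function(ssd, n_components = 3,
                                     bin_width = 0.02) {
  stopifnot(inherits(ssd, "ssd_set"))
  k <- .check_count(n_components, "n_components", lower = 1)
  .check_number(bin_width, "bin_width", lower = 1e-9)
  r <- ssd$displacements
  if (length(r) < 50L) stop("too few displacements to fit", call. = FALSE)
  rmax <- max(stats::quantile(r, 0.995), bin_width * 10)
  breaks <- seq(0, ceiling(rmax / bin_width) * bin_width, by = bin_width)
  h <- graphics::hist(r[r < max(breaks)], breaks = breaks, plot = FALSE)
  centers <- h$mids
  dens <- h$counts / (length(r) * bin_width)
  dt <- ssd$dt

  unpack <- function(par) {
    if (k == 1L) {
      list(f = 1, D = exp(par))
    } else {
      w <- c(par[seq_len(k - 1L)], 0)
      f <- exp(w - max(w))
      list(f = f / sum(f), D = exp(par[k - 1L + seq_len(k)]))
    }
  }
  objective <- function(par) {
    p <- unpack(par)
    sum((.ssd_density(centers, p$f, p$D, dt) - dens)^2)
  }
  best <- NULL
  for (D0 in .diffusivity_starts(k)) {
    par0 <- c(rep(0, k - 1L), log(D0))
    opt <- tryCatch(stats::optim(par0, objective, method = "BFGS",
                                 control = list(maxit = 500)),
                    error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("diffusion fit failed to converge", call. = FALSE)
  p <- unpack(best$par)
  ord <- order(p$D)
  D <- p$D[ord]
  f <- p$f[ord]
  if (k > 1L && any(abs(diff(log(D))) < 0.1)) {
    warning("diffusion components nearly collapsed; ",
            "consider fewer components")
  }
  structure(list(fractions = f, diffusivities = D,
                 objective = best$value, n_components = k,
                 n_displacements = length(r),
                 breaks = breaks, density = dens),
            class = "diffusion_fit")
}

#' Bound fraction from a diffusion-mixture fit
#'
#' The bound fraction is the weight of the slowest mixture component,
#' provided its diffusivity matches that of the immobile chromatin control
#' (H2B-like, ~0.04 um^2/s) within a factor `tol_factor`. If the slowest
#' component is faster than that window, no bound population was resolved
#' and 0 is returned with a warning.
#'
#' @param fit a `diffusion_fit`.
#' @param d_ref reference diffusivity of the immobile control, um^2/s.
#' @param tol_factor multiplicative matching window (default 3).
#' @return The bound fraction, a probability.
#' @export
bound_fraction <- function(fit, d_ref = 0.04, tol_factor = 3) {
  stopifnot(inherits(fit, "diffusion_fit"))
  .check_number(d_ref, "d_ref", lower = 1e-12)
  .check_number(tol_factor, "tol_factor", lower = 1)
  D1 <- fit$diffusivities[1L]
  if (D1 > d_ref * tol_factor || D1 < d_ref / tol_factor) {
    warning(sprintf(paste0("slowest component D = %.3g um^2/s does not ",
                           "match the immobile reference %.3g um^2/s; ",
                           "returning bound fraction 0"), D1, d_ref))
    return(0)
  }
  fit$fractions[1L]
}

#' Pseudo-first-order association rate from the bound fraction
#'
#' Inverts the steady-state relation \eqn{BF = k^*_{on} / (k^*_{on} +
#' k_{off})}, giving \eqn{k^*_{on} = k_{off} \, BF / (1 - BF)}.
#'
#' @param BF bound fraction in `[0, 1)`.
#' @param k_off dissociation rate, 1/s (> 0); by convention the reciprocal
#'   of the long-lived residence time.
#' @return k_on*, 1/s.
#' @export
compute_kon_star <- function(BF, k_off) {
  .check_number(BF, "BF", lower = 0)
  if (BF >= 1) stop("BF must be < 1 (BF = 1 implies an infinite k_on*)",
                    call. = FALSE)
  .check_number(k_off, "k_off", lower = 1e-300)
  k_off * BF / (1 - BF)
}
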