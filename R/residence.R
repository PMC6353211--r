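# Residence-time analysis: bound-event extraction by spatiotemporal
# thresholding, empirical survival (1-CDF) curves, photobleaching correction
# against an immobile control, mono/bi-exponential dwell fitting and F-test
# model selection.

#' Spatiotemporal binding filter parameters
#'
#' A molecule is classified as chromatin-bound while every frame-to-frame
#' displacement stays below `r_max` (default 3 pixels = 435 nm, calibrated
#' on an immobile histone control) and the run lasts at least
#' `min_bound_frames` camera cycles (default 10 frames = 1 s at the 100 ms
#' slow-movie cycle).
#'
#' @param r_max spatial threshold, um.
#' @param min_bound_frames minimum run length, frames.
#' @param cycle_dt camera cycle duration, s.
#' @return An object of class `binding_filter_params`.
#' @export
binding_filter_params <- function(r_max = 0.435, min_bound_frames = 10,
                                  cycle_dt = 0.1) {
  .check_number(r_max, "r_max", lower = 1e-12)
  .check_count(min_bound_frames, "min_bound_frames", lower = 1)
  .check_number(cycle_dt, "cycle_dt", lower = 1e-12)
  structure(list(r_max = r_max,
                 min_bound_frames = as.integer(min_bound_frames),
                 cycle_dt = cycle_dt),
            class = "binding_filter_params")
}

#' Extract bound events from linked tracks
#'
#' Scans each track for maximal runs of consecutive detections whose every
#' displacement between successive detections is below `r_max`; runs of at
#' least `min_bound_frames` frames become bound events. Frame gaps from
#' blinking count toward the event length (gap closing during linking
#' already asserts the molecule's continuity), and the displacement across
#' a gap is subject to the same threshold. Event duration is
#' `n_frames * cycle_dt`, so a 10-frame event at the 100 ms cycle lasts
#' exactly 1 s.
#'
#' @param tracks data.frame with columns `track_id`, `frame`, `x_um`,
#'   `y_um` (as returned by [link_localizations()]).
#' @param params a [binding_filter_params()].
#' @return data.frame of bound events: `track_id`, `start_frame`,
#'   `n_frames`, `duration_s`. May have zero rows.
#' @export
extract_bound_events <- function(tracks, params = binding_filter_params()) {
  stopifnot(inherits(params, "binding_filter_params"))
  cols <- c("track_id", "frame", "x_um", "y_um")
  stopifnot(all(cols %in% names(tracks)))
  empty <- data.frame(track_id = integer(), start_frame = integer(),
                      n_frames = integer(), duration_s = numeric())
  if (nrow(tracks) == 0L) return(empty)
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  # steps between successive detections of the same track
  same <- diff(tracks$track_id) == 0L
  d <- sqrt(diff(tracks$x_um)^2 + diff(tracks$y_um)^2)
  ok <- same & d < params$r_max
  # maximal runs of below-threshold steps (runs never span tracks because
  # cross-track steps have ok = FALSE)
  r <- rle(c(ok, FALSE))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) return(empty)
  i0 <- starts[runs]            # first step index: detections i0 .. ends+1
  i1 <- ends[runs] + 1L
  nf <- tracks$frame[i1] - tracks$frame[i0] + 1L  # blink gaps count as bound
  keep <- nf >= params$min_bound_frames
  if (!any(keep)) return(empty)
  out <- data.frame(track_id = tracks$track_id[i0[keep]],
                    start_frame = tracks$frame[i0[keep]],
                    n_frames = as.integer(nf[keep]),
                    duration_s = nf[keep] * params$cycle_dt)
  rownames(out) <- NULL
  out
}

#' Empirical survival (1-CDF) curve of bound durations
#'
#' Computes the survival probability S(t) = fraction of events with duration
#' at least t, evaluated on the sorted unique duration grid. By
#' construction, S at the minimum observed duration is 1.
#'
#' @param events data.frame with a `duration_s` column (from
#'   [extract_bound_events()]), or a numeric vector of durations.
#' @return An object of class `survival_curve` with fields `times`,
#'   `survival` and `n_events`.
#' @export
survival_curve <- function(events) {
  durations <- if (is.data.frame(events)) events$duration_s else events
  durations <- as.numeric(durations)
  if (length(durations) < 1L || anyNA(durations)) {
    stop("at least one event with a finite duration is required",
         call. = FALSE)
  }
  times <- sort(unique(durations))
  n <- length(durations)
  # fraction of events with duration >= t
  surv <- vapply(times, function(t) sum(durations >= t) / n, numeric(1))
  structure(list(times = times, survival = surv, n_events = n),
            class = "survival_curve")
}

#' Photobleaching correction of a survival curve
#'
#' Divides the target survival curve pointwise by the survival curve of an
#' immobile control imaged under identical conditions; apparent track
#' termination caused by fluorophore bleaching then cancels and the
#' remaining decay reflects unbinding. The control is interpolated
#' log-linearly onto the target grid, the ratio is restricted to times
#' where the control survival is at least `control_floor` (division
#' blow-up control), and the corrected curve is renormalized so its first
#' point is 1 and projected onto the non-increasing cone (it estimates a
#' survival function; sampling noise in the ratio can otherwise blip
#' upward).
#'
#' @param target,control `survival_curve` objects.
#' @param control_floor minimum control survival used (default 0.05).
#' @return A corrected `survival_curve` on the (possibly truncated) target
#'   grid.
#' @export
correct_photobleaching <- function(target, control, control_floor = 0.05) {
  stopifnot(inherits(target, "survival_curve"),
            inherits(control, "survival_curve"))
  .check_number(control_floor, "control_floor", lower = 0, upper = 1)
  tt <- target$times
  if (max(tt) > max(control$times)) {
    warning("control curve shorter than target range; truncating target")
    tt <- tt[tt <= max(control$times)]
  }
  keep <- tt >= min(control$times)
  tt <- tt[keep]
  if (!length(tt)) stop("no overlap between target and control grids",
                        call. = FALSE)
  log_ctrl <- stats::approx(control$times, log(control$survival), xout = tt,
                            rule = 2)$y
  ctrl <- exp(log_ctrl)
  ok <- ctrl >= control_floor
  tt <- tt[ok]
  corr <- target$survival[match(tt, target$times)] / ctrl[ok]
  if (!length(tt)) stop("control survival below floor over the whole grid",
                        call. = FALSE)
  corr <- corr / corr[1L]
  # the corrected curve estimates a survival function: project onto the
  # non-increasing cone (sampling noise in the ratio can blip upward)
  corr <- cummin(corr)
  structure(list(times = tt, survival = corr, n_events = target$n_events),
            class = "survival_curve")
}

# Deterministic multistart list of lifetime k-tuples, log-spaced over the
# curve's time range.
#' @keywords internal
.lifetime_starts <- function(times, k, n_starts) {
  lo <- max(min(times) / 4, 1e-6)
  hi <- max(times) * 2
  if (k == 1L) {
    taus <- exp(seq(log(lo), log(hi), length.out = n_starts))
    return(lapply(taus, function(t) t))
  }
  g <- exp(seq(log(lo), log(hi), length.out = max(4L, ceiling(sqrt(2 * n_starts)) + 1L)))
  pairs <- t(utils::combn(g, 2L))
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  idx <- round(seq(1L, nrow(pairs), length.out = min(n_starts, nrow(pairs))))
  lapply(unique(idx), function(i) pairs[i, ])
}

#' Fit a multi-exponential decay to a survival curve
#'
#' Unweighted nonlinear least squares of
#' \eqn{y(t) = \sum_i A_i e^{-t/t_i}} to the survival values on the
#' empirical grid (one point per unique duration), mirroring fitting of
#' exported 1-CDF tables. Amplitudes are unconstrained; reported
#' fractions are the normalized amplitudes \eqn{A_i / \sum_j A_j}, which for
#' a curve renormalized at a truncation time recover the untruncated mixture
#' weights. Initialization uses a deterministic multistart list of
#' log-spaced lifetimes; the best residual sum of squares is kept.
#'
#' @param curve a `survival_curve`.
#' @param n_components 1 or 2.
#' @param n_starts number of multistart initializations (default 20).
#' @return An object of class `exp_fit` with fields `n_components`,
#'   `fractions`, `lifetimes` (ascending, s), `amplitudes`, `rss`,
#'   `n_points`, `n_params`, `param_se` (SE of each lifetime, from the
#'   Jacobian), `converged`.
#' @export
fit_exponential_survival <- function(curve, n_components = 2, n_starts = 20) {
  stopifnot(inherits(curve, "survival_curve"))
  k <- .check_count(n_components, "n_components", lower = 1)
  if (k > 2L) stop("only 1 or 2 components are supported", call. = FALSE)
  tt <- curve$times
  yy <- curve$survival
  n_params <- 2L * k
  if (length(tt) < 2L * n_params) {
    stop("need at least ", 2L * n_params, " distinct time points",
         call. = FALSE)
  }
  # amplitudes free (unconstrained sign, as in standard curve-fitting
  # software); lifetimes positive via log parameterization
  model <- function(par) {
    A <- par[seq_len(k)]
    tau <- exp(par[k + seq_len(k)])
    rowSums(vapply(seq_len(k),
                   function(i) A[i] * exp(-tt / tau[i]), numeric(length(tt))))
  }
  resid_fn <- function(par) model(par) - yy
  best <- NULL
  for (tau0 in .lifetime_starts(tt, k, n_starts)) {
    par0 <- c(rep(1 / k, k), log(tau0))
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("exponential fit failed to converge from any start", call. = FALSE)
  }
  par <- best$fit$par
  A <- par[seq_len(k)]
  tau <- exp(par[k + seq_len(k)])
  ord <- order(tau)
  A <- A[ord]
  tau <- tau[ord]
  # SEs via the Jacobian at the optimum (delta method for the log params)
  se_tau <- rep(NA_real_, k)
  cov <- tryCatch({
    dof <- length(tt) - n_params
    s2 <- best$rss / max(dof, 1L)
    s2 * solve(best$fit$hessian / 2)
  }, error = function(e) NULL)
  if (!is.null(cov)) {
    se_log_tau <- sqrt(pmax(diag(cov)[k + seq_len(k)], 0))
    se_tau <- (exp(par[k + seq_len(k)]) * se_log_tau)[ord]
  }
  structure(list(n_components = k,
                 fractions = A / sum(A),
                 lifetimes = tau,
                 amplitudes = A,
                 rss = best$rss,
                 n_points = length(tt),
                 n_params = n_params,
                 param_se = se_tau,
                 converged = TRUE),
            class = "exp_fit")
}

#' F-test comparison of nested exponential fits
#'
#' Compares a mono-exponential fit (2 parameters) against a bi-exponential
#' fit (4 parameters) of the same survival curve:
#' \deqn{F = \frac{(RSS_1 - RSS_2)/(p_2 - p_1)}{RSS_2/(n - p_2)}}
#' with the p-value from the F distribution on (p2 - p1, n - p2) degrees of
#' freedom. The richer model is preferred when p < `alpha`. If the richer
#' model somehow has the larger RSS (which multistart fitting excludes in
#' practice), the simpler model is preferred.
#'
#' @param fit1,fit2 `exp_fit` objects for the same curve, `fit1` nested in
#'   `fit2`.
#' @param alpha significance level (default 0.05).
#' @return An object of class `f_test` with fields `F`, `df_num`, `df_den`,
#'   `p_value`, `preferred` (1 or 2).
#' @export
compare_models_ftest <- function(fit1, fit2, alpha = 0.05) {
  stopifnot(inherits(fit1, "exp_fit"), inherits(fit2, "exp_fit"))
  .check_number(alpha, "alpha", lower = 0, upper = 1)
  if (fit1$n_points != fit2$n_points) {
    stop("fits must come from the same curve", call. = FALSE)
  }
  n <- fit2$n_points
  p1 <- fit1$n_params
  p2 <- fit2$n_params
  if (p2 <= p1) stop("fit1 must be nested in fit2", call. = FALSE)
  # an RSS improvement at machine precision is a tie, not evidence
  if (fit2$rss > fit1$rss ||
      fit1$rss - fit2$rss <= 1e-12 * (1 + fit1$rss)) {
    return(structure(list(F = 0, df_num = p2 - p1, df_den = n - p2,
                          p_value = 1, preferred = 1L), class = "f_test"))
  }
  Fs <- ((fit1$rss - fit2$rss) / (p2 - p1)) / (fit2$rss / (n - p2))
  p <- stats::pf(Fs, p2 - p1, n - p2, lower.tail = FALSE)
  structure(list(F = Fs, df_num = p2 - p1, df_den = n - p2,
                 p_value = p, preferred = if (p < alpha) 2L else 1L),
            class = "f_test")
}

#' Full residence-time analysis of a tracked data set
#'
#' Composes the residence pipeline: bound events are extracted from target
#' and control tracks with the same spatiotemporal filter, survival curves
#' built, the target curve corrected for photobleaching by division with
#' the control (immobile molecules imaged identically), and mono- and
#' bi-exponential models fitted and compared with an F-test.
#'
#' @param tracks target track table ([link_localizations()] format).
#' @param control_tracks immobile-control track table.
#' @param params a [binding_filter_params()].
#' @param alpha F-test significance level.
#' @param n_starts multistart size passed to [fit_exponential_survival()].
#' @return A list of class `kinetic_summary` with the corrected curve, both
#'   fits, the F-test, the chosen model and the headline quantities
#'   `t_fast`, `t_slow` (s), `frac_fast`, `frac_slow` and `k_off`
#'   (1/`t_slow` of the chosen model).
#' @export
estimate_binding_times <- function(tracks, control_tracks,
                                   params = binding_filter_params(),
                                   alpha = 0.05, n_starts = 20) {
  ev_t <- extract_bound_events(tracks, params)
  ev_c <- extract_bound_events(control_tracks, params)
  if (nrow(ev_t) == 0L) stop("no bound events in target tracks",
                             call. = FALSE)
  if (nrow(ev_c) == 0L) stop("no bound events in control tracks",
                             call. = FALSE)
  surv_t <- survival_curve(ev_t)
  surv_c <- survival_curve(ev_c)
  corrected <- correct_photobleaching(surv_t, surv_c)
  fit1 <- fit_exponential_survival(corrected, 1, n_starts = n_starts)
  fit2 <- fit_exponential_survival(corrected, 2, n_starts = n_starts)
  ft <- compare_models_ftest(fit1, fit2, alpha = alpha)
  chosen <- if (ft$preferred == 2L) fit2 else fit1
  if (chosen$n_components == 2L) {
    t_fast <- chosen$lifetimes[1L]
    t_slow <- chosen$lifetimes[2L]
    frac_fast <- chosen$fractions[1L]
    frac_slow <- chosen$fractions[2L]
  } else {
    t_fast <- chosen$lifetimes[1L]
    t_slow <- chosen$lifetimes[1L]
    frac_fast <- 1
    frac_slow <- 0
  }
  structure(list(n_events = surv_t$n_events,
                 n_control_events = surv_c$n_events,
                 survival_target = surv_t,
                 survival_control = surv_c,
                 survival_corrected = corrected,
                 fit_mono = fit1, fit_bi = fit2, f_test = ft,
                 chosen_model = ft$preferred,
                 t_fast = t_fast, t_slow = t_slow,
                 frac_fast = frac_fast, frac_slow = frac_slow,
                 k_off = 1 / t_slow),
            class = "kinetic_summary")
}
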