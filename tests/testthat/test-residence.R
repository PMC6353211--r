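# Residence-time analysis: event extraction, survival curves,
# photobleaching correction, exponential fitting and model selection.

test_that("an immobile 10-frame track yields one 1-second event", {
  tr <- data.frame(track_id = 1L, frame = 0:9, x_um = 1, y_um = 1)
  ev <- extract_bound_events(tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_frames, 10L)
  expect_equal(ev$duration_s, 1.0)
})

test_that("a large internal displacement splits a run", {
  x <- c(rep(1, 8), rep(1.5, 8))  # 0.5 um jump in the middle
  tr <- data.frame(track_id = 1L, frame = 0:15, x_um = x, y_um = 1)
  expect_equal(nrow(extract_bound_events(tr)), 0L)  # halves < 10 frames
  x2 <- c(rep(1, 12), rep(1.5, 12))
  tr2 <- data.frame(track_id = 1L, frame = 0:23, x_um = x2, y_um = 1)
  ev <- extract_bound_events(tr2)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$n_frames, c(12L, 12L))
})

test_that("blink gaps inside a bound run count toward its length", {
  frames <- c(0:3, 6:11)  # 2 missed frames bridged by gap closing
  tr <- data.frame(track_id = 1L, frame = frames, x_um = 1, y_um = 1)
  ev <- extract_bound_events(tr)
  expect_equal(ev$n_frames, 12L)
  expect_equal(ev$duration_s, 1.2)
})

test_that("simulator truth events are recovered through the track filter", {
  cfg <- smt_sim_config(n_molecules = 600, frac_bound = 1, t_fast = 0.53,
                        t_slow = 4.13, frac_slow_bound = 0.3,
                        p_bleach = 0.002, p_blink = 0, seed = 31)
  s <- simulate_tracks(cfg)
  ev <- extract_bound_events(tracks_from_truth(s$localizations))
  # truth events observable for >= 10 frames before bleach/movie end
  truth_frames <- pmin(ceiling(s$events$t_true_s / 0.1), cfg$n_frames)
  expect_gt(nrow(ev) / sum(truth_frames >= 10), 0.9)
  # durations match the discretized truth for matched molecules
  m <- match(ev$track_id, s$events$event_id)
  ok <- !is.na(m) & truth_frames[m] < cfg$n_frames
  err_frames <- abs(ev$n_frames[ok] - truth_frames[m][ok])
  expect_gte(mean(err_frames <= 1), 0.9)
})

test_that("survival curves follow the direct count definition", {
  sc <- survival_curve(c(1, 1, 2, 4))
  expect_equal(sc$times, c(1, 2, 4))
  expect_equal(sc$survival, c(1, 0.5, 0.25))
  expect_equal(sc$n_events, 4L)
  one <- survival_curve(rep(2.5, 7))
  expect_equal(one$times, 2.5)
  expect_equal(one$survival, 1)
  expect_error(survival_curve(numeric()), "at least one")
})

test_that("log-survival slope recovers an exponential rate", {
  set.seed(32)
  sc <- survival_curve(rexp(1e4, rate = 0.5))
  keep <- sc$survival > 0.01
  slope <- coef(lm(log(sc$survival[keep]) ~ sc$times[keep]))[2]
  expect_lt(abs(-slope - 0.5) / 0.5, 0.05)
})

test_that("photobleaching correction has its closed-form limits", {
  tt <- seq(0.1, 20, by = 0.1)
  mk <- function(s) structure(list(times = tt, survival = s,
                                   n_events = 100L),
                              class = "survival_curve")
  tgt <- mk(exp(-tt / 4) * exp(-0.2 * tt))
  ctl <- mk(exp(-0.2 * tt))
  corr <- correct_photobleaching(tgt, ctl)
  expect_lt(max(abs(corr$survival -
                      exp(-(corr$times - corr$times[1]) / 4))), 1e-9)
  # control identical to target: constant 1
  same <- correct_photobleaching(tgt, tgt)
  expect_lt(max(abs(same$survival - 1)), 1e-12)
  # no bleaching: correction is the identity (after renormalization at t1)
  flat <- mk(rep(1, length(tt)))
  ident <- correct_photobleaching(tgt, flat)
  expect_equal(ident$survival, tgt$survival / tgt$survival[1],
               tolerance = 1e-12)
  # correction preserves monotonicity and S(t1) = 1
  expect_true(all(diff(corr$survival) <= 1e-12))
  expect_equal(corr$survival[1], 1)
})

test_that("correction truncates at the control floor and range", {
  tt <- seq(1, 30, by = 0.5)
  mk <- function(times, s) structure(list(times = times, survival = s,
                                          n_events = 50L),
                                     class = "survival_curve")
  tgt <- mk(tt, exp(-tt / 10))
  ctl <- mk(tt, exp(-tt / 5))            # drops below 0.05 at t = 15
  corr <- correct_photobleaching(tgt, ctl)
  expect_lte(max(corr$times), 5 * log(1 / 0.05) + 1e-9)
  short <- mk(seq(1, 10, by = 0.5), exp(-seq(1, 10, by = 0.5) / 50))
  expect_warning(correct_photobleaching(tgt, short), "truncating")
})

test_that("noiseless exponential fits are exact", {
  tt <- seq(0.1, 15, by = 0.1)
  mono <- structure(list(times = tt, survival = exp(-tt / 2),
                         n_events = 100L), class = "survival_curve")
  f <- fit_exponential_survival(mono, 1)
  expect_equal(f$lifetimes, 2, tolerance = 1e-6)
  expect_equal(f$fractions, 1)
  expect_lt(f$rss, 1e-12)
})

test_that("the two-class dwell mixture is recovered to 1 percent", {
  tt <- seq(0.1, 30, by = 0.1)
  y <- 0.957 * exp(-tt / 0.53) + 0.043 * exp(-tt / 4.13)
  cv <- structure(list(times = tt, survival = y, n_events = 1000L),
                  class = "survival_curve")
  f <- fit_exponential_survival(cv, 2)
  expect_lt(abs(f$lifetimes[1] - 0.53) / 0.53, 0.01)
  expect_lt(abs(f$lifetimes[2] - 4.13) / 4.13, 0.01)
  expect_equal(f$fractions, c(0.957, 0.043), tolerance = 1e-4)
  expect_equal(sum(f$fractions), 1, tolerance = 1e-12)
})

test_that("the fit matches an independent grid-search oracle", {
  set.seed(33)
  sc <- survival_curve(round(rexp(2000, 1 / 1.7), 1) + 0.1)
  f <- fit_exponential_survival(sc, 1)
  o <- oracle_grid_exp_fit(sc, 1)
  # optimum at least as good as the grid, and lifetime within grid spacing
  expect_lte(f$rss, o$rss + 1e-9)
  expect_lt(abs(log(f$lifetimes) - log(o$tau)), 0.2)
})

test_that("fitting is scale-equivariant in time", {
  set.seed(34)
  d <- rexp(3000, 1 / 2.2)
  f1 <- fit_exponential_survival(survival_curve(d), 1)
  f2 <- fit_exponential_survival(survival_curve(3 * d), 1)
  expect_equal(f2$lifetimes, 3 * f1$lifetimes, tolerance = 1e-4)
})

test_that("F-test handles the trivial and degenerate cases", {
  mkfit <- function(rss, p) structure(list(rss = rss, n_params = p,
                                           n_points = 100L),
                                      class = "exp_fit")
  eq <- compare_models_ftest(mkfit(1.0, 2L), mkfit(1.0, 4L))
  expect_equal(eq$F, 0)
  expect_equal(eq$p_value, 1)
  expect_equal(eq$preferred, 1L)
  worse <- compare_models_ftest(mkfit(1.0, 2L), mkfit(1.1, 4L))
  expect_equal(worse$preferred, 1L)
  better <- compare_models_ftest(mkfit(1.0, 2L), mkfit(0.2, 4L))
  expect_equal(better$preferred, 2L)
  expect_equal(better$F, ((1 - 0.2) / 2) / (0.2 / 96), tolerance = 1e-12)
})

test_that("a strong two-class signal always selects the richer model", {
  set.seed(35)
  tgrid <- seq(0.1, 12, by = 0.1)
  picks <- replicate(40, {
    y <- 0.957 * exp(-tgrid / 0.53) + 0.043 * exp(-tgrid / 4.13) +
      rnorm(length(tgrid), 0, 0.005)
    cv <- structure(list(times = tgrid, survival = y, n_events = 10000L),
                    class = "survival_curve")
    compare_models_ftest(fit_exponential_survival(cv, 1, n_starts = 8),
                         fit_exponential_survival(cv, 2, n_starts = 8))$preferred
  })
  expect_gte(mean(picks == 2L), 0.99)
})

test_that("median recovery error stays within bounds over replicates", {
  set.seed(36)
  errs <- t(replicate(50, {
    ev <- sample_durations(20000, 0.043, 0.53, 4.13)
    evc <- sample_control_durations(20000)
    cc <- correct_photobleaching(survival_curve(ev), survival_curve(evc))
    f <- fit_exponential_survival(cc, 2, n_starts = 10)
    c(t = abs(f$lifetimes[2] - 4.13) / 4.13,
      fr = abs(f$fractions[2] - 0.043) / 0.043)
  }))
  expect_lte(median(errs[, "t"]), 0.15)
  expect_lte(median(errs[, "fr"]), 0.30)
})

test_that("control as its own target gives a flat curve and one component", {
  cfg <- smt_sim_config(n_molecules = 4000, frac_bound = 1, t_fast = Inf,
                        t_slow = Inf, p_bleach = 0.01, p_blink = 0.02,
                        seed = 38)
  trc <- tracks_from_truth(simulate_tracks(cfg)$localizations)
  ks <- estimate_binding_times(trc, trc)
  expect_lt(max(abs(ks$survival_corrected$survival - 1)), 1e-12)
  expect_equal(ks$chosen_model, 1L)
  # the uncorrected control decay reflects the photobleaching rate
  ctl_fit <- fit_exponential_survival(ks$survival_control, 1)
  expect_lt(abs(ctl_fit$lifetimes - 0.1 / (-log(1 - 0.01))) /
              (0.1 / (-log(1 - 0.01))), 0.1)
})

test_that("a 99 percent short-lived population yields a small slow share", {
  set.seed(40)
  ev <- sample_durations(40000, 0.01, 0.43, 9.39)
  evc <- sample_control_durations(30000)
  cc <- correct_photobleaching(survival_curve(ev), survival_curve(evc))
  f <- fit_exponential_survival(cc, 2)
  expect_lte(f$fractions[2], 0.05)
  expect_lt(abs(f$lifetimes[1] - 0.43) / 0.43, 0.15)
})
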