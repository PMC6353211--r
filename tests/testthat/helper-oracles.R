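# Independent oracles used to cross-check the package's fitted or computed
# quantities. These deliberately use brute force / enumeration / closed
# forms, never the implementation they verify.

# coarse grid search for the best (A1, tau1[, A2, tau2]) exponential fit of
# a survival curve; returns the best rss and parameters on the grid
oracle_grid_exp_fit <- function(curve, n_components,
                                taus = exp(seq(log(0.1), log(20),
                                               length.out = 40)),
                                amps = seq(0, 1.2, by = 0.05)) {
  tt <- curve$times
  yy <- curve$survival
  best <- list(rss = Inf)
  if (n_components == 1L) {
    for (tau in taus) {
      e <- exp(-tt / tau)
      for (A in amps) {
        rss <- sum((A * e - yy)^2)
        if (rss < best$rss) best <- list(rss = rss, A = A, tau = tau)
      }
    }
  } else {
    for (i in seq_along(taus)) {
      e1 <- exp(-tt / taus[i])
      for (j in seq_along(taus)) {
        if (j <= i) next
        e2 <- exp(-tt / taus[j])
        for (A1 in amps) {
          r <- yy - A1 * e1
          # best A2 given the rest is linear least squares (1D)
          A2 <- sum(r * e2) / sum(e2^2)
          rss <- sum((r - A2 * e2)^2)
          if (rss < best$rss) {
            best <- list(rss = rss, A = c(A1, A2), tau = taus[c(i, j)])
          }
        }
      }
    }
  }
  best
}

# all-pairs interval overlap scan (0-based half-open, strand-aware window)
oracle_overlap <- function(genes, peaks, pad = 2000) {
  hit <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    ws <- if (genes$strand[i] == "+") max(genes$start[i] - pad, 0)
          else genes$start[i]
    we <- if (genes$strand[i] == "+") genes$end[i] else genes$end[i] + pad
    for (j in seq_len(nrow(peaks))) {
      if (genes$chrom[i] == peaks$chrom[j] &&
          ws < peaks$end[j] && peaks$start[j] < we) {
        hit[i] <- TRUE
        break
      }
    }
  }
  genes$gene_id[hit]
}

# dense-grid location of the half-recovery root
oracle_root_grid <- function(I1, I2, tau1, tau2, step = 1e-5) {
  g <- function(t) I1 * (0.5 - exp(-t / tau1)) + I2 * (0.5 - exp(-t / tau2))
  tg <- seq(0, 20 * max(tau1, tau2), by = step)
  i <- which(g(tg) > 0)[1L]
  tg[i]
}

# exhaustive minimum-cost assignment by permutation enumeration
oracle_lap <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    val <- sum(cost[cbind(seq_len(n), p)])
    if (val < best) best <- val
  }
  best
}

# duration-level generator mirroring the stroboscopic experiment: two-class
# exponential dwells discretized to camera cycles, truncated by per-exposure
# bleaching and the movie length; used where track-level detail is not
# under test
sample_durations <- function(n, frac_slow, t_fast, t_slow,
                             p_bleach = 0.01, dt = 0.1, n_frames = 300,
                             min_frames = 10) {
  slow <- stats::runif(n) < frac_slow
  T <- stats::rexp(n) * ifelse(slow, t_slow, t_fast)
  nfr <- pmin(ceiling(T / dt), stats::rgeom(n, p_bleach) + 1L, n_frames)
  nfr[nfr >= min_frames] * dt
}

sample_control_durations <- function(n, p_bleach = 0.01, dt = 0.1,
                                     n_frames = 300, min_frames = 10) {
  nfr <- pmin(stats::rgeom(n, p_bleach) + 1L, n_frames)
  nfr[nfr >= min_frames] * dt
}

# fraction of links in a linked track table that connect detections of the
# same ground-truth molecule
link_truth_agreement <- function(linked, localizations) {
  key <- paste(localizations$frame, round(localizations$x_um, 7),
               round(localizations$y_um, 7))
  truth <- localizations$track_truth_id[
    match(paste(linked$frame, round(linked$x_um, 7),
                round(linked$y_um, 7)), key)]
  agree <- 0L
  tot <- 0L
  for (tid in unique(linked$track_id)) {
    m <- truth[linked$track_id == tid]
    if (length(m) > 1L) {
      tot <- tot + length(m) - 1L
      agree <- agree + sum(diff(m) == 0L)
    }
  }
  c(agree = agree, total = tot)
}
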