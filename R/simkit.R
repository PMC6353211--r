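# Seeded simulators for single-molecule trajectories, FRAP recovery curves
# and negative-binomial count matrices. These generators reproduce the
# statistical structure that the downstream analyses assume, so that every
# stage of the pipeline can be validated by parameter recovery.

#' Configuration for the single-molecule trajectory simulator
#'
#' Describes a population of fluorophore-labelled molecules diffusing in a
#' square nuclear region and imaged stroboscopically: short laser exposures
#' of `t_int` seconds separated by dark gaps of `t_gap` seconds, so one
#' camera cycle lasts `t_int + t_gap` seconds. Molecules are either
#' chromatin-bound (diffusing slowly with `D_bound`, emulating chromatin
#' motion), slowly diffusing, or freely diffusing. Bound molecules unbind
#' after an exponential dwell whose mean is `t_fast` or `t_slow`; the
#' long-lived class is drawn once per binding event with probability
#' `frac_slow_bound`. Each visible exposure can permanently photobleach the
#' fluorophore (probability `p_bleach`) or send it into a transient dark
#' state (probability `p_blink`, at most `max_blink` consecutive dark
#' frames). Localizations carry isotropic Gaussian noise of `sigma_loc`
#' micrometres per axis.
#'
#' Defaults correspond to the slow-movie acquisition used for residence-time
#' measurements (5 ms exposure, 95 ms gap, 300-frame stacks, 18.56 um field)
#' with wild-type-like two-class binding kinetics.
#'
#' @param n_molecules number of molecules.
#' @param nucleus_size side of the square nuclear region, um.
#' @param D_bound,D_slow,D_free diffusion coefficients, um^2/s.
#' @param frac_bound,frac_slow,frac_free initial state probabilities; must
#'   sum to 1.
#' @param t_fast,t_slow mean dwell of the short- and long-lived bound
#'   classes, s. `Inf` means no unbinding.
#' @param frac_slow_bound probability that a binding event is long-lived.
#' @param p_bleach per-exposure probability of permanent photobleaching.
#' @param p_blink per-exposure probability of entering a dark state.
#' @param max_blink maximum number of consecutive dark frames.
#' @param sigma_loc localization noise SD per axis, um.
#' @param t_int,t_gap exposure and gap time, s.
#' @param n_frames number of camera cycles.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `smt_sim_config`.
#' @seealso [simulate_tracks()]
#' @export
smt_sim_config <- function(n_molecules = 200,
                           nucleus_size = 18.56,
                           D_bound = 0.04,
                           D_slow = 0.5,
                           D_free = 5,
                           frac_bound = 1,
                           frac_slow = 0,
                           frac_free = 0,
                           t_fast = 0.53,
                           t_slow = 4.13,
                           frac_slow_bound = 0.043,
                           p_bleach = 0.01,
                           p_blink = 0.02,
                           max_blink = 3,
                           sigma_loc = 0.03,
                           t_int = 0.005,
                           t_gap = 0.095,
                           n_frames = 300,
                           seed = NULL) {
  .check_count(n_molecules, "n_molecules", lower = 1)
  .check_number(nucleus_size, "nucleus_size", lower = 1e-6)
  .check_number(D_bound, "D_bound", lower = 0)
  .check_number(D_slow, "D_slow", lower = 0)
  .check_number(D_free, "D_free", lower = 0)
  .check_number(frac_bound, "frac_bound", 0, 1)
  .check_number(frac_slow, "frac_slow", 0, 1)
  .check_number(frac_free, "frac_free", 0, 1)
  if (abs(frac_bound + frac_slow + frac_free - 1) > 1e-8) {
    stop("frac_bound + frac_slow + frac_free must equal 1", call. = FALSE)
  }
  .check_number(t_fast, "t_fast", lower = 0, allow_inf = TRUE)
  .check_number(t_slow, "t_slow", lower = 0, allow_inf = TRUE)
  .check_number(frac_slow_bound, "frac_slow_bound", 0, 1)
  .check_number(p_bleach, "p_bleach", 0, 1)
  .check_number(p_blink, "p_blink", 0, 1)
  .check_count(max_blink, "max_blink", lower = 0)
  .check_number(sigma_loc, "sigma_loc", lower = 0)
  .check_number(t_int, "t_int", lower = 0)
  .check_number(t_gap, "t_gap", lower = 0)
  if (t_int + t_gap <= 0) stop("frame cycle t_int + t_gap must be > 0",
                               call. = FALSE)
  .check_count(n_frames, "n_frames", lower = 2)
  structure(list(n_molecules = as.integer(n_molecules),
                 nucleus_size = nucleus_size,
                 D_bound = D_bound, D_slow = D_slow, D_free = D_free,
                 frac_bound = frac_bound, frac_slow = frac_slow,
                 frac_free = frac_free,
                 t_fast = t_fast, t_slow = t_slow,
                 frac_slow_bound = frac_slow_bound,
                 p_bleach = p_bleach, p_blink = p_blink,
                 max_blink = as.integer(max_blink),
                 sigma_loc = sigma_loc,
                 t_int = t_int, t_gap = t_gap,
                 n_frames = as.integer(n_frames),
                 seed = seed),
            class = "smt_sim_config")
}

# Visible-exposure mask for one molecule: blink initiations are drawn per
# exposure; a blink darkens up to max_blink consecutive frames. Bleaching
# consumes one geometric "budget" unit per *visible* exposure (a dark
# fluorophore absorbs no light).
#' @keywords internal
.visibility_mask <- function(n_frames, p_bleach, p_blink, max_blink) {
  dark <- rep(FALSE, n_frames)
  if (p_blink > 0 && max_blink > 0) {
    starts <- which(stats::runif(n_frames) < p_blink)
    lens <- sample.int(max_blink, length(starts), replace = TRUE)
    dark_end <- -2L
    for (i in seq_along(starts)) {
      s <- starts[i]
      # a blink can only start from the emitting state, and never merges
      # with a previous one: dark runs are at most max_blink frames
      if (s <= dark_end + 1L) next
      dark_end <- min(n_frames, s + lens[i] - 1L)
      dark[s:dark_end] <- TRUE
    }
  }
  vis <- !dark
  if (p_bleach > 0) {
    budget <- stats::rgeom(1L, p_bleach) + 1L  # visible exposures before bleach
    vis[cumsum(vis) > budget] <- FALSE
  }
  vis
}

#' Simulate stroboscopic single-molecule trajectories
#'
#' Forward model for the residence-time and displacement analyses. Each
#' molecule performs a 2D Brownian walk whose diffusion coefficient depends
#' on its kinetic state, sampled at camera-cycle intervals (the short
#' exposure is treated as instantaneous; motion blur is ignored). Bound
#' molecules unbind after an exponential dwell and then diffuse freely.
#' Boundaries are reflecting. Photobleaching ends a trajectory permanently;
#' blinking hides a molecule for a bounded number of frames. All draws come
#' from one seeded generator stream.
#'
#' @param config an [smt_sim_config()].
#' @return A list with components:
#' \describe{
#'   \item{localizations}{data.frame with columns `frame` (0-based), `x_um`,
#'     `y_um`, `track_truth_id`, `state_truth` (one of `bound_fast`,
#'     `bound_slow`, `slow_diff`, `free`).}
#'   \item{events}{ground-truth binding events: `event_id`, `t_true_s`
#'     (the true exponential dwell, uncensored), `class` (`fast`/`slow`).}
#' }
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "smt_sim_config"))
  .set_seed_if(config$seed)
  n <- config$n_molecules
  nf <- config$n_frames
  L <- config$nucleus_size
  dt <- config$t_int + config$t_gap

  states0 <- sample(c("bound", "slow_diff", "free"), n, replace = TRUE,
                    prob = c(config$frac_bound, config$frac_slow,
                             config$frac_free))
  is_bound <- states0 == "bound"
  slow_class <- rep(FALSE, n)
  dwell <- rep(Inf, n)
  if (any(is_bound)) {
    slow_class[is_bound] <- stats::runif(sum(is_bound)) < config$frac_slow_bound
    mean_dwell <- ifelse(slow_class, config$t_slow, config$t_fast)
    dwell[is_bound] <- ifelse(is.finite(mean_dwell[is_bound]),
                              stats::rexp(sum(is_bound)) *
                                mean_dwell[is_bound], Inf)
  }

  frame_l <- vector("list", n)
  x_l <- vector("list", n)
  y_l <- vector("list", n)
  id_l <- vector("list", n)
  st_l <- vector("list", n)
  for (i in seq_len(n)) {
    # state per frame: bound until the dwell elapses, then free
    if (is_bound[i]) {
      n_bound <- min(nf, ceiling(dwell[i] / dt))
      state_i <- c(rep(if (slow_class[i]) "bound_slow" else "bound_fast",
                       n_bound), rep("free", nf - n_bound))
      D_i <- c(rep(config$D_bound, n_bound), rep(config$D_free, nf - n_bound))
    } else {
      state_i <- rep(states0[i], nf)
      D_i <- rep(if (states0[i] == "slow_diff") config$D_slow
                 else config$D_free, nf)
    }
    # Brownian steps; step k -> k+1 uses the state at frame k, except the
    # unbinding interval, whose variance mixes bound and free diffusion in
    # proportion to the time spent in each state
    sd_step <- sqrt(2 * D_i[-nf] * dt)
    if (is_bound[i] && is.finite(dwell[i])) {
      j <- min(nf, ceiling(dwell[i] / dt))    # interval containing T
      if (j < nf) {
        t_b <- dwell[i] - (j - 1) * dt
        sd_step[j] <- sqrt(2 * (config$D_bound * t_b +
                                  config$D_free * (dt - t_b)))
      }
    }
    x <- .reflect(stats::runif(1, 0, L) + cumsum(c(0, stats::rnorm(nf - 1) *
                                                     sd_step)), L)
    y <- .reflect(stats::runif(1, 0, L) + cumsum(c(0, stats::rnorm(nf - 1) *
                                                     sd_step)), L)
    vis <- .visibility_mask(nf, config$p_bleach, config$p_blink,
                            config$max_blink)
    if (!any(vis)) next
    idx <- which(vis)
    frame_l[[i]] <- idx - 1L
    x_l[[i]] <- x[idx] + stats::rnorm(length(idx)) * config$sigma_loc
    y_l[[i]] <- y[idx] + stats::rnorm(length(idx)) * config$sigma_loc
    id_l[[i]] <- rep.int(i, length(idx))
    st_l[[i]] <- state_i[idx]
  }
  fr <- unlist(frame_l)
  if (is.null(fr)) fr <- integer()
  locs <- data.frame(frame = fr,
                     x_um = as.numeric(unlist(x_l)),
                     y_um = as.numeric(unlist(y_l)),
                     track_truth_id = as.integer(unlist(id_l)),
                     state_truth = as.character(unlist(st_l)),
                     stringsAsFactors = FALSE)
  locs <- locs[order(locs$frame, locs$track_truth_id), , drop = FALSE]
  rownames(locs) <- NULL
  events <- data.frame(event_id = which(is_bound),
                       t_true_s = dwell[is_bound],
                       class = ifelse(slow_class[is_bound], "slow", "fast"),
                       stringsAsFactors = FALSE)
  list(localizations = locs, events = events)
}

#' Group simulated localizations into ground-truth tracks
#'
#' Bypasses the linking stage by using the simulator's `track_truth_id`,
#' yielding the track table format produced by [link_localizations()].
#'
#' @param localizations the `localizations` data.frame from
#'   [simulate_tracks()].
#' @return data.frame with columns `track_id`, `frame`, `x_um`, `y_um`.
#' @export
tracks_from_truth <- function(localizations) {
  stopifnot(all(c("frame", "x_um", "y_um", "track_truth_id") %in%
                  names(localizations)))
  out <- data.frame(track_id = localizations$track_truth_id,
                    frame = localizations$frame,
                    x_um = localizations$x_um,
                    y_um = localizations$y_um)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Configuration for the FRAP curve simulator
#'
#' Double-exponential recovery with amplitudes `I1`, `I2` and time constants
#' `tau1`, `tau2` (seconds), additive i.i.d. Gaussian noise, `n_pre`
#' pre-bleach frames at intensity 1 and `n_post` post-bleach frames spaced
#' `dt` seconds apart.
#'
#' @param I1,I2 normalized recovery amplitudes, `I1 + I2 <= 1`.
#' @param tau1,tau2 recovery time constants, s.
#' @param noise_sd SD of additive Gaussian noise (normalized intensity).
#' @param dt frame spacing, s.
#' @param n_pre,n_post numbers of pre- and post-bleach frames.
#' @param seed integer seed or `NULL`.
#' @return An object of class `frap_sim_config`.
#' @export
frap_sim_config <- function(I1 = 0.4, I2 = 0.4, tau1 = 0.3, tau2 = 3,
                            noise_sd = 0.01, dt = 0.069,
                            n_pre = 50, n_post = 500, seed = NULL) {
  .check_number(I1, "I1", lower = 0)
  .check_number(I2, "I2", lower = 0)
  if (I1 + I2 > 1 + 1e-12) stop("I1 + I2 must be <= 1", call. = FALSE)
  .check_number(tau1, "tau1", lower = 1e-12)
  .check_number(tau2, "tau2", lower = 1e-12)
  .check_number(noise_sd, "noise_sd", lower = 0)
  .check_number(dt, "dt", lower = 1e-12)
  .check_count(n_pre, "n_pre", lower = 1)
  .check_count(n_post, "n_post", lower = 2)
  structure(list(I1 = I1, I2 = I2, tau1 = tau1, tau2 = tau2,
                 noise_sd = noise_sd, dt = dt,
                 n_pre = as.integer(n_pre), n_post = as.integer(n_post),
                 seed = seed),
            class = "frap_sim_config")
}

#' Simulate a normalized FRAP recovery curve
#'
#' Pre-bleach frames sit at 1.0; post-bleach frames follow the
#' double-exponential recovery
#' \deqn{FRAP(t) = I_1 (1 - e^{-t/\tau_1}) + I_2 (1 - e^{-t/\tau_2})}
#' evaluated from \eqn{t = 0} at the first post-bleach frame, plus i.i.d.
#' Gaussian noise.
#'
#' @param config a [frap_sim_config()].
#' @return A `frap_curve` object (see [frap_curve()]); the pre-bleach frames
#'   are stored in its `pre` component.
#' @export
simulate_frap_curve <- function(config) {
  stopifnot(inherits(config, "frap_sim_config"))
  .set_seed_if(config$seed)
  t_post <- (seq_len(config$n_post) - 1) * config$dt
  clean <- config$I1 * (1 - exp(-t_post / config$tau1)) +
    config$I2 * (1 - exp(-t_post / config$tau2))
  noise <- if (config$noise_sd > 0)
    stats::rnorm(config$n_post + config$n_pre) * config$noise_sd
  else rep(0, config$n_post + config$n_pre)
  frap_curve(times = t_post,
             intensity = clean + noise[config$n_pre + seq_len(config$n_post)],
             pre_bleach_level = 1,
             pre = 1 + noise[seq_len(config$n_pre)])
}

#' Configuration for the count-matrix simulator
#'
#' Negative-binomial RNA-seq-like counts for a panel of transfection
#' conditions including a non-transfected reference `"NT"`, with
#' construct-specific log2 fold-change effects applied to a set of
#' differentially expressed (DE) genes, plus a matched gene annotation and
#' promoter-proximal peak intervals for a subset of the DE genes.
#'
#' @param n_genes total number of genes.
#' @param n_de_genes number of genes carrying condition effects.
#' @param n_peak_genes number of DE genes that receive a promoter peak;
#'   must satisfy `n_peak_genes <= n_de_genes <= n_genes`.
#' @param conditions character vector of condition labels; must include
#'   `"NT"`.
#' @param effects named numeric vector of per-condition log2FC effects on DE
#'   genes; the `"NT"` effect is forced to 0. Conditions absent from
#'   `effects` get 0.
#' @param n_reps replicates per condition.
#' @param dispersion negative-binomial dispersion (`size = 1/dispersion`).
#' @param lib_size expected library size per sample.
#' @param n_decoy_peaks intergenic peaks overlapping no gene window.
#' @param seed integer seed or `NULL`.
#' @return An object of class `counts_sim_config`.
#' @export
counts_sim_config <- function(n_genes = 2000, n_de_genes = 200,
                              n_peak_genes = 40,
                              conditions = c("NT", "WT"),
                              effects = c(WT = 1),
                              n_reps = 3, dispersion = 0.05,
                              lib_size = 1e6, n_decoy_peaks = 0,
                              seed = NULL) {
  .check_count(n_genes, "n_genes", lower = 1)
  .check_count(n_de_genes, "n_de_genes", lower = 0)
  .check_count(n_peak_genes, "n_peak_genes", lower = 0)
  if (!(n_peak_genes <= n_de_genes && n_de_genes <= n_genes)) {
    stop("need n_peak_genes <= n_de_genes <= n_genes", call. = FALSE)
  }
  if (!"NT" %in% conditions) stop("conditions must include 'NT'",
                                  call. = FALSE)
  .check_count(n_reps, "n_reps", lower = 1)
  .check_number(dispersion, "dispersion", lower = 1e-12)
  .check_number(lib_size, "lib_size", lower = 1)
  .check_count(n_decoy_peaks, "n_decoy_peaks", lower = 0)
  eff <- stats::setNames(rep(0, length(conditions)), conditions)
  eff[names(effects)[names(effects) %in% conditions]] <-
    effects[names(effects) %in% conditions]
  eff["NT"] <- 0
  structure(list(n_genes = as.integer(n_genes),
                 n_de_genes = as.integer(n_de_genes),
                 n_peak_genes = as.integer(n_peak_genes),
                 conditions = conditions, effects = eff,
                 n_reps = as.integer(n_reps), dispersion = dispersion,
                 lib_size = lib_size,
                 n_decoy_peaks = as.integer(n_decoy_peaks),
                 seed = seed),
            class = "counts_sim_config")
}

#' Simulate a count matrix with matched gene annotation and peaks
#'
#' Counts are negative binomial around gene baselines scaled to the library
#' size; DE genes get the per-condition log2FC effect. Genes are laid out on
#' a single chromosome with at least 10 kb spacing so that strand-extended
#' promoter windows never collide; each of the first `n_peak_genes` DE genes
#' receives one peak inside its strand-aware upstream 2 kb promoter pad.
#' Decoy peaks, if requested, fall midway between gene windows.
#'
#' @param config a [counts_sim_config()].
#' @return A list with `counts` (matrix genes x samples, columns named
#'   `<condition>_<rep>`), `conditions` (condition label per column),
#'   `genes` (BED-like data.frame: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`; 0-based half-open), `peaks` (BED3 data.frame), and `truth`
#'   (`gene_id`, `is_de`, `has_peak`, `log2fc_effect`).
#' @export
simulate_counts_and_peaks <- function(config) {
  stopifnot(inherits(config, "counts_sim_config"))
  .set_seed_if(config$seed)
  ng <- config$n_genes
  gene_id <- sprintf("gene%05d", seq_len(ng))
  # 10 kb slots, 3-5 kb gene bodies => 2 kb pads cannot reach a neighbour
  slot <- 10000L
  start <- (seq_len(ng) - 1L) * slot + 3000L
  width <- sample(3000:5000, ng, replace = TRUE)
  genes <- data.frame(gene_id = gene_id, chrom = "chr1",
                      start = start, end = start + width,
                      strand = sample(c("+", "-"), ng, replace = TRUE),
                      stringsAsFactors = FALSE)
  de_idx <- sort(sample.int(ng, config$n_de_genes))
  peak_idx <- if (config$n_peak_genes > 0) de_idx[seq_len(config$n_peak_genes)]
              else integer()
  peaks <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (length(peak_idx)) {
    up <- genes$strand[peak_idx] == "+"
    pstart <- ifelse(up, genes$start[peak_idx] - 1500L,
                     genes$end[peak_idx] + 1000L)
    peaks <- data.frame(chrom = "chr1", start = pstart, end = pstart + 500L,
                        stringsAsFactors = FALSE)
  }
  if (config$n_decoy_peaks > 0) {
    # slot layout: window of gene i spans at most [slot*i + 1000, slot*i + 10000)
    # in 0-based genome coords; [slot*i + 200, slot*i + 700) is always free
    d_idx <- sample.int(ng - 1L, min(config$n_decoy_peaks, ng - 1L))
    peaks <- rbind(peaks,
                   data.frame(chrom = "chr1",
                              start = d_idx * slot + 200L,
                              end = d_idx * slot + 700L,
                              stringsAsFactors = FALSE))
  }
  peaks <- peaks[order(peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL

  cond_per_col <- rep(config$conditions, each = config$n_reps)
  samples <- paste(cond_per_col,
                   rep(seq_len(config$n_reps), length(config$conditions)),
                   sep = "_")
  base <- 2 ^ stats::runif(ng, 2, 9)       # baseline expression, arbitrary units
  scale0 <- config$lib_size / sum(base)    # fixed scale: effects shift totals
  counts <- matrix(0L, nrow = ng, ncol = length(samples),
                   dimnames = list(gene_id, samples))
  for (j in seq_along(samples)) {
    eff_j <- config$effects[[cond_per_col[j]]]
    mu <- base
    mu[de_idx] <- mu[de_idx] * 2 ^ eff_j
    counts[, j] <- stats::rnbinom(ng, mu = mu * scale0,
                                  size = 1 / config$dispersion)
  }
  truth <- data.frame(gene_id = gene_id,
                      is_de = seq_len(ng) %in% de_idx,
                      has_peak = seq_len(ng) %in% peak_idx,
                      stringsAsFactors = FALSE)
  list(counts = counts, conditions = cond_per_col, genes = genes,
       peaks = peaks, truth = truth)
}
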