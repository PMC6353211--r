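# End-to-end orchestration. The package's functions are the primary
# interface; these helpers wire the standard analysis orders together,
# write the tabular/JSON reports, and make runs reproducible from a single
# seed.

#' Assemble a run configuration
#'
#' Bundles the stage configurations used by [run_smt()] and [run_all()].
#' Every stochastic stage derives its stream from `seed`, so identical
#' configurations produce identical outputs.
#'
#' @param seed global integer seed.
#' @param smt_slow [smt_sim_config()] for the slow-movie (residence-time)
#'   acquisition of the target molecule.
#' @param smt_control [smt_sim_config()] for the immobile control imaged
#'   identically (no unbinding).
#' @param smt_fast [smt_sim_config()] for the fast-movie (displacement)
#'   acquisition.
#' @param n_movies number of simulated movies (fields of view) per
#'   condition.
#' @param link [link_params()].
#' @param binding [binding_filter_params()].
#' @param frap [frap_sim_config()] or NULL to skip the FRAP stage.
#' @param counts [counts_sim_config()] or NULL to skip the expression
#'   stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       smt_slow = smt_sim_config(),
                       smt_control = smt_sim_config(t_fast = Inf,
                                                    t_slow = Inf),
                       smt_fast = smt_sim_config(
                         frac_bound = 0.21, frac_slow = 0.395,
                         frac_free = 0.395, t_fast = Inf, t_slow = Inf,
                         t_gap = 0.015, sigma_loc = 0),
                       n_movies = 10,
                       link = link_params(),
                       binding = binding_filter_params(),
                       frap = frap_sim_config(),
                       counts = counts_sim_config()) {
  .check_count(seed, "seed", lower = 0)
  .check_count(n_movies, "n_movies", lower = 1)
  structure(list(seed = as.integer(seed), smt_slow = smt_slow,
                 smt_control = smt_control, smt_fast = smt_fast,
                 n_movies = as.integer(n_movies), link = link,
                 binding = binding, frap = frap, counts = counts),
            class = "run_config")
}

# Simulate n_movies fields with a shared config (seed offsets keep movies
# independent but reproducible) and link each one.
#' @keywords internal
.simulate_and_link <- function(config, n_movies, link, seed0) {
  out <- vector("list", n_movies)
  offset <- 0L
  for (m in seq_len(n_movies)) {
    cfg <- config
    cfg$seed <- seed0 + m
    sim <- simulate_tracks(cfg)
    tr <- link_localizations(sim$localizations, link)
    if (nrow(tr)) tr$track_id <- tr$track_id + offset
    offset <- offset + if (nrow(tr)) max(tr$track_id) else 0L
    out[[m]] <- tr
  }
  do.call(rbind, out)
}

#' Run the single-molecule kinetic analysis end to end
#'
#' Simulates (or accepts) slow-movie target and control acquisitions plus a
#' fast-movie acquisition, links localizations, runs the residence-time
#' pipeline (spatiotemporal filter, survival curves, photobleaching
#' correction, exponential fits, F-test) and the single-step displacement
#' analysis (three-component mixture fit, bound fraction, k_on*), and
#' writes the combined kinetic summary.
#'
#' @param config a [run_config()].
#' @param out_dir output directory, created if missing; NULL to skip
#'   writing.
#' @return The kinetic summary list (invisibly if `out_dir` is set):
#'   residence results plus `BF`, `diffusivities` and `k_on_star`.
#' @export
run_smt <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  message("[smt] simulating + linking slow movies")
  tracks <- .simulate_and_link(config$smt_slow, config$n_movies,
                               config$link, config$seed * 1000L)
  control <- .simulate_and_link(config$smt_control, config$n_movies,
                                config$link, config$seed * 1000L + 500L)
  message("[smt] residence-time analysis")
  ks <- estimate_binding_times(tracks, control, config$binding)
  message("[smt] fast-movie displacement analysis")
  fast_cfg <- config$smt_fast
  fast_cfg$seed <- config$seed * 1000L + 900L
  sim_fast <- simulate_tracks(fast_cfg)
  fast_tracks <- link_localizations(sim_fast$localizations, config$link)
  ssd <- single_step_displacements(fast_tracks,
                                   dt = fast_cfg$t_int + fast_cfg$t_gap)
  dfit <- fit_diffusion_components(ssd, 3)
  BF <- bound_fraction(dfit)
  k_on_star <- if (BF < 1) compute_kon_star(BF, ks$k_off) else NA_real_
  summary <- list(chosen_model = ks$chosen_model,
                  t_fast = ks$t_fast, t_slow = ks$t_slow,
                  frac_fast = ks$frac_fast, frac_slow = ks$frac_slow,
                  k_off = ks$k_off, BF = BF, k_on_star = k_on_star,
                  diffusivities = dfit$diffusivities,
                  diffusion_fractions = dfit$fractions,
                  n_events = ks$n_events,
                  n_control_events = ks$n_control_events,
                  f_test_p = ks$f_test$p_value)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(time_s = ks$survival_corrected$times,
                                survival = ks$survival_corrected$survival,
                                n_events = ks$survival_corrected$n_events),
                     file.path(out_dir, "survival_corrected.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary,
                         file.path(out_dir, "kinetic_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(summary))
  }
  summary
}

#' Run every stage of the pipeline
#'
#' Executes simulate -> link -> residence -> displacement -> FRAP ->
#' expression classification, and writes a manifest recording the package
#' version and seed. Identical configuration and seed give identical
#' numeric outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (required).
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  smt <- run_smt(config, file.path(out_dir, "smt"))
  frap <- NULL
  if (!is.null(config$frap)) {
    message("[frap] simulating + fitting recovery curve")
    fcfg <- config$frap
    fcfg$seed <- config$seed * 1000L + 950L
    curve <- simulate_frap_curve(fcfg)
    ffit <- fit_frap(curve)
    frap <- list(I1 = ffit$I1, I2 = ffit$I2, tau1 = ffit$tau1,
                 tau2 = ffit$tau2, t_half_global = global_half_time(ffit))
    jsonlite::write_json(frap, file.path(out_dir, "frap_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  txome <- NULL
  if (!is.null(config$counts)) {
    message("[txome] simulating + classifying expression data")
    ccfg <- config$counts
    ccfg$seed <- config$seed * 1000L + 990L
    sim <- simulate_counts_and_peaks(ccfg)
    fc <- log2fc_vs_reference(sim$counts, sim$conditions)
    retained <- promoter_peak_intersect(sim$genes, sim$peaks)
    conds <- setdiff(colnames(fc), "NT")
    cls <- NULL
    if (length(conds) >= 2L) {
      wt <- conds[1L]
      cls <- lapply(setdiff(conds, wt), function(cd) {
        res <- classify_mutant(stats::setNames(fc[, cd], rownames(fc)),
                               stats::setNames(fc[, wt], rownames(fc)),
                               intersect(retained$gene_id, rownames(fc)),
                               condition = cd)
        res[c("condition", "median_log2fc_ratio", "pearson_r", "call",
              "n_genes")]
      })
    }
    txome <- list(n_retained = nrow(retained), classifications = cls)
    jsonlite::write_json(txome, file.path(out_dir, "classification.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(package = "tfdwell",
                   version = as.character(utils::packageVersion("tfdwell")),
                   seed = config$seed,
                   n_movies = config$n_movies,
                   stages = c("smt",
                              if (!is.null(frap)) "frap",
                              if (!is.null(txome)) "txome"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(smt = smt, frap = frap, txome = txome,
                 manifest = manifest))
}
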