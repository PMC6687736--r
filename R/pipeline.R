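# End-to-end orchestration: simulate (or load) a dimer trajectory, gate on the
# stable window, and assemble the full report bundle - occupancy tables,
# contact census, helical-content summary, interface report, eigen-spectra and
# projection tables - deterministically under the configured seeds, with every
# output stamped with the window, the criteria and a config hash.

#' Pipeline configuration
#'
#' All thresholds default to the analysis conventions used throughout the
#' package (hydrogen bonds 3.2 Angstrom / 120 degrees, hydrophobic contacts
#' 3.5-5.5 Angstrom, census threshold 10 percent occupancy, stable window of
#' at least `min_span_ns`).
#'
#' @param seed master RNG seed.
#' @param n_frames trajectory length in frames.
#' @param frame_interval_ps frame spacing, ps. The default 100 ps keeps the
#'   simulated span (ns) large against the 40 ns window rule at desk-scale
#'   frame counts; conversions always use this metadata.
#' @param n_res_per_helix,inter_helix_spacing bundle geometry.
#' @param hbond_occupancies,contact_occupancy,unwound_fraction,mode_variances
#'   planted ground truth, see [reference_manifest()].
#' @param drift NULL or list(n_frames, amplitude) for an initial ramp.
#' @param window "auto" (detect the stable window) or c(start_frame, end_frame).
#' @param min_span_ns,slope_tol,sd_tol stable-window rule parameters.
#' @param census_threshold occupancy threshold (percent) for the census.
#' @param target_frames PCA subsampling target.
#' @param ss_stride assign secondary structure every this many window frames.
#' @param n_sphere_points SASA quadrature density.
#' @param pvalue_samples Monte-Carlo patches for the interface P-value.
#' @param out_dir output directory, or NULL to skip writing.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1,
                            n_frames = 600,
                            frame_interval_ps = 100,
                            n_res_per_helix = 12,
                            inter_helix_spacing = 11.5,
                            hbond_occupancies = c(0.719, 0.574),
                            contact_occupancy = 0.30,
                            unwound_fraction = 0.20,
                            mode_variances = c(4, 1),
                            drift = NULL,
                            window = "auto",
                            min_span_ns = 40,
                            slope_tol = 0.01,
                            sd_tol = 0.5,
                            census_threshold = 10,
                            target_frames = 2500,
                            ss_stride = 2,
                            n_sphere_points = 480,
                            pvalue_samples = 200,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% .Machine$integer.max)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline aborted at stage '", name, "': ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' simulate -> stability gating -> occupancies and census -> secondary
#' structure -> interface energetics -> essential dynamics, then write the
#' report bundle. Deterministic: the same config produces byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with every intermediate and final result, plus
#'   `meta` (window, criteria, config hash) and `paths` when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  bundle <- stage("build", {
    note("build: bundle n_res_per_helix=", config$n_res_per_helix)
    build_ideal_bundle(config$n_res_per_helix,
                       inter_helix_spacing = config$inter_helix_spacing)
  })
  sim <- stage("simulate", {
    man <- reference_manifest(bundle, seed = config$seed,
                              hbond_occupancies = config$hbond_occupancies,
                              contact_occupancy = config$contact_occupancy,
                              unwound_fraction = config$unwound_fraction,
                              mode_variances = config$mode_variances,
                              drift = config$drift)
    note("simulate: ", config$n_frames, " frames @ ",
         config$frame_interval_ps, " ps")
    simulate_trajectory(bundle, man, config$n_frames, config$frame_interval_ps)
  })
  traj <- sim$trajectory

  rmsd <- stage("stability", rmsd_series(traj))
  window <- stage("stability", {
    if (identical(config$window, "auto")) {
      find_stable_window(rmsd, config$frame_interval_ps, config$min_span_ns,
                         config$slope_tol, config$sd_tol)
    } else {
      window_frames(config$window[1], config$window[2], config$frame_interval_ps)
    }
  })
  note("stability: window frames ", window$start_frame, "-", window$end_frame,
       " (", round(window$span_ns, 2), " ns)")
  avg <- stage("average", average_structure(traj, window))

  hb <- stage("contacts", hbond_occupancy(traj, window))
  hi <- stage("contacts", hydrophobic_occupancy(traj, window))
  census <- stage("contacts",
                  contact_census(hb, hi, bundle$helices,
                                 config$census_threshold, traj$topology))
  note("contacts: ", nrow(hb), " HB rows, ", nrow(hi), " HI rows, census total ",
       census$total)

  prof <- stage("ssc", ss_profile(traj, window, stride = config$ss_stride))
  helicity <- stage("ssc", ssc(prof, bundle$helices))
  note("ssc: accumulated ", round(helicity$accumulated, 1), "%")

  iface <- stage("interface", {
    rep <- interface_analysis(list(topology = traj$topology, coords = avg),
                              n_sphere_points = config$n_sphere_points)
    if (rep$in_contact)
      rep <- delta_g_pvalue(list(topology = traj$topology, coords = avg), rep,
                            n_samples = config$pvalue_samples,
                            seed = config$seed)
    rep
  })
  note("interface: area ", round(iface$interface_area, 1), " A^2, deltaG ",
       round(iface$delta_G, 2))

  hs <- bundle$helices
  central <- atom_select(traj$topology, "CA",
                         residues = unlist(lapply(hs, function(r) r[1]:r[2])))
  pca1 <- stage("ed", pca_cartesian(traj, window, target_frames = config$target_frames))
  pca2 <- stage("ed", pca_cartesian(traj, window, selection = central,
                                    target_frames = config$target_frames))
  feats <- stage("ed", helix_distance_features(traj, hs, stride = 1,
                                               window = window,
                                               system = "run"))
  pca3 <- stage("ed", pca_features(feats))
  note("ed: PC1 explains ", round(100 * pca1$explained_fraction[1], 1),
       "% (global), ", round(100 * pca2$explained_fraction[1], 1),
       "% (central helices)")

  meta <- list(window = unclass(window),
               frame_interval_ps = config$frame_interval_ps,
               census_threshold = config$census_threshold,
               config_hash = config_hash(config))
  res <- list(config = config, meta = meta, bundle = bundle,
              manifest = sim$manifest, trajectory = traj, rmsd = rmsd,
              window = window, average = avg, hbonds = hb, hydrophobic = hi,
              census = census, ss = prof, ssc = helicity, interface = iface,
              pca1 = pca1, pca2 = pca2, features = feats, pca3 = pca3,
              log = log)

  if (!is.null(config$out_dir)) {
    res$paths <- stage("report", write_report_bundle(res, config$out_dir))
  }
  invisible(res)
}

#' Write the report bundle of a pipeline run.
#' @noRd
write_report_bundle <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- write_tables(list(
    occupancy_hb = res$hbonds,
    occupancy_hi = res$hydrophobic,
    eigen_pca1 = mode_summary(res$pca1),
    eigen_pca2 = mode_summary(res$pca2),
    features_pca3 = as.data.frame(res$features),
    interface = res$interface), dir)
  j <- function(x, nm) {
    p <- file.path(dir, nm)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    p
  }
  paths <- c(paths,
             census = j(list(pair_counts = as.list(res$census$pair_counts),
                             total = res$census$total,
                             intersubunit = res$census$intersubunit,
                             a1_balance = res$census$a1_balance,
                             meta = res$meta), "census.json"),
             ssc = j(c(list(per_helix = as.list(res$ssc$per_helix),
                            accumulated = res$ssc$accumulated),
                       list(meta = res$meta)), "ssc.json"),
             config = j(c(unclass(res$config), list(hash = res$meta$config_hash)),
                        "config.json"))
  writeLines(res$log, file.path(dir, "log.txt"))
  c(paths, log = file.path(dir, "log.txt"))
}
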