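# End-to-end synthetic pipeline driver and tabular writers. The numbered
# scripts under analysis/ are thin narratives over these helpers, and the
# determinism harness reruns the whole chain and hash-compares outputs.

#' Write a per-frame descriptor series as TSV
#'
#' @param series a `ligdyn_series`.
#' @param path output path.
#' @param frame_spacing time per frame in ps for the time column.
#' @export
write_series_tsv <- function(series, path, frame_spacing = 10) {
  df <- data.frame(frame = seq_along(series$values),
                   time_ps = (seq_along(series$values) - 1) * frame_spacing,
                   value = series$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a numeric matrix as TSV
#'
#' @param m matrix.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run the full synthetic analysis pipeline
#'
#' Exercises every stage on synthetic data with known ground truth:
#' docking funnel (Pnear + top models), structural descriptors, pairwise
#' RMSD + DBSCAN clustering, pocket volumes, essential-dynamics PCA,
#' interaction persistence, and pucker classification. All outputs are
#' plain TSV files under `out_dir` plus a `manifest.tsv` listing them;
#' every stochastic stage derives its stream from `seed`, so a rerun with
#' the same seed is byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed controlling all randomness.
#' @param n_frames trajectory length used by the frame-based stages.
#' @param n_models docking ensemble size.
#' @return invisibly, a data.frame manifest (stage, file).
#' @export
run_demo_pipeline <- function(out_dir, seed = 1, n_frames = 200,
                              n_models = 2000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- NULL
  emit <- function(stage, file) {
    manifest <<- rbind(manifest, data.frame(stage = stage,
                                            file = basename(file),
                                            stringsAsFactors = FALSE))
  }
  fmt <- function(x, digits = 6) formatC(x, digits = digits, format = "g")

  # -- docking funnel ------------------------------------------------
  fg <- gen_funnel_scores(n_models = n_models, seed = seed)
  rep_ <- funnel_report(fg$ensemble, n_by_total = min(1000, n_models),
                        n_by_interface = 10)
  f <- file.path(out_dir, "funnel_top_models.tsv")
  utils::write.table(rep_$top_models, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  emit("funnel", f)
  f <- file.path(out_dir, "funnel_summary.tsv")
  utils::write.table(
    data.frame(metric = c("pnear", "true_pnear", "reference_model"),
               value = c(fmt(rep_$pnear, 10), fmt(fg$true_pnear, 10),
                         rep_$reference_model)),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  emit("funnel", f)

  # -- descriptors on the two-domain system --------------------------
  td <- gen_two_domain_protein(n_frames = n_frames, seed = seed + 1)
  traj <- td$trajectory
  ca <- td$calpha
  f <- file.path(out_dir, "rmsd_backbone.tsv")
  write_series_tsv(rmsd_series(traj, 1, ca), f)
  emit("descriptors", f)
  f <- file.path(out_dir, "rg_calpha.tsv")
  write_series_tsv(radius_of_gyration(traj, ca), f)
  emit("descriptors", f)
  f <- file.path(out_dir, "rmsf_calpha.tsv")
  utils::write.table(data.frame(atom = ca$indices, rmsf = rmsf(traj, ca)),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  emit("descriptors", f)
  m <- pairwise_rmsd_matrix(traj, ca, stride = max(1, n_frames %/% 50))
  f <- file.path(out_dir, "pairwise_rmsd.tsv")
  write_matrix_tsv(round(m, 6), f)
  emit("descriptors", f)

  # -- clustering ----------------------------------------------------
  cl <- dbscan_rmsd(dist_matrix = m, eps = 1.0, min_points = min(42, nrow(m) %/% 2))
  f <- file.path(out_dir, "clusters.tsv")
  utils::write.table(data.frame(frame = cl$frames, label = cl$labels),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  emit("cluster", f)

  # -- pocket volume -------------------------------------------------
  cav <- gen_cavity_system(n_frames = 5, radius = c(3.5, 4.5),
                           state_schedule = rep(c(1, 2), length.out = 5),
                           seed = seed + 2, shell_spacing = 0.6)
  cfg <- cav$config
  cfg$grid_spacing <- 0.5
  vs <- volume_series(cav$trajectory, cfg)
  f <- file.path(out_dir, "pocket_volumes.tsv")
  utils::write.table(
    data.frame(frame = seq_along(vs$volumes), volume_A3 = fmt(vs$volumes, 8),
               true_A3 = fmt(cav$true_volumes, 8)),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  emit("pocket", f)

  # -- essential dynamics -------------------------------------------
  res <- fit_pca(list(synthetic = traj), calpha = ca)
  f <- file.path(out_dir, "pca_variance.tsv")
  utils::write.table(round(variance_report(res, 10), 8), f, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  emit("pca", f)
  f <- file.path(out_dir, "pca_projections.tsv")
  utils::write.table(
    data.frame(frame = seq_len(nrow(res$projections)),
               ensemble = res$ensemble,
               PC1 = round(res$projections[, 1], 6),
               PC2 = round(res$projections[, 2], 6)),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  emit("pca", f)

  # -- interactions --------------------------------------------------
  ig <- gen_interaction_system(n_frames = n_frames, seed = seed + 3)
  s <- ig$selections
  traces <- c(detect_hbonds(ig$trajectory, s$donors, s$acceptors),
              detect_salt_bridges(ig$trajectory, s$cations, s$anions),
              detect_hydrophobic(ig$trajectory, s$protein_nonpolar,
                                 s$ligand_nonpolar),
              detect_pi_stacking(ig$trajectory, s$rings_protein,
                                 s$rings_ligand))
  f <- file.path(out_dir, "interactions.tsv")
  utils::write.table(traces_table(traces), f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  emit("interactions", f)

  # -- pucker --------------------------------------------------------
  set.seed(seed + 4)
  nfp <- min(60, n_frames)
  n_south <- round(0.78 * nfp)
  sched <- data.frame(
    P = c(rep(162, n_south), rep(18, nfp - n_south)) + stats::runif(nfp, -5, 5),
    tau_m = stats::runif(nfp, 35, 42))
  fur <- gen_furanose_trajectory(sched, seed = seed + 5)
  f <- file.path(out_dir, "pucker.tsv")
  utils::write.table(
    within(pucker_series(fur$trajectory, fur$ring),
           { P <- round(P, 4); amplitude <- round(amplitude, 4) }),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  emit("pucker", f)

  f <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, f, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
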