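#' Default end-to-end run configuration
#'
#' Every value with a stated convention elsewhere in the package keeps it
#' here: the four activation-switch pairs, the RRCS kernel constants, the
#' state-call threshold of 1, head training with batch size 32 over 25
#' epochs, 5 seeded repetitions, 3-fold splits.
#'
#' @param seed Base seed for the whole run.
#' @return Nested configuration list; round-trips through YAML losslessly.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = seed,
    ensemble = list(n_frames = 60L, n_residues = 10L, displacement = 1.5,
                    noise_sd = 0.1),
    rrcs = list(d_full = 3.23, d_zero = 4.63, threshold = 1),
    selection = list(n_target = "auto"),
    features = list(n_ligands = 120L, n_conformations = 6L, dim_p = 16L,
                    delta = 2, mode = "state-contrast"),
    scores = list(n_ligands_per_class = 20L,
                  n_conformations_per_state = 200L),
    training = list(batch_size = 32L, epochs = 25L, lr = 1e-2,
                    repetitions = 5L),
    split = list(strategy = "random", k = 3L)
  )
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @param config Configuration list.
#' @return The configuration list (`read_run_config`) or `path`.
#' @export
read_run_config <- function(path) {
  cfg <- utils::modifyList(default_run_config(), yaml::read_yaml(path))
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full synthetic efficacy-prediction workflow
#'
#' Executes every stage on generated data: two-state ensemble generation,
#' contact-score profiling and state calls, frame filtering and
#' representative selection, per-state alignment and PCA, feature-ensemble
#' generation, transfer-learning head evaluation with repeated
#' cross-validation, the static / two-states / random-forest baselines, and
#' the per-state Welch score test. Stage outputs are written as CSV/JSON
#' under `out_dir` together with a manifest (config hash, seed). The run is
#' deterministic for a fixed config.
#'
#' @param config Configuration list (see [default_run_config()]) or a YAML
#'   path.
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the main in-memory results: `calls`,
#'   `selection`, `pca` (per state), `tl_report`, `baseline_aucs`,
#'   `welch` and `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile()) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  seed <- config$seed

  # stage 1: conformational ensembles + contact profiling
  sim <- gen_two_state_ensemble(
    n_frames = config$ensemble$n_frames,
    n_residues = config$ensemble$n_residues,
    displacement = config$ensemble$displacement,
    noise_sd = config$ensemble$noise_sd, seed = seed)
  both <- bind_ensembles(sim$active, sim$inactive)
  kern <- rrcs_kernel(config$rrcs$d_full, config$rrcs$d_zero)
  profile <- delta_rrcs(both, sim$bw_map, pairs = sim$pairs,
                        reference = sim$reference, kernel = kern)
  calls <- call_state(profile, threshold = config$rrcs$threshold)
  utils::write.csv(dplyr::left_join(tidy(profile),
                                    calls[, c("frame_id", "frame_call")],
                                    by = "frame_id"),
                   file.path(out_dir, "profile.csv"), row.names = FALSE)
  acc <- mean(calls$frame_call == sim$truth$state)
  logf("state-call accuracy vs generating state: %.3f", acc)

  # stage 2: filtering + representative selection
  aligned <- align_ensemble(both, reference_frame = 1L)
  kept <- filter_frames(both, profile, aligned$rmsd)
  logf("frames retained by filter: %d / %d", length(kept), n_frames(both))
  sel <- select_representatives(profile, calls,
                                n_target = config$selection$n_target)
  sel <- intersect(sel, kept)
  utils::write.csv(data.frame(frame = sel),
                   file.path(out_dir, "selection.csv"), row.names = FALSE)
  logf("representative frames selected: %d", length(sel))

  # stage 3: per-state PCA of aligned C-alpha coordinates
  pca_out <- list()
  for (st in c("active", "inactive")) {
    ens <- if (st == "active") sim$active else sim$inactive
    al <- align_ensemble(ens, reference_frame = 1L)
    pca <- run_pca(ca_matrix(al$ensemble), n_components = 2L)
    offset <- if (st == "active") 0L else n_frames(sim$active)
    sel_local <- sel[sel > offset & sel <= offset + n_frames(ens)] - offset
    proj <- project_selection(pca, sel_local)
    utils::write.csv(proj, file.path(out_dir, paste0("pca_", st, ".csv")),
                     row.names = FALSE)
    pca_out[[st]] <- pca
    logf("%s PCA EVR: %s", st,
         paste(sprintf("%.3f", pca$evr), collapse = ", "))
  }

  # stage 4: feature ensemble + TL head evaluation
  fe <- gen_feature_ensemble(
    n_ligands = config$features$n_ligands,
    n_conformations = config$features$n_conformations,
    dim_p = config$features$dim_p, delta = config$features$delta,
    mode = config$features$mode, seed = seed + 1L)
  X <- stack_features(fe)
  plan <- make_split(length(fe$labels), strategy = config$split$strategy,
                     k = config$split$k, seed = seed + 2L,
                     fingerprints = if (config$split$strategy == "tanimoto") {
                       gen_fingerprints(length(fe$labels),
                                        seed = seed + 3L)$fingerprints
                     } else NULL)
  report <- evaluate_tl(X, fe$labels, plan,
                        n_rep = config$training$repetitions,
                        base_seed = seed + 10L,
                        epochs = config$training$epochs,
                        batch_size = config$training$batch_size,
                        lr = config$training$lr)
  jsonlite::write_json(list(per_repetition = report$per_rep,
                            summary = report$summary),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  # stage 5: score-table baselines + per-state Welch test
  st <- gen_score_table(
    n_ligands_per_class = config$scores$n_ligands_per_class,
    n_conformations_per_state = config$scores$n_conformations_per_state,
    seed = seed + 4L)
  first_active <- which(st$conf_states == "active")[1]
  first_inactive <- which(st$conf_states == "inactive")[1]
  stat <- static_classifier(st$score_matrix[, first_active])
  two <- two_states_classifier(st$score_matrix[, first_active],
                               st$score_matrix[, first_inactive])
  plan_rf <- make_split(nrow(st$score_matrix), "random", k = config$split$k,
                        seed = seed + 5L)
  rf <- rf_ensemble_classifier(st$score_matrix, st$ligands$label, plan_rf,
                               seed = seed + 6L)
  baseline_aucs <- tibble::tibble(
    model = c("static_active", "two_states", "rf_ensemble"),
    auc = c(auc_midrank(stat$ranking, st$ligands$label),
            auc_midrank(two$ranking, st$ligands$label),
            auc_midrank(rf$prob, st$ligands$label[rf$ligand])))
  utils::write.csv(baseline_aucs, file.path(out_dir, "baselines.csv"),
                   row.names = FALSE)
  welch <- dplyr::bind_rows(lapply(split(st$scores, st$scores$ligand_id),
    function(d) {
      w <- welch_test(d$score[d$state == "active"],
                      d$score[d$state == "inactive"])
      dplyr::bind_cols(tibble::tibble(ligand_id = d$ligand_id[1]), w)
    }))
  utils::write.csv(welch, file.path(out_dir, "welch.csv"),
                   row.names = FALSE)

  manifest <- list(config = config, config_hash = rlang::hash(config),
                   seed = seed, package_version =
                     as.character(utils::packageVersion("dyneff")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(calls = calls, selection = sel, pca = pca_out,
                 tl_report = report, baseline_aucs = baseline_aucs,
                 welch = welch, manifest = manifest))
}

#' Concatenate two ensembles sharing an atom table
#' @param a,b `conf_ensemble`s with identical atom metadata.
#' @return A combined `conf_ensemble` with renumbered frame ids and
#'   `state_tag = "unknown"`.
#' @export
bind_ensembles <- function(a, b) {
  if (!identical(a$atoms, b$atoms)) stop("atom tables differ")
  coords <- array(NA_real_, c(n_frames(a) + n_frames(b), n_atoms(a), 3))
  coords[seq_len(n_frames(a)), , ] <- a$coords
  coords[n_frames(a) + seq_len(n_frames(b)), , ] <- b$coords
  new_conf_ensemble(a$atoms, coords, seq_len(dim(coords)[1]), "unknown",
                    paste(a$source, b$source, sep = "+"))
}
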