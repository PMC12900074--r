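#' Default synthetic contact-pair layout
#'
#' Four switch pairs over five residues, labelled with the canonical
#' TM3-TM7 Ballesteros-Weinstein activation-switch positions.
#'
#' @param offset Residue index of the first switch residue.
#' @return Tibble: `a`, `b` (residue indices), `bw_a`, `bw_b`.
#' @export
default_contact_pairs <- function(offset = 1L) {
  tibble::tibble(
    a = offset + c(0L, 0L, 1L, 2L),
    b = offset + c(3L, 4L, 4L, 4L),
    bw_a = c("3x43", "3x43", "3x46", "3x50"),
    bw_b = c("7x49", "7x53", "7x53", "7x53")
  )
}

#' Generate a synthetic two-state receptor ensemble
#'
#' Emulates active/inactive conformational ensembles whose designated
#' contact pairs differ between states. Each residue carries a C-alpha and
#' one side-chain proxy heavy atom; in the active geometry the switch-pair
#' side chains sit at `d_active` = 3.3 A (inside the contact kernel), in the
#' inactive geometry they are pushed `displacement` A further apart (outside
#' it). The reference frame is a noiseless "initial activated" structure
#' whose contacts are slightly looser (3.8 A) than the active ensemble's, so
#' active frames normalize above 1 and inactive frames below 1. Gaussian
#' coordinate noise of sd `noise_sd` is added per frame; output is a pure
#' function of the spec (seed included).
#'
#' @param n_frames Frames per state.
#' @param n_residues Total residues (must cover the pair indices).
#' @param contact_pairs Pair table from [default_contact_pairs()]; the pair
#'   graph must be acyclic.
#' @param displacement Extra side-chain separation (A) of the inactive
#'   state.
#' @param noise_sd Coordinate noise sd (A).
#' @param seed RNG seed.
#' @param d_active,d_reference Active-state and reference contact
#'   distances (A).
#' @return List: `active`, `inactive` (conf_ensembles), `reference`
#'   (1-frame conf_ensemble), `bw_map`, `pairs` (BW pair table for
#'   [delta_rrcs()]), `truth` (tibble: state per frame of the combined
#'   active-then-inactive ordering).
#' @export
gen_two_state_ensemble <- function(n_frames = 200L, n_residues = 10L,
                                   contact_pairs = default_contact_pairs(),
                                   displacement = 1.5, noise_sd = 0.1,
                                   seed = 1L, d_active = 3.3,
                                   d_reference = 3.8) {
  if (displacement <= 0) stop("displacement must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (max(contact_pairs$a, contact_pairs$b) > n_residues) {
    stop("n_residues smaller than the largest pair index")
  }
  switch_res <- sort(unique(c(contact_pairs$a, contact_pairs$b)))
  # unit-scale side-chain layout of the switch residues (tree embedding);
  # scaling by the target distance realizes each state's geometry
  unit <- place_pair_tree(contact_pairs, switch_res)
  sc_base <- function(t_contact) {
    sc <- matrix(NA_real_, n_residues, 3)
    sc[switch_res, ] <- unit * t_contact
    others <- setdiff(seq_len(n_residues), switch_res)
    sc[others, ] <- cbind(100 + 8 * seq_along(others), 0, 0)
    sc
  }
  build_coords <- function(t_contact) {
    sc <- sc_base(t_contact)
    ca <- sc + matrix(c(0, 0, 10), n_residues, 3, byrow = TRUE)
    out <- matrix(NA_real_, 2L * n_residues, 3)
    out[seq(1, 2 * n_residues, 2), ] <- ca
    out[seq(2, 2 * n_residues, 2), ] <- sc
    out
  }
  atoms <- tibble::tibble(
    atom_name = rep(c("CA", "CB"), n_residues),
    element = "C",
    residue_seq = rep(seq_len(n_residues), each = 2L),
    chain = "A",
    resid = "ALA",
    is_heavy = TRUE
  )
  base_active <- build_coords(d_active)
  base_inactive <- build_coords(d_active + displacement)
  base_ref <- build_coords(d_reference)
  set.seed(seed)
  make_frames <- function(base, nf) {
    coords <- array(NA_real_, c(nf, nrow(base), 3))
    for (f in seq_len(nf)) {
      coords[f, , ] <- base +
        matrix(stats::rnorm(length(base), 0, noise_sd), nrow(base), 3)
    }
    coords
  }
  active <- new_conf_ensemble(atoms, make_frames(base_active, n_frames),
                              seq_len(n_frames), "active", "synthetic")
  inactive <- new_conf_ensemble(atoms, make_frames(base_inactive, n_frames),
                                seq_len(n_frames), "inactive", "synthetic")
  ref <- new_conf_ensemble(atoms, array(base_ref, c(1, nrow(base_ref), 3)),
                           1L, "active", "synthetic-reference")
  labels <- rep("1x1", n_residues)
  labels[switch_res] <- bw_label_of_switch(contact_pairs, switch_res)
  others <- setdiff(seq_len(n_residues), switch_res)
  labels[others] <- paste0("1x", seq_along(others))
  bw <- bw_map_from_df(data.frame(chain = "A",
                                  residue_seq = seq_len(n_residues),
                                  bw_label = labels))
  list(active = active, inactive = inactive, reference = ref, bw_map = bw,
       pairs = contact_pairs[, c("bw_a", "bw_b")],
       truth = tibble::tibble(
         state = rep(c("active", "inactive"), each = n_frames),
         frame = rep(seq_len(n_frames), 2)))
}

bw_label_of_switch <- function(pairs, switch_res) {
  lab <- character(length(switch_res))
  for (i in seq_along(switch_res)) {
    r <- switch_res[i]
    hit_a <- pairs$bw_a[pairs$a == r]
    hit_b <- pairs$bw_b[pairs$b == r]
    lab[i] <- c(hit_a, hit_b)[1]
  }
  lab
}

# Embed the switch residues so every designated pair sits at unit distance.
# BFS over the pair graph; cycles would over-constrain the embedding and are
# rejected.
place_pair_tree <- function(pairs, switch_res) {
  pos <- matrix(NA_real_, max(switch_res), 3)
  dirs <- function(k) {
    v <- c(cos(2.39996 * k), sin(2.39996 * k), 0.6 * cos(1.7 * k))
    v / sqrt(sum(v^2))
  }
  placed <- logical(max(switch_res))
  edge_used <- rep(FALSE, nrow(pairs))
  comp_seed <- switch_res[1]
  pos[comp_seed, ] <- 0
  placed[comp_seed] <- TRUE
  repeat {
    progressed <- FALSE
    for (e in seq_len(nrow(pairs))) {
      if (edge_used[e]) next
      a <- pairs$a[e]; b <- pairs$b[e]
      if (placed[a] && placed[b]) {
        d <- sqrt(sum((pos[a, ] - pos[b, ])^2))
        if (abs(d - 1) > 1e-9) {
          stop("contact pair graph contains a cycle; cannot embed")
        }
        edge_used[e] <- TRUE; progressed <- TRUE
      } else if (placed[a] || placed[b]) {
        src <- if (placed[a]) a else b
        tgt <- if (placed[a]) b else a
        pos[tgt, ] <- pos[src, ] + dirs(e)
        placed[tgt] <- TRUE
        edge_used[e] <- TRUE; progressed <- TRUE
      }
    }
    if (all(edge_used)) break
    if (!progressed) {
      nxt <- switch_res[!placed[switch_res]][1]
      if (is.na(nxt)) break
      pos[nxt, ] <- c(0, 0, 5 + 5 * nxt)
      placed[nxt] <- TRUE
    }
  }
  pos[switch_res, , drop = FALSE]
}

#' Generate a synthetic ensemble-docking score table
#'
#' Scores are Normal per (class, state) with defaults taken from the printed
#' per-state means/SDs of a full agonist (better scores against active
#' conformations: -6.53 +/- 0.55 active vs -6.02 +/- 0.66 inactive) and a
#' nonagonist (better against inactive: -5.36 +/- 0.79 inactive vs
#' -4.95 +/- 0.55 active), in kcal/mol.
#'
#' @param n_ligands_per_class Ligands per class.
#' @param n_conformations_per_state Conformations per state.
#' @param agonist_means,agonist_sds Named `c(active=, inactive=)` score
#'   moments for agonists.
#' @param nonagonist_means,nonagonist_sds Same for nonagonists.
#' @param seed RNG seed.
#' @return List: `scores` (long tibble: `ligand_id`, `conformation_id`,
#'   `state`, `score`), `score_matrix` (ligands x conformations),
#'   `conf_states` (state per conformation column), `ligands` (tibble with
#'   `ligand_id`, `label`).
#' @export
gen_score_table <- function(n_ligands_per_class = 20L,
                            n_conformations_per_state = 200L,
                            agonist_means = c(active = -6.53,
                                              inactive = -6.02),
                            agonist_sds = c(active = 0.55, inactive = 0.66),
                            nonagonist_means = c(active = -4.95,
                                                 inactive = -5.36),
                            nonagonist_sds = c(active = 0.55,
                                               inactive = 0.79),
                            seed = 1L) {
  stopifnot(all(agonist_sds > 0), all(nonagonist_sds > 0))
  set.seed(seed)
  nc <- n_conformations_per_state
  conf_states <- rep(c("active", "inactive"), each = nc)
  conf_ids <- paste0(conf_states, "_", rep(seq_len(nc), 2))
  lig <- tibble::tibble(
    ligand_id = sprintf("L%03d", seq_len(2L * n_ligands_per_class)),
    label = rep(c("agonist", "nonagonist"), each = n_ligands_per_class)
  )
  mat <- matrix(NA_real_, nrow(lig), 2L * nc,
                dimnames = list(lig$ligand_id, conf_ids))
  for (i in seq_len(nrow(lig))) {
    mu <- if (lig$label[i] == "agonist") agonist_means else nonagonist_means
    sd <- if (lig$label[i] == "agonist") agonist_sds else nonagonist_sds
    mat[i, ] <- stats::rnorm(2L * nc, mean = mu[conf_states],
                             sd = sd[conf_states])
  }
  long <- tibble::tibble(
    ligand_id = rep(lig$ligand_id, each = 2L * nc),
    conformation_id = rep(conf_ids, nrow(lig)),
    state = rep(conf_states, nrow(lig)),
    score = as.vector(t(mat))
  )
  list(scores = long, score_matrix = mat, conf_states = conf_states,
       ligands = lig)
}

#' Generate a synthetic multi-conformation feature ensemble
#'
#' Emulates the penultimate-layer complex representations of a scorer
#' evaluated over an ordered conformation set. Baseline features are
#' standard normal. In `"uniform"` mode the class signal is a mean shift of
#' `+/- delta/2` along one random unit direction in every conformation
#' block. In `"state-contrast"` mode agonists are shifted `+delta/2` along
#' the direction in active-conformation blocks and `-delta/2` in inactive
#' blocks while nonagonists are unshifted, so the class signal is
#' conformation-state-dependent and the contrast across states carries most
#' of the information.
#'
#' @param n_ligands Total ligands (balanced classes).
#' @param n_conformations Conformations per ligand (even; first half tagged
#'   active, second half inactive).
#' @param dim_p Feature dimension per conformation.
#' @param delta Class-mean separation in units of the feature SD.
#' @param mode `"uniform"` or `"state-contrast"`.
#' @param seed RNG seed.
#' @return A `feature_ensemble`: list with `features` (list of
#'   `n_conformations x dim_p` matrices), `labels`, `conf_states`,
#'   `signal_direction`.
#' @export
gen_feature_ensemble <- function(n_ligands = 120L, n_conformations = 6L,
                                 dim_p = 16L, delta = 2,
                                 mode = c("uniform", "state-contrast"),
                                 seed = 1L) {
  mode <- match.arg(mode)
  if (delta < 0) stop("delta must be non-negative")
  set.seed(seed)
  conf_states <- rep(c("active", "inactive"),
                     length.out = n_conformations)
  conf_states <- sort(conf_states)  # first half active
  u <- stats::rnorm(dim_p); u <- u / sqrt(sum(u^2))
  labels <- rep(c("agonist", "nonagonist"), length.out = n_ligands)
  feats <- vector("list", n_ligands)
  for (i in seq_len(n_ligands)) {
    m <- matrix(stats::rnorm(n_conformations * dim_p), n_conformations,
                dim_p)
    for (cf in seq_len(n_conformations)) {
      shift <- if (mode == "uniform") {
        if (labels[i] == "agonist") delta / 2 else -delta / 2
      } else {
        if (labels[i] == "agonist") {
          if (conf_states[cf] == "active") delta / 2 else -delta / 2
        } else 0
      }
      m[cf, ] <- m[cf, ] + shift * u
    }
    feats[[i]] <- m
  }
  structure(list(features = feats, labels = labels,
                 conf_states = conf_states, signal_direction = u),
            class = "feature_ensemble")
}

#' @export
print.feature_ensemble <- function(x, ...) {
  cat(sprintf("<feature_ensemble> %d ligands x %d conformations x %d dims\n",
              length(x$features), nrow(x$features[[1]]),
              ncol(x$features[[1]])))
  invisible(x)
}

#' Generate binary fingerprints with planted scaffold clusters
#'
#' Cluster cores are sparse random bit vectors; members perturb their core
#' with a small flip probability, yielding within-cluster Tanimoto
#' similarity well above, and between-cluster similarity well below, the
#' usual 0.4 scaffold-split threshold.
#'
#' @param n Number of fingerprints.
#' @param n_clusters Planted clusters (n >= n_clusters).
#' @param bits Fingerprint length.
#' @param density Core on-bit density.
#' @param flip_prob Per-bit member perturbation probability.
#' @param seed RNG seed.
#' @return List: `fingerprints` (n x bits binary matrix), `cluster`
#'   (integer vector of planted assignments).
#' @export
gen_fingerprints <- function(n = 30L, n_clusters = 3L, bits = 512L,
                             density = 0.15, flip_prob = 0.02, seed = 1L) {
  if (n < n_clusters) stop("n must be >= n_clusters")
  set.seed(seed)
  cores <- matrix(stats::rbinom(n_clusters * bits, 1, density),
                  n_clusters, bits)
  cluster <- rep(seq_len(n_clusters), length.out = n)
  fp <- matrix(0L, n, bits)
  for (i in seq_len(n)) {
    base <- cores[cluster[i], ]
    flip <- stats::rbinom(bits, 1, flip_prob) == 1
    fp[i, ] <- ifelse(flip, 1L - base, base)
  }
  list(fingerprints = fp, cluster = cluster)
}
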