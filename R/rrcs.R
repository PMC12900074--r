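#' Default activation-switch residue pairs
#'
#' The four Ballesteros-Weinstein residue pairs whose contact rearrangement
#' tracks Class A GPCR activation (TM3-TM7 microswitch region):
#' 3x43-7x49, 3x43-7x53, 3x46-7x53, 3x50-7x53.
#'
#' @return Tibble with columns `bw_a`, `bw_b`.
#' @export
default_switch_pairs <- function() {
  tibble::tibble(
    bw_a = c("3x43", "3x43", "3x46", "3x50"),
    bw_b = c("7x49", "7x53", "7x53", "7x53")
  )
}

#' RRCS kernel parameters
#'
#' The residue-residue contact score sums a piecewise-linear kernel over all
#' heavy-atom pairs between two residues: 1 below `d_full`, 0 above `d_zero`,
#' linear in between. Defaults follow the published RRCS definition
#' (d_full = 3.23 A, d_zero = 4.63 A).
#'
#' @param d_full Distance (A) at or below which an atom pair contributes 1.
#' @param d_zero Distance (A) at or above which an atom pair contributes 0.
#' @return List of kernel parameters.
#' @export
rrcs_kernel <- function(d_full = 3.23, d_zero = 4.63) {
  stopifnot(is.numeric(d_full), is.numeric(d_zero))
  if (!(d_full > 0 && d_full < d_zero)) {
    stop("require 0 < d_full < d_zero")
  }
  list(d_full = d_full, d_zero = d_zero)
}

#' Residue-residue contact score between two heavy-atom sets
#'
#' Sum over all cross atom pairs of the piecewise-linear contact kernel.
#' Symmetric in its two arguments and non-negative.
#'
#' @param atoms_a,atoms_b Numeric matrices (n x 3) of heavy-atom coordinates
#'   in Angstrom.
#' @param kernel Kernel parameters from [rrcs_kernel()].
#' @return Scalar score (unitless, >= 0).
#' @export
#' @examples
#' a <- matrix(c(0, 0, 0), ncol = 3)
#' b <- matrix(c(3.93, 0, 0), ncol = 3)
#' residue_contact_score(a, b)  # (4.63 - 3.93) / 1.40 = 0.5
residue_contact_score <- function(atoms_a, atoms_b, kernel = rrcs_kernel()) {
  atoms_a <- as_coord_matrix(atoms_a, "atoms_a")
  atoms_b <- as_coord_matrix(atoms_b, "atoms_b")
  d2 <- outer(rowSums(atoms_a^2), rowSums(atoms_b^2), "+") -
    2 * atoms_a %*% t(atoms_b)
  d <- sqrt(pmax(d2, 0))
  w <- (kernel$d_zero - d) / (kernel$d_zero - kernel$d_full)
  # sorted summation makes the score bitwise-symmetric in its arguments
  sum(sort(pmin(1, pmax(0, w))))
}

as_coord_matrix <- function(x, what) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  if (!is.matrix(x) || ncol(x) != 3 || nrow(x) == 0) {
    stop(what, " must be a non-empty n x 3 coordinate matrix")
  }
  x
}

#' Reference-normalized residue contact profile of an ensemble
#'
#' For each frame and each switch residue pair, computes the heavy-atom RRCS
#' and normalizes it as a ratio to the same pair's score in a reference
#' (initial activated) conformation. Pairs whose reference score is below
#' `eps` are flagged undefined rather than divided.
#'
#' @param ensemble A `conf_ensemble`.
#' @param bw_map A `bw_map` resolving the pair labels.
#' @param pairs Tibble with columns `bw_a`, `bw_b`
#'   (default [default_switch_pairs()]).
#' @param reference Either a frame index into `ensemble` or a separate
#'   one-frame (or indexed) `conf_ensemble` sharing residue identities.
#' @param reference_frame Frame index within `reference` when it is an
#'   ensemble (default 1).
#' @param kernel [rrcs_kernel()] parameters.
#' @param eps Reference scores below this are treated as undefined (no
#'   division).
#' @param mode `"ratio"` (default; normalized = raw / reference) or
#'   `"difference"` (normalized = raw - reference; the threshold semantics of
#'   [call_state()] assume ratio mode).
#' @return A `delta_rrcs` object: matrices `raw`, `normalized`,
#'   `defined_mask` (`n_frames x n_pairs`), vector `reference_raw`, plus the
#'   pair table and frame ids. Use [tidy()] for a long tibble.
#' @export
delta_rrcs <- function(ensemble, bw_map, pairs = default_switch_pairs(),
                       reference = 1L, reference_frame = 1L,
                       kernel = rrcs_kernel(), eps = 1e-9,
                       mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  if (any(pairs$bw_a == pairs$bw_b)) stop("pair with identical BW labels")
  pair_names <- paste0(pairs$bw_a, ":", pairs$bw_b)
  if (is.numeric(reference)) {
    ref_ens <- ensemble
    ref_frame <- as.integer(reference)
  } else {
    ref_ens <- reference
    ref_frame <- as.integer(reference_frame)
  }
  addr <- lapply(seq_len(nrow(pairs)), function(p) {
    list(a = bw_lookup(bw_map, pairs$bw_a[p]),
         b = bw_lookup(bw_map, pairs$bw_b[p]))
  })
  score_frame <- function(ens, f) {
    vapply(addr, function(ad) {
      residue_contact_score(
        residue_heavy_coords(ens, f, ad$a$chain, ad$a$residue_seq),
        residue_heavy_coords(ens, f, ad$b$chain, ad$b$residue_seq),
        kernel)
    }, numeric(1))
  }
  reference_raw <- score_frame(ref_ens, ref_frame)
  nf <- n_frames(ensemble)
  raw <- matrix(NA_real_, nf, nrow(pairs),
                dimnames = list(NULL, pair_names))
  for (f in seq_len(nf)) raw[f, ] <- score_frame(ensemble, f)
  defined <- reference_raw >= eps
  normalized <- raw
  for (p in seq_len(ncol(raw))) {
    if (defined[p]) {
      normalized[, p] <- if (mode == "ratio") raw[, p] / reference_raw[p]
      else raw[, p] - reference_raw[p]
    } else {
      normalized[, p] <- NA_real_
    }
  }
  structure(list(
    raw = raw, normalized = normalized,
    reference_raw = stats::setNames(reference_raw, pair_names),
    defined_mask = matrix(rep(defined, each = nf), nf,
                          dimnames = list(NULL, pair_names)),
    pairs = pairs, frame_ids = ensemble$frame_ids, mode = mode
  ), class = "delta_rrcs")
}

#' @export
print.delta_rrcs <- function(x, ...) {
  cat(sprintf("<delta_rrcs> %d frames x %d pairs (%s mode)\n",
              nrow(x$raw), ncol(x$raw), x$mode))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a contact-score profile into a long tibble
#'
#' @param x A `delta_rrcs`.
#' @param ... Unused.
#' @return Tibble with `frame_id`, `pair`, `raw`, `normalized`, `defined`.
#' @export
tidy.delta_rrcs <- function(x, ...) {
  tibble::tibble(
    frame_id = rep(x$frame_ids, times = ncol(x$raw)),
    pair = rep(colnames(x$raw), each = nrow(x$raw)),
    raw = as.vector(x$raw),
    normalized = as.vector(x$normalized),
    defined = as.vector(x$defined_mask)
  )
}

#' Per-frame activation-state calls from a normalized contact profile
#'
#' A pair with normalized score above `threshold` favors the active
#' conformation; below, the inactive one. The frame-level call is the
#' majority over defined pairs; an exact tie yields `"intermediate"`.
#'
#' @param profile A `delta_rrcs`.
#' @param threshold Ratio threshold separating active- from
#'   inactive-favoring (default 1).
#' @return Tibble with `frame_id`, per-pair call columns, `n_active`,
#'   `n_inactive`, and `frame_call` in
#'   `{"active","inactive","intermediate","undefined"}`.
#' @export
call_state <- function(profile, threshold = 1) {
  norm <- profile$normalized
  if (is.null(colnames(norm))) {
    colnames(norm) <- paste0("pair", seq_len(ncol(norm)))
  }
  defined <- profile$defined_mask & is.finite(norm)
  per_pair <- matrix("undefined", nrow(norm), ncol(norm),
                     dimnames = dimnames(norm))
  per_pair[defined & norm > threshold] <- "active-favoring"
  per_pair[defined & norm <= threshold] <- "inactive-favoring"
  n_act <- rowSums(per_pair == "active-favoring")
  n_inact <- rowSums(per_pair == "inactive-favoring")
  frame_call <- ifelse(n_act + n_inact == 0, "undefined",
                ifelse(n_act > n_inact, "active",
                ifelse(n_inact > n_act, "inactive", "intermediate")))
  if (any(frame_call == "undefined")) {
    warning("all pairs undefined for frame(s): ",
            paste(profile$frame_ids[frame_call == "undefined"],
                  collapse = ", "))
  }
  out <- tibble::as_tibble(as.data.frame(per_pair, stringsAsFactors = FALSE))
  names(out) <- colnames(norm)
  dplyr::bind_cols(
    tibble::tibble(frame_id = profile$frame_ids),
    out,
    tibble::tibble(n_active = n_act, n_inactive = n_inact,
                   frame_call = frame_call)
  )
}

#' Filter redundant or non-converged frames
#'
#' Applies, in order: (1) a backbone-RMSD convergence filter dropping frames
#' whose RMSD to the reference deviates from a trailing-window median by more
#' than `mad_mult` times the window MAD; (2) profile deduplication, keeping
#' the lowest frame id among frames whose normalized contact profiles are
#' equal after rounding to `round_digits`; (3) an optional user-supplied
#' pocket filter hook (e.g. a pocket-volume consistency check) returning the
#' indices to keep.
#'
#' @param ensemble A `conf_ensemble` (only used by the pocket hook).
#' @param profile A `delta_rrcs` aligned with `ensemble`.
#' @param rmsd_series Numeric vector, per-frame backbone RMSD to the
#'   reference (Angstrom).
#' @param window Trailing window length for the RMSD filter.
#' @param mad_mult Deviation multiple of the window MAD beyond which a frame
#'   is dropped.
#' @param round_digits Rounding used by the duplicate-profile filter.
#' @param pocket_filter Optional `function(ensemble, keep_idx) -> integer`
#'   hook applied last.
#' @return Integer vector of retained frame indices (positions, 1-based).
#' @export
filter_frames <- function(ensemble, profile, rmsd_series,
                          window = 10L, mad_mult = 5,
                          round_digits = 3L, pocket_filter = NULL) {
  nf <- nrow(profile$normalized)
  if (length(rmsd_series) != nf) {
    stop("rmsd_series length must match frame count")
  }
  if (window > nf) stop("window longer than series")
  keep <- rep(TRUE, nf)
  for (f in seq_len(nf)) {
    lo <- max(1L, f - window + 1L)
    win <- rmsd_series[lo:f]
    med <- stats::median(win)
    mad <- stats::mad(win, center = med)
    if (mad > 0 && abs(rmsd_series[f] - med) > mad_mult * mad) {
      keep[f] <- FALSE
    }
  }
  idx <- which(keep)
  prof_key <- apply(round(profile$normalized[idx, , drop = FALSE],
                          round_digits), 1, paste, collapse = ",")
  idx <- idx[!duplicated(prof_key)]
  if (!is.null(pocket_filter)) idx <- pocket_filter(ensemble, idx)
  idx
}

#' Select representative, non-redundant conformations
#'
#' Deduplicates frames by rounded normalized profile, then picks
#' representatives by greedy farthest-point sampling in normalized contact
#' space, stratified so active- and inactive-called frames are represented in
#' proportion to their abundance. Deterministic: the seed frame is the lowest
#' frame id of the majority state, and ties in the farthest-point step go to
#' the lower frame id.
#'
#' @param profile A `delta_rrcs`.
#' @param calls Output of [call_state()] on `profile`.
#' @param n_target Number of representatives, or `"auto"` (all unique
#'   profiles).
#' @param round_digits Rounding used for deduplication.
#' @return Sorted integer vector of selected frame positions (1-based).
#' @export
select_representatives <- function(profile, calls, n_target = "auto",
                                   round_digits = 3L) {
  norm <- profile$normalized
  nf <- nrow(norm)
  key <- apply(round(norm, round_digits), 1, paste, collapse = ",")
  unique_idx <- which(!duplicated(key))
  if (identical(n_target, "auto")) n_target <- length(unique_idx)
  n_target <- as.integer(n_target)
  if (n_target >= length(unique_idx)) {
    if (n_target > length(unique_idx)) {
      warning("n_target exceeds unique frames; returning all ",
              length(unique_idx))
    }
    return(sort(unique_idx))
  }
  state <- calls$frame_call[unique_idx]
  groups <- split(unique_idx, factor(state %in% c("active"),
                                     levels = c(TRUE, FALSE),
                                     labels = c("active", "other")))
  groups <- groups[vapply(groups, length, 1L) > 0]
  # proportional allocation, every non-empty stratum gets >= 1
  sizes <- vapply(groups, length, 1L)
  alloc <- stats::setNames(pmax(1L, round(n_target * sizes / sum(sizes))),
                           names(sizes))
  while (sum(alloc) > n_target) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < n_target) {
    room <- sizes - alloc
    alloc[which.max(room)] <- alloc[which.max(room)] + 1L
  }
  majority <- names(groups)[which.max(sizes)]
  selected <- integer(0)
  for (g in names(groups)) {
    idx <- groups[[g]]
    k <- min(alloc[[g]], length(idx))
    pts <- norm[idx, , drop = FALSE]
    pts[!is.finite(pts)] <- 0
    seed <- if (g == majority) 1L else 1L  # lowest frame id within stratum
    chosen <- farthest_point_sample(pts, k, seed)
    selected <- c(selected, idx[chosen])
  }
  sort(selected)
}

farthest_point_sample <- function(pts, k, seed_row) {
  n <- nrow(pts)
  chosen <- seed_row
  if (k <= 1L) return(chosen)
  d2 <- rowSums((pts - matrix(pts[seed_row, ], n, ncol(pts), byrow = TRUE))^2)
  for (i in seq_len(k - 1L)) {
    avail <- setdiff(seq_len(n), chosen)
    mx <- max(d2[avail])
    nxt <- min(avail[d2[avail] == mx])  # tie -> lowest index
    chosen <- c(chosen, nxt)
    nd2 <- rowSums((pts - matrix(pts[nxt, ], n, ncol(pts), byrow = TRUE))^2)
    d2 <- pmin(d2, nd2)
  }
  chosen
}
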