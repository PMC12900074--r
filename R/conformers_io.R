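#' Read a multi-conformation structure into a conformational ensemble
#'
#' Parses either a multi-model PDB file (frames delimited by `MODEL`/`ENDMDL`)
#' or a directory of single-model PDB files (one frame per file, lexicographic
#' order) into a [conf_ensemble] object. All frames must share the same atom
#' count and atom ordering; hydrogens are retained but flagged so that
#' heavy-atom operations (contact scoring) can exclude them.
#'
#' @param path Path to a PDB file or a directory of PDB files.
#' @param format `"auto"` (default, decided by [file.info()]), `"pdb"` for a
#'   multi-model file, or `"dir"` for a frame directory.
#' @param state_tag Activation-state annotation for the whole ensemble:
#'   `"active"`, `"inactive"` or `"unknown"`.
#' @return A `conf_ensemble`: list with `atoms` (tibble of per-atom metadata:
#'   `atom_name`, `element`, `residue_seq`, `chain`, `resid`, `is_heavy`),
#'   `coords` (numeric array `n_frames x n_atoms x 3`, Angstrom),
#'   `frame_ids` (integer), `state_tag` and `source`.
#' @export
#' @examples
#' pdb <- system.file("extdata", "toy_ensemble.pdb", package = "dyneff")
#' ens <- read_ensemble(pdb)
#' n_frames(ens)
read_ensemble <- function(path, format = c("auto", "pdb", "dir"),
                          state_tag = c("unknown", "active", "inactive")) {
  format <- match.arg(format)
  state_tag <- match.arg(state_tag)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dir" else "pdb"
  }
  if (format == "dir") {
    files <- sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE))
    if (length(files) == 0L) stop("no .pdb files found in directory: ", path)
    frames <- lapply(seq_along(files), function(i) {
      parse_pdb_block_lines(files[[i]], lines = NULL, frame_label = files[[i]])
    })
  } else {
    lines <- readLines(path, warn = FALSE)
    blocks <- split_model_blocks(lines)
    frames <- lapply(seq_along(blocks), function(i) {
      parse_pdb_block_lines(NULL, lines = blocks[[i]],
                            frame_label = paste0("model ", i))
    })
  }
  ref <- frames[[1L]]
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (nrow(fr$atoms) != nrow(ref$atoms)) {
      stop(sprintf("inconsistent atom count in frame %d (%s): %d vs %d",
                   i, fr$label, nrow(fr$atoms), nrow(ref$atoms)))
    }
    same <- all(fr$atoms$atom_name == ref$atoms$atom_name) &&
      all(fr$atoms$residue_seq == ref$atoms$residue_seq) &&
      all(fr$atoms$chain == ref$atoms$chain)
    if (!same) {
      stop(sprintf("atom ordering differs in frame %d (%s)", i, fr$label))
    }
  }
  coords <- array(NA_real_, dim = c(length(frames), nrow(ref$atoms), 3L))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]$xyz
  new_conf_ensemble(atoms = ref$atoms, coords = coords,
                    frame_ids = seq_along(frames),
                    state_tag = state_tag, source = path)
}

#' @keywords internal
new_conf_ensemble <- function(atoms, coords, frame_ids, state_tag, source) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == nrow(atoms),
            dim(coords)[3] == 3L, !anyDuplicated(frame_ids))
  structure(list(atoms = atoms, coords = coords,
                 frame_ids = as.integer(frame_ids),
                 state_tag = state_tag, source = source),
            class = "conf_ensemble")
}

#' Number of frames / atoms in an ensemble
#' @param ensemble A `conf_ensemble`.
#' @return Integer count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(ensemble) dim(ensemble$coords)[2]

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf("<conf_ensemble> %d frames x %d atoms (%d residues), state: %s\n",
              n_frames(x), n_atoms(x),
              nrow(unique(x$atoms[, c("chain", "residue_seq")])), x$state_tag))
  invisible(x)
}

# Split raw PDB lines into per-model line blocks. A file without MODEL records
# is a single block.
split_model_blocks <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) return(list(lines))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  mapply(function(s, e) lines[s:e], starts, ends, SIMPLIFY = FALSE)
}

# Parse one PDB model (a file path or a character block) via bio3d, keeping
# hydrogens but flagging them. Alternate locations: highest occupancy wins,
# ties go to the first encountered.
parse_pdb_block_lines <- function(path, lines, frame_label = path %||% "block") {
  if (is.null(path)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop(sprintf("unparsable PDB in %s: %s",
                                     frame_label, conditionMessage(e)))
  )
  at <- pdb$atom
  keep <- resolve_altloc(at)
  at <- at[keep, , drop = FALSE]
  elem <- ifelse(is.na(at$elesy) | at$elesy == "",
                 guess_element(at$elety), trimws(at$elesy))
  atoms <- tibble::tibble(
    atom_name = trimws(at$elety),
    element = toupper(elem),
    residue_seq = as.integer(at$resno),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resid = at$resid,
    is_heavy = toupper(elem) != "H"
  )
  if (nrow(atoms) == 0L) stop("no atoms parsed in ", frame_label)
  xyz <- cbind(at$x, at$y, at$z)
  if (any(!is.finite(xyz))) stop("non-finite coordinates in ", frame_label)
  list(atoms = atoms, xyz = xyz, label = frame_label)
}

resolve_altloc <- function(at) {
  alt <- at$alt
  if (all(is.na(alt))) return(rep(TRUE, nrow(at)))
  key <- paste(at$chain, at$resno, at$elety)
  keep <- rep(TRUE, nrow(at))
  for (k in unique(key[!is.na(alt)])) {
    idx <- which(key == k)
    if (length(idx) <= 1L) next
    occ <- at$o[idx]
    best <- idx[which.max(occ)]  # which.max: first max wins ties
    keep[setdiff(idx, best)] <- FALSE
    message("alternate locations at ", k, ": kept highest occupancy")
  }
  keep
}

guess_element <- function(elety) {
  nm <- trimws(elety)
  ifelse(grepl("^[0-9]*H", nm), "H", substr(gsub("[0-9]", "", nm), 1, 1))
}

#' Write an ensemble as a multi-model PDB file
#'
#' Coordinates are written in the wwPDB fixed-column dialect (3 decimal
#' places), so `read_ensemble(write_ensemble(x))` round-trips coordinates
#' exactly at that precision.
#'
#' @param ensemble A `conf_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  at <- ensemble$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ensemble))) {
    writeLines(sprintf("MODEL     %4d", ensemble$frame_ids[f]), con)
    xyz <- ensemble$coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    recs <- sprintf(
      "ATOM  %5d %-4s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)), format_atom_name(at$atom_name), at$resid,
      at$chain, at$residue_seq, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
      at$element)
    writeLines(recs, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

format_atom_name <- function(nm) {
  # PDB columns 13-16: names of <4 chars start in column 14
  ifelse(nchar(nm) >= 4, nm, paste0(" ", formatC(nm, width = -3)))
}

#' Load a Ballesteros-Weinstein residue-number map
#'
#' Reads a TSV with columns `chain`, `residue_seq`, `bw_label` mapping author
#' residue numbering to Ballesteros-Weinstein generic numbers (e.g. `3x50`).
#' The map must be bijective: duplicate BW labels or duplicate residues are
#' errors.
#'
#' @param path TSV file path.
#' @return A `bw_map`: tibble with the three columns, plus lookup helpers
#'   [bw_lookup()] / [bw_reverse()].
#' @export
load_bw_map <- function(path) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character"))
  required <- c("chain", "residue_seq", "bw_label")
  if (!all(required %in% names(df))) {
    stop("BW map must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warning("empty BW map: ", path)
    return(new_bw_map(tibble::as_tibble(df)))
  }
  bad <- which(!grepl("^[0-9]+x[0-9]+$", df$bw_label))
  if (length(bad)) {
    stop("malformed BW label(s) in row(s) ", paste(bad, collapse = ", "),
         ": ", paste(df$bw_label[bad], collapse = ", "))
  }
  if (anyDuplicated(df$bw_label)) {
    stop("duplicate BW label(s): ",
         paste(unique(df$bw_label[duplicated(df$bw_label)]), collapse = ", "))
  }
  key <- paste(df$chain, df$residue_seq)
  if (anyDuplicated(key)) {
    stop("duplicate residue(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  new_bw_map(tibble::as_tibble(df))
}

new_bw_map <- function(df) structure(df, class = c("bw_map", class(df)))

#' Look up a BW label or residue in a BW map
#'
#' @param map A `bw_map` from [load_bw_map()] or [bw_map_from_df()].
#' @param bw_label A BW generic number such as `"3x50"`.
#' @return `bw_lookup`: one-row tibble `(chain, residue_seq)`;
#'   `bw_reverse`: the BW label for a `(chain, residue_seq)` pair.
#' @export
bw_lookup <- function(map, bw_label) {
  hit <- map[map$bw_label == bw_label, c("chain", "residue_seq")]
  if (nrow(hit) == 0L) stop("BW label not in map: ", bw_label)
  hit
}

#' @rdname bw_lookup
#' @param chain,residue_seq Author residue address.
#' @export
bw_reverse <- function(map, chain, residue_seq) {
  hit <- map$bw_label[map$chain == chain & map$residue_seq == residue_seq]
  if (length(hit) == 0L) stop("residue not in map: ", chain, "/", residue_seq)
  hit
}

#' Build a BW map directly from a data frame (programmatic fixtures)
#' @param df Data frame with `chain`, `residue_seq`, `bw_label`.
#' @return A `bw_map`.
#' @export
bw_map_from_df <- function(df) {
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  utils::write.table(df, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  load_bw_map(tf)
}

#' Flattened C-alpha coordinate matrix of an ensemble
#'
#' Returns the `n_frames x 3N` matrix whose row *f* is frame *f*'s C-alpha
#' coordinates flattened in fixed residue order (x1, y1, z1, x2, ...), the
#' input expected by [run_pca()].
#'
#' @param ensemble A `conf_ensemble`; every residue must have exactly one CA.
#' @return Numeric matrix, Angstrom.
#' @export
ca_matrix <- function(ensemble) {
  idx <- ca_indices(ensemble)
  nf <- n_frames(ensemble)
  out <- matrix(NA_real_, nf, 3L * length(idx))
  for (f in seq_len(nf)) {
    out[f, ] <- as.vector(t(ensemble$coords[f, idx, , drop = TRUE]))
  }
  out
}

ca_indices <- function(ensemble) {
  at <- ensemble$atoms
  res_key <- paste(at$chain, at$residue_seq)
  is_ca <- at$atom_name == "CA" & at$element == "C"
  per_res <- tapply(is_ca, factor(res_key, levels = unique(res_key)), sum)
  missing <- names(per_res)[per_res == 0]
  if (length(missing)) {
    stop("residue(s) lacking a CA atom: ", paste(missing, collapse = "; "))
  }
  multi <- names(per_res)[per_res > 1]
  if (length(multi)) {
    stop("residue(s) with multiple CA atoms: ", paste(multi, collapse = "; "))
  }
  which(is_ca)[order(match(res_key[is_ca], unique(res_key)))]
}

#' C-alpha/C-alpha distance map between two BW-labelled residue sets
#'
#' Computes all pairwise C-alpha Euclidean distances between two sets of
#' residues addressed by Ballesteros-Weinstein labels, e.g. TM5 vs TM6
#' positions for an interhelical contact map.
#'
#' @param ensemble A `conf_ensemble`.
#' @param frame Frame index (1-based).
#' @param set_a,set_b Character vectors of BW labels.
#' @param bw_map A `bw_map` resolving the labels.
#' @return Matrix of distances (Angstrom) with `set_a` rows, `set_b` columns;
#'   symmetric when the sets are identical.
#' @export
ca_distance_map <- function(ensemble, frame, set_a, set_b, bw_map) {
  ca <- ca_coords_for_labels(ensemble, frame, c(set_a, set_b), bw_map)
  a <- ca[set_a, , drop = FALSE]
  b <- ca[set_b, , drop = FALSE]
  out <- matrix(NA_real_, nrow(a), nrow(b), dimnames = list(set_a, set_b))
  for (i in seq_len(nrow(a))) {
    out[i, ] <- sqrt(colSums((t(b) - a[i, ])^2))
  }
  out
}

ca_coords_for_labels <- function(ensemble, frame, labels, bw_map) {
  labels <- unique(labels)
  at <- ensemble$atoms
  out <- matrix(NA_real_, length(labels), 3, dimnames = list(labels, NULL))
  for (lb in labels) {
    addr <- bw_lookup(bw_map, lb)
    hit <- which(at$chain == addr$chain & at$residue_seq == addr$residue_seq &
                   at$atom_name == "CA")
    if (length(hit) != 1L) {
      stop("cannot resolve a unique CA for BW label ", lb)
    }
    out[lb, ] <- ensemble$coords[frame, hit, ]
  }
  out
}

#' Heavy-atom coordinates of one residue in one frame
#' @keywords internal
residue_heavy_coords <- function(ensemble, frame, chain, residue_seq) {
  at <- ensemble$atoms
  idx <- which(at$chain == chain & at$residue_seq == residue_seq & at$is_heavy)
  if (length(idx) == 0L) {
    stop("no heavy atoms for residue ", chain, "/", residue_seq)
  }
  m <- ensemble$coords[frame, idx, , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, ncol = 3)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
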