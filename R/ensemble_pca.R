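#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between a
#' mobile point set and a reference, via SVD of the cross-covariance with the
#' usual determinant sign correction (reflections are never returned).
#'
#' @param mobile,reference Numeric matrices (n x 3), n >= 3, not all
#'   collinear.
#' @return List with `rotation` (3x3, det = +1), `translation` (length 3),
#'   `rmsd` (Angstrom) and `aligned` (the transformed mobile coordinates:
#'   `aligned = mobile %*% t(rotation) + translation`).
#' @export
kabsch_align <- function(mobile, reference) {
  mobile <- as_coord_matrix(mobile, "mobile")
  reference <- as_coord_matrix(reference, "reference")
  if (nrow(mobile) != nrow(reference)) stop("point counts differ")
  if (nrow(mobile) < 3L) stop("need at least 3 points")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  a <- sweep(mobile, 2, cm)
  b <- sweep(reference, 2, cr)
  if (qr(a)$rank < 2L) stop("degenerate (collinear) point set")
  h <- t(a) %*% b
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- a %*% t(rot) + matrix(cr, nrow(mobile), 3, byrow = TRUE)
  translation <- as.vector(cr - rot %*% cm)
  rmsd <- sqrt(mean(rowSums((aligned - reference)^2)))
  list(rotation = rot, translation = translation, rmsd = rmsd,
       aligned = aligned)
}

#' Align every frame of an ensemble to a reference on C-alpha atoms
#'
#' Removes overall translation and rotation per frame so the remaining
#' variance reflects internal motion only, the standard preprocessing before
#' coordinate PCA.
#'
#' @param ensemble A `conf_ensemble`.
#' @param reference_frame Frame index used as the reference (default 1), or a
#'   `n_residues x 3` matrix of reference C-alpha coordinates.
#' @return List: `ensemble` (aligned copy, all atoms transformed),
#'   `rmsd` (per-frame C-alpha RMSD to the reference, Angstrom).
#' @export
align_ensemble <- function(ensemble, reference_frame = 1L) {
  idx <- ca_indices(ensemble)
  ref <- if (is.matrix(reference_frame)) reference_frame
  else ensemble$coords[reference_frame, idx, , drop = TRUE]
  out <- ensemble
  rmsd <- numeric(n_frames(ensemble))
  for (f in seq_len(n_frames(ensemble))) {
    fit <- kabsch_align(ensemble$coords[f, idx, , drop = TRUE], ref)
    all_xyz <- ensemble$coords[f, , , drop = TRUE]
    out$coords[f, , ] <- all_xyz %*% t(fit$rotation) +
      matrix(fit$translation, n_atoms(ensemble), 3, byrow = TRUE)
    rmsd[f] <- fit$rmsd
  }
  list(ensemble = out, rmsd = rmsd)
}

#' Principal component analysis of a flattened coordinate matrix
#'
#' Mean-centers the rows of an `n x 3N` C-alpha coordinate matrix (see
#' [ca_matrix()]) and eigendecomposes their covariance (divisor n - 1).
#' Explained variance ratios (EVRs) are eigenvalue / total variance.
#' Component signs are fixed by making each component's largest-magnitude
#' loading positive, so results are deterministic.
#'
#' @param coord_matrix Numeric matrix, frames x 3N.
#' @param n_components Number of components to retain (default
#'   `min(n - 1, 3N)`).
#' @return An `ensemble_pca` object: `components` (rows are the orthonormal
#'   basis), `evr`, `projections` (frames x components), `mean`,
#'   `total_variance`. [tidy()] returns per-frame projections; [glance()]
#'   the EVR summary.
#' @export
run_pca <- function(coord_matrix, n_components = NULL) {
  n <- nrow(coord_matrix)
  if (n < 2L) stop("need at least 2 frames")
  max_comp <- min(n - 1L, ncol(coord_matrix))
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > max_comp) {
    stop("n_components exceeds min(n - 1, 3N) = ", max_comp)
  }
  pc <- stats::prcomp(coord_matrix, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  k <- n_components
  comps <- t(pc$rotation[, seq_len(k), drop = FALSE])
  proj <- pc$x[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (i in seq_len(k)) {
    j <- which.max(abs(comps[i, ]))
    if (comps[i, j] < 0) {
      comps[i, ] <- -comps[i, ]
      proj[, i] <- -proj[, i]
    }
  }
  structure(list(
    components = comps,
    evr = pc$sdev[seq_len(k)]^2 / total_var,
    projections = proj,
    mean = pc$center,
    total_variance = total_var
  ), class = "ensemble_pca")
}

#' @export
print.ensemble_pca <- function(x, ...) {
  cat(sprintf("<ensemble_pca> %d frames, %d components; EVR: %s\n",
              nrow(x$projections), length(x$evr),
              paste(sprintf("%.1f%%", 100 * utils::head(x$evr, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname run_pca
#' @param x An `ensemble_pca`.
#' @param ... Unused.
#' @export
tidy.ensemble_pca <- function(x, ...) {
  proj <- x$projections
  colnames(proj) <- paste0("pc", seq_len(ncol(proj)))
  dplyr::bind_cols(tibble::tibble(frame = seq_len(nrow(proj))),
                   tibble::as_tibble(proj))
}

#' @rdname run_pca
#' @export
glance.ensemble_pca <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$evr),
    evr1 = x$evr[1],
    evr2 = if (length(x$evr) >= 2) x$evr[2] else NA_real_,
    cum_evr = sum(x$evr),
    total_variance = x$total_variance
  )
}

#' Project frames onto PC1-PC2 and flag a selected subset
#'
#' Companion to [select_representatives()]: returns the PC1-PC2 coordinates
#' of every frame with the selected representatives flagged, ready for
#' plotting with [autoplot.pca_projection()] or writing to CSV.
#'
#' @param pca An `ensemble_pca` with at least 2 components.
#' @param selected Integer vector of selected frame indices (may be empty).
#' @return A `pca_projection` tibble: `frame`, `pc1`, `pc2`, `selected`.
#' @export
project_selection <- function(pca, selected = integer(0)) {
  n <- nrow(pca$projections)
  if (length(selected) && (any(selected < 1L) || any(selected > n))) {
    stop("selected index out of range 1..", n)
  }
  if (ncol(pca$projections) < 2L) stop("need at least 2 components")
  out <- tibble::tibble(
    frame = seq_len(n),
    pc1 = pca$projections[, 1],
    pc2 = pca$projections[, 2],
    selected = seq_len(n) %in% selected
  )
  class(out) <- c("pca_projection", class(out))
  out
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a PC1-PC2 projection with selected representatives highlighted
#'
#' @param object A `pca_projection` from [project_selection()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_projection <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_point(data = object[!object$selected, ],
                        colour = "grey55", size = 1.2, alpha = 0.7) +
    ggplot2::geom_point(data = object[object$selected, ],
                        colour = "firebrick", shape = 17, size = 2.4) +
    ggplot2::labs(x = "PC1", y = "PC2",
                  title = "C-alpha PCA projection",
                  subtitle = "triangles: selected representative frames") +
    ggplot2::theme_minimal()
}
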