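# Programmatic fixtures shared across the suite.

# A small ligand: benzene-like aromatic ring plus one charged amine N.
toy_ligand <- function() {
  list(
    atoms = tibble::tibble(
      element = c(rep("C", 6), "N"),
      x = c(cos(0:5 * pi / 3), 2.5),
      y = c(sin(0:5 * pi / 3), 0),
      z = 0,
      aromatic = c(rep(TRUE, 6), FALSE),
      charge = c(rep(0L, 6), 1L),
      hb_donor = c(rep(FALSE, 6), TRUE),
      hb_acceptor = FALSE
    ),
    bonds = tibble::tibble(a = c(1:6, 1), b = c(2:6, 1, 7))
  )
}

toy_protein_nodes <- function() {
  tibble::tibble(
    x = c(3, 0, -3), y = c(3, 4, 3), z = c(1, 0, 1),
    residue_class = 1:3, charge = c(-1L, 0L, 0L),
    hb_donor = FALSE, hb_acceptor = c(TRUE, FALSE, FALSE)
  )
}

toy_complex_graph <- function() {
  build_complex_graph(toy_protein_nodes(), toy_ligand())
}

small_egnn_config <- function() {
  egnn_config(dim_h = 16, dim_e = 8, n_layers = 2, n_heads = 2,
              head_hidden = 8)
}

# ligand whose class is readable from one atom's element (separable task)
separable_graph <- function(has_nitrogen, seed) {
  set.seed(seed)
  lig <- list(
    atoms = tibble::tibble(
      element = c("C", "C", if (has_nitrogen) "N" else "C"),
      x = c(0, 1.4, 2.6) + stats::rnorm(3, 0, 0.05),
      y = stats::rnorm(3, 0, 0.05),
      z = stats::rnorm(3, 0, 0.05),
      aromatic = FALSE, charge = 0L,
      hb_donor = FALSE, hb_acceptor = FALSE),
    bonds = tibble::tibble(a = c(1, 2), b = c(2, 3)))
  prot <- tibble::tibble(x = c(0, 3), y = c(3, 3), z = 0,
                         residue_class = 1:2)
  build_complex_graph(prot, lig)
}

# atoms within `radius` of the centroid, so two residues whose centers are
# more than 2 * radius apart cannot interpenetrate (makes the pull-apart
# monotonicity of the contact kernel geometrically guaranteed)
ball_residue <- function(center, n_atoms = 3, radius = 1) {
  dirs <- matrix(stats::rnorm(3 * n_atoms), n_atoms)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  dirs * stats::runif(n_atoms, 0, radius) +
    matrix(center, n_atoms, 3, byrow = TRUE)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# apply an isometry to a prepared scorer input (edge sets are preserved by
# rigid motion, so only coordinates change)
transform_prep <- function(prep, rot, trans) {
  prep$x0 <- prep$x0 %*% t(rot) +
    matrix(trans, nrow(prep$x0), 3, byrow = TRUE)
  prep
}

write_toy_pdb_lines <- function(path, n_models = 3, n_atoms = 5,
                                drop_atom_in_model = NULL) {
  lines <- character(0)
  base <- matrix(c(0, 0, 0, 1.458, 0, 0, 2.009, 1.42, 0,
                   1.251, 2.39, 0, 3.332, 1.536, 0), ncol = 3, byrow = TRUE)
  names_ <- c("N", "CA", "C", "O", "CA")
  resno <- c(1, 1, 1, 1, 2)
  resid <- c(rep("ALA", 4), "GLY")
  elem <- c("N", "C", "C", "O", "C")
  for (m in seq_len(n_models)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    keep <- seq_len(n_atoms)
    if (!is.null(drop_atom_in_model) && m == drop_atom_in_model) {
      keep <- keep[-n_atoms]
    }
    for (i in keep) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        i, names_[i], resid[i], "A", resno[i],
        base[i, 1] + 0.1 * (m - 1), base[i, 2], base[i, 3], 1, 0, elem[i]))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}
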