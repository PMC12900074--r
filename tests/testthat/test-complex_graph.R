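test_that("pocket extraction respects the closed radius boundary", {
  sim <- gen_two_state_ensemble(n_frames = 1, noise_sd = 0, seed = 1)
  lig <- matrix(sim$active$coords[1, 2, ], 1)  # at residue 1's side chain
  pocket <- extract_pocket(sim$active, 1, lig, radius = 8)
  expect_true(1 %in% pocket$residue_seq)
  expect_false(10 %in% pocket$residue_seq)
  all_res <- extract_pocket(sim$active, 1, lig, radius = 500)
  expect_equal(nrow(all_res), 10L)
  # exact-boundary residue included (closed interval): non-switch residues
  # sit on an integer-coordinate line, so the 8 A distance is exact
  sc6 <- sim$active$atoms$residue_seq == 6 &
    sim$active$atoms$atom_name == "CB"
  sc6_xyz <- sim$active$coords[1, which(sc6), ]
  lig8 <- matrix(sc6_xyz - c(8, 0, 0), 1)
  pocket_exact <- extract_pocket(sim$active, 1, lig8, radius = 8)
  expect_true(6 %in% pocket_exact$residue_seq)
  expect_false(7 %in% pocket_exact$residue_seq)
  far <- matrix(c(-500, 0, 0), 1)
  expect_error(extract_pocket(sim$active, 1, far, radius = 8),
               "larger radius")
})

test_that("aromatic ring detection finds SSSR rings and centroids", {
  lig <- toy_ligand()
  rings <- detect_aromatic_rings(lig)
  expect_length(rings, 1L)
  expect_equal(rings[[1]]$atoms, 1:6)
  expect_equal(rings[[1]]$centroid,
               colMeans(as.matrix(lig$atoms[1:6, c("x", "y", "z")])))
  # non-aromatic ring (cyclohexane flags) yields nothing
  lig2 <- lig
  lig2$atoms$aromatic <- FALSE
  expect_length(detect_aromatic_rings(lig2), 0L)
  # naphthalene topology: 10 atoms, 11 bonds, two fused 6-rings
  naph <- list(
    atoms = tibble::tibble(
      element = "C",
      x = c(0, 1, 2, 2, 1, 0, -1, -2, -2, -1),
      y = c(0, 0.5, 0, -1, -1.5, -1, 0.5, 0, -1, -1.5),
      z = 0, aromatic = TRUE),
    bonds = tibble::tibble(a = c(1, 2, 3, 4, 5, 6, 1, 7, 8, 9, 10),
                           b = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 6)))
  rings2 <- detect_aromatic_rings(naph)
  expect_length(rings2, 2L)
  expect_equal(sort(vapply(rings2, function(r) length(r$atoms), 1L)),
               c(6L, 6L))
  # the two rings share the fusion bond atoms 1 and 6
  shared <- intersect(rings2[[1]]$atoms, rings2[[2]]$atoms)
  expect_equal(sort(shared), c(1L, 6L))
  bad <- naph
  bad$bonds$b[1] <- 99L
  expect_error(detect_aromatic_rings(bad), "non-existent")
})

test_that("geometric edges respect per-kind cutoffs and the bin grid", {
  nodes <- tibble::tibble(
    id = 1:2, kind = c("ligand_atom", "protein"),
    x = c(0, 3), y = 0, z = 0)
  e <- build_geometric_edges(nodes, geometric_cutoffs(lig_prot = 5))
  expect_equal(nrow(e), 2L)  # both directions
  expect_equal(e$dist, c(3, 3))
  nodes$x[2] <- 7
  expect_equal(nrow(build_geometric_edges(
    nodes, geometric_cutoffs(lig_prot = 5))), 0L)
  # triangle at mutual 4.1 A: 3 undirected = 6 directed edges; bins match
  # the floor(d / width) oracle
  s <- 4.1
  tri <- tibble::tibble(
    id = 1:3, kind = "ligand_atom",
    x = c(0, s, s / 2), y = c(0, 0, s * sqrt(3) / 2), z = 0)
  e3 <- build_geometric_edges(tri, geometric_cutoffs(lig_prot = 4.5))
  expect_equal(nrow(e3), 6L)
  expect_equal(e3$bin, as.integer(floor(e3$dist / 0.5)))
  expect_true(all(e3$bin == 8L))  # 4.1 / 0.5 = 8.2
  # protein-protein pairs use the wider adjacency cutoff
  pp <- tibble::tibble(id = 1:2, kind = "protein", x = c(0, 7), y = 0, z = 0)
  epp <- build_geometric_edges(pp)
  expect_equal(unique(epp$type), "prot_adj")
  expect_equal(nrow(epp), 2L)
})

test_that("structural edges carry covalent bonds and typed interactions", {
  nodes <- tibble::tibble(
    id = 1:4, kind = c("ligand_atom", "ligand_atom", "protein", "protein"),
    x = c(0, 1.5, 0, 3), y = c(0, 0, 2.9, 0), z = 0)
  e <- build_structural_edges(
    nodes, ligand_bonds = tibble::tibble(a = 1L, b = 2L),
    interactions = tibble::tibble(src = 1L, dst = 3L, type = "hbond"))
  expect_equal(sum(e$type == "covalent"), 2L)
  expect_equal(sum(e$type == "hbond"), 2L)
  expect_error(build_structural_edges(
    nodes, tibble::tibble(a = 1L, b = 9L)), "non-existent")
  expect_error(build_structural_edges(
    nodes, tibble::tibble(a = 1L, b = 2L),
    interactions = tibble::tibble(src = 1L, dst = 3L, type = "vdw")),
    "unknown interaction")
})

test_that("the minimal IFP detector applies its distance/angle thresholds", {
  # donor N at 2.9 A from acceptor O with a 170-degree D-H...A angle
  nodes <- tibble::tibble(
    id = 1:2, kind = c("ligand_atom", "protein"),
    x = c(0, 2.9), y = 0, z = 0,
    hb_donor = c(TRUE, FALSE), hb_acceptor = c(FALSE, TRUE),
    charge = 0L,
    h_coord = list(c(1.0, 0.09, 0), NULL))
  det <- detect_interactions(nodes)
  expect_equal(det$type, "hbond")
  # too far: no bond
  nodes2 <- nodes; nodes2$x[2] <- 3.8
  expect_equal(nrow(detect_interactions(nodes2)), 0L)
  # bad angle (acute): no bond
  nodes3 <- nodes; nodes3$h_coord[[1]] <- c(-1.0, 0.09, 0)
  expect_equal(nrow(detect_interactions(nodes3)), 0L)
  # parallel ring centroids at 4.0 A -> pi-pi; at 6.0 A -> none
  rings <- tibble::tibble(
    id = 1:2, kind = "aromatic_virtual",
    x = c(0, 0), y = c(0, 4), z = 0,
    hb_donor = FALSE, hb_acceptor = FALSE, charge = 0L)
  expect_equal(detect_interactions(rings)$type, "pi_pi")
  rings$y[2] <- 6
  expect_equal(nrow(detect_interactions(rings)), 0L)
  # salt bridge between opposite charges within 4 A
  salt <- tibble::tibble(
    id = 1:2, kind = c("ligand_atom", "protein"),
    x = c(0, 3.5), y = 0, z = 0,
    hb_donor = FALSE, hb_acceptor = FALSE, charge = c(1L, -1L))
  expect_true("salt_bridge" %in% detect_interactions(salt)$type)
})

test_that("assembled complex graphs satisfy their structural invariants", {
  g <- toy_complex_graph()
  expect_s3_class(g, "complex_graph")
  expect_equal(length(g$virtual_node_ids), 1L)
  # virtual node sits at the ring centroid
  cent <- colMeans(as.matrix(toy_ligand()$atoms[1:6, c("x", "y", "z")]))
  vn <- g$nodes[g$nodes$kind == "aromatic_virtual", ]
  expect_equal(c(vn$x, vn$y, vn$z), unname(cent))
  # every virtual node linked by structural edges to all its ring atoms
  ring_e <- g$edges[g$edges$type == "ring_member" &
                      g$edges$src == vn$id, ]
  expect_equal(sort(ring_e$dst), g$ligand_node_ids[1:6])
  # no self-edges; geometric edges obey the cutoff iff rule
  expect_false(any(g$edges$src == g$edges$dst))
  geo <- g$edges[g$edges$channel == "geometric", ]
  xyz <- as.matrix(g$nodes[, c("x", "y", "z")])
  for (r in seq_len(nrow(geo))) {
    expect_lte(geo$dist[r],
               if (geo$type[r] == "prot_adj") 8 else 4.5)
  }
  # ligand subgraph connected under covalent edges
  cov <- g$edges[g$edges$type == "covalent", ]
  reach <- g$ligand_node_ids[1]
  repeat {
    nxt <- unique(c(reach, cov$dst[cov$src %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  expect_setequal(reach, g$ligand_node_ids)
})

test_that("graph construction is invariant to whole-complex translation", {
  g <- toy_complex_graph()
  lig <- toy_ligand()
  prot <- toy_protein_nodes()
  shift <- c(11, -7, 3)
  lig$atoms$x <- lig$atoms$x + shift[1]
  lig$atoms$y <- lig$atoms$y + shift[2]
  lig$atoms$z <- lig$atoms$z + shift[3]
  prot$x <- prot$x + shift[1]; prot$y <- prot$y + shift[2]
  prot$z <- prot$z + shift[3]
  g2 <- build_complex_graph(prot, lig)
  expect_equal(g2$edges$src, g$edges$src)
  expect_equal(g2$edges$dst, g$edges$dst)
  expect_equal(g2$edges$type, g$edges$type)
  expect_equal(g2$edges$dist, g$edges$dist, tolerance = 1e-9)
  expect_equal(g2$edges$bin, g$edges$bin)
})

test_that("complex graphs serialize to JSON and back", {
  g <- toy_complex_graph()
  tf <- tempfile(fileext = ".json")
  write_complex_graph(g, tf)
  g2 <- read_complex_graph(tf)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$ligand_node_ids, g$ligand_node_ids)
  expect_equal(g2$nodes$x, g$nodes$x)
})
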