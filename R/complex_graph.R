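#' Extract the binding-pocket residues around a ligand
#'
#' Returns the protein residues having any heavy atom within `radius` of any
#' ligand atom. The boundary is closed: a residue at exactly `radius` is
#' included. Ordering is deterministic by (chain, residue_seq).
#'
#' @param ensemble A `conf_ensemble`.
#' @param frame Frame index.
#' @param ligand_coords Numeric matrix (n x 3) of ligand atom coordinates.
#' @param radius Pocket radius in Angstrom (> 0).
#' @return Tibble with `chain`, `residue_seq`, `min_dist`.
#' @export
extract_pocket <- function(ensemble, frame, ligand_coords, radius = 8) {
  if (radius <= 0) stop("radius must be positive")
  ligand_coords <- as_coord_matrix(ligand_coords, "ligand_coords")
  at <- ensemble$atoms
  xyz <- ensemble$coords[frame, , , drop = TRUE]
  heavy <- which(at$is_heavy)
  d2 <- outer(rowSums(xyz[heavy, , drop = FALSE]^2),
              rowSums(ligand_coords^2), "+") -
    2 * xyz[heavy, , drop = FALSE] %*% t(ligand_coords)
  dmin <- sqrt(pmax(apply(d2, 1, min), 0))
  hits <- tibble::tibble(chain = at$chain[heavy],
                         residue_seq = at$residue_seq[heavy],
                         dist = dmin)
  out <- hits |>
    dplyr::group_by(.data$chain, .data$residue_seq) |>
    dplyr::summarise(min_dist = min(.data$dist), .groups = "drop") |>
    dplyr::filter(.data$min_dist <= radius) |>
    dplyr::arrange(.data$chain, .data$residue_seq)
  if (nrow(out) == 0L) {
    stop("empty pocket at radius ", radius, " A; try a larger radius")
  }
  out
}

#' Detect aromatic rings in a ligand topology
#'
#' Finds the smallest set of smallest rings (SSSR) whose member atoms are all
#' flagged aromatic, and the centroid of each (unweighted mean of member
#' coordinates). These centroids become virtual aromatic nodes in the complex
#' graph, making pi-pi and cation-pi geometry explicit.
#'
#' @param ligand A ligand table set: list with `atoms` (tibble: `element`,
#'   `x`, `y`, `z`, `aromatic` logical, optional `charge`) and `bonds`
#'   (tibble: `a`, `b` 1-based atom indices, optional `order`).
#' @return List of rings, each a list with `atoms` (integer indices) and
#'   `centroid` (length-3 numeric). Empty list when there is no aromatic
#'   ring.
#' @export
detect_aromatic_rings <- function(ligand) {
  atoms <- ligand$atoms
  bonds <- ligand$bonds
  if (nrow(bonds) &&
      (max(bonds$a, bonds$b) > nrow(atoms) || min(bonds$a, bonds$b) < 1)) {
    stop("bond list references non-existent atoms")
  }
  arom <- which(atoms$aromatic %||% rep(FALSE, nrow(atoms)))
  if (length(arom) < 3L) return(list())
  sub_bonds <- bonds[bonds$a %in% arom & bonds$b %in% arom, , drop = FALSE]
  rings <- sssr_cycles(arom, sub_bonds)
  lapply(rings, function(r) {
    xyz <- as.matrix(atoms[r, c("x", "y", "z")])
    list(atoms = sort(r), centroid = colMeans(xyz))
  })
}

# Smallest-set-of-smallest-rings on a small molecular graph: for every edge,
# find the shortest cycle through it (BFS with the edge removed), then keep a
# minimal independent set of the resulting cycles, smallest first.
sssr_cycles <- function(vertices, bonds) {
  if (nrow(bonds) == 0L) return(list())
  adj <- lapply(stats::setNames(vertices, vertices), function(v) {
    c(bonds$b[bonds$a == v], bonds$a[bonds$b == v])
  })
  n_ring <- nrow(bonds) - length(vertices) + n_components(vertices, adj)
  if (n_ring <= 0L) return(list())
  cycles <- list()
  for (e in seq_len(nrow(bonds))) {
    cyc <- shortest_cycle_through(bonds$a[e], bonds$b[e], adj)
    if (!is.null(cyc)) cycles[[length(cycles) + 1L]] <- cyc
  }
  if (!length(cycles)) return(list())
  keys <- vapply(cycles, function(c) paste(sort(c), collapse = ","), "")
  cycles <- cycles[!duplicated(keys)]
  cycles <- cycles[order(vapply(cycles, length, 1L))]
  chosen <- list()
  covered_edges <- character(0)
  for (cyc in cycles) {
    eds <- cycle_edges(cyc)
    if (!all(eds %in% covered_edges)) {
      chosen[[length(chosen) + 1L]] <- cyc
      covered_edges <- union(covered_edges, eds)
    }
    if (length(chosen) == n_ring) break
  }
  chosen
}

n_components <- function(vertices, adj) {
  seen <- stats::setNames(rep(FALSE, length(vertices)), vertices)
  ncomp <- 0L
  for (v in vertices) {
    if (seen[[as.character(v)]]) next
    ncomp <- ncomp + 1L
    queue <- v
    seen[[as.character(v)]] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (w in adj[[as.character(u)]]) {
        if (!seen[[as.character(w)]]) {
          seen[[as.character(w)]] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
  }
  ncomp
}

shortest_cycle_through <- function(a, b, adj) {
  # BFS from a to b with edge (a,b) removed; cycle = path + edge
  prev <- list()
  seen <- c(as.character(a))
  queue <- a
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (w in adj[[as.character(u)]]) {
      if (u == a && w == b) next
      if (u == b && w == a) next
      cw <- as.character(w)
      if (cw %in% seen) next
      seen <- c(seen, cw)
      prev[[cw]] <- u
      if (w == b) {
        path <- b
        while (path[1] != a) path <- c(prev[[as.character(path[1])]], path)
        return(path)
      }
      queue <- c(queue, w)
    }
  }
  NULL
}

cycle_edges <- function(cyc) {
  nxt <- c(cyc[-1], cyc[1])
  vapply(seq_along(cyc),
         function(i) paste(sort(c(cyc[i], nxt[i])), collapse = "-"), "")
}

#' Geometric edge cutoffs and distance-bin grid
#'
#' Defaults: ligand-protein (and ligand-ligand, virtual) atom-atom contacts
#' at 4.5 A; protein-protein C-alpha adjacency at 8.0 A; distances binned on
#' a fixed 0.5 A grid from 0 up to the largest cutoff.
#'
#' @param lig_prot Cutoff (A) for edges involving a ligand or virtual node.
#' @param prot_prot Cutoff (A) for protein-protein C-alpha adjacency.
#' @param bin_width Width (A) of the distance bins.
#' @return List of cutoff parameters.
#' @export
geometric_cutoffs <- function(lig_prot = 4.5, prot_prot = 8.0,
                              bin_width = 0.5) {
  stopifnot(lig_prot > 0, prot_prot > 0, bin_width > 0)
  list(lig_prot = lig_prot, prot_prot = prot_prot, bin_width = bin_width)
}

#' Build the geometric edge channel of a complex graph
#'
#' Emits both directions of every qualifying pair: protein-protein edges
#' between nodes within the C-alpha adjacency cutoff, and all other pairs
#' (ligand-protein, ligand-ligand, virtual) within the contact cutoff. The
#' boundary is closed. Each edge carries its distance and the index of its
#' 0.5 A distance bin (`floor(dist / bin_width)`).
#'
#' @param nodes Node tibble with `id`, `kind`
#'   (`protein`/`ligand_atom`/`aromatic_virtual`), `x`, `y`, `z`.
#' @param cutoffs [geometric_cutoffs()].
#' @return Edge tibble: `src`, `dst`, `channel = "geometric"`,
#'   `type`, `dist`, `bin`.
#' @export
build_geometric_edges <- function(nodes, cutoffs = geometric_cutoffs()) {
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  n <- nrow(nodes)
  if (n < 2L) {
    return(tibble::tibble(src = integer(0), dst = integer(0),
                          channel = character(0), type = character(0),
                          dist = numeric(0), bin = integer(0)))
  }
  d <- as.matrix(stats::dist(xyz))
  pp <- nodes$kind == "protein"
  src <- integer(0); dst <- integer(0); ty <- character(0); dd <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both_prot <- pp[i] && pp[j]
      cut <- if (both_prot) cutoffs$prot_prot else cutoffs$lig_prot
      if (d[i, j] <= cut) {
        src <- c(src, i, j); dst <- c(dst, j, i)
        ty <- c(ty, rep(if (both_prot) "prot_adj" else "contact", 2))
        dd <- c(dd, rep(d[i, j], 2))
      }
    }
  }
  # the 1e-9 offset keeps bins stable when a distance sits on a bin
  # boundary up to floating-point jitter (e.g. after a rigid translation)
  tibble::tibble(src = nodes$id[src], dst = nodes$id[dst],
                 channel = "geometric", type = ty, dist = dd,
                 bin = as.integer(floor((dd + 1e-9) / cutoffs$bin_width)))
}

#' Interaction-fingerprint detection thresholds
#'
#' Minimal built-in detector thresholds: hydrogen bonds at donor-acceptor
#' distance <= 3.5 A and donor-H...acceptor angle >= 120 degrees (when no
#' hydrogen positions are available, distance-only); pi-pi at ring-centroid
#' distance <= 5.5 A; cation-pi at cation-centroid distance <= 6.0 A; salt
#' bridges at opposite-charge heavy-atom distance <= 4.0 A.
#'
#' @param hbond_dist,hbond_angle,pipi_dist,cation_pi_dist,salt_dist
#'   Thresholds (A; angle in degrees).
#' @return List of thresholds.
#' @export
ifp_params <- function(hbond_dist = 3.5, hbond_angle = 120,
                       pipi_dist = 5.5, cation_pi_dist = 6.0,
                       salt_dist = 4.0) {
  list(hbond_dist = hbond_dist, hbond_angle = hbond_angle,
       pipi_dist = pipi_dist, cation_pi_dist = cation_pi_dist,
       salt_dist = salt_dist)
}

#' Build the structural edge channel of a complex graph
#'
#' Covalent edges come from the ligand bond list (plus ring-membership edges
#' linking each virtual aromatic node to its ring atoms). Noncovalent
#' interaction edges (`hbond`, `pi_pi`, `cation_pi`, `salt_bridge`) come
#' either from a user-supplied interaction table or from the built-in minimal
#' detector ([detect_interactions()]). Both directions of each edge are
#' emitted.
#'
#' @param nodes Node tibble (see [build_complex_graph()]).
#' @param ligand_bonds Tibble `a`, `b` of ligand-atom node ids.
#' @param ring_membership Tibble `virtual_id`, `atom_id` linking virtual
#'   nodes to their ring atoms.
#' @param interactions Optional tibble `src`, `dst`, `type`; entries must
#'   reference existing node ids.
#' @return Edge tibble: `src`, `dst`, `channel = "structural"`, `type`,
#'   `dist`, `bin` (dist/bin NA for covalent edges).
#' @export
build_structural_edges <- function(nodes, ligand_bonds,
                                   ring_membership = NULL,
                                   interactions = NULL) {
  ids <- nodes$id
  src <- integer(0); dst <- integer(0); ty <- character(0)
  add_both <- function(a, b, t) {
    src <<- c(src, a, b); dst <<- c(dst, b, a); ty <<- c(ty, t, t)
  }
  if (nrow(ligand_bonds)) {
    if (!all(c(ligand_bonds$a, ligand_bonds$b) %in% ids)) {
      stop("ligand bond references a non-existent node id")
    }
    for (e in seq_len(nrow(ligand_bonds))) {
      add_both(ligand_bonds$a[e], ligand_bonds$b[e], "covalent")
    }
  }
  if (!is.null(ring_membership) && nrow(ring_membership)) {
    for (e in seq_len(nrow(ring_membership))) {
      add_both(ring_membership$virtual_id[e], ring_membership$atom_id[e],
               "ring_member")
    }
  }
  if (!is.null(interactions) && nrow(interactions)) {
    if (!all(c(interactions$src, interactions$dst) %in% ids)) {
      stop("interaction references a non-existent node id")
    }
    ok <- c("hbond", "pi_pi", "cation_pi", "salt_bridge")
    if (!all(interactions$type %in% ok)) {
      stop("unknown interaction type(s): ",
           paste(setdiff(interactions$type, ok), collapse = ", "))
    }
    for (e in seq_len(nrow(interactions))) {
      add_both(interactions$src[e], interactions$dst[e],
               interactions$type[e])
    }
  }
  tibble::tibble(src = src, dst = dst, channel = "structural", type = ty,
                 dist = NA_real_, bin = NA_integer_)
}

#' Minimal interaction-fingerprint detector
#'
#' Detects hydrogen bonds, pi-pi stacking, cation-pi and salt bridges between
#' protein and ligand nodes using the distance/angle thresholds in
#' [ifp_params()]. Deliberately simple: a documented approximation meant for
#' synthetic and desk-scale complexes; supply an external interaction table
#' to override.
#'
#' @param nodes Node tibble with `id`, `kind`, `x`, `y`, `z`, and optional
#'   annotation columns `hb_donor`, `hb_acceptor`, `charge` (integer-coded
#'   class: -1, 0, +1), `h_coord` (list of donor-H coordinates).
#' @param params [ifp_params()].
#' @return Interaction tibble `src`, `dst`, `type` suitable for
#'   [build_structural_edges()].
#' @export
detect_interactions <- function(nodes, params = ifp_params()) {
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  get <- function(col, default) {
    if (col %in% names(nodes)) nodes[[col]] else rep(default, nrow(nodes))
  }
  donor <- get("hb_donor", FALSE)
  acceptor <- get("hb_acceptor", FALSE)
  charge <- get("charge", 0L)
  prot <- nodes$kind == "protein"
  lig <- nodes$kind == "ligand_atom"
  virt <- nodes$kind == "aromatic_virtual"
  out <- tibble::tibble(src = integer(0), dst = integer(0),
                        type = character(0))
  add <- function(i, j, t) {
    out <<- dplyr::bind_rows(out, tibble::tibble(
      src = nodes$id[i], dst = nodes$id[j], type = t))
  }
  cross <- function(i, j) (prot[i] && !prot[j]) || (!prot[i] && prot[j])
  n <- nrow(nodes)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (cross(i, j)) {
        dpair <- (donor[i] && acceptor[j]) || (donor[j] && acceptor[i])
        if (dpair && d <= params$hbond_dist &&
            hbond_angle_ok(nodes, i, j, params$hbond_angle)) {
          add(i, j, "hbond")
        }
        if (abs(charge[i]) > 0 && abs(charge[j]) > 0 &&
            sign(charge[i]) != sign(charge[j]) && d <= params$salt_dist) {
          add(i, j, "salt_bridge")
        }
        if (((virt[i] && abs(charge[j]) > 0) ||
             (virt[j] && abs(charge[i]) > 0)) &&
            d <= params$cation_pi_dist) {
          add(i, j, "cation_pi")
        }
      }
      if (virt[i] && virt[j] && d <= params$pipi_dist) add(i, j, "pi_pi")
    }
  }
  out
}

hbond_angle_ok <- function(nodes, i, j, min_angle) {
  if (!("h_coord" %in% names(nodes))) return(TRUE)  # distance-only mode
  donor <- if (isTRUE(nodes$hb_donor[i])) i else j
  accep <- if (donor == i) j else i
  h <- nodes$h_coord[[donor]]
  if (is.null(h)) return(TRUE)
  dxyz <- c(nodes$x[donor], nodes$y[donor], nodes$z[donor])
  axyz <- c(nodes$x[accep], nodes$y[accep], nodes$z[accep])
  v1 <- dxyz - h
  v2 <- axyz - h
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  ang >= min_angle
}

#' Assemble a heterogeneous protein-ligand complex graph
#'
#' Builds the full graph G = (V, E_geometric, E_structural): protein nodes
#' (pocket C-alpha positions with residue-class features), ligand-atom nodes
#' and virtual aromatic nodes at ring centroids; geometric edges by distance
#' cutoff with binned-distance attributes; structural edges from covalent
#' bonds, ring membership and interaction fingerprints.
#'
#' @param protein_nodes Tibble: `x`, `y`, `z`, `residue_class`
#'   (integer-coded), plus optional annotation columns used by the
#'   interaction detector.
#' @param ligand A ligand table set (see [detect_aromatic_rings()]).
#' @param cutoffs [geometric_cutoffs()].
#' @param interactions Optional external interaction tibble; `NULL` runs the
#'   built-in detector.
#' @param ifp [ifp_params()] for the built-in detector.
#' @return A `complex_graph`: list with `nodes`, `edges`,
#'   `ligand_node_ids`, `pocket_node_ids`, `virtual_node_ids`.
#' @export
build_complex_graph <- function(protein_nodes, ligand,
                                cutoffs = geometric_cutoffs(),
                                interactions = NULL, ifp = ifp_params()) {
  la <- ligand$atoms
  n_prot <- nrow(protein_nodes)
  n_lig <- nrow(la)
  if (n_lig == 0L) stop("empty ligand")
  rings <- detect_aromatic_rings(ligand)
  get <- function(df, col, default) {
    if (col %in% names(df)) df[[col]] else rep(default, nrow(df))
  }
  nodes <- dplyr::bind_rows(
    tibble::tibble(
      kind = "protein",
      x = protein_nodes$x, y = protein_nodes$y, z = protein_nodes$z,
      element = get(protein_nodes, "element", "C"),
      residue_class = get(protein_nodes, "residue_class", 0L),
      charge = get(protein_nodes, "charge", 0L),
      aromatic = FALSE,
      hb_donor = get(protein_nodes, "hb_donor", FALSE),
      hb_acceptor = get(protein_nodes, "hb_acceptor", FALSE)
    ),
    tibble::tibble(
      kind = "ligand_atom",
      x = la$x, y = la$y, z = la$z,
      element = la$element,
      residue_class = 0L,
      charge = get(la, "charge", 0L),
      aromatic = get(la, "aromatic", FALSE),
      hb_donor = get(la, "hb_donor", FALSE),
      hb_acceptor = get(la, "hb_acceptor", FALSE)
    )
  )
  if (length(rings)) {
    cents <- do.call(rbind, lapply(rings, `[[`, "centroid"))
    nodes <- dplyr::bind_rows(nodes, tibble::tibble(
      kind = "aromatic_virtual",
      x = unname(cents[, 1]), y = unname(cents[, 2]),
      z = unname(cents[, 3]),
      element = "X", residue_class = 0L, charge = 0L, aromatic = TRUE,
      hb_donor = FALSE, hb_acceptor = FALSE))
  }
  nodes$id <- seq_len(nrow(nodes))
  nodes <- nodes[, c("id", setdiff(names(nodes), "id"))]
  lig_ids <- n_prot + seq_len(n_lig)
  virt_ids <- if (length(rings)) n_prot + n_lig + seq_along(rings)
  else integer(0)
  # compute degree on ligand atoms from the bond list
  nodes$degree <- 0L
  if (nrow(ligand$bonds)) {
    tab <- table(c(ligand$bonds$a, ligand$bonds$b))
    nodes$degree[lig_ids[as.integer(names(tab))]] <- as.integer(tab)
  }
  geo <- build_geometric_edges(nodes, cutoffs)
  bonds_nodeids <- tibble::tibble(a = lig_ids[ligand$bonds$a],
                                  b = lig_ids[ligand$bonds$b])
  ring_mem <- if (length(rings)) {
    dplyr::bind_rows(lapply(seq_along(rings), function(r) {
      tibble::tibble(virtual_id = virt_ids[r],
                     atom_id = lig_ids[rings[[r]]$atoms])
    }))
  } else NULL
  if (is.null(interactions)) interactions <- detect_interactions(nodes, ifp)
  str_e <- build_structural_edges(nodes, bonds_nodeids, ring_mem,
                                  interactions)
  structure(list(
    nodes = nodes,
    edges = dplyr::bind_rows(geo, str_e),
    ligand_node_ids = lig_ids,
    pocket_node_ids = seq_len(n_prot),
    virtual_node_ids = virt_ids
  ), class = "complex_graph")
}

#' @export
print.complex_graph <- function(x, ...) {
  cat(sprintf(paste0("<complex_graph> %d nodes (%d protein, %d ligand,",
                     " %d virtual), %d directed edges\n"),
              nrow(x$nodes), length(x$pocket_node_ids),
              length(x$ligand_node_ids), length(x$virtual_node_ids),
              nrow(x$edges)))
  invisible(x)
}

#' Serialize / deserialize a complex graph as JSON
#' @param graph A `complex_graph`.
#' @param path Output (input) file path.
#' @return `path` invisibly; `read_complex_graph()` returns the graph.
#' @export
write_complex_graph <- function(graph, path) {
  nodes <- graph$nodes
  nodes$h_coord <- NULL
  jsonlite::write_json(list(
    nodes = nodes, edges = graph$edges,
    ligand_node_ids = graph$ligand_node_ids,
    pocket_node_ids = graph$pocket_node_ids,
    virtual_node_ids = graph$virtual_node_ids
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_complex_graph
#' @export
read_complex_graph <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    nodes = tibble::as_tibble(x$nodes),
    edges = tibble::as_tibble(x$edges),
    ligand_node_ids = as.integer(x$ligand_node_ids),
    pocket_node_ids = as.integer(x$pocket_node_ids),
    virtual_node_ids = as.integer(x$virtual_node_ids)
  ), class = "complex_graph")
}
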