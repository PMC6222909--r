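#' Build a toy gas-phase solute
#'
#' Constructs a gas-phase [system_model()] from a flat solute
#' specification.  Each atom is given its own atom type (named
#' `S1 ... Sn`), so per-bond and per-angle parameters can be supplied
#' directly.  Angle triples are derived from the connectivity (every
#' bonded path i-j-k), and the 1-2/1-3 exclusion set is populated
#' automatically.  A deterministic starting geometry (a jittered chain
#' respecting `b0`) is attached as `frame0`.
#'
#' @param spec a list with elements
#'   * `atoms`: data frame with columns `mass`, `charge` and optionally
#'     `lj_epsilon`, `lj_rmin_half`, `polarizability`, `drude_spring`;
#'   * `bonds`: data frame with columns `i`, `j`, `k_b`, `b0`;
#'   * `angle_k`, `angle_theta0`: scalars (or vectors, one per derived
#'     angle) with the angle force constant (kcal/mol/rad^2) and
#'     equilibrium angle (rad); defaults 60 and 109.47 degrees.
#' @param seed integer seed controlling the geometry jitter.
#' @return a gas-phase `system_model` at level `"MM"`.
#' @export
#' @examples
#' m <- build_solute(toy_triatomic_spec(), seed = 1)
#' nrow(m$topology$bonds)  # 2
build_solute <- function(spec, seed = 1L) {
  atoms <- as.data.frame(spec$atoms)
  n <- nrow(atoms)
  if (n < 1) abort("spec$atoms is empty", class = "alchemr_validation")
  for (fld in c("mass", "charge"))
    if (is.null(atoms[[fld]]) || length(atoms[[fld]]) != n)
      abort(paste0("spec$atoms$", fld, " missing or wrong length"),
            class = "alchemr_validation")
  defaults <- list(lj_epsilon = 0.1, lj_rmin_half = 1.6,
                   polarizability = 0, drude_spring = 1000)
  for (fld in names(defaults))
    if (is.null(atoms[[fld]])) atoms[[fld]] <- defaults[[fld]]
  bonds <- as.data.frame(spec$bonds %||% data.frame())
  if (nrow(bonds)) {
    for (fld in c("i", "j", "k_b", "b0"))
      if (is.null(bonds[[fld]]))
        abort(paste0("spec$bonds$", fld, " missing"),
              class = "alchemr_validation")
    if (max(bonds$i, bonds$j) > n || min(bonds$i, bonds$j) < 1)
      abort("spec$bonds refers to an atom id outside spec$atoms",
            class = "alchemr_validation")
  }

  type_names <- paste0("S", seq_len(n))
  atom_types <- lapply(seq_len(n), function(k)
    atom_type(type_names[k], atoms$mass[k], atoms$charge[k],
              atoms$lj_epsilon[k], atoms$lj_rmin_half[k],
              atoms$polarizability[k], atoms$drude_spring[k]))

  bond_mat <- if (nrow(bonds)) cbind(bonds$i, bonds$j) else NULL
  angle_mat <- derive_angles(bond_mat, n)
  bp <- if (nrow(bonds))
    tibble(type_i = type_names[bonds$i], type_j = type_names[bonds$j],
           k_b = bonds$k_b, b0 = bonds$b0)
  else NULL
  ap <- if (nrow(angle_mat)) {
    k_th <- rep_len(spec$angle_k %||% 60, nrow(angle_mat))
    th0 <- rep_len(spec$angle_theta0 %||% (109.47 * pi / 180), nrow(angle_mat))
    tibble(type_i = type_names[angle_mat[, 1]],
           type_j = type_names[angle_mat[, 2]],
           type_k = type_names[angle_mat[, 3]],
           k_theta = k_th, theta0 = th0)
  } else NULL

  top <- topology(
    atoms = tibble(id = seq_len(n), type = type_names, group = "solute"),
    bonds = bond_mat, angles = angle_mat)
  pars <- parameter_set(atom_types, bp, ap)
  coords <- chain_geometry(top, pars, seed)
  system_model(top, pars, level = "MM", frame0 = new_frame(coords))
}

derive_angles <- function(bonds, n) {
  if (is.null(bonds) || !nrow(bonds)) return(matrix(integer(), 0, 3))
  nb <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    nb[[bonds[r, 1]]] <- c(nb[[bonds[r, 1]]], bonds[r, 2])
    nb[[bonds[r, 2]]] <- c(nb[[bonds[r, 2]]], bonds[r, 1])
  }
  out <- NULL
  for (j in seq_len(n)) {
    v <- sort(unique(nb[[j]]))
    if (length(v) > 1) {
      cmb <- utils::combn(v, 2)
      out <- rbind(out, cbind(cmb[1, ], j, cmb[2, ]))
    }
  }
  if (is.null(out)) matrix(integer(), 0, 3) else out
}

# deterministic chain-ish starting geometry: follow bonds breadth-first,
# placing each new atom at its b0 from the parent in a jittered direction
chain_geometry <- function(top, pars, seed) {
  n <- nrow(top$atoms)
  set.seed(as.integer(seed))
  coords <- matrix(0, n, 3)
  if (n == 1 || !nrow(top$bonds)) {
    coords[, 1] <- seq_len(n) * 2.0
    return(coords)
  }
  types <- top$atoms$type
  placed <- rep(FALSE, n)
  placed[1] <- TRUE
  queue <- 1L
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    hits <- which(top$bonds[, 1] == cur | top$bonds[, 2] == cur)
    for (h in hits) {
      other <- setdiff(top$bonds[h, ], cur)
      if (placed[other]) next
      bp <- lookup_bond_param(pars, types[cur], types[other])
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      coords[other, ] <- coords[cur, ] + bp$b0 * dir
      placed[other] <- TRUE
      queue <- c(queue, other)
    }
  }
  coords
}

#' A small bent-triatomic solute specification
#'
#' A convenient built-in three-atom dipolar solute (one heavy site plus
#' two light sites, net charge zero) used throughout the examples and
#' tests.
#'
#' @param polarizable attach a polarizability to the heavy site.
#' @return a solute spec list for [build_solute()].
#' @export
toy_triatomic_spec <- function(polarizable = FALSE) {
  list(
    atoms = data.frame(
      mass = c(16, 1, 1),
      charge = c(-0.8, 0.4, 0.4),
      lj_epsilon = c(0.15, 0.03, 0.03),
      lj_rmin_half = c(1.75, 0.6, 0.6),
      polarizability = c(if (polarizable) 0.003 else 0, 0, 0)),
    bonds = data.frame(i = c(1, 1), j = c(2, 3),
                       k_b = c(450, 450), b0 = c(1.0, 1.0)),
    angle_k = 55, angle_theta0 = 104.52 * pi / 180)
}

#' Build a toy solvent box
#'
#' Places `n_molecules` copies of a rigid-geometry-by-stiff-springs
#' three-site solvent (a water-like bent triatomic) on a jittered cubic
#' lattice inside a periodic box.  `model = "polarizable4site"` adds an
#' isotropic polarizability (a Drude-bearing site) to each heavy site.
#' Placement is deterministic for a fixed seed and guarantees no
#' intermolecular atom pair closer than 0.8 times the sum of the two LJ
#' half-Rmin values.
#'
#' @param n_molecules number of solvent molecules (>= 1).
#' @param edge cubic box edge (A).
#' @param model `"fixed3site"` or `"polarizable4site"`.
#' @param seed integer seed.
#' @return a periodic `system_model` at level `"MM"` with `frame0` set.
#' @export
#' @examples
#' box <- build_solvent_box(8, edge = 8, model = "fixed3site", seed = 1)
#' n_atoms <- nrow(box$topology$atoms)  # 24
build_solvent_box <- function(n_molecules, edge,
                              model = c("fixed3site", "polarizable4site"),
                              seed = 1L) {
  model <- match.arg(model)
  if (n_molecules < 1) abort("n_molecules must be >= 1",
                             class = "alchemr_validation")
  polar <- model == "polarizable4site"
  types <- list(
    atom_type("OW", 16, -0.8, 0.15, 1.75,
              polarizability = if (polar) 0.003 else 0, drude_spring = 1000),
    atom_type("HW", 1, 0.4, 0.03, 0.6))
  bp <- tibble(type_i = "OW", type_j = "HW", k_b = 450, b0 = 1.0)
  ap <- tibble(type_i = "HW", type_j = "OW", type_k = "HW",
               k_theta = 55, theta0 = 104.52 * pi / 180)

  per_cell <- ceiling(n_molecules^(1 / 3))
  spacing <- edge / per_cell
  # conservative packing check: molecule "radius" ~ b0 + rmin_half(H)
  if (spacing < 2 * (1.0 + 0.8 * (1.75 + 0.6)) / 2)
    abort(paste0("cannot place ", n_molecules, " molecules in a box of edge ",
                 edge, " A without overlap; use a larger edge"),
          class = "alchemr_packing")
  set.seed(as.integer(seed))
  theta0 <- 104.52 * pi / 180
  local_geom <- rbind(c(0, 0, 0),
                      c(1.0, 0, 0),
                      c(cos(theta0), sin(theta0), 0))
  coords <- matrix(0, 3 * n_molecules, 3)
  mol <- 0L
  for (ix in seq_len(per_cell)) for (iy in seq_len(per_cell))
    for (iz in seq_len(per_cell)) {
      if (mol >= n_molecules) break
      mol <- mol + 1L
      centre <- (c(ix, iy, iz) - 0.5) * spacing +
        runif(3, -0.05, 0.05) * spacing
      rot <- random_rotation()
      coords[(3 * mol - 2):(3 * mol), ] <-
        sweep(local_geom %*% t(rot), 2, centre, `+`)
    }
  n <- 3 * n_molecules
  atoms <- tibble(id = seq_len(n),
                  type = rep(c("OW", "HW", "HW"), n_molecules),
                  group = "solvent")
  base <- 3 * (seq_len(n_molecules) - 1)
  bonds <- rbind(cbind(base + 1, base + 2), cbind(base + 1, base + 3))
  top <- topology(atoms, bonds = bonds)
  pars <- parameter_set(types, bp, ap)
  m <- system_model(top, pars, level = "MM", box_edge = edge,
                    frame0 = new_frame(coords))
  check_packing(m)
  m
}

random_rotation <- function() {
  # QR-based uniform random rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

check_packing <- function(model) {
  f <- model$frame0
  top <- model$topology
  rmh <- vapply(model$parameters$atom_types[top$atoms$type],
                `[[`, 0, "lj_rmin_half")
  d <- pair_distances(f$coordinates, model$box_edge)
  mol_of <- (top$atoms$id - 1) %/% 3
  same_mol <- outer(mol_of, mol_of, `==`)
  thresh <- 0.8 * outer(rmh, rmh, `+`)
  bad <- d < thresh & !same_mol & upper.tri(d)
  if (any(bad))
    abort("solvent packing produced an intermolecular overlap; use a larger edge",
          class = "alchemr_packing")
  invisible(model)
}

pair_distances <- function(coords, box_edge = NULL) {
  n <- nrow(coords)
  d <- matrix(0, n, n)
  for (k in 1:3) {
    dx <- outer(coords[, k], coords[, k], `-`)
    if (!is.null(box_edge)) dx <- dx - box_edge * round(dx / box_edge)
    d <- d + dx^2
  }
  sqrt(d)
}

#' Merge a solute into a solvent box
#'
#' Places the solute at the box centre (solvent molecules overlapping the
#' solute within the packing threshold are removed) and concatenates
#' topologies.  Used to assemble the aqueous-phase systems.
#'
#' @param solute gas-phase solute [system_model()].
#' @param box solvent box [system_model()].
#' @return a combined periodic `system_model`.
#' @export
solvate <- function(solute, box) {
  ns <- n_atoms(solute)
  edge <- box$box_edge
  sol_coords <- solute$frame0$coordinates
  sol_coords <- sweep(sol_coords, 2, colMeans(sol_coords), `-`)
  sol_coords <- sweep(sol_coords, 2, rep(edge / 2, 3), `+`)

  rmh_s <- vapply(solute$parameters$atom_types[solute$topology$atoms$type],
                  `[[`, 0, "lj_rmin_half")
  rmh_w <- vapply(box$parameters$atom_types[box$topology$atoms$type],
                  `[[`, 0, "lj_rmin_half")
  keep_mol <- rep(TRUE, nrow(box$topology$atoms) / 3)
  for (im in seq_along(keep_mol)) {
    rows <- (3 * im - 2):(3 * im)
    for (r in rows) {
      dx <- sweep(sol_coords, 2, box$frame0$coordinates[r, ], `-`)
      dx <- dx - edge * round(dx / edge)
      gap <- sqrt(rowSums(dx^2)) - 0.8 * (rmh_s + rmh_w[r])
      if (min(gap) < 0) { keep_mol[im] <- FALSE; break }
    }
  }
  keep_rows <- as.vector(t(outer(which(keep_mol) * 3 - 2, 0:2, `+`)))
  nw <- length(keep_rows)

  w_atoms <- box$topology$atoms[keep_rows, ]
  w_atoms$id <- ns + seq_len(nw)
  atoms <- dplyr::bind_rows(solute$topology$atoms, w_atoms)
  remap <- setNames(ns + seq_len(nw), keep_rows)
  w_bonds <- box$topology$bonds[box$topology$bonds[, 1] %in% keep_rows, ,
                                drop = FALSE]
  w_bonds <- matrix(remap[as.character(w_bonds)], ncol = 2)
  bonds <- rbind(solute$topology$bonds, w_bonds)
  top <- topology(atoms, bonds = bonds)
  pars <- parameter_set(
    c(solute$parameters$atom_types, box$parameters$atom_types),
    dplyr::bind_rows(solute$parameters$bond_params, box$parameters$bond_params),
    dplyr::bind_rows(solute$parameters$angle_params, box$parameters$angle_params))
  coords <- rbind(sol_coords, box$frame0$coordinates[keep_rows, , drop = FALSE])
  system_model(top, pars, level = solute$level, box_edge = edge,
               frame0 = new_frame(coords))
}

#' Build a surrogate target Hamiltonian
#'
#' Derives a level-`TARGET` model from a base `MM` model by shifting
#' equilibrium bond lengths, shifting equilibrium angles, scaling all
#' charges, and optionally replacing the harmonic bonds by Morse bonds
#' `D * (1 - exp(-a (b - b0)))^2` with `a = sqrt(k_b / D)` (curvature
#' matched to the harmonic form).  The surrogate plays the role of a
#' high-level (QM-like) Hamiltonian with a displaced energy minimum, the
#' regime in which reweighting between Hamiltonian levels degrades and a
#' tailored force field helps.
#'
#' @param base a level-`MM` [system_model()].
#' @param bond_shifts numeric, shift of each bond's `b0` (A); recycled.
#' @param angle_shifts numeric, shift of each angle's `theta0` (rad);
#'   recycled.
#' @param charge_scale multiplier applied to every charge.
#' @param morse use Morse bonds in the target.
#' @param morse_depth Morse well depth D (kcal/mol).
#' @return a level-`TARGET` `system_model` sharing the base topology.
#' @export
#' @examples
#' m <- build_solute(toy_triatomic_spec(), seed = 1)
#' tgt <- make_surrogate_target(m, bond_shifts = 0.36)
make_surrogate_target <- function(base, bond_shifts = 0, angle_shifts = 0,
                                  charge_scale = 1, morse = FALSE,
                                  morse_depth = 100) {
  if (base$level != "MM")
    abort("surrogate targets must be derived from a level-MM model",
          class = "alchemr_validation")
  nb <- nrow(base$topology$bonds)
  na <- nrow(base$topology$angles)
  bond_shifts <- rep_len(bond_shifts, max(nb, 1))
  angle_shifts <- rep_len(angle_shifts, max(na, 1))

  tgt <- base
  tgt$level <- "TARGET"
  tgt$charge_scale <- charge_scale
  tgt$morse <- isTRUE(morse)
  tgt$morse_depth <- if (isTRUE(morse)) morse_depth else NA_real_
  if (nb) {
    types <- base$topology$atoms$type
    bp <- lookup_bond_param(base$parameters, types[base$topology$bonds[, 1]],
                            types[base$topology$bonds[, 2]])
    b0_new <- bp$b0 + bond_shifts
    if (any(b0_new <= 0))
      abort("bond_shifts would make an equilibrium bond length <= 0",
            class = "alchemr_validation")
    tgt$bond_overrides <- tibble(bond = seq_len(nb), k_b = bp$k_b, b0 = b0_new)
  }
  if (na && any(angle_shifts != 0)) {
    types <- base$topology$atoms$type
    ap <- lookup_angle_param(base$parameters,
                             types[base$topology$angles[, 1]],
                             types[base$topology$angles[, 2]],
                             types[base$topology$angles[, 3]])
    th_new <- ap$theta0 + angle_shifts
    if (any(th_new <= 0) || any(th_new >= pi))
      abort("angle_shifts would push theta0 outside (0, pi)",
            class = "alchemr_validation")
    tgt$angle_overrides <- tibble(angle = seq_len(na), k_theta = ap$k_theta,
                                  theta0 = th_new)
  }
  tgt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
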