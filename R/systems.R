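#' Atom types
#'
#' An atom type bundles the per-type force-field parameters: mass, partial
#' charge, Lennard-Jones well depth and half-Rmin, and (for polarizable
#' sites) an isotropic polarizability with the spring constant of the
#' attached Drude particle.  The Drude charge is derived, not stored:
#' `q_D = -sqrt(polarizability * drude_spring)`, the standard
#' charge-on-spring relation (so `alpha = q_D^2 / k_D`).
#'
#' @param name short unique type name.
#' @param mass atomic mass (amu).
#' @param charge partial charge (e).
#' @param lj_epsilon LJ well depth (kcal/mol), >= 0.
#' @param lj_rmin_half half the LJ minimum-energy distance (angstrom).
#' @param polarizability isotropic polarizability in package units
#'   (e^2 A^2 mol/kcal); 0 for non-polarizable sites.
#' @param drude_spring Drude spring constant (kcal/mol/A^2).
#' @return an `atom_type` object.
#' @export
#' @examples
#' ot <- atom_type("OW", 16, -0.8, lj_epsilon = 0.15, lj_rmin_half = 1.75)
#' drude_charge(atom_type("OD", 16, -0.8, 0.15, 1.75,
#'                        polarizability = 0.003, drude_spring = 1000))
atom_type <- function(name, mass, charge, lj_epsilon = 0, lj_rmin_half = 1,
                      polarizability = 0, drude_spring = 1000) {
  stopifnot(is.character(name), nchar(name) > 0)
  if (lj_epsilon < 0) abort("lj_epsilon must be >= 0", class = "alchemr_validation")
  if (lj_epsilon > 0 && lj_rmin_half <= 0)
    abort("lj_rmin_half must be > 0 when lj_epsilon > 0", class = "alchemr_validation")
  if (polarizability < 0)
    abort("polarizability must be >= 0", class = "alchemr_validation")
  if (polarizability > 0 && drude_spring <= 0)
    abort("drude_spring must be > 0 when polarizability > 0",
          class = "alchemr_validation")
  structure(
    list(name = name, mass = mass, charge = charge,
         lj_epsilon = lj_epsilon, lj_rmin_half = lj_rmin_half,
         polarizability = polarizability, drude_spring = drude_spring),
    class = "atom_type")
}

#' @rdname atom_type
#' @param x an `atom_type`.
#' @export
drude_charge <- function(x) {
  if (x$polarizability == 0) return(0)
  -sqrt(x$polarizability * x$drude_spring)
}

#' Parameter sets
#'
#' A parameter set maps atom-type names to [atom_type()] records and
#' (unordered) type tuples to harmonic bond and angle parameters.  Bond
#' and angle energies use the convention `K * (x - x0)^2` without the 1/2
#' prefactor.
#'
#' @param atom_types list of [atom_type()] objects.
#' @param bond_params tibble with columns `type_i`, `type_j`, `k_b`
#'   (kcal/mol/A^2) and `b0` (A).
#' @param angle_params tibble with columns `type_i`, `type_j`, `type_k`,
#'   `k_theta` (kcal/mol/rad^2) and `theta0` (rad); `type_j` is the apex.
#' @return a `parameter_set` object.
#' @export
parameter_set <- function(atom_types, bond_params = NULL, angle_params = NULL) {
  names(atom_types) <- vapply(atom_types, `[[`, "", "name")
  bond_params <- if (is.null(bond_params)) {
    tibble(type_i = character(), type_j = character(),
           k_b = numeric(), b0 = numeric())
  } else as_tibble(bond_params)
  angle_params <- if (is.null(angle_params)) {
    tibble(type_i = character(), type_j = character(), type_k = character(),
           k_theta = numeric(), theta0 = numeric())
  } else as_tibble(angle_params)
  if (any(bond_params$k_b <= 0) || any(bond_params$b0 <= 0))
    abort("bond parameters require k_b > 0 and b0 > 0",
          class = "alchemr_validation")
  if (any(angle_params$k_theta <= 0) ||
      any(angle_params$theta0 <= 0) || any(angle_params$theta0 >= pi))
    abort("angle parameters require k_theta > 0 and 0 < theta0 < pi",
          class = "alchemr_validation")
  structure(list(atom_types = atom_types, bond_params = bond_params,
                 angle_params = angle_params),
            class = "parameter_set")
}

bond_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "~")
angle_key <- function(a, b, c) paste(pmin(a, c), b, pmax(a, c), sep = "~")

lookup_bond_param <- function(params, type_a, type_b) {
  keys <- with(params$bond_params, bond_key(type_i, type_j))
  idx <- match(bond_key(type_a, type_b), keys)
  if (any(is.na(idx))) {
    bad <- paste(type_a[is.na(idx)], type_b[is.na(idx)], sep = "-")
    abort(paste0("no bond parameters for type pair(s): ",
                 paste(unique(bad), collapse = ", ")),
          class = "alchemr_missing_parameter")
  }
  params$bond_params[idx, ]
}

lookup_angle_param <- function(params, type_a, type_b, type_c) {
  keys <- with(params$angle_params, angle_key(type_i, type_j, type_k))
  idx <- match(angle_key(type_a, type_b, type_c), keys)
  if (any(is.na(idx))) {
    bad <- paste(type_a[is.na(idx)], type_b[is.na(idx)], type_c[is.na(idx)],
                 sep = "-")
    abort(paste0("no angle parameters for type triple(s): ",
                 paste(unique(bad), collapse = ", ")),
          class = "alchemr_missing_parameter")
  }
  params$angle_params[idx, ]
}

#' Topologies
#'
#' A topology lists atoms (with their type names and a group tag, solute
#' or solvent), bonds, angles and nonbonded exclusions.  Atom ids are
#' 1-based and contiguous.  1-2 and 1-3 pairs are always excluded from
#' nonbonded interactions; [auto_exclusions()] derives that set from the
#' bond list.
#'
#' @param atoms tibble with columns `id`, `type`, `group`
#'   (`"solute"` or `"solvent"`).
#' @param bonds integer matrix with two columns of atom ids.
#' @param angles integer matrix with three columns of atom ids (apex in
#'   the middle).
#' @param exclusions integer matrix of excluded pairs; defaults to the
#'   1-2/1-3 set implied by the bonds.
#' @return a `topology` object.
#' @export
topology <- function(atoms, bonds = NULL, angles = NULL, exclusions = NULL) {
  atoms <- as_tibble(atoms)
  n <- nrow(atoms)
  if (!identical(as.integer(atoms$id), seq_len(n)))
    abort("atom ids must be unique and contiguous starting at 1",
          class = "alchemr_validation")
  if (!all(atoms$group %in% c("solute", "solvent")))
    abort("group tags must be 'solute' or 'solvent'",
          class = "alchemr_validation")
  bonds <- if (is.null(bonds)) matrix(integer(), 0, 2) else
    matrix(as.integer(bonds), ncol = 2)
  angles <- if (is.null(angles)) matrix(integer(), 0, 3) else
    matrix(as.integer(angles), ncol = 3)
  if (nrow(bonds) && (max(bonds) > n || min(bonds) < 1))
    abort("bond refers to an invalid atom id", class = "alchemr_validation")
  if (nrow(angles) && (max(angles) > n || min(angles) < 1))
    abort("angle refers to an invalid atom id", class = "alchemr_validation")
  auto <- auto_exclusions(bonds, angles)
  exclusions <- if (is.null(exclusions)) auto else
    unique(rbind(normalize_pairs(matrix(as.integer(exclusions), ncol = 2)), auto))
  structure(list(atoms = atoms, bonds = bonds, angles = angles,
                 exclusions = exclusions),
            class = "topology")
}

normalize_pairs <- function(p) {
  if (!nrow(p)) return(p)
  unique(cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2])))
}

#' @rdname topology
#' @export
auto_exclusions <- function(bonds, angles = NULL) {
  ex <- bonds
  if (!is.null(angles) && nrow(angles))
    ex <- rbind(ex, angles[, c(1, 3), drop = FALSE])
  # 1-3 pairs implied by shared bonded neighbours
  if (nrow(bonds)) {
    nb <- split(c(bonds[, 2], bonds[, 1]), c(bonds[, 1], bonds[, 2]))
    for (centre in names(nb)) {
      v <- unique(nb[[centre]])
      if (length(v) > 1) {
        cmb <- utils::combn(sort(v), 2)
        ex <- rbind(ex, t(cmb))
      }
    }
  }
  normalize_pairs(matrix(as.integer(ex), ncol = 2))
}

#' System models
#'
#' A system model binds a [topology()] to a [parameter_set()] and tags it
#' with a Hamiltonian level: `"MM"` (the base force field), `"MM'"` (a
#' tailored force field) or `"TARGET"` (the surrogate high-level
#' Hamiltonian that plays the QM role).  `box_edge` gives the cubic
#' periodic box edge in angstrom, or `NULL` for the gas phase.
#'
#' Surrogate targets may carry per-bond equilibrium-length overrides, an
#' optional Morse bond form, and a global charge scaling; see
#' [make_surrogate_target()].
#'
#' @param topology a [topology()].
#' @param parameters a [parameter_set()].
#' @param level one of `"MM"`, `"MM'"`, `"TARGET"`.
#' @param box_edge cubic box edge (A) or `NULL`.
#' @param frame0 optional reference [new_frame()] with starting
#'   coordinates.
#' @return a `system_model` object.
#' @export
system_model <- function(topology, parameters, level = "MM", box_edge = NULL,
                         frame0 = NULL) {
  level <- match.arg(level, c("MM", "MM'", "TARGET"))
  m <- structure(
    list(topology = topology, parameters = parameters, level = level,
         box_edge = box_edge, frame0 = frame0,
         bond_overrides = NULL, charge_scale = 1,
         morse = FALSE, morse_depth = NA_real_),
    class = "system_model")
  validate_system(m)
  m
}

#' Validate a system model
#'
#' Checks type-resolution of all bonds and angles, exclusion coverage of
#' 1-2/1-3 pairs, and per-type invariants.  Called by the builders;
#' errors carry class `alchemr_validation`.
#'
#' @param model a [system_model()].
#' @return the model, invisibly.
#' @export
validate_system <- function(model) {
  top <- model$topology
  par <- model$parameters
  types <- top$atoms$type
  if (!all(types %in% names(par$atom_types)))
    abort(paste0("unknown atom type(s): ",
                 paste(setdiff(types, names(par$atom_types)), collapse = ", ")),
          class = "alchemr_validation")
  if (nrow(top$bonds))
    lookup_bond_param(par, types[top$bonds[, 1]], types[top$bonds[, 2]])
  if (nrow(top$angles))
    lookup_angle_param(par, types[top$angles[, 1]], types[top$angles[, 2]],
                       types[top$angles[, 3]])
  need <- auto_exclusions(top$bonds, top$angles)
  if (nrow(need)) {
    have <- paste(top$exclusions[, 1], top$exclusions[, 2])
    if (!all(paste(need[, 1], need[, 2]) %in% have))
      abort("1-2/1-3 pairs missing from exclusions",
            class = "alchemr_validation")
  }
  invisible(model)
}

n_atoms <- function(model) nrow(model$topology$atoms)

#' Coordinate frames
#'
#' A frame holds per-atom Cartesian coordinates and, for polarizable
#' systems, per-atom Drude displacements (rows for non-polarizable atoms
#' are zero and ignored).
#'
#' @param coordinates numeric n x 3 matrix (A).
#' @param drude numeric n x 3 matrix of Drude displacements (A), or
#'   `NULL` for all-zero.
#' @param replica_index integer replica label.
#' @param step integer step label.
#' @return a `frame` object.
#' @export
new_frame <- function(coordinates, drude = NULL, replica_index = 0L, step = 0L) {
  coordinates <- matrix(as.numeric(coordinates), ncol = 3)
  if (is.null(drude)) drude <- matrix(0, nrow(coordinates), 3)
  drude <- matrix(as.numeric(drude), ncol = 3)
  if (nrow(drude) != nrow(coordinates))
    abort("drude displacement rows must match atom count",
          class = "alchemr_validation")
  if (!all(is.finite(coordinates)) || !all(is.finite(drude)))
    abort("non-finite coordinates", class = "alchemr_validation")
  structure(list(coordinates = coordinates, drude = drude,
                 replica_index = as.integer(replica_index),
                 step = as.integer(step)),
            class = "frame")
}

check_frame <- function(model, frame) {
  if (nrow(frame$coordinates) != n_atoms(model))
    abort("frame does not match topology (atom count differs)",
          class = "alchemr_validation")
  invisible(frame)
}
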