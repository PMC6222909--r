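#' Gas-phase geometry minimization
#'
#' BFGS minimization of the gas-phase potential energy with the analytic
#' gradient, reported with the infinity norm of the final gradient.
#' Deterministic: no randomness is involved.  Hitting `max_iter` returns
#' `converged = FALSE` rather than an error.
#'
#' @param model gas-phase [system_model()] (level MM or TARGET).
#' @param start starting [new_frame()]; defaults to the model's
#'   `frame0`.
#' @param tol convergence tolerance on the gradient infinity norm
#'   (kcal/mol/A).
#' @param max_iter iteration cap.
#' @return a `minimization_report` list: `final_coordinates` (a frame),
#'   `final_energy`, `grad_inf_norm`, `n_iterations`, `converged`,
#'   `tol`.
#' @export
#' @examples
#' m <- build_solute(toy_triatomic_spec(), seed = 1)
#' rep <- minimize_geometry(m)
#' rep$converged
minimize_geometry <- function(model, start = NULL, tol = 1e-6,
                              max_iter = 2000) {
  if (!is.null(model$box_edge))
    abort("minimize_geometry expects a gas-phase model",
          class = "alchemr_validation")
  start <- start %||% model$frame0
  if (is.null(start))
    abort("no starting frame available", class = "alchemr_validation")
  cs <- compile_system(model)
  settings <- nonbonded_settings()
  n <- cs$n
  fn <- function(x) total_energy(cs, new_frame(matrix(x, n, 3)),
                                 settings = settings)
  gr <- function(x) as.vector(energy_gradient(cs, new_frame(matrix(x, n, 3)),
                                              settings = settings))
  x0 <- as.vector(start$coordinates)
  opt <- optim(x0, fn, gr, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-16))
  # polish with a few extra restarts if the gradient is not yet tight
  tries <- 0
  while (max(abs(gr(opt$par))) > tol && tries < 5) {
    opt <- optim(opt$par, fn, gr, method = "BFGS",
                 control = list(maxit = max_iter, reltol = 1e-16))
    tries <- tries + 1
  }
  gnorm <- max(abs(gr(opt$par)))
  structure(
    list(final_coordinates = new_frame(matrix(opt$par, n, 3)),
         final_energy = opt$value,
         grad_inf_norm = gnorm,
         n_iterations = opt$counts[["function"]],
         converged = gnorm <= tol,
         tol = tol),
    class = "minimization_report")
}

#' Generate a tailored force field (MM')
#'
#' Builds the tailored level-MM' model from a base MM model and a
#' converged target-minimized geometry: every atom is assigned a fresh
#' unique atom type; every bond's `b0` and every angle's `theta0` are
#' set to the values measured in the target geometry; charges,
#' Lennard-Jones parameters, polarizabilities and force constants are
#' copied unchanged from the base types.  Matching the bonded minima of
#' the target Hamiltonian raises the phase-space overlap between the
#' sampled and target states, which is what makes the subsequent
#' one-sided reweighting converge faster.
#'
#' @param base level-MM [system_model()].
#' @param target_geometry either a converged [minimize_geometry()]
#'   report or a frame from one.
#' @return a level-MM' `system_model`.
#' @export
make_tailored_parameters <- function(base, target_geometry) {
  if (inherits(target_geometry, "minimization_report")) {
    if (!isTRUE(target_geometry$converged))
      abort("refusing to tailor against an unconverged geometry",
            class = "alchemr_validation")
    geom <- target_geometry$final_coordinates
  } else if (inherits(target_geometry, "frame")) {
    geom <- target_geometry
  } else {
    abort("target_geometry must be a minimization_report or frame",
          class = "alchemr_validation")
  }
  top <- base$topology
  n <- nrow(top$atoms)
  check_frame(base, geom)
  old_types <- base$parameters$atom_types[top$atoms$type]
  new_names <- paste0("T", seq_len(n))
  new_types <- lapply(seq_len(n), function(k) {
    t <- old_types[[k]]
    atom_type(new_names[k], t$mass, t$charge, t$lj_epsilon, t$lj_rmin_half,
              t$polarizability, t$drude_spring)
  })

  X <- geom$coordinates
  bp <- NULL
  if (nrow(top$bonds)) {
    old_bp <- lookup_bond_param(base$parameters, top$atoms$type[top$bonds[, 1]],
                                top$atoms$type[top$bonds[, 2]])
    b_meas <- sqrt(rowSums((X[top$bonds[, 1], , drop = FALSE] -
                              X[top$bonds[, 2], , drop = FALSE])^2))
    bp <- tibble(type_i = new_names[top$bonds[, 1]],
                 type_j = new_names[top$bonds[, 2]],
                 k_b = old_bp$k_b, b0 = b_meas)
  }
  ap <- NULL
  if (nrow(top$angles)) {
    old_ap <- lookup_angle_param(base$parameters,
                                 top$atoms$type[top$angles[, 1]],
                                 top$atoms$type[top$angles[, 2]],
                                 top$atoms$type[top$angles[, 3]])
    th_meas <- angle_values(X, list(i = top$angles[, 1], j = top$angles[, 2],
                                    k_atom = top$angles[, 3]))
    ap <- tibble(type_i = new_names[top$angles[, 1]],
                 type_j = new_names[top$angles[, 2]],
                 type_k = new_names[top$angles[, 3]],
                 k_theta = old_ap$k_theta, theta0 = th_meas)
  }
  new_top <- topology(
    tibble(id = top$atoms$id, type = new_names, group = top$atoms$group),
    bonds = top$bonds, angles = top$angles, exclusions = top$exclusions)
  m <- system_model(new_top, parameter_set(new_types, bp, ap), level = "MM'",
                    box_edge = base$box_edge, frame0 = geom)
  m
}
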