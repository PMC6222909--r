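#' Self-consistent Drude relaxation
#'
#' Minimizes the total energy over the Drude displacements while all
#' atoms are held in place, by damped successive substitution:
#' `d <- (1 - damping) d + damping q_D E_local / k_D`, where `E_local`
#' is the electric field at the Drude site from all other charge sites
#' (plus any uniform external field).  With the spring self-energy
#' `(1/2) k_D d^2` the fixed point satisfies `k_D d = q_D E_local`, so
#' an isolated site in a uniform field relaxes to `d = q_D E / k_D` with
#' induced dipole `alpha E`.
#'
#' An optional `radius` restricts relaxation to Drude sites within that
#' distance (minimum image) of any solute atom; sites outside keep
#' their displacements.
#'
#' @inheritParams total_energy
#' @param tol convergence tolerance on the largest component of the
#'   energy gradient with respect to the displacements (kcal/mol/A).
#' @param max_iter iteration cap.
#' @param radius relaxation radius around the solute (A) or `NULL` for
#'   all sites.
#' @param damping mixing factor of the successive-substitution update.
#' @return a list with `frame` (relaxed displacements), `energy`
#'   (kcal/mol, never above the input frame's energy), `n_iter` and
#'   `converged`.
#' @export
#' @examples
#' spec <- toy_triatomic_spec(polarizable = TRUE)
#' m <- build_solute(spec, seed = 1)
#' out <- drude_relax(m, m$frame0, efield = c(0.5, 0, 0))
drude_relax <- function(model, frame, tol = 1e-8, max_iter = 500,
                        radius = NULL, state = alchemical_state(),
                        settings = NULL, efield = NULL, damping = 0.5) {
  cs <- as_compiled(model)
  if (!any(cs$pol))
    abort("model has no polarizable sites", class = "alchemr_validation")
  if (is.null(settings))
    settings <- if (inherits(model, "system_model"))
      default_settings(model, bookend = TRUE) else nonbonded_settings()

  active <- cs$pol
  if (!is.null(radius)) {
    sol <- which(cs$is_solute)
    if (length(sol)) {
      X <- frame$coordinates
      for (i in which(cs$pol)) {
        dx <- sweep(X[sol, , drop = FALSE], 2, X[i, ], `-`)
        if (settings$use_min_image && !is.null(cs$box_edge))
          dx <- min_image(dx, cs$box_edge)
        if (sqrt(min(rowSums(dx^2))) > radius) active[i] <- FALSE
      }
    }
  }

  f <- frame
  e_prev <- total_energy(cs, f, state, settings, efield)
  e0 <- e_prev
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- drude_gradient(cs, f, state, settings, efield)
    gmax <- if (any(active)) max(abs(g[active, , drop = FALSE])) else 0
    if (gmax < tol) { converged <- TRUE; break }
    # field-based update: k_D d* = q_D E  <=>  d* = d - grad/k_D
    d_new <- f$drude
    d_new[active, ] <- f$drude[active, , drop = FALSE] -
      damping * g[active, , drop = FALSE] / cs$kd[active]
    f <- new_frame(f$coordinates, d_new, f$replica_index, f$step)
    e_now <- total_energy(cs, f, state, settings, efield)
    if (e_now > e_prev + 1e-8)
      abort(paste0("Drude relaxation diverged (energy increased by ",
                   format(e_now - e_prev), " kcal/mol); this is a ",
                   "polarization catastrophe - use a larger drude_spring"),
            class = "alchemr_polarization_catastrophe")
    e_prev <- e_now
  }
  if (!converged) {
    g <- drude_gradient(cs, f, state, settings, efield)
    converged <- (if (any(active)) max(abs(g[active, , drop = FALSE])) else 0) < tol
  }
  e_final <- total_energy(cs, f, state, settings, efield)
  stopifnot(e_final <= e0 + 1e-10)
  list(frame = f, energy = e_final, n_iter = iter, converged = converged)
}
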