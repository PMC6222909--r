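# Analytic gradients of the potential energy.  Used by the geometry
# minimizer and the Drude self-consistent relaxation; checked against
# finite differences in the test suite.

#' Gradient of the total potential energy
#'
#' Returns the derivative of [total_energy()] with respect to the atom
#' coordinates (an n x 3 matrix, kcal/mol/A).  Drude displacements are
#' held fixed and ride with their parent atoms.
#'
#' @inheritParams total_energy
#' @return n x 3 numeric matrix.
#' @export
energy_gradient <- function(model, frame, state = alchemical_state(),
                            settings = nonbonded_settings(), efield = NULL) {
  cs <- as_compiled(model)
  X <- frame$coordinates
  G <- matrix(0, cs$n, 3)

  # bonds
  if (!is.null(cs$bonds)) {
    i <- cs$bonds$i; j <- cs$bonds$j
    dv <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
    b <- sqrt(rowSums(dv^2))
    if (isTRUE(cs$morse)) {
      a <- sqrt(cs$bonds$k / cs$morse_depth)
      ex <- exp(-a * (b - cs$bonds$b0))
      dudb <- 2 * cs$morse_depth * a * ex * (1 - ex)
    } else {
      dudb <- 2 * cs$bonds$k * (b - cs$bonds$b0)
    }
    f <- dv * (dudb / b)
    G <- accumulate_rows(G, i, f)
    G <- accumulate_rows(G, j, -f)
  }

  # angles
  if (!is.null(cs$angles)) {
    ai <- cs$angles$i; aj <- cs$angles$j; ak <- cs$angles$k_atom
    u <- X[ai, , drop = FALSE] - X[aj, , drop = FALSE]
    v <- X[ak, , drop = FALSE] - X[aj, , drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    cth <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
    th <- acos(cth)
    sth <- pmax(sqrt(1 - cth^2), 1e-10)
    dudth <- 2 * cs$angles$k * (th - cs$angles$th0)
    # d(theta)/d(r_a) = -(v/(|u||v|) - cos(theta) u/|u|^2)/sin(theta)
    ga <- -(v / (nu * nv) - u * (cth / nu^2)) / sth * dudth
    gc <- -(u / (nu * nv) - v * (cth / nv^2)) / sth * dudth
    G <- accumulate_rows(G, ai, ga)
    G <- accumulate_rows(G, ak, gc)
    G <- accumulate_rows(G, aj, -(ga + gc))
  }

  edge <- if (settings$use_min_image) cs$box_edge else NULL

  # plain switched LJ on solvent-solvent pairs
  sel <- cs$pair_class == "vv"
  if (any(sel))
    G <- G + lj_pair_gradient(cs, X, cs$pair_i[sel], cs$pair_j[sel],
                              settings, edge)

  # soft-core LJ on solute-involving pairs
  sel <- cs$pair_class %in% c("ss", "sv")
  if (any(sel) && state$lambda_vdw < 1)
    G <- G + softcore_pair_gradient(cs, X, cs$pair_i[sel], cs$pair_j[sel],
                                    state$lambda_vdw, settings, edge)

  # coulomb over charge sites, accumulated to parent atoms
  if (length(cs$cpair_i)) {
    dv <- site_pair_dvec(cs, frame, edge)
    r <- sqrt(rowSums(dv^2))
    scale <- (1 - state$lambda_elec)^cs$c_scale_pow
    qq <- K_COULOMB * cs$cq_i * cs$cq_j * scale
    f <- dv * (-qq / r^3)
    G <- accumulate_rows(G, cs$cpair_i, f)
    G <- accumulate_rows(G, cs$cpair_j, -f)
  }

  # uniform external field
  if (!is.null(efield) && any(efield != 0)) {
    scale <- ifelse(cs$is_solute, 1 - state$lambda_elec, 1)
    qtot <- cs$q_core * scale
    qtot[cs$pol] <- qtot[cs$pol] + cs$qd[cs$pol] * scale[cs$pol]
    G <- G - outer(qtot, efield)
  }
  G
}

accumulate_rows <- function(G, idx, add) {
  for (k in 1:3)
    G[, k] <- G[, k] + tabulate_add(nrow(G), idx, add[, k])
  G
}

tabulate_add <- function(n, idx, vals) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

lj_pair_gradient <- function(cs, X, i, j, settings, edge) {
  G <- matrix(0, cs$n, 3)
  dv <- pair_dvec(X, i, j, edge)
  r <- sqrt(rowSums(dv^2))
  eps <- sqrt(cs$eps[i] * cs$eps[j])
  rmin <- cs$rmh[i] + cs$rmh[j]
  live <- eps > 0 & r < settings$r_off
  if (!any(live)) return(G)
  i <- i[live]; j <- j[live]; dv <- dv[live, , drop = FALSE]
  r <- r[live]; eps <- eps[live]; rmin <- rmin[live]
  x6 <- (rmin / r)^6
  u <- eps * (x6^2 - 2 * x6)
  dudr <- eps * (-12 * x6^2 + 12 * x6) / r
  s <- switch_fn(r, settings$r_on, settings$r_off)
  dsdr <- switch_fn_deriv(r, settings$r_on, settings$r_off)
  f <- dv * ((dudr * s + u * dsdr) / r)
  G <- accumulate_rows(G, i, f)
  accumulate_rows(G, j, -f)
}

softcore_pair_gradient <- function(cs, X, i, j, lam, settings, edge) {
  G <- matrix(0, cs$n, 3)
  dv <- pair_dvec(X, i, j, edge)
  r2 <- rowSums(dv^2)
  r <- sqrt(r2)
  eps <- sqrt(cs$eps[i] * cs$eps[j])
  rmin <- cs$rmh[i] + cs$rmh[j]
  live <- eps > 0 & r < settings$r_off
  if (!any(live)) return(G)
  i <- i[live]; j <- j[live]; dv <- dv[live, , drop = FALSE]
  r2 <- r2[live]; r <- r[live]; eps <- eps[live]; rmin <- rmin[live]
  sig2 <- (rmin / 2^(1 / 6))^2
  den <- r2 + settings$softcore_delta * lam * sig2
  u <- sig2 / den
  e <- (1 - lam) * 4 * eps * (u^6 - u^3)
  dudr <- -2 * r * sig2 / den^2
  dedr <- (1 - lam) * 4 * eps * (6 * u^5 - 3 * u^2) * dudr
  s <- switch_fn(r, settings$r_on, settings$r_off)
  dsdr <- switch_fn_deriv(r, settings$r_on, settings$r_off)
  f <- dv * ((dedr * s + e * dsdr) / r)
  G <- accumulate_rows(G, i, f)
  accumulate_rows(G, j, -f)
}

# gradient of the total energy with respect to Drude displacements
# (n x 3; rows of non-polarizable atoms are zero)
drude_gradient <- function(cs, frame, state = alchemical_state(),
                           settings = nonbonded_settings(), efield = NULL) {
  G <- matrix(0, cs$n, 3)
  if (!any(cs$pol)) return(G)
  # spring term: d/dd (1/2 k d^2) = k d
  G[cs$pol, ] <- frame$drude[cs$pol, , drop = FALSE] * cs$kd[cs$pol]
  if (length(cs$cpair_i)) {
    dv <- site_pair_dvec(cs, frame,
                         if (settings$use_min_image) cs$box_edge else NULL)
    r <- sqrt(rowSums(dv^2))
    scale <- (1 - state$lambda_elec)^cs$c_scale_pow
    qq <- K_COULOMB * cs$cq_i * cs$cq_j * scale
    f <- dv * (-qq / r^3)
    di <- cs$cdr_i; dj <- cs$cdr_j
    if (any(di)) G <- accumulate_rows(G, cs$cpair_i[di], f[di, , drop = FALSE])
    if (any(dj)) G <- accumulate_rows(G, cs$cpair_j[dj], -f[dj, , drop = FALSE])
  }
  if (!is.null(efield) && any(efield != 0)) {
    scale <- ifelse(cs$is_solute, 1 - state$lambda_elec, 1)
    qd_eff <- cs$qd * scale
    G[cs$pol, ] <- G[cs$pol, , drop = FALSE] -
      outer(qd_eff[cs$pol], efield)
  }
  G
}
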