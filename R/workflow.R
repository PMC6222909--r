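#' Hydration free energy from two annihilation legs
#'
#' `dG_hyd = dG_annih(gas) - dG_annih(aq)`: a solute whose interactions
#' cost more to remove in water than in vacuum has a favourable
#' (negative) hydration free energy.  Standard deviations combine in
#' quadrature across the two legs.
#'
#' @param gas_leg,aq_leg `fe_result`s from [run_alchemical_leg()]
#'   covering the same stages.
#' @return a `hydration_cycle` object with `dg_hyd`, per-leg totals,
#'   per-stage breakdowns and combined `sd`.
#' @export
hydration_cycle <- function(gas_leg, aq_leg) {
  st_g <- gas_leg$diagnostics$stage_totals
  st_a <- aq_leg$diagnostics$stage_totals
  if (!is.null(st_g) && !is.null(st_a) &&
      !setequal(st_g$stage, st_a$stage))
    abort("gas and aqueous legs cover different stages",
          class = "alchemr_validation")
  dg_hyd <- gas_leg$delta_g - aq_leg$delta_g
  sd_c <- sqrt(sum(c(gas_leg$std_dev, aq_leg$std_dev)^2, na.rm = TRUE))
  structure(
    list(dg_annih_gas = gas_leg$delta_g, dg_annih_aq = aq_leg$delta_g,
         dg_hyd = dg_hyd, sd = sd_c,
         stage_gas = st_g, stage_aq = st_a,
         repeats = max(gas_leg$n_repeats, aq_leg$n_repeats),
         route = "mm"),
    class = "hydration_cycle")
}

#' @export
print.hydration_cycle <- function(x, ...) {
  cat(sprintf("<hydration_cycle> dG_hyd = %.4g +/- %.3g kcal/mol (route %s)\n",
              x$dg_hyd, x$sd, x$route))
  cat(sprintf("  gas annihilation: %.4g   aqueous annihilation: %.4g\n",
              x$dg_annih_gas, x$dg_annih_aq))
  invisible(x)
}

#' Bookend-correct a hydration cycle to a target Hamiltonian
#'
#' Adds the end-point corrections between the sampling Hamiltonian and
#' the target Hamiltonian to a low-level hydration cycle:
#' `dG_hyd(TARGET) = dG_hyd(MM) + dG_corr(aq) - dG_corr(gas)`, where
#' each correction is a free-energy difference MM -> TARGET computed at
#' the fully interacting physical end point of that phase.
#'
#' @param mm_cycle a [hydration_cycle()] at the sampling level.
#' @param gas_corr,aq_corr `fe_result`s for the MM -> TARGET correction
#'   in each phase (from [exp_zwanzig()], [bar_estimate()] or
#'   [nbb_estimate()]).
#' @param route label of the bookend route: `"direct"` (one-sided
#'   reweighting from MM), `"via_mm_prime"` (through a tailored force
#'   field) or `"nbb"`.
#' @return a corrected `hydration_cycle`.
#' @export
bookend_correct <- function(mm_cycle, gas_corr, aq_corr,
                            route = c("direct", "via_mm_prime", "nbb")) {
  route <- match.arg(route)
  if (is.null(gas_corr) || is.null(aq_corr))
    abort("both gas and aqueous corrections are required",
          class = "alchemr_validation")
  out <- mm_cycle
  out$dg_hyd <- mm_cycle$dg_hyd + aq_corr$delta_g - gas_corr$delta_g
  out$sd <- sqrt(sum(c(mm_cycle$sd, gas_corr$std_dev, aq_corr$std_dev)^2,
                     na.rm = TRUE))
  out$route <- route
  out$corr_gas <- gas_corr$delta_g
  out$corr_aq <- aq_corr$delta_g
  out
}

#' Evaluate bookend work samples between two Hamiltonian levels
#'
#' Computes [bookend_delta_u()] on every frame of the two sampling
#' ensembles and packs the results as a [work_samples()] set for
#' MM -> TARGET estimation.  For the NBB route, `bias_model` names the
#' Hamiltonian the reverse-side frames were actually sampled from (the
#' tailored MM'), and the reverse biases `U_MM' - U_TARGET` are filled
#' in.
#'
#' @param model_a,model_b the two levels (A = sampling, B = target).
#' @param frames_a frames sampled at level A.
#' @param frames_b frames for the reverse direction (sampled at level B,
#'   or at `bias_model` for NBB); may be `NULL`.
#' @param beta inverse temperature (mol/kcal).
#' @param bias_model optional biased sampling Hamiltonian of the
#'   reverse-side frames.
#' @return a [work_samples()] set.
#' @export
bookend_samples <- function(model_a, model_b, frames_a, frames_b = NULL,
                            beta = beta_at(300), bias_model = NULL) {
  ca <- as_compiled(model_a); cb <- as_compiled(model_b)
  fwd <- vapply(frames_a, function(f) bookend_delta_u(ca, cb, f), 0)
  rev_ <- numeric(); br <- numeric()
  if (!is.null(frames_b)) {
    rev_ <- vapply(frames_b, function(f) -bookend_delta_u(ca, cb, f), 0)
    if (!is.null(bias_model)) {
      cbias <- as_compiled(bias_model)
      br <- vapply(frames_b, function(f) bookend_delta_u(cb, cbias, f), 0)
    }
  }
  work_samples(fwd, rev_, bias_reverse = br, beta = beta)
}

#' Tabulate per-frame bookend energies between two levels
#'
#' One row per frame: the bookend component energies `U_A`, `U_B`
#' (solute-solute + solute bonded + electrostatic solute-solvent, no
#' cutoff), their difference, and the full energy decomposition of the
#' A level.  The result round-trips through [write_energy_log()].
#'
#' @inheritParams bookend_samples
#' @param frames frames to evaluate.
#' @return a tibble.
#' @export
bookend_log <- function(model_a, model_b, frames) {
  ca <- as_compiled(model_a); cb <- as_compiled(model_b)
  set_a <- if (inherits(model_a, "system_model"))
    default_settings(model_a, bookend = TRUE) else nonbonded_settings()
  rows <- lapply(seq_along(frames), function(k) {
    f <- frames[[k]]
    ua <- bookend_part_energy(ca, f)
    ub <- bookend_part_energy(cb, f)
    dec <- decompose_energy(ca, f, settings = set_a)
    dplyr::bind_cols(
      tibble(frame = k, step = f$step,
             level_A = if (is.null(model_a$level)) "A" else model_a$level,
             level_B = if (is.null(model_b$level)) "B" else model_b$level,
             U_A = ua, U_B = ub, delta_U = ub - ua),
      as_tibble(dec))
  })
  dplyr::bind_rows(rows)
}

#' The three bookend routes between MM and a target Hamiltonian
#'
#' Estimates the same free-energy difference MM -> TARGET three ways:
#' (a) `direct` - one-sided Zwanzig reweighting from the MM ensemble;
#' (b) `via_mm_prime` - BAR between MM and the tailored MM', plus
#' Zwanzig from the MM' ensemble to the target;
#' (c) `nbb` - Non-Boltzmann-Bennett combining both ensembles, with the
#' MM' frames reweighted by their bias against the target.
#' The three are theoretically equivalent; they differ in variance
#' according to the phase-space overlap each one exploits.
#'
#' @param mm,mm_prime,target the three Hamiltonian levels
#'   ([system_model()]s sharing a topology).
#' @param frames_mm frames sampled under MM.
#' @param frames_mmp frames sampled under MM'.
#' @param beta inverse temperature (mol/kcal).
#' @return a named list of `fe_result`s: `direct`, `via_mm_prime`,
#'   `nbb`.
#' @export
bookend_routes <- function(mm, mm_prime, target, frames_mm, frames_mmp,
                           beta = beta_at(300)) {
  cmm <- as_compiled(mm); cmp_ <- as_compiled(mm_prime)
  ct <- as_compiled(target)
  direct <- exp_zwanzig(bookend_samples(cmm, ct, frames_mm, beta = beta))

  ws_mm_mmp <- work_samples(
    forward = vapply(frames_mm, function(f) bookend_delta_u(cmm, cmp_, f), 0),
    reverse = vapply(frames_mmp, function(f) -bookend_delta_u(cmm, cmp_, f), 0),
    beta = beta)
  leg1 <- bar_estimate(ws_mm_mmp)
  leg2 <- exp_zwanzig(bookend_samples(cmp_, ct, frames_mmp, beta = beta))
  via <- new_fe_result(leg1$delta_g + leg2$delta_g, "BAR+EXP",
                       per_window = tibble(window = 1:2,
                                           delta_g = c(leg1$delta_g,
                                                       leg2$delta_g)))

  nbb <- nbb_estimate(bookend_samples(cmm, ct, frames_mm, frames_mmp,
                                      beta = beta, bias_model = cmp_))
  list(direct = direct, via_mm_prime = via, nbb = nbb)
}

#' Agreement metrics against reference values
#'
#' Root mean squared deviation, mean signed deviation (predicted minus
#' reference) and the square of the Pearson correlation coefficient,
#' computed on all rows and again on the subset excluding the labels in
#' `exclusions` (the starred metrics).
#'
#' @param data data frame with columns `label`, `reference`,
#'   `predicted` (kcal/mol); an `sd` column is carried through if
#'   present.
#' @param exclusions labels excluded from the starred subset.
#' @return a `metrics_table`: the row tibble with a `deviation` column,
#'   plus summary attributes; see [glance.metrics_table()].
#' @export
#' @examples
#' d <- tibble::tibble(label = c("a", "b", "c"),
#'                     reference = c(1, 2, 3), predicted = c(1.1, 2.2, 2.7))
#' glance(fep_metrics(d))
fep_metrics <- function(data, exclusions = character()) {
  data <- as_tibble(data)
  if (nrow(data) < 2)
    abort("at least 2 rows are required (correlation undefined)",
          class = "alchemr_validation")
  if (nrow(data[!data$label %in% exclusions, ]) < 2)
    abort("fewer than 2 rows remain after exclusions",
          class = "alchemr_validation")
  summ <- function(d) {
    dev <- d$predicted - d$reference
    list(rmsd = sqrt(mean(dev^2)), msd = mean(dev),
         r2 = cor(d$reference, d$predicted)^2, n = nrow(d))
  }
  all_rows <- summ(data)
  starred <- summ(data[!data$label %in% exclusions, ])
  out <- dplyr::mutate(data, deviation = .data$predicted - .data$reference)
  attr(out, "summary") <- all_rows
  attr(out, "summary_starred") <- starred
  attr(out, "exclusions") <- exclusions
  class(out) <- c("metrics_table", class(out))
  out
}

#' @export
print.metrics_table <- function(x, ...) {
  NextMethod()
  s <- attr(x, "summary"); st <- attr(x, "summary_starred")
  cat(sprintf("RMSD %.4g  MSD %.4g  R2 %.4g  (n = %d)\n",
              s$rmsd, s$msd, s$r2, s$n))
  if (length(attr(x, "exclusions")))
    cat(sprintf("RMSD* %.4g  MSD* %.4g  R2* %.4g  (n = %d; excl. %s)\n",
                st$rmsd, st$msd, st$r2, st$n,
                paste(attr(x, "exclusions"), collapse = ", ")))
  invisible(x)
}

#' Least-squares multiplicative rescaling of predictions
#'
#' Fits the single factor `s = sum(ref * pred) / sum(pred^2)` that
#' minimizes the squared deviation of `s * predicted` from the
#' reference, and reports the metrics before and after rescaling.  This
#' is the simplest correction for a systematic over- or under-estimation
#' of solute-solvent interaction strength.
#'
#' @inheritParams fep_metrics
#' @return a list with `scale`, `before` and `after` (both
#'   `metrics_table`s).
#' @export
scale_fit <- function(data, exclusions = character()) {
  data <- as_tibble(data)
  if (nrow(data) < 2)
    abort("at least 2 rows required", class = "alchemr_validation")
  if (all(data$predicted == 0))
    abort("all predictions are zero; scale undefined",
          class = "alchemr_validation")
  s <- sum(data$reference * data$predicted) / sum(data$predicted^2)
  rescaled <- dplyr::mutate(data, predicted = s * .data$predicted)
  list(scale = s,
       before = fep_metrics(data, exclusions),
       after = fep_metrics(rescaled, exclusions))
}

#' Read a packaged reference-results table
#'
#' The package ships the printed hydration-free-energy tables of the
#' reference study as plain-text fixtures (`inst/extdata/table*.tsv`),
#' stored verbatim with their `+/-` standard deviations.  The reader
#' normalizes the typographic minus to ASCII and splits `value+/-sd`
#' cells into numeric columns `<name>` and `<name>_sd`.
#'
#' @param name fixture name, e.g. `"table1_mm_hydration"`; see
#'   [list_reference_tables()].
#' @return a tibble with `label`, `expt` and one (or two) numeric
#'   columns per method.
#' @export
read_reference_table <- function(name) {
  path <- system.file("extdata", paste0(name, ".tsv"), package = "alchemr")
  if (!nzchar(path))
    abort(paste0("no packaged table '", name, "'"),
          class = "alchemr_validation")
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  parse_cell <- function(x) {
    x <- gsub("−", "-", x)
    has_sd <- grepl("±", x)
    val <- as.numeric(sub("±.*", "", x))
    sd <- ifelse(has_sd, suppressWarnings(as.numeric(sub(".*±", "", x))),
                 NA_real_)
    list(value = val, sd = sd)
  }
  out <- tibble(label = raw[[1]])
  for (col in names(raw)[-1]) {
    p <- parse_cell(raw[[col]])
    out[[col]] <- p$value
    if (any(!is.na(p$sd))) out[[paste0(col, "_sd")]] <- p$sd
  }
  out
}

#' @rdname read_reference_table
#' @export
list_reference_tables <- function() {
  f <- list.files(system.file("extdata", package = "alchemr"),
                  pattern = "^table.*\\.tsv$")
  sub("\\.tsv$", "", f)
}

#' Metrics for one method column of a packaged table
#'
#' Convenience wrapper: pulls `label`, the experimental reference and
#' one predicted column out of a packaged table and runs
#' [fep_metrics()].
#'
#' @param table_name packaged table name.
#' @param column predicted-value column.
#' @param exclusions starred-subset exclusions.
#' @return a `metrics_table`.
#' @export
#' @examples
#' glance(reference_metrics("table1_mm_hydration", "fc"))
reference_metrics <- function(table_name, column, exclusions = character()) {
  tab <- read_reference_table(table_name)
  d <- tibble(label = tab$label, reference = tab$expt,
              predicted = tab[[column]])
  sd_col <- paste0(column, "_sd")
  if (sd_col %in% names(tab)) d$sd <- tab[[sd_col]]
  fep_metrics(d, exclusions)
}
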