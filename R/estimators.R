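#' Work sample sets
#'
#' Per-frame potential-energy differences between two Hamiltonian
#' levels A and B: `forward` holds `U_B(x) - U_A(x)` on frames sampled
#' from A, `reverse` holds `U_A(x) - U_B(x)` on frames sampled from B
#' (may be empty for one-sided estimation).  `bias_forward` /
#' `bias_reverse` carry the biases `U_sampling - U_target` when the
#' frames were drawn from a biased (non-Boltzmann) state; zero when the
#' sampling state is the target state.
#'
#' @param forward numeric, forward energy differences (kcal/mol).
#' @param reverse numeric, reverse energy differences (kcal/mol).
#' @param bias_forward,bias_reverse numeric biases aligned with the
#'   sample vectors (kcal/mol).
#' @param beta inverse temperature (mol/kcal).
#' @return a `work_samples` object.
#' @export
#' @examples
#' ws <- work_samples(forward = rnorm(100, 1), reverse = rnorm(100, -1),
#'                    beta = 1)
work_samples <- function(forward, reverse = numeric(),
                         bias_forward = numeric(), bias_reverse = numeric(),
                         beta = beta_at(300)) {
  if (!length(bias_forward)) bias_forward <- rep(0, length(forward))
  if (!length(bias_reverse)) bias_reverse <- rep(0, length(reverse))
  if (length(bias_forward) != length(forward) ||
      length(bias_reverse) != length(reverse))
    abort("bias lengths must match sample lengths",
          class = "alchemr_validation")
  if (!all(is.finite(c(forward, reverse, bias_forward, bias_reverse))) ||
      !is.finite(beta) || beta <= 0)
    abort("work samples, biases and beta must be finite (beta > 0)",
          class = "alchemr_validation")
  structure(list(forward = as.numeric(forward),
                 reverse = as.numeric(reverse),
                 bias_forward = as.numeric(bias_forward),
                 bias_reverse = as.numeric(bias_reverse),
                 beta = beta),
            class = "work_samples")
}

logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

new_fe_result <- function(delta_g, method, std_dev = NA_real_,
                          per_window = NULL, n_repeats = 1L,
                          diagnostics = list()) {
  if (is.null(per_window))
    per_window <- tibble(window = 1L, delta_g = delta_g)
  structure(list(delta_g = delta_g, std_dev = std_dev,
                 per_window = per_window, method = method,
                 n_repeats = as.integer(n_repeats),
                 diagnostics = diagnostics),
            class = "fe_result")
}

#' @export
print.fe_result <- function(x, ...) {
  cat(sprintf("<fe_result> method=%s  dG = %.6g kcal/mol", x$method,
              x$delta_g))
  if (is.finite(x$std_dev)) cat(sprintf(" +/- %.3g (n=%d repeats)",
                                        x$std_dev, x$n_repeats))
  cat("\n")
  invisible(x)
}

#' Zwanzig (exponential / FEP) free-energy estimator
#'
#' `dG = -(1/beta) ln < exp(-beta dU_f) >` over the forward samples,
#' evaluated with log-sum-exp so arbitrarily large `|beta dU|` cannot
#' overflow.  Nonzero forward biases reweight the average to the
#' intended sampling state.  Diagnostics carry the effective sample
#' size of the exponential weights.
#'
#' @param samples a [work_samples()] set with non-empty `forward`.
#' @return an `fe_result`.
#' @export
#' @examples
#' exp_zwanzig(work_samples(forward = c(2, 2, 2), beta = 1))$delta_g  # 2
exp_zwanzig <- function(samples) {
  if (!length(samples$forward))
    abort("exp_zwanzig requires forward samples", class = "alchemr_validation")
  b <- samples$beta
  lw <- b * samples$bias_forward          # log reweighting factors
  lw <- lw - logsumexp(lw)                # normalized: sum w = 1
  lse <- logsumexp(lw - b * samples$forward)
  dg <- -lse / b
  x <- lw - b * samples$forward
  ess <- exp(2 * logsumexp(x) - logsumexp(2 * x))
  new_fe_result(dg, "EXP",
                diagnostics = list(ess_forward = ess,
                                   n_forward = length(samples$forward)))
}

# Bennett implicit function: increasing in C, root at the BAR estimate
bar_objective <- function(C, samples, weighted = FALSE) {
  b <- samples$beta
  nf <- length(samples$forward); nr <- length(samples$reverse)
  M <- log(nf / nr)
  if (weighted) {
    lwf <- b * samples$bias_forward
    lwf <- lwf - logsumexp(lwf) + log(nf)
    lwr <- b * samples$bias_reverse
    lwr <- lwr - logsumexp(lwr) + log(nr)
    wf <- exp(lwf); wr <- exp(lwr)
  } else {
    wf <- rep(1, nf); wr <- rep(1, nr)
  }
  sum(wf * stats::plogis(-(b * (samples$forward - C) + M))) -
    sum(wr * stats::plogis(-(b * (samples$reverse + C) - M)))
}

solve_bennett <- function(samples, tol, max_iter, weighted, method) {
  if (!length(samples$forward) || !length(samples$reverse))
    abort("both forward and reverse samples are required",
          class = "alchemr_validation")
  dg_f <- exp_zwanzig(work_samples(samples$forward,
                                   bias_forward = samples$bias_forward,
                                   beta = samples$beta))$delta_g
  dg_r <- -exp_zwanzig(work_samples(samples$reverse,
                                    bias_forward = samples$bias_reverse,
                                    beta = samples$beta))$delta_g
  lo <- min(dg_f, dg_r) - 50
  hi <- max(dg_f, dg_r) + 50
  g <- function(C) bar_objective(C, samples, weighted)
  expand <- 0
  while (g(lo) > 0 && expand < 8) { lo <- lo - 100; expand <- expand + 1 }
  expand <- 0
  while (g(hi) < 0 && expand < 8) { hi <- hi + 100; expand <- expand + 1 }
  if (g(lo) > 0 || g(hi) < 0) {
    od <- overlap_diagnostics(samples)
    abort(paste0("Bennett solve failed to bracket a root; overlap ",
                 "diagnostics: ess_forward=", format(od$ess_forward),
                 ", ess_reverse=", format(od$ess_reverse)),
          class = "alchemr_no_bracket")
  }
  root <- uniroot(g, c(lo, hi), tol = tol, maxiter = max_iter)
  od <- overlap_diagnostics(samples)
  new_fe_result(root$root, method,
                diagnostics = c(od, list(n_forward = length(samples$forward),
                                         n_reverse = length(samples$reverse),
                                         tol = tol)))
}

#' Bennett's acceptance ratio (BAR)
#'
#' Solves the self-consistent Bennett equation: with
#' `M = ln(n_f/n_r)`, find `C` such that
#' `sum_f [1 + exp(beta (dU_f - C) + M)]^-1 =
#'  sum_r [1 + exp(beta (dU_r + C) - M)]^-1`; the free energy is
#' `dG = C`.  The root is found by bisection on the (monotone)
#' objective, bracketed by the two one-sided exponential estimates
#' widened by 50 kcal/mol.
#'
#' @param samples a [work_samples()] set with both directions.
#' @param tol root tolerance (kcal/mol).
#' @param max_iter iteration cap for the root search.
#' @return an `fe_result`.
#' @export
bar_estimate <- function(samples, tol = 1e-8, max_iter = 500) {
  solve_bennett(samples, tol, max_iter, weighted = FALSE, method = "BAR")
}

#' Non-Boltzmann-Bennett (NBB)
#'
#' The Bennett equation in which every sample carries a normalized
#' weight `w_i` proportional to `exp(+beta b_i)` for its side, where
#' `b = U_sampling - U_target` is the bias of the (non-Boltzmann) state
#' the frame was actually drawn from.  With all biases zero this reduces
#' exactly to [bar_estimate()].
#'
#' @inheritParams bar_estimate
#' @return an `fe_result`.
#' @export
nbb_estimate <- function(samples, tol = 1e-8, max_iter = 500) {
  b <- samples$beta
  for (side in c("forward", "reverse")) {
    bias <- samples[[paste0("bias_", side)]]
    lw <- b * bias - logsumexp(b * bias)
    ess <- exp(-logsumexp(2 * lw))
    if (ess < 2)
      abort(paste0("NBB ", side, " weights are numerically degenerate ",
                   "(ESS = ", format(ess), " < 2)"),
            class = "alchemr_degenerate_weights")
  }
  solve_bennett(samples, tol, max_iter, weighted = TRUE, method = "NBB")
}

#' Phase-space overlap diagnostics
#'
#' Effective sample sizes of the exponential reweighting factors in each
#' direction, `ESS = (sum w)^2 / sum w^2` with `w = exp(-beta dU)`, and
#' the gap between the two one-sided exponential estimates (forward
#' minus negated reverse) when both directions exist.
#'
#' @param samples a [work_samples()] set.
#' @return a list with `ess_forward`, `ess_reverse`, `exp_gap`.
#' @export
overlap_diagnostics <- function(samples) {
  if (!length(samples$forward))
    abort("forward samples required", class = "alchemr_validation")
  b <- samples$beta
  ess_of <- function(du) {
    x <- -b * du
    exp(2 * logsumexp(x) - logsumexp(2 * x))
  }
  out <- list(ess_forward = ess_of(samples$forward),
              ess_reverse = if (length(samples$reverse))
                ess_of(samples$reverse) else NA_real_,
              exp_gap = NA_real_)
  if (length(samples$reverse)) {
    dg_f <- exp_zwanzig(work_samples(samples$forward, beta = b))$delta_g
    dg_r <- -exp_zwanzig(work_samples(samples$reverse, beta = b))$delta_g
    out$exp_gap <- dg_f - dg_r
  }
  out
}

#' Aggregate per-window, per-repeat free-energy results
#'
#' Sums windows within each repeat, then reports the mean over repeats
#' with the sample standard deviation (n - 1 denominator).  Repeats must
#' share the window structure.
#'
#' @param results a list of repeats; each repeat is a list of
#'   per-window `fe_result`s (or a single `fe_result`).
#' @return an `fe_result` whose `per_window` holds the across-repeat
#'   mean of each window.
#' @export
#' @examples
#' r <- lapply(c(1, 2, 3, 4), function(x)
#'   list(new_fe_result(x, "EXP")))
#' aggregate_repeats(r)$delta_g  # 2.5
aggregate_repeats <- function(results) {
  as_rep <- function(r) if (inherits(r, "fe_result")) list(r) else r
  results <- lapply(results, as_rep)
  nw <- vapply(results, length, 0L)
  if (length(unique(nw)) != 1)
    abort("repeats have mismatched window structure",
          class = "alchemr_validation")
  totals <- vapply(results, function(r)
    sum(vapply(r, `[[`, 0, "delta_g")), 0)
  wmeans <- vapply(seq_len(nw[1]), function(w)
    mean(vapply(results, function(r) r[[w]]$delta_g, 0)), 0)
  method <- results[[1]][[1]]$method
  new_fe_result(mean(totals), method,
                std_dev = if (length(totals) > 1) sd(totals) else 0,
                per_window = tibble(window = seq_len(nw[1]),
                                    delta_g = wmeans),
                n_repeats = length(totals),
                diagnostics = list(repeat_totals = totals))
}

#' Build work samples from a pair of energy-log tables
#'
#' Forward samples come from the `delta_U` column of frames sampled at
#' level A, reverse samples from the negated `delta_U` of frames
#' sampled at level B (both logs store `U_B - U_A`).
#'
#' @param log_a,log_b energy-log tibbles ([read_energy_log()]); `log_b`
#'   may be `NULL` for one-sided sets.
#' @param beta inverse temperature (mol/kcal).
#' @return a [work_samples()] object.
#' @export
work_samples_from_logs <- function(log_a, log_b = NULL, beta = beta_at(300)) {
  work_samples(forward = log_a$delta_U,
               reverse = if (is.null(log_b)) numeric() else -log_b$delta_U,
               beta = beta)
}

#' Serialize a free-energy result with provenance
#'
#' @param result an `fe_result`.
#' @param path output JSON path.
#' @param provenance named list (seeds, schedule, softcore delta, ...).
#' @return `path`, invisibly.
#' @export
write_fe_result <- function(result, path, provenance = list()) {
  obj <- list(delta_g = result$delta_g, std_dev = result$std_dev,
              method = result$method, n_repeats = result$n_repeats,
              per_window = result$per_window,
              diagnostics = result$diagnostics[!vapply(result$diagnostics,
                                                       is.null, TRUE)],
              provenance = provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
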