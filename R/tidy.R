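#' Tidiers for free-energy results
#'
#' `tidy()` returns the per-window breakdown; `glance()` returns a
#' one-row summary.
#'
#' @param x an `fe_result`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.fe_result <- function(x, ...) {
  dplyr::mutate(x$per_window, method = x$method)
}

#' @rdname tidy.fe_result
#' @export
glance.fe_result <- function(x, ...) {
  tibble(delta_g = x$delta_g, std_dev = x$std_dev, method = x$method,
         n_repeats = x$n_repeats, n_windows = nrow(x$per_window))
}

#' @rdname tidy.fe_result
#' @export
tidy.hydration_cycle <- function(x, ...) {
  tibble(quantity = c("dg_annih_gas", "dg_annih_aq", "dg_hyd"),
         value = c(x$dg_annih_gas, x$dg_annih_aq, x$dg_hyd),
         route = x$route)
}

#' @rdname tidy.fe_result
#' @export
glance.hydration_cycle <- function(x, ...) {
  tibble(dg_hyd = x$dg_hyd, sd = x$sd, route = x$route,
         repeats = x$repeats)
}

#' Summaries of agreement-metric tables
#'
#' `glance()` on a [fep_metrics()] result returns the RMSD, MSD and R2
#' for the full set and the starred (exclusion-filtered) subset.
#'
#' @param x a `metrics_table`.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.metrics_table <- function(x, ...) {
  s <- attr(x, "summary"); st <- attr(x, "summary_starred")
  tibble(rmsd = s$rmsd, msd = s$msd, r2 = s$r2, n = s$n,
         rmsd_starred = st$rmsd, msd_starred = st$msd,
         r2_starred = st$r2, n_starred = st$n)
}

#' @rdname glance.metrics_table
#' @export
tidy.metrics_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "metrics_table")
  out
}

#' Plot predicted against reference values
#'
#' Scatter of predicted versus reference values with the identity line;
#' starred exclusions are hollow.
#'
#' @param object a `metrics_table`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.metrics_table <- function(object, ...) {
  d <- tidy(object)
  d$excluded <- d$label %in% attr(object, "exclusions")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$reference, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$excluded), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "reference (kcal/mol)", y = "predicted (kcal/mol)")
}

#' Plot a per-window free-energy breakdown
#'
#' @param object an `fe_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fe_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$window),
                                  y = .data$delta_g)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "window", y = "per-window dG (kcal/mol)",
                  title = paste0(object$method, ": total ",
                                 signif(object$delta_g, 4), " kcal/mol"))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance
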