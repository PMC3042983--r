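#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot methods
#'
#' `autoplot()` methods return ggplot objects for the package's result
#' types: trajectories (pressure vs time, with the deterministic solution
#' and stationary mean overlaid when available), ensemble summaries (mean
#' with quantile ribbon), risk curves and risk surfaces.
#'
#' @param object A result object from this package.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-csfsde
NULL

#' @rdname autoplot-csfsde
#' @export
autoplot.icp_trajectory <- function(object, ...) {
  gg <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min,
                                             y = .data$icp_mmHg)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::labs(x = "time (min)", y = "ICP (mmHg)")
  params <- attr(object, "params")
  if (!is.null(params) && params$sigma > 0 && stationary_exists(params)) {
    gg <- gg + ggplot2::geom_hline(yintercept = stationary_mean(params),
                                   linetype = "dashed", colour = "firebrick")
  }
  gg
}

#' @rdname autoplot-csfsde
#' @export
autoplot.icp_ensemble <- function(object, ...) {
  gg <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min))
  qcols <- grep("^q\\d+$", names(object), value = TRUE)
  if (length(qcols) >= 2) {
    gg <- gg + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data[[qcols[1]]],
                   ymax = .data[[qcols[length(qcols)]]]),
      fill = "steelblue", alpha = 0.25)
  }
  gg +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "steelblue4") +
    ggplot2::labs(x = "time (min)", y = "ICP (mmHg)")
}

#' @rdname autoplot-csfsde
#' @export
autoplot.csf_risk_curve <- function(object, ...) {
  axis <- attr(object, "axis")
  xlab <- if (axis == "sigma") {
    expression(sigma ~ "(mL/min)")
  } else {
    expression(R ~ "(mmHg" %.% "mL"^-1 %.% "min)")
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[axis]],
                                       y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = xlab, y = "P(reach b before a)") +
    ggplot2::ylim(0, 1)
}

#' @rdname autoplot-csfsde
#' @export
autoplot.csf_risk_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$R, y = .data$sigma,
                                       fill = .data$probability)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = expression(R ~ "(mmHg" %.% "mL"^-1 %.% "min)"),
                  y = expression(sigma ~ "(mL/min)"),
                  fill = "probability")
}

#' @rdname autoplot-csfsde
#' @param p_max Upper pressure limit for the density curve (mmHg).
#' @export
autoplot.stationary_gamma <- function(object, p_max = NULL, ...) {
  if (is.null(p_max)) {
    p_max <- stats::qgamma(0.999, shape = object$shape, rate = object$rate)
  }
  df <- tibble::tibble(p = seq(1e-6, p_max, length.out = 512))
  df$density <- stats::dgamma(df$p, shape = object$shape, rate = object$rate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$mean, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "ICP (mmHg)", y = expression("density (mmHg"^-1 * ")"))
}
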