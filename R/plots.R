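#' Plot a solution-space envelope over growth rate
#'
#' Ribbon of the feasible interval of the phenotype variable across
#' growth rates, with the yield-maximized curve overlaid when supplied.
#'
#' @param object An `ssme_envelope` from [envelope_over_mu()].
#' @param curve Optional yield-maximized curve from [phenotype_curve()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ssme_envelope <- function(object, curve = NULL, ...) {
  variable <- attr(object, "variable")
  lo <- paste0(variable, "_min"); hi <- paste0(variable, "_max")
  df <- dplyr::filter(as_tibble(object), .data$status == "optimal")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mu)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[lo]],
                                      ymax = .data[[hi]]),
                         fill = "steelblue", alpha = 0.35) +
    ggplot2::labs(
      x = expression(mu ~ (h^-1)),
      y = if (variable == "q_ac")
        expression(q[ac] ~ (mmol ~ gDW^-1 ~ h^-1))
      else expression(Y ~ (gDW ~ g^-1)),
      title = "Feasible solution space over growth rate") +
    ggplot2::theme_minimal()
  if (!is.null(curve)) {
    yvar <- if (variable == "q_ac") "q_ac" else "Y"
    p <- p + ggplot2::geom_line(
      data = dplyr::filter(curve, .data$status == "optimal"),
      ggplot2::aes(y = .data[[yvar]]), linewidth = 0.8)
  }
  p
}

#' Plot a fixed-growth-rate contour in the uptake-acetate plane
#'
#' @param object An `ssme_contour` from [contour_at_mu()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ssme_contour <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$status == "optimal")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q_glc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q_ac_min,
                                      ymax = .data$q_ac_max),
                         fill = "steelblue", alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = .data$q_ac_max), linewidth = 0.6) +
    ggplot2::labs(x = expression(q[glc] ~ (mmol ~ gDW^-1 ~ h^-1)),
                  y = expression(q[ac] ~ (mmol ~ gDW^-1 ~ h^-1)),
                  title = sprintf("Solution space at mu = %.3g",
                                  attr(object, "mu"))) +
    ggplot2::theme_minimal()
}

#' Plot a rate-yield tradeoff report
#'
#' Scatter of per-strain yields against glucose uptake, colored by growth
#' bin, with per-bin d2 regression lines in the acetate panel and
#' optional model curves overlaid.
#'
#' @param report A `tradeoff_report` from [tradeoff_report()].
#' @param panel `"q_ac"` (uptake vs acetate, the d2 regressions) or
#'   `"Y"` (uptake vs yield).
#' @return A ggplot object.
#' @export
plot_tradeoff <- function(report, panel = c("q_ac", "Y")) {
  panel <- match.arg(panel)
  stopifnot(inherits(report, "tradeoff_report"))
  recs <- report$records
  if (panel == "q_ac") {
    p <- ggplot2::ggplot(recs, ggplot2::aes(x = .data$q_glc,
                                            y = .data$q_ac,
                                            color = .data$growth_bin)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(x = expression(q[glc] ~ (mmol ~ gDW^-1 ~ h^-1)),
                    y = expression(q[ac] ~ (mmol ~ gDW^-1 ~ h^-1)),
                    color = "growth bin") +
      ggplot2::theme_minimal()
    fits <- report$d2_fits
    if (nrow(fits) > 0 && any(!fits$degenerate))
      p <- p + ggplot2::geom_abline(
        data = dplyr::filter(fits, !.data$degenerate),
        ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                     color = .data$growth_bin),
        linetype = "dashed")
    p
  } else {
    ggplot2::ggplot(recs, ggplot2::aes(x = .data$q_glc, y = .data$Y,
                                       color = .data$growth_bin)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(x = expression(q[glc] ~ (mmol ~ gDW^-1 ~ h^-1)),
                    y = expression(Y ~ (gDW ~ g^-1)),
                    color = "growth bin") +
      ggplot2::theme_minimal()
  }
}
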