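#' Plot a per-residue track
#'
#' Draws any per-residue scalar profile (relaxation rate, NOE, CSP,
#' intensity ratio, propensity) against the sequence, in the style of the
#' usual per-residue figure panels: points/bars over residue number with
#' optional shaded residue intervals (e.g. a helix or an RGG box) and an
#' optional horizontal reference line (e.g. a significance threshold).
#'
#' @param profile Tibble with `residue_number` and a value column.
#' @param col Value column name (default auto, as in [profile_summary()]).
#' @param highlight Optional list of `c(first, last)` intervals to shade.
#' @param hline Optional y value for a dashed reference line.
#' @param ylab Y-axis label.
#' @return A ggplot object.
#' @export
plot_residue_track <- function(profile, col = NULL, highlight = NULL,
                               hline = NULL, ylab = col %||% "value") {
  if (is.null(col)) {
    col <- if ("value" %in% names(profile)) "value" else
      setdiff(names(profile)[vapply(profile, is.numeric, logical(1))],
              "residue_number")[1]
  }
  p <- ggplot2::ggplot(
    profile,
    ggplot2::aes(x = .data$residue_number, y = .data[[col]])
  )
  for (iv in highlight %||% list()) {
    p <- p + ggplot2::annotate(
      "rect",
      xmin = iv[1] - 0.5, xmax = iv[2] + 0.5, ymin = -Inf, ymax = Inf,
      alpha = 0.15, fill = "grey40"
    )
  }
  if (!is.null(hline)) {
    p <- p + ggplot2::geom_hline(yintercept = hline, linetype = "dashed")
  }
  p +
    ggplot2::geom_col(width = 0.8, fill = "steelblue4", na.rm = TRUE) +
    ggplot2::labs(x = "residue number", y = ylab) +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Kd fit: observed vs fitted binding isotherms
#'
#' @param object A [fit_kd()] result.
#' @param ... Unused.
#' @return A ggplot object: per-residue CSP against ligand:protein ratio,
#'   points observed, lines fitted.
#' @export
autoplot.kd_fit <- function(object, ...) {
  d <- object$residuals
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ratio, group = .data$residue_number)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(
      x = "ligand : protein ratio", y = "CSP (ppm)",
      title = sprintf("Kd = %.3g uM", object$kd * 1e6)
    ) +
    ggplot2::theme_classic()
}

#' Plot a FRAP recovery fit
#'
#' @param object A [fit_frap_recovery()] result.
#' @param ... Unused.
#' @return A ggplot object: normalized recovery trace with the fitted curve
#'   and the 95% plateau time marked.
#' @export
autoplot.frap_fit <- function(object, ...) {
  p <- ggplot2::ggplot(
    object$data,
    ggplot2::aes(x = .data$time_s, y = .data$intensity)
  ) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time (s)", y = "normalized intensity") +
    ggplot2::theme_classic()
  if (object$converged) {
    p <- p +
      ggplot2::geom_line(
        ggplot2::aes(y = .data$fitted), colour = "firebrick"
      ) +
      ggplot2::geom_vline(
        xintercept = object$plateau_time, linetype = "dashed"
      )
  }
  p
}
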