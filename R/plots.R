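# ggplot2 views of the main result types.

#' Plot a pore-radius profile
#'
#' Radius against axial coordinate, with the selectivity-filter window
#' shaded when set.
#'
#' @param object A `pore_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pore_profile
#' @export
autoplot.pore_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$radius)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$converged), size = 1) +
    ggplot2::labs(x = "axial coordinate z (Å)",
                  y = "pore radius (Å)") +
    ggplot2::theme_minimal()
  fw <- filter_window(object)
  if (!is.null(fw)) {
    p <- p + ggplot2::annotate("rect", xmin = fw[1], xmax = fw[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.12)
  }
  p
}

#' Plot per-mutation filter radii
#'
#' Mutant minimum filter radius per mutation, ordered by effect, with the
#' wild-type radius as a horizontal reference; points colored by the
#' open/close/neutral call.
#'
#' @param calls Impact calls from [compute_impact()].
#' @return A ggplot.
#' @export
plot_impact_calls <- function(calls) {
  df <- calls[calls$site_resolved %in% TRUE & !is.na(calls$label), ]
  df <- df[order(df$delta), ]
  df$rank <- seq_len(nrow(df))
  wt <- attr(calls, "wt_min_radius") %||% df$wt_min_radius[1]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$mut_min_radius,
                                   color = .data$label)) +
    ggplot2::geom_hline(yintercept = wt, linetype = "dashed") +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "mutation (ordered by effect)",
                  y = "mutant minimum filter radius (Å)",
                  color = "call") +
    ggplot2::theme_minimal()
}

#' Plot filter radii by tumor stage
#'
#' Jittered mutant filter radii per stage with a median bar, the standard
#' view for stage-graded pore closure.
#'
#' @param calls Impact calls with stage labels.
#' @return A ggplot.
#' @export
plot_stage_radii <- function(calls) {
  df <- calls[calls$site_resolved %in% TRUE & !is.na(calls$mut_min_radius) &
                calls$stage != "UNKNOWN", ]
  df$stage <- droplevels(factor(df$stage, levels = stage_levels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$mut_min_radius)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::stat_summary(fun = median, geom = "crossbar", width = 0.5,
                          linewidth = 0.4) +
    ggplot2::labs(x = "tumor stage", y = "mutant minimum filter radius (Å)") +
    ggplot2::theme_minimal()
}
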