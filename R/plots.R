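#' Mean trajectory plot by condition
#'
#' Averages the time-normalized paths pointwise (per time step) first
#' within participant, then across participants, and draws thin
#' per-participant averages under thick group averages, one colour per
#' compatibility condition. With `exclude_multistep = TRUE`, only trials
#' surviving the cutoff enter the averages.
#'
#' @param data A classified [rec_data] object.
#' @param exclude_multistep Drop cutoff-classified trials before
#'   averaging.
#' @return A ggplot object.
#' @export
plot_mean_trajectories <- function(data, exclude_multistep = FALSE) {
  stopifnot(inherits(data, "rec_data"))
  trials <- analysis_set(data)
  if (exclude_multistep) {
    if (is.null(trials$multistep)) {
      stop("classify_multistep() first", call. = FALSE)
    }
    trials <- trials[!trials$multistep, , drop = FALSE]
  }
  key <- paste(data$paths$participant, data$paths$trial, sep = "\r")
  keep <- key %in% paste(trials$participant, trials$trial, sep = "\r")
  paths <- data$paths[keep, , drop = FALSE]

  by_part <- paths |>
    dplyr::group_by(.data$participant, .data$compatibility, .data$step) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop")
  grand <- by_part |>
    dplyr::group_by(.data$compatibility, .data$step) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop")

  ggplot2::ggplot(mapping = ggplot2::aes(
    x = .data$x, y = .data$y, colour = .data$compatibility
  )) +
    ggplot2::geom_path(
      data = by_part,
      ggplot2::aes(group = interaction(.data$participant,
                                       .data$compatibility)),
      linewidth = 0.3, alpha = 0.35
    ) +
    ggplot2::geom_path(data = grand, linewidth = 1.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (px)", y = "y (px)", colour = NULL,
      title = if (exclude_multistep) {
        "Mean trajectories, single-step movements only"
      } else {
        "Mean trajectories, all retained movements"
      }
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the cutoff-relaxation sweep
#'
#' Standardized effect size (Cohen's dz) of the compatibility effect as a
#' function of the allowed horizontal excursion toward the wrong target
#' (percent of the start-to-wrong-target distance). The dashed vertical
#' line marks the default cutoff (start-area left edge).
#'
#' @param object A `rec_sweep` tibble from [cutoff_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rec_sweep <- function(object, ...) {
  f0 <- attr(object, "default_f")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = 100 * .data$fraction, y = .data$dz)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 100 * f0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "allowed horizontal movement toward wrong target (%)",
      y = expression("effect size" ~ d[z]),
      title = "Compatibility effect vs. cutoff criterion"
    ) +
    ggplot2::theme_minimal()
}

#' Plot averaged velocity profiles
#'
#' Mean speed over the renormalized pre-MAD (0-100%) and post-MAD
#' (100-200%) segment time, one line per group; the vertical line marks
#' the MAD alignment point.
#'
#' @param object A `velocity_profiles` tibble from [average_profiles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.velocity_profiles <- function(object, ...) {
  df <- tibble::as_tibble(object)
  group_cols <- setdiff(names(df), c("segment", "percent", "speed", "n"))
  df$time_axis <- ifelse(df$segment == "pre", df$percent, 100 + df$percent)
  if (length(group_cols) > 0) {
    df$group <- interaction(df[group_cols], drop = TRUE)
  } else {
    df$group <- factor("all")
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time_axis, y = .data$speed,
    colour = .data$group, group = .data$group
  )) +
    ggplot2::geom_vline(xintercept = 100, colour = "grey40") +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::labs(
      x = "normalized time (% pre-MAD | % post-MAD)",
      y = "speed (px/ms)", colour = NULL,
      title = "Velocity profiles aligned at the MAD timepoint"
    ) +
    ggplot2::theme_minimal()
}
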