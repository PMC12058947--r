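#' Paired within-subject comparison of condition means
#'
#' Classical paired t test across participants with the within-subject
#' standardized effect size Cohen's dz = mean(diff) / SD(diff) (sample
#' SD). Differences are taken as incompatible minus compatible, so
#' positive t and dz mean larger values in the incompatible condition.
#' Participants missing either condition mean are dropped. With fewer
#' than 2 complete participants, or zero-variance differences, the test
#' statistics are `NA` and the reason is recorded.
#'
#' @param means A tibble of per-participant condition means: columns
#'   `participant`, `compatibility`, and the value column.
#' @param value Name of the value column (default `"m"`).
#' @param levels The two factor levels, ordered
#'   (reference first; default `c("compatible", "incompatible")`).
#' @return A one-row tibble: `mean_compatible`, `mean_incompatible`, `t`,
#'   `df`, `p` (two-sided), `dz`, `n_participants`, `note`.
#' @examples
#' means <- tibble::tibble(
#'   participant = rep(1:4, each = 2),
#'   compatibility = rep(c("compatible", "incompatible"), 4),
#'   m = c(0, 2, 1, 5, 2, 8, 3, 11)
#' )
#' paired_t(means)
#' @export
paired_t <- function(means, value = "m",
                     levels = c("compatible", "incompatible")) {
  stopifnot(all(c("participant", "compatibility", value) %in% names(means)))
  wide <- tidyr::pivot_wider(
    means[, c("participant", "compatibility", value)],
    names_from = "compatibility", values_from = dplyr::all_of(value)
  )
  for (lv in levels) if (!lv %in% names(wide)) wide[[lv]] <- NA_real_
  complete <- !is.na(wide[[levels[1]]]) & !is.na(wide[[levels[2]]])
  wide <- wide[complete, , drop = FALSE]
  n <- nrow(wide)

  out <- tibble::tibble(
    mean_compatible = NA_real_, mean_incompatible = NA_real_,
    t = NA_real_, df = NA_real_, p = NA_real_, dz = NA_real_,
    n_participants = n, note = NA_character_
  )
  if (n < 2) {
    out$note <- "fewer than 2 participants with both conditions"
    return(out)
  }
  a <- wide[[levels[1]]]
  b <- wide[[levels[2]]]
  d <- b - a
  out$mean_compatible <- mean(a)
  out$mean_incompatible <- mean(b)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    out$note <- "zero-variance differences; t undefined"
    return(out)
  }
  tt <- stats::t.test(b, a, paired = TRUE)
  out$t <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p <- tt$p.value
  out$dz <- mean(d) / sd_d
  out
}

#' Main effect of compatibility in multifactorial designs
#'
#' Collapses any additional within-subject factors to per-participant
#' compatibility means and runs the paired comparison. With a balanced
#' design the collapse averages cell means with equal weights (identical
#' to the trial-level mean); unbalanced cells trigger a warning and a
#' trial-weighted collapse. `F = t^2` is reported alongside for
#' comparison with F statistics from two-level repeated-measures ANOVA,
#' to which the paired t is equivalent.
#'
#' @param trials A per-trial tibble with `participant`, `compatibility`,
#'   possibly further condition columns, and the measure column.
#' @param value Name of the measure column.
#' @return A one-row tibble as [paired_t()], plus `F`.
#' @export
main_effect <- function(trials, value) {
  stopifnot(all(c("participant", "compatibility", value) %in% names(trials)))
  extra <- setdiff(condition_columns(trials), c("compatibility", value))
  extra <- intersect(extra, names(trials))
  if (length(extra) == 0) {
    means <- trials |>
      dplyr::group_by(.data$participant, .data$compatibility) |>
      dplyr::summarise(m = mean(.data[[value]]), .groups = "drop")
  } else {
    cells <- trials |>
      dplyr::group_by(dplyr::across(dplyr::all_of(
        c("participant", "compatibility", extra)
      ))) |>
      dplyr::summarise(m = mean(.data[[value]]), n = dplyr::n(),
                       .groups = "drop")
    balanced <- length(unique(cells$n)) <= 1
    if (!balanced) {
      warning("unbalanced cells: collapsing with trial weights",
              call. = FALSE)
    }
    means <- cells |>
      dplyr::group_by(.data$participant, .data$compatibility) |>
      dplyr::summarise(
        m = if (balanced) mean(.data$m) else
          stats::weighted.mean(.data$m, .data$n),
        .groups = "drop"
      )
  }
  res <- paired_t(means, value = "m")
  res$F <- res$t^2
  res
}
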