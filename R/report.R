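#' Preprocess a raw trajectory dataset
#'
#' Runs the full trial-level preprocessing chain and returns a `rec_data`
#' object holding every intermediate product the downstream analyses
#' need:
#' \enumerate{
#'   \item canonicalize coordinates (origin at the start-area centre,
#'     y up, correct target flipped to the right);
#'   \item drop response-error trials (wrong target reached) before any
#'     measure computation;
#'   \item flag and drop downward movements (post-exit y strictly below
#'     the start area's bottom edge);
#'   \item truncate each remaining trajectory to the movement proper and
#'     record IT and MT; trials never leaving the start area or never
#'     reaching the correct target become "unusable";
#'   \item time-normalize to `n_steps` points and compute signed AUC,
#'     signed MAD and the MAD step index;
#'   \item flag outliers: any of IT/MT/AUC/MAD further than `k_outlier`
#'     SDs from its participant-by-condition cell mean, in a single pass
#'     before any multi-step classification.
#' }
#' Excluded trials are never deleted: the per-trial table keeps every
#' trial with its exclusion flags, so with- and without-cutoff analyses
#' run from one table.
#'
#' @param samples A samples tibble (see [read_trajectories()]).
#' @param geometry A [display_geometry()] in the same frame as the
#'   sample coordinates.
#' @param n_steps Time-normalization resolution (default 101).
#' @param k_outlier Outlier SD multiplier (default 2.5).
#' @param on_violation Passed to [canonicalize()]; the pipeline default
#'   `"drop"` discards (and records) trials starting outside the start
#'   area instead of failing the whole dataset.
#' @return An object of class `rec_data`: list with `trials` (one row per
#'   trial: metadata, flags, measures, `min_x`, `retained`), `paths`
#'   (normalized trajectories of measurable trials), `movement`
#'   (truncated raw samples), `audit` (per-participant exclusion counts),
#'   `geometry`, `n_steps`.
#' @export
preprocess_trials <- function(samples, geometry, n_steps = 101,
                              k_outlier = 2.5, on_violation = "drop") {
  canon <- canonicalize(samples, geometry, on_violation = on_violation)

  groups <- split_trials(canon)
  all_meta <- trial_meta(canon, groups)
  all_meta$error <- as.logical(all_meta$response_error)

  ok <- canon[!as.logical(canon$response_error), , drop = FALSE]
  down <- flag_downward(ok, geometry)
  dkey <- paste(down$participant, down$trial, sep = "\r")
  akey <- paste(all_meta$participant, all_meta$trial, sep = "\r")
  all_meta$downward <- !all_meta$error &
    dplyr::coalesce(down$downward[match(akey, dkey)], FALSE)

  keep_key <- akey[!all_meta$error & !all_meta$downward]
  ok <- ok[paste(ok$participant, ok$trial, sep = "\r") %in% keep_key, ,
           drop = FALSE]
  movement <- truncate_movements(ok, geometry)
  unusable <- attr(movement, "unusable")
  ukey <- paste(unusable$participant, unusable$trial, sep = "\r")
  all_meta$unusable_reason <- unusable$reason[match(akey, ukey)]
  all_meta$unusable <- !is.na(all_meta$unusable_reason)

  paths <- normalize_time(movement, n_steps = n_steps)
  measures <- trial_measures(paths)
  measures <- flag_outliers(measures, k = k_outlier)
  mx <- movement_min_x(movement)

  mkey <- paste(measures$participant, measures$trial, sep = "\r")
  xkey <- paste(mx$participant, mx$trial, sep = "\r")
  pick <- match(akey, mkey)
  trials <- all_meta
  for (col in c("it_ms", "mt_ms", "auc_px2", "mad_px")) {
    trials[[col]] <- measures[[col]][pick]
  }
  trials$mad_index <- measures$mad_index[pick]
  trials$min_x <- mx$min_x[match(akey, xkey)]
  trials$outlier <- dplyr::coalesce(measures$outlier[pick], FALSE)
  trials$outlier_reasons <- dplyr::coalesce(measures$outlier_reasons[pick], "")
  trials$retained <- !trials$error & !trials$downward & !trials$unusable &
    !trials$outlier

  audit <- trials |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      n_raw = dplyr::n(),
      n_error = sum(.data$error),
      n_downward = sum(.data$downward),
      n_unusable = sum(.data$unusable),
      n_outlier = sum(.data$outlier),
      n_retained = sum(.data$retained),
      .groups = "drop"
    )

  structure(
    list(
      trials = tibble::as_tibble(trials), paths = paths,
      movement = movement, audit = audit,
      geometry = geometry, n_steps = n_steps
    ),
    class = "rec_data"
  )
}

#' @export
print.rec_data <- function(x, ...) {
  cat("<rec_data>", nrow(x$trials), "trials,",
      length(unique(x$trials$participant)), "participants\n")
  cat("  retained:", sum(x$trials$retained),
      "| errors:", sum(x$trials$error),
      "| downward:", sum(x$trials$downward),
      "| unusable:", sum(x$trials$unusable),
      "| outliers:", sum(x$trials$outlier), "\n")
  if (!is.null(x$cutoff)) {
    cat(sprintf("  cutoff: f = %.4f (x_cut = %g px), multi-step: %d\n",
                x$cutoff$fraction, x$cutoff$x_cut,
                sum(x$trials$multistep, na.rm = TRUE)))
  }
  invisible(x)
}

#' Apply the cutoff classifier to a preprocessed dataset
#'
#' Adds a logical `multistep` column to the per-trial table (strictly
#' beyond the cutoff line at any truncated raw sample) and stores the
#' cutoff on the object. Excluded trials keep their rows; downstream
#' analyses filter on the flag.
#'
#' @param data A [rec_data] object from [preprocess_trials()].
#' @param cutoff A [cutoff_spec()]; default [default_cutoff()] of the
#'   data's geometry.
#' @return The `rec_data` object with `trials$multistep` and `$cutoff`
#'   set.
#' @export
classify_multistep <- function(data, cutoff = NULL) {
  stopifnot(inherits(data, "rec_data"))
  if (is.null(cutoff)) cutoff <- default_cutoff(data$geometry)
  data$trials$multistep <- data$trials$min_x < cutoff$x_cut
  data$cutoff <- cutoff
  data
}

# trials entering analysis: all preprocessing exclusions applied
analysis_set <- function(data) {
  stopifnot(inherits(data, "rec_data"))
  data$trials[data$trials$retained, , drop = FALSE]
}

#' With/without-cutoff compatibility report
#'
#' Analyses all four measures (AUC, MAD, IT, MT) twice — once on all
#' retained trials, once on single-step trials only — with the paired
#' compatibility test ([main_effect()]: collapsed to the compatibility
#' main effect in multifactorial designs), and adds the paired comparison
#' of per-participant %CC across conditions plus the exclusion audit.
#'
#' @param data A [rec_data] object.
#' @param cutoff Optional [cutoff_spec()] (default: the cutoff already on
#'   the object, else [default_cutoff()]).
#' @return An object of class `rec_report` with elements `results` (one
#'   row per measure and cutoff application), `pcc` (the %CC comparison),
#'   `pcc_table` (per-participant %CC), `audit`, `cutoff`.
#' @export
rec_report <- function(data, cutoff = NULL) {
  stopifnot(inherits(data, "rec_data"))
  if (!is.null(cutoff) || is.null(data$cutoff)) {
    data <- classify_multistep(data, cutoff)
  }
  trials <- analysis_set(data)
  if (nrow(trials) == 0) {
    stop("no retained trials to analyse", call. = FALSE)
  }
  vars <- c(AUC = "auc_px2", MAD = "mad_px", IT = "it_ms", MT = "mt_ms")
  rows <- list()
  for (lab in names(vars)) {
    without <- main_effect(trials, vars[[lab]])
    with_co <- main_effect(trials[!trials$multistep, , drop = FALSE],
                           vars[[lab]])
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(measure = lab, cutoff = "without"), without
    )
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(measure = lab, cutoff = "with"), with_co
    )
  }
  results <- dplyr::bind_rows(rows)

  pcc_table <- percent_cc(trials)
  pcc <- paired_t(pcc_table, value = "pct_cc")

  audit <- data$audit
  ms <- trials |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(n_multistep = sum(.data$multistep), .groups = "drop")
  audit$n_multistep <- ms$n_multistep[match(audit$participant,
                                            ms$participant)]

  structure(
    list(results = results, pcc = pcc, pcc_table = pcc_table,
         audit = audit, cutoff = data$cutoff),
    class = "rec_report"
  )
}

#' @export
print.rec_report <- function(x, digits = 3, ...) {
  cat("Response-effect compatibility report",
      sprintf("(cutoff fraction %.4f)\n", x$cutoff$fraction))
  fmt <- function(r) {
    if (is.na(r$t)) return(sprintf("  (%s)", r$note))
    sprintf("t(%.0f) = %.2f, p = %.4g, dz = %.2f (%.4g vs. %.4g)",
            r$df, r$t, r$p, r$dz, r$mean_compatible, r$mean_incompatible)
  }
  for (m in unique(x$results$measure)) {
    cat(sprintf("%-4s", m), "\n")
    for (co in c("without", "with")) {
      r <- x$results[x$results$measure == m & x$results$cutoff == co, ]
      cat(sprintf("  %-8s cutoff: %s\n", co, fmt(r)))
    }
  }
  cat("%CC ", "\n  ", fmt(x$pcc), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a compatibility report
#'
#' One row per test: the four measures with and without the cutoff, plus
#' the %CC comparison.
#'
#' @param x A `rec_report`.
#' @param ... Unused.
#' @return A tibble with columns `measure`, `cutoff`, `mean_compatible`,
#'   `mean_incompatible`, `t`, `df`, `p`, `dz`, `F`, `n_participants`,
#'   `note`.
#' @export
tidy.rec_report <- function(x, ...) {
  pcc <- dplyr::bind_cols(
    tibble::tibble(measure = "%CC", cutoff = "classifier"), x$pcc
  )
  dplyr::bind_rows(x$results, pcc)
}

#' Glance at a compatibility report
#'
#' @param x A `rec_report`.
#' @param ... Unused.
#' @return A one-row tibble with participant and exclusion totals and the
#'   cutoff fraction.
#' @export
glance.rec_report <- function(x, ...) {
  tibble::tibble(
    n_participants = nrow(x$audit),
    n_trials = sum(x$audit$n_raw),
    n_retained = sum(x$audit$n_retained),
    n_error = sum(x$audit$n_error),
    n_downward = sum(x$audit$n_downward),
    n_unusable = sum(x$audit$n_unusable),
    n_outlier = sum(x$audit$n_outlier),
    n_multistep = sum(x$audit$n_multistep),
    cutoff_fraction = x$cutoff$fraction
  )
}

#' @export
tidy.rec_sweep <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
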