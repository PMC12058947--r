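#' Run the full analysis pipeline and write its artifacts
#'
#' Executes preprocess, measures, cutoff classification, velocity
#' profiles, the cutoff sweep and the with/without-cutoff statistics, and
#' writes everything to `out_dir`: `measures.csv` (per-trial measures and
#' flags), `report.csv` (tidy report), `pcc.csv`, `sweep.csv`,
#' `velocity_profiles.csv`, `audit.csv`, figures
#' (`mean_trajectories.pdf`, `mean_trajectories_single_step.pdf`,
#' `sweep.pdf`, `velocity_profiles.pdf`) and `provenance.json`
#' (parameters, package version, counts). Every figure's underlying
#' numbers are also written as CSV.
#'
#' @param samples A samples tibble, or a CSV path accepted by
#'   [read_trajectories()].
#' @param geometry A [display_geometry()], or a config path accepted by
#'   [read_geometry()].
#' @param out_dir Output directory (created if needed).
#' @param cutoff_fraction `"auto"` (default cutoff: start-area left edge)
#'   or a numeric fraction in \\[0, 1\\].
#' @param n_steps,k_outlier,m_velocity Pipeline resolution parameters
#'   (see [preprocess_trials()] and [speed_profiles()]).
#' @param sweep_fractions Optional sweep grid (see [cutoff_sweep()]).
#' @param figures Write PDF figures (default TRUE).
#' @return Invisibly, a list with the `rec_data` object, the `rec_report`
#'   and the sweep.
#' @export
run_rec_pipeline <- function(samples, geometry, out_dir,
                             cutoff_fraction = "auto",
                             n_steps = 101, k_outlier = 2.5,
                             m_velocity = 101,
                             sweep_fractions = NULL,
                             figures = TRUE) {
  if (is.character(geometry)) geometry <- read_geometry(geometry)
  if (is.character(samples)) samples <- read_trajectories(samples, geometry)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cutoff <- if (identical(cutoff_fraction, "auto")) {
    default_cutoff(geometry)
  } else {
    cutoff_spec(geometry, as.numeric(cutoff_fraction))
  }

  dat <- preprocess_trials(samples, geometry, n_steps = n_steps,
                           k_outlier = k_outlier)
  dat <- classify_multistep(dat, cutoff)
  report <- rec_report(dat)
  sweep <- cutoff_sweep(dat)

  trials <- analysis_set(dat)
  key <- paste(dat$paths$participant, dat$paths$trial, sep = "\r")
  paths_kept <- dat$paths[key %in% paste(trials$participant, trials$trial,
                                         sep = "\r"), , drop = FALSE]
  profiles <- speed_profiles(
    paths_kept,
    trials[, c("participant", "trial", "mad_index", "multistep",
               "compatibility")],
    m = m_velocity
  )
  prof_avg <- average_profiles(profiles, by = "multistep")

  readr::write_csv(dat$trials, file.path(out_dir, "measures.csv"),
                   progress = FALSE)
  readr::write_csv(tidy(report), file.path(out_dir, "report.csv"),
                   progress = FALSE)
  readr::write_csv(report$pcc_table, file.path(out_dir, "pcc.csv"),
                   progress = FALSE)
  readr::write_csv(tibble::as_tibble(unclass(sweep)),
                   file.path(out_dir, "sweep.csv"), progress = FALSE)
  readr::write_csv(tibble::as_tibble(unclass(prof_avg)),
                   file.path(out_dir, "velocity_profiles.csv"),
                   progress = FALSE)
  readr::write_csv(report$audit, file.path(out_dir, "audit.csv"),
                   progress = FALSE)

  if (figures) {
    save_fig <- function(plot, name, width = 7, height = 5) {
      grDevices::pdf(file.path(out_dir, name), width = width,
                     height = height)
      print(plot)
      grDevices::dev.off()
    }
    save_fig(plot_mean_trajectories(dat), "mean_trajectories.pdf")
    save_fig(plot_mean_trajectories(dat, exclude_multistep = TRUE),
             "mean_trajectories_single_step.pdf")
    save_fig(ggplot2::autoplot(sweep), "sweep.pdf")
    save_fig(ggplot2::autoplot(prof_avg), "velocity_profiles.pdf")
  }

  provenance <- list(
    package = "trajsplit",
    version = as.character(utils::packageVersion("trajsplit")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    cutoff_fraction = cutoff$fraction,
    n_steps = n_steps, k_outlier = k_outlier, m_velocity = m_velocity,
    counts = as.list(glance(report))
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(data = dat, report = report, sweep = sweep,
                 profiles = prof_avg))
}
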