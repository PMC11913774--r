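# On-disk layout: a study directory holds subjects.csv, blocks.csv,
# trials.csv, a DCF manifest and one signal CSV per subject-block. All files
# are plain text so a study can be regenerated, inspected or shared without
# binary formats.

#' Write an IBI series to CSV
#'
#' Columns: `beat_time_s`, `ibi_ms`, `replaced`.
#'
#' @param ibi An [ibi_series()].
#' @param path Output file.
#' @export
write_ibi_csv <- function(ibi, path) {
  stopifnot(inherits(ibi, "ibi_series"))
  utils::write.csv(
    data.frame(beat_time_s = ibi$beat_times_s, ibi_ms = ibi$ibi_ms,
               replaced = ibi$replaced),
    path, row.names = FALSE
  )
}

#' Read an IBI series from CSV
#'
#' @param path A file written by [write_ibi_csv()].
#' @return An [ibi_series()].
#' @export
read_ibi_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("beat_time_s", "ibi_ms") %in% names(df)))
  ibi_series(df$beat_time_s, df$ibi_ms,
             replaced = if ("replaced" %in% names(df)) df$replaced else
               logical(nrow(df)))
}

#' Write a uniform series to CSV
#'
#' Columns: `time_s`, `value`.
#'
#' @param us A [uniform_series()].
#' @param path Output file.
#' @export
write_uniform_csv <- function(us, path) {
  stopifnot(inherits(us, "uniform_series"))
  utils::write.csv(
    data.frame(time_s = time_points(us), value = us$values),
    path, row.names = FALSE
  )
}

#' Read a uniform series from CSV
#'
#' The sampling rate is recovered from the (strictly uniform) time column.
#'
#' @param path A file written by [write_uniform_csv()].
#' @return A [uniform_series()].
#' @export
read_uniform_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "value") %in% names(df)), nrow(df) >= 2)
  dt <- diff(df$time_s)
  if (max(abs(dt - dt[1])) > 1e-6) {
    stop("time column is not uniformly spaced", call. = FALSE)
  }
  uniform_series(df$value, rate_hz = 1 / dt[1], t0_s = df$time_s[1])
}

#' Write a synthetic study to a directory
#'
#' Produces `manifest.dcf`, `subjects.csv`, `blocks.csv`, `trials.csv` and a
#' `signals/` folder with one CSV per subject-block, i.e. the same layout the
#' reading helpers consume.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(file.path(dir, "signals"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  utils::write.csv(study$blocks, file.path(dir, "blocks.csv"), row.names = FALSE)
  utils::write.csv(study$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  for (key in names(study$signals)) {
    f <- file.path(dir, "signals", paste0(key, ".csv"))
    sig <- study$signals[[key]]
    if (inherits(sig, "uniform_series")) write_uniform_csv(sig, f)
    else write_ibi_csv(sig, f)
  }
  write.dcf(
    data.frame(
      package = "dyadsync",
      domain = study$domain,
      n_dyads = study$params$n_dyads,
      n_blocks_per_condition = study$params$n_blocks_per_condition,
      include_baseline = study$params$include_baseline,
      n_signals = length(study$signals)
    ),
    file.path(dir, "manifest.dcf")
  )
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Study directory.
#' @return A list with the same shape as a `synthetic_study` (class
#'   `synthetic_study`), usable by all study-level drivers.
#' @export
read_study <- function(dir) {
  man <- read.dcf(file.path(dir, "manifest.dcf"))
  domain <- unname(man[1, "domain"])
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"))
  blocks <- utils::read.csv(file.path(dir, "blocks.csv"))
  trials_path <- file.path(dir, "trials.csv")
  trials <- if (file.exists(trials_path)) utils::read.csv(trials_path) else NULL
  files <- list.files(file.path(dir, "signals"), pattern = "\\.csv$",
                      full.names = TRUE)
  signals <- lapply(files, function(f) {
    if (domain == "uniform") read_uniform_csv(f) else read_ibi_csv(f)
  })
  names(signals) <- sub("\\.csv$", "", basename(files))
  structure(
    list(subjects = subjects, blocks = blocks, trials = trials,
         signals = signals, domain = domain,
         params = list(
           n_dyads = as.integer(man[1, "n_dyads"]),
           n_blocks_per_condition = as.integer(man[1, "n_blocks_per_condition"]),
           include_baseline = as.logical(man[1, "include_baseline"])
         )),
    class = "synthetic_study"
  )
}

#' Write the per-series prewhitening QC report
#'
#' @param fits The `fits` table from [prewhiten_study()].
#' @param path Output CSV.
#' @export
write_qc_log <- function(fits, path) {
  utils::write.csv(fits, path, row.names = FALSE)
}
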