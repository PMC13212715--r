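#' Write a trial to disk
#'
#' CSV dialect: UTF-8, comma-separated, `.` decimal, mandatory header, time
#' column `time_s`. The 2-kHz channels share `<id>.csv`
#' (`time_s,torque_Nm[,emg_V]`); the fascicle channel keeps its native frame
#' rate in `<id>_fascicle.csv` (`time_s,fascicle_mm`). A JSON sidecar
#' `<id>_meta.json` records sampling rates, units and identifiers, and
#' `<id>_truth.json` stores the scalar simulation ground truth when present.
#'
#' @param trial a `sim_trial` (or compatible list with `channels`,
#'   `condition`, `experiment`).
#' @param dir output directory (created if missing).
#' @param id trial identifier used as the file stem.
#' @param participant participant label stored in the sidecar.
#' @return Invisibly, the meta-file path.
#' @export
write_trial <- function(trial, dir, id, participant = "S01") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ch <- trial$channels
  tq <- ch$torque
  df <- data.frame(time_s = channel_times(tq), torque_Nm = tq$values)
  if (!is.null(ch$emg)) df$emg_V <- ch$emg$values
  utils::write.csv(df, file.path(dir, paste0(id, ".csv")), row.names = FALSE)
  meta <- list(participant = participant, condition = trial$condition,
               experiment = trial$experiment,
               channels = list(torque = list(sampling_rate = tq$sampling_rate,
                                             units = "Nm")))
  if (!is.null(ch$emg))
    meta$channels$emg <- list(sampling_rate = ch$emg$sampling_rate,
                              units = "V")
  if (!is.null(ch$fascicle)) {
    utils::write.csv(
      data.frame(time_s = ch$fascicle$times,
                 fascicle_mm = ch$fascicle$lengths),
      file.path(dir, paste0(id, "_fascicle.csv")), row.names = FALSE)
    meta$channels$fascicle <- list(
      sampling_rate = 1 / stats::median(diff(ch$fascicle$times)),
      units = "mm", drift_flag = ch$fascicle$drift_flag)
  }
  meta_path <- file.path(dir, paste0(id, "_meta.json"))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  gt <- trial$ground_truth
  if (!is.null(gt)) {
    scalars <- gt[vapply(gt, function(x) is.numeric(x) && length(x) == 1L,
                         logical(1))]
    jsonlite::write_json(scalars, file.path(dir, paste0(id, "_truth.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(meta_path)
}

#' Read a trial from disk
#'
#' Inverse of [write_trial()]; validates the schema (required channels,
#' units, monotonic time, sampling rate consistent with the time column) and
#' names the offending field in every error. Extra unknown CSV columns are
#' ignored.
#'
#' @param meta_path path to the `<id>_meta.json` sidecar.
#' @return A list with `channels`, `condition`, `experiment`,
#'   `participant`, and `ground_truth` (scalars, if a truth sidecar exists).
#' @export
read_trial <- function(meta_path) {
  if (!file.exists(meta_path)) stop("missing metadata file: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  stem <- sub("_meta\\.json$", "", meta_path)
  main <- paste0(stem, ".csv")
  if (!file.exists(main)) stop("missing trial file: ", main)
  df <- utils::read.csv(main)
  if (!"time_s" %in% names(df)) stop("column 'time_s' absent in ", main)
  if (any(diff(df$time_s) <= 0)) stop("non-monotonic time_s in ", main)
  channels <- list()
  for (nm in names(meta$channels)) {
    info <- meta$channels[[nm]]
    if (nm == "fascicle") next
    col <- paste0(nm, "_", info$units)
    if (!col %in% names(df))
      stop("channel '", nm, "' absent: expected column '", col, "'")
    fs_file <- 1 / stats::median(diff(df$time_s))
    if (abs(fs_file - info$sampling_rate) / info$sampling_rate > 0.01)
      stop(sprintf("channel '%s': declared rate %g Hz but time column implies %g Hz",
                   nm, info$sampling_rate, fs_file))
    channels[[nm]] <- ts_channel(df[[col]], info$sampling_rate, name = nm,
                                 units = info$units, t0 = df$time_s[1])
  }
  if (is.null(channels$torque)) stop("channel 'torque' absent")
  if ("fascicle" %in% names(meta$channels)) {
    fpath <- paste0(stem, "_fascicle.csv")
    if (!file.exists(fpath)) stop("missing fascicle file: ", fpath)
    fd <- utils::read.csv(fpath)
    if (!all(c("time_s", "fascicle_mm") %in% names(fd)))
      stop("fascicle file must have columns time_s, fascicle_mm")
    channels$fascicle <- fascicle_trace(
      fd$time_s, fd$fascicle_mm, source = "tracked",
      drift_flag = isTRUE(meta$channels$fascicle$drift_flag))
  }
  truth <- NULL
  tpath <- paste0(stem, "_truth.json")
  if (file.exists(tpath))
    truth <- jsonlite::read_json(tpath, simplifyVector = TRUE)
  list(channels = channels, condition = meta$condition,
       experiment = meta$experiment, participant = meta$participant,
       ground_truth = truth)
}

#' Write a simulated dataset to disk
#'
#' One directory per subject holding the MVC trial (`MVC`) and numbered
#' submaximal trials (`T01`, ...), plus a top-level `manifest.tsv`.
#'
#' @param dataset a `sim_dataset` from [generate_dataset()].
#' @param dir output directory.
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in dataset) {
    sdir <- file.path(dir, s$id)
    write_trial(s$mvc, sdir, "MVC", participant = s$id)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s$id, trial_id = "MVC", condition = "MVC")
    for (i in seq_along(s$trials)) {
      tid <- sprintf("T%02d", i)
      write_trial(s$trials[[i]], sdir, tid, participant = s$id)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s$id, trial_id = tid,
        condition = s$trials[[i]]$condition)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$experiment <- attr(dataset, "experiment")
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(mpath)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.tsv`.
#' @return A `sim_dataset`-shaped list of subjects with `id`, `mvc`,
#'   `trials`.
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.tsv")
  if (!file.exists(mpath)) stop("missing manifest.tsv in ", dir)
  manifest <- utils::read.delim(mpath)
  subjects <- list()
  for (sid in unique(manifest$subject)) {
    rows <- manifest[manifest$subject == sid, ]
    sdir <- file.path(dir, sid)
    mvc <- read_trial(file.path(sdir, "MVC_meta.json"))
    trials <- lapply(rows$trial_id[rows$trial_id != "MVC"], function(tid)
      read_trial(file.path(sdir, paste0(tid, "_meta.json"))))
    subjects[[length(subjects) + 1L]] <- list(id = sid, mvc = mvc,
                                              trials = trials)
  }
  structure(subjects, experiment = manifest$experiment[1],
            class = "sim_dataset")
}

# tiny rolling hash for provenance blocks (no external digest dependency)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}
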