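#' Write a session bundle to disk
#'
#' Serialises a session as plain-text files in `path`: `spikes.csv`
#' (unit_id, region, unit_class, spike_time_s), `events.csv` (trial_index,
#' run_index, stimulus_id, category_id, onset_s) and a `metadata.json`
#' sidecar carrying the session id, format version, generator seed, config
#' hash, and the unit and stimulus tables.  Ground truth of synthetic
#' sessions, when present, goes to `ground_truth.json`; it is written for
#' inspection only and never read back by analysis code.  Times are stored
#' in seconds with 6 decimal places (32 kHz resolution is ~3e-5 s).
#'
#' @param session An `mtl_session`.
#' @param path Directory to create/populate.
#' @param session_id Identifier stored in the metadata.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, session_id = "session01") {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  spk <- data.frame(
    unit_id = rep(session$units$unit_id, lengths(session$spikes)),
    region = rep(session$units$region, lengths(session$spikes)),
    unit_class = rep(session$units$unit_class, lengths(session$spikes)),
    spike_time_s = sprintf("%.6f", unlist(session$spikes, use.names = FALSE)),
    stringsAsFactors = FALSE)
  ev <- session$events
  ev$onset_s <- sprintf("%.6f", ev$onset_s)
  write_table <- function(d, f) {
    if (requireNamespace("data.table", quietly = TRUE))
      data.table::fwrite(d, f)
    else utils::write.csv(d, f, row.names = FALSE, quote = FALSE)
  }
  write_table(spk, file.path(path, "spikes.csv"))
  write_table(ev, file.path(path, "events.csv"))
  meta <- list(session_id = session_id,
               format_version = "1.0",
               rng_seed = session$config$rng_seed,
               config_hash = config_hash(session$config),
               duration_s = round(session$duration_s, 6),
               units = session$units,
               stimuli = session$stimuli)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  if (!is.null(session$ground_truth))
    jsonlite::write_json(session$ground_truth,
                         file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  invisible(path)
}

# Hash of the canonical serialisation of a config (used to stamp outputs).
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}

#' Read a session bundle from disk
#'
#' Inverse of [write_session()]; validates the schema and referential
#' integrity (every spike's unit_id and every event's stimulus_id must
#' appear in the metadata tables; onsets strictly increasing; spike times
#' non-negative) and reports the offending row on failure.
#'
#' @param path Directory written by [write_session()].
#' @return An `mtl_session` (without ground truth and generator config;
#'   `config` holds the metadata stub).
#' @export
read_session <- function(path) {
  meta_file <- file.path(path, "metadata.json")
  if (!file.exists(meta_file)) stop("no metadata.json in ", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  units <- as.data.frame(meta$units, stringsAsFactors = FALSE)
  stimuli <- as.data.frame(meta$stimuli, stringsAsFactors = FALSE)

  read_table <- function(f) {
    if (requireNamespace("data.table", quietly = TRUE))
      as.data.frame(data.table::fread(f, colClasses = "character"))
    else utils::read.csv(f, colClasses = "character",
                         stringsAsFactors = FALSE)
  }
  spk <- read_table(file.path(path, "spikes.csv"))
  ev <- read_table(file.path(path, "events.csv"))

  need <- function(d, cols, file) {
    miss <- setdiff(cols, names(d))
    if (length(miss))
      stop(sprintf("%s: missing column(s) %s", file,
                   paste(miss, collapse = ", ")))
  }
  need(spk, c("unit_id", "region", "unit_class", "spike_time_s"),
       "spikes.csv")
  need(ev, c("trial_index", "run_index", "stimulus_id", "category_id",
             "onset_s"), "events.csv")

  check_num <- function(x, file, col, nonneg = TRUE) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) | (nonneg & v < 0))
    if (length(bad))
      stop(sprintf("%s row %d: invalid %s value '%s'",
                   file, bad[1], col, x[bad[1]]))
    v
  }
  spk_t <- check_num(spk$spike_time_s, "spikes.csv", "spike_time_s")
  onset <- check_num(ev$onset_s, "events.csv", "onset_s")
  if (any(diff(onset) <= 0))
    stop(sprintf("events.csv row %d: onsets not strictly increasing",
                 which(diff(onset) <= 0)[1] + 1L))
  bad_unit <- which(!(spk$unit_id %in% units$unit_id))
  if (length(bad_unit))
    stop(sprintf("spikes.csv row %d: unknown unit_id '%s'",
                 bad_unit[1], spk$unit_id[bad_unit[1]]))
  bad_stim <- which(!(ev$stimulus_id %in% stimuli$stimulus_id))
  if (length(bad_stim))
    stop(sprintf("events.csv row %d: unknown stimulus_id '%s'",
                 bad_stim[1], ev$stimulus_id[bad_stim[1]]))

  spikes <- lapply(stats::setNames(units$unit_id, units$unit_id),
                   function(u) sort(spk_t[spk$unit_id == u]))
  events <- data.frame(trial_index = as.integer(ev$trial_index),
                       run_index = as.integer(ev$run_index),
                       stimulus_id = ev$stimulus_id,
                       category_id = ev$category_id,
                       onset_s = onset,
                       stringsAsFactors = FALSE)
  structure(list(units = units, spikes = spikes, events = events,
                 stimuli = stimuli, ground_truth = NULL,
                 config = meta[c("session_id", "rng_seed", "config_hash",
                                 "format_version")],
                 duration_s = as.numeric(meta$duration_s)),
            class = "mtl_session")
}

#' Canonical form of a session (for round-trip comparison)
#'
#' Rounds all times to the stored 6-decimal resolution and sorts spikes, so
#' that `read_session(write_session(x))` equals `canonical_session(x)` up to
#' ground truth and generator config.
#'
#' @param session An `mtl_session`.
#' @return The canonicalised `mtl_session`.
#' @export
canonical_session <- function(session) {
  session$spikes <- lapply(session$spikes,
                           function(s) sort(round(s, 6)))
  session$events$onset_s <- round(session$events$onset_s, 6)
  session$duration_s <- round(session$duration_s, 6)
  session
}
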