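#' Write a synthetic study to disk
#'
#' Writes a study-level `participants.csv` (subject_id, group, moca,
#' age_years), and per subject a BIDS-inspired events TSV (onset_sample,
#' session, role, category, image_id) plus the continuous signal as a plain
#' CSV (one column per channel, microvolts), with the sampling rate recorded
#' in a JSON sidecar.
#'
#' @param study An `eeg_study`.
#' @param dir Output directory (created if missing).
#' @param signals Write the (large) signal CSVs too; the participants and
#'   events tables are always written.
#' @return Invisibly, the directory.
#' @export
write_study <- function(study, dir, signals = TRUE) {
  stopifnot(inherits(study, "eeg_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(study$participants[, c("subject_id", "group", "moca",
                                   "age_years")],
            file.path(dir, "participants.csv"), row.names = FALSE)
  for (sid in names(study$recordings)) {
    rec <- study$recordings[[sid]]
    ev <- rec$events
    names(ev)[names(ev) == "session_index"] <- "session"
    utils::write.table(ev, file.path(dir, paste0(sid, "_events.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (signals) {
      sig <- as.data.frame(t(rec$data))
      names(sig) <- rec$channel_names
      write.csv(sig, file.path(dir, paste0(sid, "_eeg.csv")),
                row.names = FALSE)
    }
    jsonlite::write_json(list(subject_id = sid,
                              sampling_rate_hz = rec$sampling_rate_hz,
                              channel_names = rec$channel_names),
                         file.path(dir, paste0(sid, "_eeg.json")),
                         auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' @param dir Directory containing `participants.csv` and per-subject
#'   `*_eeg.csv` / `*_events.tsv` / `*_eeg.json` files.
#' @return An `eeg_study` (with `config = NULL`; severity is not persisted).
#' @export
read_study <- function(dir) {
  participants <- read.csv(file.path(dir, "participants.csv"),
                           stringsAsFactors = FALSE)
  recordings <- list()
  for (sid in participants$subject_id) {
    meta <- jsonlite::read_json(file.path(dir, paste0(sid, "_eeg.json")),
                                simplifyVector = TRUE)
    sig <- read.csv(file.path(dir, paste0(sid, "_eeg.csv")),
                    check.names = FALSE)
    ev <- utils::read.table(file.path(dir, paste0(sid, "_events.tsv")),
                            sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    names(ev)[names(ev) == "session"] <- "session_index"
    data <- t(as.matrix(sig))
    rownames(data) <- meta$channel_names
    recordings[[sid]] <- structure(
      list(subject_id = sid, channel_names = meta$channel_names,
           sampling_rate_hz = meta$sampling_rate_hz, data = data,
           events = ev),
      class = "eeg_recording")
  }
  structure(list(config = NULL, participants = participants,
                 recordings = recordings),
            class = "eeg_study")
}
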