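#' Write a session to a directory of plain-text tables
#'
#' The on-disk container is a directory holding `header.json` (duration,
#' clock conventions, provenance, schema version), `units.csv` (metadata,
#' one row per unit), `spikes.csv` (long table of `unit_id`, `time_s` at
#' source resolution), `velocity.csv` (10 ms rows x 4 paw columns, mm per
#' 10 ms) and `labels.csv` (500 ms rows). All bins are half-open
#' `[t, t + dt)` with 0-based time origin.
#'
#' @param session A `cd_session`.
#' @param path Target directory (created if missing; files overwritten).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "cd_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  header <- list(schema_version = 1L,
                 duration_s = session$duration_s,
                 bin_s = session$bin_s, snippet_s = session$snippet_s,
                 subject = session$subject, session_id = session$session_id,
                 seed = session$seed,
                 n_units = nrow(session$units),
                 label_levels = levels(session$labels))
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(session$units, file.path(path, "units.csv"),
                   row.names = FALSE)
  sp <- data.frame(
    unit_id = rep(session$units$unit_id, lengths(session$spike_times)),
    time_s = unlist(session$spike_times, use.names = FALSE) %||% numeric(0))
  utils::write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(session$velocity),
                   file.path(path, "velocity.csv"), row.names = FALSE)
  utils::write.csv(data.frame(label = as.character(session$labels)),
                   file.path(path, "labels.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a session directory, validating the schema
#'
#' Validation errors name the offending field and row. A missing
#' somatotopic `region` column is tolerated (read as `"unknown"` with a
#' warning); the somatotopy-shuffle analysis refuses such sessions later.
#'
#' @param path Session directory written by [write_session()].
#' @return A `cd_session`.
#' @export
read_session <- function(path) {
  need <- c("header.json", "units.csv", "spikes.csv", "velocity.csv",
            "labels.csv")
  miss <- need[!file.exists(file.path(path, need))]
  if (length(miss)) stop("session at ", path, " missing: ",
                         paste(miss, collapse = ", "))
  header <- jsonlite::read_json(file.path(path, "header.json"),
                                simplifyVector = TRUE)
  units <- utils::read.csv(file.path(path, "units.csv"),
                           stringsAsFactors = FALSE)
  if (!"unit_id" %in% names(units)) stop("units.csv: missing field unit_id")
  if (!"region" %in% names(units)) {
    warning("units.csv has no somatotopic region column; set to 'unknown'")
    units$region <- "unknown"
  }
  sp <- utils::read.csv(file.path(path, "spikes.csv"),
                        stringsAsFactors = FALSE)
  dur <- header$duration_s
  bad <- which(sp$time_s < 0 | sp$time_s > dur)
  if (length(bad))
    stop("spikes.csv: time_s outside [0, duration] at row ", bad[1])
  unknown_units <- setdiff(unique(sp$unit_id), units$unit_id)
  if (length(unknown_units))
    stop("spikes.csv: unknown unit_id ", unknown_units[1])
  vel <- as.matrix(utils::read.csv(file.path(path, "velocity.csv")))
  colnames(vel) <- PAWS
  if (nrow(vel) != round(dur * 100))
    stop("velocity.csv: ", nrow(vel), " rows for a ", dur, " s session")
  labs <- utils::read.csv(file.path(path, "labels.csv"),
                          stringsAsFactors = FALSE)$label
  if (length(labs) != round(dur * 2))
    stop("labels.csv: ", length(labs), " rows for a ", dur, " s session")
  spike_times <- lapply(units$unit_id, function(u)
    sort(sp$time_s[sp$unit_id == u]))
  lev <- header$label_levels %||% unique(c(CLASSES, unique(labs)))
  structure(list(
    units = units, spike_times = spike_times, velocity = vel,
    labels = factor(labs, levels = lev),
    duration_s = dur, bin_s = header$bin_s %||% 0.01,
    snippet_s = header$snippet_s %||% 0.5,
    subject = header$subject, session_id = header$session_id,
    seed = header$seed
  ), class = "cd_session")
}
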