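#' Write or read a trajectory table (CSV)
#'
#' Floats are serialized at full precision; write-then-read is the identity
#' on the data model.
#'
#' @param traj trajectory data.frame (see [trajectory()]).
#' @param path file path.
#' @return `read_trajectory`: data.frame; `write_trajectory`: path,
#'   invisibly.
#' @export
write_trajectory <- function(traj, path) {
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(traj, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  if (file.size(path) == 0) stop("empty trajectory file: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(out) == 0) stop("trajectory file contains no records: ", path)
  out
}

#' Write or read an event log (JSONL)
#'
#' One JSON object per line: day, type, parent_id, child_id, target.
#'
#' @param events event data.frame (see [event_log()]).
#' @param path file path.
#' @return `read_events`: data.frame; `write_events`: path, invisibly.
#' @export
write_events <- function(events, path) {
  con <- file(path, "w"); on.exit(close(con))
  if (nrow(events)) {
    for (r in seq_len(nrow(events)))
      writeLines(jsonlite::toJSON(as.list(events[r, ]), auto_unbox = TRUE,
                                  digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  lines <- readLines(path)
  if (!length(lines))
    return(data.frame(day = integer(0), type = character(0),
                      parent_id = integer(0), child_id = integer(0),
                      target = integer(0)))
  do.call(rbind, lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
}

#' Write or read a cohort result
#'
#' The cohort is serialized as a directory: `tumors.csv`, `treatments.csv`
#' (if present), `top5.json` and `meta.json`.
#'
#' @param cohort an `ip_cohort`.
#' @param dir output directory (created if needed).
#' @return `read_cohort`: an `ip_cohort` (without simulation states);
#'   `write_cohort`: the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ip_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(cohort$tumors, file.path(dir, "tumors.csv"), row.names = FALSE)
  if (!is.null(cohort$treatments))
    utils::write.csv(cohort$treatments, file.path(dir, "treatments.csv"),
                     row.names = FALSE)
  jsonlite::write_json(cohort$top5, file.path(dir, "top5.json"), digits = NA)
  jsonlite::write_json(list(master_seed = cohort$master_seed,
                            preset_name = cohort$preset_name,
                            n_redrawn = cohort$n_redrawn),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  tfile <- file.path(dir, "tumors.csv")
  if (!file.exists(tfile)) stop("no cohort found in ", dir)
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  trfile <- file.path(dir, "treatments.csv")
  structure(list(
    tumors = utils::read.csv(tfile, stringsAsFactors = FALSE),
    treatments = if (file.exists(trfile)) utils::read.csv(trfile, stringsAsFactors = FALSE) else NULL,
    top5 = lapply(jsonlite::fromJSON(file.path(dir, "top5.json")), as.numeric),
    n_redrawn = meta$n_redrawn, states = NULL,
    master_seed = meta$master_seed, preset_name = meta$preset_name),
    class = "ip_cohort")
}
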