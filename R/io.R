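#' @title Observation records: schemas, validation and delimited-text IO
#' @description
#' The interchange format is plain CSV with a header row, one file per
#' record kind, mirroring exports from behavioural-observation software.
#' Timestamps are seconds from study start; AU onsets/offsets are seconds
#' from the start of their video. IDs are opaque strings and groups are
#' closed universes (no cross-group dyads).
#'
#' Files and columns (in this order):
#' \describe{
#'   \item{individuals.csv}{`id, group_id, sex, age_class, is_subject_male`}
#'   \item{scans.csv}{long format: `scan_id, group_id, focal_id, timestamp,
#'     individual_id, x, y, room` — one row per positioned individual}
#'   \item{follows.csv}{`follow_id, group_id, focal_id, start, duration`}
#'   \item{grooming_bouts.csv}{`follow_id, partner_id, start, duration`
#'     (start relative to the follow)}
#'   \item{agonistic.csv}{`group_id, winner_id, loser_id, timestamp, kind`}
#'   \item{au_events.csv}{`subject_id, video_id, au_code, onset, offset,
#'     context` — includes `AUX`, `AD50a` and `AU43` rows}
#'   \item{context_timeline.csv}{`subject_id, video_id, context, onset,
#'     offset` — the context active over each stretch of footage}
#' }
#' @name observation-io
NULL

# Enclosure footprint (metres): the main indoor room and the caged annex.
.rooms <- list(main = c(3.5, 8), annex = c(1.5, 6))

.schemas <- list(
  individuals = c("id", "group_id", "sex", "age_class", "is_subject_male"),
  scans = c("scan_id", "group_id", "focal_id", "timestamp",
            "individual_id", "x", "y", "room"),
  follows = c("follow_id", "group_id", "focal_id", "start", "duration"),
  grooming_bouts = c("follow_id", "partner_id", "start", "duration"),
  agonistic = c("group_id", "winner_id", "loser_id", "timestamp", "kind"),
  au_events = c("subject_id", "video_id", "au_code", "onset", "offset",
                "context"),
  context_timeline = c("subject_id", "video_id", "context", "onset",
                       "offset")
)

.check_schema <- function(df, kind) {
  want <- .schemas[[kind]]
  missing <- setdiff(want, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", kind,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df[want]
}

.bad_rows <- function(kind, what, idx) {
  stop(sprintf("%s: %s in row(s) %s", kind, what,
               paste(utils::head(idx, 10), collapse = ", ")),
       call. = FALSE)
}

#' Validate a set of observation records
#'
#' Checks every type invariant: interval orientation (offset > onset,
#' durations positive), AU codes drawn from the vocabulary plus the special
#' codes, exactly one subject male among the adults of each group, agonistic
#' winners distinct from losers and both group members, scan positions
#' inside the enclosure footprint, and grooming bouts contained in their
#' follow.
#'
#' @param data Named list with elements as in [read_observations()]. Any
#'   element may be absent; present ones are validated jointly.
#' @param config A [run_config()]; supplies the context label set.
#' @return `data`, invisibly, with columns coerced to canonical types.
#' @export
validate_observations <- function(data, config = run_config()) {
  vocab <- maqfacs_vocabulary()$code
  if (!is.null(data$individuals)) {
    ind <- .check_schema(data$individuals, "individuals")
    ind$is_subject_male <- as.logical(ind$is_subject_male)
    if (anyNA(ind$is_subject_male))
      .bad_rows("individuals", "unparseable is_subject_male",
                which(is.na(ind$is_subject_male)))
    bad <- which(!ind$sex %in% c("male", "female"))
    if (length(bad)) .bad_rows("individuals", "sex not male/female", bad)
    bad <- which(!ind$age_class %in% c("adult", "juvenile", "infant"))
    if (length(bad)) .bad_rows("individuals", "unknown age_class", bad)
    adults <- ind[ind$age_class == "adult", ]
    n_male <- tapply(adults$is_subject_male, adults$group_id, sum)
    off <- names(n_male)[n_male != 1]
    if (length(off))
      stop("individuals: groups without exactly one subject male: ",
           paste(off, collapse = ", "), call. = FALSE)
    if (any(ind$is_subject_male & ind$sex != "male"))
      stop("individuals: subject male flagged on a non-male", call. = FALSE)
    data$individuals <- ind
  }
  if (!is.null(data$au_events)) {
    ev <- .check_schema(data$au_events, "au_events")
    bad <- which(!(ev$offset > ev$onset))
    if (length(bad)) .bad_rows("au_events", "offset <= onset", bad)
    bad <- which(ev$onset < 0)
    if (length(bad)) .bad_rows("au_events", "negative onset", bad)
    bad <- which(!ev$au_code %in% c(vocab, .special_codes))
    if (length(bad)) .bad_rows("au_events", "au_code outside vocabulary", bad)
    bad <- which(!ev$context %in% config$contexts)
    if (length(bad)) .bad_rows("au_events", "unknown context label", bad)
    data$au_events <- ev
  }
  if (!is.null(data$context_timeline)) {
    tl <- .check_schema(data$context_timeline, "context_timeline")
    bad <- which(!(tl$offset > tl$onset) | tl$onset < 0)
    if (length(bad)) .bad_rows("context_timeline", "bad interval", bad)
    bad <- which(!tl$context %in% config$contexts)
    if (length(bad)) .bad_rows("context_timeline", "unknown context", bad)
    data$context_timeline <- tl
  }
  if (!is.null(data$agonistic)) {
    ag <- .check_schema(data$agonistic, "agonistic")
    bad <- which(ag$winner_id == ag$loser_id)
    if (length(bad)) .bad_rows("agonistic", "winner equals loser", bad)
    bad <- which(!ag$kind %in% c("contact", "non-contact", "displacement"))
    if (length(bad)) .bad_rows("agonistic", "unknown kind", bad)
    if (!is.null(data$individuals)) {
      grp <- stats::setNames(data$individuals$group_id, data$individuals$id)
      bad <- which(grp[ag$winner_id] != ag$group_id |
                   grp[ag$loser_id] != ag$group_id)
      if (length(bad)) .bad_rows("agonistic", "participant outside group", bad)
    }
    data$agonistic <- ag
  }
  if (!is.null(data$follows)) {
    fo <- .check_schema(data$follows, "follows")
    bad <- which(fo$duration <= 0 | fo$duration > 600)
    if (length(bad)) .bad_rows("follows", "duration outside (0, 600] s", bad)
    data$follows <- fo
    if (!is.null(data$grooming_bouts)) {
      gb <- .check_schema(data$grooming_bouts, "grooming_bouts")
      bad <- which(gb$duration <= 0 | gb$start < 0)
      if (length(bad)) .bad_rows("grooming_bouts", "non-positive bout", bad)
      dur <- stats::setNames(fo$duration, fo$follow_id)
      bad <- which(!gb$follow_id %in% fo$follow_id)
      if (length(bad)) .bad_rows("grooming_bouts", "unknown follow_id", bad)
      bad <- which(gb$start + gb$duration > dur[gb$follow_id] + 1e-9)
      if (length(bad)) .bad_rows("grooming_bouts", "bout exceeds follow", bad)
      data$grooming_bouts <- gb
    }
  }
  if (!is.null(data$scans)) {
    sc <- .check_schema(data$scans, "scans")
    bad <- which(!sc$room %in% names(.rooms))
    if (length(bad)) .bad_rows("scans", "unknown room label", bad)
    dims <- do.call(rbind, .rooms)[sc$room, , drop = FALSE]
    bad <- which(sc$x < 0 | sc$y < 0 | sc$x > dims[, 1] | sc$y > dims[, 2])
    if (length(bad)) .bad_rows("scans", "position outside enclosure", bad)
    data$scans <- sc
  }
  invisible(data)
}

#' Read observation files from a directory
#'
#' Reads whichever of the schema files are present in `dir`, validates all
#' invariants and logs row counts to stderr.
#'
#' @param dir Directory containing the CSV files.
#' @param config A [run_config()].
#' @return Named list of data.frames (`individuals`, `scans`, `follows`,
#'   `grooming_bouts`, `agonistic`, `au_events`, `context_timeline`).
#' @export
read_observations <- function(dir, config = run_config()) {
  data <- list()
  for (kind in names(.schemas)) {
    path <- file.path(dir, paste0(kind, ".csv"))
    if (!file.exists(path)) next
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    num_cols <- intersect(names(df), c("timestamp", "x", "y", "start",
                                       "duration", "onset", "offset"))
    for (cc in num_cols) df[[cc]] <- as.numeric(df[[cc]])
    data[[kind]] <- df
  }
  data <- validate_observations(data, config)
  for (kind in names(data))
    message(sprintf("read %s: %d rows", kind, nrow(data[[kind]])))
  data
}

#' Write observation records to a directory
#'
#' Writes one CSV per record kind with the canonical column order, so that
#' reading the directory back reproduces the records exactly.
#'
#' @param data Named list as returned by [read_observations()] or
#'   [simulate_study()].
#' @param dir Output directory; created if needed.
#' @param config A [run_config()] used to re-validate before writing.
#' @return `dir`, invisibly.
#' @export
write_observations <- function(data, dir, config = run_config()) {
  data <- validate_observations(data, config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (kind in intersect(names(.schemas), names(data))) {
    df <- data[[kind]][.schemas[[kind]]]
    # 17 significant digits: doubles survive the text round trip exactly
    for (cc in names(df))
      if (is.numeric(df[[cc]]))
        df[[cc]] <- formatC(df[[cc]], digits = 17, format = "g")
    utils::write.csv(df, file.path(dir, paste0(kind, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
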