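# Reading, validating, anonymizing and bundling the per-participant tables.
#
# One directory per participant holds CSV tables named after the collection
# app's schema (SCREEN_ONOFF, LOCATIONS, ACTIVITY_TRANSITION, FACE_LANDMARK,
# plus parsed-but-unused logs such as CALL_LOGS) and a QUESTIONNAIRES table.
# A cohort manifest CSV (participant_id, window_start, window_end, diagnosis)
# lists participants and their collection windows.

ACTIVITY_CLASSES <- c("VEHICLE", "CYCLING", "WALKING", "RUNNING",
                      "WALKING_OR_RUNNING", "STATIONARY", "TILTING", "UNKNOWN")
INSTRUMENTS <- c("PHQ9", "CESDR", "ISI", "PHQ2", "TAM")
WAVES <- c("M1", "M2", "M3", "DAILY")
EMBEDDING_DIM <- 16L
EXPR_COLS <- sprintf("expr_%02d", seq_len(EMBEDDING_DIM))

# Tables that generate features vs tables that are parsed and validated only.
FEATURE_TABLES <- c("SCREEN_ONOFF", "LOCATIONS", "ACTIVITY_TRANSITION",
                    "FACE_LANDMARK")
PASSTHROUGH_TABLES <- c("CALL_LOGS", "SMS_LOGS", "WIFI_INFO",
                        "BLUETOOTH_DEVICES", "BATTERY_INFO", "CELL_INFO",
                        "SENSORS")
SENSOR_TABLES <- c(FEATURE_TABLES, PASSTHROUGH_TABLES)

#' Anonymize a raw device identifier
#'
#' Participants are identified only by a salted hash of the raw device
#' identifier, so stored records cannot be traced back to a device.
#'
#' @param raw_identifier non-empty character vector of raw identifiers.
#' @param salt character scalar; the cohort-level secret salt.
#' @return character vector of 32-character hexadecimal hashes. Deterministic
#'   for a fixed salt; different salts give unrelated hashes.
#' @examples
#' anonymizeId("deviceA", salt = "s1")
#' @export
anonymizeId <- function(raw_identifier, salt) {
  stopifnot(is.character(salt), length(salt) == 1L)
  raw_identifier <- as.character(raw_identifier)
  if (length(raw_identifier) == 0L || any(!nzchar(raw_identifier)) ||
      any(is.na(raw_identifier))) {
    stop("anonymizeId: empty identifier", call. = FALSE)
  }
  vapply(raw_identifier, function(id) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(paste0(salt, "\x1f", id), f)
    unname(tools::md5sum(f))
  }, character(1), USE.NAMES = FALSE)
}

# Column schema per table: required columns beyond participant_id/timestamp.
tableSchema <- function(table_name) {
  switch(table_name,
    SCREEN_ONOFF = c("state"),
    LOCATIONS = c("latitude", "longitude"),
    ACTIVITY_TRANSITION = c("activity_class", "transition"),
    FACE_LANDMARK = EXPR_COLS,
    QUESTIONNAIRES = c("instrument", "wave"),
    character(0))
}

validateRows <- function(df, table_name, ts) {
  ok <- !is.na(ts$utc)
  reason <- ifelse(ok, "", "bad timestamp")
  flagBad <- function(bad, why) {
    bad <- bad & ok
    reason[bad] <<- why
    ok <<- ok & !bad
  }
  if (table_name == "SCREEN_ONOFF") {
    flagBad(!(toupper(trimws(df$state)) %in% c("ON", "OFF")), "bad state")
  } else if (table_name == "LOCATIONS") {
    lat <- suppressWarnings(as.numeric(df$latitude))
    lon <- suppressWarnings(as.numeric(df$longitude))
    flagBad(is.na(lat) | is.na(lon), "non-numeric coordinate")
    flagBad(!is.na(lat) & !is.na(lon) &
              (abs(lat) > 90 | abs(lon) > 180), "coordinate out of bounds")
  } else if (table_name == "ACTIVITY_TRANSITION") {
    flagBad(!(toupper(trimws(df$activity_class)) %in% ACTIVITY_CLASSES),
            "unknown activity class")
    flagBad(!(toupper(trimws(df$transition)) %in% c("ENTER", "EXIT")),
            "bad transition")
  } else if (table_name == "FACE_LANDMARK") {
    emb <- suppressWarnings(
      vapply(df[EXPR_COLS], as.numeric, numeric(nrow(df))))
    emb <- matrix(emb, nrow = nrow(df))
    flagBad(apply(emb, 1L, function(v) any(!is.finite(v))),
            "non-finite embedding")
  }
  list(ok = ok, reason = reason)
}

#' Read one raw sensor table
#'
#' Parses a CSV in the collection schema, validates each row against the
#' table's type constraints (timestamps, coordinate bounds, the eight activity
#' classes, embedding finiteness), skips and counts malformed rows, and
#' returns records sorted by timestamp. Tables that the study collected but
#' never used for features (call/SMS/WiFi/Bluetooth/battery/cell/raw sensors)
#' are parsed and timestamp-validated but generate no features downstream.
#'
#' @param path path to the CSV file.
#' @param table_name one of `SCREEN_ONOFF`, `LOCATIONS`, `ACTIVITY_TRANSITION`,
#'   `FACE_LANDMARK`, `CALL_LOGS`, `SMS_LOGS`, `WIFI_INFO`,
#'   `BLUETOOTH_DEVICES`, `BATTERY_INFO`, `CELL_INFO`, `SENSORS`.
#' @return list with `records` (a data.frame sorted by timestamp, with
#'   `participant_id`, `timestamp` (POSIXct, UTC), `offset_min`, and the
#'   table-specific columns) and `report` (list: `n_rows`, `n_parsed`,
#'   `n_skipped`, `skip_reasons` table).
#' @export
readSensorTable <- function(path, table_name) {
  table_name <- toupper(table_name)
  if (!table_name %in% SENSOR_TABLES) {
    stop("readSensorTable: unknown table_name '", table_name, "'",
         call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("readSensorTable: file not found: ", path, call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("participant_id", "timestamp", tableSchema(table_name))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("readSensorTable: ", table_name, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    return(list(records = emptyRecords(table_name),
                report = list(n_rows = 0L, n_parsed = 0L, n_skipped = 0L,
                              skip_reasons = table(character(0)))))
  }
  ts <- parseTimestamp(df$timestamp)
  v <- validateRows(df, table_name, ts)
  if (mean(!v$ok) > 0.5) {
    stop("readSensorTable: more than 50% malformed rows in table ",
         table_name, call. = FALSE)
  }
  keep <- which(v$ok)
  out <- data.frame(participant_id = df$participant_id[keep],
                    timestamp = ts$utc[keep],
                    offset_min = ts$offset_min[keep],
                    stringsAsFactors = FALSE)
  if (table_name == "SCREEN_ONOFF") {
    out$state <- toupper(trimws(df$state[keep]))
  } else if (table_name == "LOCATIONS") {
    out$latitude <- as.numeric(df$latitude[keep])
    out$longitude <- as.numeric(df$longitude[keep])
  } else if (table_name == "ACTIVITY_TRANSITION") {
    out$activity_class <- toupper(trimws(df$activity_class[keep]))
    out$transition <- toupper(trimws(df$transition[keep]))
  } else if (table_name == "FACE_LANDMARK") {
    for (cc in EXPR_COLS) out[[cc]] <- as.numeric(df[[cc]][keep])
  }
  ord <- order(out$timestamp)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out,
       report = list(n_rows = nrow(df), n_parsed = nrow(out),
                     n_skipped = nrow(df) - nrow(out),
                     skip_reasons = table(v$reason[!v$ok])))
}

emptyRecords <- function(table_name) {
  out <- data.frame(participant_id = character(0),
                    timestamp = as.POSIXct(character(0), tz = "UTC"),
                    offset_min = integer(0), stringsAsFactors = FALSE)
  for (cc in tableSchema(table_name)) out[[cc]] <- character(0)
  if (table_name == "SCREEN_ONOFF") out$state <- character(0)
  if (table_name == "LOCATIONS") {
    out$latitude <- numeric(0); out$longitude <- numeric(0)
  }
  if (table_name == "FACE_LANDMARK") for (cc in EXPR_COLS) out[[cc]] <- numeric(0)
  out
}

#' Read a questionnaire-response table
#'
#' Item-level responses, one row per (instrument, wave): columns
#' `participant_id`, `instrument`, `wave`, `item_1 ... item_N`. Totals are not
#' stored; they are computed by [scoreInstrument()].
#'
#' @param path CSV path.
#' @return data.frame with item columns as integers (NA where an instrument
#'   has fewer items than the widest one in the file).
#' @export
readQuestionnaireTable <- function(path) {
  if (!file.exists(path)) {
    stop("readQuestionnaireTable: file not found: ", path, call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "instrument", "wave")
  if (!all(need %in% names(df))) {
    stop("readQuestionnaireTable: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  df$instrument <- toupper(trimws(df$instrument))
  df$wave <- toupper(trimws(df$wave))
  bad <- !(df$instrument %in% INSTRUMENTS) | !(df$wave %in% WAVES)
  df <- df[!bad, , drop = FALSE]
  item_cols <- grep("^item_\\d+$", names(df), value = TRUE)
  item_cols <- item_cols[order(as.integer(sub("item_", "", item_cols)))]
  for (cc in item_cols) df[[cc]] <- suppressWarnings(as.integer(df[[cc]]))
  rownames(df) <- NULL
  df[, c(need, item_cols), drop = FALSE]
}

#' Collapse duplicate consecutive same-state screen events
#'
#' Downstream interval logic requires ON/OFF alternation; repeated same-state
#' events (e.g. duplicated log uploads) are collapsed to the first occurrence.
#'
#' @param screen data.frame of screen events sorted by timestamp.
#' @return the deduplicated data.frame.
#' @export
dedupScreenEvents <- function(screen) {
  if (nrow(screen) <= 1L) return(screen)
  keep <- c(TRUE, screen$state[-1L] != screen$state[-nrow(screen)])
  out <- screen[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a participant's sensor bundle
#'
#' Combines parsed streams into a single validated `sensor_bundle`: checks
#' that all streams carry one participant id, drops (and counts) records
#' outside the collection window, and collapses duplicate same-state screen
#' events.
#'
#' @param tables named list with any of `screen`, `gps`, `activity`, `face`
#'   (record data.frames from [readSensorTable()]) and `questionnaires`
#'   (from [readQuestionnaireTable()]). Absent streams are treated as empty.
#' @param window length-2 POSIXct (UTC) or ISO-8601 character: collection
#'   window start and end.
#' @param diagnosis optional `"DEPRESSIVE"` / `"NON_DEPRESSIVE"` clinician
#'   label.
#' @param participant_id optional; inferred from the records when omitted.
#' @return an object of class `sensor_bundle`: a list with the streams, the
#'   window, the diagnosis, per-stream dropped-record counts (`drop_log`) and
#'   degenerate-stream flags (`flags`, e.g. `"sleep features unavailable"`
#'   when the screen stream is empty).
#' @export
assembleBundle <- function(tables, window, diagnosis = NULL,
                           participant_id = NULL) {
  if (is.character(window)) {
    pw <- parseTimestamp(window)
    if (any(is.na(pw$utc))) stop("assembleBundle: unparseable window",
                                 call. = FALSE)
    window_off <- pw$offset_min[1L]
    window <- pw$utc
  } else {
    window_off <- attr(window, "offset_min") %||% 0L
  }
  stopifnot(length(window) == 2L, window[1L] <= window[2L])
  streams <- list(
    screen = tables$screen %||% emptyRecords("SCREEN_ONOFF"),
    gps = tables$gps %||% emptyRecords("LOCATIONS"),
    activity = tables$activity %||% emptyRecords("ACTIVITY_TRANSITION"),
    face = tables$face %||% emptyRecords("FACE_LANDMARK"))
  ids <- unique(unlist(c(lapply(streams, function(s) s$participant_id),
                         list(tables$questionnaires$participant_id))))
  ids <- ids[!is.na(ids)]
  if (length(ids) > 1L) {
    stop("assembleBundle: mixed participant ids: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  if (is.null(participant_id)) {
    if (length(ids) == 0L) stop("assembleBundle: no participant id",
                                call. = FALSE)
    participant_id <- ids
  } else if (length(ids) == 1L && ids != participant_id) {
    stop("assembleBundle: records belong to a different participant",
         call. = FALSE)
  }
  drop_log <- list()
  for (nm in names(streams)) {
    s <- streams[[nm]]
    inside <- s$timestamp >= window[1L] & s$timestamp <= window[2L]
    drop_log[[nm]] <- sum(!inside)
    streams[[nm]] <- s[inside, , drop = FALSE]
    rownames(streams[[nm]]) <- NULL
  }
  streams$screen <- dedupScreenEvents(streams$screen)
  flags <- character(0)
  if (nrow(streams$screen) == 0L) flags <- c(flags, "sleep features unavailable")
  if (nrow(streams$gps) == 0L) flags <- c(flags, "mobility features unavailable")
  if (nrow(streams$activity) == 0L) flags <- c(flags, "activity feature unavailable")
  if (nrow(streams$face) == 0L) flags <- c(flags, "expression features unavailable")
  q <- tables$questionnaires
  if (is.null(q)) {
    q <- data.frame(participant_id = character(0), instrument = character(0),
                    wave = character(0), stringsAsFactors = FALSE)
  }
  structure(list(participant_id = participant_id,
                 window = window, window_offset_min = window_off,
                 screen = streams$screen, gps = streams$gps,
                 activity = streams$activity, face = streams$face,
                 questionnaires = q, diagnosis = diagnosis,
                 drop_log = drop_log, flags = flags),
            class = "sensor_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sensor_bundle <- function(x, ...) {
  cat("<sensor_bundle> participant", x$participant_id, "\n")
  cat("  window:", formatTimestamp(x$window[1L], x$window_offset_min), "to",
      formatTimestamp(x$window[2L], x$window_offset_min), "\n")
  cat(sprintf("  screen: %d  gps: %d  activity: %d  face: %d  questionnaire rows: %d\n",
              nrow(x$screen), nrow(x$gps), nrow(x$activity), nrow(x$face),
              nrow(x$questionnaires)))
  if (!is.null(x$diagnosis)) cat("  diagnosis:", x$diagnosis, "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Participant-exclusion policy
#'
#' The study protocol drops participants who did not answer every
#' questionnaire wave or whose feature-required sensor streams are largely
#' missing. The thresholds are parameterized.
#'
#' @param required_instruments instruments that must be present at every
#'   required wave (default PHQ-9 and CESD-R).
#' @param required_waves waves each required instrument must cover (default
#'   baseline, middle and final: M1, M2, M3).
#' @param min_screen_day_fraction minimum fraction of window days with at
#'   least one screen event (default 0.5).
#' @param min_face_records minimum number of expression-embedding records
#'   (default 1).
#' @return an `exclusion_policy` list.
#' @export
exclusionPolicy <- function(required_instruments = c("PHQ9", "CESDR"),
                            required_waves = c("M1", "M2", "M3"),
                            min_screen_day_fraction = 0.5,
                            min_face_records = 1L) {
  structure(list(required_instruments = required_instruments,
                 required_waves = required_waves,
                 min_screen_day_fraction = min_screen_day_fraction,
                 min_face_records = min_face_records),
            class = "exclusion_policy")
}

windowDays <- function(bundle) {
  d1 <- localDate(bundle$window[1L], bundle$window_offset_min)
  d2 <- localDate(bundle$window[2L], bundle$window_offset_min)
  as.integer(d2 - d1) + 1L
}

#' Apply participant-exclusion rules
#'
#' A bundle is excluded when (a) any required questionnaire wave is missing,
#' or (b) a feature-required stream has coverage below the policy threshold.
#' Every exclusion reason is recorded, so retained + excluded = input.
#'
#' @param bundles list of `sensor_bundle`.
#' @param policy an [exclusionPolicy()].
#' @return list with `retained` (bundles passing all rules) and `report`
#'   (data.frame: participant_id, excluded, reasons).
#' @export
applyExclusionRules <- function(bundles, policy = exclusionPolicy()) {
  stopifnot(inherits(policy, "exclusion_policy"))
  rows <- lapply(bundles, function(b) {
    reasons <- character(0)
    q <- b$questionnaires
    for (ins in policy$required_instruments) {
      have <- unique(q$wave[q$instrument == ins])
      if (!all(policy$required_waves %in% have)) {
        reasons <- c(reasons, "questionnaire incomplete")
        break
      }
    }
    n_days <- windowDays(b)
    screen_days <- length(unique(localDate(b$screen$timestamp,
                                           b$screen$offset_min)))
    if (nrow(b$screen) == 0L ||
        screen_days / n_days < policy$min_screen_day_fraction) {
      reasons <- c(reasons, "sensor missing: screen")
    }
    if (nrow(b$face) < policy$min_face_records) {
      reasons <- c(reasons, "sensor missing: face embedding")
    }
    data.frame(participant_id = b$participant_id,
               excluded = length(reasons) > 0L,
               reasons = paste(reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant_id = character(0), excluded = logical(0),
               reasons = character(0), stringsAsFactors = FALSE)
  list(retained = bundles[!report$excluded], report = report)
}

#' Write a bundle back to collection-schema CSVs
#'
#' Inverse of [readParticipantDir()]: field-for-field round-trip of the
#' streams and questionnaires.
#'
#' @param bundle a `sensor_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, extra, file) {
    out <- data.frame(participant_id = df$participant_id,
                      timestamp = formatTimestamp(df$timestamp, df$offset_min),
                      stringsAsFactors = FALSE)
    for (cc in extra) out[[cc]] <- df[[cc]]
    write.csv(out, file.path(dir, file), row.names = FALSE)
  }
  wr(bundle$screen, "state", "SCREEN_ONOFF.csv")
  wr(bundle$gps, c("latitude", "longitude"), "LOCATIONS.csv")
  wr(bundle$activity, c("activity_class", "transition"),
     "ACTIVITY_TRANSITION.csv")
  wr(bundle$face, EXPR_COLS, "FACE_LANDMARK.csv")
  write.csv(bundle$questionnaires, file.path(dir, "QUESTIONNAIRES.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read one participant directory into a bundle
#'
#' @param dir directory containing the collection-schema CSVs.
#' @param window length-2 ISO-8601 character or POSIXct collection window.
#' @param diagnosis optional clinician label.
#' @return a `sensor_bundle`.
#' @export
readParticipantDir <- function(dir, window, diagnosis = NULL) {
  rd <- function(file, table) {
    p <- file.path(dir, file)
    if (file.exists(p)) readSensorTable(p, table)$records else NULL
  }
  qpath <- file.path(dir, "QUESTIONNAIRES.csv")
  assembleBundle(
    tables = list(screen = rd("SCREEN_ONOFF.csv", "SCREEN_ONOFF"),
                  gps = rd("LOCATIONS.csv", "LOCATIONS"),
                  activity = rd("ACTIVITY_TRANSITION.csv", "ACTIVITY_TRANSITION"),
                  face = rd("FACE_LANDMARK.csv", "FACE_LANDMARK"),
                  questionnaires = if (file.exists(qpath))
                    readQuestionnaireTable(qpath) else NULL),
    window = window, diagnosis = diagnosis)
}

#' Read a cohort directory
#'
#' Expects `manifest.csv` with columns `participant_id`, `window_start`,
#' `window_end` and optionally `diagnosis`, plus one subdirectory per
#' participant named by its id.
#'
#' @param dir cohort directory.
#' @return list of `sensor_bundle`.
#' @export
readCohort <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("readCohort: no manifest.csv in ", dir,
                             call. = FALSE)
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    diag <- manifest$diagnosis[i]
    if (is.null(diag) || is.na(diag) || !nzchar(diag)) diag <- NULL
    readParticipantDir(file.path(dir, manifest$participant_id[i]),
                       window = c(manifest$window_start[i],
                                  manifest$window_end[i]),
                       diagnosis = diag)
  })
}
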