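# Timestamp handling.
#
# All timestamps are ISO-8601 strings with an explicit UTC offset
# ("2021-08-19T23:10:00+09:00"). Internally every record stores the instant
# as POSIXct in UTC plus the participant's local offset in minutes, because
# the sleep rules (noon-to-noon day windows, the 12:00-18:00 afternoon
# exclusion) are defined on the local clock while interval arithmetic is done
# on the absolute timeline.

#' Parse ISO-8601 timestamps with offset
#'
#' @param x character vector like `"2021-08-19T23:10:00+09:00"`. `"Z"` and
#'   offsets without a colon are accepted; a space may replace the `"T"`.
#' @return list with `utc` (POSIXct, UTC) and `offset_min` (integer minutes);
#'   unparseable entries are `NA` in both.
#' @keywords internal
parseTimestamp <- function(x) {
  x <- as.character(x)
  x <- sub("Z$", "+00:00", x)
  x <- sub(" ", "T", x, fixed = TRUE)
  m <- regmatches(x, regexec(
    "^(\\d{4}-\\d{2}-\\d{2})T(\\d{2}:\\d{2}:\\d{2}(?:\\.\\d+)?)([+-])(\\d{2}):?(\\d{2})$",
    x))
  utc <- rep(as.POSIXct(NA_character_, tz = "UTC"), length(x))
  off <- rep(NA_integer_, length(x))
  ok <- lengths(m) == 6L
  if (any(ok)) {
    parts <- do.call(rbind, m[ok])
    sgn <- ifelse(parts[, 4L] == "-", -1L, 1L)
    off_ok <- sgn * (as.integer(parts[, 5L]) * 60L + as.integer(parts[, 6L]))
    naive <- as.POSIXct(paste(parts[, 2L], parts[, 3L]),
                        format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
    utc[ok] <- naive - off_ok * 60
    off[ok] <- off_ok
    # reject nonsense like month 13 that format-parsing returns NA for
    off[ok][is.na(naive)] <- NA_integer_
  }
  list(utc = utc, offset_min = off)
}

#' Format UTC instants back to ISO-8601 with offset
#' @param utc POSIXct in UTC
#' @param offset_min integer minutes east of UTC
#' @return character vector
#' @keywords internal
formatTimestamp <- function(utc, offset_min) {
  local <- utc + offset_min * 60
  sgn <- ifelse(offset_min < 0, "-", "+")
  a <- abs(offset_min)
  out <- format(local, "%Y-%m-%dT%H:%M:%OS6", tz = "UTC")
  out <- sub("\\.?0+$", "", out)  # trim trailing zero fractions
  sprintf("%s%s%02d:%02d", out, sgn, a %/% 60L, a %% 60L)
}

# Local clock-time views of a UTC instant.
localTime <- function(utc, offset_min) utc + offset_min * 60

localDate <- function(utc, offset_min) {
  as.Date(format(localTime(utc, offset_min), "%Y-%m-%d", tz = "UTC"))
}

# Hours (fractional) since local midnight.
localHour <- function(utc, offset_min) {
  lt <- localTime(utc, offset_min)
  as.numeric(difftime(lt, trunc(lt, "days"), units = "hours"))
}

hoursBetween <- function(a, b) as.numeric(difftime(b, a, units = "hours"))

# Build a UTC instant from a local date, fractional local hour and offset.
utcFromLocal <- function(date, hour, offset_min) {
  as.POSIXct(as.numeric(as.POSIXct(paste(date, "00:00:00"), tz = "UTC")) +
               hour * 3600 - offset_min * 60,
             origin = "1970-01-01", tz = "UTC")
}
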