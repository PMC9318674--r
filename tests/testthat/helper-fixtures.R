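# In-code fixture builders shared across test files.

TZ9 <- 540L  # UTC+9, the cohort's local offset

utc9 <- function(...) {
  # local KST clock times -> UTC instants
  as.POSIXct(c(...), tz = "UTC") - TZ9 * 60
}

mkScreen <- function(times_local, states, id = "p1") {
  data.frame(participant_id = id, timestamp = utc9(times_local),
             offset_min = TZ9, state = states, stringsAsFactors = FALSE)
}

mkActivity <- function(times_local, classes, transitions, id = "p1") {
  data.frame(participant_id = id, timestamp = utc9(times_local),
             offset_min = TZ9, activity_class = classes,
             transition = transitions, stringsAsFactors = FALSE)
}

mkGps <- function(lat, lon, id = "p1", t0 = "2021-08-19 08:00:00") {
  data.frame(participant_id = id,
             timestamp = utc9(t0) + seq_along(lat) * 60,
             offset_min = TZ9, latitude = lat, longitude = lon,
             stringsAsFactors = FALSE)
}

mkFace <- function(embeddings, id = "p1") {
  # embeddings: matrix, one row per record
  out <- data.frame(participant_id = id,
                    timestamp = utc9("2021-08-19 10:00:00") +
                      seq_len(nrow(embeddings)) * 86400,
                    offset_min = TZ9, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(embeddings))) {
    out[[sprintf("expr_%02d", j)]] <- embeddings[, j]
  }
  out
}

mkQuestionnaires <- function(id = "p1", waves = c("M1", "M2", "M3"),
                             phq9_items = rep(1L, 9),
                             cesdr_items = rep(1L, 20)) {
  rows <- lapply(waves, function(w) {
    r1 <- data.frame(participant_id = id, instrument = "PHQ9", wave = w,
                     stringsAsFactors = FALSE)
    r2 <- data.frame(participant_id = id, instrument = "CESDR", wave = w,
                     stringsAsFactors = FALSE)
    for (i in 1:20) {
      r1[[sprintf("item_%d", i)]] <- if (i <= 9) phq9_items[i] else NA_integer_
      r2[[sprintf("item_%d", i)]] <- cesdr_items[i]
    }
    rbind(r1, r2)
  })
  do.call(rbind, rows)
}

# A complete, valid single-participant bundle over a two-day window.
mkBundle <- function(id = "p1", diagnosis = "DEPRESSIVE") {
  screen <- mkScreen(
    c("2021-08-19 07:00:00", "2021-08-19 09:00:00",
      "2021-08-19 13:00:00", "2021-08-19 15:00:00",
      "2021-08-19 19:00:00", "2021-08-19 23:00:00",
      "2021-08-20 07:00:00", "2021-08-20 09:00:00"),
    rep(c("ON", "OFF"), 4), id = id)
  gps <- mkGps(lat = rep(c(37.5, 37.55), each = 6),
               lon = rep(c(127.0, 127.05), each = 6), id = id)
  act <- mkActivity(c("2021-08-19 09:30:00", "2021-08-19 10:30:00"),
                    "WALKING", c("ENTER", "EXIT"), id = id)
  face <- mkFace(matrix(rnorm(32), nrow = 2), id = id)
  assembleBundle(
    list(screen = screen, gps = gps, activity = act, face = face,
         questionnaires = mkQuestionnaires(id = id)),
    window = c("2021-08-19T00:00:00+09:00", "2021-08-21T00:00:00+09:00"),
    diagnosis = diagnosis)
}

# Small balanced cohort spec for pipeline tests (no single-class risk).
smallSpec <- function(n = 20L, days = 7L, seed = 1L) {
  cohortSpec(n_participants = n, depressed_fraction = 0.5, days = days,
             seed = seed)
}
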