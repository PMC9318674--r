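# PHQ-9 / CESD-R scoring, severity bands and cut-point labels.
#
# PHQ-9: nine items scored 0-3, total 0-27; a total of 10 or more defines the
# depressed-mood label. CESD-R: twenty items scored 0-3 here (total 0-60); a
# total of 13 or more (Korean calibration) defines the depressed-mood label.
# ISI, PHQ-2 and TAM are stored but never scored.

instrumentSpec <- function(instrument) {
  switch(instrument,
    PHQ9 = list(n_items = 9L, item_range = c(0L, 3L), total_range = c(0L, 27L)),
    CESDR = list(n_items = 20L, item_range = c(0L, 3L), total_range = c(0L, 60L)),
    NULL)
}

#' Score a questionnaire record
#'
#' Validates the item count and per-item range for the instrument, then
#' returns the total (sum of item scores). Only PHQ-9 and CESD-R have scoring
#' semantics; other instruments are pass-through storage.
#'
#' @param instrument `"PHQ9"` or `"CESDR"`.
#' @param items integer vector of item scores.
#' @return integer total.
#' @examples
#' scoreInstrument("PHQ9", rep(3L, 9))   # 27
#' scoreInstrument("CESDR", rep(3L, 20)) # 60
#' @export
scoreInstrument <- function(instrument, items) {
  spec <- instrumentSpec(toupper(instrument))
  if (is.null(spec)) {
    stop("scoreInstrument: no scoring semantics for instrument '",
         instrument, "'", call. = FALSE)
  }
  items <- as.integer(items)
  if (length(items) != spec$n_items) {
    stop(sprintf("scoreInstrument: %s expects %d items, got %d",
                 instrument, spec$n_items, length(items)), call. = FALSE)
  }
  bad <- which(is.na(items) | items < spec$item_range[1L] |
                 items > spec$item_range[2L])
  if (length(bad)) {
    stop(sprintf("scoreInstrument: item %d out of range [%d, %d]",
                 bad[1L], spec$item_range[1L], spec$item_range[2L]),
         call. = FALSE)
  }
  sum(items)
}

checkTotal <- function(total, instrument) {
  spec <- instrumentSpec(instrument)
  if (is.na(total) || total < spec$total_range[1L] ||
      total > spec$total_range[2L]) {
    stop(sprintf("%s total %s outside [%d, %d]", instrument,
                 format(total), spec$total_range[1L], spec$total_range[2L]),
         call. = FALSE)
  }
  invisible(as.numeric(total))
}

#' Depressed-mood label from a PHQ-9 total
#'
#' @param total integer in \[0, 27\].
#' @param cutpoint label threshold; `DEPRESSED` iff `total >= cutpoint`
#'   (default 10).
#' @return `"DEPRESSED"` or `"NON_DEPRESSED"` (vectorized).
#' @export
phq9Label <- function(total, cutpoint = 10L) {
  vapply(total, checkTotal, numeric(1), instrument = "PHQ9")
  ifelse(total >= cutpoint, "DEPRESSED", "NON_DEPRESSED")
}

#' Depressed-mood label from a CESD-R total
#'
#' @param total integer in \[0, 60\].
#' @param cutpoint label threshold; `DEPRESSED` iff `total >= cutpoint`
#'   (default 13, the Korean calibration).
#' @return `"DEPRESSED"` or `"NON_DEPRESSED"` (vectorized).
#' @export
cesdrLabel <- function(total, cutpoint = 13L) {
  vapply(total, checkTotal, numeric(1), instrument = "CESDR")
  ifelse(total >= cutpoint, "DEPRESSED", "NON_DEPRESSED")
}

#' PHQ-9 severity band
#'
#' Default five-band scheme: normal (0-4), minimum (5-9), mild (10-14),
#' moderate (15-19), severe (20-27). A six-band variant splits the bands as
#' severe (20-27), moderately severe (15-19), moderate (10-14) and divides
#' 0-9 into minimal and normal at `minor_edge`.
#'
#' @param total integer in \[0, 27\] (vectorized).
#' @param scheme `"five"` (default) or `"six"`.
#' @param minor_edge six-band scheme only: totals `>= minor_edge` but `< 10`
#'   are `"minor"`, totals below it but `>= 5` are `"minimal"` (default 8).
#' @return character band labels.
#' @export
phq9SeverityBand <- function(total, scheme = c("five", "six"),
                             minor_edge = 8L) {
  scheme <- match.arg(scheme)
  vapply(total, checkTotal, numeric(1), instrument = "PHQ9")
  if (scheme == "five") {
    cut(total, breaks = c(-1, 4, 9, 14, 19, 27),
        labels = c("normal", "minimum", "mild", "moderate", "severe")) |>
      as.character()
  } else {
    cut(total, breaks = c(-1, 4, minor_edge - 1L, 9, 14, 19, 27),
        labels = c("normal", "minimal", "minor", "moderate",
                   "moderately severe", "severe")) |>
      as.character()
  }
}

#' Label a cohort of bundles from questionnaire totals
#'
#' Scores the configured wave's PHQ-9 and CESD-R responses for each bundle and
#' derives the binary depressed-mood labels and the PHQ-9 severity band.
#'
#' @param bundles list of `sensor_bundle`.
#' @param label_wave which administration defines the participant's label
#'   (default `"M1"`, the baseline).
#' @param phq9_cutpoint,cesdr_cutpoint label thresholds (defaults 10 and 13).
#' @return data.frame: participant_id, phq9_total, cesdr_total, phq9_label,
#'   cesdr_label, phq9_severity, diagnosis (NA when not provided).
#' @export
labelCohort <- function(bundles, label_wave = "M1", phq9_cutpoint = 10L,
                        cesdr_cutpoint = 13L) {
  rows <- lapply(bundles, function(b) {
    q <- b$questionnaires
    one <- function(ins) {
      r <- q[q$instrument == ins & q$wave == label_wave, , drop = FALSE]
      if (nrow(r) == 0L) return(NA_integer_)
      spec <- instrumentSpec(ins)
      items <- as.integer(r[1L, sprintf("item_%d", seq_len(spec$n_items))])
      scoreInstrument(ins, items)
    }
    phq9 <- one("PHQ9"); cesdr <- one("CESDR")
    data.frame(
      participant_id = b$participant_id,
      phq9_total = phq9, cesdr_total = cesdr,
      phq9_label = if (is.na(phq9)) NA_character_ else
        phq9Label(phq9, phq9_cutpoint),
      cesdr_label = if (is.na(cesdr)) NA_character_ else
        cesdrLabel(cesdr, cesdr_cutpoint),
      phq9_severity = if (is.na(phq9)) NA_character_ else
        phq9SeverityBand(phq9),
      diagnosis = b$diagnosis %||% NA_character_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
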