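# Synthetic participant cohorts with a latent depressed / non-depressed state.
#
# Clinical smartphone-sensing data are rarely shareable, so every pipeline
# stage is validated against generated cohorts: per-day screen sessions with a
# controlled nocturnal off interval (so the sleep proxy round-trips), GPS
# fixes hopping between well-separated places with a known visit distribution
# (so entropy has an analytic target), alternating activity episodes with a
# known daily total, weekly expression embeddings around a group mean, and
# questionnaire totals drawn around group means. Ground truth records the
# realized (post-clipping) values, so recovery checks compare like with like.

# Clipped-normal draw; sd = 0 gives the (clamped) mean exactly.
rclip <- function(n, mean, sd, lo, hi) {
  x <- if (sd == 0) rep(mean, n) else rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

subSeed <- function(root, participant, stream) {
  as.integer((as.numeric(root) * 48271 + participant * 2017 +
                stream * 7919) %% 2147483629 + 1)
}

withSeed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Generative parameters for one latent group
#'
#' @param sleep_mean,sleep_sd nightly sleep hours (clipped to \[5.5, 10.5\]).
#' @param usage_mean,usage_sd daily screen-on hours.
#' @param visit_probs visit-probability vector over significant places; its
#'   Shannon entropy is the analytic location-entropy target.
#' @param activity_mean,activity_sd daily physical-activity hours across the
#'   included classes (clipped to \[0.25, 10.5\]).
#' @param expression_mean length-16 embedding group mean.
#' @param expression_sd per-coordinate embedding noise SD.
#' @param phq9_mean,phq9_sd,cesdr_mean,cesdr_sd questionnaire total
#'   distributions (rounded, clamped to the instrument range).
#' @return a `group_params` list.
#' @export
groupParams <- function(sleep_mean, sleep_sd, usage_mean, usage_sd,
                        visit_probs, activity_mean, activity_sd,
                        expression_mean, expression_sd,
                        phq9_mean, phq9_sd, cesdr_mean, cesdr_sd) {
  stopifnot(abs(sum(visit_probs) - 1) < 1e-8, all(visit_probs >= 0),
            length(expression_mean) == EMBEDDING_DIM,
            sleep_sd >= 0, usage_sd >= 0, activity_sd >= 0,
            expression_sd >= 0, phq9_sd >= 0, cesdr_sd >= 0)
  structure(as.list(environment()), class = "group_params")
}

defaultDepressedParams <- function() {
  groupParams(sleep_mean = 9.5, sleep_sd = 0.75,
              usage_mean = 6, usage_sd = 1,
              visit_probs = c(0.9, 0.1),
              activity_mean = 9, activity_sd = 1,
              expression_mean = rep(0.5, EMBEDDING_DIM), expression_sd = 0.5,
              phq9_mean = 16, phq9_sd = 3, cesdr_mean = 28, cesdr_sd = 6)
}

defaultNonDepressedParams <- function() {
  groupParams(sleep_mean = 7, sleep_sd = 0.75,
              usage_mean = 3, usage_sd = 0.75,
              visit_probs = rep(0.25, 4),
              activity_mean = 5.5, activity_sd = 1,
              expression_mean = rep(0, EMBEDDING_DIM), expression_sd = 0.5,
              phq9_mean = 4, phq9_sd = 2.5, cesdr_mean = 5, cesdr_sd = 3)
}

#' Cohort-generation specification
#'
#' The default scenario mirrors the study shape: 106 participants observed
#' for 28 days with a CESD-R-like 84:22 depressed/non-depressed imbalance and
#' well-separated group parameters (depressed participants sleep longer, use
#' the phone more, are more homebound, log more stationary-inclusive activity
#' time, and have shifted expression embeddings and questionnaire totals).
#'
#' @param n_participants cohort size (default 106).
#' @param depressed_fraction latent depressed fraction (default 84/106).
#' @param days collection days (default 28, a four-week study).
#' @param seed root seed; all randomness flows from it through named
#'   per-participant per-stream sub-streams.
#' @param depressed,non_depressed [groupParams()] for the two latent groups.
#' @param fixes_per_day GPS sampling density (default 12, i.e. a
#'   battery-friendly duty-cycled fix roughly every waking hour).
#' @param tz_offset_min participants' local UTC offset in minutes
#'   (default 540, UTC+9).
#' @param start_date first collection day.
#' @return a `cohort_spec` list.
#' @export
cohortSpec <- function(n_participants = 106L, depressed_fraction = 84 / 106,
                       days = 28L, seed = 1L,
                       depressed = defaultDepressedParams(),
                       non_depressed = defaultNonDepressedParams(),
                       fixes_per_day = 12L, tz_offset_min = 540L,
                       start_date = as.Date("2021-08-19")) {
  stopifnot(n_participants >= 0L, days >= 1L,
            depressed_fraction >= 0, depressed_fraction <= 1,
            inherits(depressed, "group_params"),
            inherits(non_depressed, "group_params"))
  structure(list(n_participants = as.integer(n_participants),
                 depressed_fraction = depressed_fraction,
                 days = as.integer(days), seed = as.integer(seed),
                 depressed = depressed, non_depressed = non_depressed,
                 fixes_per_day = as.integer(fixes_per_day),
                 tz_offset_min = as.integer(tz_offset_min),
                 start_date = start_date),
            class = "cohort_spec")
}

#' No-signal control specification
#'
#' Both latent groups share identical sensor and expression parameters and a
#' questionnaire distribution that straddles the cut-points (PHQ-9 totals
#' around 9.5 with SD 6), so labels are unrelated to features: a classifier
#' should do no better than the class prior.
#'
#' @param n_participants,days,seed as in [cohortSpec()].
#' @return a `cohort_spec`.
#' @export
nullCohortSpec <- function(n_participants = 106L, days = 28L, seed = 1L) {
  shared <- defaultNonDepressedParams()
  shared$phq9_mean <- 9.5; shared$phq9_sd <- 6
  shared$cesdr_mean <- 12.5; shared$cesdr_sd <- 8
  cohortSpec(n_participants = n_participants, depressed_fraction = 0.5,
             days = days, seed = seed,
             depressed = shared, non_depressed = shared)
}

#' Generate a screen on/off stream
#'
#' Each day holds five on-sessions between wake and bedtime realizing the
#' day's usage draw; bedtime is placed so that the nocturnal off interval
#' (bed to next morning's wake) equals the night's sleep draw exactly, and an
#' opening off event the evening before day 1 makes the first night
#' recoverable too. The emitted collection window runs from that first off
#' event to the final bedtime.
#'
#' @param params [groupParams()].
#' @param days number of days.
#' @param start_date first day.
#' @param tz_offset_min local offset (minutes).
#' @return list: `events` (screen records), `window` (POSIXct length 2),
#'   `sleep_hours` (realized nightly sleep, one per day),
#'   `usage_hours` (realized daily usage, one per day).
#' @export
generateScreenStream <- function(params, days, start_date = as.Date("2021-08-19"),
                                 tz_offset_min = 540L) {
  wake_jit <- rclip(days + 1L, 0, if (params$sleep_sd == 0) 0 else 0.2,
                    -0.6, 0.6)
  wake <- utcFromLocal(start_date + 0:days, 7 + wake_jit, tz_offset_min)
  # wake[d] is the morning of day d; the virtual wake[days+1] fixes the final
  # bedtime. Night d ends at wake[d] and starts at off_start[d] =
  # wake[d] - sleep[d]; sessions of day d run in [wake[d], off_start[d+1]].
  sleep <- rclip(days, params$sleep_mean, params$sleep_sd, 5.5, 10.5)
  off_start <- wake[seq_len(days)] - sleep * 3600
  final_bed <- wake[days + 1L] -
    rclip(1L, params$sleep_mean, params$sleep_sd, 5.5, 10.5) * 3600
  sess_end_of_day <- c(off_start[-1L], final_bed)
  usage <- numeric(days)
  ev_t <- list(); ev_s <- list()
  ev_t[[1L]] <- off_start[1L]; ev_s[[1L]] <- "OFF"
  for (d in seq_len(days)) {
    frame <- hoursBetween(wake[d], sess_end_of_day[d])
    u <- rclip(1L, params$usage_mean, params$usage_sd, 0.25, 0.8 * frame)
    usage[d] <- u
    m <- 5L
    gap <- (frame - u) / (m - 1L)
    starts <- wake[d] + (seq_len(m) - 1L) * (u / m + gap) * 3600
    ends <- starts + (u / m) * 3600
    ev_t[[length(ev_t) + 1L]] <- as.vector(rbind(starts, ends))
    ev_s[[length(ev_s) + 1L]] <- rep(c("ON", "OFF"), m)
  }
  tvec <- as.POSIXct(unlist(ev_t), origin = "1970-01-01", tz = "UTC")
  events <- data.frame(participant_id = NA_character_, timestamp = tvec,
                       offset_min = as.integer(tz_offset_min),
                       state = unlist(ev_s), stringsAsFactors = FALSE)
  list(events = events,
       window = structure(c(off_start[1L], final_bed),
                          offset_min = as.integer(tz_offset_min)),
       sleep_hours = sleep, usage_hours = usage)
}

#' Generate a GPS trace over significant places
#'
#' Place centers lie kilometres apart (far beyond the clustering radius);
#' each fix is assigned a place by the visit-probability vector and jittered
#' by ~20 m, so the density clustering recovers places exactly and the
#' realized entropy equals the entropy of the realized visit counts.
#'
#' @param params [groupParams()].
#' @param days,fixes_per_day sampling scheme (fixes between 08:00 and 19:30
#'   local).
#' @param start_date,tz_offset_min as elsewhere.
#' @return list: `fixes` (GPS records), `entropy` (realized, nats).
#' @export
generateGpsTrace <- function(params, days, fixes_per_day = 12L,
                             start_date = as.Date("2021-08-19"),
                             tz_offset_min = 540L) {
  k <- length(params$visit_probs)
  centers_lat <- 37.5 + 0.05 * (seq_len(k) - 1L)
  centers_lon <- 127.0 + 0.03 * (seq_len(k) - 1L)
  n <- days * fixes_per_day
  place <- sample.int(k, n, replace = TRUE, prob = params$visit_probs)
  hours <- rep(seq(8, 19.5, length.out = fixes_per_day), days) +
    runif(n, 0, 0.02)
  dates <- rep(start_date + (seq_len(days) - 1L), each = fixes_per_day)
  jitter_deg <- 20 / 111320
  fixes <- data.frame(
    participant_id = NA_character_,
    timestamp = utcFromLocal(dates, hours, tz_offset_min),
    offset_min = as.integer(tz_offset_min),
    latitude = centers_lat[place] + rnorm(n, 0, jitter_deg),
    longitude = centers_lon[place] + rnorm(n, 0, jitter_deg),
    stringsAsFactors = FALSE)
  counts <- tabulate(place, nbins = k)
  p <- counts[counts > 0] / n
  list(fixes = fixes, entropy = if (length(p) <= 1L) 0 else -sum(p * log(p)))
}

#' Generate an activity-transition log
#'
#' Per day: one episode each of stationary, walking and running realizing the
#' day's physical-activity draw (70/25/5 split), plus a cycling episode that
#' must not count towards the feature.
#'
#' @param params [groupParams()].
#' @param days,start_date,tz_offset_min as elsewhere.
#' @return list: `events` (activity records), `activity_hours` (realized
#'   daily included-class totals).
#' @export
generateActivityLog <- function(params, days,
                                start_date = as.Date("2021-08-19"),
                                tz_offset_min = 540L) {
  totals <- rclip(days, params$activity_mean, params$activity_sd, 0.25, 10.5)
  shares <- c(CYCLING = NA, STATIONARY = 0.7, WALKING = 0.25, RUNNING = 0.05)
  # durations matrix: rows = episodes in daily order, cols = days
  dur <- rbind(CYCLING = rep(0.3, days),
               outer(shares[-1L], totals))
  starts <- apply(rbind(7.6, dur[-nrow(dur), , drop = FALSE] + 0.2), 2L,
                  cumsum)
  classes <- rownames(dur)
  n_ep <- length(classes)
  date_vec <- rep(start_date + (seq_len(days) - 1L), each = 2L * n_ep)
  hour_vec <- as.vector(rbind(as.vector(starts), as.vector(starts + dur)))
  events <- data.frame(
    participant_id = NA_character_,
    timestamp = utcFromLocal(date_vec, hour_vec, tz_offset_min),
    offset_min = as.integer(tz_offset_min),
    activity_class = rep(rep(classes, each = 2L), days),
    transition = rep(c("ENTER", "EXIT"), n_ep * days),
    stringsAsFactors = FALSE)
  list(events = events, activity_hours = totals)
}

itemVectorFromTotal <- function(total, n_items, item_max = 3L) {
  items <- integer(n_items)
  total <- min(total, n_items * item_max)
  while (total > 0L) {
    open <- which(items < item_max)
    i <- open[sample.int(length(open), 1L)]
    items[i] <- items[i] + 1L
    total <- total - 1L
  }
  items
}

#' Generate expression embeddings and questionnaire responses
#'
#' Weekly 16-dimensional embeddings around the group mean, and PHQ-9 /
#' CESD-R / ISI item responses at waves M1, M2, M3 whose PHQ-9 and CESD-R
#' totals follow the group's total distribution (items individually in
#' range).
#'
#' @param params [groupParams()].
#' @param days,start_date,tz_offset_min as elsewhere.
#' @return list: `face` (embedding records), `questionnaires` (item table),
#'   `phq9_total`, `cesdr_total` (the M1 baseline totals).
#' @export
generateExpressionAndQuestionnaires <- function(params, days,
                                                start_date = as.Date("2021-08-19"),
                                                tz_offset_min = 540L) {
  capture_days <- seq(1L, days, by = 7L)
  emb <- t(vapply(capture_days, function(d)
    params$expression_mean + rnorm(EMBEDDING_DIM, 0, params$expression_sd),
    numeric(EMBEDDING_DIM)))
  face <- data.frame(participant_id = NA_character_,
                     timestamp = utcFromLocal(start_date + capture_days - 1L,
                                              10, tz_offset_min),
                     offset_min = as.integer(tz_offset_min),
                     stringsAsFactors = FALSE)
  for (j in seq_len(EMBEDDING_DIM)) face[[EXPR_COLS[j]]] <- emb[, j]

  waves <- c("M1", "M2", "M3")
  qrows <- list()
  totals <- list(PHQ9 = integer(3), CESDR = integer(3))
  for (w in seq_along(waves)) {
    phq <- as.integer(round(rclip(1L, params$phq9_mean, params$phq9_sd, 0, 27)))
    ces <- as.integer(round(rclip(1L, params$cesdr_mean, params$cesdr_sd, 0, 60)))
    totals$PHQ9[w] <- phq; totals$CESDR[w] <- ces
    mk <- function(ins, items, n_all = 20L) {
      row <- data.frame(participant_id = NA_character_, instrument = ins,
                        wave = waves[w], stringsAsFactors = FALSE)
      for (i in seq_len(n_all)) {
        row[[sprintf("item_%d", i)]] <-
          if (i <= length(items)) items[i] else NA_integer_
      }
      row
    }
    qrows[[length(qrows) + 1L]] <- mk("PHQ9", itemVectorFromTotal(phq, 9L))
    qrows[[length(qrows) + 1L]] <- mk("CESDR", itemVectorFromTotal(ces, 20L))
    qrows[[length(qrows) + 1L]] <- mk("ISI", sample(0:3, 7L, replace = TRUE))
  }
  list(face = face, questionnaires = do.call(rbind, qrows),
       phq9_total = totals$PHQ9[1L], cesdr_total = totals$CESDR[1L])
}

#' Generate a synthetic cohort
#'
#' Draws each participant's latent group, generates all streams through
#' per-participant per-stream seed sub-streams (adding a stream type never
#' perturbs existing draws), assembles validated bundles, and returns the
#' realized ground truth alongside.
#'
#' @param spec a [cohortSpec()].
#' @return list with `bundles` (list of `sensor_bundle`) and `ground_truth`
#'   (data.frame: participant_id, group, mean_sleep, mean_usage, entropy,
#'   mean_activity, phq9_total, cesdr_total, diagnosis).
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  if (n == 0L) {
    return(list(bundles = list(),
                ground_truth = data.frame(participant_id = character(0))))
  }
  n_dep <- round(n * spec$depressed_fraction)
  group <- withSeed(subSeed(spec$seed, 0L, 0L),
                    sample(rep(c("depressed", "non_depressed"),
                               c(n_dep, n - n_dep))))
  ids <- sprintf("p%03d", seq_len(n))
  bundles <- vector("list", n)
  gt <- vector("list", n)
  for (i in seq_len(n)) {
    params <- if (group[i] == "depressed") spec$depressed else spec$non_depressed
    scr <- withSeed(subSeed(spec$seed, i, 1L),
                    generateScreenStream(params, spec$days, spec$start_date,
                                         spec$tz_offset_min))
    gps <- withSeed(subSeed(spec$seed, i, 2L),
                    generateGpsTrace(params, spec$days, spec$fixes_per_day,
                                     spec$start_date, spec$tz_offset_min))
    act <- withSeed(subSeed(spec$seed, i, 3L),
                    generateActivityLog(params, spec$days, spec$start_date,
                                        spec$tz_offset_min))
    eq <- withSeed(subSeed(spec$seed, i, 4L),
                   generateExpressionAndQuestionnaires(params, spec$days,
                                                       spec$start_date,
                                                       spec$tz_offset_min))
    tables <- list(screen = scr$events, gps = gps$fixes, activity = act$events,
                   face = eq$face, questionnaires = eq$questionnaires)
    tables <- lapply(tables, function(tb) {
      tb$participant_id <- ids[i]
      tb[order(tb$timestamp %||% seq_len(nrow(tb))), , drop = FALSE]
    })
    diagnosis <- if (group[i] == "depressed") "DEPRESSIVE" else "NON_DEPRESSIVE"
    bundles[[i]] <- assembleBundle(tables, window = scr$window,
                                   diagnosis = diagnosis,
                                   participant_id = ids[i])
    gt[[i]] <- data.frame(participant_id = ids[i], group = group[i],
                          mean_sleep = mean(scr$sleep_hours),
                          mean_usage = mean(scr$usage_hours),
                          entropy = gps$entropy,
                          mean_activity = mean(act$activity_hours),
                          phq9_total = eq$phq9_total,
                          cesdr_total = eq$cesdr_total,
                          diagnosis = diagnosis, stringsAsFactors = FALSE)
  }
  list(bundles = bundles, ground_truth = do.call(rbind, gt))
}

#' Write a cohort to collection-schema CSVs
#'
#' One directory per participant plus `manifest.csv` and (when ground truth
#' is supplied) `ground_truth.csv`.
#'
#' @param bundles list of `sensor_bundle`.
#' @param dir output directory.
#' @param ground_truth optional ground-truth data.frame.
#' @return `dir`, invisibly.
#' @export
writeCohortDir <- function(bundles, dir, ground_truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- do.call(rbind, lapply(bundles, function(b) {
    writeBundle(b, file.path(dir, b$participant_id))
    data.frame(participant_id = b$participant_id,
               window_start = formatTimestamp(b$window[1L],
                                              b$window_offset_min),
               window_end = formatTimestamp(b$window[2L],
                                            b$window_offset_min),
               diagnosis = b$diagnosis %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(ground_truth)) {
    write.csv(ground_truth, file.path(dir, "ground_truth.csv"),
              row.names = FALSE)
  }
  invisible(dir)
}
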