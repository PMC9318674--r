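# The 33 multimodal derived features.
#
# Order (fixed, documented): 14 sleep features (7 summary statistics of the
# daily screen-off sleep proxy, then 7 of daily screen-on usage), location
# variance, location entropy, mean daily physical-activity hours, then the
# 16-dimensional aggregated facial-expression embedding.

SLEEP_STATS <- c("max", "min", "mean", "sd", "q1", "q2", "q3")

#' Names of the 33 features, in canonical order
#' @return character vector of length 33.
#' @export
featureNames <- function() {
  c(paste0("sleep_", SLEEP_STATS), paste0("usage_", SLEEP_STATS),
    "location_variance", "location_entropy", "activity_hours", EXPR_COLS)
}

FEATURE_GROUPS <- list(sleep = 1:14, mobility = 15:16, activity = 17L,
                       expression = 18:33)

#' Column indices of the feature groups
#'
#' `sleep` (14 columns), `mobility` (location variance + entropy),
#' `activity` (mean daily physical-activity hours) and `expression`
#' (16 embedding dimensions). The per-group model comparison treats mobility
#' and activity together as the physical-activity block.
#' @return named list of integer index vectors into [featureNames()].
#' @export
featureGroups <- function() FEATURE_GROUPS

#' Maximal screen-off intervals
#'
#' Every maximal interval from an OFF event to the next ON event. A trailing
#' OFF with no later ON is closed at the collection-window end and flagged
#' `unterminated`. A leading segment before the first event has unknown state
#' and produces no interval.
#'
#' @param screen deduplicated, time-sorted screen events.
#' @param window_end POSIXct (UTC) collection-window end.
#' @return data.frame: start, end (POSIXct UTC), offset_min (local offset at
#'   interval start), hours, unterminated.
#' @export
screenOffIntervals <- function(screen, window_end) {
  n <- nrow(screen)
  empty <- data.frame(start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"),
                      offset_min = integer(0), hours = numeric(0),
                      unterminated = logical(0))
  if (n == 0L) return(empty)
  off_idx <- which(screen$state == "OFF")
  if (length(off_idx) == 0L) return(empty)
  unterminated <- off_idx == n
  ends <- screen$timestamp[pmin(off_idx + 1L, n)]
  ends[unterminated] <- window_end
  out <- data.frame(start = screen$timestamp[off_idx], end = ends,
                    offset_min = screen$offset_min[off_idx],
                    unterminated = unterminated)
  out$hours <- hoursBetween(out$start, out$end)
  out <- out[out$hours > 0, , drop = FALSE]
  rownames(out) <- NULL
  out[, c("start", "end", "offset_min", "hours", "unterminated")]
}

#' Daily sleep estimates from screen-off intervals
#'
#' Sleep is estimated as the longest screen-off interval of the day. Days run
#' noon to noon on the local clock (candidates are grouped by interval
#' midpoint) and the estimate is attributed to the calendar date on which the
#' window ends, so overnight sleep is never split. Candidates lying entirely
#' within local 12:00-18:00 are discarded (an afternoon-only interval cannot
#' be night sleep), as are candidates longer than 24 h. A day with no
#' surviving candidate has no row (sleep missing).
#'
#' @param intervals output of [screenOffIntervals()].
#' @param last_date optional local Date: estimates attributed past it (day
#'   windows that end after the collection window's last local date) are
#'   dropped — they describe days outside the study window.
#' @return data.frame: date (the attributed local date), sleep_hours.
#' @export
estimateDailySleep <- function(intervals, last_date = NULL) {
  if (nrow(intervals) == 0L) {
    return(data.frame(date = as.Date(character(0)), sleep_hours = numeric(0)))
  }
  mid <- intervals$start + intervals$hours * 1800  # midpoint (seconds)
  # noon-to-noon window index: date of (local midpoint - 12 h), +1 = end date
  wdate <- as.Date(format(localTime(mid, intervals$offset_min) - 12 * 3600,
                          "%Y-%m-%d", tz = "UTC")) + 1L
  start_h <- localHour(intervals$start, intervals$offset_min)
  end_h <- localHour(intervals$end, intervals$offset_min)
  same_day <- localDate(intervals$start, intervals$offset_min) ==
    localDate(intervals$end, intervals$offset_min)
  afternoon_only <- same_day & start_h >= 12 & end_h <= 18
  keep <- !afternoon_only & intervals$hours <= 24
  if (!is.null(last_date)) keep <- keep & wdate <= last_date
  if (!any(keep)) {
    return(data.frame(date = as.Date(character(0)), sleep_hours = numeric(0)))
  }
  sleep <- tapply(intervals$hours[keep], as.character(wdate[keep]), max)
  data.frame(date = as.Date(names(sleep)), sleep_hours = as.numeric(sleep))
}

#' Daily smartphone usage (screen-on hours)
#'
#' Sums screen-on interval durations per local calendar day; intervals that
#' span midnight are split at midnight. Every date covered by the collection
#' window gets a row (0 when the screen was never on).
#'
#' @param screen deduplicated, time-sorted screen events.
#' @param window length-2 POSIXct (UTC) collection window.
#' @param window_offset_min local offset of the window, minutes.
#' @return data.frame: date, usage_hours.
#' @export
dailyUsage <- function(screen, window, window_offset_min = 0L) {
  dates <- seq(localDate(window[1L], window_offset_min),
               localDate(window[2L], window_offset_min), by = "day")
  usage <- setNames(numeric(length(dates)), as.character(dates))
  n <- nrow(screen)
  if (n > 0L) {
    on_idx <- which(screen$state == "ON")
    s <- screen$timestamp[on_idx]
    e <- screen$timestamp[pmin(on_idx + 1L, n)]
    e[on_idx == n] <- window[2L]
    off <- screen$offset_min[on_idx]
    d1 <- localDate(s, off)
    d2 <- localDate(e - 1e-6, off)  # end-exclusive date
    same <- d1 == d2 & e > s
    if (any(same)) {
      add <- tapply(hoursBetween(s[same], e[same]), as.character(d1[same]),
                    sum)
      hit <- intersect(names(add), names(usage))
      usage[hit] <- usage[hit] + add[hit]
    }
    for (i in which(!same & e > s)) {  # rare: intervals spanning midnight
      si <- s[i]
      while (si < e[i]) {
        d <- localDate(si, off[i])
        seg_end <- min(e[i], utcFromLocal(d + 1L, 0, off[i]))
        key <- as.character(d)
        if (key %in% names(usage)) {
          usage[key] <- usage[key] + hoursBetween(si, seg_end)
        }
        si <- seg_end
      }
    }
  }
  data.frame(date = dates, usage_hours = as.numeric(usage))
}

#' Seven-number statistical summary
#'
#' Maximum, minimum, mean, standard deviation (n-1 denominator; 0 for a
#' single value), and the three quartiles by linear interpolation.
#'
#' @param series numeric vector; NAs are dropped.
#' @return named numeric of length 7 (max, min, mean, sd, q1, q2, q3), or
#'   all-NA when no non-missing value remains (feature-group-missing signal).
#' @export
statSummary <- function(series) {
  series <- series[!is.na(series)]
  if (length(series) == 0L) {
    return(setNames(rep(NA_real_, 7L), SLEEP_STATS))
  }
  qs <- quantile(series, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  s <- if (length(series) == 1L) 0 else sd(series)
  setNames(c(max(series), min(series), mean(series), s, qs), SLEEP_STATS)
}

#' The 14 sleep features of a bundle
#'
#' [statSummary()] of daily sleep estimates followed by [statSummary()] of
#' daily usage hours.
#'
#' @param bundle a `sensor_bundle`.
#' @return named numeric of length 14 (all NA when the screen stream is
#'   empty or no day survives the sleep-candidate filters).
#' @export
sleepFeatureBlock <- function(bundle) {
  if (nrow(bundle$screen) == 0L) {
    return(setNames(rep(NA_real_, 14L), featureNames()[1:14]))
  }
  iv <- screenOffIntervals(bundle$screen, bundle$window[2L])
  # last date whose noon-to-noon window is fully covered by the collection
  # window; later attributions could only be trailing daytime gaps
  end_date <- localDate(bundle$window[2L], bundle$window_offset_min)
  if (localHour(bundle$window[2L], bundle$window_offset_min) < 12) {
    end_date <- end_date - 1L
  }
  sleep <- estimateDailySleep(iv, last_date = end_date)
  usage <- dailyUsage(bundle$screen, bundle$window, bundle$window_offset_min)
  setNames(c(statSummary(sleep$sleep_hours), statSummary(usage$usage_hours)),
           featureNames()[1:14])
}

#' Location variance
#'
#' Natural log of (population variance of latitude + population variance of
#' longitude), in degrees squared; the sum is floored at `epsilon` before the
#' log so a participant who never leaves one place stays finite.
#'
#' @param fixes GPS fixes data.frame.
#' @param epsilon variance floor in degrees squared (default 1e-12).
#' @return numeric scalar; NA when fewer than 2 fixes.
#' @export
locationVariance <- function(fixes, epsilon = 1e-12) {
  if (nrow(fixes) < 2L) return(NA_real_)
  popvar <- function(x) mean((x - mean(x))^2)
  log(max(popvar(fixes$latitude) + popvar(fixes$longitude), epsilon))
}

#' Location entropy over significant places
#'
#' Shannon entropy (nats) of the distribution of non-noise fixes across
#' density clusters: p_i is the fraction of non-noise fixes in cluster i.
#' Low entropy indicates homebound behaviour.
#'
#' @param labels cluster labels from [clusterGps()] (-1 = noise).
#' @return entropy in nats; 0 for a single cluster; NA when every fix is
#'   noise (feature missing).
#' @export
locationEntropy <- function(labels) {
  labels <- labels[labels > 0]
  if (length(labels) == 0L) return(NA_real_)
  p <- as.numeric(table(labels)) / length(labels)
  if (length(p) <= 1L) return(0)
  -sum(p * log(p))
}

#' Mean daily physical-activity hours
#'
#' Episodes are ENTER-to-EXIT spans per activity class; an ENTER left open at
#' the window end is closed there. The feature is the mean over observed days
#' (local dates with at least one activity event of any class) of the summed
#' episode hours of the included classes. The default included set is
#' stationary, running and walking — the classes the protocol counts as
#' physical activity, cycling being excluded as confusable with vehicle; an
#' alternative locomotion-only set is available via `included_classes`.
#'
#' @param activity activity-transition events, time-sorted.
#' @param window length-2 POSIXct (UTC) collection window.
#' @param included_classes character set of counted classes.
#' @return mean hours/day; NA when there are no activity events.
#' @export
dailyActivityTime <- function(activity, window,
                              included_classes = c("STATIONARY", "RUNNING",
                                                   "WALKING")) {
  if (nrow(activity) == 0L) return(NA_real_)
  obs_days <- unique(localDate(activity$timestamp, activity$offset_min))
  per_day <- setNames(numeric(length(obs_days)), as.character(obs_days))
  addHours <- function(keys, hours) {
    add <- tapply(hours, keys, sum)
    new <- setdiff(names(add), names(per_day))
    if (length(new)) per_day[new] <<- 0
    per_day[names(add)] <<- per_day[names(add)] + add
  }
  for (cls in intersect(unique(activity$activity_class), included_classes)) {
    ev <- activity[activity$activity_class == cls, , drop = FALSE]
    # pair each ENTER with the next EXIT; an unmatched trailing ENTER is
    # closed at the window end
    enter <- which(ev$transition == "ENTER")
    enter <- enter[c(diff(enter) > 1L, TRUE)]  # skip doubled ENTERs
    s <- ev$timestamp[enter]
    e <- ev$timestamp[pmin(enter + 1L, nrow(ev))]
    e[enter == nrow(ev) | ev$transition[pmin(enter + 1L, nrow(ev))] != "EXIT"] <-
      window[2L]
    off <- ev$offset_min[enter]
    d1 <- localDate(s, off)
    d2 <- localDate(e - 1e-6, off)
    same <- d1 == d2 & e > s
    if (any(same)) {
      addHours(as.character(d1[same]), hoursBetween(s[same], e[same]))
    }
    for (i in which(!same & e > s)) {  # rare: episodes spanning midnight
      si <- s[i]
      while (si < e[i]) {
        d <- localDate(si, off[i])
        seg_end <- min(e[i], utcFromLocal(d + 1L, 0, off[i]))
        addHours(as.character(d), hoursBetween(si, seg_end))
        si <- seg_end
      }
    }
  }
  mean(per_day)
}

#' Aggregate facial-expression embeddings
#'
#' Element-wise mean of the (weekly) 16-dimensional expression embeddings —
#' one participant-level expression representation.
#'
#' @param face data.frame of embedding records with columns `expr_01..expr_16`.
#' @return named numeric of length 16; all NA when no records.
#' @export
aggregateExpression <- function(face) {
  if (nrow(face) == 0L) {
    return(setNames(rep(NA_real_, EMBEDDING_DIM), EXPR_COLS))
  }
  emb <- as.matrix(face[, EXPR_COLS, drop = FALSE])
  if (ncol(emb) != EMBEDDING_DIM || any(!is.finite(emb))) {
    stop("aggregateExpression: embeddings must be finite and 16-dimensional",
         call. = FALSE)
  }
  setNames(colMeans(emb), EXPR_COLS)
}

#' Deterministic stub face embedder
#'
#' Maps an image-identifier string to a unit-norm 16-vector. A stand-in for a
#' real metric-learning expression embedder (the pipeline consumes embedding
#' vectors; the embedder itself is pluggable): deterministic, so fixtures and
#' tests are reproducible, with no claim to expression semantics.
#'
#' @param image_id character scalar.
#' @return unit-norm numeric vector of length 16.
#' @export
stubFaceEmbedder <- function(image_id) {
  stopifnot(is.character(image_id), length(image_id) == 1L, nzchar(image_id))
  codes <- utf8ToInt(image_id)
  h <- sum(codes * seq_along(codes)) + length(codes) * 131
  v <- sin(h * seq_len(EMBEDDING_DIM) + seq_len(EMBEDDING_DIM)^2)
  v / sqrt(sum(v^2))
}

#' Feature-extraction configuration
#'
#' @param eps_meters,min_samples DBSCAN radius (m) and minimum neighbourhood
#'   size (defaults 300 m, 5).
#' @param variance_epsilon floor for the location-variance log (degrees^2).
#' @param included_classes activity classes counted as physical activity.
#' @param missing_policy `"drop"` (study default: a participant with any
#'   missing feature group is dropped) or `"impute"` (missing groups are
#'   filled with training-set column means at modelling time).
#' @return a `feature_config` list.
#' @export
featureConfig <- function(eps_meters = 300, min_samples = 5L,
                          variance_epsilon = 1e-12,
                          included_classes = c("STATIONARY", "RUNNING",
                                               "WALKING"),
                          missing_policy = c("drop", "impute")) {
  structure(list(eps_meters = eps_meters, min_samples = min_samples,
                 variance_epsilon = variance_epsilon,
                 included_classes = included_classes,
                 missing_policy = match.arg(missing_policy)),
            class = "feature_config")
}

#' Assemble the 33-feature vector of one participant
#'
#' Concatenates the sleep block (14), location variance, location entropy,
#' mean daily activity hours and the aggregated expression embedding (16), in
#' the canonical [featureNames()] order, with a per-group provenance flag
#' (`observed` / `missing`).
#'
#' @param bundle a `sensor_bundle` (should already have passed the exclusion
#'   rules).
#' @param config a [featureConfig()].
#' @return a `feature_vector`: named numeric of length 33 with attribute
#'   `provenance` (named character over the four groups).
#' @export
assembleFeatures <- function(bundle, config = featureConfig()) {
  sleep <- sleepFeatureBlock(bundle)
  if (nrow(bundle$gps) >= 2L) {
    labels <- clusterGps(bundle$gps, config$eps_meters, config$min_samples)
    mobility <- c(location_variance =
                    locationVariance(bundle$gps, config$variance_epsilon),
                  location_entropy = locationEntropy(labels))
  } else {
    mobility <- c(location_variance = NA_real_, location_entropy = NA_real_)
  }
  act <- c(activity_hours = dailyActivityTime(bundle$activity, bundle$window,
                                              config$included_classes))
  expr <- aggregateExpression(bundle$face)
  v <- c(sleep, mobility, act, expr)
  names(v) <- featureNames()
  prov <- vapply(FEATURE_GROUPS, function(idx)
    if (anyNA(v[idx])) "missing" else "observed", character(1))
  structure(v, provenance = prov, participant_id = bundle$participant_id,
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector> participant", attr(x, "participant_id"), "\n")
  prov <- attr(x, "provenance")
  cat("  groups:", paste(sprintf("%s=%s", names(prov), prov),
                         collapse = "  "), "\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Extract the cohort feature matrix
#'
#' Applies [assembleFeatures()] to every bundle. Under the `"drop"` policy
#' (study default) participants with any missing feature group are removed;
#' under `"impute"` missing entries are kept as NA for training-set mean
#' imputation at modelling time.
#'
#' @param bundles list of `sensor_bundle`.
#' @param config a [featureConfig()].
#' @return data.frame: `participant_id`, 33 feature columns, and the four
#'   `prov_*` provenance columns; attribute `dropped` lists dropped
#'   participants with reasons.
#' @export
extractFeatures <- function(bundles, config = featureConfig()) {
  vecs <- lapply(bundles, assembleFeatures, config = config)
  prov <- do.call(rbind, lapply(vecs, attr, "provenance"))
  mat <- do.call(rbind, lapply(vecs, unclass))
  df <- data.frame(participant_id = vapply(bundles, `[[`, character(1),
                                           "participant_id"),
                   mat, stringsAsFactors = FALSE, check.names = FALSE)
  for (g in colnames(prov)) df[[paste0("prov_", g)]] <- prov[, g]
  dropped <- data.frame(participant_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  if (config$missing_policy == "drop") {
    bad <- apply(prov, 1L, function(r) any(r == "missing"))
    if (any(bad)) {
      dropped <- data.frame(
        participant_id = df$participant_id[bad],
        reason = apply(prov[bad, , drop = FALSE], 1L, function(r)
          paste("missing group:", paste(names(r)[r == "missing"],
                                        collapse = ", "))),
        stringsAsFactors = FALSE)
      df <- df[!bad, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  attr(df, "dropped") <- dropped
  df
}
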