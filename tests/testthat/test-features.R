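test_that("screen-off intervals are maximal OFF-to-ON spans", {
  s <- mkScreen(c("2021-08-19 08:00:00", "2021-08-19 23:00:00",
                  "2021-08-20 07:00:00"), c("ON", "OFF", "ON"))
  iv <- screenOffIntervals(s, utc9("2021-08-20 09:00:00"))
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$hours, 8)
  expect_false(iv$unterminated)
  # a trailing OFF is closed at the window end and flagged
  s2 <- mkScreen("2021-08-19 23:00:00", "OFF")
  iv2 <- screenOffIntervals(s2, utc9("2021-08-20 09:00:00"))
  expect_equal(iv2$hours, 10)
  expect_true(iv2$unterminated)
  # off time + on time partitions the observed span
  s3 <- mkScreen(c("2021-08-19 08:00:00", "2021-08-19 09:00:00",
                   "2021-08-19 11:00:00", "2021-08-19 11:30:00",
                   "2021-08-19 20:00:00", "2021-08-19 21:00:00",
                   "2021-08-20 07:00:00"),
                 c("ON", "OFF", "ON", "OFF", "ON", "OFF", "ON"))
  iv3 <- screenOffIntervals(s3, utc9("2021-08-20 07:00:00"))
  on_hours <- 1 + 0.5 + 1
  expect_equal(sum(iv3$hours), 23 - on_hours)
})

test_that("daily sleep keeps the longest candidate and applies the filters", {
  s <- mkScreen(c("2021-08-19 23:00:00", "2021-08-20 07:00:00"),
                c("OFF", "ON"))
  est <- estimateDailySleep(screenOffIntervals(s, utc9("2021-08-20 09:00:00")))
  expect_equal(est$sleep_hours, 8)
  expect_equal(est$date, as.Date("2021-08-20"))
  # afternoon-only candidate (13:00-16:00) is discarded: day has no estimate
  s2 <- mkScreen(c("2021-08-19 13:00:00", "2021-08-19 16:00:00"),
                 c("OFF", "ON"))
  est2 <- estimateDailySleep(screenOffIntervals(s2, utc9("2021-08-19 23:00:00")))
  expect_equal(nrow(est2), 0L)
  # candidates above 24 h are discarded
  s3 <- mkScreen(c("2021-08-19 06:00:00", "2021-08-20 08:00:00"),
                 c("OFF", "ON"))
  est3 <- estimateDailySleep(screenOffIntervals(s3, utc9("2021-08-20 09:00:00")))
  expect_equal(nrow(est3), 0L)
  # partial overlap with 12:00-18:00 survives
  s4 <- mkScreen(c("2021-08-19 11:00:00", "2021-08-19 17:00:00"),
                 c("OFF", "ON"))
  est4 <- estimateDailySleep(screenOffIntervals(s4, utc9("2021-08-19 23:00:00")))
  expect_equal(est4$sleep_hours, 6)
})

test_that("daily usage sums ON time per local day, splitting at midnight", {
  s <- mkScreen(c("2021-08-19 10:00:00", "2021-08-19 12:00:00"),
                c("ON", "OFF"))
  w <- c(utc9("2021-08-19 00:00:00"), utc9("2021-08-19 23:59:00"))
  u <- dailyUsage(s, w, TZ9)
  expect_equal(u$usage_hours, 2)
  # midnight span: one hour on each side
  s2 <- mkScreen(c("2021-08-19 23:00:00", "2021-08-20 01:00:00"),
                 c("ON", "OFF"))
  w2 <- c(utc9("2021-08-19 00:00:00"), utc9("2021-08-20 23:59:00"))
  u2 <- dailyUsage(s2, w2, TZ9)
  expect_equal(u2$usage_hours, c(1, 1))
  # no ON intervals -> all zero
  s3 <- mkScreen("2021-08-19 23:00:00", "OFF")
  expect_equal(dailyUsage(s3, w, TZ9)$usage_hours, 0)
})

test_that("statSummary computes the seven functionals with interpolated quartiles", {
  expect_equal(unname(statSummary(c(2, 2, 2))), c(2, 2, 2, 0, 2, 2, 2))
  s <- statSummary(c(1, 2, 3, 4))
  expect_equal(unname(s[c("q2", "mean")]), c(2.5, 2.5))
  expect_equal(unname(s[c("q1", "q3")]), c(1.75, 3.25))
  expect_equal(unname(s["sd"]), sd(1:4))
  expect_equal(unname(statSummary(5)["sd"]), 0)  # single value
  set.seed(8)
  x <- rnorm(31)
  expect_equal(statSummary(sample(x)), statSummary(x))  # permutation invariant
  expect_true(all(is.na(statSummary(numeric(0)))))
})

test_that("the sleep block is 14 stats and ignores redundant same-state events", {
  sim <- generateCohort(cohortSpec(n_participants = 1, days = 6, seed = 2))
  b <- sim$bundles[[1]]
  blk <- sleepFeatureBlock(b)
  expect_length(blk, 14L)
  expect_equal(names(blk), featureNames()[1:14])
  # duplicate every screen event (same-state repeats): features unchanged
  b2 <- b
  dup <- b2$screen[rep(seq_len(nrow(b2$screen)), each = 2), ]
  dup$timestamp <- dup$timestamp + rep(c(0, 1), nrow(b2$screen))
  b2$screen <- dedupScreenEvents(dup[order(dup$timestamp), ])
  expect_equal(sleepFeatureBlock(b2), blk, tolerance = 1e-3)
})

test_that("location variance is the log of summed population variances", {
  fx <- mkGps(lat = c(0, 0), lon = c(0, 2))
  # population variances: lat 0, lon 1 -> log(1) = 0
  expect_equal(locationVariance(fx), 0)
  # all fixes identical -> floored at epsilon
  fx2 <- mkGps(lat = rep(37.5, 5), lon = rep(127, 5))
  expect_equal(locationVariance(fx2), log(1e-12))
  expect_true(is.na(locationVariance(mkGps(37.5, 127))))
  # translation invariance
  set.seed(11)
  fx3 <- mkGps(lat = 37.5 + rnorm(40, 0, 0.01), lon = 127 + rnorm(40, 0, 0.01))
  fx4 <- fx3
  fx4$latitude <- fx4$latitude + 0.3
  fx4$longitude <- fx4$longitude + 0.2
  expect_equal(locationVariance(fx4), locationVariance(fx3))
})

test_that("location entropy matches hand-computed cluster proportions", {
  expect_equal(locationEntropy(c(1, 1, 2, 2)), log(2))
  expect_equal(locationEntropy(rep(1, 10)), 0)
  expect_equal(locationEntropy(c(rep(1, 3), 2)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)))
  expect_equal(locationEntropy(c(1, 1, -1, -1)), 0)  # noise excluded
  expect_true(is.na(locationEntropy(rep(-1, 5))))
  # bounded by log(k), maximal iff uniform
  set.seed(13)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    lab <- sample(seq_len(k), 60, replace = TRUE, prob = runif(k) + 0.1)
    h <- locationEntropy(lab)
    expect_gte(h, 0)
    expect_lte(h, log(length(unique(lab))) + 1e-12)
  }
  expect_equal(locationEntropy(rep(1:4, each = 15)), log(4))
})

test_that("density clustering separates distant clumps and flags sparse noise", {
  fx <- mkGps(lat = c(rep(37.5, 10), rep(37.545, 10)),
              lon = rep(127, 20))  # 5 km apart
  lab <- clusterGps(fx, eps_meters = 300, min_samples = 5)
  expect_equal(sort(unique(lab)), c(1L, 2L))
  expect_equal(as.vector(table(lab)), c(10L, 10L))
  # isolated fixes >= 1 km apart are all noise
  fx2 <- mkGps(lat = 37.5 + 0.01 * (0:19), lon = rep(127, 20))
  expect_true(all(clusterGps(fx2, 300, 5) == -1L))
  # small translation leaves labels unchanged
  fx3 <- fx
  fx3$latitude <- fx3$latitude + 1e-5   # ~1 m << eps/100
  fx3$longitude <- fx3$longitude + 1e-5
  expect_identical(clusterGps(fx3, 300, 5), lab)
})

test_that("density clustering agrees with the brute-force oracle", {
  for (seed in 1:12) {
    n <- sample(8:60, 1)
    fx <- randomFixes(n, seed)
    expect_identical(clusterGps(fx, 300, 5), dbscanOracle(fx, 300, 5),
                     label = sprintf("seed %d", seed))
  }
})

test_that("daily physical activity averages included-class hours per observed day", {
  w <- c(utc9("2021-08-19 00:00:00"), utc9("2021-08-20 23:00:00"))
  a <- mkActivity(c("2021-08-19 09:00:00", "2021-08-19 10:00:00"),
                  "WALKING", c("ENTER", "EXIT"))
  expect_equal(dailyActivityTime(a, w), 1)
  # cycling never counts
  a2 <- mkActivity(c("2021-08-19 09:00:00", "2021-08-19 10:00:00"),
                   "CYCLING", c("ENTER", "EXIT"))
  expect_equal(dailyActivityTime(a2, w), 0)
  # two observed days at 1 h and 3 h -> 2 h/day
  a3 <- mkActivity(c("2021-08-19 09:00:00", "2021-08-19 10:00:00",
                     "2021-08-20 09:00:00", "2021-08-20 12:00:00"),
                   c("WALKING", "WALKING", "STATIONARY", "STATIONARY"),
                   rep(c("ENTER", "EXIT"), 2))
  expect_equal(dailyActivityTime(a3, w), 2)
  # unmatched trailing ENTER closes at the window end
  a4 <- mkActivity("2021-08-20 21:00:00", "WALKING", "ENTER")
  expect_equal(dailyActivityTime(a4, w), 2)
  expect_true(is.na(dailyActivityTime(a4[0, ], w)))
  # alternative locomotion-only class set
  expect_equal(dailyActivityTime(a3, w, included_classes =
                                   c("WALKING", "RUNNING",
                                     "WALKING_OR_RUNNING")), 0.5)
})

test_that("expression aggregation is the element-wise mean", {
  v <- matrix(rnorm(16), nrow = 1)
  expect_equal(unname(aggregateExpression(mkFace(v))), as.vector(v))
  expect_equal(unname(aggregateExpression(mkFace(rbind(v, -v)))), rep(0, 16))
  set.seed(21)
  m <- matrix(rnorm(48), nrow = 3)
  expect_equal(unname(aggregateExpression(mkFace(m))),
               vapply(seq_len(16), function(j) mean(m[, j]), numeric(1)))
})

test_that("the stub embedder is deterministic and unit-norm", {
  e1 <- stubFaceEmbedder("img-001.jpg")
  expect_identical(e1, stubFaceEmbedder("img-001.jpg"))
  expect_false(identical(e1, stubFaceEmbedder("img-002.jpg")))
  expect_length(e1, 16L)
  expect_equal(sqrt(sum(e1^2)), 1)
})

test_that("assembled vectors have 33 dimensions with provenance and policies", {
  set.seed(31)
  b <- mkBundle()
  fv <- assembleFeatures(b)
  expect_length(fv, 33L)
  expect_equal(names(fv), featureNames())
  expect_equal(unname(attr(fv, "provenance")),
               rep("observed", 4))
  expect_equal(lengths(featureGroups()), c(sleep = 14L, mobility = 2L,
                                           activity = 1L, expression = 16L))
  # no GPS: drop policy removes the participant, impute keeps it flagged
  b_nogps <- b
  b_nogps$gps <- b_nogps$gps[0, ]
  fm_drop <- extractFeatures(list(b, b_nogps),
                             featureConfig(missing_policy = "drop"))
  expect_equal(nrow(fm_drop), 1L)
  expect_match(attr(fm_drop, "dropped")$reason, "mobility")
  fm_imp <- extractFeatures(list(b, b_nogps),
                            featureConfig(missing_policy = "impute"))
  expect_equal(nrow(fm_imp), 2L)
  expect_equal(fm_imp$prov_mobility, c("observed", "missing"))
  # cohort of k complete bundles -> k x 33 matrix
  sim <- generateCohort(smallSpec(n = 5, days = 5, seed = 3))
  fm <- extractFeatures(sim$bundles)
  expect_equal(dim(fm[, featureNames()]), c(5L, 33L))
})
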