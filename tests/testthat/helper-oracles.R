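# Independent oracles, kept deliberately separate from the package's code
# paths: an explicit haversine formula plus graph components for density
# clustering, and plain counting loops for classification metrics.

# Great-circle distance (m), explicit haversine formula, radius matching
# geosphere's default.
haversineOracle <- function(lat1, lon1, lat2, lon2, r = 6378137) {
  toRad <- pi / 180
  dlat <- (lat2 - lat1) * toRad
  dlon <- (lon2 - lon1) * toRad
  a <- sin(dlat / 2)^2 + cos(lat1 * toRad) * cos(lat2 * toRad) *
    sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Brute-force density clustering: core points by neighbourhood count
# (self included), clusters = connected components of the core-core graph
# numbered by smallest core index, border points joined to the
# earliest-founded adjacent cluster, everything else noise (-1).
dbscanOracle <- function(fixes, eps_meters = 300, min_samples = 5L) {
  n <- nrow(fixes)
  if (n == 0L) return(integer(0))
  d <- outer(seq_len(n), seq_len(n), function(i, j)
    haversineOracle(fixes$latitude[i], fixes$longitude[i],
                    fixes$latitude[j], fixes$longitude[j]))
  adj <- d <= eps_meters
  core <- which(rowSums(adj) >= min_samples)
  labels <- rep(-1L, n)
  if (length(core) == 0L) return(labels)
  g <- igraph::graph_from_adjacency_matrix(
    adj[core, core, drop = FALSE], mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  # number clusters by the smallest original index of their core points
  founding <- tapply(core, comp, min)
  renum <- rank(founding)
  labels[core] <- as.integer(renum[comp])
  border <- setdiff(which(rowSums(adj[, core, drop = FALSE]) > 0), core)
  for (b in border) {
    adjacent <- labels[core[adj[b, core]]]
    labels[b] <- min(adjacent)
  }
  labels
}

# Count-based classification metrics for one positive class.
metricsOracle <- function(pred, truth, positive) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == positive && truth[i] == positive) tp <- tp + 1L
    else if (pred[i] == positive) fp <- fp + 1L
    else if (truth[i] == positive) fn <- fn + 1L
    else tn <- tn + 1L
  }
  prec <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  list(precision = prec, recall = rec,
       f1 = if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
         2 * prec * rec / (prec + rec) else NA_real_,
       accuracy = 100 * (tp + tn) / length(pred))
}

# Random GPS instances mixing tight clumps and scattered points, for
# clustering equivalence checks.
randomFixes <- function(n, seed) {
  set.seed(seed)
  k <- sample(1:4, 1)
  centers_lat <- 37.5 + runif(k, -0.02, 0.02)
  centers_lon <- 127 + runif(k, -0.02, 0.02)
  pick <- sample.int(k, n, replace = TRUE)
  spread <- sample(c(50, 200, 800), 1) / 111320
  data.frame(
    participant_id = "x",
    timestamp = as.POSIXct("2021-08-19", tz = "UTC") + seq_len(n) * 60,
    offset_min = 540L,
    latitude = centers_lat[pick] + rnorm(n, 0, spread),
    longitude = centers_lon[pick] + rnorm(n, 0, spread))
}
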