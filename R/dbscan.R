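# Density-based clustering of GPS fixes (DBSCAN, haversine metric).
#
# Significant places are recovered as density clusters: a fix is a core point
# when at least min_samples fixes (itself included) lie within eps meters of
# it by great-circle distance; clusters are grown from core points and
# low-density fixes are labelled noise. Determinism: fixes are processed in
# timestamp order, so cluster numbering follows first appearance and a border
# fix reachable from several clusters joins the earliest-founded one.

#' Cluster GPS fixes with DBSCAN (haversine distance)
#'
#' @param fixes data.frame with `latitude`, `longitude` (degrees), sorted by
#'   timestamp.
#' @param eps_meters neighbourhood radius in meters (default 300).
#' @param min_samples minimum neighbourhood size (the fix itself counts) for a
#'   core point (default 5).
#' @return integer cluster label per fix: 1, 2, ... in order of first
#'   appearance; -1 marks noise.
#' @export
clusterGps <- function(fixes, eps_meters = 300, min_samples = 5L) {
  n <- nrow(fixes)
  if (n == 0L) return(integer(0))
  pts <- cbind(fixes$longitude, fixes$latitude)
  ii <- rep(seq_len(n), times = n)
  jj <- rep(seq_len(n), each = n)
  d <- geosphere::distHaversine(pts[ii, , drop = FALSE],
                                pts[jj, , drop = FALSE])
  adj <- matrix(d <= eps_meters, n, n)
  neighbours <- lapply(seq_len(n), function(i) which(adj[, i]))
  core <- lengths(neighbours) >= min_samples
  labels <- rep(NA_integer_, n)
  cluster <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) && labels[i] > 0L) next
    if (!core[i]) { if (is.na(labels[i])) labels[i] <- -1L; next }
    cluster <- cluster + 1L
    labels[i] <- cluster
    queue <- i
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      nb <- neighbours[[p]]
      lab_nb <- labels[nb]
      claim <- nb[is.na(lab_nb) | lab_nb == -1L]
      unvisited <- is.na(labels[claim])
      labels[claim] <- cluster
      queue <- c(queue, claim[core[claim] & unvisited])
    }
  }
  labels
}
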