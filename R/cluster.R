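# Greedy peak grouping shared by scan merging, cross-sample alignment and
# PIS/NLS transposition. Clusters are seeded from the most intense remaining
# peak; peaks within the resolution-model tolerance of the seed join it. With
# unique_owner = TRUE each owner (sample) contributes at most one peak per
# cluster — the nearest in m/z wins, the displaced peak re-enters the pool.
# Fully deterministic: ties broken by m/z, then owner, then input order.
group_peaks <- function(mz, intensity, owner, model, unique_owner = FALSE) {
  n <- length(mz)
  cluster <- integer(n)
  alive <- rep(TRUE, n)
  ord <- order(-intensity, mz, owner, seq_len(n))
  next_id <- 0L
  for (seed in ord) {
    if (!alive[seed]) next
    next_id <- next_id + 1L
    tol <- tolerance_at(model, mz[seed])
    cand <- which(alive & abs(mz - mz[seed]) <= tol)
    if (unique_owner) {
      keep <- vapply(split(cand, owner[cand]), function(idx) {
        d <- abs(mz[idx] - mz[seed])
        idx[order(d, -intensity[idx], mz[idx], idx)][1]
      }, integer(1))
      cand <- sort(unname(keep))
    }
    cluster[cand] <- next_id
    alive[cand] <- FALSE
  }
  cluster
}
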