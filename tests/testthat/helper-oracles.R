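# Independent brute-force oracles used to cross-check vectorised code paths.

# Naive double-loop confusion tabulation at a cutoff.
brute_confusion <- function(p, truth, tau) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(p)) {
    pos <- p[i] <= tau
    if (pos && truth[i]) tp <- tp + 1L
    if (pos && !truth[i]) fp <- fp + 1L
    if (!pos && !truth[i]) tn <- tn + 1L
    if (!pos && truth[i]) fn <- fn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Brute-force FDP curve built from the naive tabulation.
brute_fdp <- function(p, truth, cutoffs) {
  vapply(cutoffs, function(tau) {
    cc <- brute_confusion(p, truth, tau)
    if (cc["tp"] + cc["fp"] == 0) 0 else unname(cc["fp"] / (cc["fp"] + cc["tp"]))
  }, numeric(1))
}
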