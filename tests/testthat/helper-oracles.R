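# Independent brute-force oracles used to verify the analytic routes.

# Exact two-sided Mann-Whitney p by full enumeration of all group labelings
# of the pooled sample (no ties assumed): P(|U - n1 n2 / 2| >= observed).
mw_enumeration_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  idx <- utils::combn(length(pooled), n1)
  u_all <- apply(idx, 2L, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  center <- n1 * length(y) / 2
  mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
}

# Two-sided Fisher p by hypergeometric enumeration over tables with the
# observed margins: sum of probabilities <= that of the observed table
# (relative tolerance for floating-point equality of mathematically equal
# probabilities).
fisher_enumeration_p <- function(tab) {
  a <- tab[1L, 1L]
  r1 <- sum(tab[1L, ])
  c1 <- sum(tab[, 1L])
  n <- sum(tab)
  lo <- max(0L, c1 - (n - r1))
  hi <- min(r1, c1)
  dens <- stats::dhyper(lo:hi, r1, n - r1, c1)
  sum(dens[dens <= dens[a - lo + 1L] * (1 + 1e-7)])
}

# AUC by all-pairs concordance counting (ties half-counted).
auc_bruteforce <- function(scores, labels, orientation = "higher") {
  s <- if (orientation == "lower") -scores else scores
  pos <- s[labels == 1]
  neg <- s[labels == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# ROI membership and mean by per-pixel distance check.
roi_mean_bruteforce <- function(map, center, radius, mask = NULL) {
  vals <- c()
  for (r in seq_len(nrow(map))) {
    for (cc in seq_len(ncol(map))) {
      if ((r - 1 - center[1L])^2 + (cc - 1 - center[2L])^2 <= radius^2) {
        if (is.null(mask) || !mask[r, cc]) vals <- c(vals, map[r, cc])
      }
    }
  }
  list(mean = mean(vals), n = length(vals))
}
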