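# Independent oracles used across the suite. These deliberately avoid the
# package's own sampling code paths: enumeration and recursion here,
# vectorized exponential races and binomial draws there.

# Exact distribution of a daughter's heteroplasmy after one binomial
# partition of a pool (wt, mut): daughter class counts are independent
# Binomial(n, 1/2). Heteroplasmy is conditioned on a non-empty daughter.
# Returns list(mean, var) by full enumeration.
partition_heteroplasmy_oracle <- function(wt, mut) {
  probs <- outer(dbinom(0:wt, wt, 0.5), dbinom(0:mut, mut, 0.5))
  h <- outer(0:wt, 0:mut, function(i, j) ifelse(i + j > 0, j / (i + j), NA))
  keep <- !is.na(h)
  w <- probs[keep] / sum(probs[keep])
  m <- sum(w * h[keep])
  list(mean = m, var = sum(w * (h[keep] - m)^2))
}

# Exact pmf of the number of deletion genomes removed when k genomes are
# drawn without replacement from (wt, mut) with relative weight w on the
# deletion class. Sequential-draw recursion over states.
weighted_removal_pmf <- function(wt, mut, k, w) {
  # pmf over number of mutants removed after d draws, by recursion
  pmf <- setNames(1, "0")  # state: mutants removed so far
  for (d in seq_len(k)) {
    nxt <- numeric(0)
    for (nm in names(pmf)) {
      m_rm <- as.integer(nm)
      wt_rm <- (d - 1) - m_rm
      m_left <- mut - m_rm; w_left <- wt - wt_rm
      tot_w <- w * m_left + w_left
      if (m_left > 0) {
        key <- as.character(m_rm + 1)
        nxt[key] <- (if (key %in% names(nxt)) nxt[[key]] else 0) +
          pmf[[nm]] * w * m_left / tot_w
      }
      if (w_left > 0) {
        key <- as.character(m_rm)
        nxt[key] <- (if (key %in% names(nxt)) nxt[[key]] else 0) +
          pmf[[nm]] * w_left / tot_w
      }
    }
    pmf <- nxt
  }
  pmf
}

# Match detected foci against truth coordinates within an anisotropic
# tolerance; returns recovered fraction and false-positive fraction.
match_foci <- function(truth, coords, tol = c(z = 1, y = 2, x = 2)) {
  if (nrow(truth) == 0)
    return(c(recovered = NA, fp = if (nrow(coords)) 1 else 0))
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(abs(truth$z[i] - coords$z) <= tol[["z"]] &
          abs(truth$y[i] - coords$y) <= tol[["y"]] &
          abs(truth$x[i] - coords$x) <= tol[["x"]])
  }, logical(1))
  c(recovered = mean(hit),
    fp = (nrow(coords) - sum(hit)) / max(1, nrow(coords)))
}

# Monte-Carlo standard error of a mean from replicate values.
mc_se <- function(x) sd(x) / sqrt(length(x))
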