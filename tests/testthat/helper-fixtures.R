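# shared in-code fixtures

# straight horizontal strand of given pixel length, n points
straight_strand <- function(id, length_px, n_points = 2L, y = 0) {
  strand_trace(id, cbind(seq(0, length_px, length.out = n_points),
                         rep(y, n_points)))
}

# two parallel straight strands sep px apart
parallel_molecule <- function(sep = 5, length_px = 461, n_points = 24L,
                              template = 461L) {
  molecule_trace("par",
                 straight_strand("A", length_px, n_points, y = 0),
                 straight_strand("B", length_px, n_points, y = sep),
                 template)
}

# independent brute-force run-length segmentation (no cleanup)
oracle_runs <- function(labels) {
  out <- NULL
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    if (labels[i]) {
      j <- i
      while (j < n && labels[j + 1L]) j <- j + 1L
      out <- rbind(out, c(start = i - 1L, end = j))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# independent Otsu: direct two-class scan over the same histogram bins,
# averaging the bin edges that tie for maximal between-class variance
oracle_otsu <- function(x, n_bins = 256L) {
  edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  bin <- pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  v <- vapply(seq_len(n_bins - 1L), function(k) {
    lo <- bin <= k
    if (!any(lo) || all(lo)) return(0)
    w0 <- mean(lo)
    m0 <- sum(tabulate(bin[lo], n_bins) * mids) / sum(lo)
    m1 <- sum(tabulate(bin[!lo], n_bins) * mids) / sum(!lo)
    w0 * (1 - w0) * (m0 - m1)^2
  }, numeric(1))
  mean(edges[which(v >= max(v) * (1 - 1e-12)) + 1L])
}

# two-sided tail-doubling binomial p by explicit pmf summation
oracle_exact_p <- function(ka, k, p0) {
  pmf <- vapply(0:k, function(j) choose(k, j) * p0^j * (1 - p0)^(k - j),
                numeric(1))
  lower <- sum(pmf[seq_len(ka + 1L)])
  upper <- sum(pmf[(ka + 1L):(k + 1L)])
  min(1, 2 * min(lower, upper))
}

# mass-balance root for the single-site model: bracketing root find
# polished to machine precision with Newton steps
oracle_fraction_bound <- function(kd, Rt, Lt) {
  if (Rt == 0 || Lt == 0) return(if (Lt == 0) Rt / (Rt + kd) else 0)
  g <- function(C) C^2 - (Rt + Lt + kd) * C + Rt * Lt
  dg <- function(C) 2 * C - (Rt + Lt + kd)
  C <- stats::uniroot(g, c(0, min(Rt, Lt)), tol = 1e-18)$root
  for (i in 1:6) C <- C - g(C) / dg(C)
  C / Lt
}
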