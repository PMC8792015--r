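make_frags <- function(starts, lens, chrom = "chr1", sample = "ip") {
  data.frame(chrom = chrom, start = as.integer(starts),
             end = as.integer(starts + lens), sample = sample,
             stringsAsFactors = FALSE)
}

random_frags <- function(n, genome = 5000L) {
  starts <- sample.int(genome - 300L, n, replace = TRUE) - 1L
  make_frags(starts, sample(50:250, n, replace = TRUE))
}

test_that("insert-size filter keeps the mononucleosome window inclusively", {
  f <- make_frags(c(0, 0, 0, 0), c(150, 90, 120, 181))
  kept <- filter_by_insert_size(f)
  expect_identical(kept$end - kept$start, c(150L, 120L))
  expect_error(filter_by_insert_size(f, 200, 100), "min_bp")
  set.seed(8)
  rf <- random_frags(500)
  len <- rf$end - rf$start
  expect_identical(nrow(filter_by_insert_size(rf, 130, 170)),
                   sum(len >= 130 & len <= 170))
})

test_that("occupancy track counts overlapping fragments per base", {
  f <- make_frags(100, 150)
  cov <- occupancy_track(f, "chr1", c(0, 400))
  expect_identical(cov, c(rep(0L, 100), rep(1L, 150), rep(0L, 150)))
  cov2 <- occupancy_track(rbind(f, f), "chr1", c(0, 400))
  expect_identical(cov2, 2L * cov)
  # midpoint mode marks one base per fragment
  covm <- occupancy_track(f, "chr1", c(0, 400), mode = "midpoint")
  expect_identical(sum(covm), 1L)
  expect_identical(which(covm == 1L) - 1L, 175L)
})

test_that("occupancy track matches a naive per-base loop and conserves
           mass", {
  set.seed(9)
  for (i in 1:20) {
    f <- random_frags(60)
    cov <- occupancy_track(f, "chr1", c(0, 5000))
    naive <- integer(5000)
    for (j in seq_len(nrow(f)))
      naive[(f$start[j] + 1L):f$end[j]] <-
        naive[(f$start[j] + 1L):f$end[j]] + 1L
    expect_identical(cov, naive)
    expect_identical(sum(cov), sum(f$end - f$start))
  }
})

test_that("TSS matrices are transcription-oriented and reflection
           equivariant", {
  # + strand gene with fragment midpoint at TSS+110
  anch <- data.frame(gene_id = "g1", chrom = "chr1", tss = 2000L,
                     strand = "+", stringsAsFactors = FALSE)
  f <- make_frags(2110 - 75, 150)
  m <- tss_matrix(f, anch, window_bp = 300L)
  expect_identical(dim(m), c(1L, 600L))
  peak_cols <- as.integer(colnames(m))[m[1L, ] == max(m[1L, ])]
  expect_true(all(peak_cols >= 35 & peak_cols <= 185))
  expect_true(110 %in% peak_cols)
  # mirror the genome: the minus-strand version must be bit-identical
  L <- 4000L
  anch_m <- data.frame(gene_id = "g1", chrom = "chr1", tss = L - 1L - 2000L,
                       strand = "-", stringsAsFactors = FALSE)
  f_m <- data.frame(chrom = "chr1", start = L - f$end, end = L - f$start,
                    sample = f$sample, stringsAsFactors = FALSE)
  m_m <- tss_matrix(f_m, anch_m, window_bp = 300L)
  expect_identical(unclass(m)[, ], unclass(m_m)[, ])
})

test_that("strand reflection leaves a whole random matrix bit-identical", {
  set.seed(10)
  f <- random_frags(300)
  anch <- data.frame(gene_id = paste0("g", 1:5), chrom = "chr1",
                     tss = as.integer(seq(900, 4100, length.out = 5)),
                     strand = sample(c("+", "-"), 5, replace = TRUE),
                     stringsAsFactors = FALSE)
  m <- tss_matrix(f, anch, window_bp = 200L)
  L <- 6000L
  f_m <- data.frame(chrom = "chr1", start = L - f$end, end = L - f$start,
                    sample = f$sample, stringsAsFactors = FALSE)
  anch_m <- anch
  anch_m$tss <- L - 1L - anch$tss
  anch_m$strand <- ifelse(anch$strand == "+", "-", "+")
  m_m <- tss_matrix(f_m, anch_m, window_bp = 200L)
  expect_identical(unclass(m)[, ], unclass(m_m)[, ])
})

test_that("windows running off the chromosome are zero-padded and
           flagged; no fragments give a zero matrix", {
  anch <- data.frame(gene_id = "edge", chrom = "chr1", tss = 50L,
                     strand = "+", stringsAsFactors = FALSE)
  f <- make_frags(0, 30)
  m <- tss_matrix(f, anch, window_bp = 100L)
  expect_identical(attr(m, "clipped"), "edge")
  expect_identical(unname(m[1L, as.character(-100:-51)]), rep(0L, 50L))
  empty <- f[0, ]
  m0 <- tss_matrix(empty, anch, window_bp = 100L)
  expect_true(all(m0 == 0L))
})

test_that("aggregate profile normalises per gene then averages columns", {
  anch <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                     tss = c(1000L, 3000L), strand = "+",
                     stringsAsFactors = FALSE)
  f <- rbind(make_frags(c(1050, 3050), c(150, 150)))
  m <- tss_matrix(f, anch, window_bp = 200L)
  prof <- aggregate_profile(m)
  expect_equal(unname(prof), unname(unclass(m)[1L, ] / mean(m[1L, ])),
               tolerance = 1e-12)
  # zero rows are excluded from the mean, not averaged in as zeros
  anch3 <- rbind(anch, data.frame(gene_id = "c", chrom = "chr1",
                                  tss = 4500L, strand = "+"))
  m3 <- tss_matrix(f, anch3, window_bp = 200L)
  expect_equal(aggregate_profile(m3), prof, tolerance = 1e-12)
  expect_error(aggregate_profile(m3[0, ]), "empty")
})

test_that("fold enrichment is 1 for identical samples and approaches the
           count ratio for large counts", {
  set.seed(11)
  f <- random_frags(400)
  anch <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                     tss = c(1500L, 3500L), strand = "+",
                     stringsAsFactors = FALSE)
  enr <- gene_enrichment(f, f, anch, window_bp = 500L)
  expect_equal(enr$fold, c(1, 1))
  # IP counts exactly 5x control at equal library size: pseudocount vanishes
  folds <- vapply(c(10L, 100L, 1000L), function(c0) {
    ctrl <- make_frags(rep(1500L, c0), 100)
    ip <- make_frags(rep(1500L, 5L * c0), 100)
    libpad_ctrl <- make_frags(rep(100000L, 5L * c0 - c0), 100)
    gene_enrichment(ip, rbind(ctrl, libpad_ctrl),
                    data.frame(gene_id = "g", chrom = "chr1", tss = 1500L,
                               strand = "+"),
                    window_bp = 500L)$fold
  }, numeric(1))
  expect_true(all(abs(folds - 5) < c(0.5, 0.05, 0.005)))
  expect_error(gene_enrichment(f[0, ], f, anch), "zero library")
})

test_that("fold enrichment is invariant to scaling both libraries", {
  set.seed(12)
  f1 <- random_frags(200); f2 <- random_frags(300)
  anch <- data.frame(gene_id = "g1", chrom = "chr1", tss = 2500L,
                     strand = "+", stringsAsFactors = FALSE)
  base <- gene_enrichment(f1, f2, anch)$fold
  trip <- gene_enrichment(f1[rep(1:200, 3), ], f2[rep(1:300, 3), ],
                          anch)$fold
  # counts in windows triple along with library sizes; pseudocount keeps
  # this approximate, converging as counts grow
  expect_equal(base, trip, tolerance = 0.05)
})

test_that("window occupancy difference: null gives zero effect and p = 1;
           fuzziness difference is detected downstream", {
  sim <- simulate_mnase_fragments(fragment_sim_config(
    n_genes = 120L, fuzziness_bp = 10, seed = 13))
  anch <- sim$anchors[sim$truth$enriched, ]
  m <- tss_matrix(filter_by_insert_size(sim$ip), anch, window_bp = 500L)
  same <- window_occupancy_difference(m, m, n_boot = 500, seed = 1)
  expect_equal(same$effect, c(0, 0))
  expect_equal(same$p_value, c(1, 1))
  sim2 <- simulate_mnase_fragments(fragment_sim_config(
    n_genes = 120L, fuzziness_bp = 60, seed = 14))
  anch2 <- sim2$anchors[sim2$truth$enriched, ]
  rownames_match <- intersect(anch$gene_id, anch2$gene_id)
  m2 <- tss_matrix(filter_by_insert_size(sim2$ip), anch2,
                   window_bp = 500L)
  d <- window_occupancy_difference(m, m2, n_boot = 2000, seed = 2)
  down <- d[d$window == "downstream", ]
  expect_gt(down$effect, 0)    # sharp +1 packs more occupancy at +100..200
  expect_lt(down$p_value, 0.05)
})

test_that("bootstrap p of the window difference tracks a sign-flip
           permutation oracle on small fixed inputs", {
  set.seed(15)
  n_genes <- 40L
  mk <- function(shift) {
    m <- matrix(rpois(n_genes * 40L, 5) + 1, n_genes, 40L,
                dimnames = list(paste0("g", 1:n_genes),
                                as.character(-20:19)))
    m[, as.character(0:9)] <- m[, as.character(0:9)] + shift
    structure(m, window_bp = 20L)
  }
  a <- mk(shift = matrix(rpois(n_genes * 10L, 1), n_genes))
  b <- mk(shift = 0L)
  win <- list(test = c(0L, 9L))
  res <- window_occupancy_difference(a, b, windows = win,
                                     n_boot = 20000, seed = 3)
  # oracle: paired sign-flip permutation of the per-gene differences
  norm_rows <- function(m) m / rowMeans(m)
  va <- rowMeans(norm_rows(a)[, as.character(0:9)])
  vb <- rowMeans(norm_rows(b)[, as.character(0:9)])
  d <- va - vb
  set.seed(4)
  perm <- replicate(20000, mean(d * sample(c(-1, 1), length(d),
                                           replace = TRUE)))
  p_perm <- mean(abs(perm) >= abs(mean(d)))
  expect_lt(abs(res$p_value - p_perm), 0.02)
})
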