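test_that("Otsu threshold splits a clearly bimodal sample and matches the
           brute-force scan", {
  set.seed(2)
  x <- c(rnorm(500, 2, 0.1), rnorm(500, 10, 0.1))
  t_pkg <- otsu_threshold(x)
  expect_gt(t_pkg, 3)
  expect_lt(t_pkg, 9)
  expect_equal(t_pkg, oracle_otsu(x), tolerance = 1e-12)
  # also on an unbalanced mixture
  y <- c(rnorm(900, 1, 0.2), rnorm(100, 6, 0.3))
  expect_equal(otsu_threshold(y), oracle_otsu(y), tolerance = 1e-12)
})

test_that("degenerate distance distributions are an error", {
  expect_error(otsu_threshold(rep(4, 500)), "degenerate")
  prof <- data.frame(molecule_id = "m", bp_index = 0:460,
                     distance_px = rep(2, 461))
  expect_error(calibrate_threshold(prof), "degenerate")
  expect_error(calibrate_threshold(prof[1:50, ]), "at least 100")
  expect_equal(calibrate_threshold(NULL, method = "fixed", fixed_px = 4.2),
               4.2)
})

test_that("threshold calibrated on simulated data falls between the duplex
           and open separations", {
  cfg <- trace_sim_config(n_molecules = 30L, lambda_true = 1.3, seed = 40)
  ds <- simulate_trace_dataset(cfg)
  thr <- calibrate_threshold(profile_molecules(ds$traces))
  expect_gt(thr, cfg$duplex_sep_px)
  expect_lt(thr, cfg$open_sep_px)
})

test_that("single-stranded labelling is strictly greater-than", {
  prof <- data.frame(molecule_id = "m", bp_index = 0:4,
                     distance_px = c(1, 5, 5.0000001, 4.9999999, 9))
  expect_identical(label_single_stranded(prof, 5),
                   c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_identical(label_single_stranded(prof, 10), rep(FALSE, 5L))
  expect_error(label_single_stranded(prof, 0), "threshold")
})

test_that("segmentation returns maximal runs as half-open spans", {
  lab <- rep(FALSE, 461)
  expect_identical(nrow(segment_bubbles(lab, 0L, 0L)), 0L)
  lab[11:60] <- TRUE
  lab[101:250] <- TRUE
  b <- segment_bubbles(lab, close_gap_bp = 0L, drop_len_bp = 0L)
  expect_identical(b$start_bp, c(10L, 100L))
  expect_identical(b$end_bp, c(60L, 250L))
  expect_identical(b$length_bp, c(50L, 150L))
})

test_that("segmentation matches a brute-force run-length oracle on random
           vectors", {
  set.seed(7)
  for (i in 1:1000) {
    lab <- runif(60) < runif(1)
    b <- segment_bubbles(lab, close_gap_bp = 0L, drop_len_bp = 0L)
    o <- oracle_runs(lab)
    if (is.null(o)) {
      expect_identical(nrow(b), 0L)
    } else {
      expect_identical(b$start_bp, unname(o[, "start"]))
      expect_identical(b$end_bp, unname(o[, "end"]))
    }
  }
})

test_that("morphological cleanup closes small gaps then drops short runs", {
  lab <- rep(FALSE, 40)
  lab[c(5:10, 13:20)] <- TRUE   # 2-bp gap at 11:12
  lab[30:32] <- TRUE            # short 3-bp run
  b <- segment_bubbles(lab, close_gap_bp = 2L, drop_len_bp = 3L)
  expect_identical(b$start_bp, 4L)
  expect_identical(b$end_bp, 20L)
  # leading/trailing false runs are never "closed"
  lab2 <- c(TRUE, rep(FALSE, 38), TRUE)
  expect_identical(nrow(segment_bubbles(lab2, 2L, 0L)), 2L)
})

test_that("nucleosome rule is strict at 90 bp and fusions count once", {
  mk <- function(lens) {
    start <- cumsum(c(0L, head(lens, -1L) + 10L))
    data.frame(molecule_id = "m", start_bp = start,
               end_bp = start + lens, length_bp = lens)
  }
  expect_identical(call_nucleosomes(mk(90L))$nucleosome_count, 0L)
  expect_identical(call_nucleosomes(mk(91L))$nucleosome_count, 1L)
  call300 <- call_nucleosomes(mk(300L))
  expect_identical(call300$nucleosome_count, 1L)
  expect_true(call300$bubbles$is_fusion_suspect)
  expect_identical(call_nucleosomes(mk(c(50L, 95L, 95L)))$nucleosome_count,
                   2L)
  # sensitivity-only divide policy splits long fusions
  expect_identical(
    call_nucleosomes(mk(300L), fusion_policy = "divide")$nucleosome_count,
    2L)
})

test_that("nucleosome counts are monotone in threshold (calibrated
           regime) and in the length rule", {
  # counts are non-increasing in the threshold wherever raising it cannot
  # split a bubble: on noise-free data that is the whole regime between
  # the inter-bubble saddle separation and the open plateau
  cfg <- trace_sim_config(n_molecules = 20L, lambda_true = 1.5,
                          coord_noise_px = 0, seed = 41)
  prof <- profile_molecules(simulate_trace_dataset(cfg)$traces)
  # below ~4.5 px neighbouring bubbles can merge across their ramp saddle
  # (a fusion), so the count is only monotone above the saddle separation
  thrs <- seq(5, 9, by = 0.5)
  tot_thr <- vapply(thrs, function(t)
    sum(call_dataset(prof, t)$counts), integer(1))
  expect_true(all(diff(tot_thr) <= 0L))
  # the length rule is monotone unconditionally, also under noise
  cfg2 <- trace_sim_config(n_molecules = 20L, lambda_true = 1.5,
                           seed = 41)
  prof2 <- profile_molecules(simulate_trace_dataset(cfg2)$traces)
  lens <- c(30L, 60L, 90L, 120L, 150L)
  for (p in list(prof, prof2)) {
    tot_len <- vapply(lens, function(l)
      sum(call_dataset(p, 6, min_len_bp = l)$counts), integer(1))
    expect_true(all(diff(tot_len) <= 0L))
  }
})

test_that("per-molecule calls are local: batching molecules together does
           not change any call", {
  cfg <- trace_sim_config(n_molecules = 8L, lambda_true = 1.5, seed = 42)
  prof <- profile_molecules(simulate_trace_dataset(cfg)$traces)
  joint <- call_dataset(prof, 6, close_gap_bp = 0L, drop_len_bp = 0L)
  for (id in unique(prof$molecule_id)) {
    single <- call_dataset(prof[prof$molecule_id == id, ], 6,
                           close_gap_bp = 0L, drop_len_bp = 0L)
    expect_identical(unname(single$counts), unname(joint$counts[id]))
  }
})
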