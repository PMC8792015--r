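test_that("base calibration: scale is arc length over template length", {
  s <- straight_strand("A", 461)
  pos <- assign_base_positions(s, 461L)
  expect_equal(pos[, 1L], (0:460) + 0.5, tolerance = 1e-12)
  expect_equal(pos[, 2L], rep(0, 461), tolerance = 1e-12)
  # same 461 bp template read from a 922 px trace: 2 px/bp
  s2 <- straight_strand("A", 922)
  pos2 <- assign_base_positions(s2, 461L)
  expect_equal(pos2[, 1L], 2 * ((0:460) + 0.5), tolerance = 1e-12)
})

test_that("interpolated base positions match a dense-resampling oracle", {
  set.seed(1)
  for (rep in 1:5) {
    pts <- cbind(cumsum(runif(40, 0.5, 3)), cumsum(rnorm(40, 0, 1.5)))
    s <- strand_trace("A", pts)
    pos <- assign_base_positions(s, 200L)
    # oracle: walk the polyline segment by segment
    seg <- diff(c(0, cumsum(sqrt(rowSums(diff(pts)^2)))))
    cum <- c(0, cumsum(seg))
    total <- cum[length(cum)]
    at <- ((0:199) + 0.5) * total / 200
    oracle <- t(vapply(at, function(a) {
      i <- max(which(cum <= a + 1e-12))
      i <- min(i, nrow(pts) - 1L)
      f <- (a - cum[i]) / seg[i]
      pts[i, ] + f * (pts[i + 1L, ] - pts[i, ])
    }, numeric(2)))
    expect_lt(max(abs(pos - oracle)), 1e-6)
  }
})

test_that("degenerate strands are rejected", {
  expect_error(strand_trace("A", matrix(c(0, 0), 1, 2)), "at least 2")
  expect_error(strand_trace("A", rbind(c(0, 0), c(0, 0))), "distinct")
})

test_that("parallel strands give a constant profile; a strand against
           itself gives zero", {
  m <- parallel_molecule(sep = 5)
  prof <- pair_and_profile(m)
  expect_equal(prof$distance_px, rep(5, 461), tolerance = 1e-9)
  expect_identical(prof$bp_index, 0:460)
  self <- molecule_trace("self", straight_strand("A", 461),
                         straight_strand("B", 461), 461L)
  expect_equal(pair_and_profile(self)$distance_px, rep(0, 461),
               tolerance = 1e-12)
})

test_that("a reversed strand B is restored by orientation and the profile
           matches the co-oriented molecule", {
  cfg <- trace_sim_config(n_molecules = 4L, lambda_true = 1.5,
                          coord_noise_px = 0, flip_prob = 0, seed = 30)
  ds <- simulate_trace_dataset(cfg)
  m <- ds$traces[[2L]]
  ref <- pair_and_profile(orient_strands(m))
  flipped <- m
  flipped$strand_b$points <-
    m$strand_b$points[rev(seq_len(nrow(m$strand_b$points))), ]
  out <- orient_strands(flipped)
  expect_false(out$ambiguous_orientation)
  expect_identical(out$strand_b$points, m$strand_b$points)
  expect_equal(pair_and_profile(out)$distance_px, ref$distance_px,
               tolerance = 1e-12)
})

test_that("orientation ties are flagged ambiguous", {
  a <- straight_strand("A", 10)
  b <- strand_trace("B", rbind(c(5, -1), c(5, 1)))
  m <- molecule_trace("tie", a, b, 10L)
  expect_true(orient_strands(m)$ambiguous_orientation)
})

test_that("profiles are isometry invariant and scale proportionally", {
  cfg <- trace_sim_config(n_molecules = 2L, lambda_true = 1.5, seed = 31)
  ds <- simulate_trace_dataset(cfg)
  m <- orient_strands(ds$traces[[1L]])
  prof <- pair_and_profile(m)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  shift <- c(-37.5, 112.25)
  mv <- m
  mv$strand_a$points <- sweep(m$strand_a$points %*% R, 2L, shift, "+")
  mv$strand_b$points <- sweep(m$strand_b$points %*% R, 2L, shift, "+")
  expect_lt(max(abs(pair_and_profile(mv)$distance_px - prof$distance_px)),
            1e-6)
  ms <- m
  ms$strand_a$points <- 3.7 * m$strand_a$points
  ms$strand_b$points <- 3.7 * m$strand_b$points
  expect_equal(pair_and_profile(ms)$distance_px, 3.7 * prof$distance_px,
               tolerance = 1e-9)
})

test_that("closest-distance pairing reproduces the planted separation on
           noise-free molecules", {
  # a straight backbone keeps per-strand arc length proportional to bp
  # (no curvature or ramp path-length distortion of the base mapping), so
  # the measured profile must match the planted separation to
  # interpolation error away from the ramp shoulders
  cfg <- trace_sim_config(n_molecules = 6L, lambda_true = 1.3,
                          coord_noise_px = 0, point_spacing_bp = 1L,
                          turn_sd_rad = 0, seed = 32)
  ds <- simulate_trace_dataset(cfg)
  prof <- profile_molecules(ds$traces)
  for (id in unique(prof$molecule_id)) {
    tr <- ds$truth[ds$truth$molecule_id == id, ]
    p <- prof[prof$molecule_id == id, ]
    for (j in seq_len(nrow(tr))) {
      core <- (tr$start_bp[j] + 5L):(tr$end_bp[j] - 4L)
      expect_lt(max(abs(p$distance_px[core] - cfg$open_sep_px)), 0.1)
    }
    outside <- setdiff(seq_len(461),
                       unlist(lapply(seq_len(nrow(tr)), function(j)
                         (tr$start_bp[j] - 4L):(tr$end_bp[j] + 5L))))
    outside <- outside[outside >= 1L & outside <= 461L]
    expect_lt(max(abs(p$distance_px[outside] - cfg$duplex_sep_px)), 0.1)
  }
})

test_that("mismatched strand arc lengths raise the QC flag", {
  m <- molecule_trace("qc", straight_strand("A", 461),
                      straight_strand("B", 300, y = 2), 461L)
  expect_true(orient_strands(m)$arc_length_flag)
  expect_false(orient_strands(parallel_molecule())$arc_length_flag)
})
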