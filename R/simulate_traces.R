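#' Configuration for the synthetic EM trace generator
#'
#' Defines the study conditions for simulated psoralen-crosslink EM molecules:
#' a template of known length carries 0--5 nucleosome-sized single-stranded
#' bubbles (per-molecule counts approximately Poisson, truncated by physical
#' packing) plus occasional sub-threshold small bubbles. Strands are rendered
#' as polylines along a smooth random backbone, separated by `duplex_sep_px`
#' where the duplex is crosslinked and opening to `open_sep_px` inside
#' bubbles.
#'
#' Nucleosome-bubble lengths are drawn from a normal distribution truncated at
#' `bubble_len_trunc_sd` standard deviations (default 147 +/- 3x15 bp, i.e.
#' 102--192 bp): a bubble left by a real octamer footprint cannot be much
#' shorter than ~100 bp. The strand separation ramps smoothly (cosine
#' shoulder of half-width `ramp_halfwidth_bp`) across each planted span edge,
#' crossing the duplex/open midpoint exactly at the span boundary, so the
#' noise-free separation is strictly above the midpoint at every base inside
#' a planted span and strictly below outside.
#'
#' @param template_len_bp Template length in bp (default 461).
#' @param n_molecules Number of molecules to simulate.
#' @param lambda_true Mean nucleosome-sized bubbles per molecule before
#'   packing truncation.
#' @param bubble_len_mean,bubble_len_sd Nucleosome bubble length distribution
#'   (bp).
#' @param bubble_len_trunc_sd Truncation of the length distribution in SD
#'   units.
#' @param small_bubble_rate Expected sub-threshold (non-nucleosome) bubbles
#'   per molecule.
#' @param small_bubble_len_range Length range (bp) of small bubbles.
#' @param px_per_bp Rendering scale, pixels per base pair.
#' @param duplex_sep_px Inter-strand separation of crosslinked duplex
#'   regions.
#' @param open_sep_px Peak inter-strand separation inside a bubble; must
#'   exceed `duplex_sep_px` by at least `2 * coord_noise_px`.
#' @param coord_noise_px Gaussian jitter SD added to every rendered
#'   coordinate.
#' @param min_gap_bp Minimum duplex gap between planted bubbles (>= 1).
#' @param point_spacing_bp Spacing of rendered polyline vertices along the
#'   strand, in bp (tracing "click density").
#' @param ramp_halfwidth_bp Half-width of the cosine opening shoulder.
#' @param turn_sd_rad Per-bp SD of backbone turning angle before smoothing.
#' @param curvature_smooth_bp Running-mean window (bp) applied to turning
#'   angles.
#' @param flip_prob Probability that strand B is recorded in reversed order,
#'   exercising orientation recovery.
#' @param seed Integer RNG seed recorded in the dataset metadata.
#' @return A validated `trace_sim_config` list.
#' @export
trace_sim_config <- function(template_len_bp = 461L,
                             n_molecules = 150L,
                             lambda_true = 1.3,
                             bubble_len_mean = 147,
                             bubble_len_sd = 15,
                             bubble_len_trunc_sd = 3,
                             small_bubble_rate = 0.2,
                             small_bubble_len_range = c(20L, 60L),
                             px_per_bp = 2,
                             duplex_sep_px = 2,
                             open_sep_px = 10,
                             coord_noise_px = 0.5,
                             min_gap_bp = 5L,
                             point_spacing_bp = 4L,
                             ramp_halfwidth_bp = 2,
                             turn_sd_rad = 0.05,
                             curvature_smooth_bp = 11L,
                             flip_prob = 0.5,
                             seed = 1L) {
  cfg <- list(template_len_bp = as.integer(template_len_bp),
              n_molecules = as.integer(n_molecules),
              lambda_true = lambda_true,
              bubble_len_mean = bubble_len_mean,
              bubble_len_sd = bubble_len_sd,
              bubble_len_trunc_sd = bubble_len_trunc_sd,
              small_bubble_rate = small_bubble_rate,
              small_bubble_len_range = as.integer(small_bubble_len_range),
              px_per_bp = px_per_bp,
              duplex_sep_px = duplex_sep_px,
              open_sep_px = open_sep_px,
              coord_noise_px = coord_noise_px,
              min_gap_bp = as.integer(min_gap_bp),
              point_spacing_bp = as.integer(point_spacing_bp),
              ramp_halfwidth_bp = ramp_halfwidth_bp,
              turn_sd_rad = turn_sd_rad,
              curvature_smooth_bp = as.integer(curvature_smooth_bp),
              flip_prob = flip_prob,
              seed = as.integer(seed))
  validate_trace_sim_config(cfg)
  structure(cfg, class = "trace_sim_config")
}

validate_trace_sim_config <- function(cfg) {
  stopifnot(cfg$template_len_bp > 0L, cfg$n_molecules >= 0L,
            cfg$lambda_true >= 0, cfg$px_per_bp > 0,
            cfg$duplex_sep_px >= 0, cfg$coord_noise_px >= 0,
            cfg$min_gap_bp >= 1L, cfg$point_spacing_bp >= 1L,
            cfg$small_bubble_rate >= 0)
  if (cfg$open_sep_px <= cfg$duplex_sep_px)
    stop("open_sep_px must exceed duplex_sep_px")
  if (cfg$open_sep_px - cfg$duplex_sep_px < 2 * cfg$coord_noise_px)
    stop("open/duplex separations are not distinguishable given noise: ",
         "need open_sep_px - duplex_sep_px >= 2 * coord_noise_px")
  if (cfg$lambda_true * cfg$bubble_len_mean > cfg$template_len_bp)
    warning("lambda_true x mean bubble length exceeds the template length; ",
            "counts will be strongly truncated by packing")
  invisible(cfg)
}

# truncated-normal lengths for nucleosome bubbles (rejection sampling)
rtrunc_lengths <- function(k, mean, sd, trunc_sd) {
  lo <- mean - trunc_sd * sd
  hi <- mean + trunc_sd * sd
  out <- numeric(0)
  while (length(out) < k) {
    x <- rnorm(2L * (k - length(out)) + 4L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  round(out[seq_len(k)])
}

# place k intervals of the given lengths with >= gap bp between them,
# uniformly over the feasible arrangements; returns start positions or NULL
place_spans <- function(lens, template_len, gap) {
  k <- length(lens)
  if (k == 0L) return(integer(0))
  slack <- template_len - sum(lens) - (k - 1L) * gap
  if (slack < 0) return(NULL)
  cuts <- sort(runif(k, 0, slack))
  extra <- floor(c(cuts[1L], diff(cuts)))   # k leading free gaps
  starts <- integer(k)
  pos <- 0L
  for (i in seq_len(k)) {
    pos <- pos + extra[i]
    starts[i] <- pos
    pos <- pos + lens[i] + gap
  }
  starts
}

# per-molecule planted spans honouring packing: Poisson count, decremented
# when the drawn lengths cannot fit (rejection-resample of lengths first)
plant_molecule_spans <- function(cfg) {
  k <- rpois(1L, cfg$lambda_true)
  spans <- NULL
  while (is.null(spans)) {
    ok <- FALSE
    for (try in seq_len(60L)) {
      lens <- rtrunc_lengths(k, cfg$bubble_len_mean, cfg$bubble_len_sd,
                             cfg$bubble_len_trunc_sd)
      starts <- place_spans(lens, cfg$template_len_bp, cfg$min_gap_bp)
      if (!is.null(starts)) { ok <- TRUE; break }
    }
    if (ok || k == 0L) {
      if (!ok) { lens <- numeric(0); starts <- integer(0) }
      spans <- data.frame(start = as.integer(starts),
                          end = as.integer(starts + lens))
    } else k <- k - 1L
  }
  # sub-threshold small bubbles, dropped when they cannot be placed
  m <- rpois(1L, cfg$small_bubble_rate)
  if (m > 0L) {
    rng <- cfg$small_bubble_len_range
    for (i in seq_len(m)) {
      len <- sample(rng[1L]:rng[2L], 1L)
      for (try in seq_len(30L)) {
        s <- sample.int(cfg$template_len_bp - len + 1L, 1L) - 1L
        e <- s + len
        clear <- nrow(spans) == 0L ||
          all(s >= spans$end + cfg$min_gap_bp |
              e <= spans$start - cfg$min_gap_bp)
        if (clear) {
          spans <- rbind(spans, data.frame(start = s, end = e))
          break
        }
      }
    }
  }
  spans <- spans[order(spans$start), , drop = FALSE]
  rownames(spans) <- NULL
  spans
}

# separation (px) at continuous bp positions x for a set of planted spans;
# cosine shoulder of half-width w crossing the duplex/open midpoint at the
# span boundary
planted_separation <- function(x, spans, cfg) {
  w <- cfg$ramp_halfwidth_bp
  openness <- numeric(length(x))
  for (i in seq_len(nrow(spans))) {
    d <- pmin(x - spans$start[i], spans$end[i] - x)  # signed depth into span
    o <- ifelse(d <= -w, 0,
                ifelse(d >= w, 1, (1 + sin(pi * d / (2 * w))) / 2))
    openness <- pmax(openness, o)
  }
  cfg$duplex_sep_px + (cfg$open_sep_px - cfg$duplex_sep_px) * openness
}

render_molecule <- function(molecule_id, spans, cfg) {
  n <- cfg$template_len_bp
  xs <- seq(0, n, by = 1)                     # backbone sampled every bp
  dtheta <- rnorm(length(xs) - 1L, 0, cfg$turn_sd_rad)
  w <- cfg$curvature_smooth_bp
  if (w > 1L) {
    sm <- stats::filter(dtheta, rep(1 / w, w), sides = 2)
    dtheta <- ifelse(is.na(sm), dtheta, as.numeric(sm))
  }
  theta <- cumsum(c(runif(1, 0, 2 * pi), dtheta))
  bx <- c(0, cumsum(cos(theta[-1L]) * cfg$px_per_bp))
  by <- c(0, cumsum(sin(theta[-1L]) * cfg$px_per_bp))
  nx <- -sin(theta); ny <- cos(theta)         # unit normals
  sep <- planted_separation(xs, spans, cfg)
  ax <- bx + nx * sep / 2; ay <- by + ny * sep / 2
  bx2 <- bx - nx * sep / 2; by2 <- by - ny * sep / 2
  keep <- unique(c(seq(1L, length(xs), by = cfg$point_spacing_bp),
                   length(xs)))
  a <- cbind(ax[keep], ay[keep])
  b <- cbind(bx2[keep], by2[keep])
  if (cfg$coord_noise_px > 0) {
    a <- a + matrix(rnorm(length(a), 0, cfg$coord_noise_px), ncol = 2L)
    b <- b + matrix(rnorm(length(b), 0, cfg$coord_noise_px), ncol = 2L)
  }
  if (runif(1) < cfg$flip_prob) b <- b[rev(seq_len(nrow(b))), , drop = FALSE]
  molecule_trace(molecule_id,
                 strand_trace("A", a), strand_trace("B", b),
                 cfg$template_len_bp)
}

#' Simulate a psoralen-EM trace dataset with planted bubbles
#'
#' Draws per-molecule nucleosome-sized bubble counts from a packing-truncated
#' Poisson distribution, plants non-overlapping bubble spans (plus occasional
#' sub-threshold small bubbles), and renders each molecule as two noisy
#' strand polylines along a smooth random backbone. The ground-truth table
#' records every planted span with its size class, so downstream bubble
#' calling can be scored molecule by molecule.
#'
#' @param cfg A [trace_sim_config()].
#' @return A list of class `trace_sim` with elements `traces` (list of
#'   [molecule_trace()]), `truth` (data frame: `molecule_id`, `start_bp`,
#'   `end_bp`, `length_bp`, `size_class`), `planted_counts` (named integer
#'   vector of nucleosome-sized bubbles per molecule), and `config`.
#' @export
simulate_trace_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "trace_sim_config"))
  set.seed(cfg$seed)
  traces <- vector("list", cfg$n_molecules)
  truth <- vector("list", cfg$n_molecules)
  counts <- integer(cfg$n_molecules)
  ids <- sprintf("mol%04d", seq_len(cfg$n_molecules))
  for (i in seq_len(cfg$n_molecules)) {
    spans <- plant_molecule_spans(cfg)
    traces[[i]] <- render_molecule(ids[i], spans, cfg)
    len <- spans$end - spans$start
    counts[i] <- sum(len > 90L)
    truth[[i]] <- if (nrow(spans))
      data.frame(molecule_id = ids[i],
                 start_bp = spans$start, end_bp = spans$end,
                 length_bp = len,
                 size_class = ifelse(len > 90L, "nucleosome", "small"),
                 stringsAsFactors = FALSE)
    else NULL
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth))
    truth <- data.frame(molecule_id = character(0), start_bp = integer(0),
                        end_bp = integer(0), length_bp = integer(0),
                        size_class = character(0))
  names(counts) <- ids
  structure(list(traces = traces, truth = truth,
                 planted_counts = counts, config = cfg),
            class = "trace_sim")
}
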