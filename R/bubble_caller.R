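#' Calibrate the single-stranded distance threshold
#'
#' The distance separating "closed" (crosslinked duplex) from "open"
#' (bubble) base pairs is determined empirically from the pooled per-base
#' inter-strand distances. The default method is Otsu's two-class split of
#' the pooled histogram, which maximises between-class variance and is
#' deterministic; a fixed threshold can be supplied instead.
#'
#' @param profiles A `distance_profile` data frame (one or several molecules
#'   row-bound), or a list of them.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_px Threshold in pixels when `method = "fixed"`.
#' @param n_bins Histogram bins for the Otsu scan.
#' @return Threshold in pixels, strictly between the pooled minimum and
#'   maximum distance.
#' @export
calibrate_threshold <- function(profiles, method = c("otsu", "fixed"),
                                fixed_px = NULL, n_bins = 256L) {
  method <- match.arg(method)
  if (method == "fixed") {
    stopifnot(is.numeric(fixed_px), fixed_px > 0)
    return(fixed_px)
  }
  if (is.data.frame(profiles)) profiles <- list(profiles)
  d <- unlist(lapply(profiles, `[[`, "distance_px"), use.names = FALSE)
  if (length(d) < 100L)
    stop("need at least 100 pooled base records to calibrate a threshold")
  otsu_threshold(d, n_bins = n_bins)
}

#' Otsu's method on a numeric sample
#'
#' Bins the sample and returns the bin edge maximising the between-class
#' variance of the two-class split; when a plateau of splits ties for the
#' maximum (an empty gap between two tight modes), the plateau centre is
#' returned. Degenerate (effectively unimodal or constant) samples, where
#' no split yields positive between-class variance, are an error: set a
#' manual threshold instead.
#'
#' @param x Numeric vector.
#' @param n_bins Number of histogram bins.
#' @return Threshold strictly between `min(x)` and `max(x)`.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) <= 0)
    stop("degenerate distance distribution: set a manual threshold")
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE),
                     n_bins), nbins = n_bins)
  p <- h / sum(h)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sb2 <- numeric(n_bins)
  sb2[valid] <- (mu_t * w0[valid] - mu0[valid])^2 / (w0[valid] * w1[valid])
  if (max(sb2) <= 0)
    stop("degenerate distance distribution: set a manual threshold")
  at_max <- which(sb2 >= max(sb2) * (1 - 1e-12))
  mean(edges[at_max + 1L])
}

#' Label single-stranded base pairs
#'
#' A base pair is labelled single-stranded when its inter-strand distance
#' strictly exceeds the threshold; a distance exactly equal to the threshold
#' is double-stranded.
#'
#' @param profile A `distance_profile` for one molecule.
#' @param threshold_px Positive distance threshold.
#' @return Logical vector, one element per base.
#' @export
label_single_stranded <- function(profile, threshold_px) {
  stopifnot(is.numeric(threshold_px), threshold_px > 0)
  profile$distance_px > threshold_px
}

#' Segment contiguous single-stranded stretches into bubbles
#'
#' Maximal runs of single-stranded labels become bubbles, reported as
#' 0-based half-open spans. Optional morphological cleanup first closes
#' double-stranded gaps of at most `close_gap_bp` bases between bubbles,
#' then drops bubbles of at most `drop_len_bp` bases; both default small and
#' both at 0 give the literal run-length behaviour.
#'
#' @param labels Logical vector from [label_single_stranded()].
#' @param close_gap_bp Close internal gaps of at most this many bases.
#' @param drop_len_bp Drop runs of at most this many bases.
#' @param molecule_id Optional molecule label carried into the output.
#' @return Data frame: `molecule_id`, `start_bp`, `end_bp`, `length_bp`;
#'   spans disjoint and sorted.
#' @export
segment_bubbles <- function(labels, close_gap_bp = 2L, drop_len_bp = 3L,
                            molecule_id = NA_character_) {
  stopifnot(is.logical(labels))
  labels[is.na(labels)] <- FALSE
  if (close_gap_bp > 0L && any(labels)) {
    r <- rle(labels)
    k <- length(r$values)
    inner_gap <- !r$values & r$lengths <= close_gap_bp &
      seq_len(k) > 1L & seq_len(k) < k
    r$values[inner_gap] <- TRUE
    labels <- inverse.rle(r)
  }
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths > drop_len_bp
  out <- data.frame(molecule_id = rep(molecule_id, sum(keep)),
                    start_bp = starts[keep], end_bp = ends[keep],
                    stringsAsFactors = FALSE)
  out$length_bp <- out$end_bp - out$start_bp
  out
}

#' Call nucleosomes from segmented bubbles
#'
#' A bubble is a nucleosome when its length strictly exceeds `min_len_bp`
#' (default 90 bp). Unusually long bubbles (length > `fusion_suspect_len`)
#' are flagged as possible fusions of adjacent nucleosomes; under the
#' default policy `"single"` a fusion still counts as one nucleosome. The
#' alternative policy `"divide"` counts `max(1, floor(length / 147))`
#' nucleosomes per nucleosome-sized bubble, for sensitivity analysis only.
#'
#' @param bubbles Data frame from [segment_bubbles()].
#' @param min_len_bp Strict nucleosome length threshold (bp).
#' @param fusion_policy `"single"` (default) or `"divide"`.
#' @param fusion_suspect_len Bubbles longer than this (bp) are flagged
#'   `is_fusion_suspect`.
#' @param threshold_px Distance threshold used upstream, recorded in the
#'   call.
#' @return A `bubble_call` list: `molecule_id`, `bubbles` (with
#'   `is_nucleosome`, `is_fusion_suspect`), `nucleosome_count`,
#'   `threshold_px`.
#' @export
call_nucleosomes <- function(bubbles, min_len_bp = 90L,
                             fusion_policy = c("single", "divide"),
                             fusion_suspect_len = 240L,
                             threshold_px = NA_real_) {
  fusion_policy <- match.arg(fusion_policy)
  bubbles$is_nucleosome <- bubbles$length_bp > min_len_bp
  bubbles$is_fusion_suspect <- bubbles$length_bp > fusion_suspect_len
  count <- if (fusion_policy == "single") {
    sum(bubbles$is_nucleosome)
  } else {
    sum(pmax(1L, floor(bubbles$length_bp[bubbles$is_nucleosome] / 147)))
  }
  structure(list(molecule_id = if (nrow(bubbles))
                   bubbles$molecule_id[1L] else NA_character_,
                 bubbles = bubbles,
                 nucleosome_count = as.integer(count),
                 threshold_px = threshold_px),
            class = "bubble_call")
}

#' Bubble-call every molecule of a profiled dataset
#'
#' Applies threshold labelling, segmentation, and nucleosome calling per
#' molecule and returns the per-molecule nucleosome counts together with the
#' full bubble table.
#'
#' @param profiles `distance_profile` data frame covering one or more
#'   molecules.
#' @param threshold_px Distance threshold (e.g. from
#'   [calibrate_threshold()]).
#' @inheritParams segment_bubbles
#' @inheritParams call_nucleosomes
#' @return List with `counts` (named integer vector per molecule) and
#'   `bubbles` (row-bound bubble table).
#' @export
call_dataset <- function(profiles, threshold_px, close_gap_bp = 2L,
                         drop_len_bp = 3L, min_len_bp = 90L,
                         fusion_policy = "single",
                         fusion_suspect_len = 240L) {
  ids <- unique(profiles$molecule_id)
  counts <- integer(length(ids))
  names(counts) <- ids
  tabs <- vector("list", length(ids))
  split_idx <- split(seq_len(nrow(profiles)), profiles$molecule_id)
  for (i in seq_along(ids)) {
    p <- profiles[split_idx[[ids[i]]], , drop = FALSE]
    lab <- label_single_stranded(p, threshold_px)
    bub <- segment_bubbles(lab, close_gap_bp, drop_len_bp,
                           molecule_id = ids[i])
    bc <- call_nucleosomes(bub, min_len_bp, fusion_policy,
                           fusion_suspect_len, threshold_px)
    counts[i] <- bc$nucleosome_count
    tabs[[i]] <- bc$bubbles
  }
  list(counts = counts, bubbles = do.call(rbind, tabs))
}
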