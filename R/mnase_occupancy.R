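#' Filter fragments to mononucleosome-sized inserts
#'
#' Keeps fragments whose insert size (end - start) lies within the given
#' bounds, inclusive. The default window 120--180 bp brackets the ~150 bp
#' mononucleosome insert.
#'
#' @param frags Fragment data frame (`chrom`, `start`, `end`, ...), 0-based
#'   half-open.
#' @param min_bp,max_bp Inclusive insert-size bounds.
#' @return The surviving fragments.
#' @export
filter_by_insert_size <- function(frags, min_bp = 120L, max_bp = 180L) {
  if (min_bp > max_bp) stop("min_bp must not exceed max_bp")
  check_fragments(frags)
  len <- frags$end - frags$start
  frags[len >= min_bp & len <= max_bp, , drop = FALSE]
}

check_fragments <- function(frags) {
  stopifnot(is.data.frame(frags),
            all(c("chrom", "start", "end") %in% names(frags)))
  if (any(frags$start >= frags$end))
    stop("fragments must have start < end")
  if (any(frags$start < 0))
    stop("fragment coordinates must be non-negative")
  invisible(frags)
}

# coverage Rle of fragments on one chromosome, long enough for `min_width`
chrom_coverage <- function(frags, chrom, min_width, midpoint = FALSE) {
  f <- frags[frags$chrom == chrom, , drop = FALSE]
  width <- max(min_width, if (nrow(f)) max(f$end) else 0L)
  if (!nrow(f)) return(S4Vectors::Rle(0L, width))
  if (midpoint) {
    mids <- f$start + floor((f$end - f$start) / 2)
    IRanges::coverage(IRanges::IRanges(mids + 1L, width = 1L),
                      width = width)
  } else {
    IRanges::coverage(IRanges::IRanges(f$start + 1L, f$end), width = width)
  }
}

#' Per-base fragment coverage over a region
#'
#' Counts, at single base-pair resolution, the fragments overlapping each
#' base of a half-open region (full-fragment overlap, NucTools-style). A
#' midpoint mode counts only each fragment's midpoint base, for dyad-style
#' maps.
#'
#' @inheritParams filter_by_insert_size
#' @param chrom Chromosome to profile.
#' @param region Length-2 vector, 0-based half-open `c(start, end)`.
#' @param mode `"fragment"` (default) or `"midpoint"`.
#' @return Integer vector of length `diff(region)`; element `i` is the
#'   coverage of base `region[1] + i - 1`.
#' @export
occupancy_track <- function(frags, chrom, region,
                            mode = c("fragment", "midpoint")) {
  mode <- match.arg(mode)
  check_fragments(frags)
  stopifnot(length(region) == 2L, region[1L] >= 0, region[1L] < region[2L])
  cov <- chrom_coverage(frags, chrom, min_width = region[2L],
                        midpoint = mode == "midpoint")
  as.integer(S4Vectors::window(cov, start = region[1L] + 1L,
                               end = region[2L]))
}

#' TSS-oriented occupancy matrix
#'
#' Builds a genes x positions matrix of per-base coverage centred on each
#' gene's TSS and oriented in the direction of transcription: column `r`
#' (for `r` in `-window_bp .. window_bp - 1`) is the coverage `r` bp
#' downstream of the TSS, with column 0 the first transcribed base. Rows of
#' minus-strand genes are reversed genomic windows. Anchors whose window
#' runs off the chromosome are zero-padded and recorded in
#' `attr(, "clipped")`.
#'
#' @inheritParams occupancy_track
#' @param anchors Anchor data frame (`gene_id`, `chrom`, `tss`, `strand`).
#' @param window_bp Half-window size W; the matrix has `2 * W` columns.
#' @return Integer matrix with `rownames` = `gene_id` (input order) and
#'   `colnames` the relative positions; class `occupancy_matrix` with
#'   attributes `window_bp` and `clipped`.
#' @export
tss_matrix <- function(frags, anchors, window_bp = 1000L,
                       mode = c("fragment", "midpoint")) {
  mode <- match.arg(mode)
  check_fragments(frags)
  stopifnot(nrow(anchors) >= 1L,
            all(c("gene_id", "chrom", "tss", "strand") %in% names(anchors)))
  w <- as.integer(window_bp)
  m <- matrix(0L, nrow(anchors), 2L * w,
              dimnames = list(anchors$gene_id,
                              as.character(seq(-w, w - 1L))))
  clipped <- character(0)
  covs <- lapply(setNames(nm = unique(anchors$chrom)), function(ch)
    chrom_coverage(frags, ch, min_width = 0L, midpoint = mode == "midpoint"))
  for (i in seq_len(nrow(anchors))) {
    tss <- anchors$tss[i]
    minus <- anchors$strand[i] == "-"
    # genomic 0-based window covering columns -w .. w-1
    lo <- if (minus) tss - w + 1L else tss - w
    hi <- lo + 2L * w              # half-open [lo, hi)
    cov <- covs[[anchors$chrom[i]]]
    glo <- max(lo, 0L)
    ghi <- min(hi, length(cov))
    vals <- integer(2L * w)
    if (ghi > glo)
      vals[(glo - lo + 1L):(ghi - lo)] <-
        as.integer(S4Vectors::window(cov, start = glo + 1L, end = ghi))
    if (glo > lo || ghi < hi) clipped <- c(clipped, anchors$gene_id[i])
    if (minus) vals <- rev(vals)
    m[i, ] <- vals
  }
  structure(m, class = c("occupancy_matrix", class(m)),
            window_bp = w, clipped = clipped)
}

#' Aggregate occupancy profile across genes
#'
#' Normalises each gene row to unit mean over the window (rows with zero
#' total are left as zeros and excluded from the averaging), then takes the
#' column-wise mean; this is the "aggregated and normalized" profile drawn
#' under TSS heat maps. `normalization = "none"` averages raw coverage.
#'
#' @param m An [tss_matrix()] result (genes x positions).
#' @param normalization `"per-gene"` (default) or `"none"`.
#' @return Named numeric vector over the matrix's relative positions.
#' @export
aggregate_profile <- function(m, normalization = c("per-gene", "none")) {
  normalization <- match.arg(normalization)
  if (nrow(m) == 0L) stop("empty occupancy matrix")
  mm <- unclass(m)
  if (normalization == "per-gene") {
    rm <- rowMeans(mm)
    keep <- rm > 0
    if (!any(keep)) return(setNames(numeric(ncol(mm)), colnames(mm)))
    colMeans(mm[keep, , drop = FALSE] / rm[keep])
  } else {
    colMeans(mm)
  }
}

count_in_windows <- function(frags, anchors, window_bp) {
  counts <- integer(nrow(anchors))
  for (ch in unique(anchors$chrom)) {
    ai <- which(anchors$chrom == ch)
    f <- frags[frags$chrom == ch, , drop = FALSE]
    wins <- IRanges::IRanges(pmax(anchors$tss[ai] - window_bp, 0L) + 1L,
                             anchors$tss[ai] + window_bp)
    counts[ai] <- IRanges::countOverlaps(
      wins, IRanges::IRanges(f$start + 1L, f$end))
  }
  counts
}

#' Per-gene IP/input fold enrichment around the TSS
#'
#' A deliberately simple surrogate for peak-caller enrichment: fragments
#' overlapping the +/- `window_bp` TSS window are counted in IP and
#' control, each count gets a +1 pseudocount, the counts are scaled by
#' library size, and their ratio is thresholded (default > 4.7-fold).
#'
#' @param ip,control Fragment data frames.
#' @param anchors Anchor data frame.
#' @param window_bp Half-window around the TSS.
#' @param threshold Strict fold threshold for flagging.
#' @return Data frame: `gene_id`, `ip_count`, `control_count`, `fold`,
#'   `flagged`.
#' @export
gene_enrichment <- function(ip, control, anchors, window_bp = 1000L,
                            threshold = 4.7) {
  check_fragments(ip); check_fragments(control)
  if (nrow(ip) == 0L || nrow(control) == 0L)
    stop("zero library size in IP or control")
  ci <- count_in_windows(ip, anchors, window_bp)
  cc <- count_in_windows(control, anchors, window_bp)
  fold <- ((ci + 1) / nrow(ip)) / ((cc + 1) / nrow(control))
  data.frame(gene_id = anchors$gene_id, ip_count = ci, control_count = cc,
             fold = fold, flagged = fold > threshold,
             stringsAsFactors = FALSE)
}

#' Windowed occupancy difference between two conditions
#'
#' Compares mean normalised occupancy between two TSS matrices inside
#' TSS-relative windows (defaults: 100--200 bp downstream and 100--200 bp
#' upstream). Rows are normalised to unit mean as in
#' [aggregate_profile()], the matrices are restricted to their shared gene
#' set, and the per-window effect is the difference of across-gene means
#' (`a - b`). Significance comes from a paired gene-level bootstrap
#' (default 10,000 resamples) with an add-one smoothed two-sided percentile
#' p-value.
#'
#' @param a,b `occupancy_matrix` objects with overlapping rownames.
#' @param windows Named list of inclusive TSS-relative windows
#'   `c(from, to)`.
#' @param n_boot Bootstrap resamples.
#' @param seed Optional seed.
#' @return Data frame: `window`, `from`, `to`, `effect`, `p_value`,
#'   `n_genes`.
#' @export
window_occupancy_difference <- function(a, b,
                                        windows = list(
                                          downstream = c(100L, 200L),
                                          upstream = c(-200L, -100L)),
                                        n_boot = 10000L, seed = NULL) {
  genes <- intersect(rownames(a), rownames(b))
  if (length(genes) == 0L) stop("empty gene intersection")
  norm_rows <- function(m) {
    mm <- unclass(m)[genes, , drop = FALSE]
    rm <- rowMeans(mm)
    mm[rm > 0, ] <- mm[rm > 0, , drop = FALSE] / rm[rm > 0]
    mm
  }
  na <- norm_rows(a); nb <- norm_rows(b)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(names(windows), function(wn) {
    wi <- windows[[wn]]
    cols <- intersect(as.character(wi[1L]:wi[2L]), colnames(na))
    va <- rowMeans(na[, cols, drop = FALSE])
    vb <- rowMeans(nb[, cols, drop = FALSE])
    d <- va - vb
    n <- length(d)
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    boot <- colMeans(matrix(d[idx], nrow = n))
    p <- min(1, 2 * min(sum(boot <= 0) + 1, sum(boot >= 0) + 1) /
                  (n_boot + 1))
    data.frame(window = wn, from = wi[1L], to = wi[2L],
               effect = mean(d), p_value = p, n_genes = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
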