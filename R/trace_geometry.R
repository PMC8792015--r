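#' Co-orient the two strand traces of a molecule
#'
#' Each strand is traced from a designated molecule "end", but the two
#' strands of one molecule may have been traced from opposite ends. The
#' orientation that minimises the summed endpoint-to-endpoint distance
#' (start-start + end-end vs. start-end + end-start) decides whether strand
#' B is reversed. When the two pairings differ by less than `margin_px` the
#' molecule is flagged ambiguous (`$ambiguous_orientation`) for exclusion.
#'
#' Molecules whose strand arc lengths differ by more than
#' `max_arc_ratio_diff` (likely tracing errors) are flagged via
#' `$arc_length_flag` but still returned.
#'
#' @param m A [molecule_trace()].
#' @param margin_px Ambiguity margin in pixels.
#' @param max_arc_ratio_diff Relative arc-length difference that triggers
#'   the QC flag.
#' @return The molecule, with strand B reversed if needed and flags set.
#' @export
orient_strands <- function(m, margin_px = 1, max_arc_ratio_diff = 0.15) {
  stopifnot(inherits(m, "molecule_trace"))
  a <- m$strand_a$points
  b <- m$strand_b$points
  d2 <- function(p, q) sqrt(sum((p - q)^2))
  same <- d2(a[1L, ], b[1L, ]) + d2(a[nrow(a), ], b[nrow(b), ])
  flip <- d2(a[1L, ], b[nrow(b), ]) + d2(a[nrow(a), ], b[1L, ])
  if (flip < same)
    m$strand_b$points <- b[rev(seq_len(nrow(b))), , drop = FALSE]
  m$ambiguous_orientation <- abs(same - flip) < margin_px
  la <- total_arc_length(m$strand_a)
  lb <- total_arc_length(m$strand_b)
  m$arc_length_flag <- abs(la - lb) / max(la, lb) > max_arc_ratio_diff
  m
}

#' Assign base-pair positions along a strand polyline
#'
#' Calibrates pixel arc length to base pairs using the known template
#' length: the per-strand scale is total arc length / `template_len_bp`, and
#' base `k` (0-based) is placed at arc length `(k + 0.5) * scale` by linear
#' interpolation along the polyline. The half-base offset treats the first
#' and last base symmetrically, matching the 0-based half-open convention
#' used throughout.
#'
#' @param s A [strand_trace()], already oriented.
#' @param template_len_bp Template length in bp.
#' @return Numeric matrix `template_len_bp` x 2 of (x, y) positions; row `k`
#'   is base index `k - 1`.
#' @export
assign_base_positions <- function(s, template_len_bp) {
  stopifnot(inherits(s, "strand_trace"))
  template_len_bp <- as.integer(template_len_bp)
  stopifnot(template_len_bp > 0L)
  cum <- arc_lengths(s$points)
  total <- cum[length(cum)]
  if (total <= 0) stop("strand has zero total arc length")
  scale <- total / template_len_bp
  at <- (seq_len(template_len_bp) - 0.5) * scale
  x <- approx(cum, s$points[, 1L], xout = at, ties = "ordered")$y
  y <- approx(cum, s$points[, 2L], xout = at, ties = "ordered")$y
  cbind(x, y)
}

# minimum distance from each row of P (n x 2) to polyline Q (m x 2),
# point-to-segment (robust to uneven tracing density)
min_dist_to_polyline <- function(P, Q) {
  n <- nrow(P)
  m <- nrow(Q) - 1L
  A <- Q[-nrow(Q), , drop = FALSE]
  D <- Q[-1L, , drop = FALSE] - A
  len2 <- rowSums(D^2)
  len2[len2 == 0] <- .Machine$double.xmin
  dx1 <- outer(P[, 1L], A[, 1L], "-")
  dy1 <- outer(P[, 2L], A[, 2L], "-")
  Dx <- matrix(D[, 1L], n, m, byrow = TRUE)
  Dy <- matrix(D[, 2L], n, m, byrow = TRUE)
  tt <- (dx1 * Dx + dy1 * Dy) / matrix(len2, n, m, byrow = TRUE)
  tt[tt < 0] <- 0
  tt[tt > 1] <- 1
  ex <- dx1 - tt * Dx
  ey <- dy1 - tt * Dy
  d2 <- ex * ex + ey * ey
  sqrt(d2[cbind(seq_len(n), max.col(-d2, ties.method = "first"))])
}

#' Per-base inter-strand distance profile of a molecule
#'
#' Anchors base positions on a reference strand (by default the strand with
#' the longer arc, which preserves resolution) and measures, for every base,
#' the Euclidean distance to the closest point on the complementary strand's
#' polyline (point-to-segment). A symmetric variant averages the A-to-B and
#' B-to-A distances.
#'
#' @param m An oriented [molecule_trace()].
#' @param reference `"longer"` (default), `"a"`, or `"b"`: which strand
#'   anchors the per-base mapping.
#' @param symmetric If `TRUE`, average the two directed distance profiles.
#' @return Data frame of class `distance_profile`: `molecule_id`,
#'   `bp_index` (0-based, contiguous), `distance_px`.
#' @export
pair_and_profile <- function(m, reference = c("longer", "a", "b"),
                             symmetric = FALSE) {
  stopifnot(inherits(m, "molecule_trace"))
  reference <- match.arg(reference)
  n <- m$template_len_bp
  ref_is_a <- switch(reference,
    longer = total_arc_length(m$strand_a) >= total_arc_length(m$strand_b),
    a = TRUE, b = FALSE)
  ref <- if (ref_is_a) m$strand_a else m$strand_b
  oth <- if (ref_is_a) m$strand_b else m$strand_a
  d <- min_dist_to_polyline(assign_base_positions(ref, n), oth$points)
  if (symmetric) {
    d2 <- min_dist_to_polyline(assign_base_positions(oth, n), ref$points)
    d <- (d + d2) / 2
  }
  out <- data.frame(molecule_id = m$molecule_id,
                    bp_index = 0:(n - 1L),
                    distance_px = d,
                    stringsAsFactors = FALSE)
  class(out) <- c("distance_profile", "data.frame")
  out
}

#' Profile every molecule of a dataset
#'
#' Convenience wrapper: orients each molecule, drops those flagged as
#' orientation-ambiguous, and concatenates the per-base distance profiles.
#'
#' @param traces List of [molecule_trace()].
#' @inheritParams pair_and_profile
#' @inheritParams orient_strands
#' @return Single `distance_profile` data frame for all retained molecules;
#'   dropped molecule ids are in `attr(, "dropped")`.
#' @export
profile_molecules <- function(traces, reference = "longer",
                              symmetric = FALSE, margin_px = 1) {
  oriented <- lapply(traces, orient_strands, margin_px = margin_px)
  amb <- vapply(oriented, `[[`, logical(1), "ambiguous_orientation")
  profs <- lapply(oriented[!amb], pair_and_profile,
                  reference = reference, symmetric = symmetric)
  out <- do.call(rbind, profs)
  if (is.null(out))
    out <- data.frame(molecule_id = character(0), bp_index = integer(0),
                      distance_px = numeric(0))
  class(out) <- c("distance_profile", "data.frame")
  attr(out, "dropped") <- vapply(traces[amb], `[[`, character(1),
                                 "molecule_id")
  out
}
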