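#' Strand and molecule trace containers
#'
#' A `strand_trace` is one traced DNA strand: an ordered polyline in pixel
#' coordinates whose first point is the designated molecule "end". A
#' `molecule_trace` pairs two strand traces with the known template length in
#' base pairs, which calibrates pixel arc length to base positions.
#'
#' @param strand_id Label, conventionally `"A"` or `"B"`.
#' @param points Two-column numeric matrix of (x, y) pixel coordinates,
#'   ordered along the strand; at least two points, consecutive points
#'   distinct.
#' @return `strand_trace()` returns a `strand_trace`; `molecule_trace()`
#'   returns a `molecule_trace`.
#' @export
strand_trace <- function(strand_id, points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L)
    stop("strand points must be a numeric 2-column matrix")
  if (nrow(points) < 2L)
    stop("a strand trace needs at least 2 points")
  step <- rowSums((points[-1L, , drop = FALSE] -
                   points[-nrow(points), , drop = FALSE])^2)
  if (any(step == 0))
    stop("consecutive strand points must be distinct (strand '",
         strand_id, "')")
  structure(list(strand_id = as.character(strand_id), points = points),
            class = "strand_trace")
}

#' @rdname strand_trace
#' @param molecule_id Molecule label.
#' @param strand_a,strand_b The two `strand_trace` objects.
#' @param template_len_bp Known template length in base pairs (> 0).
#' @export
molecule_trace <- function(molecule_id, strand_a, strand_b, template_len_bp) {
  stopifnot(inherits(strand_a, "strand_trace"),
            inherits(strand_b, "strand_trace"))
  template_len_bp <- as.integer(template_len_bp)
  if (is.na(template_len_bp) || template_len_bp <= 0L)
    stop("template_len_bp must be a positive integer")
  structure(list(molecule_id = as.character(molecule_id),
                 strand_a = strand_a, strand_b = strand_b,
                 template_len_bp = template_len_bp,
                 ambiguous_orientation = FALSE,
                 arc_length_flag = FALSE),
            class = "molecule_trace")
}

#' @export
print.molecule_trace <- function(x, ...) {
  cat("<molecule_trace>", x$molecule_id, "\n",
      " template:", x$template_len_bp, "bp;",
      " strand A:", nrow(x$strand_a$points), "pts;",
      " strand B:", nrow(x$strand_b$points), "pts\n")
  invisible(x)
}

arc_lengths <- function(points) {
  d <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                     points[-nrow(points), , drop = FALSE])^2))
  c(0, cumsum(d))
}

total_arc_length <- function(strand) {
  p <- strand$points
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}
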