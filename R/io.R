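#' Read and write trace datasets
#'
#' A trace dataset on disk is a directory holding one CSV per molecule
#' (columns `strand_id` in A/B, `point_index`, `x_px`, `y_px`), a
#' `manifest.tsv` (molecule_id, file, template_len_bp), a ground-truth
#' `truth.tsv` when available, and `meta.json` recording the seed and
#' configuration. Coordinates are written with 17 significant digits so a
#' write/read round trip is bit-identical. All coordinates persisted by the
#' package are 0-based half-open, noted in each file header.
#'
#' @param ds A `trace_sim` dataset (or a list with `traces`, optionally
#'   `truth` and `config`).
#' @param dir Target directory (created if needed).
#' @return `write_trace_dataset()` returns `dir` invisibly;
#'   `read_trace_dataset()` returns a list with `traces`, `truth`,
#'   `planted_counts`, and `meta`.
#' @export
write_trace_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "traces"), recursive = TRUE,
             showWarnings = FALSE)
  manifest <- data.frame(molecule_id = character(0), file = character(0),
                         template_len_bp = integer(0))
  for (m in ds$traces) {
    fn <- file.path("traces", paste0(m$molecule_id, ".csv"))
    rows <- lapply(list(m$strand_a, m$strand_b), function(s)
      data.frame(strand_id = s$strand_id,
                 point_index = seq_len(nrow(s$points)) - 1L,
                 x_px = sprintf("%.17g", s$points[, 1L]),
                 y_px = sprintf("%.17g", s$points[, 2L]),
                 stringsAsFactors = FALSE))
    write.table(do.call(rbind, rows), file.path(dir, fn), sep = ",",
                quote = FALSE, row.names = FALSE)
    manifest <- rbind(manifest,
                      data.frame(molecule_id = m$molecule_id, file = fn,
                                 template_len_bp = m$template_len_bp))
  }
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(ds$truth))
    write.table(ds$truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  meta <- list(coordinates = "0-based half-open",
               seed = ds$config$seed,
               config = unclass(ds$config))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_trace_dataset
#' @export
read_trace_dataset <- function(dir) {
  manifest <- read_tsv_strict(file.path(dir, "manifest.tsv"),
                              c("molecule_id", "file", "template_len_bp"))
  traces <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    path <- file.path(dir, manifest$file[i])
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("strand_id", "point_index", "x_px", "y_px")
    if (!all(need %in% names(tab)))
      stop(path, ": expected columns ", paste(need, collapse = ", "))
    mk <- function(id) {
      s <- tab[tab$strand_id == id, , drop = FALSE]
      s <- s[order(s$point_index), , drop = FALSE]
      strand_trace(id, cbind(s$x_px, s$y_px))
    }
    traces[[i]] <- molecule_trace(manifest$molecule_id[i], mk("A"), mk("B"),
                                  manifest$template_len_bp[i])
  }
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path))
    read_tsv_strict(truth_path, c("molecule_id", "start_bp", "end_bp",
                                  "length_bp", "size_class"))
  else NULL
  meta_path <- file.path(dir, "meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  counts <- setNames(integer(nrow(manifest)), manifest$molecule_id)
  if (!is.null(truth)) {
    nuc <- truth[truth$size_class == "nucleosome", , drop = FALSE]
    tab <- table(nuc$molecule_id)
    counts[names(tab)] <- as.integer(tab)
  }
  list(traces = traces, truth = truth, planted_counts = counts,
       meta = meta)
}

read_tsv_strict <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(
    read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE),
    error = function(e) stop(path, ": malformed TSV (", conditionMessage(e),
                             ")"))
  missing <- setdiff(required_cols, names(tab))
  if (length(missing))
    stop(path, ": missing column(s) ", paste(missing, collapse = ", "))
  tab
}

#' Read and write fragment intervals as BED / BEDPE
#'
#' `read_fragments_bed()` parses a headerless BED file (>= 3 columns;
#' column 4, when present, is taken as the sample label) into the fragment
#' data frame used across the package; coordinates stay 0-based half-open.
#' Rows with `start >= end` or negative coordinates are rejected with their
#' line number. `read_fragments_bedpe()` parses BEDPE mate pairs and
#' returns the outer fragment spanned by each pair (both mates must share a
#' chromosome).
#'
#' @param path File to read.
#' @param sample Sample label to attach when the file carries none.
#' @return Fragment data frame: `chrom`, `start`, `end`, `sample`.
#' @export
read_fragments_bed <- function(path, sample = NA_character_) {
  tab <- read_bedlike(path, min_cols = 3L)
  bad <- which(!is.finite(tab[[2L]]) | !is.finite(tab[[3L]]) |
                 tab[[2L]] >= tab[[3L]] | tab[[2L]] < 0)
  if (length(bad))
    stop(path, ": invalid interval (start >= end or negative) at line ",
         paste(bad, collapse = ", "))
  data.frame(chrom = as.character(tab[[1L]]),
             start = as.integer(tab[[2L]]), end = as.integer(tab[[3L]]),
             sample = if (ncol(tab) >= 4L) as.character(tab[[4L]])
                      else sample,
             stringsAsFactors = FALSE)
}

#' @rdname read_fragments_bed
#' @export
read_fragments_bedpe <- function(path, sample = NA_character_) {
  tab <- read_bedlike(path, min_cols = 6L)
  if (any(tab[[1L]] != tab[[4L]])) {
    bad <- which(tab[[1L]] != tab[[4L]])
    stop(path, ": interchromosomal pair at line ",
         paste(bad, collapse = ", "))
  }
  start <- pmin(tab[[2L]], tab[[5L]])
  end <- pmax(tab[[3L]], tab[[6L]])
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop(path, ": invalid pair coordinates at line ",
         paste(bad, collapse = ", "))
  data.frame(chrom = as.character(tab[[1L]]), start = as.integer(start),
             end = as.integer(end),
             sample = if (ncol(tab) >= 7L) as.character(tab[[7L]])
                      else sample,
             stringsAsFactors = FALSE)
}

read_bedlike <- function(path, min_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
               comment.char = "#"),
    error = function(e) stop(path, ": malformed file (",
                             conditionMessage(e), ")"))
  if (ncol(tab) < min_cols)
    stop(path, ": expected at least ", min_cols, " tab-separated columns")
  tab
}

#' @rdname read_fragments_bed
#' @param frags Fragment data frame to write.
#' @export
write_fragments_bed <- function(frags, path) {
  check_fragments(frags)
  out <- data.frame(frags$chrom, frags$start, frags$end,
                    if (!is.null(frags$sample)) frags$sample else ".")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read and write TSS anchors as BED6
#'
#' Anchors are single-base BED6 intervals: the interval `[tss, tss + 1)`
#' with the gene id in the name column and the strand in column 6.
#'
#' @param path File path.
#' @return Anchor data frame: `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_anchors_bed <- function(path) {
  tab <- read_bedlike(path, min_cols = 6L)
  bad <- which(tab[[3L]] != tab[[2L]] + 1L | tab[[2L]] < 0 |
                 !(tab[[6L]] %in% c("+", "-")))
  if (length(bad))
    stop(path, ": anchors must be single-base stranded intervals; bad line ",
         paste(bad, collapse = ", "))
  data.frame(gene_id = as.character(tab[[4L]]),
             chrom = as.character(tab[[1L]]),
             tss = as.integer(tab[[2L]]),
             strand = as.character(tab[[6L]]),
             stringsAsFactors = FALSE)
}

#' @rdname read_anchors_bed
#' @param anchors Anchor data frame to write.
#' @export
write_anchors_bed <- function(anchors, path) {
  out <- data.frame(anchors$chrom, anchors$tss, anchors$tss + 1L,
                    anchors$gene_id, 0L, anchors$strand)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read and write FP titration tables
#'
#' Titrations are TSVs with columns `conc_molar`, `polarization`,
#' `replicate`; the fixed probe concentration is carried in a
#' `# probe_conc_molar=` header comment.
#'
#' @param series A [titration_series()].
#' @param path File path.
#' @return `read_titration_tsv()` returns a `titration_series`.
#' @export
write_titration_tsv <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# probe_conc_molar=%.17g", series$probe_conc), con)
  write.table(data.frame(conc_molar = sprintf("%.17g",
                                              series$points$conc_molar),
                         polarization = sprintf("%.17g",
                                                series$points$polarization),
                         replicate = series$points$replicate),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration_tsv
#' @export
read_titration_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  probe <- if (grepl("^# *probe_conc_molar=", first))
    as.numeric(sub("^# *probe_conc_molar=", "", first)) else 20e-9
  tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  need <- c("conc_molar", "polarization", "replicate")
  if (!all(need %in% names(tab)))
    stop(path, ": expected columns ", paste(need, collapse = ", "))
  titration_series(tab[need], probe_conc = probe)
}

#' Write a distance-profile or bubble table as TSV
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
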