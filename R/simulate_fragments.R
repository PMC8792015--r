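#' Configuration for the synthetic MNase fragment generator
#'
#' Emulates an MNase-ChIP experiment on a simulated genome: oriented genes
#' with a planted +1 nucleosome whose dyad sits `plus_one_offset_bp`
#' downstream of the TSS (in the direction of transcription), positional
#' fuzziness, mononucleosome-sized insert lengths, and an IP sample that
#' concentrates on an enriched gene subset while the input sample spreads
#' across the genome.
#'
#' `background_frac` is the uniform (genome-wide) fraction of each enriched
#' gene's IP fragments; a non-enriched gene sheds only that nonspecific
#' fraction into the IP (`round(background_frac * frags_per_gene_ip)`
#' uniform fragments), since unbound loci contribute no pulled-down
#' material beyond background. The input sample has its own diffuse
#' fraction `input_background_frac`, defaulting high (0.95): an input
#' library samples the entire genome, so the positioned signal at any
#' single promoter is heavily diluted relative to the IP.
#'
#' @param n_genes Number of genes.
#' @param genome_len Simulated genome (single chromosome) length, bp.
#' @param plus_one_offset_bp Planted dyad offset downstream of the TSS.
#' @param fuzziness_bp SD (bp) of the per-fragment dyad jitter.
#' @param frag_len_mean,frag_len_sd Insert length distribution (bp).
#' @param frags_per_gene_ip IP fragments generated per enriched gene.
#' @param frags_per_gene_input Input fragments generated per gene.
#' @param background_frac Uniform fraction of IP fragments per enriched
#'   gene; non-enriched genes' IP fragments are entirely uniform.
#' @param input_background_frac Uniform fraction of input fragments.
#' @param enriched_gene_frac Fraction of genes carrying the planted IP
#'   signal.
#' @param chrom Chromosome label.
#' @param seed Integer RNG seed.
#' @return A validated `fragment_sim_config` list.
#' @export
fragment_sim_config <- function(n_genes = 200L,
                                genome_len = 10000000L,
                                plus_one_offset_bp = 110L,
                                fuzziness_bp = 20,
                                frag_len_mean = 150,
                                frag_len_sd = 20,
                                frags_per_gene_ip = 200L,
                                frags_per_gene_input = 200L,
                                background_frac = 0.2,
                                input_background_frac = 0.95,
                                enriched_gene_frac = 0.5,
                                chrom = "chrSim",
                                seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              genome_len = as.integer(genome_len),
              plus_one_offset_bp = as.integer(plus_one_offset_bp),
              fuzziness_bp = fuzziness_bp,
              frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
              frags_per_gene_ip = as.integer(frags_per_gene_ip),
              frags_per_gene_input = as.integer(frags_per_gene_input),
              background_frac = background_frac,
              input_background_frac = input_background_frac,
              enriched_gene_frac = enriched_gene_frac,
              chrom = chrom, seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1L, cfg$genome_len > 0L,
            cfg$fuzziness_bp >= 0, cfg$frag_len_mean > 0,
            cfg$frags_per_gene_ip >= 0L, cfg$frags_per_gene_input >= 0L,
              cfg$background_frac >= 0, cfg$background_frac <= 1,
              cfg$input_background_frac >= 0, cfg$input_background_frac <= 1,
              cfg$enriched_gene_frac >= 0, cfg$enriched_gene_frac <= 1)
  structure(cfg, class = "fragment_sim_config")
}

# fragments centred on dyad positions; midpoint (floor) equals the dyad
fragments_at_dyads <- function(dyads, lens, genome_len, chrom, sample) {
  start <- dyads - floor(lens / 2)
  end <- start + lens
  start <- pmax(start, 0L)
  end <- pmin(end, genome_len)
  end <- pmax(end, start + 1L)
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), sample = sample,
             stringsAsFactors = FALSE)
}

uniform_fragments <- function(n, lens, genome_len, chrom, sample) {
  if (n == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), sample = character(0)))
  start <- floor(runif(n, 0, genome_len - lens))
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + lens), sample = sample,
             stringsAsFactors = FALSE)
}

draw_lengths <- function(n, cfg) {
  pmax(1L, as.integer(round(rnorm(n, cfg$frag_len_mean, cfg$frag_len_sd))))
}

#' Simulate MNase-ChIP fragment sets with a planted +1 nucleosome
#'
#' Places `n_genes` oriented TSS anchors evenly along a simulated
#' chromosome, marks an `enriched_gene_frac` subset as IP-enriched, and
#' generates paired IP and input fragment sets. IP fragments at enriched
#' genes are centred on the jittered planted dyad (TSS +
#' `plus_one_offset_bp` in the direction of transcription); IP fragments at
#' other genes, and the diffuse portions of both samples, are uniform over
#' the genome. Per-gene fragment totals match the configured counts
#' exactly.
#'
#' @param cfg A [fragment_sim_config()].
#' @return List of class `fragment_sim`: `ip` and `input` fragment data
#'   frames (`chrom`, `start`, `end`, `sample`; 0-based half-open),
#'   `anchors` (`gene_id`, `chrom`, `tss`, `strand`), `truth` (`gene_id`,
#'   `dyad_pos`, `enriched`), and `config`.
#' @export
simulate_mnase_fragments <- function(cfg) {
  stopifnot(inherits(cfg, "fragment_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  spacing <- cfg$genome_len / n
  tss <- as.integer(round(spacing * (seq_len(n) - 0.5)))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_id <- sprintf("gene%04d", seq_len(n))
  enriched <- seq_len(n) %in%
    sample.int(n, round(cfg$enriched_gene_frac * n))
  sgn <- ifelse(strand == "+", 1L, -1L)
  dyad_pos <- tss + sgn * cfg$plus_one_offset_bp
  anchors <- data.frame(gene_id = gene_id, chrom = cfg$chrom, tss = tss,
                        strand = strand, stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = gene_id, dyad_pos = as.integer(dyad_pos),
                      enriched = enriched, stringsAsFactors = FALSE)

  gene_frags <- function(i, n_total, bg_frac, sample, positioned) {
    n_pos <- if (positioned) round((1 - bg_frac) * n_total) else 0L
    n_bg <- n_total - n_pos
    out <- list()
    if (n_pos > 0L) {
      jit <- if (cfg$fuzziness_bp > 0)
        as.integer(round(rnorm(n_pos, 0, cfg$fuzziness_bp))) else 0L
      out$pos <- fragments_at_dyads(dyad_pos[i] + jit,
                                    draw_lengths(n_pos, cfg),
                                    cfg$genome_len, cfg$chrom, sample)
    }
    if (n_bg > 0L)
      out$bg <- uniform_fragments(n_bg, draw_lengths(n_bg, cfg),
                                  cfg$genome_len, cfg$chrom, sample)
    do.call(rbind, out)
  }

  ip <- do.call(rbind, lapply(seq_len(n), function(i) {
    n_ip <- if (enriched[i]) cfg$frags_per_gene_ip
            else as.integer(round(cfg$background_frac *
                                  cfg$frags_per_gene_ip))
    gene_frags(i, n_ip, cfg$background_frac, "ip",
               positioned = enriched[i])
  }))
  input <- do.call(rbind, lapply(seq_len(n), function(i)
    gene_frags(i, cfg$frags_per_gene_input, cfg$input_background_frac,
               "input", positioned = TRUE)))
  rownames(ip) <- rownames(input) <- NULL
  structure(list(ip = ip, input = input, anchors = anchors, truth = truth,
                 config = cfg),
            class = "fragment_sim")
}
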