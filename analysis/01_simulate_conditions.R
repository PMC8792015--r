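#!/usr/bin/env Rscript

# Generate the synthetic datasets for the whole workflow:
#   - psoralen-EM trace datasets for five reconstitution conditions of the
#     461 bp promoter template (free DNA, octamer alone, octamer with high
#     or low MuvB, and a CHR-site mutant), with planted bubble ground truth
#   - MNase-ChIP fragment sets with a planted +1 nucleosome (sharp and
#     fuzzy positioning, emulating repressed vs. active promoters)
#   - FP titrations for a binder, a weaker binder, and a nonbinder
#
# The per-condition bubble rates are chosen study conditions (the original
# figure-panel values are not machine-readable); what matters downstream
# is their ordering: MuvB raises occupancy, the CHR mutation lowers it
# part-way, free DNA carries none.

suppressPackageStartupMessages(library(promnuc))

out <- "results"
raw <- "scratch/sim_inputs"   # regenerable raw inputs; tables go to results/
dir.create(file.path(raw, "sim_traces"), recursive = TRUE,
           showWarnings = FALSE)

conditions <- list(
  free_dna           = 0.0,
  octamer            = 0.60,
  octamer_low_muvb   = 0.90,
  octamer_muvb       = 1.30,
  octamer_muvb_mutchr = 0.95
)

message("Simulating EM trace datasets (150 molecules each) ...")
for (i in seq_along(conditions)) {
  nm <- names(conditions)[i]
  ds <- simulate_trace_dataset(trace_sim_config(
    n_molecules = 150L, lambda_true = conditions[[i]], seed = 100L + i))
  write_trace_dataset(ds, file.path(raw, "sim_traces", nm))
  message(sprintf("  %-20s lambda_true = %.2f, planted mean = %.3f",
                  nm, conditions[[i]], mean(ds$planted_counts)))
}

message("Simulating MNase-ChIP fragments (sharp and fuzzy +1) ...")
for (cfg in list(list(name = "sharp", fuzz = 20), list(name = "fuzzy",
                                                       fuzz = 60))) {
  sim <- simulate_mnase_fragments(fragment_sim_config(
    fuzziness_bp = cfg$fuzz, seed = 200L + cfg$fuzz))
  d <- file.path(raw, "sim_fragments", cfg$name)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  write_fragments_bed(sim$ip, file.path(d, "ip.bed"))
  write_fragments_bed(sim$input, file.path(d, "input.bed"))
  write_anchors_bed(sim$anchors, file.path(d, "anchors.bed"))
  write_profile_tsv(sim$truth, file.path(d, "truth.tsv"))
  message(sprintf("  %-6s %d IP + %d input fragments over %d genes",
                  cfg$name, nrow(sim$ip), nrow(sim$input),
                  nrow(sim$anchors)))
}

message("Simulating FP titrations (20 nM probe, triplicate) ...")
dir.create(file.path(raw, "sim_titrations"), showWarnings = FALSE)
tits <- list(
  h3_tail   = titration_sim_config(2.5e-7, seed = 301),
  h3_tail_n = titration_sim_config(6.0e-7, seed = 302),
  h4_tail   = titration_sim_config(2.5e-7, fp_bound = 50, seed = 303)
)
for (nm in names(tits)) {
  s <- simulate_fp_titration(tits[[nm]])
  write_titration_tsv(s, file.path(raw, "sim_titrations",
                                   paste0(nm, ".tsv")))
}
message("  wrote ", length(tits), " titration tables")
message("Done: raw simulated inputs under ", normalizePath(raw))
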