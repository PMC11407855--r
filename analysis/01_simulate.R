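#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohort all later stages analyse.
#
# Six reciprocal crosses between two partially inbred colonies ("K" and
# "N"): parental and F1-sibling genotypes, per-cross allelic count tables
# at informative SNPs, gene annotation, a copy-number table, a species
# tree with gene presence/absence, and sweep/CRM interval sets — with the
# ground truth (which genes are cis-regulated, where CNVs sit, gene ages)
# recorded alongside. Defaults: 1000 genes, 20% cis-regulated at true
# major-allele fraction 0.7, beta-binomial overdispersion 0.038, mean
# coverage 100, two crosses unphased.

suppressMessages(library(crossASE))

out_dir <- "results/cohort"
cfg <- sim_config(seed = 20260924L)
cohort <- simulate_cohort(cfg, dir = out_dir)

cat("wrote cohort bundle to", out_dir, "\n")
cat(sprintf("genes: %d (%d planted ASE, %d with planted CNV)\n",
            nrow(cohort$genes), sum(cohort$truth$is_ase),
            sum(cohort$truth$has_cnv)))
for (cid in cohort$crosses$cross_id)
  cat(sprintf("  cross %s (%s): %d informative SNPs\n", cid,
              ifelse(cohort$crosses$phased[cohort$crosses$cross_id == cid],
                     "phased", "unphased"),
              nrow(cohort$counts[[cid]])))
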