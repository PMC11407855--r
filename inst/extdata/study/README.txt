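Summary tables from the Kisumu x Nagongera F1 crossing experiment this
package models, transcribed from the published report. Used as inputs by
scripts/acceptance.R and the reproduction vignette:

  mapping_rates.tsv            per-cross percentage of RNA-seq reads mapping
                               to the reference genome
  colony_consensus_snps.tsv    fixed homozygous SNP differences between the
                               colony consensus sequences, per chromosome arm
  cnv_ase_counts.tsv           2x2 counts: autosomal ASE / non-ASE genes with
                               and without a possible copy-number variant
  sweep_ase_counts.tsv         2x2 counts: ASE / non-ASE genes inside and
                               outside swept regions
  cross_significant_counts.tsv genes with significant ASE (FDR 5%) and genes
                               detectable, per cross, plus the all-cross
                               intersection and its shared universe
  study_constants.tsv          genome-wide gene count, recommended per-gene
                               read depth, and bendiocarb mortality with and
                               without PBO pre-exposure
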