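#!/usr/bin/env Rscript
# Stage 5: confounder and enrichment statistics.
#
#  - CNV vs ASE and sweep vs ASE two-sided Fisher tests (autosomal genes;
#    "ASE" = the consistency list, "non-ASE" = detectable everywhere but
#    significant nowhere), including the same tests on the published study
#    2x2 tables;
#  - Wagner-parsimony gene ages and per-age-class enrichment;
#  - two-way ANOVA of ASE proportion by chromosome arm and cross;
#  - CRM flanking-gene assignment.

suppressMessages(library(crossASE))

cohort <- read_cohort("results/cohort")
dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)

sets <- lapply(cohort$crosses$cross_id, function(cid)
  cross_result_set(read_results(sprintf("results/ase/ase_%s.tsv", cid))))
consist <- read.table("results/compare/consistency.tsv", sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
universe <- Reduce(intersect, lapply(sets, function(s) s$detectable))
ever_sig <- unique(unlist(lapply(sets, function(s) s$significant)))
ase_genes <- consist$gene_id
non_ase <- setdiff(universe, ever_sig)
arm <- setNames(cohort$genes$arm, cohort$genes$gene_id)
auto <- function(g) g[arm[g] %in% c("2L", "2R", "3L", "3R")]

cnv <- cnv_flag(cohort$cn_table)
has_cnv <- setNames(cnv$has_cnv, cnv$gene_id)
a <- auto(ase_genes); n <- auto(non_ase)
ft_cnv <- fisher_exact_2x2(sum(has_cnv[a]), sum(!has_cnv[a]),
                           sum(has_cnv[n]), sum(!has_cnv[n]))
cat(sprintf("synthetic cohort CNV vs ASE: OR = %.2f, p = %.3g\n",
            ft_cnv$odds_ratio, ft_cnv$p_value))

swp <- sweep_flag(cohort$genes, cohort$sweeps)
in_sw <- setNames(swp$in_sweep, swp$gene_id)
ft_sw <- fisher_exact_2x2(sum(in_sw[ase_genes]), sum(!in_sw[ase_genes]),
                          sum(in_sw[non_ase]), sum(!in_sw[non_ase]))
cat(sprintf("synthetic cohort sweep vs ASE: OR = %.2f, p = %.3g\n",
            ft_sw$odds_ratio, ft_sw$p_value))

# the published 2x2 tables, recomputed
study <- function(f) read.table(system.file("extdata", "study", f,
                                            package = "crossASE"),
                                sep = "\t", header = TRUE)
for (f in c("cnv_ase_counts.tsv", "sweep_ase_counts.tsv")) {
  tb <- study(f)
  ft <- fisher_exact_2x2(tb$feature_present[1], tb$feature_absent[1],
                         tb$feature_present[2], tb$feature_absent[2])
  cat(sprintf("study table %s: OR = %.2f, p = %.4g\n", f, ft$odds_ratio,
              ft$p_value))
}

ages <- age_assign(cohort$presence, cohort$tree_newick, focal = "t1")
enr <- age_enrichment(ase_genes, non_ase, ages)
cat("\nage-class enrichment of ASE genes:\n")
print(enr)
write.table(enr, "results/enrichment/age_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

arm_rows <- do.call(rbind, lapply(sets, function(s) {
  arms <- c("2L", "2R", "3L", "3R")
  data.frame(arm = arms, cross = s$cross_id,
             proportion = as.vector(table(factor(arm[s$significant], arms))) /
               pmax(1L, as.vector(table(factor(arm[s$detectable], arms)))))
}))
av <- arm_anova(arm_rows)
cat("\narm x cross ANOVA on ASE proportions:\n")
print(av)
write.table(av, "results/enrichment/arm_anova.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

crm_map <- flank_assign(cohort$crms, cohort$genes)
n_flanked <- length(unique(crm_map$label[crm_map$gene_id %in% ase_genes]))
cat(sprintf("\nCRMs flanked by a consistency-list gene: %d of %d\n",
            n_flanked, nrow(cohort$crms)))
write.table(crm_map, "results/enrichment/crm_flanking.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
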