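#!/usr/bin/env Rscript
# Stage 4: combine the per-cross results.
#
#  - UpSet-style exclusive intersection counts of the significant gene sets;
#  - permutation null for the all-cross overlap (random draws of each
#    cross's significant count from the shared detectable universe);
#  - the consistency list: genes significant in at least 4 of 6 crosses,
#    with maternal/paternal direction tallies from the phased crosses.

suppressMessages(library(crossASE))

cohort <- read_cohort("results/cohort")
dir.create("results/compare", showWarnings = FALSE, recursive = TRUE)

sets <- lapply(cohort$crosses$cross_id, function(cid)
  cross_result_set(read_results(sprintf("results/ase/ase_%s.tsv", cid))))

inter <- intersect_ase(sets)
write.table(inter, "results/compare/intersections.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("top intersections:\n")
print(head(inter, 8))

universe <- Reduce(intersect, lapply(sets, function(s) s$detectable))
perm <- permute_intersection(sets, universe, n_perm = 1e4, seed = 20260924L)
cat(sprintf("\nall-cross overlap: %d observed vs null max %d (expected %.3f), p = %.2g\n",
            perm$observed, perm$null_max, perm$expected, perm$p))

consist <- consistency_table(sets, k = 4)
truth <- read.table("results/cohort/truth.tsv", sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
precision <- mean(consist$gene_id %in% truth$gene_id[truth$is_ase])
cat(sprintf("consistency list (>= 4/6 crosses): %d genes, precision vs truth %.2f\n",
            nrow(consist), precision))
write.table(consist, "results/compare/consistency.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

dirs <- direction_summary(sets)
write.table(dirs, "results/compare/direction_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
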