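# End-to-end orchestration: from a cohort bundle (simulated or read from
# disk) through per-cross gene-level ASE, cross intersections with a
# permutation null, the consistency list, and the enrichment statistics,
# to a directory of TSV report tables plus a machine-readable manifest.

#' Pipeline run configuration
#'
#' Bundles the analysis constants: overdispersion and simulation count of
#' the null model, the per-SNP depth filter (10 reads), the nominal FDR
#' (5%), the consistency threshold (4 crosses), the permutation count
#' (100000) and a single global seed that fans out into named substreams
#' per stage.
#'
#' @param rho null-model overdispersion.
#' @param n_sims null replicates per gene (`fast = TRUE` drops this to 1e4).
#' @param min_total per-SNP total-count filter.
#' @param alpha nominal FDR.
#' @param min_crosses consistency-list threshold.
#' @param n_perm intersection permutations (`fast = TRUE` drops this to 1e4).
#' @param seed global seed.
#' @param fast desk-scale mode: 1e4 simulations and permutations.
#' @return list of class `run_config`.
#' @export
run_config <- function(rho = 0.038, n_sims = 1e6, min_total = 10L,
                       alpha = 0.05, min_crosses = 4L, n_perm = 1e5,
                       seed = 1L, fast = FALSE) {
  if (fast) { n_sims <- 1e4; n_perm <- 1e4 }
  structure(list(rho = rho, n_sims = as.integer(n_sims),
                 min_total = as.integer(min_total), alpha = alpha,
                 min_crosses = as.integer(min_crosses),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 fast = fast),
            class = "run_config")
}

#' Read a cohort bundle from disk
#'
#' Loads the directory layout written by [write_cohort()] back into the
#' in-memory cohort structure via the package readers.
#'
#' @param dir bundle directory.
#' @return list mirroring [simulate_cohort()] output (without `truth`
#'   unless `truth.tsv` is present).
#' @export
read_cohort <- function(dir) {
  crosses <- utils::read.table(file.path(dir, "crosses.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
  counts <- list(); sib_gms <- list()
  for (cid in crosses$cross_id) {
    counts[[cid]] <- read_count_table(file.path(dir, sprintf("counts_%s.tsv", cid)))
    sib_path <- file.path(dir, sprintf("sibs_%s.vcf", cid))
    if (file.exists(sib_path)) sib_gms[[cid]] <- read_vcf_subset(sib_path)
  }
  out <- list(genes = read_gene_annotation(file.path(dir, "annotation.bed")),
              parents = list(gm = read_vcf_subset(file.path(dir, "parents.vcf"))),
              crosses = crosses, sib_gms = sib_gms, counts = counts,
              cn_table = read_copy_number(file.path(dir, "copy_number.tsv")),
              tree_newick = readLines(file.path(dir, "tree.nwk"))[1],
              presence = read_presence_matrix(file.path(dir, "presence.tsv")),
              sweeps = read_intervals(file.path(dir, "sweeps.bed")),
              crms = read_intervals(file.path(dir, "crms.bed")))
  truth_path <- file.path(dir, "truth.tsv")
  if (file.exists(truth_path))
    out$truth <- utils::read.table(truth_path, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
  out
}

#' Validate a cohort bundle before analysis
#'
#' Checks id cross-references (count-table genes against the annotation,
#' cross parents against the parent genotypes), coordinate sanity, and
#' phase-mode compatibility: a phased cross needs its parents genotyped;
#' an unphased cross needs sibling genotypes to infer its SNP set.
#'
#' @param cohort cohort list ([simulate_cohort()] or [read_cohort()]).
#' @return data.frame of diagnostics (`level` in `{"error", "warning"}`,
#'   `message`); zero rows when the bundle is clean.
#' @export
validate_inputs <- function(cohort) {
  diags <- list()
  note <- function(level, msg)
    diags[[length(diags) + 1L]] <<- data.frame(level = level, message = msg,
                                               stringsAsFactors = FALSE)
  gene_ids <- cohort$genes$gene_id
  for (cid in names(cohort$counts)) {
    unknown <- setdiff(unique(cohort$counts[[cid]]$gene_id), gene_ids)
    if (length(unknown))
      note("error", sprintf("cross %s: %d gene id(s) absent from annotation (e.g. %s)",
                            cid, length(unknown), unknown[1]))
    if (any(cohort$counts[[cid]]$pos < 1L))
      note("error", sprintf("cross %s: non-positive SNP position", cid))
  }
  parent_ids <- cohort$parents$gm$individuals
  for (i in seq_len(nrow(cohort$crosses))) {
    cr <- cohort$crosses[i, ]
    if (cr$phased) {
      if (!all(c(cr$mother, cr$father) %in% parent_ids))
        note("error", sprintf("phased cross %s: parent genotypes missing", cr$cross_id))
    } else {
      if (is.null(cohort$sib_gms[[cr$cross_id]]))
        note("error", sprintf("unphased cross %s: sibling genotypes missing", cr$cross_id))
      if (all(c(cr$mother, cr$father) %in% parent_ids))
        note("warning", sprintf("unphased cross %s: parental genotypes supplied; proceeding unphased",
                                cr$cross_id))
    }
  }
  if (length(diags)) do.call(rbind, diags)
  else data.frame(level = character(), message = character())
}

#' Run the full ASE analysis over a cohort
#'
#' Stages: input validation; per-cross SNP filtering and gene-level ASE
#' with BH correction; cross intersections with the permutation null over
#' the genes detectable in every cross; the consistency list
#' (significant in >= `min_crosses`); and enrichment statistics — CNV vs
#' ASE and sweep vs ASE Fisher tests (autosomal genes), per-cross gene-age
#' enrichment, the chromosome-arm ANOVA, and CRM flanking-gene assignment.
#' For the 2x2 tests, "ASE" genes are the consistency list and "non-ASE"
#' genes are those detectable in every cross but significant in none.
#'
#' @param cohort cohort list ([simulate_cohort()] or [read_cohort()]).
#' @param config a [run_config()].
#' @param out_dir optional output directory for the report tables and
#'   manifest.
#' @return list of class `ase_report`: `results` (per-cross result
#'   data.frames), `result_sets`, `intersections`, `permutation`,
#'   `consistency`, `enrichment` (list: `cnv`, `sweep`, `ages`, `arm`,
#'   `crm`), `diagnostics`, `config`.
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir = NULL) {
  diags <- validate_inputs(cohort)
  if (any(diags$level == "error"))
    stop("input validation failed:\n  ",
         paste(diags$message[diags$level == "error"], collapse = "\n  "))
  nm <- null_model(rho = config$rho, n_sims = config$n_sims,
                   seed = substream_seed(config$seed, "ase"))

  results <- list()
  for (i in seq_len(nrow(cohort$crosses))) {
    cr <- cohort$crosses[i, ]
    results[[cr$cross_id]] <- ase_gene_table(
      cohort$counts[[cr$cross_id]], nm, phased = cr$phased,
      min_total = config$min_total, alpha = config$alpha)
  }
  result_sets <- lapply(results, cross_result_set, alpha = config$alpha)

  universe <- Reduce(intersect, lapply(result_sets, function(s) s$detectable))
  inter <- intersect_ase(result_sets)
  perm <- permute_intersection(result_sets, universe,
                               n_perm = config$n_perm,
                               seed = substream_seed(config$seed, "permute"))
  consist <- consistency_table(result_sets, k = config$min_crosses,
                               alpha = config$alpha)

  # enrichment universe: detectable in every cross; ASE = consistency list,
  # non-ASE = significant nowhere
  n_sig <- table(unlist(lapply(result_sets, function(s) s$significant)))
  ase_genes <- consist$gene_id
  non_ase <- setdiff(universe, names(n_sig))
  gene_arm <- stats::setNames(cohort$genes$arm, cohort$genes$gene_id)
  autosomal <- function(g) g[gene_arm[g] %in% AUTOSOMES]

  cnv <- cnv_flag(cohort$cn_table)
  has_cnv <- stats::setNames(cnv$has_cnv, cnv$gene_id)
  a_genes <- autosomal(ase_genes); na_genes <- autosomal(non_ase)
  cnv_test <- fisher_exact_2x2(sum(has_cnv[a_genes], na.rm = TRUE),
                               sum(!has_cnv[a_genes], na.rm = TRUE),
                               sum(has_cnv[na_genes], na.rm = TRUE),
                               sum(!has_cnv[na_genes], na.rm = TRUE))

  swp <- sweep_flag(cohort$genes, cohort$sweeps)
  in_sweep <- stats::setNames(swp$in_sweep, swp$gene_id)
  sweep_test <- fisher_exact_2x2(sum(in_sweep[ase_genes]),
                                 sum(!in_sweep[ase_genes]),
                                 sum(in_sweep[non_ase]),
                                 sum(!in_sweep[non_ase]))

  ages <- age_assign(cohort$presence, cohort$tree_newick, focal = "t1")
  age_tests <- lapply(result_sets, function(s) {
    ns <- setdiff(s$detectable, s$significant)
    age_enrichment(s$significant, ns, ages)
  })

  arm_rows <- do.call(rbind, lapply(result_sets, function(s) {
    det_arm <- gene_arm[s$detectable]
    sig_arm <- gene_arm[s$significant]
    arms <- AUTOSOMES  # X excluded: undetectable in sibling-inferred crosses
    data.frame(arm = arms, cross = s$cross_id,
               proportion = as.vector(table(factor(sig_arm, arms))) /
                 pmax(1L, as.vector(table(factor(det_arm, arms)))),
               stringsAsFactors = FALSE)
  }))
  arm_test <- arm_anova(arm_rows)

  crm_map <- flank_assign(cohort$crms, cohort$genes)
  crm_ase <- unique(crm_map$label[crm_map$gene_id %in% ase_genes])

  report <- structure(list(results = results, result_sets = result_sets,
                           intersections = inter, permutation = perm,
                           consistency = consist,
                           enrichment = list(cnv = cnv_test,
                                             sweep = sweep_test,
                                             ages = age_tests,
                                             arm = arm_test,
                                             crm = list(map = crm_map,
                                                        n_ase_flanked = length(crm_ase))),
                           diagnostics = diags, universe = universe,
                           config = config),
                      class = "ase_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.ase_report <- function(x, ...) {
  cat("ASE analysis report\n")
  for (cid in names(x$result_sets))
    cat(sprintf("  %s: %d significant / %d detectable genes\n", cid,
                length(x$result_sets[[cid]]$significant),
                length(x$result_sets[[cid]]$detectable)))
  cat(sprintf("  all-cross overlap %d (perm p = %.3g), %d genes in >= %d crosses\n",
              x$permutation$observed, x$permutation$p,
              nrow(x$consistency), x$config$min_crosses))
  cat(sprintf("  CNV OR %.2f (p %.3g); sweep OR %.2f (p %.3g)\n",
              x$enrichment$cnv$odds_ratio, x$enrichment$cnv$p_value,
              x$enrichment$sweep$odds_ratio, x$enrichment$sweep$p_value))
  invisible(x)
}

#' Write an analysis report to a directory
#'
#' Emits per-cross result TSVs, the UpSet-style intersection table, the
#' consistency list, enrichment tables and a JSON manifest (config echo,
#' seeds, package version).
#'
#' @param report an `ase_report`.
#' @param dir output directory.
#' @return named list of paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list()
  for (cid in names(report$results)) {
    p[[paste0("results_", cid)]] <- file.path(dir, sprintf("ase_%s.tsv", cid))
    write_results(report$results[[cid]], p[[paste0("results_", cid)]])
  }
  wt <- function(d, f) {
    path <- file.path(dir, f)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  p$intersections <- wt(report$intersections, "intersections.tsv")
  p$consistency <- wt(report$consistency, "consistency.tsv")
  p$arm_anova <- wt(report$enrichment$arm, "arm_anova.tsv")
  p$crm <- wt(report$enrichment$crm$map, "crm_flanking.tsv")
  fisher_tab <- data.frame(
    test = c("cnv_vs_ase", "sweep_vs_ase"),
    odds_ratio = c(report$enrichment$cnv$odds_ratio,
                   report$enrichment$sweep$odds_ratio),
    p_value = c(report$enrichment$cnv$p_value,
                report$enrichment$sweep$p_value))
  p$fisher <- wt(fisher_tab, "fisher_tests.tsv")
  manifest <- list(package_version = as.character(utils::packageVersion("crossASE")),
                   config = unclass(report$config),
                   permutation = list(observed = report$permutation$observed,
                                      p = report$permutation$p,
                                      null_max = report$permutation$null_max,
                                      mode = report$permutation$mode),
                   n_universe = length(report$universe))
  p$manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(p)
}
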