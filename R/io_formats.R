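# Readers and writers for the minimal file dialects the workflow touches.
# Coordinate conventions are enforced here and nowhere else: VCF positions
# are 1-based, BED-like interval files are 0-based half-open. All readers
# reject malformed rows rather than silently coercing them.

#' Construct a genotype matrix
#'
#' A `genotype_matrix` holds unphased diploid calls for a set of individuals
#' at a set of biallelic sites: two integer allele matrices (`a1`, `a2`,
#' values 0 = REF, 1 = ALT, `NA` = missing) of dimension sites x individuals,
#' plus a site table (`chrom`, `pos`, `ref`, `alt`). Calls are stored in
#' canonical order (`a1 <= a2`) so genotype comparison is order-free.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param a1,a2 integer matrices of allele indices (0/1/NA), one column per
#'   individual; column names are the individual ids.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, a1, a2) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            nrow(a1) == nrow(sites), nrow(a2) == nrow(sites),
            identical(dim(a1), dim(a2)),
            identical(colnames(a1), colnames(a2)))
  if (any(sites$pos < 1L)) stop("VCF positions must be >= 1")
  if (any(!nzchar(sites$ref)) || any(!nzchar(sites$alt)))
    stop("allele strings must be non-empty")
  bad <- (!is.na(a1) & !(a1 %in% c(0L, 1L))) | (!is.na(a2) & !(a2 %in% c(0L, 1L)))
  if (any(bad)) stop("genotype allele indices must be 0, 1 or missing")
  # canonicalise: a1 <= a2, and a call with one missing allele is all-missing
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  half <- xor(is.na(a1), is.na(a2))
  a1[half] <- NA_integer_; a2[half] <- NA_integer_
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  dimnames(a1) <- list(NULL, colnames(a1))
  dimnames(a2) <- list(NULL, colnames(a2))
  rownames(sites) <- NULL
  structure(list(sites = sites,
                 a1 = a1, a2 = a2,
                 individuals = colnames(a1)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d individuals\n",
              nrow(x$sites), length(x$individuals)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$sites), length(x$individuals))

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param sites integer or logical index over sites.
#' @param individuals character, integer or logical index over individuals.
#' @return a `genotype_matrix`.
#' @export
gm_subset <- function(x, sites = NULL, individuals = NULL) {
  if (is.null(sites)) sites <- seq_len(nrow(x$sites))
  if (is.null(individuals)) individuals <- x$individuals
  if (is.character(individuals)) {
    missing_ind <- setdiff(individuals, x$individuals)
    if (length(missing_ind))
      stop("individual(s) not present: ", paste(missing_ind, collapse = ", "))
  }
  genotype_matrix(x$sites[sites, , drop = FALSE],
                  x$a1[sites, individuals, drop = FALSE],
                  x$a2[sites, individuals, drop = FALSE])
}

#' Read diploid GT calls from a VCF file
#'
#' Parses a VCF 4.x file (only the GT field is used) into a
#' [genotype_matrix()]. Only biallelic SNP records are supported end-to-end;
#' multi-allelic rows are dropped with a message reporting how many.
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @param individuals optional character vector restricting (and ordering)
#'   the individuals returned; an absent individual is an error.
#' @return a [genotype_matrix()] with records in file order.
#' @export
read_vcf_subset <- function(path, individuals = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- !grepl(",", fix$ALT, fixed = TRUE)
  if (any(!keep))
    message(sum(!keep), " multi-allelic record(s) dropped")
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  if (!is.null(individuals)) {
    absent <- setdiff(individuals, colnames(gt))
    if (length(absent))
      stop("individual(s) absent from VCF: ", paste(absent, collapse = ", "))
    gt <- gt[, individuals, drop = FALSE]
  }
  parse_allele <- function(x) {
    a <- suppressWarnings(as.integer(x))
    a[x %in% c(".", "")] <- NA_integer_
    if (any(is.na(a) & !(x %in% c(".", ""))))
      stop("malformed GT allele: ", x[which(is.na(a) & !(x %in% c(".", "")))[1]])
    a
  }
  # split "0/1" / "0|1" / "./." into two allele matrices; vcfR returns
  # missing GT as NA
  gt_chr <- sub("\\|", "/", gt)
  gt_chr[is.na(gt_chr)] <- "./."
  parts <- strsplit(as.vector(gt_chr), "/", fixed = TRUE)
  n_alleles <- lengths(parts)
  if (any(n_alleles != 2L & !is.na(as.vector(gt_chr))))
    stop("non-diploid GT at record ",
         which(matrix(n_alleles != 2L, nrow = nrow(gt)), arr.ind = TRUE)[1, 1])
  a1 <- matrix(parse_allele(vapply(parts, `[`, "", 1L)), nrow = nrow(gt),
               dimnames = dimnames(gt))
  a2 <- matrix(parse_allele(vapply(parts, `[`, "", 2L)), nrow = nrow(gt),
               dimnames = dimnames(gt))
  sites <- data.frame(chrom = fix$CHROM,
                      pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  if (any(is.na(sites$pos))) stop("malformed POS in VCF record")
  genotype_matrix(sites, a1, a2)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Writes a VCF 4.2 file containing CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO
#' and a GT-only FORMAT column per individual.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf_subset <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$individuals), collapse = "\t")),
             con)
  fmt_call <- function(a1, a2) {
    out <- paste(a1, a2, sep = "/")
    out[is.na(a1)] <- "./."
    out
  }
  calls <- vapply(seq_along(gm$individuals), function(j)
    fmt_call(gm$a1[, j], gm$a2[, j]), character(nrow(gm$sites)))
  if (nrow(gm$sites) == 1L) calls <- matrix(calls, nrow = 1L)
  body <- cbind(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
                ".", "PASS", ".", "GT", calls)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read gene annotation (BED-like, 5 columns)
#'
#' Expects a headerless TSV with columns chrom, start, end, gene_id, arm;
#' intervals are 0-based half-open as in BED.
#'
#' @param path path to the annotation file.
#' @return data.frame with columns `chrom`, `start`, `end`, `gene_id`, `arm`.
#' @export
read_gene_annotation <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      gene_id = character(), arm = character()))
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "gene_id", "arm"),
                         colClasses = c("character", "integer", "integer",
                                        "character", "character"))
  if (any(d$start >= d$end))
    stop("invalid interval (start >= end) at row ", which(d$start >= d$end)[1])
  bad_arm <- !(d$arm %in% ARM_LEVELS)
  if (any(bad_arm))
    stop("unknown arm label '", d$arm[which(bad_arm)[1]], "' at row ",
         which(bad_arm)[1])
  d
}

#' @rdname read_gene_annotation
#' @param genes data.frame as returned by `read_gene_annotation`.
#' @export
write_gene_annotation <- function(genes, path) {
  utils::write.table(genes[, c("chrom", "start", "end", "gene_id", "arm")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genomic intervals (BED, 3 or 4 columns)
#'
#' 0-based half-open intervals; the optional fourth column is a free-text
#' label (filled with `interval_<i>` when absent).
#'
#' @param path path to a BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `label`.
#' @export
read_intervals <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character()))
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 3L) stop("BED file needs at least 3 columns")
  d <- d[, 1:min(4L, ncol(d))]
  names(d) <- c("chrom", "start", "end", "label")[seq_len(ncol(d))]
  if (ncol(d) == 3L) d$label <- sprintf("interval_%d", seq_len(nrow(d)))
  d$start <- as.integer(d$start); d$end <- as.integer(d$end)
  if (any(is.na(d$start)) || any(is.na(d$end)))
    stop("non-integer interval bound")
  if (any(d$start >= d$end))
    stop("invalid interval (start >= end) at row ", which(d$start >= d$end)[1])
  d
}

#' @rdname read_intervals
#' @param intervals data.frame with columns `chrom`, `start`, `end`, `label`.
#' @export
write_intervals <- function(intervals, path) {
  utils::write.table(intervals[, c("chrom", "start", "end", "label")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

COUNT_COLS <- c("sample_id", "chrom", "pos", "gene_id",
                "count_a", "count_b", "phase_known")

#' Read a per-SNP allelic count table
#'
#' TSV with header columns `sample_id`, `chrom`, `pos` (1-based), `gene_id`,
#' `count_a`, `count_b`, `phase_known`. For phased crosses `count_a` holds
#' reads supporting the maternal allele; for unphased crosses it holds reads
#' supporting the reference allele.
#'
#' @param path path to the TSV.
#' @return data.frame with the columns above.
#' @export
read_count_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  miss <- setdiff(COUNT_COLS, names(d))
  if (length(miss))
    stop("count table missing column(s): ", paste(miss, collapse = ", "))
  d <- d[, COUNT_COLS]
  d$pos <- as.integer(d$pos)
  d$count_a <- as.integer(d$count_a); d$count_b <- as.integer(d$count_b)
  if (any(is.na(d$count_a)) || any(is.na(d$count_b)))
    stop("non-integer read count")
  if (any(d$count_a < 0L) || any(d$count_b < 0L))
    stop("negative read count at row ",
         which(d$count_a < 0L | d$count_b < 0L)[1])
  d$phase_known <- as.logical(d$phase_known)
  d
}

#' @rdname read_count_table
#' @param counts data.frame of count rows.
#' @export
write_count_table <- function(counts, path) {
  stopifnot(all(COUNT_COLS %in% names(counts)))
  if (any(counts$count_a < 0) || any(counts$count_b < 0))
    stop("negative read count")
  utils::write.table(counts[, COUNT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

RESULT_COLS <- c("cross_id", "gene_id", "n_snps", "maf", "maternal_fraction",
                 "p_ase", "p_het", "q_ase", "q_het", "direction")

#' Read/write gene-level ASE result tables
#'
#' The results TSV carries one row per gene per cross with a fixed,
#' documented column order so downstream diffs are bit-stable:
#' `cross_id, gene_id, n_snps, maf, maternal_fraction, p_ase, p_het,
#' q_ase, q_het, direction`.
#'
#' @param results data.frame of gene-level results.
#' @param path file path.
#' @return `write_results` returns `path` invisibly; `read_results` the
#'   data.frame.
#' @export
write_results <- function(results, path) {
  miss <- setdiff(RESULT_COLS, names(results))
  if (length(miss))
    stop("results missing column(s): ", paste(miss, collapse = ", "))
  utils::write.table(results[, RESULT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  miss <- setdiff(RESULT_COLS, names(d))
  if (length(miss))
    stop("results missing column(s): ", paste(miss, collapse = ", "))
  d[, RESULT_COLS]
}

#' Read/write a per-gene per-individual copy-number table
#'
#' Long-format TSV with header `gene_id`, `individual`, `copy_number`.
#'
#' @param path file path.
#' @return data.frame with the three columns.
#' @export
read_copy_number <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "individual", "copy_number"), names(d))
  if (length(miss))
    stop("copy-number table missing column(s): ", paste(miss, collapse = ", "))
  d$copy_number <- as.integer(d$copy_number)
  if (any(is.na(d$copy_number)) || any(d$copy_number < 0L))
    stop("copy numbers must be non-negative integers")
  d
}

#' @rdname read_copy_number
#' @param cn data.frame with columns `gene_id`, `individual`, `copy_number`.
#' @export
write_copy_number <- function(cn, path) {
  utils::write.table(cn[, c("gene_id", "individual", "copy_number")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a gene presence/absence matrix
#'
#' TSV with header: first column `gene_id`, remaining columns one per
#' species-tree tip, entries 0/1.
#'
#' @param path file path.
#' @return integer matrix (genes x tips) with gene ids as row names.
#' @export
read_presence_matrix <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "gene_id") stop("first column must be 'gene_id'")
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || !all(m %in% c(0L, 1L)))
    stop("presence matrix entries must be 0 or 1")
  rownames(m) <- d$gene_id
  m
}

#' @rdname read_presence_matrix
#' @param presence integer matrix (genes x tips), 0/1, row names = gene ids.
#' @export
write_presence_matrix <- function(presence, path) {
  d <- data.frame(gene_id = rownames(presence), presence,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
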