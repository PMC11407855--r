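#' @keywords internal
"_PACKAGE"

# Chromosome-arm universe. Anything else falls into "other" (Y, UNKN, mito).
ARM_LEVELS <- c("2L", "2R", "3L", "3R", "X", "other")
AUTOSOMES <- c("2L", "2R", "3L", "3R")

#' Map a chromosome label to its arm bucket
#'
#' Arms outside the canonical \{2L, 2R, 3L, 3R, X\} universe (Y, unplaced
#' contigs, mitochondrion) collapse into `"other"`.
#'
#' @param chrom character vector of chromosome labels.
#' @return factor with levels `c("2L","2R","3L","3R","X","other")`.
#' @export
arm_of <- function(chrom) {
  out <- ifelse(chrom %in% ARM_LEVELS[ARM_LEVELS != "other"], chrom, "other")
  factor(out, levels = ARM_LEVELS)
}

# Deterministic 31-bit string hash, used to fan a global seed out into
# independent per-unit substreams (per gene, per stage) so results do not
# depend on processing order.
hash31 <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

#' Derive a reproducible substream seed
#'
#' Combines a global seed with a named label so that independent pipeline
#' stages (and independent genes within a stage) get decoupled random
#' streams. The result is always a valid 31-bit seed.
#'
#' @param seed integer global seed.
#' @param label character scalar naming the substream.
#' @return integer seed.
#' @export
substream_seed <- function(seed, label) {
  as.integer((as.numeric(seed) %% 2147483647 + hash31(label)) %% 2147483647)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name))
  invisible(x)
}
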