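#' @importFrom data.table data.table as.data.table setkey setkeyv setorder
#'   setorderv rbindlist setnames fread fwrite := .N .SD
NULL

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream of child seeds from a master seed, staying inside 32-bit
# integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset)) %% 2147483647L)
}

DNA_BASES <- c("A", "C", "G", "T")

is_dna <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  grepl(pat, x)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Reverse complement for plain character vectors (Biostrings does the work).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Plain string reversal (no complement), vectorised.
revstr <- function(x) {
  as.character(Biostrings::reverse(Biostrings::DNAStringSet(x)))
}

complement_str <- function(x) {
  as.character(Biostrings::complement(Biostrings::DNAStringSet(x)))
}

#' Share of the genome covered by a capture target
#'
#' Computes the percentage of a genome taken up by a capture target region,
#' the figure used to express the fold enrichment achievable by in-solution
#' capture (e.g. a 215.5 kb HLA target on a 3.23 Gb genome is about 0.007%
#' of the genome, so a 5% on-target rate is a roughly 700-fold enrichment).
#'
#' @param target_bp Target region size in base pairs.
#' @param genome_bp Genome size in base pairs.
#' @return Percentage of the genome covered by the target (0-100 scale).
#' @examples
#' target_genome_fraction(215500, 3.23e9)
#' @export
target_genome_fraction <- function(target_bp, genome_bp) {
  stopifnot(target_bp > 0, genome_bp > 0)
  100 * target_bp / genome_bp
}

# Interval coverage: given 0-based starts and lengths, return per-position
# depth over [0, seq_len).
footprint_coverage <- function(starts, lens, seq_len) {
  d <- numeric(seq_len + 1L)
  if (length(starts)) {
    add <- tabulate(starts + 1L, nbins = seq_len)
    rem <- tabulate(pmin(starts + lens, seq_len) + 1L, nbins = seq_len + 1L)
    d[seq_len(seq_len)] <- add
    d <- d - rem
  }
  cumsum(d)[seq_len(seq_len)]
}

# Maximal runs of TRUE in a logical vector, as 0-based half-open intervals.
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.table(start = starts[keep], end = ends[keep])
}
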