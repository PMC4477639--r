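#' Select a diversity-maximising benchmark sample panel
#'
#' Picks a small subset of reference samples that still carries every
#' distinct allele of a genotype table. Each restart draws samples
#' uniformly at random without replacement; a drawn sample enters the pool
#' only if it contributes at least one allele not yet in the pool, and
#' drawing stops once all distinct alleles are covered. The smallest pool
#' over all restarts is returned (ties resolved in favour of the first
#' restart that found it). This is the randomised greedy strategy used to
#' reduce large cell-line collections to a compact, maximally diverse
#' benchmark panel.
#'
#' @param genotypes A genotype table (data.frame with columns `sample`,
#'   `locus`, `allele1`, `allele2`), e.g. from [read_genotype_table()].
#' @param n_restarts Number of independent random selections.
#' @param seed Master seed; restart `r` uses `seed + r - 1`.
#' @return Character vector of selected sample ids (in the order kept by
#'   the winning restart). The union of their alleles always equals the
#'   full distinct-allele set of the table.
#' @export
select_diverse_panel <- function(genotypes, n_restarts = 1000L, seed = 1L) {
  stopifnot(n_restarts >= 1L)
  gt <- as.data.table(genotypes)
  if (nrow(gt) == 0L) return(character())
  samples <- unique(gt$sample)
  # per-sample allele sets, as indices into the allele universe
  long <- rbindlist(list(gt[, list(sample = sample, allele = allele1)],
                         gt[, list(sample = sample, allele = allele2)]))
  universe <- unique(long$allele)
  long[, ai := match(allele, universe)]
  sets <- split(long$ai, factor(long$sample, levels = samples))
  sets <- lapply(sets, unique)
  n_all <- length(universe)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    pool <- with_seed(seed + r - 1L, {
      ord <- sample.int(length(samples))
      seen <- logical(n_all)
      kept <- integer(0)
      n_seen <- 0L
      for (i in ord) {
        s <- sets[[i]]
        new <- s[!seen[s]]
        if (length(new)) {
          seen[new] <- TRUE
          n_seen <- n_seen + length(new)
          kept <- c(kept, i)
          if (n_seen == n_all) break
        }
      }
      kept
    })
    if (is.null(best) || length(pool) < length(best)) best <- pool
  }
  samples[best]
}
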