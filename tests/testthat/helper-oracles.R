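# Shared fixtures and independent oracles used across the suite.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rc_chr <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# A tiny two-locus reference built by hand (not via the simulator).
tiny_reference <- function() {
  set.seed(404)
  a1 <- rand_dna(300)
  a2 <- local({ch <- strsplit(a1, "")[[1]]; ch[c(50, 151, 250)] <- c("A", "C", "G"); paste(ch, collapse = "")})
  if (a2 == a1) a2 <- sub("^.", "T", a2)
  b1 <- rand_dna(280)
  allele_reference(
    c("A*01:01", "A*02:01", "B*07:02"),
    c(a1, a2, b1),
    list(cbind(start = c(0L, 100L, 200L), end = c(100L, 200L, 300L)),
         cbind(start = c(0L, 100L, 200L), end = c(100L, 200L, 300L)),
         cbind(start = c(0L, 140L), end = c(140L, 280L)))
  )
}

# Naive Hamming mismatch scan of a probe (and its reverse complement)
# against a target, counting mismatches at every offset by direct
# character comparison.
naive_mismatch_hits <- function(probe, target, max_mm) {
  pl <- nchar(probe); tl <- nchar(target)
  tch <- strsplit(target, "")[[1]]
  hits <- list()
  for (strand in c("+", "-")) {
    p <- if (strand == "+") probe else rc_chr(probe)
    pch <- strsplit(p, "")[[1]]
    for (off in 0:(tl - pl)) {
      mm <- sum(pch != tch[(off + 1):(off + pl)])
      if (mm <= max_mm) {
        hits[[length(hits) + 1]] <- data.frame(offset = off,
                                               mismatch_count = mm,
                                               strand = strand)
      }
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(offset = integer(), mismatch_count = integer(),
                      strand = character())
  }
  out[order(out$offset, out$strand), , drop = FALSE]
}

# Exhaustive admissibility oracle for the perfect-match mapper, built on
# Biostrings exact matching rather than the package's k-mer join. Every
# admissible truncated placement of length >= min_trunc_len contains the
# min_trunc_len-long probe end on its truncated side, so enumerating all
# occurrences of those probe ends and checking each (boundary, length)
# combination by direct substring comparison loses nothing. The same
# placement-preference rule as the mapper (full first, then longest
# truncation per (allele, start, strand)) is applied independently.
oracle_map_reads <- function(seqs, reference, min_trunc_len = 70L) {
  alleles <- reference$name[!reference$excluded]
  R <- nchar(seqs[1])
  Tm <- min_trunc_len
  stopifnot(all(nchar(seqs) == R))
  # one subject: all cDNAs joined by N runs no ACGT pattern can cross
  cds <- unname(reference$cdna[alleles])
  lens <- nchar(cds)
  sep <- strrep("N", R + 1L)
  offs <- cumsum(c(0L, head(lens + R + 1L, -1L)))   # 0-based allele starts
  subj <- Biostrings::DNAString(paste(cds, collapse = sep))
  probes <- list("+" = seqs, "-" = rc_chr(seqs))
  occ <- function(p) {
    m <- Biostrings::matchPDict(Biostrings::PDict(Biostrings::DNAStringSet(p)), subj)
    st <- BiocGenerics::start(m)
    g <- unlist(st) - 1L
    ai <- findInterval(g, offs)
    data.frame(pidx = rep(seq_along(st), lengths(st)), ai = ai,
               pos = g - offs[ai])
  }
  ends_df <- do.call(rbind, lapply(seq_along(alleles), function(i) {
    data.frame(ai = i, e = sort(unique(reference$exons[[alleles[i]]][, "end"])))
  }))
  starts_df <- do.call(rbind, lapply(seq_along(alleles), function(i) {
    data.frame(ai = i, b = sort(unique(reference$exons[[alleles[i]]][, "start"])))
  }))
  res <- list()
  for (strand in c("+", "-")) {
    probe <- probes[[strand]]
    f <- occ(probe)
    if (nrow(f)) {
      res[[length(res) + 1]] <-
        data.frame(pidx = f$pidx, allele = alleles[f$ai], start = f$pos,
                   matched_len = R, full = TRUE, strand = strand,
                   truncated_5p = FALSE, truncated_3p = FALSE)
    }
    # prefix of probe ends at an exon end (3' truncation of footprint):
    # candidate start positions are the occurrences of the Tm-prefix
    p <- merge(occ(substring(probe, 1, Tm)), ends_df, by = "ai")
    p$L <- p$e - p$pos
    p <- p[p$L >= Tm & p$L <= R - 1, ]
    if (nrow(p)) {
      hit <- substring(probe[p$pidx], 1, p$L) ==
        substring(cds[p$ai], p$pos + 1, p$e)
      p <- p[hit, ]
    }
    if (nrow(p)) {
      res[[length(res) + 1]] <-
        data.frame(pidx = p$pidx, allele = alleles[p$ai], start = p$pos,
                   matched_len = p$L, full = FALSE, strand = strand,
                   truncated_5p = FALSE, truncated_3p = TRUE)
    }
    # suffix of probe starts at an exon start (5' truncation): a Tm-suffix
    # occurrence at q implies truncation length L = q - b + Tm
    s <- merge(occ(substring(probe, R - Tm + 1, R)), starts_df, by = "ai")
    s$L <- s$pos - s$b + Tm
    s <- s[s$L >= Tm & s$L <= R - 1 & s$b + s$L <= lens[s$ai], ]
    if (nrow(s)) {
      hit <- substring(probe[s$pidx], R - s$L + 1, R) ==
        substring(cds[s$ai], s$b + 1, s$b + s$L)
      s <- s[hit, ]
    }
    if (nrow(s)) {
      res[[length(res) + 1]] <-
        data.frame(pidx = s$pidx, allele = alleles[s$ai], start = s$b,
                   matched_len = s$L, full = FALSE, strand = strand,
                   truncated_5p = TRUE, truncated_3p = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(out)
  # same preference rule: full beats truncated, longer truncation beats
  # shorter, at the same (read, allele, start, strand)
  out <- out[order(out$pidx, out$allele, out$start, out$strand,
                   -out$full, -out$matched_len), ]
  key <- paste(out$pidx, out$allele, out$start, out$strand)
  out <- out[!duplicated(key), ]
  rownames(out) <- NULL
  out
}

# Canonical string form of a mapping table for set comparison.
mapping_key <- function(df) {
  sort(paste(df$pidx, df$allele, df$start, df$matched_len, df$strand,
             df$truncated_5p, df$truncated_3p))
}

empty_mappings_for_test <- function() {
  data.table::data.table(id = character(), mate = integer(),
                         allele = character(), start = integer(),
                         matched_len = integer(), truncated_5p = logical(),
                         truncated_3p = logical(), strand = character())
}

# Brute-force minimum set cover size over all sample subsets (n <= 12).
min_cover_size <- function(sets, universe) {
  n <- length(sets)
  for (k in 1:n) {
    for (comb in utils::combn(n, k, simplify = FALSE)) {
      if (setequal(unique(unlist(sets[comb])), universe)) return(k)
    }
  }
  n
}

# Random small genotype table for the panel selector.
random_genotype_table <- function(n_samples, n_alleles_universe, seed) {
  set.seed(seed)
  alle <- sprintf("A*%02d:01", seq_len(n_alleles_universe))
  data.frame(
    sample = sprintf("S%02d", seq_len(n_samples)),
    locus = "A",
    allele1 = sample(alle, n_samples, TRUE),
    allele2 = sample(alle, n_samples, TRUE)
  )
}
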