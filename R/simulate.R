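#' Configuration for the synthetic allele reference generator
#'
#' The generator emulates an IMGT-style multi-locus cDNA collection: per
#' locus a random founder sequence partitioned into exons, from which each
#' allele is derived by a fixed number of substitutions at random
#' positions, so alleles of a locus are highly similar but pairwise
#' distinct. Near-identical pairs (e.g. two alleles differing only at two
#' positions a few bases upstream of an exon 3' end) can be engineered on
#' top via [make_erroneous_reference_fixture()].
#'
#' @param n_loci Number of loci (up to 8 named HLA-style loci, further
#'   loci are named `L09`, `L10`, ...).
#' @param alleles_per_locus Alleles per locus.
#' @param n_exons Exons per locus.
#' @param exon_len_range Range (min, max) of exon lengths in bp.
#' @param divergence Substitutions per allele relative to the locus
#'   founder (pairwise allele distance is at least 1 and at most
#'   `2 * divergence`).
#' @param seed RNG seed; the generator is deterministic for a fixed seed.
#' @return A list of class `sim_reference_config`.
#' @export
sim_reference_config <- function(n_loci = 8L, alleles_per_locus = 20L,
                                 n_exons = 3L, exon_len_range = c(140L, 260L),
                                 divergence = 5L, seed = 1L) {
  stopifnot(n_loci >= 1L, alleles_per_locus >= 1L, n_exons >= 1L,
            divergence >= 1L, exon_len_range[1L] <= exon_len_range[2L])
  cfg <- list(n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              n_exons = as.integer(n_exons),
              exon_len_range = as.integer(exon_len_range),
              divergence = as.integer(divergence),
              seed = as.integer(seed))
  class(cfg) <- "sim_reference_config"
  cfg
}

HLA_LOCI <- c("A", "B", "C", "DRB1", "DQA1", "DQB1", "DPA1", "DPB1")

sim_locus_names <- function(n) {
  if (n <= length(HLA_LOCI)) return(HLA_LOCI[seq_len(n)])
  c(HLA_LOCI, sprintf("L%02d", seq.int(length(HLA_LOCI) + 1L, n)))
}

#' Simulate an IMGT-like multi-locus allele reference
#'
#' @param cfg A [sim_reference_config()].
#' @return List with `reference` (an `allele_reference`) and `truth`
#'   (list with per-locus founder sequences and a data.table of the
#'   substitution positions of every allele).
#' @export
simulate_reference <- function(cfg = sim_reference_config()) {
  with_seed(cfg$seed, {
    loci <- sim_locus_names(cfg$n_loci)
    names <- character(); cdna <- character(); exons <- list()
    founders <- list(); subs <- list()
    for (l in loci) {
      exon_lens <- sample(seq.int(cfg$exon_len_range[1L], cfg$exon_len_range[2L]),
                          cfg$n_exons, replace = TRUE)
      len <- sum(exon_lens)
      if (cfg$divergence > len) {
        stop("divergence exceeds cDNA length at locus ", l)
      }
      founder <- random_dna(len)
      founders[[l]] <- founder
      bounds <- cbind(start = cumsum(c(0L, exon_lens[-cfg$n_exons])),
                      end = cumsum(exon_lens))
      seqs <- character(cfg$alleles_per_locus)
      for (j in seq_len(cfg$alleles_per_locus)) {
        for (try in seq_len(200L)) {
          pos <- sort(sample.int(len, cfg$divergence))
          s <- mutate_at(founder, pos)
          if (!s %in% seqs[seq_len(j - 1L)]) break
          s <- NA_character_
        }
        if (is.na(s)) stop("could not generate distinct alleles at locus ", l)
        seqs[j] <- s
        nm <- sprintf("%s*%02d:01:01", l, j)
        names <- c(names, nm)
        cdna <- c(cdna, s)
        exons[[nm]] <- bounds
        subs[[nm]] <- pos
      }
    }
    truth_tab <- data.table(
      allele = names, locus = allele_locus(names),
      n_subs = vapply(subs[names], length, 0L),
      positions = subs[names]
    )
    list(reference = allele_reference(names, cdna, exons[names]),
         truth = list(founders = founders, alleles = truth_tab))
  })
}

# Substitute the bases at 1-based positions `pos` with a different random
# base each (draws from the RNG stream).
mutate_at <- function(seq, pos) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  paste(ch, collapse = "")
}

#' Add a decoy allele differing from a true allele at chosen offsets
#'
#' Builds the erroneous-reference scenario: a decoy allele identical to
#' `allele_name` except at the given offsets relative to the 3' end of one
#' exon (offset -1 is the exon's last base, so offsets `c(-32, -34)`
#' reproduce the classic case of two alleles separated only by the
#' nucleotides 32 and 34 bases upstream of an exon 3' end). Each decoy
#' base is deterministically substituted (A->C, C->G, G->T, T->A). Reads
#' simulated from the true allele then leave a characteristic coverage gap
#' abutting that boundary on the decoy, which
#' [discriminate_boundary_variant()] flags.
#'
#' @param sim A list with `reference` (an `allele_reference`), e.g. from
#'   [simulate_reference()], or an `allele_reference` directly.
#' @param allele_name Allele to copy.
#' @param offsets Negative integer offsets from the exon 3' end (must be
#'   nonempty and lie inside the exon).
#' @param exon Exon index the offsets refer to (default 2).
#' @param decoy_name Name for the decoy; default bumps the allele-group
#'   field past the locus maximum.
#' @return The input with the decoy appended to the reference; the decoy
#'   name is stored in `attr(, "decoy")`.
#' @export
make_erroneous_reference_fixture <- function(sim, allele_name, offsets,
                                             exon = 2L, decoy_name = NULL) {
  ref <- if (inherits(sim, "allele_reference")) sim else sim$reference
  if (length(offsets) == 0L) stop("offsets must be nonempty (decoy would be identical)")
  if (!allele_name %in% ref$name) stop("unknown allele: ", allele_name)
  offsets <- as.integer(offsets)
  stopifnot(all(offsets < 0L))
  bounds <- ref$exons[[allele_name]]
  if (exon > nrow(bounds)) stop("allele has no exon ", exon)
  e_start <- bounds[exon, "start"]; e_end <- bounds[exon, "end"]
  pos0 <- e_end + offsets            # 0-based indices
  if (any(pos0 < e_start) || any(pos0 >= e_end)) {
    stop("offset(s) fall outside exon ", exon)
  }
  if (anyDuplicated(pos0)) stop("duplicate offsets")
  ch <- strsplit(ref$cdna[[allele_name]], "", fixed = TRUE)[[1L]]
  map <- c(A = "C", C = "G", G = "T", T = "A")
  ch[pos0 + 1L] <- map[ch[pos0 + 1L]]
  decoy_seq <- paste(ch, collapse = "")
  if (decoy_seq %in% ref$cdna) {
    stop("decoy collides with an existing allele sequence")
  }
  locus <- allele_locus(allele_name)
  if (is.null(decoy_name)) {
    groups <- as.integer(sub(":.*$", "", sub("^.*\\*", "", ref$name[ref$locus == locus])))
    decoy_name <- sprintf("%s*%02d:01:01", locus, max(groups) + 1L)
  }
  ref2 <- allele_reference(
    c(ref$name, decoy_name), c(unname(ref$cdna), decoy_seq),
    c(unname(ref$exons), list(bounds)),
    excluded = ref$exclusion_reason
  )
  out <- if (inherits(sim, "allele_reference")) ref2 else {
    sim$reference <- ref2
    sim
  }
  attr(out, "decoy") <- decoy_name
  out
}

#' Configuration for the paired-end read simulator
#'
#' Emulates a 100 bp paired-end capture sequencing run with fragment sizes
#' of 150-300 bp. Reads are drawn from a genomic construct of each allele:
#' its exons separated by random intron sequence and bracketed by random
#' flanks (capture targets the complete genes including flanking
#' sequence), so reads straddling exon boundaries arise at realistic rates
#' and map only as boundary-truncated alignments. Intron and flank
#' sequences are shared by all alleles of a locus, as they would be in a
#' real gene.
#'
#' @param read_len Read length (default 100).
#' @param frag_range Fragment size range (default 150-300 bp).
#' @param depth Target unique start-point coverage per allele copy at
#'   interior cDNA positions (default 50).
#' @param error_rate Per-base substitution error rate (default 0; the
#'   error model is substitution-only since the mapper is perfect-match).
#' @param flanks Include genomic flanks/introns (default TRUE). With
#'   FALSE, fragments are drawn from the bare cDNA and every read maps
#'   full length.
#' @param flank_len Outer flank length (default = max fragment size, so
#'   boundary reads are unconstrained).
#' @param intron_len_range Intron length range; the minimum is kept at or
#'   above the read length so no read can bridge two exons genomically.
#' @param seed RNG seed.
#' @return A list of class `sim_read_config`.
#' @export
sim_read_config <- function(read_len = 100L, frag_range = c(150L, 300L),
                            depth = 50, error_rate = 0, flanks = TRUE,
                            flank_len = NULL, intron_len_range = c(150L, 300L),
                            seed = 1L) {
  stopifnot(frag_range[1L] >= read_len, frag_range[1L] <= frag_range[2L],
            depth >= 0, error_rate >= 0, error_rate < 1)
  if (is.null(flank_len)) flank_len <- frag_range[2L]
  if (intron_len_range[1L] < read_len) {
    stop("intron length minimum must be at least the read length")
  }
  cfg <- list(read_len = as.integer(read_len),
              frag_range = as.integer(frag_range), depth = depth,
              error_rate = error_rate, flanks = isTRUE(flanks),
              flank_len = as.integer(flank_len),
              intron_len_range = as.integer(intron_len_range),
              seed = as.integer(seed))
  class(cfg) <- "sim_read_config"
  cfg
}

# Genomic construct of one allele: flank + exon1 + intron1 + ... + flank.
# Introns/flanks are generated from the locus-level seed so all alleles of
# a locus share them. Returns the construct string plus the exon spans in
# construct coordinates.
build_genomic_construct <- function(cdna, exon_bounds, locus_seed, cfg) {
  n_ex <- nrow(exon_bounds)
  ex_seqs <- substring(cdna, exon_bounds[, "start"] + 1L, exon_bounds[, "end"])
  if (!cfg$flanks) {
    # bare cDNA: one contiguous mappable span, junction-crossing reads are
    # full-length matches
    return(list(seq = cdna,
                spans = cbind(start = 0L, end = nchar(cdna)),
                cdna_off = 0L))
  }
  fill <- with_seed(locus_seed, {
    intron_lens <- sample(seq.int(cfg$intron_len_range[1L],
                                  cfg$intron_len_range[2L]),
                          max(n_ex - 1L, 1L), replace = TRUE)
    list(f5 = random_dna(cfg$flank_len), f3 = random_dna(cfg$flank_len),
         introns = vapply(intron_lens, random_dna, ""))
  })
  parts <- character(0)
  spans <- matrix(0L, n_ex, 2L, dimnames = list(NULL, c("start", "end")))
  cur <- cfg$flank_len
  parts <- fill$f5
  for (i in seq_len(n_ex)) {
    spans[i, ] <- c(cur, cur + nchar(ex_seqs[i]))
    parts <- c(parts, ex_seqs[i])
    cur <- cur + nchar(ex_seqs[i])
    if (i < n_ex) {
      parts <- c(parts, fill$introns[i])
      cur <- cur + nchar(fill$introns[i])
    }
  }
  parts <- c(parts, fill$f3)
  list(seq = paste(parts, collapse = ""), spans = spans,
       cdna_off = exon_bounds[, "start"])
}

# Number of fragments per allele copy needed to reach the target unique
# start-point coverage at interior positions: per strand, a position is
# overlapped by read_len admissible start positions, each occupied with
# probability 1 - exp(-n/U) for n fragments over U start positions.
fragments_for_depth <- function(depth, construct_len, cfg) {
  U <- max(construct_len - mean(cfg$frag_range) + 1, 1)
  per_strand <- depth / 2
  if (per_strand >= cfg$read_len) {
    stop("target depth exceeds saturation (2 * read_len)")
  }
  n <- U * -log(1 - per_strand / cfg$read_len)
  as.integer(ceiling(n * 1.15))     # headroom for start-point collisions
}

#' Simulate paired-end reads from a diploid genotype
#'
#' Fragments are drawn uniformly from the genomic construct of each
#' genotype allele (both copies of a homozygous genotype contribute), with
#' uniform fragment lengths in the configured range; the mates are the two
#' fragment ends, reverse-complemented on the far side, with random
#' fragment orientation. A truth table records, for every mate, its source
#' allele and construct position together with the cDNA mapping it should
#' produce under the perfect-match rules: a full-length placement when the
#' read lies inside one exon, a boundary-truncated placement when it
#' overlaps one exon by at least `min_trunc_len`, or no mapping at all
#' (reads lost to introns/flanks).
#'
#' @param genotype Character vector of two allele names (equal for a
#'   homozygous genotype).
#' @param reference An `allele_reference` (or a list with a `$reference`).
#' @param cfg A [sim_read_config()].
#' @param min_trunc_len Minimum truncated mapping length used for the
#'   truth annotation (default 70).
#' @return List with `reads1`, `reads2` (character vectors), `ids`
#'   (Casava 1.8 style read names) and `truth` (data.table: `id`, `mate`,
#'   `allele`, `construct_start`, `strand`, `expect_start`, `expect_len`,
#'   `mappable`).
#' @export
simulate_reads <- function(genotype, reference, cfg = sim_read_config(),
                           min_trunc_len = 70L) {
  ref <- if (inherits(reference, "allele_reference")) reference else reference$reference
  stopifnot(length(genotype) == 2L, all(genotype %in% ref$name))
  loci <- unique(ref$locus)
  R <- cfg$read_len
  out <- vector("list", 2L)
  for (ci in 1:2) {
    al <- genotype[ci]
    locus_seed <- derive_seed(cfg$seed, match(allele_locus(al), loci))
    con <- build_genomic_construct(ref$cdna[[al]], ref$exons[[al]],
                                   locus_seed, cfg)
    G <- nchar(con$seq)
    n <- fragments_for_depth(cfg$depth, G, cfg)
    sim <- with_seed(derive_seed(cfg$seed, 1000L + ci), {
      flen <- sample(seq.int(cfg$frag_range[1L], cfg$frag_range[2L]), n,
                     replace = TRUE)
      fs <- as.integer(floor(stats::runif(n) * (G - flen + 1L)))
      flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
      list(flen = flen, fs = fs, flip = flip)
    })
    if (n == 0L) {
      out[[ci]] <- data.table(copy = integer(), allele = character(),
                              reads1 = character(), reads2 = character(),
                              m1_start = integer(), m2_start = integer(),
                              m1_strand = character(), m2_strand = character())
      attr(out[[ci]], "construct") <- con
      next
    }
    s1 <- sim$fs                         # left read, construct start
    s2 <- sim$fs + sim$flen - R          # right read, construct start
    left <- substring(con$seq, s1 + 1L, s1 + R)
    right <- revcomp(substring(con$seq, s2 + 1L, s2 + R))
    reads1 <- ifelse(sim$flip, right, left)
    reads2 <- ifelse(sim$flip, left, right)
    m1_start <- ifelse(sim$flip, s2, s1)
    m2_start <- ifelse(sim$flip, s1, s2)
    m1_strand <- ifelse(sim$flip, "-", "+")
    m2_strand <- ifelse(sim$flip, "+", "-")
    out[[ci]] <- data.table(
      copy = ci, allele = al, reads1 = reads1, reads2 = reads2,
      m1_start = m1_start, m2_start = m2_start,
      m1_strand = m1_strand, m2_strand = m2_strand
    )
    attr(out[[ci]], "construct") <- con
  }
  cons <- lapply(out, attr, "construct")
  tab <- rbindlist(out)
  n_tot <- nrow(tab)
  ids <- sprintf("SIM:1:FC1:1:1:%d:%d", seq_len(n_tot) %/% 10000L + 1000L,
                 seq_len(n_tot) %% 10000L + 1000L)
  reads1 <- tab$reads1
  reads2 <- tab$reads2
  if (cfg$error_rate > 0) {
    reads1 <- with_seed(derive_seed(cfg$seed, 31L),
                        add_substitution_errors(reads1, cfg$error_rate))
    reads2 <- with_seed(derive_seed(cfg$seed, 32L),
                        add_substitution_errors(reads2, cfg$error_rate))
  }
  truth <- rbindlist(lapply(1:2, function(mate) {
    st <- if (mate == 1L) tab$m1_start else tab$m2_start
    sr <- if (mate == 1L) tab$m1_strand else tab$m2_strand
    exp <- expected_mapping(st, R, cons[tab$copy], min_trunc_len)
    data.table(id = ids, mate = mate, allele = tab$allele,
               construct_start = st, strand = sr,
               expect_start = exp$start, expect_len = exp$len,
               mappable = exp$mappable)
  }))
  list(reads1 = reads1, reads2 = reads2, ids = ids, truth = truth)
}

# For construct-coordinate reads [st, st+R), derive the expected cDNA
# placement under the perfect-match + boundary-truncation rules.
expected_mapping <- function(st, R, cons, min_trunc_len) {
  n <- length(st)
  start <- rep(NA_integer_, n); len <- rep(NA_integer_, n)
  grp <- vapply(cons, function(x) paste(x$spans, collapse = ","), "")
  for (g in unique(grp)) {
    sel <- which(grp == g)
    spans <- cons[[sel[1L]]]$spans
    off <- cons[[sel[1L]]]$cdna_off
    a <- st[sel]; b <- a + R
    # per-exon overlap of each read, reads x exons
    ov_s <- outer(a, spans[, "start"], pmax)
    ov_e <- outer(b, spans[, "end"], pmin)
    ov <- ov_e - ov_s
    j <- max.col(ov, ties.method = "first")
    pick <- cbind(seq_along(sel), j)
    ovj <- ov[pick]
    ok <- ovj >= min_trunc_len        # full reads have ovj == R >= this
    start[sel[ok]] <- off[j[ok]] + (ov_s[pick][ok] - spans[j[ok], "start"])
    len[sel[ok]] <- ovj[ok]
  }
  list(start = start, len = len, mappable = !is.na(start))
}

add_substitution_errors <- function(reads, rate) {
  R <- nchar(reads[1L])
  n_err <- stats::rbinom(length(reads), R, rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    reads[i] <- mutate_at(reads[i], sample.int(R, n_err[i]))
  }
  reads
}

#' Write simulated reads as paired FASTQ files
#'
#' Casava 1.8 style headers; qualities are uniform since the pipeline
#' ignores them. Files are gzipped when the paths end in `.gz`.
#'
#' @param sim Output of [simulate_reads()].
#' @param fastq1,fastq2 Output paths for mate 1 and mate 2.
#' @return Invisibly, the read count.
#' @export
write_sim_fastq <- function(sim, fastq1, fastq2) {
  write_one <- function(seqs, ids, mate, path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
    writeLines(paste0("@", ids, " ", mate, ":N:0:1\n", seqs, "\n+\n", qual), con)
  }
  write_one(sim$reads1, sim$ids, 1L, fastq1)
  write_one(sim$reads2, sim$ids, 2L, fastq2)
  invisible(length(sim$ids))
}

#' Read a FASTQ file (plain or gzipped)
#'
#' @param path FASTQ path.
#' @return List with `seqs` (character) and `ids` (header up to the first
#'   space, Casava 1.8 style).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  list(seqs = unname(as.character(x)), ids = sub("[ \t].*$", "", names(x)))
}

#' Simulate a miniature MHC region for bait design
#'
#' Builds, from a simulated allele reference, the three input collections
#' of the bait design procedure: genomic haplotypes (one allele per locus,
#' joined with random intergenic sequence), the per-allele genomic
#' sequences (exons plus shared introns and flanks) and the stand-alone
#' exon records of the cDNA collection.
#'
#' @param sim Output of [simulate_reference()].
#' @param n_haplotypes Number of genomic haplotypes (default 3).
#' @param cfg A [sim_read_config()] supplying intron/flank geometry.
#' @param seed Seed for the intergenic filler.
#' @return List with named character vectors `haplotypes`, `gdna`,
#'   `exons`.
#' @export
simulate_mini_mhc <- function(sim, n_haplotypes = 3L, cfg = sim_read_config(),
                              seed = 99L) {
  ref <- sim$reference
  loci <- unique(ref$locus)
  gdna <- character(); exon_recs <- character()
  construct <- list()
  for (al in ref$name) {
    locus_seed <- derive_seed(cfg$seed, match(allele_locus(al), loci))
    con <- build_genomic_construct(ref$cdna[[al]], ref$exons[[al]],
                                   locus_seed, cfg)
    construct[[al]] <- con$seq
    gdna[[al]] <- con$seq
    b <- ref$exons[[al]]
    for (i in seq_len(nrow(b))) {
      exon_recs[[sprintf("%s_exon%d", al, i)]] <-
        substring(ref$cdna[[al]], b[i, "start"] + 1L, b[i, "end"])
    }
  }
  haplotypes <- with_seed(seed, {
    vapply(seq_len(n_haplotypes), function(h) {
      picks <- vapply(loci, function(l) ref$name[ref$locus == l][h], "")
      inter <- replicate(length(picks) + 1L, random_dna(200L))
      paste0(paste0(inter[seq_along(picks)], construct[picks], collapse = ""),
             inter[length(inter)])
    }, "")
  })
  names(haplotypes) <- sprintf("hap%d", seq_len(n_haplotypes))
  list(haplotypes = haplotypes, gdna = gdna, exons = exon_recs)
}
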