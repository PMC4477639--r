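test_that("harmonic mean: unity at all-ones, annihilation at any zero", {
  w <- default_weights()
  expect_identical(harmonic_score(rep(1, 5), w), 1)
  for (k in 1:5) {
    p <- rep(0.8, 5); p[k] <- 0
    expect_identical(harmonic_score(p, w), 0)
  }
  expect_identical(harmonic_score(rep(0, 5), w), 0)
  expect_equal(harmonic_score(rep(0.5, 5), w), 0.0625)
  expect_error(harmonic_score(rep(1, 5), c(0.5, 1, 0.1, 0, 1)), "> 0")
})

test_that("general and concrete harmonic formulas agree to machine precision", {
  concrete <- function(asm, req, msl, mppr, auc) {
    (2 + 1 + 10 + 10 + 1) * asm * req * msl * mppr * auc /
      (2 * asm + 1 * req + 10 * msl + 10 * mppr + 1 * auc)
  }
  set.seed(12)
  for (i in 1:200) {
    p <- runif(5)
    expect_equal(harmonic_score(p), do.call(concrete, as.list(p)),
                 tolerance = 1e-14)
  }
})

test_that("harmonic mean is strictly monotone in each parameter", {
  w <- default_weights()
  grid <- seq(0.1, 1, by = 0.3)
  vals <- seq(0.05, 1, by = 0.05)
  for (base in list(rep(0.4, 5), rep(0.9, 5), c(0.2, 0.9, 0.5, 0.3, 0.7))) {
    for (k in 1:5) {
      h <- vapply(vals, function(v) { p <- base; p[k] <- v; harmonic_score(p, w) }, 0)
      expect_true(all(diff(h) > 0), info = paste("param", k))
    }
  }
  # bounds: 0 <= H <= 1 over random scaled parameter vectors
  set.seed(9)
  hs <- replicate(500, harmonic_score(runif(5), w))
  expect_true(all(hs >= 0 & hs <= 1))
})

test_that("divide-by-max scaling hits 1 per column and is idempotent", {
  raw <- data.table::data.table(asm = c(10, 5), req = c(0.5, 1),
                                msl = c(500, 500), mppr = c(0, 0),
                                auc = c(0.8, 0.4))
  sc <- scale_params(raw)
  expect_equal(sc[, "asm"], c(1, 0.5))
  expect_equal(sc[, "mppr"], c(0, 0))       # max 0 -> all 0
  expect_equal(unname(apply(sc[, c("asm", "req", "msl", "auc")], 2, max)),
               rep(1, 4))
  sc2 <- scale_params(data.table::as.data.table(sc))
  expect_equal(sc2, sc)
  one <- scale_params(raw[1])
  expect_equal(one[1, c("asm", "req", "msl", "auc")],
               c(asm = 1, req = 1, msl = 1, auc = 1))
})

test_that("central read ratio: boundary semantics of the 0.2 rule", {
  mk_prof <- function(n_central, n_noncentral, len = 2000, R = 100) {
    starts <- c(rep(1000L, n_central), rep(0L, n_noncentral))
    kept <- data.table::data.table(
      id = sprintf("r%d", seq_along(starts)), mate = 1L, allele = "A*01:01",
      start = starts, matched_len = 100L, truncated_5p = FALSE,
      truncated_3p = FALSE, strand = "+")
    # distinct placements so reduction keeps them all
    kept$start <- kept$start + seq_along(starts)
    list(allele = "A*01:01", cdna_len = len, read_len = R, kept = kept,
         starts = integer(len), coverage = integer(len))
  }
  expect_equal(central_read_ratio(mk_prof(5, 0)), Inf)
  expect_equal(central_read_ratio(mk_prof(1, 10)), 0.1)
  expect_equal(central_read_ratio(mk_prof(2, 10)), 0.2)
  expect_true(is.na(central_read_ratio(mk_prof(0, 0))))
})

test_that("prefilter demands full coverage and central ratio >= 0.2", {
  sim <- simulate_reference(sim_reference_config(n_loci = 1,
                                                 alleles_per_locus = 8,
                                                 seed = 13))
  ref <- sim$reference
  idx <- build_index(ref)
  truth <- sort(c(ref$name[2], ref$name[5]))
  reads <- simulate_reads(truth, ref, sim_read_config(seed = 4))
  m <- map_reads(c(reads$reads1, reads$reads2), idx,
                 ids = c(reads$ids, reads$ids),
                 mate = rep(1:2, each = length(reads$ids)))
  profiles <- lapply(ref$name, function(a) {
    reduce_start_points(m[m$allele == a], nchar(ref$cdna[[a]]), allele = a)
  })
  names(profiles) <- ref$name
  pf <- prefilter_candidates(profiles)
  expect_true(all(truth %in% pf$candidates))
  # every non-true allele differs somewhere, so it cannot be fully covered
  expect_setequal(pf$candidates, truth)
  expect_true(all(pf$qc$failed$error > 0))
  expect_equal(pf$qc$undercovered$uncovered,
               sort(pf$qc$undercovered$uncovered))
})

test_that("undercovered QC table is capped at the top 50", {
  profs <- lapply(1:60, function(i) {
    len <- 100L
    list(allele = sprintf("A*%02d:01", i), cdna_len = len, read_len = 100L,
         kept = data.table::data.table(id = "r", mate = 1L,
                                       allele = sprintf("A*%02d:01", i),
                                       start = 0L, matched_len = 100L,
                                       truncated_5p = FALSE,
                                       truncated_3p = FALSE, strand = "+")[0],
         starts = integer(len), coverage = c(rep(1L, 100L - i), rep(0L, i)))
  })
  names(profs) <- vapply(profs, `[[`, "", "allele")
  pf <- prefilter_candidates(profs)
  expect_equal(nrow(pf$qc$undercovered), 50L)
  expect_equal(pf$qc$undercovered$uncovered[1], 1L)
  expect_length(pf$candidates, 0L)
})

test_that("pair parameters match a brute-force recount of the mapping table", {
  sim <- simulate_reference(sim_reference_config(n_loci = 1,
                                                 alleles_per_locus = 6,
                                                 seed = 29))
  ref <- sim$reference
  idx <- build_index(ref)
  truth <- sort(c(ref$name[1], ref$name[4]))
  reads <- simulate_reads(truth, ref, sim_read_config(seed = 8))
  m <- map_reads(c(reads$reads1, reads$reads2), idx,
                 ids = c(reads$ids, reads$ids),
                 mate = rep(1:2, each = length(reads$ids)))
  profiles <- lapply(ref$name, function(a) {
    reduce_start_points(m[m$allele == a], nchar(ref$cdna[[a]]), allele = a)
  })
  names(profiles) <- ref$name
  cand <- prefilter_candidates(profiles)$candidates
  call <- call_genotype(cand, m, profiles, locus = "A")
  a <- truth[1]; b <- truth[2]
  row <- call$pairs[call$pairs$allele1 == a & call$pairs$allele2 == b]

  # brute-force recount over distinct (id, mate) instances
  inst <- unique(data.frame(rid = paste(m$id, m$mate), allele = m$allele))
  set_a <- inst$rid[inst$allele == a]; set_b <- inst$rid[inst$allele == b]
  asm_a <- length(setdiff(set_a, set_b))
  asm_b <- length(setdiff(set_b, set_a))
  expect_equal(row$asm_a, asm_a)
  expect_equal(row$asm_b, asm_b)
  expect_equal(row$asm, asm_a + asm_b)
  expect_equal(row$req, min(asm_a, asm_b) / max(asm_a, asm_b))
  expect_equal(row$msl, mean(c(nchar(ref$cdna[[a]]), nchar(ref$cdna[[b]]))))
  # balanced heterozygote: near-equal exclusive evidence
  expect_gt(row$req, 0.7)
  # truth ranked first
  expect_equal(sort(call$best), truth)
})

test_that("identical-sequence alleles yield req 0 pairs and alternatives", {
  set.seed(404)
  a1 <- rand_dna(300)
  a2 <- local({
    ch <- strsplit(a1, "")[[1]]
    ch[c(50, 151, 250)] <- c("A", "C", "G")
    paste(ch, collapse = "")
  })
  one_exon <- cbind(start = 0L, end = 300L)
  dup <- allele_reference(
    c("A*01:01", "A*02:01", "A*03:01"),
    c(a1, a2, a2),                       # A*03:01 duplicates A*02:01
    list(one_exon, one_exon, one_exon)
  )
  idx <- build_index(dup)
  reads <- simulate_reads(c("A*01:01", "A*02:01"), dup,
                          sim_read_config(seed = 31))
  m <- map_reads(c(reads$reads1, reads$reads2), idx,
                 ids = c(reads$ids, reads$ids),
                 mate = rep(1:2, each = length(reads$ids)))
  la <- m[m$allele %in% c("A*01:01", "A*02:01", "A*03:01")]
  profiles <- lapply(c("A*01:01", "A*02:01", "A*03:01"), function(a) {
    reduce_start_points(la[la$allele == a], nchar(dup$cdna[[a]]), allele = a)
  })
  names(profiles) <- c("A*01:01", "A*02:01", "A*03:01")
  cand <- prefilter_candidates(profiles)$candidates
  expect_setequal(cand, c("A*01:01", "A*02:01", "A*03:01"))
  call <- call_genotype(cand, la, profiles, locus = "A")
  # identical pair (A*02:01, A*03:01): no exclusive reads
  pr <- call$pairs[call$pairs$allele1 == "A*02:01" &
                     call$pairs$allele2 == "A*03:01"]
  expect_equal(pr$asm, 0)
  expect_equal(pr$req, 0)
  # best is one of the two indistinguishable truth-pairs, other is alternative
  expect_equal(call$best[1], "A*01:01")
  expect_true(call$best[2] %in% c("A*02:01", "A*03:01"))
  expect_equal(nrow(call$alternatives), 1L)
})

test_that("homozygous simulations call the homozygote", {
  sim <- simulate_reference(sim_reference_config(n_loci = 1,
                                                 alleles_per_locus = 8,
                                                 seed = 37))
  ref <- sim$reference
  idx <- build_index(ref)
  a <- ref$name[3]
  reads <- simulate_reads(c(a, a), ref, sim_read_config(seed = 5))
  res <- genotype_sample(reads$reads1, reads$reads2, ids = reads$ids,
                         reference = ref, index = idx)
  expect_equal(res$results$allele1, a)
  expect_equal(res$results$allele2, a)
  # homozygous pair req is 1 by definition
  expect_equal(res$results$req, 1)
})

test_that("no candidates produce a flagged no_call", {
  call <- call_genotype(character(), empty_mappings_for_test(), list(),
                        locus = "A")
  expect_true(call$flags$no_call)
  expect_true(all(is.na(call$best)))
})

test_that("boundary-variant discrimination flags 3' gap segments", {
  sim <- simulate_reference(sim_reference_config(n_loci = 1,
                                                 alleles_per_locus = 5,
                                                 seed = 43))
  fix <- make_erroneous_reference_fixture(sim, sim$reference$name[2],
                                          offsets = c(-32, -34), exon = 2)
  decoy <- attr(fix, "decoy")
  ref <- fix$reference
  truth_allele <- ref$name[2]
  idx <- build_index(ref)
  reads <- simulate_reads(c(truth_allele, truth_allele), ref,
                          sim_read_config(seed = 6))
  m <- map_reads(c(reads$reads1, reads$reads2), idx,
                 ids = c(reads$ids, reads$ids),
                 mate = rep(1:2, each = length(reads$ids)))
  prof_decoy <- reduce_start_points(m[m$allele == decoy],
                                    nchar(ref$cdna[[decoy]]), allele = decoy)
  rep_decoy <- discriminate_boundary_variant(prof_decoy, ref$exons[[decoy]])
  expect_gt(nrow(rep_decoy), 0)
  expect_true(any(rep_decoy$exon == 2 & rep_decoy$abuts_3p))
  # the gap contains both changed positions and runs to the exon 3' end
  g <- rep_decoy[rep_decoy$exon == 2 & rep_decoy$abuts_3p]
  e_end <- ref$exons[[decoy]][2, "end"]
  expect_true(all(g$start <= e_end - 34 & g$end > e_end - 32))
  # the true allele itself is clean
  prof_true <- reduce_start_points(m[m$allele == truth_allele],
                                   nchar(ref$cdna[[truth_allele]]),
                                   allele = truth_allele)
  expect_equal(nrow(discriminate_boundary_variant(prof_true,
                                                  ref$exons[[truth_allele]])),
               0L)
})
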