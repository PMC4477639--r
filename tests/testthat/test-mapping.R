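test_that("index lookups agree with naive find-all-substrings", {
  ref <- tiny_reference()
  idx <- build_index(ref)
  # planted probe
  probe <- substring(ref$cdna[[1]], 1, 70)
  hit <- query_index(idx, probe)
  expect_true(any(hit$allele == "A*01:01" & hit$start == 0 & hit$strand == "+"))
  expect_equal(nrow(query_index(idx, strrep("ACGTT", 14))), 0L)

  set.seed(17)
  for (i in 1:200) {
    if (i %% 2 == 0) {
      src <- sample(ref$name, 1)
      at <- sample(nchar(ref$cdna[[src]]) - 79, 1)
      q <- substring(ref$cdna[[src]], at, at + 79)
      if (i %% 4 == 0) q <- rc_chr(q)
    } else {
      q <- rand_dna(80)
    }
    got <- query_index(idx, q)
    # naive oracle over both strands of every allele
    exp <- list()
    for (a in ref$name) {
      for (strand in c("+", "-")) {
        p <- if (strand == "+") q else rc_chr(q)
        m <- gregexpr(p, ref$cdna[[a]], fixed = TRUE)[[1]]
        if (m[1] != -1) {
          exp[[length(exp) + 1]] <- data.frame(allele = a, start = m - 1L,
                                               strand = strand)
        }
      }
    }
    exp <- if (length(exp)) do.call(rbind, exp) else
      data.frame(allele = character(), start = integer(), strand = character())
    expect_equal(paste(got$allele, got$start, got$strand),
                 sort(paste(exp$allele, exp$start, exp$strand)))
  }
})

test_that("interior reads map full-length; boundary reads map truncated", {
  ref <- tiny_reference()
  idx <- build_index(ref)
  cd <- ref$cdna[[1]]

  full <- map_read(substring(cd, 11, 110), idx)
  self <- full[full$allele == "A*01:01"]
  expect_equal(self$start, 10L)
  expect_equal(self$matched_len, 100L)
  expect_false(any(self$truncated_5p | self$truncated_3p))

  # 80 nt ending at the exon-1/exon-2 boundary (position 100), then noise:
  # the genomic picture of a read running into intron 1
  noise <- strrep("A", 20)
  rd <- paste0(substring(cd, 21, 100), noise)
  m <- map_read(rd, idx)
  m <- m[m$allele == "A*01:01"]
  expect_equal(m$start, 20L)
  expect_equal(m$matched_len, 80L)
  expect_true(all(m$truncated_3p))

  # 69 matching nt is below the truncation minimum: no mapping
  rd69 <- paste0(substring(cd, 32, 100), strrep("C", 31))
  m69 <- map_read(rd69, idx)
  expect_equal(nrow(m69[m69$allele == "A*01:01" & m69$truncated_3p]), 0L)

  # suffix matching from an exon start maps 5'-truncated
  rd5 <- paste0(strrep("G", 25), substring(cd, 101, 175))
  m5 <- map_read(rd5, idx)
  m5 <- m5[m5$allele == "A*01:01"]
  expect_equal(m5$start, 100L)
  expect_equal(m5$matched_len, 75L)
  expect_true(all(m5$truncated_5p))
})

test_that("reads with N never match at the N positions", {
  ref <- tiny_reference()
  idx <- build_index(ref)
  rd <- substring(ref$cdna[[1]], 11, 110)
  rdN <- paste0(substring(rd, 1, 50), "N", substring(rd, 52, 100))
  m <- map_read(rdN, idx)
  expect_false(any(m$matched_len == 100))
})

test_that("mapper equals the exhaustive-scan oracle on mixed reads", {
  sim <- simulate_reference(sim_reference_config(n_loci = 2,
                                                 alleles_per_locus = 6,
                                                 seed = 23))
  ref <- sim$reference
  idx <- build_index(ref)
  reads <- simulate_reads(c(ref$name[1], ref$name[8]), ref,
                          sim_read_config(depth = 12, seed = 9))
  set.seed(55)
  seqs <- c(reads$reads1[seq_len(min(150, length(reads$reads1)))],
            vapply(1:50, function(i) rand_dna(100), ""))
  got <- map_reads(seqs, idx)
  got$pidx <- match(got$id, unique(got$id))  # ids are seq_along already
  got$pidx <- got$id
  exp <- oracle_map_reads(seqs, ref)
  expect_identical(mapping_key(data.frame(pidx = got$id, allele = got$allele,
                                          start = got$start,
                                          matched_len = got$matched_len,
                                          strand = got$strand,
                                          truncated_5p = got$truncated_5p,
                                          truncated_3p = got$truncated_3p)),
                   mapping_key(exp))
})

test_that("every emitted mapping is a perfect substring match", {
  ref <- tiny_reference()
  idx <- build_index(ref)
  set.seed(77)
  seqs <- c(
    vapply(1:30, function(i) {
      a <- sample(ref$name, 1)
      at <- sample(nchar(ref$cdna[[a]]) - 99, 1)
      substring(ref$cdna[[a]], at, at + 99)
    }, ""),
    vapply(1:10, function(i) rand_dna(100), "")
  )
  m <- map_reads(seqs, idx)
  expect_gt(nrow(m), 0)
  for (r in seq_len(nrow(m))) {
    cd <- ref$cdna[[m$allele[r]]]
    sub_cd <- substring(cd, m$start[r] + 1, m$start[r] + m$matched_len[r])
    read <- seqs[m$id[r]]
    probe <- switch(paste0(m$strand[r], m$truncated_5p[r]),
                    "+FALSE" = substring(read, 1, m$matched_len[r]),
                    "+TRUE" = substring(read, 101 - m$matched_len[r], 100),
                    "-FALSE" = substring(rc_chr(read), 1, m$matched_len[r]),
                    "-TRUE" = substring(rc_chr(read), 101 - m$matched_len[r], 100))
    expect_identical(sub_cd, probe)
  }
})

test_that("start-point reduction deduplicates placements and is idempotent", {
  ref <- tiny_reference()
  idx <- build_index(ref)
  rd <- substring(ref$cdna[[1]], 1, 100)
  m <- map_reads(rep(rd, 50), idx)
  m <- m[m$allele == "A*01:01"]
  prof <- reduce_start_points(m, 300, allele = "A*01:01")
  expect_equal(prof$starts[1], 1L)
  expect_true(all(prof$coverage[1:100] == 1))
  expect_true(all(prof$coverage[101:300] == 0))

  rd2 <- substring(ref$cdna[[1]], 2, 101)
  m2 <- map_reads(c(rd, rd2), idx)
  m2 <- m2[m2$allele == "A*01:01"]
  prof2 <- reduce_start_points(m2, 300, allele = "A*01:01")
  expect_equal(sum(prof2$starts > 0), 2L)
  expect_true(all(prof2$coverage[2:100] == 2))

  again <- reduce_start_points(prof2$kept, 300, allele = "A*01:01")
  expect_equal(again$kept, prof2$kept)
  expect_equal(again$coverage, prof2$coverage)
})

test_that("reduced coverage equals a brute-force pileup of kept mappings", {
  sim <- simulate_reference(sim_reference_config(n_loci = 1,
                                                 alleles_per_locus = 4,
                                                 seed = 3))
  ref <- sim$reference
  idx <- build_index(ref)
  reads <- simulate_reads(c(ref$name[1], ref$name[2]), ref,
                          sim_read_config(depth = 10, seed = 2))
  m <- map_reads(c(reads$reads1, reads$reads2), idx,
                 ids = c(reads$ids, reads$ids),
                 mate = rep(1:2, each = length(reads$ids)))
  for (a in ref$name[1:2]) {
    ma <- m[m$allele == a]
    prof <- reduce_start_points(ma, nchar(ref$cdna[[a]]), allele = a)
    pile <- integer(nchar(ref$cdna[[a]]))
    k <- prof$kept
    for (r in seq_len(nrow(k))) {
      span <- (k$start[r] + 1):(k$start[r] + k$matched_len[r])
      pile[span] <- pile[span] + 1L
    }
    expect_equal(prof$coverage, pile)
  }
})

test_that("ideal profile matches direct window enumeration", {
  # oracle: nested loop over every admissible window, one strand, doubled
  oracle_ideal <- function(len, R, Tm) {
    cov <- integer(len)
    seen <- character()
    addwin <- function(s, e) {
      key <- paste(s, e)
      if (key %in% seen) return()
      seen <<- c(seen, key)
      cov[(s + 1):e] <<- cov[(s + 1):e] + 1L
    }
    if (len >= R) for (s in 0:(len - R)) addwin(s, s + R)
    for (t in Tm:min(R - 1, len)) { addwin(0, t); addwin(len - t, len) }
    2L * cov
  }
  for (len in c(70, 100, 150, 400)) {
    expect_equal(ideal_profile(len, 100, 70), oracle_ideal(len, 100, 70),
                 info = paste("len", len))
  }
  ip <- ideal_profile(400, 100, 70)
  expect_equal(ip[200], 200L)                 # interior plateau = 2 * read_len
  expect_equal(ip[1], 2L * (1L + 30L))        # 1 full + truncations 70..99
  expect_true(all(ideal_profile(70, 100, 70) ==
                    ideal_profile(70, 100, 70)[1]))  # uniform at len == min
  expect_error(ideal_profile(69, 100, 70), "min_trunc_len")
})
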