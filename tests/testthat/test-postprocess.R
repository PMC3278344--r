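# Postprocess: coordinate translation, mapping quality, hit files, SAM.

test_that("interval_to_positions resolves, truncates and drops boundary spans", {
  idx <- build_index(c(c1 = "ACAACG"))
  iv <- exact_search(idx$fwd, "AC")
  pos <- interval_to_positions(idx, list(low = iv[1L], high = iv[2L], span = 2L))
  expect_setequal(pos$offset, c(0L, 3L))
  expect_true(all(pos$contig == "c1"))
  expect_false(attr(pos, "too_many"))

  # truncation flag
  idx2 <- build_index(c(c1 = strrep("AC", 30)))
  iv2 <- exact_search(idx2$fwd, "AC")
  p2 <- interval_to_positions(idx2, list(low = iv2[1L], high = iv2[2L], span = 2L),
                              max_occurrences = 5L)
  expect_equal(nrow(p2), 5L)
  expect_true(attr(p2, "too_many"))

  # a hit spanning two contigs is dropped
  idx3 <- build_index(c(a = "ACGT", b = "TTTT"))
  iv3 <- exact_search(idx3$fwd, "GTTT") # matches only across the junction
  expect_equal(iv3[2L] - iv3[1L], 1L)
  p3 <- interval_to_positions(idx3, list(low = iv3[1L], high = iv3[2L], span = 4L))
  expect_equal(nrow(p3), 0L)

  # masked-region flag
  idx4 <- build_index(c(a = "ACGTNNACGT"))
  iv4 <- exact_search(idx4$fwd, "GTAA") # Ns packed as A
  p4 <- interval_to_positions(idx4, list(low = iv4[1L], high = iv4[2L], span = 4L))
  expect_true(all(p4$masked))
})

test_that("mapping quality formula is deterministic and monotone", {
  expect_equal(compute_mapq(1L, 0L), 37L)
  expect_equal(compute_mapq(2L, 0L), 0L)
  expect_equal(compute_mapq(5L, 3L), 0L)
  expect_equal(compute_mapq(1L, 1L), 23L)
  expect_equal(compute_mapq(1L, 2L), 15L)
  expect_equal(compute_mapq(1L, 1L, n_diff_gap = 0L), 20L)
  grid <- expand.grid(best = 1:3, sub = 0:6)
  for (b in unique(grid$best)) {
    q <- vapply(0:6, function(s) compute_mapq(b, s), integer(1))
    expect_true(all(diff(q) <= 0L))
  }
})

test_that("hit files round-trip and refuse a foreign index", {
  set.seed(131)
  ref <- random_dna(1000)
  idx <- build_index(c(chr = ref))
  reads <- vapply(1:15, function(i) mutated_read(ref, 30L, sample(0:2, 1)),
                  character(1))
  aln <- align_reads(idx, reads, aln_opts(max_diff = 3))
  path <- file.path(tempdir(), "hits.sai")
  write_hit_file(aln, path)
  back <- read_hit_file(path)
  expect_equal(back$n_reads, 15L)
  expect_equal(back$z, aln$z)
  got <- back$hits[, c("read_id", "strand", "low", "high", "n_mm", "n_gapo",
                       "n_gape", "n_diff")]
  want <- aln$hits[, c("read_id", "strand", "low", "high", "n_mm", "n_gapo",
                       "n_gape", "n_diff")]
  expect_same_hits(got, want)

  # an empty hit set round-trips
  aln0 <- align_reads(idx, "TTTTTAATTTTTCCCCTTTTTGGGGTTTTTT",
                      aln_opts(max_diff = 0))
  p0 <- file.path(tempdir(), "empty.sai")
  write_hit_file(aln0, p0)
  expect_equal(nrow(read_hit_file(p0)$hits), 0L)

  # samse refuses hits built against a different index
  other <- build_index(c(chr = random_dna(1000)))
  expect_error(samse(other, path, aln$reads), "fingerprint")
  suppressWarnings(expect_error(read_hit_file(tempfile()), "cannot open|magic"))
})

test_that("samse emits truth-consistent records and unmapped placeholders", {
  set.seed(137)
  ref <- random_dna(2000)
  idx <- build_index(c(chr7 = ref))
  st <- 500L
  reads <- data.frame(
    name = c("u1", "u2_rc", "nohit"),
    seq = c(substring(ref, st + 1L, st + 40L),
            fmalign:::string_from_codes(fmalign:::revcomp_codes(
              fmalign:::codes_from_string(substring(ref, 801L, 840L))), "N"),
            strrep("ACGTT", 8L)),
    qual = strrep("I", 40L), stringsAsFactors = FALSE)
  aln <- align_reads(idx, reads, aln_opts(max_diff = 1))
  sam <- samse(idx, aln)
  rec <- parse_sam(sam)
  expect_equal(nrow(rec), 3L) # record count == read count
  expect_equal(rec$pos[1L], st)
  expect_equal(rec$strand[1L], "+")
  expect_equal(rec$pos[2L], 800L)
  expect_equal(rec$strand[2L], "-")
  expect_equal(rec$flag[3L], 4L)
  f3 <- strsplit(sam[length(sam)], "\t")[[1L]]
  expect_equal(f3[3L], "*")
  expect_equal(f3[6L], "*")
  # SEQ column of a reverse-strand record is the reverse complement
  f2 <- strsplit(sam[grep("^u2_rc", sam)], "\t")[[1L]]
  expect_equal(f2[10L], substring(ref, 801L, 840L))
  # NM equals the chosen hit's difference count (exact hits here)
  expect_match(sam[grep("^u1", sam)], "NM:i:0")
})

test_that("gapped hits get a consistent CIGAR", {
  set.seed(139)
  ref <- random_dna(1500)
  idx <- build_index(c(chr = ref))
  # deletion read: remove one base from a 40 bp window
  win <- substring(ref, 301L, 340L)
  del_read <- paste0(substring(win, 1L, 19L), substring(win, 21L, 40L))
  # insertion read: add one base mid-window
  ins_read <- paste0(substring(win, 1L, 20L), "A", substring(win, 21L, 39L))
  aln <- align_reads(idx, c(d = del_read, i = ins_read),
                     aln_opts(max_diff = 3))
  sam <- samse(idx, aln)
  body <- sam[!startsWith(sam, "@")]
  f1 <- strsplit(body[1L], "\t")[[1L]]
  f2 <- strsplit(body[2L], "\t")[[1L]]
  expect_match(f1[6L], "D")
  expect_match(f2[6L], "I")
  # CIGAR reference span must match the reported placement
  span_from_cigar <- function(cg) {
    ops <- gregexpr("\\d+[MID]", cg)[[1L]]
    parts <- regmatches(cg, gregexpr("\\d+[MID]", cg))[[1L]]
    sum(vapply(parts, function(p) {
      n <- as.integer(sub("[MID]", "", p))
      if (grepl("[MD]", p)) n else 0L
    }, integer(1)))
  }
  expect_equal(span_from_cigar(f1[6L]), 40L) # 39 read bases + 1 deleted base
  expect_equal(span_from_cigar(f2[6L]), 39L) # 40 read bases - 1 inserted base
  expect_equal(as.integer(f1[4L]), 301L)
})

test_that("emitted SAM parses cleanly with samtools", {
  set.seed(149)
  genome <- simulate_genome(20000, 0.5, rng_seed = 7, name = "ctg1")
  idx <- build_index(genome)
  pr <- sample_read_pairs(genome[[1L]],
                          sim_params(n_pairs = 120, read_len = 50,
                                     base_error_rate = 0.02,
                                     insert_mean = 250, insert_sd = 25,
                                     rng_seed = 8))
  a1 <- align_reads(idx, pr$reads1)
  a2 <- align_reads(idx, pr$reads2)
  sam_path <- file.path(tempdir(), "pairs.sam")
  sampe(idx, a1, a2, out = sam_path)
  out <- system2("samtools", c("view", "-c", sam_path), stdout = TRUE,
                 stderr = TRUE)
  expect_equal(tail(out, 1L), "240")
  flg <- system2("samtools", c("flagstat", sam_path), stdout = TRUE)
  expect_match(flg[1L], "^240")
})

test_that("pair flags, tlen and orientation follow the SAM conventions", {
  set.seed(151)
  genome <- simulate_genome(30000, 0.5, rng_seed = 17, name = "c")
  idx <- build_index(genome)
  pr <- sample_read_pairs(genome[[1L]],
                          sim_params(n_pairs = 150, read_len = 60,
                                     base_error_rate = 0.01,
                                     insert_mean = 400, insert_sd = 40,
                                     rng_seed = 18))
  a1 <- align_reads(idx, pr$reads1)
  a2 <- align_reads(idx, pr$reads2)
  sam <- sampe(idx, a1, a2)
  body <- sam[!startsWith(sam, "@")]
  f <- strsplit(body, "\t")
  flags <- vapply(f, function(x) as.integer(x[2L]), integer(1))
  tlen <- vapply(f, function(x) as.integer(x[9L]), integer(1))
  proper <- bitwAnd(flags, 2L) > 0L
  expect_gt(mean(proper), 0.95)
  # flags are self-consistent within each pair
  for (i in seq(1L, length(body), by = 2L)) {
    expect_equal(bitwAnd(flags[i], 64L), 64L)
    expect_equal(bitwAnd(flags[i + 1L], 128L), 128L)
    if (proper[i]) {
      expect_true(proper[i + 1L])
      s1 <- bitwAnd(flags[i], 16L) > 0L
      s2 <- bitwAnd(flags[i + 1L], 16L) > 0L
      expect_true(xor(s1, s2))
      expect_equal(tlen[i], -tlen[i + 1L])
      expect_equal(bitwAnd(flags[i], 32L) > 0L, s2)
    }
  }
  # proper-pair insert sizes track the simulated distribution
  isz <- abs(tlen[proper & tlen > 0])
  expect_lt(abs(mean(isz) - 400), 2 * 40 / sqrt(length(isz)) + 2)

  # one mate unmapped: partner carries the mate-unmapped flag
  reads_bad <- pr$reads2[1:3, ]
  reads_bad$seq <- vapply(1:3, function(i) random_dna(60L), character(1))
  a2b <- align_reads(idx, reads_bad)
  a1b <- align_reads(idx, pr$reads1[1:3, ])
  samb <- sampe(idx, a1b, a2b)
  bb <- samb[!startsWith(samb, "@")]
  fb <- strsplit(bb, "\t")
  flag1 <- as.integer(fb[[1L]][2L]); flag2 <- as.integer(fb[[2L]][2L])
  expect_equal(bitwAnd(flag1, 8L), 8L)  # mate unmapped
  expect_equal(bitwAnd(flag2, 4L), 4L)  # unmapped itself
  expect_equal(bitwAnd(flag1, 2L), 0L)  # not proper

  # mates mapping to the same strand are never a proper pair
  rc2 <- pr$reads2[4:6, ]
  rc2$seq <- vapply(rc2$seq, function(s)
    fmalign:::string_from_codes(fmalign:::revcomp_codes(
      fmalign:::codes_from_string(s)), "N"), character(1), USE.NAMES = FALSE)
  a2c <- align_reads(idx, rc2)
  a1c <- align_reads(idx, pr$reads1[4:6, ])
  samc <- sampe(idx, a1c, a2c)
  bc <- samc[!startsWith(samc, "@")]
  flc <- vapply(strsplit(bc, "\t"), function(x) as.integer(x[2L]), integer(1))
  expect_true(all(bitwAnd(flc, 2L) == 0L))

  # mismatched pair counts are an error
  expect_error(sampe(idx, a1b, align_reads(idx, pr$reads2[1:2, ])), "mismatch")
})
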