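# FM-index module: packing, suffix array, BWT, occ/SA queries, persistence.

test_that("pack_reference codes bases, masks ambiguity, and round-trips", {
  p <- pack_reference(c(c1 = "ACGT"))
  expect_equal(unpack_reference(p), c(0L, 1L, 2L, 3L))
  expect_equal(p$length, 4L)
  expect_length(p$ambig, 0L)

  p2 <- pack_reference(c(c1 = "ACN"))
  expect_equal(p2$length, 3L)
  expect_equal(p2$ambig, 2L)
  expect_equal(unpack_reference(p2)[3L], 0L) # substitution rule: N -> A

  set.seed(11)
  s <- random_dna(1000)
  p3 <- pack_reference(c(c1 = s))
  expect_equal(fmalign:::string_from_codes(unpack_reference(p3), "N"), s)
  # 2-bit payload: at most ceil(n/4) bytes
  expect_lte(length(p3$packed), ceiling(p3$length / 4))

  expect_error(pack_reference(character(0)), "at least one")
  expect_error(pack_reference(c(c1 = "ACXGT")), "position 3")
})

test_that("multi-contig packing concatenates in input order", {
  p <- pack_reference(c(a = "ACGT", b = "GGNTA"))
  expect_equal(p$contigs$offset, c(0L, 4L))
  expect_equal(p$contigs$length, c(4L, 5L))
  expect_equal(p$length, 9L)
  expect_equal(p$ambig, 6L) # the N, in concatenated coordinates
})

test_that("suffix array and BWT match the worked examples", {
  p <- pack_reference(c(c1 = "ACAACG"))
  sa <- build_suffix_array(p)
  expect_equal(sa, c(6L, 2L, 0L, 3L, 1L, 4L, 5L))
  expect_equal(fmalign:::string_from_codes(bwt_from_sa(p, sa)), "GC$AAAC")

  pA <- pack_reference(c(c1 = "A"))
  expect_equal(build_suffix_array(pA), c(1L, 0L))
  expect_equal(fmalign:::string_from_codes(bwt_from_sa(pA, build_suffix_array(pA))), "A$")

  pR <- pack_reference(c(c1 = "AAAA"))
  expect_equal(build_suffix_array(pR), c(4L, 3L, 2L, 1L, 0L))
})

test_that("suffix order is strictly increasing and sa is a permutation", {
  set.seed(21)
  for (rep in 1:20) {
    s <- random_dna(sample(50:300, 1))
    codes <- fmalign:::codes_from_string(s)
    sa <- build_suffix_array(codes)
    n <- length(codes)
    expect_setequal(sa, 0:n)
    # brute-force: sort all suffixes as strings (sentinel "00" sorts first)
    key <- vapply(0:n, function(i)
      paste(sprintf("%02d", c(codes[seq(i + 1L, length.out = n - i)], -1L) + 1L),
            collapse = ""), character(1))
    expect_equal(sa, order(key) - 1L)
  }
})

test_that("bwt is a permutation of text plus sentinel and inverts", {
  set.seed(31)
  for (rep in 1:20) {
    codes <- sample(0:3, sample(20:1000, 1), replace = TRUE)
    sa <- build_suffix_array(codes)
    bwt <- bwt_from_sa(codes, sa)
    expect_equal(sort(bwt), sort(c(codes, 4L)))
    expect_equal(invert_bwt(bwt), codes)
  }
  expect_error(invert_bwt(c(0L, 1L)), "sentinel")
  expect_error(invert_bwt(c(4L, 4L, 0L)), "sentinel")
})

test_that("occ agrees with a direct scan and is stride-invariant", {
  set.seed(41)
  codes <- sample(0:3, 10000, replace = TRUE)
  sa <- build_suffix_array(codes)
  fm64 <- build_fm_index(codes, sa, occ_stride = 64L)
  fm1 <- build_fm_index(codes, sa, occ_stride = 1L)
  fm32 <- build_fm_index(codes, sa, occ_stride = 32L)
  fm128 <- build_fm_index(codes, sa, occ_stride = 128L)
  bwt <- fm64$bwt
  for (i in 1:300) {
    c_ <- sample(0:3, 1)
    p <- sample(0:(length(bwt)), 1)
    want <- sum(bwt[seq_len(p)] == c_)
    expect_identical(fm_occ(fm64, c_, p), want)
    expect_identical(fm_occ(fm1, c_, p), want)
    expect_identical(fm_occ(fm32, c_, p), want)
    expect_identical(fm_occ(fm128, c_, p), want)
  }
  # stride 1 checkpoints are the full prefix-count table
  expect_equal(nrow(fm1$occ_cp), length(bwt) + 1L)
  expect_true(all(diff(fm64$C) >= 0L))
  expect_error(fm_occ(fm64, 0L, length(bwt) + 5L), "out of range")
})

test_that("LF mapping from the sentinel row visits every row once", {
  set.seed(43)
  codes <- sample(0:3, 500, replace = TRUE)
  fm <- build_fm_index(codes)
  nb <- fm$n + 1L
  # LF(r) derived from C and occ
  r <- 0L
  seen <- logical(nb)
  for (step in seq_len(nb)) {
    expect_false(seen[r + 1L])
    seen[r + 1L] <- TRUE
    c_ <- fm$bwt[r + 1L]
    r <- if (c_ == 4L) 0L else fm$C[c_ + 1L] + fm_occ(fm, c_, r)
  }
  expect_true(all(seen))
})

test_that("backward extension narrows intervals per the subset property", {
  idx <- toy_index(c(c1 = "ACAACG"))
  fm <- idx$fwd
  full <- c(0L, fm$n + 1L)
  ivC <- backward_ext(fm, full, 1L) # strings starting with C: CAACG$, CG$
  expect_equal(ivC[2L] - ivC[1L], 2L)
  expect_equal(backward_ext(fm, c(0L, 0L), 2L), c(0L, 0L))
  set.seed(5)
  for (i in 1:20) {
    iv <- sort(sample(0:(fm$n + 1L), 2))
    out <- backward_ext(fm, iv, sample(0:3, 1))
    expect_lte(out[2L] - out[1L], iv[2L] - iv[1L])
  }
})

test_that("exact search finds all and only the naive scan positions", {
  idx <- toy_index(c(c1 = "ACAACG"))
  iv <- exact_search(idx$fwd, "AC")
  expect_equal(iv[2L] - iv[1L], 2L)
  expect_setequal(sa_lookup(idx$fwd, iv[1L]:(iv[2L] - 1L)), c(0L, 3L))
  expect_equal(exact_search(idx$fwd, "T"), c(0L, 0L))
  expect_equal(exact_search(idx$fwd, ""), c(0L, idx$fwd$n + 1L))
})

test_that("sa_lookup recovers the full suffix array at any stride", {
  set.seed(51)
  codes <- sample(0:3, 800, replace = TRUE)
  sa <- build_suffix_array(codes)
  for (stride in c(1L, 8L, 32L)) {
    fm <- build_fm_index(codes, sa, sa_stride = stride)
    expect_equal(sa_lookup(fm, 0:(length(codes))), sa)
  }
  fm <- build_fm_index(codes, sa)
  expect_equal(sa_lookup(fm, fm$sentinel_row), 0L)
  expect_error(sa_lookup(fm, length(codes) + 1L), "out of range")
})

test_that("index save/load round-trips and rejects corrupt files", {
  set.seed(61)
  seqs <- c(chrA = random_dna(400), chrB = paste0(random_dna(100), "NNN",
                                                  random_dna(80)))
  idx <- build_index(seqs)
  prefix <- file.path(tempdir(), "toyidx")
  save_index(idx, prefix)
  for (ext in c(".pac", ".bwt", ".sa", ".rbwt", ".rsa", ".ann"))
    expect_true(file.exists(paste0(prefix, ext)))
  idx2 <- load_index(prefix)
  expect_equal(idx2$packed$contigs, idx$packed$contigs)
  expect_equal(idx2$packed$ambig, idx$packed$ambig)
  for (q in c("ACGT", "TTT", "GGC", "")) {
    expect_equal(exact_search(idx2$fwd, q), exact_search(idx$fwd, q))
    expect_equal(exact_search(idx2$rev, q), exact_search(idx$rev, q))
  }
  expect_equal(sa_lookup(idx2$fwd, 0:20), sa_lookup(idx$fwd, 0:20))

  # corrupt magic
  bad <- paste0(prefix, "_bad")
  file.copy(paste0(prefix, ".bwt"), paste0(bad, ".bwt"), overwrite = TRUE)
  con <- file(paste0(bad, ".bwt"), "r+b")
  writeBin(charToRaw("XXXXXX"), con)
  close(con)
  for (ext in c(".pac", ".sa", ".rbwt", ".rsa", ".ann"))
    file.copy(paste0(prefix, ext), paste0(bad, ext), overwrite = TRUE)
  expect_error(load_index(bad), "magic")

  # truncated file
  trunc <- paste0(prefix, "_tr")
  for (ext in c(".pac", ".bwt", ".sa", ".rbwt", ".rsa", ".ann"))
    file.copy(paste0(prefix, ext), paste0(trunc, ext), overwrite = TRUE)
  sz <- file.size(paste0(trunc, ".sa"))
  con <- file(paste0(trunc, ".sa"), "rb")
  dat <- readBin(con, "raw", n = sz - 40L)
  close(con)
  writeBin(dat, paste0(trunc, ".sa"))
  expect_error(load_index(trunc), "truncated|version|disagree")
})
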