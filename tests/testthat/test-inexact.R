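# Inexact search: options, automatic difference bound, lower bound, DFS,
# BFS reference, and the text-space oracle.

test_that("aln_opts validates and -o 0 disables gapped branches", {
  o <- aln_opts()
  expect_true(o$gap_open_allowed)
  expect_equal(o$seed_len, 32L)
  expect_false(aln_opts(max_gap_opens = 0L)$gap_open_allowed)
  expect_error(aln_opts(pen_mismatch = 0L))
  expect_error(aln_opts(max_diff = -1))
  expect_error(aln_opts(no_indel_end = 0L))
})

test_that("auto_max_diff matches the binomial tail definition", {
  # independent recomputation of the definition: smallest z with
  # P[Binom(m, r) > z] < 0.01
  direct <- function(m, r) {
    z <- 0L
    while (sum(dbinom((z + 1L):m, m, r)) >= 1e-2 && z < m) z <- z + 1L
    z
  }
  for (m in c(1L, 36L, 50L, 70L, 100L))
    for (r in c(0.02, 0.04))
      expect_identical(auto_max_diff(m, r), direct(m, r))
  # monotone in read length
  zs <- vapply(1:120, auto_max_diff, integer(1), expected_error_rate = 0.04)
  expect_true(all(diff(zs) >= 0L))
  # vanishing error rate gives z = 0
  expect_identical(auto_max_diff(100L, 1e-9), 0L)
})

test_that("lower bound is exact-zero, worked-example-correct, and monotone", {
  idx <- toy_index(c(c1 = "ACAACG"))
  expect_equal(compute_lower_bound(idx$rev, "ACAACG"), rep(0L, 6L))
  expect_equal(compute_lower_bound(idx$rev, "CAAC"), rep(0L, 4L))
  expect_equal(compute_lower_bound(idx$rev, "TT"), c(1L, 2L))
  set.seed(71)
  for (i in 1:100) {
    ref <- random_dna(sample(50:500, 1))
    q <- random_dna(sample(5:40, 1))
    d <- compute_lower_bound(build_index(c(c1 = ref))$rev, q)
    expect_true(all(diff(d) >= 0L))
    expect_true(all(d >= 0L))
  }
})

test_that("DFS reproduces the worked examples", {
  idx <- toy_index(c(c1 = "ACAACG"))
  h0 <- dfs_inexact(idx, query = "ACG", opts = aln_opts(max_diff = 0))
  r0 <- resolve_hits(idx, h0)
  expect_equal(r0, data.frame(pos = 3L, n_diff = 0L))
  expect_equal(h0$high - h0$low, 1L)

  h1 <- dfs_inexact(idx, query = "ACG",
                    opts = aln_opts(max_diff = 1, gap_open_allowed = FALSE))
  expect_equal(resolve_hits(idx, h1),
               data.frame(pos = c(0L, 3L), n_diff = c(1L, 0L)))

  expect_equal(nrow(dfs_inexact(idx, query = "TTT", opts = aln_opts(max_diff = 0))), 0L)

  # all-mismatch path exists when z >= query length
  h <- dfs_inexact(idx, query = "TTT",
                   opts = aln_opts(max_diff = 3, gap_open_allowed = FALSE))
  expect_gt(nrow(h), 0L)

  # empty query: full-interval hit with zero differences
  he <- dfs_inexact(idx, query = "", opts = aln_opts(max_diff = 1))
  expect_equal(nrow(he), 1L)
  expect_equal(he$n_diff, 0L)
  expect_equal(c(he$low, he$high), c(0L, idx$fwd$n + 1L))
})

test_that("a read N is a forced mismatch", {
  set.seed(73)
  ref <- random_dna(300)
  st <- 50L
  q <- substring(ref, st + 1L, st + 20L)
  substr(q, 10L, 10L) <- "N"
  idx <- build_index(c(c1 = ref))
  h <- dfs_inexact(idx, query = q, opts = aln_opts(max_diff = 2))
  r <- resolve_hits(idx, h)
  expect_true(st %in% r$pos)
  expect_equal(r$n_diff[r$pos == st], 1L)
  # and N never matches: z=0 finds nothing
  expect_equal(nrow(dfs_inexact(idx, query = q, opts = aln_opts(max_diff = 0))), 0L)
})

test_that("gap-disabled runs never emit gapped hits", {
  set.seed(77)
  for (i in 1:30) {
    ref <- random_dna(400)
    q <- mutated_read(ref, 25L, n_mut = sample(0:2, 1))
    idx <- build_index(c(c1 = ref))
    h <- dfs_inexact(idx, query = q,
                     opts = aln_opts(max_diff = 3, gap_open_allowed = FALSE))
    if (nrow(h)) expect_true(all(h$n_gapo + h$n_gape == 0L))
  }
})

test_that("oracle reduces to a Hamming scan when gaps are disabled", {
  set.seed(79)
  for (i in 1:40) {
    ref <- random_dna(sample(100:400, 1))
    q <- if (i %% 2) mutated_read(ref, sample(10:30, 1), sample(0:3, 1))
         else random_dna(sample(10:30, 1))
    z <- sample(0:3, 1)
    got <- brute_force_hits(ref, q, aln_opts(max_diff = z, gap_open_allowed = FALSE))
    want <- report_rule(hamming_scan(ref, q, z), z)
    expect_equal(hit_key(got), hit_key(want))
  }
})

test_that("DFS equals the text-space oracle on randomized cases", {
  set.seed(83)
  for (case in 1:120) {
    L <- sample(100:1000, 1)
    m <- sample(8:40, 1)
    ref <- random_dna(L)
    q <- if (runif(1) < 0.7)
      mutated_read(ref, m, n_mut = sample(0:3, 1), indel = runif(1) < 0.4)
    else random_dna(m)
    z <- sample(0:3, 1)
    gaps <- sample(c(TRUE, FALSE), 1)
    opts <- aln_opts(max_diff = z, gap_open_allowed = gaps)
    idx <- build_index(c(c1 = ref))
    got <- resolve_hits(idx, dfs_inexact(idx, query = q, opts = opts))
    want <- brute_force_hits(ref, q, opts)
    expect_equal(hit_key(got), hit_key(want))
  }
})

test_that("every DFS hit is achievable at its resolved position", {
  set.seed(87)
  for (case in 1:30) {
    ref <- random_dna(400)
    q <- mutated_read(ref, 24L, n_mut = sample(0:2, 1), indel = TRUE)
    opts <- aln_opts(max_diff = 3)
    idx <- build_index(c(c1 = ref))
    hits <- dfs_inexact(idx, query = q, opts = opts)
    if (nrow(hits) == 0L) next
    res <- resolve_hits(idx, hits)
    # unfiltered oracle minimum at each position must not exceed the claim
    o2 <- opts; o2$report_suboptimal <- FALSE
    full <- brute_force_hits(ref, q, aln_opts(max_diff = 3))
    for (r in seq_len(nrow(res))) {
      omin <- full$n_diff[full$pos == res$pos[r]]
      expect_true(length(omin) == 1L && omin <= res$n_diff[r])
    }
  }
})

test_that("BFS returns the identical hit set and stores more nodes", {
  set.seed(91)
  frontier_grew <- 0L
  for (case in 1:60) {
    ref <- random_dna(sample(100:600, 1))
    m <- sample(8:40, 1)
    q <- if (runif(1) < 0.7) mutated_read(ref, m, sample(0:2, 1)) else random_dna(m)
    z <- sample(0:3, 1)
    opts <- aln_opts(max_diff = z, gap_open_allowed = sample(c(TRUE, FALSE), 1))
    idx <- build_index(c(c1 = ref))
    a <- dfs_inexact(idx, query = q, opts = opts)
    b <- bfs_inexact_reference(idx, query = q, opts = opts)
    expect_same_hits(a, b)
    expect_lte(attr(a, "peak_nodes"), nchar(q) + 1L)
    # the memory ordering: whenever the BFS frontier outgrows what a single
    # branch could ever hold, the DFS branch store is strictly below it
    if (attr(b, "peak_nodes") > nchar(q) + 1L) {
      frontier_grew <- frontier_grew + 1L
      expect_lt(attr(a, "peak_nodes"), attr(b, "peak_nodes"))
    }
  }
  expect_gt(frontier_grew, 0L) # the ordering claim was actually exercised

  # empty query: full-interval hit, and a frontier cap error is reachable
  idxt <- toy_index(c(c1 = "ACAACGTTGCA"))
  he <- bfs_inexact_reference(idxt, query = "", opts = aln_opts(max_diff = 1))
  expect_equal(nrow(he), 1L)
  expect_equal(he$n_diff, 0L)
  set.seed(93)
  bigref <- random_dna(2000)
  idxb <- build_index(c(c1 = bigref))
  expect_error(bfs_inexact_reference(idxb, query = mutated_read(bigref, 30L, 2L),
                                     opts = aln_opts(max_diff = 3),
                                     frontier_cap = 10),
               "frontier")
})

test_that("query length guard triggers", {
  idx <- toy_index(c(c1 = "ACAACG"))
  o <- aln_opts(max_query_len = 10L)
  expect_error(dfs_inexact(idx, query = strrep("A", 11L), opts = o), "length")
})
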