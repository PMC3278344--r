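# Shared fixtures: random sequences, naive oracles, hit-frame normalisation.

.bases <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(.bases, n, replace = TRUE), collapse = "")

# substring with point mutations and optionally one small indel
mutated_read <- function(ref, m, n_mut = 0L, indel = FALSE) {
  L <- nchar(ref)
  st <- sample(max(1L, L - m), 1L)
  qs <- strsplit(substring(ref, st, st + m - 1L), "")[[1L]]
  if (n_mut > 0L) {
    pos <- sample(m, n_mut)
    qs[pos] <- sample(.bases, n_mut, replace = TRUE)
  }
  if (indel && m >= 14L) {
    p <- sample(7L:(m - 7L), 1L)
    if (runif(1) < 0.5) {
      qs <- append(qs[-p], sample(.bases, 1L), p - 1L) # net substitution-free shift
    } else {
      qs <- append(qs, sample(.bases, 1L), p)[-length(qs) - 1L]
    }
  }
  paste(qs, collapse = "")
}

# naive overlapping substring positions (independent scan via Biostrings)
naive_positions <- function(ref, query) {
  if (!nzchar(query)) return(integer(0))
  m <- Biostrings::matchPattern(query, Biostrings::DNAString(ref))
  BiocGenerics::start(m) - 1L
}

# Hamming-distance scan: minimal mismatch count per start position
hamming_scan <- function(ref, query, z) {
  t <- utf8ToInt(ref); q <- utf8ToInt(query)
  L <- length(t); m <- length(q)
  if (L < m) return(data.frame(pos = integer(0), n_diff = integer(0)))
  d <- vapply(0:(L - m), function(p) sum(t[p + seq_len(m)] != q), integer(1))
  keep <- which(d <= z)
  data.frame(pos = keep - 1L, n_diff = d[keep])
}

# order-normalise a hit frame for set comparison
hit_key <- function(df) {
  df <- as.data.frame(df)
  attributes(df)[setdiff(names(attributes(df)), c("names", "class", "row.names"))] <- NULL
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

expect_same_hits <- function(a, b) {
  expect_equal(hit_key(a), hit_key(b), ignore_attr = TRUE)
}

toy_index <- function(seqs) build_index(seqs)

# apply the reporting rule to an oracle frame (pos, n_diff)
report_rule <- function(df, z, subopt = TRUE) {
  if (nrow(df) == 0L) return(df)
  best <- min(df$n_diff)
  cap <- if (subopt) min(z, best + 1L) else best
  out <- df[df$n_diff <= cap, , drop = FALSE]
  rownames(out) <- NULL
  out
}
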