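# Text-space brute-force oracle for the inexact search.
#
# A vectorised dynamic program over the raw reference text enumerating, for
# every start position, the minimal number of differences (mismatches, gap
# opens, gap extensions) of any alignment of the full query starting there,
# under the same operation model and gap placement rules as the FM-index
# search -- but computed by a completely different route (forward DP over
# linear coordinates, no index involved).  Intended for desk-scale inputs.

#' Brute-force minimal-difference occurrences
#'
#' For each reference position, the minimum differences needed to align the
#' whole query starting there (semi-global: query consumed entirely, the
#' reference free at both ends), subject to the gap budgets and end-exclusion
#' rule of `opts`.  Returns the occurrences passing the same reporting rule
#' as the index search: `n_diff <= z`, and once the best occurrence has b
#' differences only `n_diff <= min(z, b+1)` (or `== b` without suboptimal
#' reporting).
#'
#' Limited, by construction of the start-recovery step, to at most one gap
#' open per alignment (the package default); larger `max_gap_opens` is an
#' error.
#'
#' @param reference_text base string or code vector (codes 0..3).
#' @param query base string or code vector (N = code 4 matches nothing).
#' @param opts an [aln_opts()] object.
#' @return data.frame (`pos`, `n_diff`) sorted by position.
#' @export
brute_force_hits <- function(reference_text, query, opts = aln_opts()) {
  t <- query_codes(reference_text)
  q <- query_codes(query)
  L <- length(t); m <- length(q)
  stopifnot(m >= 1L, L >= 1L)
  z <- resolve_z(opts, m)
  gaps <- opts$gap_open_allowed && opts$max_gap_opens > 0L
  if (gaps && opts$max_gap_opens > 1L)
    stop("brute_force_hits supports at most one gap open", call. = FALSE)
  k <- opts$no_indel_end
  maxge <- opts$max_gap_extensions
  INF <- 1e9

  # state value vectors over p = number of reference bases consumed (0..L);
  # index p+1.  M0: no gap yet; I/D: inside an insertion/deletion gap with
  # ge extensions so far (row ge+1); MI/MD: gap closed.
  M0 <- numeric(L + 1L)
  I  <- matrix(INF, maxge + 1L, L + 1L)
  MI <- matrix(INF, maxge + 1L, L + 1L)
  D  <- matrix(INF, maxge + 1L, L + 1L)
  MD <- matrix(INF, maxge + 1L, L + 1L)

  shift_cost <- function(v, costv) c(INF, v[seq_len(L)] + costv)
  ins_ok <- function(j) gaps && (j - 1L >= k) && (m - j >= k) # base index j-1
  del_ok <- function(j) gaps && (j >= k) && (m - j >= k)      # boundary j

  for (j in seq_len(m)) {
    qc <- q[j]
    costv <- if (qc > 3L) rep(1, L) else as.numeric(t != qc)
    nM0 <- shift_cost(M0, costv)
    nMI <- matrix(INF, maxge + 1L, L + 1L)
    nMD <- matrix(INF, maxge + 1L, L + 1L)
    for (g in seq_len(maxge + 1L)) {
      nMI[g, ] <- pmin(shift_cost(MI[g, ], costv), shift_cost(I[g, ], costv))
      nMD[g, ] <- pmin(shift_cost(MD[g, ], costv), shift_cost(D[g, ], costv))
    }
    nI <- matrix(INF, maxge + 1L, L + 1L)
    if (ins_ok(j)) {
      nI[1L, ] <- M0 + 1                         # open on this query base
      if (maxge >= 1L)
        for (g in seq_len(maxge)) nI[g + 1L, ] <- pmin(nI[g + 1L, ], I[g, ] + 1)
    }
    M0 <- nM0; MI <- nMI; MD <- nMD; I <- nI
    D <- matrix(INF, maxge + 1L, L + 1L)
    if (del_ok(j)) {                             # deletion run at boundary j
      shift1 <- function(v) c(INF, v[seq_len(L)] + 1)
      D[1L, ] <- shift1(M0)
      if (maxge >= 1L)
        for (g in seq_len(maxge)) D[g + 1L, ] <- shift1(D[g, ])
    }
  }

  # read out end states; recover the start from the consumed-reference count
  p <- 0:L
  cand_pos <- integer(0); cand_d <- numeric(0)
  add <- function(v, span) {
    ok <- which(v <= z & p - span >= 0L)
    cand_pos <<- c(cand_pos, p[ok] - span)
    cand_d <<- c(cand_d, v[ok])
  }
  add(M0, m)
  for (g in seq_len(maxge + 1L)) {
    ge <- g - 1L
    add(MI[g, ], m - 1L - ge)   # one insertion gap of 1+ge query bases
    add(MD[g, ], m + 1L + ge)   # one deletion gap of 1+ge reference bases
  }
  if (length(cand_pos) == 0L)
    return(data.frame(pos = integer(0), n_diff = integer(0)))
  agg <- tapply(cand_d, cand_pos, min)
  out <- data.frame(pos = as.integer(names(agg)), n_diff = as.integer(agg),
                    row.names = NULL)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  filter_report(out, z, opts$report_suboptimal)
}
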