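# Difference-bound inexact search: options, lower bound, DFS and the BFS
# reference implementation.
#
# A "difference" is one mismatch, one gap open or one gap extension; z is the
# total allowed per alignment.  Hits never exceed z differences; once a best
# alignment with b differences is known, the search keeps candidates only
# while their count stays within min(z, b + 1) (suboptimal reporting).

#' Alignment options
#'
#' @param max_diff maximum differences z (>= 0), or `"auto"` to derive z from
#'   the read length via [auto_max_diff()].
#' @param expected_error_rate per-base error rate of the binomial model used
#'   when `max_diff = "auto"`.
#' @param gap_open_allowed logical; `FALSE` (or `max_gap_opens = 0`, the
#'   `-o 0` control) restricts the search to match/mismatch branches.
#' @param max_gap_opens,max_gap_extensions per-alignment gap budgets.
#' @param pen_mismatch,pen_gap_open,pen_gap_extend positive score penalties.
#' @param seed_len fragment length for the multi-phase search (bases).
#' @param report_suboptimal keep hits with up to best+1 differences.
#' @param no_indel_end gaps are disallowed within this many bases of either
#'   read end (>= 1, so terminal gaps cannot occur).
#' @param max_occurrences cap on reported alternate placements per read.
#' @param max_query_len guard on query length for the search kernels.
#' @param max_nodes search node budget per kernel invocation.
#' @return a list of class `aln_opts`.
#' @export
aln_opts <- function(max_diff = "auto", expected_error_rate = 0.04,
                     gap_open_allowed = TRUE, max_gap_opens = 1L,
                     max_gap_extensions = 6L, pen_mismatch = 3L,
                     pen_gap_open = 11L, pen_gap_extend = 4L,
                     seed_len = 32L, report_suboptimal = TRUE,
                     no_indel_end = 5L, max_occurrences = 10L,
                     max_query_len = 1000L, max_nodes = 5e7) {
  if (!identical(max_diff, "auto")) {
    max_diff <- as.integer(max_diff)
    stopifnot(max_diff >= 0L)
  }
  if (max_gap_opens == 0L) gap_open_allowed <- FALSE
  stopifnot(expected_error_rate > 0, expected_error_rate < 1,
            pen_mismatch > 0L, pen_gap_open > 0L, pen_gap_extend > 0L,
            seed_len >= 1L, no_indel_end >= 1L, max_gap_opens >= 0L,
            max_gap_extensions >= 0L, max_occurrences >= 1L)
  structure(list(max_diff = max_diff,
                 expected_error_rate = expected_error_rate,
                 gap_open_allowed = isTRUE(gap_open_allowed),
                 max_gap_opens = as.integer(max_gap_opens),
                 max_gap_extensions = as.integer(max_gap_extensions),
                 pen_mismatch = as.integer(pen_mismatch),
                 pen_gap_open = as.integer(pen_gap_open),
                 pen_gap_extend = as.integer(pen_gap_extend),
                 seed_len = as.integer(seed_len),
                 report_suboptimal = isTRUE(report_suboptimal),
                 no_indel_end = as.integer(no_indel_end),
                 max_occurrences = as.integer(max_occurrences),
                 max_query_len = as.integer(max_query_len),
                 max_nodes = as.numeric(max_nodes)),
            class = c("aln_opts", "list"))
}

#' @noRd
resolve_z <- function(opts, read_len) {
  if (identical(opts$max_diff, "auto"))
    auto_max_diff(read_len, opts$expected_error_rate)
  else opts$max_diff
}

#' Automatic maximum-difference threshold
#'
#' Smallest z such that the probability of more than z sequencing errors on a
#' read, under a binomial(read_length, rate) error model, falls below
#' `tail_prob`.  Deterministic; non-decreasing in `read_length`.
#'
#' @param read_length read length in bases (>= 1).
#' @param expected_error_rate per-base error probability in (0, 1).
#' @param tail_prob tail threshold (default 1e-2).
#' @return integer z.
#' @export
auto_max_diff <- function(read_length, expected_error_rate = 0.04,
                          tail_prob = 1e-2) {
  stopifnot(read_length >= 1L, expected_error_rate > 0, expected_error_rate < 1)
  z <- 0L
  while (stats::pbinom(z, read_length, expected_error_rate,
                       lower.tail = FALSE) >= tail_prob && z < read_length)
    z <- z + 1L
  z
}

#' Per-position lower bound on differences
#'
#' For each query prefix ending at position i (0-based), the minimum number
#' of differences any occurrence of that prefix in the reference must carry.
#' Computed by a left-to-right prefix walk on the reverse-text index that
#' increments the bound and restarts whenever the interval empties.  The
#' bound is non-decreasing along the query and zero wherever the prefix
#' occurs exactly.
#'
#' @param reverse_index `fm_index` over the reversed text (e.g. `index$rev`).
#' @param query base string or code vector (N counts as a forced difference).
#' @return integer vector `d` of the same length as the query.
#' @export
compute_lower_bound <- function(reverse_index, query) {
  codes <- query_codes(query)
  stopifnot(length(codes) >= 1L)
  cpp_lower_bound(reverse_index, codes)
}

#' @noRd
query_codes <- function(query) {
  if (is.character(query)) {
    if (!nzchar(query)) integer(0) else {
      ints <- utf8ToInt(toupper(query))
      codes <- .code_table[ints + 1L]
      codes[is.na(codes)] <- 4L # anything unrecognised behaves like N
      codes
    }
  } else as.integer(query)
}

#' @noRd
hits_frame <- function(mat) {
  df <- as.data.frame(mat[, c("low", "high", "n_mm", "n_gapo", "n_gape",
                              "n_ins_b", "n_del_b", "score"), drop = FALSE])
  df$n_diff <- df$n_mm + df$n_gapo + df$n_gape
  df
}

# reporting rule shared by DFS/BFS/multiphase: hits never exceed z, and once
# the best alignment has b differences only n_diff <= min(z, b+1) is kept
#' @noRd
filter_report <- function(df, z, report_suboptimal) {
  if (nrow(df) == 0L) return(df)
  best <- min(df$n_diff)
  cap <- if (report_suboptimal) min(z, best + 1L) else best
  df[df$n_diff <= cap, , drop = FALSE]
}

#' Difference-bound DFS inexact search
#'
#' Explores, right-to-left over the query, the branch set of exact match,
#' three mismatch substitutions, insertion (query base consumed) and
#' deletion (reference base consumed), expanding children best-score-first
#' and descending depth-first so that only the current branch is held in
#' memory.  Nodes are abandoned when their difference count exceeds the
#' dynamic bound, or when count plus the remaining-prefix lower bound
#' exceeds it.
#'
#' @param index forward `fm_index`, or an `fm_genome_index` (in which case
#'   `reverse_index` may be omitted).
#' @param reverse_index reverse-text `fm_index` for the lower bound.
#' @param query base string or code vector (N allowed; it matches nothing
#'   and always costs a mismatch).
#' @param opts an [aln_opts()] object.
#' @return data.frame of hits (`low`, `high`, `n_mm`, `n_gapo`, `n_gape`,
#'   `n_ins_b`, `n_del_b`, `score`, `n_diff`) with attribute `peak_nodes`,
#'   the maximum number of query-consuming branch nodes held at once.
#' @export
dfs_inexact <- function(index, reverse_index = NULL, query, opts = aln_opts()) {
  comp <- index_pair(index, reverse_index)
  codes <- query_codes(query)
  m <- length(codes)
  if (m > opts$max_query_len)
    stop(sprintf("query length %d exceeds maximum %d", m, opts$max_query_len),
         call. = FALSE)
  z <- resolve_z(opts, max(m, 1L))
  d <- if (m > 0L) cpp_lower_bound(comp$rev, codes) else integer(0)
  node <- as.integer(c(m, 0L, comp$fwd$n + 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))
  res <- cpp_dfs_segment(comp$fwd, codes, d, node, 0L, opts, as.integer(z),
                         -1L, opts$max_nodes)
  out <- filter_report(hits_frame(res$hits), z, opts$report_suboptimal)
  rownames(out) <- NULL
  attr(out, "peak_nodes") <- res$peak_nodes
  attr(out, "z") <- z
  out
}

#' BFS reference search
#'
#' Frontier-queue traversal (best score first) with the same branch set and
#' pruning rules as [dfs_inexact()]; returns the identical hit set while
#' additionally reporting the peak number of stored frontier nodes.  Intended
#' for tests and small inputs; errors if the frontier exceeds `frontier_cap`.
#'
#' @inheritParams dfs_inexact
#' @param frontier_cap maximum stored frontier nodes before erroring.
#' @return as [dfs_inexact()]; `peak_nodes` is the frontier peak.
#' @export
bfs_inexact_reference <- function(index, reverse_index = NULL, query,
                                  opts = aln_opts(), frontier_cap = 1e6) {
  comp <- index_pair(index, reverse_index)
  codes <- query_codes(query)
  m <- length(codes)
  if (m > opts$max_query_len)
    stop(sprintf("query length %d exceeds maximum %d", m, opts$max_query_len),
         call. = FALSE)
  z <- resolve_z(opts, max(m, 1L))
  d <- if (m > 0L) cpp_lower_bound(comp$rev, codes) else integer(0)
  res <- cpp_bfs(comp$fwd, codes, d, opts, as.integer(z), frontier_cap)
  out <- filter_report(hits_frame(res$hits), z, opts$report_suboptimal)
  rownames(out) <- NULL
  attr(out, "peak_nodes") <- res$peak_nodes
  attr(out, "z") <- z
  out
}

#' @noRd
index_pair <- function(index, reverse_index) {
  if (inherits(index, "fm_genome_index"))
    list(fwd = index$fwd, rev = index$rev)
  else {
    if (is.null(reverse_index))
      stop("reverse_index is required when passing a bare fm_index", call. = FALSE)
    list(fwd = index, rev = reverse_index)
  }
}

#' Resolve hits to linear positions with minimal difference counts
#'
#' SA-resolves every row of every hit interval and keeps, per text position,
#' the minimal difference count.  Used by the oracle-equivalence tests.
#'
#' @param index `fm_genome_index` or forward `fm_index`.
#' @param hits data.frame from [dfs_inexact()] and friends.
#' @return data.frame (`pos`, `n_diff`) sorted by position.
#' @export
resolve_hits <- function(index, hits) {
  fwd <- if (inherits(index, "fm_genome_index")) index$fwd else index
  if (nrow(hits) == 0L)
    return(data.frame(pos = integer(0), n_diff = integer(0)))
  rows <- unlist(lapply(seq_len(nrow(hits)),
                        function(i) hits$low[i]:(hits$high[i] - 1L)))
  nd <- rep(hits$n_diff, hits$high - hits$low)
  pos <- sa_lookup(fwd, rows)
  agg <- tapply(nd, pos, min)
  data.frame(pos = as.integer(names(agg)), n_diff = as.integer(agg),
             row.names = NULL)
}
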