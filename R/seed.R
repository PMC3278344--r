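# Multi-phase seed-fragmented search.
#
# Long reads are divided into seed-length fragments and aligned by
# consecutive bounded-DFS runs, one fragment per run.  Between runs,
# partial hits live in a host-side stack ranked by (n_diff, score, query
# position), best first; entries exceeding min(z, best_full + 1) once a
# full alignment is known are discarded.  Gap state is carried across
# fragment boundaries so a gap may span two fragments, which is what makes
# the multi-phase result identical to the single-pass search.

#' Fragment a read into seed-length pieces
#'
#' Contiguous fragments covering the read in processing order: backward
#' search consumes the read 3' to 5', so the 3'-most fragment comes first
#' and the (possibly shorter) 5'-most fragment last.
#'
#' @param read read length in bases, or a base string / code vector.
#' @param seed_len fragment length (default 32).
#' @return integer vector of fragment lengths in processing order.
#' @export
fragment_read <- function(read, seed_len = 32L) {
  m <- if (is.numeric(read) && length(read) == 1L) as.integer(read)
       else length(query_codes(read))
  stopifnot(m >= 1L, seed_len >= 1L)
  nfrag <- ceiling(m / seed_len)
  lens <- rep(as.integer(seed_len), nfrag)
  lens[nfrag] <- m - (nfrag - 1L) * seed_len
  lens
}

# stack entry columns (integer matrix)
.STACK_COLS <- c("read_id", "i", "low", "high", "state", "n_mm", "n_gapo",
                 "n_gape", "n_ins_b", "n_del_b", "score", "n_diff")

#' @noRd
new_hit_stack <- function(entries = NULL, best_full = integer(0)) {
  if (is.null(entries)) {
    entries <- matrix(integer(0), ncol = length(.STACK_COLS),
                      dimnames = list(NULL, .STACK_COLS))
  }
  list(entries = entries, best_full = best_full)
}

#' @noRd
rank_stack <- function(entries) {
  if (nrow(entries) == 0L) return(entries)
  ord <- order(entries[, "n_diff"], entries[, "score"], entries[, "i"],
               entries[, "read_id"], entries[, "low"])
  entries[ord, , drop = FALSE]
}

#' @noRd
initial_stack <- function(index, reads, best_full = NULL) {
  fwd <- index$fwd
  rows <- do.call(rbind, lapply(seq_along(reads), function(id) {
    c(read_id = id, i = length(reads[[id]]), low = 0L, high = fwd$n + 1L,
      state = 0L, n_mm = 0L, n_gapo = 0L, n_gape = 0L, n_ins_b = 0L,
      n_del_b = 0L, score = 0L, n_diff = 0L)
  }))
  if (is.null(best_full)) best_full <- rep(NA_integer_, length(reads))
  new_hit_stack(rows, best_full = best_full)
}

#' Run one phase of the multi-phase search
#'
#' Extracts every stack entry in rank order (best difference count first)
#' and extends it through its next fragment with the bounded DFS, resuming
#' any carried gap state.  Resulting partial hits are re-inserted ranked;
#' completed alignments update the per-read best and entries exceeding
#' min(z, best + 1) are discarded.  Entries at mixed phases are allowed;
#' each resumes from its own query position.
#'
#' @param index an `fm_genome_index`.
#' @param stack a hit stack as produced by [run_phase()] itself or
#'   internally by [align_multiphase()]; `NULL` starts a fresh stack over
#'   `reads`.
#' @param reads list of reads (strings or code vectors).
#' @param opts an [aln_opts()] object.
#' @return list with elements `stack` (updated), `completed` (data.frame of
#'   full hits with `read_id`), and `extracted` (the order in which entries
#'   were taken, as their difference counts).
#' @export
run_phase <- function(index, stack = NULL, reads, opts = aln_opts()) {
  reads <- lapply(reads, query_codes)
  if (is.null(stack)) stack <- initial_stack(index, reads)
  fwd <- index$fwd
  dlist <- lapply(reads, function(q) cpp_lower_bound(index$rev, q))
  zvec <- vapply(reads, function(q) resolve_z(opts, length(q)), integer(1))
  targets <- lapply(reads, function(q)
    length(q) - cumsum(fragment_read(length(q), opts$seed_len)))

  entries <- rank_stack(stack$entries)
  best <- stack$best_full
  out_partial <- list()
  out_complete <- list()
  extracted <- integer(0)

  for (r in seq_len(nrow(entries))) {
    e <- entries[r, ]
    id <- e[["read_id"]]
    cap <- if (is.na(best[id])) zvec[id] else min(zvec[id], best[id] + 1L)
    if (e[["n_diff"]] > cap) next # discard: z+1 rule after a full alignment
    extracted <- c(extracted, e[["n_diff"]])
    tg <- targets[[id]]
    i_target <- max(c(tg[tg < e[["i"]]], 0L))
    node <- as.integer(e[c("i", "low", "high", "state", "n_mm", "n_gapo",
                           "n_gape", "n_ins_b", "n_del_b", "score")])
    res <- cpp_dfs_segment(fwd, reads[[id]], dlist[[id]], node,
                           as.integer(i_target), opts, zvec[id],
                           if (is.na(best[id])) -1L else best[id],
                           opts$max_nodes)
    hits <- res$hits
    if (nrow(hits) == 0L) next
    nd <- hits[, "n_mm"] + hits[, "n_gapo"] + hits[, "n_gape"]
    done <- hits[, "i"] == 0L
    if (any(done)) {
      b <- min(nd[done])
      if (is.na(best[id]) || b < best[id]) best[id] <- b
      out_complete[[length(out_complete) + 1L]] <-
        cbind(read_id = id, hits[done, , drop = FALSE], n_diff = nd[done])
    }
    if (any(!done)) {
      out_partial[[length(out_partial) + 1L]] <-
        cbind(read_id = id, hits[!done, , drop = FALSE], n_diff = nd[!done])
    }
  }

  part <- if (length(out_partial)) do.call(rbind, out_partial) else NULL
  if (!is.null(part)) {
    keep <- vapply(seq_len(nrow(part)), function(r) {
      id <- part[r, "read_id"]
      cap <- if (is.na(best[id])) zvec[id] else min(zvec[id], best[id] + 1L)
      part[r, "n_diff"] <= cap
    }, logical(1))
    part <- part[keep, , drop = FALSE]
    part <- part[, .STACK_COLS, drop = FALSE]
  }
  comp <- if (length(out_complete)) {
    df <- as.data.frame(do.call(rbind, out_complete))
    df[, c("read_id", "low", "high", "n_mm", "n_gapo", "n_gape", "n_ins_b",
           "n_del_b", "score", "n_diff")]
  } else NULL
  list(stack = new_hit_stack(rank_stack(if (is.null(part))
         new_hit_stack()$entries else part), best_full = best),
       completed = comp, extracted = extracted)
}

#' Seed-fragmented multi-phase alignment of one read
#'
#' Runs [run_phase()] until the stack empties and applies the final
#' reporting rule; the hit set is identical to a single-pass
#' [dfs_inexact()] over the whole read.
#'
#' @inheritParams dfs_inexact
#' @return data.frame of hits as [dfs_inexact()].
#' @export
align_multiphase <- function(index, reverse_index = NULL, query,
                             opts = aln_opts()) {
  comp <- index_bundle(index, reverse_index)
  res <- batch_align(comp, list(query), opts)
  res[[1L]]
}

#' @noRd
index_bundle <- function(index, reverse_index) {
  if (inherits(index, "fm_genome_index")) return(index)
  if (is.null(reverse_index))
    stop("reverse_index is required when passing a bare fm_index", call. = FALSE)
  structure(list(packed = NULL, fwd = index, rev = reverse_index),
            class = "fm_genome_index")
}

#' Batch alignment with order-independent results
#'
#' Packs the batch into one contiguous code buffer (the batched-transfer
#' contract: per-read results are independent of batch order and size) and
#' drives the shared multi-phase stack over all reads.
#'
#' @param index an `fm_genome_index`.
#' @param reads list of reads (strings or code vectors).
#' @param opts an [aln_opts()] object.
#' @return list of per-read hit data.frames (as [dfs_inexact()]).
#' @export
batch_align <- function(index, reads, opts = aln_opts()) {
  stopifnot(length(reads) >= 1L)
  codes <- lapply(reads, query_codes)
  lens <- lengths(codes)
  if (any(lens > opts$max_query_len))
    stop(sprintf("query length %d exceeds maximum %d", max(lens),
                 opts$max_query_len), call. = FALSE)
  if (any(lens == 0L))
    stop("batch_align requires non-empty reads", call. = FALSE)
  # contiguous packed batch buffer; reads are views (offset, length) into it
  buffer <- unlist(codes, use.names = FALSE)
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  views <- lapply(seq_along(lens), function(i)
    buffer[(offsets[i] + 1L):(offsets[i] + lens[i])])
  lapply(views, function(q) align_one_escalating(index, q, opts))
}

# Multi-phase alignment of one read with budget escalation: the search is
# run at increasing difference budgets starting from the read's whole-query
# lower bound, so the first budget that admits any full alignment pins the
# best count b, and the reporting stratum (up to min(z, b+1)) is collected
# by one further bounded run.  The final hit set is identical to a single
# run at the full budget -- escalation only avoids exploring difference
# strata the reporting rule would discard.
#' @noRd
align_one_escalating <- function(index, q, opts) {
  m <- length(q)
  z <- resolve_z(opts, m)
  d <- cpp_lower_bound(index$rev, q)
  lb <- d[m]
  finish <- function(df, cap) {
    out <- filter_report(df, cap, opts$report_suboptimal)
    rownames(out) <- NULL
    attr(out, "z") <- z
    out
  }
  if (lb > z) return(finish(empty_hits(), z))
  b <- NA_integer_
  zp <- lb
  res <- empty_hits()
  while (zp <= z) {
    o2 <- opts; o2$max_diff <- as.integer(zp)
    res <- multiphase_collect(index, q, o2, best_in = NA_integer_)
    if (nrow(res) > 0L) { b <- min(res$n_diff); break }
    zp <- zp + 1L
  }
  if (is.na(b)) return(finish(empty_hits(), z))
  z_run <- if (opts$report_suboptimal) min(z, b + 1L) else b
  if (z_run > zp) {
    o2 <- opts; o2$max_diff <- as.integer(z_run)
    res <- multiphase_collect(index, q, o2, best_in = b)
  }
  finish(res, z_run)
}

# drive the ranked-stack phases for a single read until the stack empties
#' @noRd
multiphase_collect <- function(index, q, opts, best_in = NA_integer_) {
  stack <- initial_stack(index, list(q), best_full = best_in)
  completed <- list()
  repeat {
    ph <- run_phase(index, stack, list(q), opts)
    if (!is.null(ph$completed)) completed[[length(completed) + 1L]] <- ph$completed
    stack <- ph$stack
    if (nrow(stack$entries) == 0L) break
  }
  if (length(completed) == 0L) return(empty_hits())
  df <- do.call(rbind, completed)
  df <- unique(df[, c("low", "high", "n_mm", "n_gapo", "n_gape", "n_ins_b",
                      "n_del_b", "score", "n_diff")])
  rownames(df) <- NULL
  df
}

#' @noRd
empty_hits <- function() {
  data.frame(low = integer(0), high = integer(0), n_mm = integer(0),
             n_gapo = integer(0), n_gape = integer(0), n_ins_b = integer(0),
             n_del_b = integer(0), score = integer(0), n_diff = integer(0))
}
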