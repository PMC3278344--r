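# Postprocessing: binary hit files, linear-coordinate resolution, mapping
# quality, and SAM emission for single- and paired-end libraries.

.SAI_MAGIC <- "FMASAI"
.SAI_VERSION <- 1L
.SAI_COLS <- c("strand", "low", "high", "n_mm", "n_gapo", "n_gape",
               "n_ins_b", "n_del_b", "score", "span")

#' Write per-read hits to a binary hit file
#'
#' Own versioned binary dialect (the `.sai` intermediate): a header with
#' magic bytes, format version, the fingerprint of the index the hits were
#' computed against and the options used, followed by per-read hit records
#' in input read order.
#'
#' @param aln an `aln_result` from [align_reads()].
#' @param path output path (conventionally `*.sai`).
#' @return `path`, invisibly.
#' @export
write_hit_file <- function(aln, path) {
  stopifnot(inherits(aln, "aln_result"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.SAI_MAGIC), con)
  writeBin(as.integer(.SAI_VERSION), con, size = 4L, endian = "little")
  writeBin(as.numeric(aln$fingerprint), con, size = 8L, endian = "little")
  o <- aln$opts
  writeBin(as.integer(c(nrow(aln$reads), o$gap_open_allowed, o$max_gap_opens,
                        o$max_gap_extensions, o$seed_len, o$no_indel_end)),
           con, size = 4L, endian = "little")
  hits <- aln$hits
  by_read <- split(seq_len(nrow(hits)), factor(hits$read_id,
                                               levels = seq_len(nrow(aln$reads))))
  for (id in seq_len(nrow(aln$reads))) {
    rows <- by_read[[id]]
    writeBin(c(length(rows), aln$z[id]), con, size = 4L, endian = "little")
    if (length(rows) > 0L) {
      mat <- as.matrix(hits[rows, .SAI_COLS])
      writeBin(as.integer(t(mat)), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a binary hit file
#'
#' @param path path written by [write_hit_file()].
#' @return list with `hits` (data.frame including `read_id` and `n_diff`),
#'   `n_reads`, `z` (per-read difference bound), `fingerprint`, `opts_used`.
#' @export
read_hit_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = nchar(.SAI_MAGIC))
  if (length(magic) < nchar(.SAI_MAGIC) || !identical(rawToChar(magic), .SAI_MAGIC))
    stop(sprintf("bad magic in %s: not a hit file", path), call. = FALSE)
  ver <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (!identical(ver, .SAI_VERSION))
    stop(sprintf("hit file version mismatch in %s", path), call. = FALSE)
  fp <- readBin(con, "numeric", n = 1L, size = 8L, endian = "little")
  hdr <- readBin(con, "integer", n = 6L, size = 4L, endian = "little")
  if (length(hdr) != 6L) stop(sprintf("truncated hit file: %s", path), call. = FALSE)
  n_reads <- hdr[1L]
  recs <- vector("list", n_reads)
  z <- integer(n_reads)
  for (id in seq_len(n_reads)) {
    h <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
    if (length(h) != 2L) stop(sprintf("truncated hit file: %s", path), call. = FALSE)
    z[id] <- h[2L]
    if (h[1L] > 0L) {
      v <- readBin(con, "integer", n = h[1L] * length(.SAI_COLS), size = 4L,
                   endian = "little")
      if (length(v) != h[1L] * length(.SAI_COLS))
        stop(sprintf("truncated hit file: %s", path), call. = FALSE)
      mat <- matrix(v, ncol = length(.SAI_COLS), byrow = TRUE,
                    dimnames = list(NULL, .SAI_COLS))
      df <- as.data.frame(mat)
      df$read_id <- id
      recs[[id]] <- df
    }
  }
  hits <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(hits)) {
    hits <- cbind(as.data.frame(matrix(integer(0), ncol = length(.SAI_COLS),
                                       dimnames = list(NULL, .SAI_COLS))),
                  data.frame(read_id = integer(0)))
  }
  hits$n_diff <- hits$n_mm + hits$n_gapo + hits$n_gape
  list(hits = hits, n_reads = n_reads, z = z, fingerprint = fp,
       opts_used = list(gap_open_allowed = as.logical(hdr[2L]),
                        max_gap_opens = hdr[3L], max_gap_extensions = hdr[4L],
                        seed_len = hdr[5L], no_indel_end = hdr[6L]))
}

#' Translate an SA interval to linear positions
#'
#' One mapped position per suffix-array row, up to `max_occurrences`
#' (excess is flagged via the `too_many` attribute).  Placements whose
#' reference span crosses a contig boundary are dropped; placements
#' overlapping ambiguity-masked reference regions are flagged.
#'
#' @param index an `fm_genome_index`.
#' @param hit list or one-row data.frame with `low`, `high` and `span`
#'   (reference span of the alignment in bases).
#' @param max_occurrences cap on returned placements.
#' @return data.frame (`contig`, `offset` 0-based, `masked`) with attribute
#'   `too_many`.
#' @export
interval_to_positions <- function(index, hit, max_occurrences = 10L) {
  stopifnot(inherits(index, "fm_genome_index"))
  low <- hit$low[1L]; high <- hit$high[1L]; span <- hit$span[1L]
  stopifnot(high > low)
  n_take <- min(high - low, max_occurrences)
  rows <- low:(low + n_take - 1L)
  pos <- sa_lookup(index$fwd, rows)
  ctg <- index$packed$contigs
  ci <- findInterval(pos, ctg$offset)
  off <- pos - ctg$offset[ci]
  ok <- off + span <= ctg$length[ci] # drop contig-boundary-spanning hits
  amb <- index$packed$ambig
  masked <- if (length(amb) > 0L) {
    findInterval(pos + span - 0.5, amb) > findInterval(pos - 0.5, amb)
  } else rep(FALSE, length(pos))
  out <- data.frame(contig = ctg$name[ci][ok], offset = off[ok],
                    masked = masked[ok], stringsAsFactors = FALSE)
  attr(out, "too_many") <- (high - low) > max_occurrences
  out
}

#' Mapping quality from hit counts
#'
#' Deterministic Phred-scale confidence: 0 when the best difference stratum
#' holds more than one placement; 37 for a unique placement with no
#' suboptimal hits; otherwise `max(0, 23 - 8 * (suboptimal_hits - 1))`,
#' reduced by 3 when the difference gap to the best suboptimal hit is 0.
#' Never increases as `suboptimal_hits` grows.  The formula is a declared
#' package convention, version-pinned so accuracy evaluations are
#' reproducible.
#'
#' @param best_hits number of placements at the best difference count.
#' @param suboptimal_hits number of placements in the suboptimal stratum.
#' @param n_diff_gap difference-count gap between best and best suboptimal.
#' @return integer mapping quality.
#' @export
compute_mapq <- function(best_hits, suboptimal_hits, n_diff_gap = 1L) {
  stopifnot(best_hits >= 0L, suboptimal_hits >= 0L)
  if (best_hits != 1L) return(0L)
  if (suboptimal_hits == 0L) return(37L)
  q <- 23L - 8L * (suboptimal_hits - 1L)
  if (n_diff_gap == 0L) q <- q - 3L
  max(0L, as.integer(q))
}

# CIGAR reconstruction: the search records operation counts, not paths; for
# gapped hits the single gap is re-placed on the reference span by choosing
# the boundary that minimises mismatches (ties to the leftmost placement).
#' @noRd
cigar_for_hit <- function(qcodes, tcodes, n_ins_b, n_del_b, no_indel_end) {
  m <- length(qcodes)
  if (n_ins_b == 0L && n_del_b == 0L) return(sprintf("%dM", m))
  if (n_ins_b > 0L && n_del_b > 0L)
    stop("cannot reconstruct a CIGAR with both gap types in one alignment",
         call. = FALSE)
  k <- no_indel_end
  if (n_ins_b > 0L) {
    span <- m - n_ins_b
    a_range <- max(k, 0L):(m - n_ins_b - k)
    pref <- cumsum(c(0L, qcodes[seq_len(span)] != tcodes[seq_len(span)]))
    sufv <- qcodes[seq_len(span) + n_ins_b] != tcodes[seq_len(span)]
    sufc <- rev(cumsum(c(0L, rev(sufv))))
    mism <- pref[a_range + 1L] + sufc[a_range + 1L]
    a <- a_range[which.min(mism)]
    ops <- c(if (a > 0L) sprintf("%dM", a), sprintf("%dI", n_ins_b),
             if (m - n_ins_b - a > 0L) sprintf("%dM", m - n_ins_b - a))
  } else {
    a_range <- k:(m - k)
    pref <- cumsum(c(0L, qcodes != tcodes[seq_len(m)]))
    sufv <- qcodes != tcodes[seq_len(m) + n_del_b]
    sufc <- rev(cumsum(c(0L, rev(sufv))))
    mism <- pref[a_range + 1L] + sufc[a_range + 1L]
    a <- a_range[which.min(mism)]
    ops <- c(if (a > 0L) sprintf("%dM", a), sprintf("%dD", n_del_b),
             if (m - a > 0L) sprintf("%dM", m - a))
  }
  paste(ops, collapse = "")
}

#' @noRd
sam_header <- function(index, extra_cl = "") {
  ctg <- index$packed$contigs
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", ctg$name, ctg$length),
    sprintf("@PG\tID:fmalign\tPN:fmalign\tVN:%s\tCL:%s",
            as.character(utils::packageVersion("fmalign")), extra_cl))
}

# choose primary placement and mapq for one read; returns NULL when no
# valid placement survives coordinate resolution
#' @noRd
choose_placement <- function(index, h, max_occurrences) {
  if (is.null(h) || nrow(h) == 0L) return(NULL)
  best <- min(h$n_diff)
  sizes <- h$high - h$low
  n_best <- sum(sizes[h$n_diff == best])
  n_sub <- sum(sizes[h$n_diff == best + 1L])
  ord <- order(h$n_diff, h$score, h$strand, h$low)
  h <- h[ord, , drop = FALSE]
  placements <- NULL
  for (r in seq_len(nrow(h))) {
    p <- interval_to_positions(index, h[r, ], max_occurrences)
    if (nrow(p) == 0L) next
    p$strand <- h$strand[r]; p$n_diff <- h$n_diff[r]; p$score <- h$score[r]
    p$span <- h$span[r]; p$n_ins_b <- h$n_ins_b[r]; p$n_del_b <- h$n_del_b[r]
    p$n_mm <- h$n_mm[r]
    placements <- rbind(placements, p)
    if (nrow(placements) > max_occurrences) break
  }
  if (is.null(placements) || nrow(placements) == 0L) return(NULL)
  mapq <- compute_mapq(n_best, n_sub, if (n_sub > 0L) 1L else 1L)
  list(placements = placements, mapq = mapq, n_best = n_best, n_sub = n_sub)
}

#' @noRd
orient_read <- function(seq, qual, strand) {
  if (strand == 0L) list(seq = seq, qual = qual)
  else list(seq = string_from_codes(revcomp_codes(query_codes(seq)), "N"),
            qual = paste(rev(strsplit(qual, "")[[1L]]), collapse = ""))
}

#' @noRd
xa_tag <- function(index, text_codes, reads_seq, placements, opts) {
  if (nrow(placements) < 2L) return(NULL)
  alts <- placements[-1L, , drop = FALSE]
  alts <- utils::head(alts, opts$max_occurrences)
  entries <- vapply(seq_len(nrow(alts)), function(i) {
    cg <- placement_cigar(index, text_codes, reads_seq, alts[i, ], opts)
    sprintf("%s,%s%d,%s,%d", alts$contig[i],
            if (alts$strand[i] == 0L) "+" else "-", alts$offset[i] + 1L,
            cg, alts$n_diff[i])
  }, character(1))
  paste0("XA:Z:", paste(entries, collapse = ";"), ";")
}

#' @noRd
placement_cigar <- function(index, text_codes, seq, pl, opts) {
  qc <- query_codes(seq)
  if (pl$strand == 1L) qc <- revcomp_codes(qc)
  if (pl$n_ins_b == 0L && pl$n_del_b == 0L) return(sprintf("%dM", length(qc)))
  ctg <- index$packed$contigs
  gstart <- ctg$offset[match(pl$contig, ctg$name)] + pl$offset
  tc <- text_codes[(gstart + 1L):(gstart + pl$span)]
  cigar_for_hit(qc, tc, pl$n_ins_b, pl$n_del_b, opts$no_indel_end)
}

#' Emit SAM records for a single-end library
#'
#' One primary record per read, chosen as the minimal (n_diff, score) hit
#' with deterministic tie-breaks; alternate placements go to an `XA` tag
#' (capped), difference counts to `NM`/`X0`/`X1`.  Unmapped reads produce a
#' flag-4 record with `*` placeholders.
#'
#' @param index an `fm_genome_index` (must match the hit file's index
#'   fingerprint).
#' @param aln an `aln_result`, or the path to a hit file from
#'   [write_hit_file()].
#' @param reads reads data.frame (required and checked against the record
#'   count when `aln` is a file path; defaults to the reads stored in the
#'   `aln_result`).
#' @param out optional path; when given the SAM text is also written there.
#' @return character vector of SAM lines, invisibly when `out` is given.
#' @export
samse <- function(index, aln, reads = NULL, out = NULL) {
  prep <- sam_inputs(index, aln, reads)
  reads <- prep$reads
  opts <- prep$opts
  text_codes <- unpack_reference(index$packed)
  by_read <- split(prep$hits, factor(prep$hits$read_id, levels = seq_len(nrow(reads))))
  lines <- character(nrow(reads))
  for (id in seq_len(nrow(reads))) {
    ch <- choose_placement(index, by_read[[id]], max(opts$max_occurrences, 4L))
    lines[id] <- sam_record_se(index, text_codes, reads[id, ], ch, opts)
  }
  sam <- c(sam_header(index, "samse"), lines)
  if (!is.null(out)) { writeLines(sam, out); return(invisible(sam)) }
  sam
}

#' @noRd
sam_record_se <- function(index, text_codes, read, ch, opts, flag_extra = 0L,
                          rnext = "*", pnext = 0L, tlen = 0L) {
  if (is.null(ch)) {
    return(paste(read$name, 4L + flag_extra, "*", 0L, 0L, "*", rnext, pnext,
                 0L, read$seq, read$qual, sep = "\t"))
  }
  pl <- ch$placements[1L, ]
  o <- orient_read(read$seq, read$qual, pl$strand)
  cg <- placement_cigar(index, text_codes, read$seq, pl, opts)
  flag <- flag_extra + if (pl$strand == 1L) 16L else 0L
  tags <- c(sprintf("NM:i:%d", pl$n_diff), sprintf("X0:i:%d", ch$n_best),
            sprintf("X1:i:%d", ch$n_sub),
            xa_tag(index, text_codes, read$seq, ch$placements, opts))
  paste(c(read$name, flag, pl$contig, pl$offset + 1L, ch$mapq, cg, rnext,
          pnext, tlen, o$seq, o$qual, tags), collapse = "\t")
}

#' @noRd
sam_inputs <- function(index, aln, reads) {
  stopifnot(inherits(index, "fm_genome_index"))
  if (is.character(aln) && length(aln) == 1L) {
    hf <- read_hit_file(aln)
    if (is.null(reads))
      stop("reads are required when the alignment is given as a hit file",
           call. = FALSE)
    if (is.character(reads)) reads <- read_fastq(reads)
    if (nrow(reads) != hf$n_reads)
      stop(sprintf("read count mismatch: hit file has %d records, reads %d",
                   hf$n_reads, nrow(reads)), call. = FALSE)
    if (!isTRUE(all.equal(hf$fingerprint, index_fingerprint(index))))
      stop("hit file was built against a different index (fingerprint mismatch)",
           call. = FALSE)
    opts <- do.call(aln_opts, hf$opts_used)
    list(hits = hf$hits, reads = reads, opts = opts)
  } else {
    stopifnot(inherits(aln, "aln_result"))
    if (!isTRUE(all.equal(aln$fingerprint, index_fingerprint(index))))
      stop("alignment was computed against a different index (fingerprint mismatch)",
           call. = FALSE)
    list(hits = aln$hits, reads = if (is.null(reads)) aln$reads else reads,
         opts = aln$opts)
  }
}

#' Emit SAM records for a paired-end library
#'
#' For each pair, chooses the placement combination on opposite strands in
#' head-to-head orientation whose insert size falls within `insert_limits`,
#' minimising the combined difference count; when no such combination
#' exists, both mates fall back to their independent best placements with
#' the proper-pair flag unset.  `insert_limits` defaults to mean +/- 4 sd
#' inferred from up to 10000 unique opposite-strand candidate pairs.
#'
#' @param index an `fm_genome_index`.
#' @param aln1,aln2 `aln_result` objects or hit-file paths for mates 1 and 2.
#' @param reads1,reads2 reads data.frames or FASTQ paths (required for
#'   hit-file input).
#' @param insert_limits numeric `c(min, max)` insert size, or `NULL` to infer.
#' @param out optional output path.
#' @return character vector of SAM lines (two records per pair).
#' @export
sampe <- function(index, aln1, aln2, reads1 = NULL, reads2 = NULL,
                  insert_limits = NULL, out = NULL) {
  p1 <- sam_inputs(index, aln1, reads1)
  p2 <- sam_inputs(index, aln2, reads2)
  if (nrow(p1$reads) != nrow(p2$reads))
    stop(sprintf("mismatched pair counts: %d vs %d", nrow(p1$reads),
                 nrow(p2$reads)), call. = FALSE)
  n <- nrow(p1$reads)
  opts <- p1$opts
  text_codes <- unpack_reference(index$packed)
  cap <- max(opts$max_occurrences, 4L)
  by1 <- split(p1$hits, factor(p1$hits$read_id, levels = seq_len(n)))
  by2 <- split(p2$hits, factor(p2$hits$read_id, levels = seq_len(n)))
  ch1 <- lapply(seq_len(n), function(id) choose_placement(index, by1[[id]], cap))
  ch2 <- lapply(seq_len(n), function(id) choose_placement(index, by2[[id]], cap))

  if (is.null(insert_limits)) insert_limits <- infer_insert_limits(ch1, ch2)

  lines <- character(2L * n)
  for (id in seq_len(n)) {
    rec <- sam_pair_records(index, text_codes, p1$reads[id, ], p2$reads[id, ],
                            ch1[[id]], ch2[[id]], insert_limits, opts)
    lines[2L * id - 1L] <- rec[1L]
    lines[2L * id] <- rec[2L]
  }
  sam <- c(sam_header(index, "sampe"), lines)
  if (!is.null(out)) { writeLines(sam, out); return(invisible(sam)) }
  sam
}

# proper orientation: opposite strands, forward mate leftmost
#' @noRd
pair_candidates <- function(c1, c2, limits) {
  if (is.null(c1) || is.null(c2)) return(NULL)
  a <- c1$placements; b <- c2$placements
  cand <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$contig[i] != b$contig[j] || a$strand[i] == b$strand[j]) next
    if (a$strand[i] == 0L) {
      left <- a[i, ]; right <- b[j, ]
    } else {
      left <- b[j, ]; right <- a[i, ]
    }
    if (left$strand != 0L || right$strand != 1L) next
    if (left$offset > right$offset) next
    isize <- right$offset + right$span - left$offset
    if (!is.null(limits) && (isize < limits[1L] || isize > limits[2L])) next
    cand <- rbind(cand, data.frame(i = i, j = j, nd = a$n_diff[i] + b$n_diff[j],
                                   score = a$score[i] + b$score[j],
                                   isize = isize))
  }
  cand
}

#' @noRd
infer_insert_limits <- function(ch1, ch2, cap = 10000L, fallback = c(0, 2000)) {
  sizes <- numeric(0)
  for (id in seq_along(ch1)) {
    c1 <- ch1[[id]]; c2 <- ch2[[id]]
    if (is.null(c1) || is.null(c2)) next
    if (c1$n_best != 1L || c2$n_best != 1L) next
    cand <- pair_candidates(c1, c2, NULL)
    if (is.null(cand) || nrow(cand) != 1L) next
    sizes <- c(sizes, cand$isize[1L])
    if (length(sizes) >= cap) break
  }
  if (length(sizes) < 20L) return(fallback)
  c(max(0, mean(sizes) - 4 * stats::sd(sizes)), mean(sizes) + 4 * stats::sd(sizes))
}

#' @noRd
sam_pair_records <- function(index, text_codes, r1, r2, c1, c2, limits, opts) {
  base1 <- 1L + 64L; base2 <- 1L + 128L # paired, first/second in pair
  cand <- pair_candidates(c1, c2, limits)
  proper <- !is.null(cand) && nrow(cand) > 0L
  if (proper) {
    cand <- cand[order(cand$nd, cand$score, cand$isize, cand$i, cand$j), ]
    sel1 <- c1; sel1$placements <- c1$placements[cand$i[1L], , drop = FALSE]
    sel2 <- c2; sel2$placements <- c2$placements[cand$j[1L], , drop = FALSE]
    isize <- cand$isize[1L]
  } else {
    sel1 <- c1; sel2 <- c2
    if (!is.null(sel1)) sel1$placements <- sel1$placements[1L, , drop = FALSE]
    if (!is.null(sel2)) sel2$placements <- sel2$placements[1L, , drop = FALSE]
  }
  f1 <- base1; f2 <- base2
  if (proper) { f1 <- f1 + 2L; f2 <- f2 + 2L }
  p1 <- if (!is.null(sel1)) sel1$placements[1L, ] else NULL
  p2 <- if (!is.null(sel2)) sel2$placements[1L, ] else NULL
  if (is.null(p2)) f1 <- f1 + 8L else if (p2$strand == 1L) f1 <- f1 + 32L
  if (is.null(p1)) f2 <- f2 + 8L else if (p1$strand == 1L) f2 <- f2 + 32L
  same_ctg <- !is.null(p1) && !is.null(p2) && p1$contig == p2$contig
  rn1 <- if (is.null(p2)) "*" else if (same_ctg) "=" else p2$contig
  rn2 <- if (is.null(p1)) "*" else if (same_ctg) "=" else p1$contig
  pn1 <- if (is.null(p2)) 0L else p2$offset + 1L
  pn2 <- if (is.null(p1)) 0L else p1$offset + 1L
  t1 <- t2 <- 0L
  if (proper && same_ctg) {
    left_is_1 <- p1$strand == 0L
    t1 <- if (left_is_1) isize else -isize
    t2 <- -t1
  }
  c(sam_record_se(index, text_codes, r1, sel1, opts, f1, rn1, pn1, t1),
    sam_record_se(index, text_codes, r2, sel2, opts, f2, rn2, pn2, t2))
}
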