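# Mapping-accuracy evaluation at a Phred-scale mapping-quality threshold.

#' Parse primary records from SAM text
#'
#' @param sam character vector of SAM lines, or a path.
#' @return data.frame (`name`, `flag`, `contig`, `pos` 0-based, `mapq`,
#'   `strand`, `mate`).
#' @export
parse_sam <- function(sam) {
  if (length(sam) == 1L && file.exists(sam)) sam <- readLines(sam)
  recs <- sam[!startsWith(sam, "@")]
  if (length(recs) == 0L)
    return(data.frame(name = character(0), flag = integer(0),
                      contig = character(0), pos = integer(0),
                      mapq = integer(0), strand = character(0),
                      mate = integer(0), stringsAsFactors = FALSE))
  f <- strsplit(recs, "\t", fixed = TRUE)
  name <- vapply(f, `[[`, "", 1L)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  data.frame(name = name, flag = flag,
             contig = vapply(f, `[[`, "", 3L),
             pos = as.integer(vapply(f, `[[`, "", 4L)) - 1L,
             mapq = as.integer(vapply(f, `[[`, "", 5L)),
             strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
             mate = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
             stringsAsFactors = FALSE)
}

#' Evaluate mapping accuracy against simulation truth
#'
#' `pct_mapped` is the percentage of all input reads with mapping quality at
#' or above the threshold; `pct_error` is the percentage of those
#' confidently mapped reads whose reported position is on the wrong contig
#' or strand, or farther than `pos_tolerance` from the truth position.
#'
#' @param sam SAM lines or path (primary records, one per read).
#' @param truth truth data.frame from [sample_read_pairs()]; `NULL` decodes
#'   truth from the read names.
#' @param mapq_threshold Phred-scale confidence threshold (default 10).
#' @param pos_tolerance allowed positional wobble in bases (default 5).
#' @return list of class `eval_result`: `pct_mapped`, `pct_error`, and a
#'   `counts` breakdown (`n_reads`, `n_confident`, `n_wrong`).
#' @export
evaluate_alignments <- function(sam, truth = NULL, mapq_threshold = 10L,
                                pos_tolerance = 5L) {
  rec <- parse_sam(sam)
  n_reads <- nrow(rec)
  if (is.null(truth)) {
    truth <- decode_truth_names(unique(rec$name))
  }
  miss <- setdiff(rec$name, truth$name)
  if (length(miss) > 0L)
    stop(sprintf("read name not present in truth: %s", miss[1L]), call. = FALSE)
  ti <- match(rec$name, truth$name)
  true_pos <- ifelse(rec$mate == 2L, truth$pos2[ti], truth$pos1[ti])
  true_strand <- ifelse(rec$mate == 2L, truth$strand2[ti], truth$strand1[ti])
  conf <- bitwAnd(rec$flag, 4L) == 0L & rec$mapq >= mapq_threshold
  wrong <- conf & (rec$contig != truth$contig[ti] |
                   rec$strand != true_strand |
                   abs(rec$pos - true_pos) > pos_tolerance)
  n_conf <- sum(conf)
  structure(list(
    pct_mapped = 100 * n_conf / max(1L, n_reads),
    pct_error = if (n_conf > 0L) 100 * sum(wrong) / n_conf else 0,
    counts = c(n_reads = n_reads, n_confident = n_conf, n_wrong = sum(wrong)),
    mapq_threshold = mapq_threshold, pos_tolerance = pos_tolerance
  ), class = "eval_result")
}

#' @noRd
decode_truth_names <- function(names_) {
  parts <- strsplit(names_, ":", fixed = TRUE)
  bad <- lengths(parts) != 7L | vapply(parts, `[[`, "", 1L) != "sim"
  if (any(bad))
    stop(sprintf("read name does not encode a truth record: %s",
                 names_[bad][1L]), call. = FALSE)
  data.frame(name = names_,
             contig = vapply(parts, `[[`, "", 2L),
             pos1 = as.integer(vapply(parts, `[[`, "", 3L)),
             strand1 = vapply(parts, `[[`, "", 4L),
             pos2 = as.integer(vapply(parts, `[[`, "", 5L)),
             strand2 = vapply(parts, `[[`, "", 6L),
             stringsAsFactors = FALSE)
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("mapq >= %d, tolerance %d bp\n", x$mapq_threshold, x$pos_tolerance))
  cat(sprintf("pct_mapped\t%.4f\npct_error\t%.4f\n", x$pct_mapped, x$pct_error))
  cat(sprintf("reads=%d confident=%d wrong=%d\n", x$counts["n_reads"],
              x$counts["n_confident"], x$counts["n_wrong"]))
  invisible(x)
}

#' Format an evaluation result as a machine-readable block
#'
#' @param x an `eval_result`.
#' @return character vector of `key=value` lines.
#' @export
format_eval <- function(x) {
  c(sprintf("pct_mapped=%.6f", x$pct_mapped),
    sprintf("pct_error=%.6f", x$pct_error),
    sprintf("n_reads=%d", x$counts[["n_reads"]]),
    sprintf("n_confident=%d", x$counts[["n_confident"]]),
    sprintf("n_wrong=%d", x$counts[["n_wrong"]]))
}
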