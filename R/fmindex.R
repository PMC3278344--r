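# FM-index construction and queries over the packed reference.
#
# The text is the concatenation of all contigs followed by one sentinel that
# sorts before A; rows of the (implicit) sorted suffix matrix are addressed
# 0-based, intervals are half-open [low, high).

#' Build the suffix array of a coded text
#'
#' Plain comparison sort over all suffixes of text + sentinel (the sentinel,
#' lexicographically smaller than A, sorts first).  Adequate at desk scale;
#' linear-time construction is deliberately out of scope.
#'
#' @param x a `packed_ref`, or an integer vector of codes 0..3.
#' @return integer vector `sa` of length n+1, a permutation of 0..n.
#' @export
build_suffix_array <- function(x) {
  codes <- if (inherits(x, "packed_ref")) unpack_reference(x) else as.integer(x)
  if (length(codes) < 1L) stop("text must have length >= 1", call. = FALSE)
  cpp_suffix_array(codes)
}

#' Burrows-Wheeler transform from a suffix array
#'
#' `bwt[i] = text[sa[i] - 1]`, with the sentinel (code 4) emitted where
#' `sa[i] == 0`.
#'
#' @param x a `packed_ref` or integer code vector.
#' @param sa suffix array of `x` as from [build_suffix_array()].
#' @return integer vector of length n+1 over codes 0..4.
#' @export
bwt_from_sa <- function(x, sa) {
  codes <- if (inherits(x, "packed_ref")) unpack_reference(x) else as.integer(x)
  stopifnot(length(sa) == length(codes) + 1L)
  cpp_bwt_from_sa(codes, as.integer(sa))
}

#' Invert a Burrows-Wheeler transform
#'
#' Recovers the unique text whose BWT (with exactly one sentinel, code 4)
#' is the input.  Used as a self-consistency oracle for index construction.
#'
#' @param bwt integer vector over codes 0..4 containing exactly one 4.
#' @return integer code vector of length `length(bwt) - 1`.
#' @export
invert_bwt <- function(bwt) {
  cpp_invert_bwt(as.integer(bwt))
}

#' Build an FM-index from a packed reference and its suffix array
#'
#' Stores the BWT (both as an inspectable integer vector and as 2-bit packed
#' machine words for fast rank queries), cumulative symbol counts `C`,
#' occurrence checkpoints at a fixed stride, and suffix-array values sampled
#' at a fixed row stride.
#'
#' @param x a `packed_ref` or integer code vector.
#' @param sa suffix array of `x`; built on the fly if `NULL`.
#' @param occ_stride checkpoint stride for occurrence counts (bases).
#' @param sa_stride row stride for suffix-array samples.
#' @return an object of class `fm_index`.
#' @export
build_fm_index <- function(x, sa = NULL, occ_stride = 64L, sa_stride = 8L) {
  stopifnot(occ_stride >= 1L, sa_stride >= 1L)
  codes <- if (inherits(x, "packed_ref")) unpack_reference(x) else as.integer(x)
  if (is.null(sa)) sa <- cpp_suffix_array(codes)
  bwt <- cpp_bwt_from_sa(codes, as.integer(sa))
  fm_from_bwt(bwt, sa = sa, occ_stride = occ_stride, sa_stride = sa_stride)
}

# assemble the fm_index list; sa may be NULL when sa_samples given directly
#' @noRd
fm_from_bwt <- function(bwt, sa = NULL, sa_samples = NULL,
                        occ_stride = 64L, sa_stride = 8L) {
  nb <- length(bwt)
  counts <- tabulate(bwt + 1L, nbins = 5L)[1:4]
  C <- as.integer(cumsum(c(1L, counts[-4L]))) # sentinel occupies rank 0
  if (is.null(sa_samples)) {
    rows <- seq(0L, nb - 1L, by = sa_stride)
    sa_samples <- as.integer(sa[rows + 1L])
  }
  structure(list(
    bwt = as.integer(bwt),
    bwt_words = cpp_pack_bwt_words(as.integer(bwt)),
    C = C,
    occ_cp = cpp_occ_checkpoints(as.integer(bwt), as.integer(occ_stride)),
    occ_stride = as.integer(occ_stride),
    sa_samples = sa_samples,
    sa_stride = as.integer(sa_stride),
    sentinel_row = which(bwt == 4L) - 1L,
    n = nb - 1L
  ), class = "fm_index")
}

#' @export
print.fm_index <- function(x, ...) {
  cat(sprintf("fm_index: text length %d, occ stride %d, SA stride %d\n",
              x$n, x$occ_stride, x$sa_stride))
  invisible(x)
}

#' Occurrence count from checkpoints
#'
#' Number of occurrences of `symbol` in `bwt[0, position)`, recovered from
#' the checkpoint table plus a bounded scan of packed words.
#'
#' @param index an `fm_index`.
#' @param symbol code 0..3.
#' @param position 0 <= position <= n+1.
#' @return integer count.
#' @export
fm_occ <- function(index, symbol, position) {
  stopifnot(inherits(index, "fm_index"), symbol %in% 0:3)
  cpp_occ(index, as.integer(symbol), as.integer(position))
}

#' Backward extension of an SA interval
#'
#' Maps the interval of occurrences of a string W to the interval of
#' `symbol`W.  An empty result (`low == high`) is valid.
#'
#' @param index an `fm_index`.
#' @param interval integer vector `c(low, high)`, half-open.
#' @param symbol code 0..3.
#' @return integer vector `c(low, high)`.
#' @export
backward_ext <- function(index, interval, symbol) {
  stopifnot(inherits(index, "fm_index"))
  v <- cpp_backward_ext(index, as.integer(interval[1L]),
                        as.integer(interval[2L]), as.integer(symbol))
  if (v[1L] >= v[2L]) c(0L, 0L) else v
}

#' Exact backward search
#'
#' Folds [backward_ext()] over the reversed query starting from the full
#' interval; the result size equals the number of occurrences of the query
#' in the text.  An empty query returns the full interval.
#'
#' @param index an `fm_index`.
#' @param query base string over ACGT, or an integer code vector.
#' @return `c(low, high)`; `c(0, 0)` when absent.
#' @export
exact_search <- function(index, query) {
  stopifnot(inherits(index, "fm_index"))
  codes <- if (is.character(query)) {
    if (nzchar(query)) codes_from_string(query) else integer(0)
  } else as.integer(query)
  cpp_exact_search(index, codes)
}

#' Suffix-array lookup by LF-walking
#'
#' Recovers SA values for BWT rows from the sampled suffix array.
#'
#' @param index an `fm_index`.
#' @param rows integer vector of rows in 0..n.
#' @return integer vector of text positions.
#' @export
sa_lookup <- function(index, rows) {
  stopifnot(inherits(index, "fm_index"))
  cpp_sa_lookup(index, as.integer(rows))
}

#' Build forward and reverse FM-indices over a reference
#'
#' The forward index answers backward search on the text; the reverse-text
#' index exists to support the per-position lower bound on differences used
#' to prune the inexact search.
#'
#' @param ref a `packed_ref`, named character vector of contig sequences,
#'   or a path to a FASTA file.
#' @param occ_stride,sa_stride index strides, see [build_fm_index()].
#' @return an object of class `fm_genome_index` with fields `packed`,
#'   `fwd` and `rev`.
#' @export
build_index <- function(ref, occ_stride = 64L, sa_stride = 8L) {
  packed <- if (inherits(ref, "packed_ref")) ref
            else if (is.character(ref) && length(ref) == 1L && is.null(names(ref)) &&
                     file.exists(ref)) pack_reference(read_fasta(ref))
            else pack_reference(ref)
  codes <- unpack_reference(packed)
  fwd <- build_fm_index(codes, occ_stride = occ_stride, sa_stride = sa_stride)
  rev_ <- build_fm_index(rev(codes), occ_stride = occ_stride, sa_stride = sa_stride)
  structure(list(packed = packed, fwd = fwd, rev = rev_),
            class = "fm_genome_index")
}

#' @export
print.fm_genome_index <- function(x, ...) {
  cat(sprintf("fm_genome_index: %d bp, %d contig(s)\n",
              x$packed$length, nrow(x$packed$contigs)))
  invisible(x)
}

#' @noRd
index_fingerprint <- function(index) {
  int_fingerprint(index$fwd$bwt[seq(1L, length(index$fwd$bwt),
                                    by = max(1L, length(index$fwd$bwt) %/% 4096L))])
}
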