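# Reference packing: FASTA records -> 2-bit packed concatenated genome.

#' Read a FASTA file into named sequences
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a plain named
#' character vector (names truncated at the first whitespace, as aligners do).
#'
#' @param path path to a FASTA file (multi-contig, wrapped or unwrapped,
#'   case-insensitive).
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write named sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Pack a reference genome into 2-bit codes
#'
#' Contigs are concatenated in input order into a single coded text
#' (A=0, C=1, G=2, T=3) stored at 2 bits per base.  Ambiguous IUPAC bases
#' (N, R, Y, ...) are deterministically substituted with A and their
#' positions recorded in `ambig`, so downstream stages can flag hits that
#' overlap masked regions.  Characters outside the IUPAC alphabet are an
#' error naming the offending contig and position.
#'
#' @param fasta_records named character vector of contig sequences (as from
#'   [read_fasta()]), or a list of such.
#' @return an object of class `packed_ref` with fields `packed` (raw, 2-bit),
#'   `length`, `ambig` (0-based positions of substituted bases, in
#'   concatenated coordinates) and `contigs` (data.frame `name`, `offset`,
#'   `length`; offsets 0-based).
#' @export
pack_reference <- function(fasta_records) {
  recs <- unlist(fasta_records)
  if (length(recs) == 0L || is.null(names(recs)) || any(!nzchar(recs)))
    stop("at least one non-empty named FASTA record is required", call. = FALSE)
  codes_list <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    codes_list[[i]] <- tryCatch(codes_from_string(recs[[i]]),
      error = function(e) stop(sprintf("contig '%s': %s", names(recs)[i],
                                       conditionMessage(e)), call. = FALSE))
  }
  lens <- lengths(codes_list)
  codes <- unlist(codes_list, use.names = FALSE)
  ambig <- which(codes == 4L) - 1L # 0-based
  codes[codes == 4L] <- 0L         # substitution rule: ambiguous -> A
  structure(list(
    packed = pack_codes_2bit(codes),
    length = length(codes),
    ambig = ambig,
    contigs = data.frame(name = names(recs),
                         offset = cumsum(c(0L, lens[-length(lens)])),
                         length = as.integer(lens),
                         stringsAsFactors = FALSE)
  ), class = "packed_ref")
}

#' Unpack a packed reference to integer codes
#'
#' @param packed a `packed_ref` object.
#' @return integer vector of codes 0..3 (ambiguous bases appear as their
#'   substitute, A).
#' @export
unpack_reference <- function(packed) {
  stopifnot(inherits(packed, "packed_ref"))
  unpack_codes_2bit(packed$packed, packed$length)
}

#' @export
print.packed_ref <- function(x, ...) {
  cat(sprintf("packed_ref: %d bp in %d contig(s), %d ambiguous base(s)\n",
              x$length, nrow(x$contigs), length(x$ambig)))
  invisible(x)
}
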