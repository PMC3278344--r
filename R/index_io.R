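# Binary index persistence.
#
# Own little-endian dialect with magic bytes and a format version.  The file
# set mirrors the conventional roles: .pac packed reference, .bwt/.sa forward
# BWT and sampled SA, .rbwt/.rsa the same for the reversed text, .ann contig
# table plus ambiguity runs.

.IDX_VERSION <- 1L
.IDX_MAGIC <- list(pac = "FMAPAC", bwt = "FMABWT", sa = "FMASA_", ann = "FMAANN")

#' @noRd
write_header <- function(con, magic) {
  writeBin(charToRaw(magic), con)
  writeBin(as.integer(.IDX_VERSION), con, size = 4L, endian = "little")
}

#' @noRd
read_header <- function(con, magic, path) {
  got <- readBin(con, "raw", n = nchar(magic))
  if (length(got) < nchar(magic) || !identical(rawToChar(got), magic))
    stop(sprintf("bad magic in %s: not a recognised index file", path), call. = FALSE)
  ver <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(ver) != 1L || ver != .IDX_VERSION)
    stop(sprintf("index format version mismatch in %s (got %s, expected %d)",
                 path, if (length(ver)) ver else "EOF", .IDX_VERSION), call. = FALSE)
  invisible(NULL)
}

#' @noRd
read_ints <- function(con, n, path) {
  v <- readBin(con, "integer", n = n, size = 4L, endian = "little")
  if (length(v) != n) stop(sprintf("truncated index file: %s", path), call. = FALSE)
  v
}

#' @noRd
save_fm_component <- function(fm, bwt_path, sa_path) {
  con <- file(bwt_path, "wb"); on.exit(close(con))
  write_header(con, .IDX_MAGIC$bwt)
  writeBin(as.integer(c(fm$n, fm$sentinel_row, fm$occ_stride)), con,
           size = 4L, endian = "little")
  writeBin(as.raw(fm$bwt), con)
  close(con); on.exit()
  con <- file(sa_path, "wb"); on.exit(close(con))
  write_header(con, .IDX_MAGIC$sa)
  writeBin(as.integer(c(fm$n, fm$sa_stride, length(fm$sa_samples))), con,
           size = 4L, endian = "little")
  writeBin(as.integer(fm$sa_samples), con, size = 4L, endian = "little")
  invisible(NULL)
}

#' @noRd
load_fm_component <- function(bwt_path, sa_path) {
  con <- file(bwt_path, "rb"); on.exit(close(con))
  read_header(con, .IDX_MAGIC$bwt, bwt_path)
  hdr <- read_ints(con, 3L, bwt_path)
  n <- hdr[1L]; occ_stride <- hdr[3L]
  bwt <- readBin(con, "raw", n = n + 1L)
  if (length(bwt) != n + 1L) stop(sprintf("truncated index file: %s", bwt_path), call. = FALSE)
  close(con); on.exit()
  con <- file(sa_path, "rb"); on.exit(close(con))
  read_header(con, .IDX_MAGIC$sa, sa_path)
  hdr2 <- read_ints(con, 3L, sa_path)
  if (hdr2[1L] != n) stop(sprintf("index files disagree on text length: %s", sa_path), call. = FALSE)
  sa_samples <- read_ints(con, hdr2[3L], sa_path)
  fm_from_bwt(as.integer(bwt), sa_samples = sa_samples,
              occ_stride = occ_stride, sa_stride = hdr2[2L])
}

#' Save a genome index to disk
#'
#' Writes the file set `{prefix}.pac`, `.bwt`, `.sa`, `.rbwt`, `.rsa`,
#' `.ann` (forward and reverse-text indices, packed reference, annotation).
#'
#' @param index an `fm_genome_index` from [build_index()].
#' @param prefix path prefix for the index files.
#' @return `prefix`, invisibly.
#' @export
save_index <- function(index, prefix) {
  stopifnot(inherits(index, "fm_genome_index"))
  p <- index$packed
  con <- file(paste0(prefix, ".pac"), "wb"); on.exit(close(con))
  write_header(con, .IDX_MAGIC$pac)
  writeBin(as.integer(c(p$length, length(p$packed))), con, size = 4L, endian = "little")
  writeBin(p$packed, con)
  close(con); on.exit()

  # annotation: contigs + ambiguity runs
  con <- file(paste0(prefix, ".ann"), "wb"); on.exit(close(con))
  write_header(con, .IDX_MAGIC$ann)
  writeBin(nrow(p$contigs), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(p$contigs))) {
    nm <- charToRaw(p$contigs$name[i])
    writeBin(length(nm), con, size = 4L, endian = "little")
    writeBin(nm, con)
    writeBin(as.integer(c(p$contigs$offset[i], p$contigs$length[i])), con,
             size = 4L, endian = "little")
  }
  runs <- positions_to_runs(p$ambig)
  writeBin(nrow(runs), con, size = 4L, endian = "little")
  if (nrow(runs) > 0L)
    writeBin(as.integer(rbind(runs$start, runs$len)), con, size = 4L, endian = "little")
  close(con); on.exit()

  save_fm_component(index$fwd, paste0(prefix, ".bwt"), paste0(prefix, ".sa"))
  save_fm_component(index$rev, paste0(prefix, ".rbwt"), paste0(prefix, ".rsa"))
  invisible(prefix)
}

#' Load a genome index from disk
#'
#' @param prefix path prefix used with [save_index()].
#' @return an `fm_genome_index`, query-equivalent to the saved one.
#' @export
load_index <- function(prefix) {
  pac_path <- paste0(prefix, ".pac")
  for (ext in c(".pac", ".bwt", ".sa", ".rbwt", ".rsa", ".ann"))
    if (!file.exists(paste0(prefix, ext)))
      stop(sprintf("missing index file: %s%s", prefix, ext), call. = FALSE)
  con <- file(pac_path, "rb"); on.exit(close(con))
  read_header(con, .IDX_MAGIC$pac, pac_path)
  hdr <- read_ints(con, 2L, pac_path)
  packed_bytes <- readBin(con, "raw", n = hdr[2L])
  if (length(packed_bytes) != hdr[2L])
    stop(sprintf("truncated index file: %s", pac_path), call. = FALSE)
  close(con); on.exit()

  ann_path <- paste0(prefix, ".ann")
  con <- file(ann_path, "rb"); on.exit(close(con))
  read_header(con, .IDX_MAGIC$ann, ann_path)
  nctg <- read_ints(con, 1L, ann_path)
  ctg <- vector("list", nctg)
  for (i in seq_len(nctg)) {
    nlen <- read_ints(con, 1L, ann_path)
    nm <- rawToChar(readBin(con, "raw", n = nlen))
    ol <- read_ints(con, 2L, ann_path)
    ctg[[i]] <- data.frame(name = nm, offset = ol[1L], length = ol[2L],
                           stringsAsFactors = FALSE)
  }
  nruns <- read_ints(con, 1L, ann_path)
  ambig <- integer(0)
  if (nruns > 0L) {
    rr <- matrix(read_ints(con, 2L * nruns, ann_path), nrow = 2L)
    ambig <- unlist(lapply(seq_len(nruns), function(i)
      seq.int(rr[1L, i], length.out = rr[2L, i])))
  }
  close(con); on.exit()

  packed <- structure(list(packed = packed_bytes, length = hdr[1L],
                           ambig = as.integer(ambig),
                           contigs = do.call(rbind, ctg)),
                      class = "packed_ref")
  fwd <- load_fm_component(paste0(prefix, ".bwt"), paste0(prefix, ".sa"))
  rev_ <- load_fm_component(paste0(prefix, ".rbwt"), paste0(prefix, ".rsa"))
  structure(list(packed = packed, fwd = fwd, rev = rev_),
            class = "fm_genome_index")
}

#' @noRd
positions_to_runs <- function(pos) {
  if (length(pos) == 0L)
    return(data.frame(start = integer(0), len = integer(0)))
  pos <- sort(as.integer(pos))
  brk <- c(TRUE, diff(pos) != 1L)
  start <- pos[brk]
  grp <- cumsum(brk)
  data.frame(start = start, len = as.integer(tabulate(grp)))
}
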