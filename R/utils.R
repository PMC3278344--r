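# Internal helpers: symbol coding and small shared utilities.
#
# Code space: A=0, C=1, G=2, T=3.  Code 4 marks an ambiguous base (N or any
# other IUPAC symbol) in reads; references never carry code 4 (ambiguous
# reference bases are substituted at packing time and recorded in a mask).

.BASES <- c("A", "C", "G", "T")
.IUPAC <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N")

.code_table <- local({
  tab <- rep(NA_integer_, 256)
  for (i in seq_along(.BASES)) {
    tab[utf8ToInt(.BASES[i]) + 1L] <- i - 1L
    tab[utf8ToInt(tolower(.BASES[i])) + 1L] <- i - 1L
  }
  amb <- setdiff(.IUPAC, .BASES)
  for (b in amb) {
    tab[utf8ToInt(b) + 1L] <- 4L
    tab[utf8ToInt(tolower(b)) + 1L] <- 4L
  }
  tab
})

#' @noRd
codes_from_string <- function(s) {
  ints <- utf8ToInt(s)
  codes <- .code_table[ints + 1L]
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    stop(sprintf("non-IUPAC character '%s' at position %d",
                 substr(s, bad, bad), bad), call. = FALSE)
  }
  codes
}

#' @noRd
string_from_codes <- function(codes, sentinel = "$") {
  paste(c(.BASES, sentinel)[codes + 1L], collapse = "")
}

#' @noRd
revcomp_codes <- function(codes) {
  comp <- ifelse(codes <= 3L, 3L - codes, 4L)
  rev(comp)
}

# 2-bit packing of a code vector (codes 0..3 only), 4 bases per byte,
# base j of a byte at bits 2j..2j+1
#' @noRd
pack_codes_2bit <- function(codes) {
  n <- length(codes)
  pad <- (-n) %% 4L
  if (pad > 0L) codes <- c(codes, rep(0L, pad))
  m <- matrix(codes, nrow = 4L)
  as.raw(m[1L, ] + 4L * m[2L, ] + 16L * m[3L, ] + 64L * m[4L, ])
}

#' @noRd
unpack_codes_2bit <- function(bytes, n) {
  v <- as.integer(bytes)
  codes <- rbind(v %% 4L, (v %/% 4L) %% 4L, (v %/% 16L) %% 4L, (v %/% 64L) %% 4L)
  codes <- as.integer(codes)
  codes[seq_len(n)]
}

# cheap deterministic fingerprint of an integer vector (hit-file header check)
#' @noRd
int_fingerprint <- function(x) {
  if (length(x) == 0L) return(0)
  w <- (seq_along(x) - 1) %% 9973 + 1
  as.numeric(sum((as.numeric(x) + 1) * w) %% 2147483647)
}
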