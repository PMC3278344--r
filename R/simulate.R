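# wgsim-style simulation: synthetic genome, mutated haplotype, paired-end
# reads with truth tracking encoded in read names.
#
# Read names carry the full truth record:
#   sim:<contig>:<pos1>:<strand1>:<pos2>:<strand2>:<serial>
# where pos1/pos2 are the 0-based reference-projected leftmost positions of
# mate 1 and mate 2 and strands are "+"/"-".  Mate identity at evaluation
# time comes from the SAM flag (or defaults to mate 1 for single-end runs).

#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else on.exit(rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
  }
  force(expr)
}

#' Simulate a random genome
#'
#' Reproducible i.i.d. sequence with the requested GC composition
#' (G and C each drawn with probability `gc_content / 2`).
#'
#' @param length genome length in bases (>= 1).
#' @param gc_content expected fraction of G+C.
#' @param rng_seed seed; `NULL` uses the current RNG state.
#' @param name contig name.
#' @return named character vector of length 1 (a FASTA record).
#' @export
simulate_genome <- function(length, gc_content = 0.5, rng_seed = NULL,
                            name = "sim1") {
  stopifnot(length >= 1L, gc_content >= 0, gc_content <= 1)
  with_seed(rng_seed, {
    p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
           (1 - gc_content) / 2)
    codes <- sample.int(4L, length, replace = TRUE, prob = p) - 1L
    stats::setNames(string_from_codes(codes, "N"), name)
  })
}

#' Mutate a genome into a variant haplotype
#'
#' Places SNPs and short indels by independent per-base draws: with
#' probability `mutation_rate` a site mutates; a mutated site becomes an
#' indel with probability `indel_fraction` (insertion or deletion with equal
#' probability, length 1 + geometric), otherwise a SNP to a random different
#' base.  The variant list maps haplotype coordinates back to reference
#' coordinates.
#'
#' @param genome named character vector (one contig) or plain string.
#' @param mutation_rate per-base mutation probability.
#' @param indel_fraction fraction of mutations that are indels.
#' @param rng_seed seed.
#' @param indel_ext_prob geometric extension probability for indel length.
#' @return list with `haplotype` (string), `variants` (data.frame
#'   `ref_pos` 0-based, `type`, `len`) and `segments` (the
#'   haplotype-to-reference projection map).
#' @export
mutate_haplotype <- function(genome, mutation_rate, indel_fraction = 0.1,
                             rng_seed = NULL, indel_ext_prob = 0.3) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1,
            indel_fraction >= 0, indel_fraction <= 1)
  g <- genome[[1L]]
  L <- nchar(g)
  with_seed(rng_seed, {
    u <- runif(L)
    mut <- which(u < mutation_rate)
    if (length(mut) == 0L) {
      segs <- data.frame(hap_start = 0L, ref_start = 0L, len = L)
      return(list(haplotype = g,
                  variants = data.frame(ref_pos = integer(0),
                                        type = character(0), len = integer(0),
                                        stringsAsFactors = FALSE),
                  segments = segs))
    }
    is_indel <- runif(length(mut)) < indel_fraction
    is_ins <- runif(length(mut)) < 0.5
    lens <- 1L + rgeom(length(mut), 1 - indel_ext_prob)
    lens <- pmin(lens, 8L)
    gc <- query_codes(g)
    # build haplotype piecewise; events processed left to right, no overlap
    pieces <- character(0)
    vars <- vector("list", length(mut))
    cursor <- 1L # 1-based next unconsumed reference position
    segs <- list()
    hap_len <- 0L
    for (e in seq_along(mut)) {
      p <- mut[e] # 1-based mutated site
      if (p < cursor) next
      pre <- if (p > cursor) substr(g, cursor, p - 1L) else ""
      if (nzchar(pre)) {
        segs[[length(segs) + 1L]] <- c(hap_len, cursor - 1L, nchar(pre))
        hap_len <- hap_len + nchar(pre)
        pieces <- c(pieces, pre)
      }
      if (!is_indel[e]) {
        newc <- (gc[p] + sample.int(3L, 1L)) %% 4L
        pieces <- c(pieces, string_from_codes(newc, "N"))
        segs[[length(segs) + 1L]] <- c(hap_len, p - 1L, 1L)
        hap_len <- hap_len + 1L
        vars[[e]] <- data.frame(ref_pos = p - 1L, type = "snp", len = 1L,
                                stringsAsFactors = FALSE)
        cursor <- p + 1L
      } else if (is_ins[e]) {
        ins <- string_from_codes(sample.int(4L, lens[e], TRUE) - 1L, "N")
        base <- substr(g, p, p)
        pieces <- c(pieces, base, ins)
        segs[[length(segs) + 1L]] <- c(hap_len, p - 1L, 1L)
        hap_len <- hap_len + 1L + lens[e] # inserted bases project to anchor
        vars[[e]] <- data.frame(ref_pos = p - 1L, type = "ins", len = lens[e],
                                stringsAsFactors = FALSE)
        cursor <- p + 1L
      } else {
        dl <- min(lens[e], L - p + 1L)
        vars[[e]] <- data.frame(ref_pos = p - 1L, type = "del", len = dl,
                                stringsAsFactors = FALSE)
        cursor <- p + dl
      }
    }
    if (cursor <= L) {
      segs[[length(segs) + 1L]] <- c(hap_len, cursor - 1L, L - cursor + 1L)
      pieces <- c(pieces, substr(g, cursor, L))
    }
    segmat <- do.call(rbind, segs)
    segments <- data.frame(hap_start = segmat[, 1L], ref_start = segmat[, 2L],
                           len = segmat[, 3L])
    list(haplotype = paste(pieces, collapse = ""),
         variants = do.call(rbind, vars[!vapply(vars, is.null, logical(1))]),
         segments = segments)
  })
}

#' Project haplotype coordinates to reference coordinates
#'
#' Positions inside inserted material project to the insertion anchor base.
#'
#' @param hap_pos 0-based haplotype positions.
#' @param segments segment map from [mutate_haplotype()].
#' @return 0-based reference positions.
#' @export
project_to_reference <- function(hap_pos, segments) {
  # segment i covers hap coords [hap_start, next hap_start); within the first
  # `len` bases the mapping is linear, beyond (inserted bases) it clamps
  idx <- findInterval(hap_pos, segments$hap_start)
  off <- hap_pos - segments$hap_start[idx]
  segments$ref_start[idx] + pmin(off, segments$len[idx] - 1L)
}

#' Simulation parameters
#'
#' @param n_pairs number of read pairs.
#' @param read_len read length (bp).
#' @param base_error_rate per-base sequencing error probability.
#' @param mutation_rate,indel_fraction haplotype mutation model.
#' @param insert_mean,insert_sd insert-size distribution (bp).
#' @param rng_seed seed.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_pairs = 10000L, read_len = 70L,
                       base_error_rate = 0.02, mutation_rate = 0.001,
                       indel_fraction = 0.1, insert_mean = 500,
                       insert_sd = 50, rng_seed = NULL) {
  stopifnot(n_pairs >= 1L, read_len >= 1L,
            base_error_rate >= 0, base_error_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            indel_fraction >= 0, indel_fraction <= 1,
            insert_mean > read_len, insert_sd >= 0)
  structure(list(n_pairs = as.integer(n_pairs), read_len = as.integer(read_len),
                 base_error_rate = base_error_rate,
                 mutation_rate = mutation_rate,
                 indel_fraction = indel_fraction,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 rng_seed = rng_seed),
            class = c("sim_params", "list"))
}

#' Sample paired-end reads from a haplotype
#'
#' Pair start positions are uniform over the haplotype; insert lengths are
#' normal(insert_mean, insert_sd) truncated to at least the read length;
#' mate 1 is the forward strand, mate 2 the reverse complement of the insert
#' end; sequencing errors are injected per base at `base_error_rate`;
#' qualities are constant `I` (the aligner is quality-blind); truth is
#' encoded in the read names after projection to reference coordinates.
#'
#' @param haplotype haplotype string (or list from [mutate_haplotype()]).
#' @param params a [sim_params()] object.
#' @param contig contig name recorded in truth.
#' @param segments projection map (identity if omitted).
#' @return list with `reads1`, `reads2` (data.frames name/seq/qual) and
#'   `truth` (data.frame `name`, `contig`, `pos1`, `strand1`, `pos2`,
#'   `strand2`).
#' @export
sample_read_pairs <- function(haplotype, params, contig = "sim1",
                              segments = NULL) {
  if (is.list(haplotype) && !is.null(haplotype$haplotype)) {
    if (is.null(segments)) segments <- haplotype$segments
    haplotype <- haplotype$haplotype
  }
  L <- nchar(haplotype)
  rl <- params$read_len
  if (L < params$insert_mean)
    stop(sprintf("haplotype (%d bp) is shorter than the mean insert (%g bp)",
                 L, params$insert_mean), call. = FALSE)
  if (is.null(segments))
    segments <- data.frame(hap_start = 0L, ref_start = 0L, len = L)
  with_seed(params$rng_seed, {
    n <- params$n_pairs
    isize <- pmax(rl, pmin(L, round(rnorm(n, params$insert_mean, params$insert_sd))))
    start <- floor(runif(n, 0, L - isize + 1)) # 0-based
    hc <- query_codes(haplotype)
    take <- function(from) { # from: 0-based vector; returns n x rl code matrix
      idx <- rep(from, each = rl) + seq_len(rl)
      matrix(hc[idx], nrow = rl)
    }
    m1 <- take(start)
    m2 <- take(start + isize - rl)
    inject <- function(m) {
      err <- which(runif(length(m)) < params$base_error_rate)
      if (length(err)) m[err] <- (m[err] + sample.int(3L, length(err), TRUE)) %% 4L
      m
    }
    m1 <- inject(m1)
    m2 <- inject(m2) # mate 2 reverse-complemented below, post-error
    p1 <- project_to_reference(start, segments)
    p2 <- project_to_reference(start + isize - rl, segments)
    names_ <- sprintf("sim:%s:%d:+:%d:-:%d", contig, p1, p2, seq_len(n))
    seq_from <- function(m) apply(m, 2L, string_from_codes, sentinel = "N")
    rc <- function(m) apply(m, 2L, function(col) rev(3L - col))
    qual <- strrep("I", rl)
    list(reads1 = data.frame(name = names_, seq = seq_from(m1), qual = qual,
                             stringsAsFactors = FALSE),
         reads2 = data.frame(name = names_, seq = seq_from(rc(m2)), qual = qual,
                             stringsAsFactors = FALSE),
         truth = data.frame(name = names_, contig = contig, pos1 = p1,
                            strand1 = "+", pos2 = p2, strand2 = "-",
                            stringsAsFactors = FALSE))
  })
}
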