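#' Supported motif patterns
#'
#' Motif patterns describe a short nucleobase stack around a focal position:
#' `X` marks the (potentially substituted) base, `N` a flanking base. The 5'
#' side of the pattern is always written first, so `XN` is the focal base plus
#' one base in the 3' direction on the transcribed strand, and `NNXNNN` is a
#' sextuplet with two 5' and three 3' flanking bases.
#'
#' @format Character vector of the supported pattern strings.
#' @export
MOTIF_PATTERNS <- c("X", "XN", "NX", "XNN", "NNX", "XNNN", "NNNX",
                    "NXN", "NXNN", "NNXNN", "NNXNNN")

NUCLEOTIDES <- c("A", "C", "G", "T")

#' Parse a motif pattern
#'
#' @param pattern One of [MOTIF_PATTERNS].
#' @return A list with `pattern`, `k` (motif length), `x_pos` (1-based
#'   position of the focal base), `n5` and `n3` (number of 5' and 3' flanking
#'   bases).
#' @export
parse_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  if (!pattern %in% MOTIF_PATTERNS) {
    stop("unsupported motif pattern '", pattern, "'; supported: ",
         paste(MOTIF_PATTERNS, collapse = ", "))
  }
  chars <- strsplit(pattern, "")[[1L]]
  x_pos <- which(chars == "X")
  list(pattern = pattern, k = length(chars), x_pos = x_pos,
       n5 = x_pos - 1L, n3 = length(chars) - x_pos)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector over the ACGT(N) alphabet.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

#' All DNA motifs of a given length
#'
#' @param k Motif length.
#' @return Character vector of the `4^k` motifs in lexicographic order.
#' @export
all_motifs <- function(k) {
  stopifnot(k >= 1L)
  grid <- do.call(expand.grid,
                  c(rep(list(NUCLEOTIDES), k), stringsAsFactors = FALSE))
  sort(do.call(paste0, grid[rev(seq_len(k))]))
}

# Extract sense-strand motifs at genomic positions of one contig.
# `seq` is the contig sequence (plus strand), `pos` 1-based positions,
# `strand` "+" or "-".  The motif has `n5` bases 5' and `n3` bases 3' of the
# focal base in TRANSCRIPT orientation; for minus-strand positions the
# plus-strand window is mirrored and reverse-complemented.  Windows running
# off the contig or containing non-ACGT letters yield NA.
extract_motifs <- function(seq, pos, strand, n5, n3) {
  len <- nchar(seq)
  plus <- strand == "+"
  start <- ifelse(plus, pos - n5, pos - n3)
  end <- ifelse(plus, pos + n3, pos + n5)
  out <- rep(NA_character_, length(pos))
  ok <- start >= 1L & end <= len
  out[ok] <- substring(seq, start[ok], end[ok])
  neg <- which(ok & !plus)
  if (length(neg)) out[neg] <- revcomp(out[neg])
  idx <- which(!is.na(out))
  bad <- idx[grepl("[^ACGT]", out[idx])]
  if (length(bad)) out[bad] <- NA_character_
  out
}

# Motifs for a (chrom, pos, strand) table against a genome_sequence.
extract_motifs_multi <- function(genome, chrom, pos, strand, n5, n3) {
  out <- rep(NA_character_, length(pos))
  for (chr in unique(chrom)) {
    if (!chr %in% names(genome)) {
      stop("contig '", chr, "' not present in genome")
    }
    i <- which(chrom == chr)
    out[i] <- extract_motifs(genome[[chr]], pos[i], strand[i], n5, n3)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
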