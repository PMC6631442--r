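#' Read a genome from FASTA
#'
#' Sequences are uppercased and validated against the DNA alphabet
#' (A, C, G, T, N); RNA letters are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A `genome_sequence`: named list of contig sequences (character).
#' @export
read_genome <- function(path) {
  # read as raw strings first: DNAStringSet would silently coerce RNA "U"
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate contig name(s) in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  if (any(grepl("[^ACGTN]", seqs))) {
    stop("genome contains letters outside the A/C/G/T/N alphabet")
  }
  genome_sequence(stats::setNames(as.list(seqs), nm))
}

#' Construct a genome container from in-memory sequences
#'
#' @param seqs Named list (or named character vector) of contig sequences.
#' @return A `genome_sequence` object.
#' @export
genome_sequence <- function(seqs) {
  seqs <- as.list(seqs)
  stopifnot(length(seqs) > 0, !is.null(names(seqs)))
  seqs <- lapply(seqs, function(s) toupper(as.character(s)))
  if (any(grepl("[^ACGTN]", unlist(seqs)))) {
    stop("genome contains letters outside the A/C/G/T/N alphabet")
  }
  structure(seqs, class = "genome_sequence")
}

#' Fetch a genome slice
#'
#' @param genome A `genome_sequence`.
#' @param chrom Contig name.
#' @param start,end 1-based inclusive coordinates.
#' @return The plus-strand sequence of the interval.
#' @export
genome_slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown contig '", chrom, "'")
  seq <- genome[[chrom]]
  if (start < 1 || end > nchar(seq) || start > end) {
    stop("slice [", start, ", ", end, "] out of bounds for contig '",
         chrom, "' (length ", nchar(seq), ")")
  }
  substring(seq, start, end)
}

#' Construct a transcript gene model
#'
#' Coordinates are 1-based inclusive genomic coordinates (the GFF3/R
#' convention). The coding span `cds_start..cds_end` must be contained in the
#' exon union, and the spliced CDS length must be a multiple of 3; violations
#' reject the model with a warning (returning `NULL`).
#'
#' @param id Transcript identifier.
#' @param chrom Contig name.
#' @param strand "+" or "-".
#' @param exon_starts,exon_ends Parallel integer vectors of exon coordinates.
#' @param cds_start,cds_end Genomic span of the CDS.
#' @return A `gene_model`, or `NULL` (with a warning) if rejected. The model
#'   carries derived `cds_ranges`, `introns`, `utr5` and `utr3` interval sets
#'   ([IRanges::IRanges]).
#' @export
gene_model <- function(id, chrom, strand, exon_starts, exon_ends,
                       cds_start, cds_end) {
  stopifnot(strand %in% c("+", "-"), length(exon_starts) == length(exon_ends))
  ord <- order(exon_starts)
  exons <- IRanges::IRanges(start = exon_starts[ord], end = exon_ends[ord])
  if (any(IRanges::start(exons) > IRanges::end(exons)) ||
      length(IRanges::reduce(exons)) != length(exons)) {
    warning("model '", id, "' rejected: exons overlap or are malformed")
    return(NULL)
  }
  cds_span <- IRanges::IRanges(start = cds_start, end = cds_end)
  cds_ranges <- IRanges::intersect(exons, cds_span)
  ends_exonic <-
    IRanges::countOverlaps(IRanges::IRanges(cds_start, cds_start), exons) > 0 &
    IRanges::countOverlaps(IRanges::IRanges(cds_end, cds_end), exons) > 0
  if (!ends_exonic) {
    warning("model '", id, "' rejected: CDS extends outside exons")
    return(NULL)
  }
  if (sum(IRanges::width(cds_ranges)) %% 3L != 0L) {
    warning("model '", id, "' rejected: spliced CDS length not divisible by 3")
    return(NULL)
  }
  span <- range(exons)
  introns <- IRanges::setdiff(span, exons)
  exonic_left <- IRanges::intersect(
    exons, IRanges::IRanges(IRanges::start(span), cds_start - 1L))
  exonic_right <- IRanges::intersect(
    exons, IRanges::IRanges(cds_end + 1L, IRanges::end(span)))
  if (strand == "+") {
    utr5 <- exonic_left; utr3 <- exonic_right
  } else {
    utr5 <- exonic_right; utr3 <- exonic_left
  }
  structure(list(id = id, chrom = chrom, strand = strand, exons = exons,
                 cds_start = cds_start, cds_end = cds_end,
                 cds_ranges = cds_ranges, introns = introns,
                 utr5 = utr5, utr3 = utr3, span = span),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$id, " ", x$chrom, ":", IRanges::start(x$span), "-",
      IRanges::end(x$span), " (", x$strand, "), ",
      length(x$exons), " exon(s), CDS ", x$cds_start, "-", x$cds_end,
      "\n", sep = "")
  invisible(x)
}

#' Read transcript models from GFF3 or BED12
#'
#' GFF3 files must carry `mRNA` (or `transcript`) features with `exon` and
#' `CDS` children; BED12 files use the block structure for exons and the
#' thick interval for the CDS. Models failing validation (CDS outside exons,
#' CDS length not a multiple of 3) are dropped with a warning.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @param format "auto" (from extension), "gff3" or "bed".
#' @return Named list of `gene_model` objects.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    types <- as.character(gr$type)
    tx_idx <- which(types %in% c("mRNA", "transcript"))
    models <- list()
    for (i in tx_idx) {
      tx_id <- gr$ID[i]
      kids <- which(vapply(gr$Parent, function(p) tx_id %in% p, logical(1)))
      ex <- kids[types[kids] == "exon"]
      cds <- kids[types[kids] == "CDS"]
      if (!length(ex) || !length(cds)) {
        warning("transcript '", tx_id, "' skipped: missing exon or CDS features")
        next
      }
      m <- gene_model(
        id = tx_id,
        chrom = as.character(GenomicRanges::seqnames(gr))[i],
        strand = as.character(GenomicRanges::strand(gr))[i],
        exon_starts = GenomicRanges::start(gr)[ex],
        exon_ends = GenomicRanges::end(gr)[ex],
        cds_start = min(GenomicRanges::start(gr)[cds]),
        cds_end = max(GenomicRanges::end(gr)[cds]))
      if (!is.null(m)) models[[tx_id]] <- m
    }
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    models <- list()
    for (i in seq_along(gr)) {
      blocks <- if (!is.null(gr$blocks)) gr$blocks[[i]] else
        IRanges::IRanges(1L, GenomicRanges::width(gr)[i])
      off <- GenomicRanges::start(gr)[i] - 1L
      thick <- gr$thick[i]
      m <- gene_model(
        id = gr$name[i],
        chrom = as.character(GenomicRanges::seqnames(gr))[i],
        strand = as.character(GenomicRanges::strand(gr))[i],
        exon_starts = IRanges::start(blocks) + off,
        exon_ends = IRanges::end(blocks) + off,
        cds_start = IRanges::start(thick),
        cds_end = IRanges::end(thick))
      if (!is.null(m)) models[[gr$name[i]]] <- m
    }
  }
  models
}

#' Classify a position within a transcript
#'
#' "exon" denotes the coding (CDS) portion; untranslated exonic sequence is
#' reported as "utr5"/"utr3" and intervening sequence as "intron".
#'
#' @param model A `gene_model`.
#' @param pos 1-based genomic position (vectorized).
#' @return Character vector over \{"exon", "intron", "utr5", "utr3"\}.
#' @export
classify_site <- function(model, pos) {
  stopifnot(inherits(model, "gene_model"))
  q <- IRanges::IRanges(pos, pos)
  if (any(IRanges::countOverlaps(q, model$span) == 0)) {
    stop("position(s) outside the span of transcript '", model$id, "'")
  }
  out <- rep("intron", length(pos))
  out[IRanges::countOverlaps(q, model$cds_ranges) > 0] <- "exon"
  out[IRanges::countOverlaps(q, model$utr5) > 0] <- "utr5"
  out[IRanges::countOverlaps(q, model$utr3) > 0] <- "utr3"
  out
}

#' Strand-resolved sequence context of a site
#'
#' Flanks are taken from the contiguous genomic sequence (they may cross
#' exon/intron boundaries) and re-oriented so that `up_flank` is 5' and
#' `down_flank` 3' on the transcribed strand; for minus-strand transcripts
#' both flanks and the reference base are reverse-complemented.
#'
#' @param genome A `genome_sequence`.
#' @param model A `gene_model`.
#' @param pos 1-based genomic position.
#' @param flank Number of flanking bases on each side (default 15).
#' @return A `site_context` list: `chrom`, `pos`, `strand`, `region`,
#'   `sense_ref`, `up_flank`, `down_flank`, `truncated`.
#' @export
site_context <- function(genome, model, pos, flank = 15L) {
  stopifnot(inherits(model, "gene_model"), length(pos) == 1L)
  seq <- genome[[model$chrom]]
  if (is.null(seq)) stop("contig '", model$chrom, "' not in genome")
  len <- nchar(seq)
  if (pos < 1 || pos > len) stop("position out of contig bounds")
  left <- substring(seq, max(1L, pos - flank), pos - 1L)
  base <- substring(seq, pos, pos)
  right <- substring(seq, pos + 1L, min(len, pos + flank))
  truncated <- nchar(left) < flank || nchar(right) < flank
  if (model$strand == "-") {
    up <- revcomp(right); down <- revcomp(left); base <- revcomp(base)
  } else {
    up <- left; down <- right
  }
  structure(list(chrom = model$chrom, pos = pos, strand = model$strand,
                 region = classify_site(model, pos), sense_ref = base,
                 up_flank = up, down_flank = down, truncated = truncated),
            class = "site_context")
}

#' Motif around a site for a given pattern
#'
#' @param context A `site_context`.
#' @param pattern One of [MOTIF_PATTERNS].
#' @return List with `motif` (NA if the window contains an ambiguous base,
#'   so callers can skip it) and `x_pos` (1-based position of the focal base
#'   in the motif).
#' @export
motif_at <- function(context, pattern) {
  p <- parse_pattern(pattern)
  up <- context$up_flank; down <- context$down_flank
  if (nchar(up) < p$n5 || nchar(down) < p$n3) {
    stop("insufficient flank for pattern '", pattern, "'")
  }
  motif <- paste0(substring(up, nchar(up) - p$n5 + 1L, nchar(up)),
                  context$sense_ref,
                  substring(down, 1L, p$n3))
  if (grepl("[^ACGT]", motif)) motif <- NA_character_
  list(motif = motif, x_pos = p$x_pos)
}

# Spliced CDS sequence (transcript orientation) and the parallel vector of
# genomic positions, ordered 5'->3' along the transcript.
spliced_cds <- function(genome, model) {
  seq <- genome[[model$chrom]]
  parts <- substring(seq, IRanges::start(model$cds_ranges),
                     IRanges::end(model$cds_ranges))
  cds_seq <- paste(parts, collapse = "")
  pos <- unlist(lapply(seq_along(model$cds_ranges), function(i) {
    seq.int(IRanges::start(model$cds_ranges)[i],
            IRanges::end(model$cds_ranges)[i])
  }), use.names = FALSE)
  if (model$strand == "-") {
    cds_seq <- revcomp(cds_seq)
    pos <- rev(pos)
  }
  list(seq = cds_seq, pos = pos)
}

#' Coding effect of an exonic substitution
#'
#' The affected codon is assembled from the spliced CDS (so codons spanning
#' splice junctions are handled) and translated with the standard genetic
#' code before and after the substitution.
#'
#' @param model A `gene_model`.
#' @param genome A `genome_sequence`.
#' @param pos 1-based genomic position; must fall in the CDS.
#' @param ref,alt Sense-strand (transcribed-strand) bases.
#' @return One of "synonymous", "missense", "nonsense". A substitution that
#'   destroys a stop codon is reported as "missense".
#' @export
coding_effect <- function(model, genome, pos, ref, alt) {
  sc <- spliced_cds(genome, model)
  idx <- match(pos, sc$pos)
  if (is.na(idx)) stop("position ", pos, " is not in the CDS of '", model$id, "'")
  if (substring(sc$seq, idx, idx) != ref) {
    stop("reference base mismatch at ", model$chrom, ":", pos,
         " (genome has ", substring(sc$seq, idx, idx), ", record says ", ref, ")")
  }
  codon_start <- idx - (idx - 1L) %% 3L
  if (codon_start + 2L > nchar(sc$seq)) stop("incomplete terminal codon")
  codon <- substring(sc$seq, codon_start, codon_start + 2L)
  within <- idx - codon_start + 1L
  mut <- codon
  substr(mut, within, within) <- alt
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[codon])
  aa_alt <- unname(code[mut])
  if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*") "nonsense"
  else "missense"
}
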