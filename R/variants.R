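CLINICAL_LEVELS <- c("pathogenic", "likely_pathogenic", "benign",
                     "likely_benign", "vus", "other")

# ClinVar-style CLNSIG strings -> internal clinical classes.
map_clnsig <- function(x) {
  key <- gsub("[ /]", "_", tolower(trimws(as.character(x))))
  out <- rep("other", length(key))
  out[key == "pathogenic"] <- "pathogenic"
  out[key == "likely_pathogenic"] <- "likely_pathogenic"
  out[key == "benign"] <- "benign"
  out[key == "likely_benign"] <- "likely_benign"
  out[key %in% c("uncertain_significance", "vus")] <- "vus"
  out[is.na(x) | key %in% c("", ".", "na", "not_provided")] <- "other"
  out
}

#' Read single-base substitution variants
#'
#' Accepts VCF v4.x (clinical significance in the `CLNSIG` INFO key) or a
#' tab-separated table with columns `chrom`, `pos`, `ref`, `alt`, `clnsig`
#' (1-based positions, plus-strand alleles in both formats). Only
#' single-nucleotide substitutions over A/C/G/T are kept; other records are
#' silently filtered. Unrecognized clinical strings map to "other".
#'
#' @param path Path to a `.vcf` or TSV file.
#' @param format "auto" (from extension), "vcf" or "tsv".
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `clinical`.
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    cln <- vcfR::extract.info(v, "CLNSIG")
    df <- data.frame(chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     clinical = map_clnsig(cln),
                     stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "clnsig")
    if (!all(need %in% names(raw))) {
      stop("variant TSV must have columns: ", paste(need, collapse = ", "))
    }
    df <- data.frame(chrom = as.character(raw$chrom),
                     pos = as.integer(raw$pos),
                     ref = as.character(raw$ref),
                     alt = as.character(raw$alt),
                     clinical = map_clnsig(raw$clnsig),
                     stringsAsFactors = FALSE)
  }
  keep <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    df$ref %in% NUCLEOTIDES & df$alt %in% NUCLEOTIDES & df$ref != df$alt
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Annotate variants against a genome and transcript models
#'
#' Each variant is assigned to exactly one transcript: among the transcripts
#' whose span covers it, the one with the longest spliced CDS (ties broken by
#' lexicographic id). Variants outside every transcript span, or whose
#' reference allele disagrees with the genome, are dropped with a warning
#' (counts in `attr(, "skipped")`). Alleles are re-expressed on the
#' transcribed (sense) strand, the gene region is assigned, and exonic
#' variants are classified as synonymous/missense/nonsense.
#'
#' @param variants Data frame from [read_variants()] (plus-strand alleles).
#' @param genome A `genome_sequence`.
#' @param models List of `gene_model` objects.
#' @param effects If `FALSE`, skip the (more expensive) coding-effect
#'   classification; exonic records then carry effect `NA`.
#' @return An `sbs_records` data.frame: `chrom`, `pos`, `ref`, `alt`
#'   (sense strand), `strand`, `transcript`, `region`, `effect`, `clinical`.
#' @export
annotate_variants <- function(variants, genome, models, effects = TRUE) {
  stopifnot(is.data.frame(variants), length(models) > 0)
  prio <- order(-vapply(models, function(m) sum(IRanges::width(m$cds_ranges)),
                        numeric(1)),
                vapply(models, function(m) m$id, character(1)))
  models <- models[prio]
  m_chrom <- vapply(models, function(m) m$chrom, character(1))

  tx_idx <- rep(NA_integer_, nrow(variants))
  for (chr in unique(variants$chrom)) {
    vi <- which(variants$chrom == chr)
    mi <- which(m_chrom == chr)
    if (!length(mi)) next
    spans <- IRanges::IRanges(
      vapply(models[mi], function(m) IRanges::start(m$span), integer(1)),
      vapply(models[mi], function(m) IRanges::end(m$span), integer(1)))
    hits <- IRanges::findOverlaps(IRanges::IRanges(variants$pos[vi],
                                                   variants$pos[vi]), spans)
    if (length(hits)) {
      first <- !duplicated(S4Vectors::queryHits(hits))
      tx_idx[vi[S4Vectors::queryHits(hits)[first]]] <-
        mi[S4Vectors::subjectHits(hits)[first]]
    }
  }
  n_outside <- sum(is.na(tx_idx))
  keep <- which(!is.na(tx_idx))
  variants <- variants[keep, , drop = FALSE]
  tx_idx <- tx_idx[keep]

  # plus-strand reference check against the genome
  gref <- character(nrow(variants))
  for (chr in unique(variants$chrom)) {
    i <- which(variants$chrom == chr)
    gref[i] <- substring(genome[[chr]], variants$pos[i], variants$pos[i])
  }
  mismatch <- gref != variants$ref
  n_mismatch <- sum(mismatch)
  if (n_mismatch) {
    warning(n_mismatch, " variant(s) dropped: reference allele mismatch")
  }
  variants <- variants[!mismatch, , drop = FALSE]
  tx_idx <- tx_idx[!mismatch]

  strand <- vapply(models, function(m) m$strand, character(1))[tx_idx]
  tx_id <- vapply(models, function(m) m$id, character(1))[tx_idx]
  ref <- variants$ref; alt <- variants$alt
  minus <- strand == "-"
  ref[minus] <- revcomp(ref[minus])
  alt[minus] <- revcomp(alt[minus])

  region <- character(nrow(variants))
  effect <- rep(NA_character_, nrow(variants))
  for (ti in unique(tx_idx)) {
    m <- models[[ti]]
    i <- which(tx_idx == ti)
    region[i] <- classify_site(m, variants$pos[i])
    if (effects) {
      ex <- i[region[i] == "exon"]
      if (length(ex)) {
        sc <- spliced_cds(genome, m)
        idx <- match(variants$pos[ex], sc$pos)
        codon_start <- idx - (idx - 1L) %% 3L
        codons <- substring(sc$seq, codon_start, codon_start + 2L)
        within <- idx - codon_start + 1L
        muts <- codons
        substr(muts, within, within) <- alt[ex]
        code <- Biostrings::GENETIC_CODE
        aa_ref <- code[codons]; aa_alt <- code[muts]
        eff <- ifelse(aa_ref == aa_alt, "synonymous",
                      ifelse(aa_alt == "*", "nonsense", "missense"))
        effect[ex] <- eff
      }
    }
    effect[i[region[i] != "exon"]] <- "noncoding"
  }

  out <- data.frame(chrom = variants$chrom, pos = variants$pos,
                    ref = ref, alt = alt, strand = strand,
                    transcript = tx_id, region = region, effect = effect,
                    clinical = variants$clinical, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("sbs_records", "data.frame")
  attr(out, "skipped") <- c(outside_transcripts = n_outside,
                            ref_mismatch = n_mismatch)
  out
}
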