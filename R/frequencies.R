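# Positions (chrom, pos, strand) belonging to a gene region across models.
# region: "exon" (CDS), "intron", "utr5", "utr3", or "utr" (both UTRs).
region_positions <- function(models, region) {
  stopifnot(region %in% c("exon", "intron", "utr5", "utr3", "utr"))
  pick <- function(m) {
    rr <- switch(region,
                 exon = m$cds_ranges,
                 intron = m$introns,
                 utr5 = m$utr5,
                 utr3 = m$utr3,
                 utr = c(m$utr5, m$utr3))
    if (!length(rr) || sum(IRanges::width(rr)) == 0) return(NULL)
    pos <- unlist(lapply(seq_along(rr), function(i) {
      seq.int(IRanges::start(rr)[i], IRanges::end(rr)[i])
    }), use.names = FALSE)
    data.frame(chrom = m$chrom, pos = pos, strand = m$strand,
               stringsAsFactors = FALSE)
  }
  parts <- Filter(Negate(is.null), lapply(models, pick))
  if (!length(parts)) return(data.frame(chrom = character(), pos = integer(),
                                        strand = character()))
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

new_motif_counts <- function(region, pattern, counts, total, n_skipped,
                             filter_label = "none") {
  structure(list(region = region, pattern = pattern,
                 counts = counts, total = total, n_skipped = n_skipped,
                 filter_label = filter_label),
            class = "motif_counts")
}

#' @export
print.motif_counts <- function(x, ...) {
  cat("<motif_counts> region=", x$region, " pattern=", x$pattern,
      " filter=", x$filter_label, ": ", length(x$counts),
      " motifs, total ", x$total, " (", x$n_skipped, " skipped)\n", sep = "")
  invisible(x)
}

#' Background motif counts of a gene region
#'
#' Every position whose base falls in the requested region of some transcript
#' contributes the sense-strand motif centred on it according to `pattern`
#' (flanks may cross region boundaries; region membership is decided by the
#' focal base only). Overlapping occurrences are all counted; windows
#' containing N or truncated at a contig end are skipped.
#'
#' @param genome A `genome_sequence`.
#' @param models List of `gene_model` objects.
#' @param region "exon" (CDS), "intron", "utr5", "utr3" or "utr".
#' @param pattern One of [MOTIF_PATTERNS].
#' @return A `motif_counts` object (named count vector + total).
#' @export
count_region_motifs <- function(genome, models, region, pattern) {
  p <- parse_pattern(pattern)
  rp <- region_positions(models, region)
  if (!nrow(rp)) stop("region '", region, "' is empty for these models")
  motifs <- extract_motifs_multi(genome, rp$chrom, rp$pos, rp$strand,
                                 p$n5, p$n3)
  ok <- !is.na(motifs)
  tab <- table(motifs[ok])
  counts <- stats::setNames(as.integer(tab), names(tab))
  new_motif_counts(region, pattern, counts, sum(counts), sum(!ok))
}

# Normalize a region selector to the region labels it covers.
region_labels <- function(region) {
  if (identical(region, "utr")) c("utr5", "utr3") else region
}

#' Motif counts of observed substitutions
#'
#' Counts the sense-strand motifs around SBS sites in a region, optionally
#' restricted by filters: `clinical` (vector of clinical classes),
#' `class` ("transition"/"transversion"), `wt_base` (sense-strand wild-type
#' base), `effect` ("missense"/"synonymous"/"nonsense"/"noncoding").
#'
#' @param records An `sbs_records` data.frame (see [annotate_variants()]).
#' @param genome A `genome_sequence`.
#' @param region Region selector as in [count_region_motifs()].
#' @param pattern One of [MOTIF_PATTERNS].
#' @param filters Named list of filters (see Details).
#' @return A `motif_counts` object.
#' @export
count_sbs_motifs <- function(records, genome, region, pattern,
                             filters = list()) {
  p <- parse_pattern(pattern)
  keep <- records$region %in% region_labels(region)
  if (!is.null(filters$clinical)) {
    keep <- keep & records$clinical %in% filters$clinical
  }
  if (!is.null(filters$class)) {
    keep <- keep & substitution_class(records$ref, records$alt) == filters$class
  }
  if (!is.null(filters$wt_base)) keep <- keep & records$ref %in% filters$wt_base
  if (!is.null(filters$effect)) keep <- keep & records$effect %in% filters$effect
  sub <- records[keep, , drop = FALSE]
  label <- if (length(filters)) {
    paste(vapply(names(filters), function(n) {
      paste0(n, "=", paste(filters[[n]], collapse = "|"))
    }, character(1)), collapse = ";")
  } else "none"
  if (!nrow(sub)) {
    return(new_motif_counts(region, pattern, stats::setNames(integer(0),
                                                             character(0)),
                            0L, 0L, label))
  }
  motifs <- extract_motifs_multi(genome, sub$chrom, sub$pos, sub$strand,
                                 p$n5, p$n3)
  ok <- !is.na(motifs)
  if (any(!ok)) {
    warning(sum(!ok), " record(s) skipped for pattern '", pattern,
            "' (ambiguous base or insufficient flank)")
  }
  tab <- table(motifs[ok])
  counts <- stats::setNames(as.integer(tab), names(tab))
  new_motif_counts(region, pattern, counts, sum(counts), sum(!ok), label)
}

#' Normalized SBS frequency per motif
#'
#' The normalized frequency of a motif is its relative frequency among
#' substitution sites divided by its relative frequency among all positions
#' of the same gene region; 1 means "mutated as often as expected from
#' region composition". Motifs never seen in the region background have no
#' defined normalized frequency and are omitted (reported in
#' `attr(, "unmatched")`); motifs with background support but no observed
#' SBS are kept at 0.
#'
#' @param sbs_counts,region_counts `motif_counts` from [count_sbs_motifs()]
#'   and [count_region_motifs()] (same pattern).
#' @return A `norm_freq_table` data.frame: `motif`, `sbs_count`,
#'   `region_count`, `norm_freq`, with numerator/denominator totals stored as
#'   attributes.
#' @export
normalized_frequency <- function(sbs_counts, region_counts) {
  stopifnot(inherits(sbs_counts, "motif_counts"),
            inherits(region_counts, "motif_counts"))
  if (sbs_counts$pattern != region_counts$pattern) {
    stop("numerator and denominator use different motif patterns")
  }
  if (sbs_counts$total == 0) stop("no SBS motif observations to normalize")
  if (region_counts$total == 0) stop("empty region background")
  motifs <- sort(names(region_counts$counts))
  cs <- sbs_counts$counts[motifs]
  cs[is.na(cs)] <- 0L
  cr <- region_counts$counts[motifs]
  unmatched <- setdiff(names(sbs_counts$counts), motifs)
  ratio <- (cs / sbs_counts$total) / (cr / region_counts$total)
  out <- data.frame(motif = motifs, sbs_count = as.integer(cs),
                    region_count = as.integer(cr),
                    norm_freq = as.numeric(ratio),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("norm_freq_table", "data.frame")
  attr(out, "sbs_total") <- sbs_counts$total
  attr(out, "region_total") <- region_counts$total
  attr(out, "region") <- region_counts$region
  attr(out, "pattern") <- region_counts$pattern
  attr(out, "unmatched") <- unmatched
  if (length(unmatched)) {
    warning(length(unmatched), " SBS motif(s) without background support ",
            "omitted: ", paste(head(unmatched, 5), collapse = ", "))
  }
  out
}

#' Transition/transversion classification
#'
#' @param ref,alt Base vectors.
#' @return "transition" (A<->G, C<->T) or "transversion" per element.
#' @export
substitution_class <- function(ref, alt) {
  purine <- c("A", "G")
  ifelse((ref %in% purine) == (alt %in% purine), "transition", "transversion")
}

#' Transition/transversion ratio
#'
#' @param records An `sbs_records` data.frame, or a data.frame with `ref`
#'   and `alt` columns.
#' @return A `ts_tv_result` list: `n_transitions`, `n_transversions`,
#'   `R` (their ratio).
#' @export
ts_tv <- function(records) {
  stopifnot(nrow(records) > 0)
  cls <- substitution_class(records$ref, records$alt)
  n_ts <- sum(cls == "transition")
  n_tv <- sum(cls == "transversion")
  if (n_tv == 0) {
    stop("transition/transversion ratio undefined: no transversions observed")
  }
  structure(list(n_transitions = n_ts, n_transversions = n_tv,
                 R = n_ts / n_tv), class = "ts_tv_result")
}

#' @export
print.ts_tv_result <- function(x, ...) {
  cat("Ts/Tv: ", x$n_transitions, "/", x$n_transversions,
      " = ", format(x$R, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Pathogenic-minus-benign normalized frequency contrast
#'
#' For each motif, computes the normalized SBS frequency separately in the
#' pathogenic group (pathogenic + likely pathogenic) and the benign group
#' (benign + likely benign), and returns their difference
#' `delta_nu = nu_pathogenic - nu_benign`. Records of uncertain or other
#' clinical significance are excluded.
#'
#' @param records An `sbs_records` data.frame with clinical labels.
#' @param genome A `genome_sequence`.
#' @param region_counts `motif_counts` background for the region/pattern.
#' @param filters Extra filters applied to both groups (e.g.
#'   `list(class = "transversion")`).
#' @param pathogenic_labels,benign_labels Clinical classes forming the two
#'   groups.
#' @return A `delta_nu_table` data.frame: `motif`, `nu_pathogenic`,
#'   `nu_benign`, `delta_nu`, plus group sizes as attributes.
#' @export
delta_nu <- function(records, genome, region_counts, filters = list(),
                     pathogenic_labels = c("pathogenic", "likely_pathogenic"),
                     benign_labels = c("benign", "likely_benign")) {
  region <- region_counts$region
  pattern <- region_counts$pattern
  f_path <- utils::modifyList(filters, list(clinical = pathogenic_labels))
  f_ben <- utils::modifyList(filters, list(clinical = benign_labels))
  cp <- count_sbs_motifs(records, genome, region, pattern, f_path)
  cb <- count_sbs_motifs(records, genome, region, pattern, f_ben)
  if (cp$total == 0 || cb$total == 0) {
    stop("empty clinical group (pathogenic n=", cp$total,
         ", benign n=", cb$total, ")")
  }
  np <- normalized_frequency(cp, region_counts)
  nb <- normalized_frequency(cb, region_counts)
  out <- data.frame(motif = np$motif,
                    nu_pathogenic = np$norm_freq,
                    nu_benign = nb$norm_freq,
                    delta_nu = np$norm_freq - nb$norm_freq,
                    stringsAsFactors = FALSE)
  class(out) <- c("delta_nu_table", "data.frame")
  attr(out, "n_pathogenic") <- cp$total
  attr(out, "n_benign") <- cb$total
  attr(out, "region") <- region
  attr(out, "pattern") <- pattern
  out
}

#' Pathogenic-minus-benign contrast per substitution type
#'
#' For each of the 12 ordered substitution types ref->alt (sense strand), the
#' group frequency of the type is divided by the background frequency of the
#' wild-type base in the region, and the pathogenic-minus-benign difference
#' is reported together with the absolute single-base vIP change of the
#' type, ready for correlation.
#'
#' @param records An `sbs_records` data.frame with clinical labels.
#' @param region_counts Single-base (`pattern = "X"`) `motif_counts`
#'   background for the region.
#' @param base_table A `base_vip_table` (defaults to the experimental
#'   values).
#' @param pathogenic_labels,benign_labels Clinical classes forming the two
#'   groups.
#' @return Data frame with one row per ordered substitution type: `ref`,
#'   `alt`, `class`, `abs_delta_vip`, `nu_pathogenic`, `nu_benign`,
#'   `delta_nu`.
#' @export
per_substitution_delta_nu <- function(records, region_counts,
                                      base_table = builtin_base_vips(),
                                      pathogenic_labels = c("pathogenic",
                                                            "likely_pathogenic"),
                                      benign_labels = c("benign",
                                                        "likely_benign")) {
  stopifnot(identical(region_counts$pattern, "X"))
  keep <- records$region %in% region_labels(region_counts$region)
  sub <- records[keep, , drop = FALSE]
  grp <- ifelse(sub$clinical %in% pathogenic_labels, "path",
                ifelse(sub$clinical %in% benign_labels, "benign", NA))
  sub <- sub[!is.na(grp), , drop = FALSE]
  grp <- grp[!is.na(grp)]
  n_path <- sum(grp == "path"); n_ben <- sum(grp == "benign")
  if (n_path == 0 || n_ben == 0) {
    stop("empty clinical group (pathogenic n=", n_path,
         ", benign n=", n_ben, ")")
  }
  types <- expand.grid(alt = NUCLEOTIDES, ref = NUCLEOTIDES,
                       stringsAsFactors = FALSE)[, c("ref", "alt")]
  types <- types[types$ref != types$alt, , drop = FALSE]
  base_freq <- region_counts$counts[types$ref] / region_counts$total
  key <- paste0(sub$ref, ">", sub$alt)
  tkey <- paste0(types$ref, ">", types$alt)
  cnt <- function(g) {
    tab <- table(factor(key[grp == g], levels = tkey))
    as.integer(tab)
  }
  np <- (cnt("path") / n_path) / base_freq
  nb <- (cnt("benign") / n_ben) / base_freq
  out <- data.frame(ref = types$ref, alt = types$alt,
                    class = substitution_class(types$ref, types$alt),
                    abs_delta_vip = delta_vip(base_table, types$ref,
                                              types$alt, absolute = TRUE),
                    nu_pathogenic = as.numeric(np),
                    nu_benign = as.numeric(nb),
                    delta_nu = as.numeric(np - nb),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_pathogenic") <- n_path
  attr(out, "n_benign") <- n_ben
  out
}
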