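#' Experimental vertical ionization potentials of the four nucleobases
#'
#' Returns the experimental gas-phase vertical ionization potentials (vIP, in
#' eV) of the isolated nucleobases. Guanine is the most easily oxidized base
#' and thymine the least, so the values are ordered
#' vIP(G) < vIP(A) < vIP(C) < vIP(T).
#'
#' @return A `base_vip_table`: named numeric vector over A, C, G, T (eV).
#' @examples
#' builtin_base_vips()
#' @export
builtin_base_vips <- function() {
  new_base_vip_table(c(A = 8.42, C = 8.85, G = 8.20, T = 9.10))
}

new_base_vip_table <- function(values) {
  stopifnot(is.numeric(values))
  values <- values[NUCLEOTIDES]
  if (anyNA(values) || length(values) != 4L) {
    stop("base vIP table must contain exactly the four bases A, C, G, T")
  }
  if (any(values <= 5 | values >= 15)) {
    stop("base vIPs must lie in (5, 15) eV")
  }
  structure(values, class = "base_vip_table")
}

#' Construct a base-stack vIP table
#'
#' @param values Named numeric vector mapping uppercase ACGT motifs (length
#'   1-4) to vIP values in eV.
#' @param source_label Free-text provenance of the values (e.g. the
#'   quantum-chemistry method used).
#' @param expected_lengths Integer vector; for each length listed, the table
#'   must contain all `4^k` motifs of that length.
#' @return A `stack_vip_table` object.
#' @export
stack_vip_table <- function(values, source_label = "unspecified",
                            expected_lengths = NULL) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  motifs <- names(values)
  bad <- motifs[grepl("[^ACGT]", motifs) | nchar(motifs) < 1L]
  if (length(bad)) {
    stop("non-ACGT motif(s) in vIP table: ", paste(head(bad, 5), collapse = ", "))
  }
  if (anyDuplicated(motifs)) {
    stop("duplicated motif(s) in vIP table: ",
         paste(unique(motifs[duplicated(motifs)]), collapse = ", "))
  }
  if (anyNA(values)) stop("non-numeric vIP for motif(s): ",
                          paste(motifs[is.na(values)], collapse = ", "))
  for (k in expected_lengths) {
    missing <- setdiff(all_motifs(k), motifs[nchar(motifs) == k])
    if (length(missing)) {
      stop("vIP table claims completeness at length ", k,
           " but lacks motif(s): ", paste(head(missing, 5), collapse = ", "))
    }
  }
  structure(values, source_label = source_label, class = "stack_vip_table")
}

#' Load a base-stack vIP table from a TSV file
#'
#' The file must be tab-separated with a header containing columns `motif`
#' and `vip_ev` (one row per motif, vIP in eV), mirroring the layout of
#' published per-motif supplementary tables.
#'
#' @param path Path to the TSV file.
#' @param expected_lengths Motif lengths at which completeness is enforced.
#' @param source_label Provenance label stored on the table.
#' @return A `stack_vip_table`.
#' @export
load_stack_table <- function(path, expected_lengths = NULL,
                             source_label = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("motif", "vip_ev") %in% names(df))) {
    stop("vIP TSV must have columns 'motif' and 'vip_ev'")
  }
  vip <- suppressWarnings(as.numeric(df$vip_ev))
  if (anyNA(vip)) {
    stop("non-numeric vIP for motif(s): ",
         paste(df$motif[is.na(vip)], collapse = ", "))
  }
  stack_vip_table(stats::setNames(vip, as.character(df$motif)),
                  source_label = source_label,
                  expected_lengths = expected_lengths)
}

#' vIP of a nucleobase stack motif
#'
#' Motifs up to the table's stored length (typically quadruplets) are looked
#' up directly. Longer motifs are composed from the table: a quintuplet is
#' the mean of its two overlapping quadruplets, a sextuplet the mean of its
#' three overlapping quadruplets, and in general a motif of length > 4 is the
#' mean over all its contiguous quadruplet windows.
#'
#' @param table A `stack_vip_table` containing (at least) all quadruplets
#'   needed for composition.
#' @param motif Character vector of ACGT motifs (length >= 1).
#' @return Numeric vector of vIPs (eV).
#' @export
motif_vip <- function(table, motif) {
  stopifnot(inherits(table, "stack_vip_table"))
  if (any(grepl("[^ACGT]", motif)) || any(nchar(motif) < 1L)) {
    stop("motifs must be non-empty and ACGT-only")
  }
  k <- nchar(motif)
  out <- numeric(length(motif))
  direct <- k <= 4L
  if (any(direct)) {
    hit <- match(motif[direct], names(table))
    if (anyNA(hit)) {
      stop("motif(s) absent from vIP table: ",
           paste(motif[direct][is.na(hit)], collapse = ", "))
    }
    out[direct] <- unclass(table)[hit]
  }
  for (i in which(!direct)) {
    wins <- substring(motif[i], seq_len(k[i] - 3L), seq_len(k[i] - 3L) + 3L)
    hit <- match(wins, names(table))
    if (anyNA(hit)) {
      stop("quadruplet window(s) absent from vIP table: ",
           paste(wins[is.na(hit)], collapse = ", "))
    }
    out[i] <- mean(unclass(table)[hit])
  }
  out
}

#' Composition-based vIP estimate from single-base values
#'
#' Estimates the vIP of a motif as the arithmetic mean of the vIPs of its
#' constituent bases, ignoring stacking. This is the cheap estimator that the
#' full base-stack tables are meant to improve on.
#'
#' @param base_table A `base_vip_table`.
#' @param motif Character vector of ACGT motifs.
#' @return Numeric vector of vIP estimates (eV).
#' @export
additive_vip <- function(base_table, motif) {
  stopifnot(inherits(base_table, "base_vip_table"))
  if (any(nchar(motif) < 1L)) stop("empty motif")
  if (any(grepl("[^ACGT]", motif))) stop("motifs must be ACGT-only")
  vapply(strsplit(motif, ""), function(b) {
    mean(unclass(base_table)[b])
  }, numeric(1))
}

#' Change in single-base vIP upon substitution
#'
#' @param base_table A `base_vip_table`.
#' @param ref_base,alt_base Wild-type and mutant bases (vectors over ACGT).
#' @param absolute If `TRUE`, return the absolute change |delta vIP|.
#' @return Numeric vector: vIP(alt) - vIP(ref) in eV (absolute value if
#'   requested).
#' @export
delta_vip <- function(base_table, ref_base, alt_base, absolute = FALSE) {
  stopifnot(inherits(base_table, "base_vip_table"))
  if (!all(ref_base %in% NUCLEOTIDES) || !all(alt_base %in% NUCLEOTIDES)) {
    stop("bases must be one of A, C, G, T")
  }
  v <- unclass(base_table)
  d <- v[alt_base] - v[ref_base]
  names(d) <- NULL
  if (absolute) abs(d) else d
}

#' @export
print.stack_vip_table <- function(x, ...) {
  lens <- table(nchar(names(x)))
  cat("<stack_vip_table> ", length(x), " motifs (",
      paste0("len", names(lens), ":", lens, collapse = ", "), ")\n",
      "source: ", attr(x, "source_label"), "\n", sep = "")
  invisible(x)
}
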