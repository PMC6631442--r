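# Analysis groups mirroring the gene-region subdivisions of the study:
# exonic substitutions split into missense and synonymous, plus introns and
# (combined) UTRs.
analysis_groups <- function(effect_split = TRUE,
                            nonsense_as_missense = FALSE) {
  if (effect_split) {
    missense_effects <- if (nonsense_as_missense) c("missense", "nonsense")
                        else "missense"
    list(missense = list(region = "exon",
                         filters = list(effect = missense_effects)),
         synonymous = list(region = "exon",
                           filters = list(effect = "synonymous")),
         intron = list(region = "intron", filters = list()),
         utr = list(region = "utr", filters = list()))
  } else {
    list(exon = list(region = "exon", filters = list()),
         intron = list(region = "intron", filters = list()),
         utr = list(region = "utr", filters = list()))
  }
}

#' Run the full vIP / SBS-frequency analysis
#'
#' Orchestrates annotation, motif counting, normalization and statistics:
#' for each analysis group (missense, synonymous, intron, UTR) and motif
#' pattern it computes normalized SBS frequencies, the linear and
#' non-linear correlations with motif vIP (overall and per focal base),
#' regression slopes, transition/transversion ratios, the 5'-3' flank
#' asymmetry, and (when both clinical groups are populated) the
#' pathogenic-minus-benign contrasts and their vIP correlations.
#'
#' @param genome A `genome_sequence`.
#' @param models List of `gene_model` objects.
#' @param variants Raw variant data.frame (see [read_variants()]), or an
#'   already annotated `sbs_records` object.
#' @param stack_table A `stack_vip_table`.
#' @param base_table A `base_vip_table` for single-base quantities.
#' @param patterns Motif patterns to analyze.
#' @param effect_split Split exonic SBSs into missense/synonymous groups.
#' @param nonsense_as_missense Count stop-gains in the missense group.
#' @param asymmetry Compute the 5'-3' asymmetry table.
#' @param pathogenicity Compute pathogenic-vs-benign contrasts when both
#'   clinical groups are non-empty.
#' @param out_dir If non-NULL, write the result tables as TSV files there.
#' @return A `report_bundle` list: `records`, `frequencies` (named list of
#'   `norm_freq_table`s), `correlations`, `ts_tv`, `asymmetry`,
#'   `delta_nu_correlations`, `per_substitution`, `meta`.
#' @export
run_pipeline <- function(genome, models, variants, stack_table,
                         base_table = builtin_base_vips(),
                         patterns = c("XN", "NXN", "NXNN"),
                         effect_split = TRUE,
                         nonsense_as_missense = FALSE,
                         asymmetry = TRUE,
                         pathogenicity = TRUE,
                         out_dir = NULL) {
  records <- if (inherits(variants, "sbs_records")) variants
             else annotate_variants(variants, genome, models,
                                    effects = effect_split)
  groups <- analysis_groups(effect_split, nonsense_as_missense)

  frequencies <- list()
  correlations <- list()
  tstv_rows <- list()
  dnu_rows <- list()
  psub_rows <- list()
  asym <- NULL

  region_cache <- list()
  bg <- function(region, pattern) {
    key <- paste(region, pattern)
    if (is.null(region_cache[[key]])) {
      region_cache[[key]] <<- count_region_motifs(genome, models, region,
                                                  pattern)
    }
    region_cache[[key]]
  }

  for (gname in names(groups)) {
    g <- groups[[gname]]
    in_group <- records$region %in% region_labels(g$region)
    if (!is.null(g$filters$effect)) {
      in_group <- in_group & records$effect %in% g$filters$effect
    }
    if (!any(in_group)) next
    tt <- tryCatch(ts_tv(records[in_group, , drop = FALSE]),
                   error = function(e) NULL)
    if (!is.null(tt)) {
      tstv_rows[[gname]] <- data.frame(
        group = gname, n_transitions = tt$n_transitions,
        n_transversions = tt$n_transversions, R = tt$R,
        stringsAsFactors = FALSE)
    }
    for (pattern in patterns) {
      rc <- bg(g$region, pattern)
      sc <- count_sbs_motifs(records, genome, g$region, pattern, g$filters)
      if (sc$total == 0) next
      ft <- normalized_frequency(sc, rc)
      frequencies[[paste(gname, pattern, sep = ".")]] <- ft
      res <- vip_frequency_analysis(ft, stack_table)
      res$group <- gname
      correlations[[paste(gname, pattern, sep = ".")]] <- res
    }
    if (pathogenicity) {
      lab <- records$clinical[in_group]
      n_path <- sum(lab %in% c("pathogenic", "likely_pathogenic"))
      n_ben <- sum(lab %in% c("benign", "likely_benign"))
      if (n_path > 0 && n_ben > 0) {
        for (pattern in patterns) {
          rc <- bg(g$region, pattern)
          for (cls in list(NULL, "transition", "transversion")) {
            fl <- g$filters
            if (!is.null(cls)) fl$class <- cls
            dn <- tryCatch(delta_nu(records, genome, rc, fl),
                           error = function(e) NULL)
            if (is.null(dn)) next
            vip <- motif_vip(stack_table, dn$motif)
            if (length(vip) >= 4 && stats::sd(vip) > 0 &&
                stats::sd(dn$delta_nu) > 0) {
              cres <- pearson(vip, dn$delta_nu)
              dnu_rows[[length(dnu_rows) + 1L]] <- data.frame(
                group = gname, pattern = pattern,
                subset = if (is.null(cls)) "All" else cls,
                n = cres$n, r = cres$r, p = cres$p,
                stringsAsFactors = FALSE)
            }
          }
        }
        rc1 <- bg(g$region, "X")
        ps <- tryCatch({
          rec_g <- records[in_group, , drop = FALSE]
          per_substitution_delta_nu(rec_g, rc1, base_table)
        }, error = function(e) NULL)
        if (!is.null(ps)) {
          ps_ok <- is.finite(ps$delta_nu) & is.finite(ps$abs_delta_vip)
          if (sum(ps_ok) >= 4 && stats::sd(ps$abs_delta_vip[ps_ok]) > 0 &&
              stats::sd(ps$delta_nu[ps_ok]) > 0) {
            cres <- pearson(ps$abs_delta_vip[ps_ok], ps$delta_nu[ps_ok])
            psub_rows[[gname]] <- data.frame(group = gname, n = cres$n,
                                             r = cres$r, p = cres$p,
                                             stringsAsFactors = FALSE)
          }
        }
      }
    }
  }

  if (asymmetry) {
    asym_parts <- list()
    for (gname in names(groups)) {
      g <- groups[[gname]]
      res <- tryCatch(
        asymmetry_analysis(records, genome, models, stack_table,
                           regions = g$region, lengths = 2:4,
                           filters = g$filters),
        error = function(e) NULL)
      if (!is.null(res)) {
        res$group <- gname
        asym_parts[[gname]] <- res
      }
    }
    if (length(asym_parts)) asym <- do.call(rbind, asym_parts)
  }

  bundle <- structure(list(
    records = records,
    frequencies = frequencies,
    correlations = if (length(correlations)) do.call(rbind, correlations),
    ts_tv = if (length(tstv_rows)) do.call(rbind, tstv_rows),
    asymmetry = asym,
    delta_nu_correlations = if (length(dnu_rows)) do.call(rbind, dnu_rows),
    per_substitution = if (length(psub_rows)) do.call(rbind, psub_rows),
    meta = list(n_records = nrow(records),
                skipped = attr(records, "skipped"),
                patterns = patterns)),
    class = "report_bundle")
  if (!is.null(out_dir)) write_report(bundle, out_dir)
  bundle
}

#' Write a report bundle as TSV files
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_report <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (is.null(df)) return()
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  freq_rows <- lapply(names(bundle$frequencies), function(nm) {
    ft <- bundle$frequencies[[nm]]
    data.frame(group_pattern = nm, region = attr(ft, "region"),
               pattern = attr(ft, "pattern"), ft, stringsAsFactors = FALSE)
  })
  if (length(freq_rows)) {
    wt(do.call(rbind, freq_rows), "normalized_frequencies.tsv")
  }
  wt(bundle$correlations, "correlations.tsv")
  wt(bundle$ts_tv, "ts_tv.tsv")
  wt(bundle$asymmetry, "asymmetry.tsv")
  wt(bundle$delta_nu_correlations, "delta_nu_correlations.tsv")
  wt(bundle$per_substitution, "per_substitution_delta_nu.tsv")
  jsonlite::write_json(bundle$meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n",
      "  records: ", x$meta$n_records, "\n",
      "  frequency tables: ", length(x$frequencies), "\n",
      "  correlation rows: ",
      if (is.null(x$correlations)) 0 else nrow(x$correlations), "\n",
      sep = "")
  invisible(x)
}
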