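#' Configuration of the synthetic SBS study
#'
#' Defaults emulate a dbSNP/ClinVar-like gene-region SBS set: three quarters
#' of substitutions exonic, the remainder split between introns and UTRs
#' (with the 3'-UTR several times larger than the 5'-UTR share), about one
#' third of records clinically labelled, and a transition bias that yields a
#' transition/transversion ratio near 2. The mutation process couples the
#' per-site substitution rate to the vIP of the local base-stack motif
#' through `rate ~ exp(-beta * vIP)`, and the pathogenicity of labelled
#' records to the vIP change and motif vIP through a logistic model.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_genes Number of non-overlapping transcripts.
#' @param n_exons_range,exon_length_range,intron_length_range Ranges (bp) of
#'   exon count and coding-exon/intron lengths per gene.
#' @param utr5_length_range,utr3_length_range UTR length ranges (bp).
#' @param intergenic_range Range (bp) of gaps between genes.
#' @param gc_content Genome G+C fraction in (0, 1).
#' @param k Motif length driving the mutation rate (via `rate_pattern`).
#' @param rate_pattern Motif pattern whose vIP sets the site rate; its
#'   length must equal `k`.
#' @param beta Coupling (1/eV) between motif vIP and log mutation rate;
#'   positive beta makes low-vIP motifs mutate more.
#' @param n_sbs Number of substitutions to draw (without replacement).
#' @param ts_bias Relative weight of the transition alt against weight 1 for
#'   each of the two transversions; `ts_bias = 4` gives Ts/Tv = 2.
#' @param label_fraction Fraction of records given a clinical label.
#' @param alpha0,alpha1,alpha2 Logistic coefficients of the pathogenicity
#'   model: `logit P(pathogenic) = alpha0 + alpha1*|delta vIP| +
#'   alpha2*(mean motif vIP - motif vIP)` (alpha1, alpha2 in 1/eV).
#' @param region_mix Proportions of SBSs allocated to exon/intron/utr5/utr3
#'   (must sum to 1).
#' @param gg_bonus vIP lowering (eV) per GpG step in the synthetic stack
#'   vIP table, making G-runs the low-vIP motifs.
#' @param vip_noise Half-width (eV) of the uniform noise added to synthetic
#'   stack vIPs (single-base entries stay exact).
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_genes = 100L,
                         n_exons_range = c(3L, 5L),
                         exon_length_range = c(150L, 450L),
                         intron_length_range = c(500L, 4000L),
                         utr5_length_range = c(100L, 300L),
                         utr3_length_range = c(200L, 800L),
                         intergenic_range = c(500L, 2500L),
                         gc_content = 0.45,
                         k = 3L,
                         rate_pattern = "NXN",
                         beta = 0.5,
                         n_sbs = 50000L,
                         ts_bias = 4,
                         label_fraction = 1 / 3,
                         alpha0 = -0.5,
                         alpha1 = 2,
                         alpha2 = 2,
                         region_mix = c(exon = 0.75, intron = 0.10,
                                        utr5 = 0.03, utr3 = 0.12),
                         gg_bonus = 0.05,
                         vip_noise = 0.01) {
  stopifnot(gc_content > 0, gc_content < 1, n_sbs >= 1, ts_bias > 0,
            label_fraction >= 0, label_fraction <= 1,
            all(c("exon", "intron", "utr5", "utr3") %in% names(region_mix)))
  if (abs(sum(region_mix) - 1) > 1e-9) stop("region_mix must sum to 1")
  p <- parse_pattern(rate_pattern)
  if (p$k != k) stop("rate_pattern length (", p$k, ") must equal k (", k, ")")
  if (min(exon_length_range) < 3) stop("exons must hold at least one codon")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_exons_range = n_exons_range,
                 exon_length_range = exon_length_range,
                 intron_length_range = intron_length_range,
                 utr5_length_range = utr5_length_range,
                 utr3_length_range = utr3_length_range,
                 intergenic_range = intergenic_range,
                 gc_content = gc_content, k = as.integer(k),
                 rate_pattern = rate_pattern, beta = beta,
                 n_sbs = as.integer(n_sbs), ts_bias = ts_bias,
                 label_fraction = label_fraction,
                 alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2,
                 region_mix = region_mix, gg_bonus = gg_bonus,
                 vip_noise = vip_noise),
            class = "synth_config")
}

runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(as.integer(range[1]), n)
  else sample.int(range[2] - range[1] + 1L, n, replace = TRUE) + range[1] - 1L
}

#' Generate a synthetic genome with transcript models
#'
#' Bases are i.i.d. at the configured GC content. Genes are laid out
#' sequentially with intergenic gaps, each with a 5' UTR, alternating coding
#' exons and introns, and a 3' UTR; the spliced CDS length is always a
#' multiple of 3 and strands are drawn at random. Deterministic under the
#' config seed.
#'
#' @param config A `synth_config`.
#' @param dir If non-NULL, write `genome.fa` and `genes.gff3` there.
#' @return List with `genome` (a `genome_sequence`), `models` (list of
#'   `gene_model`), and the file paths when written.
#' @export
synth_genome <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  chrom <- "chr1"
  models <- list()
  cursor <- 1L
  segs <- list()
  for (g in seq_len(config$n_genes)) {
    gap <- runif_int(1, config$intergenic_range)
    n_ex <- runif_int(1, config$n_exons_range)
    cds_lens <- runif_int(n_ex, config$exon_length_range)
    trim <- sum(cds_lens) %% 3L
    cds_lens[n_ex] <- cds_lens[n_ex] - trim  # keep total CDS in frame
    intron_lens <- if (n_ex > 1) runif_int(n_ex - 1L, config$intron_length_range)
                   else integer(0)
    strand <- sample(c("+", "-"), 1)
    u5 <- runif_int(1, config$utr5_length_range)
    u3 <- runif_int(1, config$utr3_length_range)
    left_utr <- if (strand == "+") u5 else u3
    right_utr <- if (strand == "+") u3 else u5
    start <- cursor + gap
    ex_starts <- integer(n_ex); ex_ends <- integer(n_ex)
    at <- start
    for (i in seq_len(n_ex)) {
      len <- cds_lens[i] +
        (if (i == 1L) left_utr else 0L) +
        (if (i == n_ex) right_utr else 0L)
      ex_starts[i] <- at
      ex_ends[i] <- at + len - 1L
      at <- ex_ends[i] + 1L + (if (i < n_ex) intron_lens[i] else 0L)
    }
    cds_start <- start + left_utr
    cds_end <- ex_ends[n_ex] - right_utr
    id <- sprintf("tx%03d", g)
    m <- gene_model(id, chrom, strand, ex_starts, ex_ends, cds_start, cds_end)
    models[[id]] <- m
    segs[[g]] <- c(start = start, end = ex_ends[n_ex])
    cursor <- ex_ends[n_ex] + 1L
  }
  glen <- cursor + runif_int(1, config$intergenic_range)
  pr <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
          G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  seq <- paste(sample(names(pr), glen, replace = TRUE, prob = pr),
               collapse = "")
  genome <- genome_sequence(stats::setNames(list(seq), chrom))
  out <- list(genome = genome, models = models)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fasta <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(seq, chrom)), fasta)
    gff3 <- file.path(dir, "genes.gff3")
    write_gff3(models, gff3)
    out$fasta <- fasta
    out$gff3 <- gff3
  }
  out
}

# Export transcript models as GFF3 (mRNA/exon/CDS hierarchy).
write_gff3 <- function(models, path) {
  grs <- lapply(models, function(m) {
    n_ex <- length(m$exons)
    n_cds <- length(m$cds_ranges)
    starts <- c(IRanges::start(m$span), IRanges::start(m$exons),
                IRanges::start(m$cds_ranges))
    ends <- c(IRanges::end(m$span), IRanges::end(m$exons),
              IRanges::end(m$cds_ranges))
    gr <- GenomicRanges::GRanges(m$chrom, IRanges::IRanges(starts, ends),
                                 strand = m$strand)
    gr$type <- c("mRNA", rep("exon", n_ex), rep("CDS", n_cds))
    gr$ID <- c(m$id, paste0(m$id, ".e", seq_len(n_ex)),
               paste0(m$id, ".c", seq_len(n_cds)))
    gr$Parent <- S4Vectors::unname(IRanges::CharacterList(
      c(list(character(0)), rep(list(m$id), n_ex + n_cds))))
    widths <- IRanges::width(m$cds_ranges)
    tx_order <- if (m$strand == "-") rev(seq_len(n_cds)) else seq_len(n_cds)
    phase <- integer(n_cds)
    phase[tx_order] <- (3L - cumsum(c(0L, widths[tx_order][-n_cds])) %% 3L) %% 3L
    gr$phase <- c(rep(NA_integer_, 1L + n_ex), phase)
    gr
  })
  rtracklayer::export(do.call(c, S4Vectors::unname(grs)), path,
                      format = "gff3")
  invisible(path)
}

#' Generate a synthetic base-stack vIP table
#'
#' Entries for all motifs of lengths 1-4. Single bases carry the
#' experimental values; longer motifs take the additive single-base mean,
#' lowered by `gg_bonus` eV per GpG step and perturbed by small uniform
#' noise, so that G-runs (GG, GGG, GGGG) are guaranteed to be the
#' minimum-vIP motifs of their length, as expected from base stacking.
#'
#' @param config A `synth_config`.
#' @return A `stack_vip_table` complete at lengths 1-4.
#' @export
synth_vip_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  base <- builtin_base_vips()
  values <- unclass(base)
  for (k in 2:4) {
    motifs <- all_motifs(k)
    add <- additive_vip(base, motifs)
    gg <- stringi::stri_count_regex(motifs, "G(?=G)")
    noise <- stats::runif(length(motifs), -config$vip_noise, config$vip_noise)
    values <- c(values, stats::setNames(add - config$gg_bonus * gg + noise,
                                        motifs))
  }
  stack_vip_table(values, source_label = "synthetic (additive + GpG stacking bonus)",
                  expected_lengths = 1:4)
}

transition_partner <- c(A = "G", G = "A", C = "T", T = "C")

#' Simulate single base substitutions under a vIP-coupled mutation process
#'
#' Sites are drawn without replacement, region by region according to
#' `region_mix`, with per-site probability proportional to
#' `exp(-beta * vIP(motif))`, where the motif is the sense-strand
#' `rate_pattern` context of the site. The alternative base is the
#' transition partner with weight `ts_bias` against weight 1 for each
#' transversion. A fraction `label_fraction` of records receives a clinical
#' label; labelled records are pathogenic with probability
#' `plogis(alpha0 + alpha1*|delta vIP| + alpha2*(mean vIP - motif vIP))`,
#' the rest benign (each split between the plain and "likely" annotation).
#'
#' @param config A `synth_config`.
#' @param genome,models Output of [synth_genome()].
#' @param vip_table A `stack_vip_table` resolving `rate_pattern` motifs.
#' @param dir If non-NULL, write `variants.tsv`, `variants.vcf` and the
#'   ground-truth sidecar `truth.json` there.
#' @return List with `variants` (data.frame `chrom`, `pos`, `ref`, `alt`
#'   (plus strand), `clnsig`), `truth` (the [ground_truth()] record), and
#'   file paths when written.
#' @export
synth_sbs <- function(config, genome, models, vip_table, dir = NULL) {
  stopifnot(inherits(config, "synth_config"),
            inherits(vip_table, "stack_vip_table"))
  set.seed(config$seed + 2L)
  p <- parse_pattern(config$rate_pattern)
  base <- builtin_base_vips()
  vip_center <- mean(unclass(vip_table)[nchar(names(vip_table)) == p$k])

  # allocate SBS counts to regions (largest remainder)
  target <- config$region_mix * config$n_sbs
  n_alloc <- floor(target)
  rem <- config$n_sbs - sum(n_alloc)
  if (rem > 0) {
    extra <- order(target - n_alloc, decreasing = TRUE)[seq_len(rem)]
    n_alloc[extra] <- n_alloc[extra] + 1L
  }

  picks <- list()
  for (region in names(config$region_mix)) {
    n_r <- n_alloc[[region]]
    if (n_r == 0) next
    rp <- region_positions(models, region)
    if (!nrow(rp)) stop("no eligible sites in region '", region, "'")
    motifs <- extract_motifs_multi(genome, rp$chrom, rp$pos, rp$strand,
                                   p$n5, p$n3)
    ok <- which(!is.na(motifs))
    if (length(ok) < n_r) {
      stop("region '", region, "' has only ", length(ok),
           " eligible sites for ", n_r, " substitutions")
    }
    um <- unique(motifs[ok])
    vip <- motif_vip(vip_table, um)
    w <- exp(-config$beta * vip[match(motifs[ok], um)])
    keys <- stats::rexp(length(ok)) / w
    sel <- ok[order(keys)[seq_len(n_r)]]
    picks[[region]] <- data.frame(chrom = rp$chrom[sel], pos = rp$pos[sel],
                                  strand = rp$strand[sel],
                                  motif = motifs[sel], region = region,
                                  stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, c(picks, list(make.row.names = FALSE)))

  sense_ref <- substring(sites$motif, p$x_pos, p$x_pos)
  n <- nrow(sites)
  u <- stats::runif(n)
  is_ts <- u < config$ts_bias / (config$ts_bias + 2)
  sense_alt <- character(n)
  sense_alt[is_ts] <- transition_partner[sense_ref[is_ts]]
  tv_choice <- stats::runif(n) < 0.5
  for (b in NUCLEOTIDES) {
    i <- which(!is_ts & sense_ref == b)
    if (!length(i)) next
    tvs <- setdiff(NUCLEOTIDES, c(b, transition_partner[[b]]))
    sense_alt[i] <- ifelse(tv_choice[i], tvs[1], tvs[2])
  }

  abs_dvip <- delta_vip(base, sense_ref, sense_alt, absolute = TRUE)
  motif_vips <- motif_vip(vip_table, sites$motif)
  labelled <- stats::runif(n) < config$label_fraction
  p_path <- stats::plogis(config$alpha0 + config$alpha1 * abs_dvip +
                            config$alpha2 * (vip_center - motif_vips))
  pathogenic <- labelled & (stats::runif(n) < p_path)
  likely <- stats::runif(n) < 0.5
  clnsig <- rep("Uncertain_significance", n)
  clnsig[labelled & pathogenic & likely] <- "Likely_pathogenic"
  clnsig[labelled & pathogenic & !likely] <- "Pathogenic"
  clnsig[labelled & !pathogenic & likely] <- "Likely_benign"
  clnsig[labelled & !pathogenic & !likely] <- "Benign"

  minus <- sites$strand == "-"
  ref <- sense_ref; alt <- sense_alt
  ref[minus] <- revcomp(ref[minus])
  alt[minus] <- revcomp(alt[minus])
  ord <- order(sites$chrom, sites$pos)
  variants <- data.frame(chrom = sites$chrom, pos = sites$pos,
                         ref = ref, alt = alt, clnsig = clnsig,
                         stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(variants) <- NULL

  out <- list(variants = variants, truth = ground_truth(config))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    tsv <- file.path(dir, "variants.tsv")
    utils::write.table(variants, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    vcf <- file.path(dir, "variants.vcf")
    writeLines(c(
      "##fileformat=VCFv4.2",
      paste0("##source=stackvip synth_sbs (seed=", config$seed, ")"),
      "##INFO=<ID=CLNSIG,Number=1,Type=String,Description=\"Clinical significance\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
      sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tCLNSIG=%s", variants$chrom,
              variants$pos, variants$ref, variants$alt, variants$clnsig)),
      vcf)
    truth_path <- file.path(dir, "truth.json")
    jsonlite::write_json(out$truth, truth_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out$tsv <- tsv
    out$vcf <- vcf
    out$truth_path <- truth_path
  }
  out
}

#' Ground-truth parameter record of a synthetic run
#'
#' @param config A `synth_config`.
#' @return Plain list echoing every generative parameter (suitable for JSON
#'   serialization and parameter-recovery tests).
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  rec <- unclass(config)
  rec$region_mix <- as.list(rec$region_mix)
  rec
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper running [synth_genome()], [synth_vip_table()] and
#' [synth_sbs()] under one configuration.
#'
#' @param config A `synth_config`.
#' @param dir Optional output directory passed through to the writers.
#' @return List with `genome`, `models`, `vip_table`, `variants`, `truth`.
#' @export
synth_dataset <- function(config, dir = NULL) {
  gen <- synth_genome(config, dir = dir)
  vip <- synth_vip_table(config)
  sbs <- synth_sbs(config, gen$genome, gen$models, vip, dir = dir)
  c(gen, list(vip_table = vip), sbs)
}
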