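test_that("FASTA reading normalizes case and rejects bad alphabets", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "acgt", ">c2", "GGNN"), fa)
  g <- read_genome(fa)
  expect_equal(g$c1, "ACGT")
  expect_length(g, 2)

  writeLines(c(">c1", "ACGU"), fa)
  expect_error(read_genome(fa), "alphabet")

  writeLines(c(">c1", "ACGT", ">c1", "ACGT"), fa)
  expect_error(read_genome(fa), "duplicate")
})

test_that("gene models derive introns and UTRs, with strand-swapped labels", {
  m <- gene_model("t1", "c1", "+", c(1L, 101L), c(50L, 150L), 11L, 141L)
  expect_equal(as.integer(IRanges::start(m$introns)), 51L)
  expect_equal(as.integer(IRanges::end(m$introns)), 100L)
  expect_equal(c(IRanges::start(m$utr5), IRanges::end(m$utr5)), c(1L, 10L))
  expect_equal(c(IRanges::start(m$utr3), IRanges::end(m$utr3)), c(142L, 150L))

  # same geometry on the minus strand: utr5/utr3 labels swap
  mm <- gene_model("t1", "c1", "-", c(1L, 101L), c(50L, 150L), 11L, 141L)
  expect_equal(c(IRanges::start(mm$utr3), IRanges::end(mm$utr3)), c(1L, 10L))
  expect_equal(c(IRanges::start(mm$utr5), IRanges::end(mm$utr5)), c(142L, 150L))
})

test_that("invalid gene models are rejected with a warning", {
  # spliced CDS length not divisible by 3 (130 bp)
  expect_warning(
    m <- gene_model("bad", "c1", "+", c(1L, 101L), c(50L, 150L), 11L, 130L),
    "divisible by 3")
  expect_null(m)
  # CDS end in the intron
  expect_warning(
    m2 <- gene_model("bad2", "c1", "+", c(1L, 101L), c(50L, 150L), 11L, 60L),
    "outside exons")
  expect_null(m2)
})

test_that("GFF3 and BED12 representations yield identical models", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\ttest\tmRNA\t1\t150\t.\t+\t.\tID=t1",
    "c1\ttest\texon\t1\t50\t.\t+\t.\tParent=t1",
    "c1\ttest\texon\t101\t150\t.\t+\t.\tParent=t1",
    "c1\ttest\tCDS\t11\t50\t.\t+\t0\tParent=t1",
    "c1\ttest\tCDS\t101\t141\t.\t+\t0\tParent=t1"), gff)
  bed <- withr::local_tempfile(fileext = ".bed")
  # BED12: 0-based half-open, blocks relative to chromStart
  writeLines("c1\t0\t150\tt1\t0\t+\t10\t141\t0\t2\t50,50\t0,100", bed)

  mg <- read_gene_models(gff)[["t1"]]
  mb <- read_gene_models(bed)[["t1"]]
  for (m in list(mg, mb)) {
    expect_equal(as.integer(IRanges::start(m$exons)), c(1L, 101L))
    expect_equal(as.integer(IRanges::end(m$exons)), c(50L, 150L))
    expect_equal(m$cds_start, 11L)
    expect_equal(m$cds_end, 141L)
    expect_equal(m$strand, "+")
  }
})

test_that("positions are classified into exactly one region", {
  m <- gene_model("t1", "c1", "+", c(1L, 101L), c(50L, 150L), 11L, 141L)
  expect_equal(classify_site(m, 5), "utr5")
  expect_equal(classify_site(m, 70), "intron")
  expect_equal(classify_site(m, 120), "exon")
  expect_equal(classify_site(m, 145), "utr3")
  expect_error(classify_site(m, 200), "outside")
  # the whole span is partitioned
  all_pos <- 1:150
  labels <- classify_site(m, all_pos)
  expect_equal(sort(unique(labels)), c("exon", "intron", "utr3", "utr5"))
  expect_length(labels, 150)
})

test_that("site context re-orients flanks on the minus strand", {
  g <- genome_sequence(list(c1 = "AACGT"))
  m <- suppressWarnings(gene_model("t1", "c1", "-", 1L, 5L, 3L, 5L))
  # 3 bp CDS so the model validates; focal site: plus-strand C at pos 3
  ctx <- site_context(g, m, 3, flank = 2)
  expect_equal(ctx$sense_ref, "G")
  expect_equal(ctx$up_flank, "AC")   # revcomp of downstream "GT"
  expect_equal(ctx$down_flank, "TT") # revcomp of upstream "AA"

  # plus strand: flanks are the raw genome slices
  mp <- gene_model("t2", "c1", "+", 1L, 5L, 3L, 5L)
  ctxp <- site_context(g, mp, 3, flank = 2)
  expect_equal(ctxp$up_flank, "AA")
  expect_equal(ctxp$down_flank, "GT")
  expect_false(ctxp$truncated)

  # contig start: empty 5' flank, truncation flagged
  ctx0 <- site_context(g, mp, 1, flank = 2)
  expect_equal(ctx0$up_flank, "")
  expect_true(ctx0$truncated)
})

test_that("motif extraction follows the pattern around the focal base", {
  g <- genome_sequence(list(c1 = "AACGTT"))
  m <- gene_model("t1", "c1", "+", 1L, 6L, 1L, 6L)
  ctx <- site_context(g, m, 3, flank = 2)  # sense AC[C->]GTT ; focal C
  expect_equal(motif_at(ctx, "NXN"), list(motif = "ACG", x_pos = 2L))
  expect_equal(motif_at(ctx, "XN")$motif, "CG")
  expect_equal(motif_at(ctx, "NNXNN")$motif, "AACGT")
  expect_error(motif_at(ctx, "NNXNNN"), "insufficient flank")
  expect_error(motif_at(ctx, "XNXN"), "unsupported")

  gn <- genome_sequence(list(c1 = "ANCGTT"))
  mn <- gene_model("t1", "c1", "+", 1L, 6L, 1L, 6L)
  ctxn <- site_context(gn, mn, 3, flank = 2)
  expect_true(is.na(motif_at(ctxn, "NXN")$motif))
})

test_that("coding effects follow the genetic code, including splice-spanning codons", {
  fa_seq <- "ATGGAAGAGTAA"  # Met-Glu-Glu-Stop
  g <- genome_sequence(list(c1 = fa_seq))
  m <- gene_model("t1", "c1", "+", 1L, 12L, 1L, 12L)
  # codon 2 is GAA (Glu) at positions 4-6
  expect_equal(coding_effect(m, g, 6, "A", "G"), "synonymous")  # GAA->GAG
  expect_equal(coding_effect(m, g, 4, "G", "C"), "missense")    # GAA->CAA
  expect_equal(coding_effect(m, g, 4, "G", "T"), "nonsense")    # GAA->TAA
  expect_error(coding_effect(m, g, 6, "G", "C"), "mismatch")

  # random spliced transcripts: agree with brute-force full-CDS translation
  translate_cds <- function(cds) {
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    paste(Biostrings::GENETIC_CODE[codons], collapse = "")
  }
  set.seed(11)
  for (rep in 1:10) {
    strand <- sample(c("+", "-"), 1)
    tf <- toy_spliced(strand, seed = rep)
    sc <- stackvip:::spliced_cds(tf$genome, tf$model)
    i <- sample(seq_along(sc$pos), 1)
    ref <- substring(sc$seq, i, i)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    eff <- coding_effect(tf$model, tf$genome, sc$pos[i], ref, alt)
    mut <- sc$seq
    substr(mut, i, i) <- alt
    aa_wt <- translate_cds(sc$seq)
    aa_mut <- translate_cds(mut)
    expected <- if (aa_wt == aa_mut) "synonymous"
    else if (grepl("\\*", substring(aa_mut, (i - 1) %/% 3 + 1,
                                    (i - 1) %/% 3 + 1))) "nonsense"
    else "missense"
    expect_equal(eff, expected)
  }
})

test_that("minus-strand contexts equal plus-strand contexts on the reverse complement", {
  set.seed(5)
  seq <- random_seq(60)
  g_fwd <- genome_sequence(list(c1 = seq))
  g_rev <- genome_sequence(list(c1 = revcomp(seq)))
  m_minus <- gene_model("t", "c1", "-", 1L, 60L, 1L, 60L)
  m_plus <- gene_model("t", "c1", "+", 1L, 60L, 1L, 60L)
  for (pos in c(10, 30, 51)) {
    ctx_m <- site_context(g_fwd, m_minus, pos, flank = 5)
    ctx_p <- site_context(g_rev, m_plus, 61 - pos, flank = 5)
    expect_equal(ctx_m$sense_ref, ctx_p$sense_ref)
    expect_equal(ctx_m$up_flank, ctx_p$up_flank)
    expect_equal(ctx_m$down_flank, ctx_p$down_flank)
  }
})
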