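test_that("region motif counting matches hand-enumerated windows", {
  # CDS covering the whole 9-mer: every position is "exon"
  g <- genome_sequence(list(c1 = "ACGTACGTA"))
  m <- list(full_cds_model(9L))
  xn <- count_region_motifs(g, m, "exon", "XN")
  expect_equal(xn$counts[c("AC", "CG", "GT", "TA")],
               c(AC = 2L, CG = 2L, GT = 2L, TA = 2L))
  expect_equal(xn$total, 8L)  # last position truncated

  nxn <- count_region_motifs(g, m, "exon", "NXN")
  # hand enumeration: positions 2..8 give ACG CGT GTA TAC ACG CGT GTA
  expect_equal(nxn$counts[c("ACG", "CGT", "GTA", "TAC")],
               c(ACG = 2L, CGT = 2L, GTA = 2L, TAC = 1L))
  expect_equal(nxn$total, 7L)

  # homopolymer: a single motif, count len - 1
  gh <- genome_sequence(list(c1 = "AAAAAA"))
  mh <- list(full_cds_model(6L))
  h <- count_region_motifs(gh, mh, "exon", "XN")
  expect_equal(h$counts, c(AA = 5L))
})

test_that("counting engine equals the brute-force window scan on random sequences", {
  set.seed(101)
  for (i in 1:20) {
    len <- sample(30:300, 1) %/% 3 * 3
    seq <- random_seq(len)
    strand <- sample(c("+", "-"), 1)
    g <- genome_sequence(list(c1 = seq))
    m <- list(full_cds_model(len, strand = strand))
    for (pattern in sample(MOTIF_PATTERNS, 4)) {
      engine <- count_region_motifs(g, m, "exon", pattern)
      oracle <- bf_counts(seq, seq_len(len), strand, pattern)
      expect_equal(engine$counts[order(names(engine$counts))],
                   oracle[order(names(oracle))])
    }
  }
})

test_that("SBS motif counting honors region and filters", {
  g <- genome_sequence(list(c1 = "ACGTACGTACGT"))
  # XN motifs: pos 2 -> CG, pos 6 -> CG, pos 10 -> CG, pos 1 -> AC
  rec <- make_records("c1", c(2L, 6L, 10L, 1L),
                      ref = c("C", "C", "C", "A"),
                      alt = c("T", "T", "A", "C"),
                      clinical = c("pathogenic", "benign", "other", "other"))
  all_counts <- count_sbs_motifs(rec, g, "exon", "XN")
  expect_equal(all_counts$counts[c("AC", "CG")], c(AC = 1L, CG = 3L))
  expect_equal(all_counts$total, 4L)

  cfil <- count_sbs_motifs(rec, g, "exon", "XN", list(wt_base = "C"))
  expect_equal(cfil$counts, c(CG = 3L))

  path <- count_sbs_motifs(rec, g, "exon", "XN",
                           list(clinical = c("pathogenic", "likely_pathogenic")))
  expect_equal(path$total, 1L)

  none <- count_sbs_motifs(rec, g, "intron", "XN")
  expect_equal(none$total, 0L)

  ts <- count_sbs_motifs(rec, g, "exon", "XN", list(class = "transition"))
  expect_equal(ts$total, 2L)  # two C->T records
})

test_that("normalized frequencies are ratios of relative frequencies", {
  g <- genome_sequence(list(c1 = "ACGTACGTA"))
  m <- list(full_cds_model(9L))
  bg <- count_region_motifs(g, m, "exon", "XN")  # AC,CG,GT,TA each 2/8
  rec <- make_records("c1", c(2L, 6L, 1L), ref = c("C", "C", "A"),
                      alt = c("T", "T", "C"))
  sc <- count_sbs_motifs(rec, g, "exon", "XN")   # CG:2, AC:1
  ft <- normalized_frequency(sc, bg)
  expect_equal(ft$norm_freq[ft$motif == "CG"], (2 / 3) / (2 / 8))
  expect_equal(ft$norm_freq[ft$motif == "AC"], (1 / 3) / (2 / 8))
  # motif with background support but no SBS stays at 0
  expect_equal(ft$norm_freq[ft$motif == "GT"], 0)
  # proportional counts give ratio 1 everywhere
  prop <- stackvip:::new_motif_counts("exon", "XN",
                                      c(AC = 4L, CG = 4L, GT = 4L, TA = 4L),
                                      16L, 0L)
  ft1 <- normalized_frequency(prop, bg)
  expect_equal(ft1$norm_freq, rep(1, 4))
})

test_that("region-frequency-weighted mean of normalized frequencies is 1", {
  set.seed(7)
  for (i in 1:10) {
    len <- (sample(60:200, 1) %/% 3) * 3
    g <- genome_sequence(list(c1 = random_seq(len)))
    strand <- sample(c("+", "-"), 1)
    m <- list(full_cds_model(len, strand = strand))
    bg <- count_region_motifs(g, m, "exon", "NXN")
    pos <- sample(2:(len - 1), 30, replace = TRUE)
    ref <- vapply(pos, function(p) substring(g$c1, p, p), character(1))
    rec <- make_records("c1", as.integer(pos), ref = ref, alt = "A",
                        strand = strand)
    rec <- rec[rec$ref != "A", , drop = FALSE]
    sc <- count_sbs_motifs(rec, g, "exon", "NXN")
    ft <- normalized_frequency(sc, bg)
    w <- ft$region_count / attr(ft, "region_total")
    expect_equal(sum(w * ft$norm_freq), 1, tolerance = 1e-9)
  }
})

test_that("transition/transversion ratio follows the definition", {
  rec <- data.frame(ref = c("C", "T", "A", "A"), alt = c("T", "C", "G", "T"))
  r <- ts_tv(rec)
  expect_equal(r$R, 3)
  expect_equal(r$n_transitions, 3L)
  expect_error(ts_tv(data.frame(ref = "A", alt = "G")), "undefined")
  expect_equal(ts_tv(data.frame(ref = c("A", "A"), alt = c("C", "T")))$R, 0)
})

test_that("pathogenic-minus-benign contrast matches hand arithmetic", {
  g <- genome_sequence(list(c1 = "ACGTACGTACGT"))
  # background with XN frequencies CG = 0.4, AC = 0.6
  bg <- stackvip:::new_motif_counts("exon", "XN", c(AC = 6L, CG = 4L), 10L, 0L)
  # pathogenic: CG x3 (pos 2,6,10), AC x1 (pos 1); benign: the reverse
  rec <- make_records("c1", c(2L, 6L, 10L, 1L, 2L, 1L, 5L, 9L),
                      ref = c("C", "C", "C", "A", "C", "A", "A", "A"),
                      alt = "T",
                      clinical = c(rep("pathogenic", 4),
                                   "benign", rep("likely_benign", 3)))
  rec$ref <- c("C", "C", "C", "A", "C", "A", "A", "A")
  dn <- delta_nu(rec, g, bg)
  # nu_path(CG) = 0.75/0.4, nu_benign(CG) = 0.25/0.4 -> delta = 1.25
  expect_equal(dn$delta_nu[dn$motif == "CG"], 1.25)
  expect_equal(dn$delta_nu[dn$motif == "AC"], (0.25 - 0.75) / 0.6)

  # identical group distributions: contrast vanishes
  rec2 <- rbind(rec, rec)
  rec2$clinical <- rep(c("pathogenic", "benign"), each = 8)
  class(rec2) <- c("sbs_records", "data.frame")
  dn2 <- delta_nu(rec2, g, bg)
  expect_equal(dn2$delta_nu, rep(0, nrow(dn2)))

  # swapping labels negates the contrast
  rec3 <- rec
  rec3$clinical <- c(rep("benign", 4), "pathogenic",
                     rep("likely_pathogenic", 3))
  dn3 <- delta_nu(rec3, g, bg)
  expect_equal(dn3$delta_nu, -dn$delta_nu)

  # an empty clinical group is an error reporting group sizes
  rec4 <- rec
  rec4$clinical <- "pathogenic"
  expect_error(delta_nu(rec4, g, bg), "benign n=0")
})

test_that("per-substitution contrast covers the 12 ordered types", {
  g <- genome_sequence(list(c1 = "ACGTACGT"))
  bg1 <- stackvip:::new_motif_counts("exon", "X", c(A = 5L, C = 5L), 10L, 0L)
  rec <- make_records("c1", c(2L, 6L, 1L, 5L),
                      ref = c("C", "C", "A", "A"), alt = c("T", "T", "G", "G"),
                      clinical = c("pathogenic", "pathogenic",
                                   "benign", "benign"))
  ps <- per_substitution_delta_nu(rec, bg1)
  expect_equal(nrow(ps), 12)
  # pathogenic all C->T, benign all A->G, base freq 0.5 each
  expect_equal(ps$delta_nu[ps$ref == "C" & ps$alt == "T"], 1 / 0.5)
  expect_equal(ps$delta_nu[ps$ref == "A" & ps$alt == "G"], -1 / 0.5)
  # equal type frequencies cancel
  rec2 <- make_records("c1", c(2L, 6L), ref = "C", alt = "T",
                       clinical = c("pathogenic", "benign"))
  ps2 <- per_substitution_delta_nu(rec2, bg1)
  expect_equal(ps2$delta_nu[ps2$ref == "C" & ps2$alt == "T"], 0)
  # |delta vIP| column carries the single-base changes
  expect_equal(ps$abs_delta_vip[ps$ref == "C" & ps$alt == "T"], 0.25)
})
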