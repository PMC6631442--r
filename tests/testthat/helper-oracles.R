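# Independent brute-force oracles and tiny fixture builders used across tests.

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Character-by-character motif builder: the slow reference implementation the
# vectorized counting engine is checked against.
bf_motif <- function(chars, p, strand, n5, n3) {
  len <- length(chars)
  if (strand == "+") {
    idx <- (p - n5):(p + n3)
    if (idx[1] < 1 || idx[length(idx)] > len) return(NA_character_)
    m <- chars[idx]
  } else {
    idx <- (p + n5):(p - n3)  # walk the minus strand 5'->3'
    if (min(idx) < 1 || max(idx) > len) return(NA_character_)
    m <- unname(COMP[chars[idx]])
  }
  if (any(m == "N")) return(NA_character_)
  paste(m, collapse = "")
}

# Brute-force motif counts over given positions of one contig.
bf_counts <- function(seq, positions, strand, pattern) {
  chars <- strsplit(seq, "")[[1]]
  n5 <- regexpr("X", pattern) - 1L
  n3 <- nchar(pattern) - n5 - 1L
  motifs <- vapply(positions, function(p) bf_motif(chars, p, strand, n5, n3),
                   character(1))
  motifs <- motifs[!is.na(motifs)]
  tab <- table(motifs)
  setNames(as.integer(tab), names(tab))
}

# Random DNA string.
random_seq <- function(n, gc = 0.5) {
  pr <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(pr), n, replace = TRUE, prob = pr), collapse = "")
}

# A transcript whose CDS covers the whole contig (length must be a multiple
# of 3): every position is "exon".
full_cds_model <- function(len, strand = "+", chrom = "c1", id = "tx1") {
  stopifnot(len %% 3 == 0)
  gene_model(id, chrom, strand, 1L, len, 1L, len)
}

# Toy spliced transcript used in several context tests:
# exons 1..50 and 101..150, CDS 11..141 (so utr5 = 1..10, utr3 = 142..150
# on the plus strand; spliced CDS 81 nt), inside a 160 bp contig.
toy_spliced <- function(strand = "+", seed = 42) {
  set.seed(seed)
  genome <- genome_sequence(list(c1 = random_seq(160)))
  model <- gene_model("toy", "c1", strand, c(1L, 101L), c(50L, 150L),
                      11L, 141L)
  list(genome = genome, model = model)
}

# Minimal sbs_records data.frame for counting tests (no annotation step).
make_records <- function(chrom, pos, ref, alt, strand = "+",
                         region = "exon", effect = NA_character_,
                         clinical = "other") {
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   strand = strand, transcript = "tx", region = region,
                   effect = effect, clinical = clinical,
                   stringsAsFactors = FALSE)
  class(df) <- c("sbs_records", "data.frame")
  df
}

# Direct textbook Pearson correlation (sum formula), independent of cor().
bf_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}
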