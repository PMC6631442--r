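---
title: "Base-stack ionization potentials and substitution spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Base-stack ionization potentials and substitution spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stackvip)
```

## The scientific question

Single base substitutions (SBSs) in the human genome are strongly shaped by
their local sequence context. One proposed physical mechanism is electron-hole
transport: oxidative stress can eject an electron from the DNA base stack, and
the resulting radical cation migrates along the stacked bases until it is
trapped at a site of low vertical ionization potential (vIP), where it can
trigger a substitution. Under this picture, base-stack motifs with low vIP
should mutate more often than their abundance predicts, and the effect should
extend beyond the substituted base into its flanking sequence.

`stackvip` implements the statistical side of that analysis as a reusable,
tested pipeline:

1. classify each SBS by gene region (coding exon, intron, 5'/3' UTR) and
   coding effect (synonymous / missense / nonsense), on the transcribed
   strand;
2. compute, per region, the **normalized SBS frequency** of each sequence
   motif — the motif's relative frequency among substitution sites divided by
   its relative frequency among all positions of the region, so that 1 means
   "mutated exactly as often as expected from region composition";
3. correlate those normalized frequencies with motif vIPs, linearly and with
   an inverse-polynomial regression, test significance with the Fisher
   z-transformation, and quantify the 5'–3' asymmetry of the flank
   dependence and the pathogenic-vs-benign frequency contrast.

Because the original variant sets (dbSNP/ClinVar extracts against GRCh38) are
large external downloads, the package ships a synthetic-data generator that
plants a vIP-coupled mutation process in a fully specified toy genome. Every
stage of the pipeline is therefore exercisable, and its statistical behavior
verifiable, without network access.

## vIP tables

Quantum-chemistry computation of vIPs is out of scope: vIPs enter as input
tables. Two containers exist:

* `base_vip_table` (`builtin_base_vips()`): the experimental single-base
  values (eV) — G 8.20, A 8.42, C 8.85, T 9.10. Guanine is the most easily
  oxidized base, thymine the least. Experimental values are the default for
  single-base quantities because computed single-base values are known to be
  slightly off while the ordering is what matters here.
* `stack_vip_table` (`load_stack_table()`, `stack_vip_table()`): motif →
  vIP for stacks of length 1–4, loaded from a TSV with columns `motif` and
  `vip_ev` (the layout of published per-motif supplementary sheets).
  Completeness at a claimed length is enforced, as are the ACGT alphabet and
  numeric values.

Motifs longer than the stored quadruplets are composed on the fly
(`motif_vip()`): a quintuplet is the mean of its two overlapping quadruplet
windows, a sextuplet the mean of its three, and in general the mean over all
contiguous quadruplet windows. The generalization beyond length 6 is the
natural extension of the same rule; composed values always lie between the
minimum and maximum of their window vIPs. `additive_vip()` provides the
stack-free estimator (mean of constituent single-base vIPs), useful as a
baseline, and `delta_vip()` the single-base change |ΔvIP| upon substitution.

## Sequence context and gene regions

Coordinates are 1-based inclusive throughout (the GFF3/Bioconductor
convention); BED input is converted on read. A `gene_model` carries exons, a
genomic CDS span, and derived CDS/intron/UTR interval sets; models whose CDS
ends fall outside exons or whose spliced CDS length is not a multiple of 3
are rejected with a warning rather than silently mis-translated.

Motifs are always expressed on the **transcribed (sense) strand**: the
5'/3' language of flank patterns presupposes transcript orientation, so for
minus-strand genes the reference base and both flanks are
reverse-complemented and swapped. Flanking bases are taken from the
contiguous genomic sequence and may cross exon/intron boundaries — region
membership is decided by the substituted position alone. Motif patterns are
written with `X` for the focal base and `N` for flanks (`XN`, `NXN`,
`NNXNN`, ...); windows containing an ambiguous base (N) are skipped in both
numerators and denominators, since no vIP is defined for them.

Exonic substitutions are classified with the standard genetic code on the
spliced CDS, so codons spanning splice junctions are handled. Stop-gains are
reported as "nonsense" and excluded from the missense class by default
(configurable via `nonsense_as_missense`), since mixing them into missense
would conflate two different selective regimes. When transcripts overlap,
each variant is deterministically assigned to one transcript: longest
spliced CDS first, ties broken lexicographically by id. This is a
convention, not an inference about the underlying biology.

## Normalization and its invariant

For motif $m$ in region $R$, with $s_m$ substitution-site occurrences out of
$S$ and $r_m$ background occurrences out of $R_{tot}$:

$$\nu(m) = \frac{s_m / S}{r_m / R_{tot}}.$$

Motifs with $r_m = 0$ have no defined normalized frequency and are omitted
(and reported); motifs with background support but no observed SBS are kept
at 0 so that depleted motifs are visible. The construction implies an exact
identity — the background-frequency-weighted mean of $\nu$ over the motif
universe is 1 — which the pipeline and its tests verify to $10^{-9}$ on
every run; it is the strongest cheap guard against numerator/denominator
mismatches (e.g. strand conventions diverging between the two counts).

Denominator counting uses the same sense-strand, boundary-crossing motif
extraction as the numerator, one count per position per assigned transcript.

## Statistics

* **Linear correlation**: Pearson's r between motif vIP and normalized
  frequency, one unweighted point per motif (matching the one-point-per-motif
  scatter convention). Significance via the Fisher z-transformation:
  $z = \operatorname{atanh}(r)\sqrt{n-3}$ against the standard normal,
  two-sided. No multiple-testing correction is applied; raw p-values are
  exposed so users can correct externally.
* **Non-linear correlation**: the inverse-polynomial model
  $f(X) = a + bX^{-1} + cX^{-2} + dX^{-3}$ is linear in its coefficients and
  is fitted by QR least squares (SVD minimum-norm with a warning if the
  basis is rank-deficient, e.g. duplicated x with fewer than four distinct
  values). The non-linear coefficient is the Pearson correlation between
  fitted values and the response; it equals 1 to $10^{-9}$ whenever the data
  lie exactly in the model space, which the tests assert.
* **Slopes**: ordinary least squares of normalized frequency on vIP
  (units: dimensionless frequency per eV).
* **Asymmetry**: for motif lengths 2–4, the difference
  $r_{XN\ldots N} - r_{N\ldots NX}$ between the correlation with the 3'-flank
  motifs and with the mirrored 5'-flank motifs, tested with the two-sample
  Fisher z statistic
  $(\operatorname{atanh} r_1 - \operatorname{atanh} r_2)/\sqrt{1/(n_1-3)+1/(n_2-3)}$.
  A negative difference means the 3' flank is the more informative side, the
  direction expected if charge migrates preferentially 5'→3'.
* **Pathogenicity contrasts**: pathogenic (+ likely pathogenic) and benign
  (+ likely benign) records are normalized separately against the same
  region background and differenced per motif
  ($\Delta\nu = \nu_{path} - \nu_{benign}$); records of uncertain or other
  significance are excluded. The per-group-then-difference order is a
  deliberate choice (the difference-then-normalize alternative gives the
  same values here because both groups share one background, but would
  diverge if group-specific backgrounds were ever used). Per ordered
  substitution type, $\Delta\nu$ is paired with the single-base |ΔvIP| for
  the 12-point correlation.

Two-sided tests are used throughout; sidedness is a convention choice, made
explicit rather than inherited silently.

## The synthetic-data generator

`synth_config()` fixes the study conditions; its defaults describe a
dbSNP/ClinVar-like gene-region SBS set:

| parameter | default | meaning |
|---|---|---|
| `region_mix` | 0.75 / 0.10 / 0.03 / 0.12 | share of SBSs in exon / intron / 5'-UTR / 3'-UTR |
| `label_fraction` | 1/3 | fraction of records with a clinical label |
| `ts_bias` (κ) | 4 | transition weight vs 1 per transversion; Ts/Tv = κ/2 = 2 |
| `beta` | 0.5 eV⁻¹ | coupling of motif vIP to log mutation rate |
| `k`, `rate_pattern` | 3, `NXN` | motif whose vIP drives the site rate |
| `n_sbs` | 50,000 | substitutions drawn (without replacement) |
| `n_genes` | 100 | gives a ≈1 Mb genome with the default geometry |
| `gc_content` | 0.45 | between genome-wide (~0.40) and exome (~0.50–0.55) GC |
| `alpha0, alpha1, alpha2` | −0.5, 2, 2 | logistic pathogenicity coefficients |

The generator builds (i) an i.i.d. genome with non-overlapping multi-exon
genes (in-frame CDS, UTRs, random strands), written as standard FASTA/GFF3;
(ii) a synthetic stack-vIP table equal to the additive single-base mean
lowered by `gg_bonus` (0.05 eV) per GpG step plus ±0.01 eV uniform noise, so
G-runs are guaranteed to be the low-vIP motifs of each length, as base
stacking predicts; (iii) an SBS set in which sites are drawn with
probability ∝ exp(−β · vIP(motif)) via exponential-race weighted sampling
without replacement, alternative bases with transition weight κ, and
clinical labels from a logistic model in |ΔvIP| and (centered) motif vIP —
pathogenic substitutions are thereby enriched in low-vIP contexts and in
large-|ΔvIP| changes, qualitatively matching the real-data observations the
statistics are designed to detect. All randomness flows from one integer
seed (sub-streams at `seed`, `seed+1`, `seed+2` for genome, vIP table and
variants); a ground-truth JSON sidecar echoes every generative parameter.

One behavior of the synthetic data is worth flagging: the generator plants
one β for *all* exonic sites, but the synonymous analysis group keeps only
substitutions classified as synonymous downstream, and synonymous-capable
sites (largely degenerate third codon positions) have a biased motif
composition relative to the all-exon background used in the denominator.
The synonymous subgroup's correlation therefore mixes the planted coupling
with that compositional bias and is much weaker (often slightly positive)
than the pooled-exon correlation; recovery checks accordingly use the
pooled exon group. The same numerator/denominator structure exists in real
synonymous-vs-region normalizations.

What the generator deliberately does **not** emulate: deamination chemistry
and CpG methylation hotspots, APOBEC/UV-style signatures, selection,
recurrent mutation at one site, overlapping genes, and non-i.i.d. base
composition. Passing tests therefore demonstrate that the pipeline's
statistics recover a planted vIP coupling under clean conditions — not that
the biological claim holds in real data.

## Verification strategy and problem sizes

The test suite checks, among others:

* counting-engine equivalence against an independent character-by-character
  brute-force scan on 100 random sequences (up to 2 kb, both strands, all
  supported patterns);
* exact recovery of inverse-polynomial model members and the weighted-mean-1
  identity to $10^{-9}$;
* parameter recovery at study scale — β = 0.5 eV⁻¹, triplet motifs, ≈1 Mb
  genome, 50,000 SBSs — where the exon-region triplet correlation must be
  negative with p < 0.001 in at least 19 of 20 seeds;
* null calibration — β = 0, 200 replicates of 3,000 SBSs on a fixed ≈600 kb
  genome — where the Fisher z significance rate at α = 0.05 must lie in
  0.05 ± 0.02. Replicates use a small fraction (≈3%) of eligible sites
  because heavy without-replacement depletion deflates the multinomial
  variability the test assumes and makes it conservative;
* planted asymmetry — when site rates depend on the 3'-flank doublet `XN`,
  the recovered r(XN) is more negative than r(NX) in at least 80% of 20
  seeds.

These sizes were chosen as the smallest that make the planted effects
unambiguous; the recovery runs take a few seconds per seed on one core.

## Known limitations

* Normalized frequencies are ratio estimators; for rare motifs (sextuplets
  in small regions) they are noisy and the per-motif points are
  heteroskedastic, which the unweighted correlation ignores — exactly as in
  the original analysis convention the package mirrors.
* The Fisher z test treats motifs as independent observations; the
  weighted-mean-1 constraint induces weak negative dependence, making the
  test very slightly conservative for small motif universes.
* vIP composition for motifs longer than 4 assumes window-mean additivity;
  it cannot capture longer-range stacking effects.
* The XLSX workbook layout for vIP tables is supported through its TSV
  equivalent (`motif`, `vip_ev` columns per sheet); spreadsheets must be
  exported to TSV before ingestion.
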