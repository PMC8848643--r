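---
title: "Methods: allele-aware TF motif disruption analysis with regsnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-aware TF motif disruption analysis with regsnp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Genome-wide association studies report index SNPs, not causal variants:
extensive linkage disequilibrium (LD) means dozens to thousands of variants
tag the same signal, and most risk loci are non-coding. A standard
functional-genomics strategy for prioritizing candidates is to ask which
variants sit inside a transcription factor (TF) binding site and change its
sequence enough to alter binding. `regsnp` implements that strategy end to
end: LD expansion of index SNPs, motif discovery from ChIP-Seq peak
sequences, allele-aware motif scanning with exact match p-values, a
disruption call per variant and TF, genomic-context annotation,
allele-specific expression (ASE) testing, and cis-eQTL integration across
datasets. A synthetic-data module generates every input with recorded ground
truth, so the whole pipeline is testable without external downloads.

# LD expansion

Proxies are collected for each index SNP within a 1 Mb window (`window_kb =
1000`) at a strict r² cutoff (`r2_min = 0.6`, "exceeds" semantics: `r2 >
0.6`). These defaults mirror common practice for tagging a GWAS signal while
keeping borderline functional candidates.

r² is computed from two-site haplotype frequencies, `r² = D² / (pA pa pB
pb)` with `D = pAB − pA pB`. On unphased genotypes the frequencies are
maximum-likelihood estimates from the classic two-locus EM: all genotype
combinations except the double heterozygote determine their haplotypes; the
double heterozygotes are split between cis and trans configurations by their
expected frequencies. Because the two-locus likelihood can carry a second
stationary point, the EM restarts from linkage equilibrium and from both
maximal-|D| corners and keeps the fixed point with the best observed-data
likelihood; convergence is declared at a maximum frequency change below
1e-8 (cap 1000 iterations). When the input is phased — as reference-panel
genotypes are — `expand_index_snps()` counts haplotypes directly
(`method = "auto"`), which is exact; the EM remains the unphased path and a
genotype-correlation r² is available as a cross-check. Missing genotypes are
removed pairwise per site pair; this is the simplest defensible choice and
is surfaced here because LD software conventions differ.

# Motif model

## PWM construction and scanning

A position frequency matrix (PFM) holds per-column base counts; the position
weight matrix (PWM) is its log-odds transform against a background model,

```
log_odds[b, i] = log2( (counts[b, i] + pseudocount * bg[b]) /
                       (n_sites + pseudocount) / bg[b] )
```

with `pseudocount = 0.1` distributed by background frequency — small enough
to barely perturb informative columns, large enough to avoid infinite
entries. The scanning background defaults to uniform (0.25 each);
discovery estimates a 0-order background from its input sequences.

One representational choice matters for correctness: log-odds entries are
snapped to a fixed score grid whose step is the achievable score range
divided by `n_bins = 10000` (integer scoring, as FIMO-class scanners use
internally). Every window score — the log-likelihood ratio (LLR) of the
window under motif versus background, summed over columns — is then an exact
multiple of the grid step, and the null distribution of that score under
i.i.d. background bases is computed *exactly* by convolving the per-column
integer score distributions. The match p-value `P(score ≥ s)` is therefore
an exact tail probability of the scores the scanner actually reports, not a
binned approximation of them; the test suite checks it against brute-force
enumeration of all `4^w` windows. The grid coarsens reported LLRs by at most
half a step per column (about 0.004 bits per column at default resolution),
far below any decision threshold in the pipeline. Windows containing an N
score `-Inf` and can never match.

## ZOOPS-EM discovery

Motifs are learned from the summit ± 20 bp sequences (41 bp) of the top 500
peaks ranked by height; the summit is taken as the interval midpoint because
the pipeline starts from BED intervals, which do not carry subpeak calls.
Discovery runs EM under a ZOOPS model — each sequence holds zero or one
site, at a uniform offset, with per-sequence site probability λ — over
candidate widths 6–20 (`-nmotifs 5 -minw 6 -maxw 20` style defaults). Per
width, 20 restarts are seeded from the most background-enriched w-mers, each
refined for two EM iterations, and the best seed is run to convergence
(relative tolerance 1e-6 on the expected log-likelihood, cap 200
iterations). Width selection maximizes a BIC-penalized log-likelihood ratio
against the background-only model (`LLR − ½(3w+1)·log n`), which stops the
objective from drifting upward with width on noise. After a motif is
reported its sites are probabilistically erased — positions are
down-weighted by their posterior site coverage — and discovery repeats.
Everything is deterministic given the seed.

## Database matching

Discovered motifs are matched to a PWM database by the maximum, over
relative offsets with at least 4 aligned columns and both orientations, of
the mean per-column Pearson correlation between frequency columns. Ties
break toward the smaller |offset|, forward orientation, then database order.
No published similarity statistic is canonical for this step; per-column
Pearson is the simplest widely used choice (it is the core of Tomtom-style
comparisons) and is exercised against planted noisy copies in the tests.

# Allelic scanning and the disruption call

For each candidate variant the two allelic sequences are built as
flank + allele + flank with `flank_bp = 20` (41 bp for SNVs; indel alleles
change the length, and the variant span on each allelic sequence is the full
replaced segment). The reference allele is verified against the genome.
Both strands of both sequences are scanned; only windows overlapping the
variant span by at least one base participate in calling (a match elsewhere
in the flank says nothing about the variant), and the minimum-p match per
allele is kept regardless of threshold, with ties broken by higher LLR, then
leftmost offset, then + strand.

The default call (`one_pass`) flags a variant as binding-disrupting when
exactly one allele's best overlapping match is significant at `p_threshold =
1e-3`: `loss` when the reference allele passes, `gain` when the alternate
does. Requiring the other allele to *fail* encodes an allelic contrast, the
natural reading of paired allelic motif logos; because one could also read
the threshold rule as "any overlapping match on either allele", a `delta`
mode is provided (either allele passes and `|ΔLLR| > delta_min`, with ΔLLR
evaluated at the better allele's window position, mapped across indel length
changes). Neither mode is privileged by the tests beyond the defaults.

Summaries mirror the catalogue views one reports for such a screen: SNP
counts per TF, TF multiplicity per SNP, and a symmetric TF × TF
co-disruption matrix.

# Annotation

A built-in classifier assigns each variant (by the position of its first
reference base) one of `exonic, UTR5, UTR3, intronic, upstream, downstream,
intergenic` against gene models from GTF, with precedence `exonic > UTR >
intronic > upstream/downstream > intergenic` across all transcripts, and
strand-aware upstream/downstream windows of `flank_bp = 1000` (annotation
tools differ by version here; 1 kb is fixed and exposed). Exonic hits in
transcripts without a CDS are exonic with a `noncoding` flag rather than a
separate category.

# ASE testing

At a heterozygous transcribed SNP, allelic read counts are compared with an
expected null ratio by an exact binomial test; SNPs under `min_reads = 8`
total reads are filtered rather than tested. The two-sided p-value follows
the minimum-likelihood convention (sum the probabilities of all outcomes no
more likely than the observed one), the standard exact convention and the
one `stats::binom.test` implements; the suite verifies it against an
independent closed-form tail sum for every outcome up to depth 30. The null
ratio defaults to 0.5 and is accepted per SNP, because reference-bias
adjustment belongs to the upstream allele-counting pipeline and its formula
is not re-derived here. Note the test is conservative at discrete depths:
its exact size at α = 0.05 sits below 0.05, and the calibration test
compares the flagged fraction against the analytic size under the simulated
depth distribution, not against nominal α.

# eQTL integration and case-control expression

Association is ordinary least squares of expression on allele dosage (plus
optional covariates) with the usual two-sided t test — a deliberate single
stand-in for the heterogeneous consortium pipelines behind public brain eQTL
resources, since this module's role is integration, not re-deriving four
pipelines. Cross-dataset support counts, per SNP, the datasets with any gene
association at uncorrected p < 0.05, and reports nested tiers (≥1, ≥2, ≥3,
all datasets). Case-control differential expression of candidate target
genes is a per-gene Welch t test on `log2(x + 1)` with Benjamini–Hochberg
q-values at `alpha_q = 0.05`, again a declared stand-in for the source
study's statistics.

# The synthetic-data module

The generators define the study conditions under which every pipeline
property is measured:

* **Haplotype blocks** use copy-with-recombination: a proxy copies the index
  haplotype with probability `sqrt(target r²)`, else redraws from the index
  allele frequency, so haplotype correlation is `sqrt(r²)` in expectation;
  the best of up to 50 draws is kept, and realized r² (recorded as truth) is
  within ±0.05 of target at n ≥ 500, typically within 0.005. Diploids are
  formed by pairing consecutive haplotypes, so the output is phased; this
  controls pairwise r² directly, which is what the pipeline needs — it makes
  no attempt at population history, recombination maps, or realistic allele
  frequency spectra.
* **Peak sequences** plant one motif-sampled site per sequence with
  probability `zoops_prob = 0.9` at a uniform offset in 41 bp of i.i.d.
  background — exactly the ZOOPS generative model, which is why recovery is
  a clean test of the EM; real peaks have positional bias toward summits,
  flanking sequence composition, and co-occurring motifs that this does not
  emulate.
* **Disruption benchmarks** write a motif consensus into the genome so the
  variant coincides with the motif's most informative column; the reference
  allele is the consensus base and the alternate is the lowest-scoring base
  in that column (direction `loss`; weaker columns are selectable for
  sensitivity curves). The default planted motif is a width-7 core with
  consensus probability 0.88 (≈1.28 bits per column). The width matters: a
  single-base change can only push a site across a fixed significance
  threshold when the motif is short, because the exact null tail above a
  one-column-knockout score is about `(3w + 4)/4^w`. Biologically this is
  the regime of interest — disruption happens in short core recognition
  sequences — and at width 7 the consensus sits at p ≈ 6e-5 while the
  knocked-out allele sits just above 1e-3. Null variants are random
  background with a random alternate allele; nothing forbids a chance motif
  there, which is what the false-positive rate measures.
* **ASE counts** are binomial draws at Poisson depths; **eQTL datasets** are
  `beta·dosage + Normal(0, σ)`. For the end-to-end integration fixture,
  `simulate_eqtl_block()` can orthogonalize null SNP-gene pairs (noise
  residualized against the dosage matrix, effects using the dosage component
  orthogonal to the other SNPs), making every unplanted marginal coefficient
  exactly zero, so the planted support tiers are recovered exactly — an
  integration-consistency device; the honestly noisy generator (and its
  uniform null p-values) is what the calibration tests use.

Passing tests on these conditions demonstrates the algorithms are correct
under their own model assumptions; they do not certify performance on real
ChIP-Seq, real LD structure, or real expression data.

# Numerical and problem-size choices

* Score grid 10000 bins per PWM; p-values exact on the grid (see above).
* EM tolerances: LD 1e-8 (frequencies), ZOOPS 1e-6 relative (objective).
* Disruption benchmark 200 planted / 2000 null variants; motif recovery 500
  sequences × 5 seeds over the full width range 6–20; ASE calibration
  10,000 null SNPs; eQTL recovery 500 simulations at n = 400 and a
  1000-simulation null. These sizes give stable estimates (Monte Carlo
  envelopes are computed exactly where asserted) while keeping the default
  test run in minutes.
* Ties everywhere break deterministically (documented per function), and all
  generators are deterministic under their seed, so pipeline reruns are
  byte-identical.

# Known limitations

* Scanning is per-variant: nearby variants on the same haplotype are not
  scanned jointly.
* The 0-order background model ignores dinucleotide composition; no
  chromatin-accessibility or footprint weighting is applied.
* The ASE null ratio must be supplied when reference bias matters.
* The eQTL model is a single additive OLS; mixed models, latent-factor
  correction, colocalization and trans effects are out of scope.
* Discovery implements ZOOPS only (no OOPS/ANR), with a 0-order background
  and no E-value calibration of reported motifs.
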