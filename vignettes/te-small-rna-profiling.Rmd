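---
title: "Profiling TE-derived small RNAs across Drosophila strains: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling TE-derived small RNAs across Drosophila strains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaprofiler)
```

# The analysis in one paragraph

Ovarian small RNAs silence transposable elements (TEs) through the piRNA
pathway, and differences between strains in their TE-piRNA pools underlie
hybrid dysgenesis: a strain whose eggs lack piRNAs against a paternally
transmitted TE family cannot silence it in the progeny's germline.
`srnaprofiler` implements the comparative analysis used to dissect this
system: small-RNA reads are trimmed, filtered and depleted of ncRNA
contaminants, mapped to TE consensus sequences, quantified per family by
size class (21-nt siRNAs, 23–29-nt piRNAs) in counts per million (CPM),
and compared across strains for ≥10-fold asymmetries. Two signatures
characterize each family's piRNA population: the ping-pong signature (the
hallmark of germline secondary piRNA biogenesis) and the divergence
profile (whether piRNAs derive from modern, active copies or from degraded
ancestral ones).

# Pipeline stages and their parameters

## Preprocessing

Three filters run in order, each tallied in a monotone stage ledger:

1. **Adapter trimming.** The leftmost position where a prefix of the 3'
   adapter matches the read through to its end, requiring ≥ 5 nt of
   overlap and tolerating ≤ 1 mismatch. Reads without an adapter hit are
   discarded by default (`keep_untrimmed = TRUE` retains them); empty
   inserts are always discarded. The default adapter is the TruSeq
   small-RNA 3' adapter prefix (`TGGAATTCTCGGGTGCCAAGG`) — the protocol
   implied for such libraries — and is overridable everywhere.
2. **Length and quality.** Inserts must be *strictly* longer than 18 nt
   (a literal reading of a "> 18 nt" rule: the minimum retained length is
   19 nt), and at least 80% of bases must have Phred ≥ 20. Both
   comparisons are inclusive at the boundary, so a 20-nt read with exactly
   16 bases at Q20 passes.
3. **ncRNA subtraction.** A read matching any rRNA/tRNA/snRNA/miRNA
   reference exactly — as a perfect-match substring on either strand — is
   removed. Perfect match was chosen for consistency with the
   perfect-match stringency of genome mapping in this kind of analysis;
   it is deterministic and errs on the side of keeping reads.

## Mapping

Reads are aligned to every consensus on both strands by sliding Hamming
comparison (no indels), implemented in C++ and verified in the test suite
against an independent brute-force scan. Contract details:

* **Best stratum only.** With `max_mismatches` ∈ {0..3}, all placements at
  the read's minimal mismatch count `m*` are reported if `m* ≤
  max_mismatches`. Perfect-match mode (`max_mismatches = 0`) is the
  default for expression profiles; the 0–3 strata feed the divergence
  analysis.
* **Fractional weights.** A read with k best-stratum hits contributes 1/k
  to each, conserving total read mass across multi-mapping TE families.
  Each family profile therefore counts each read at most once in total.
* **Coordinates.** 0-based; for antisense hits `five_prime_pos` is the
  plus-strand coordinate of the read's 5' end (the right edge of the
  window). This convention is what makes the ping-pong overlap arithmetic
  below uniform across strands.
* **N bases** always count as mismatches, in read or reference —
  conservative and deterministic.

No k-mer seeding or heuristics are used: at consensus-library scale
(tens to hundreds of kb) the exact scan is fast enough, and any
implementation is acceptable only if it reproduces the brute-force oracle
exactly, which the exhaustive scan does by construction.

## Quantification

Size classes follow the field's boundaries: exactly 21 nt → siRNA, 23–29
nt → piRNA, all else → "other" (excluded from both totals; 22 nt is
deliberately in neither class). CPM uses, per sample, the number of
retained reads that map anywhere in the analysis references as the
denominator — the most common reading of library-level normalization when
no explicit denominator is stated; it is configurable. The low-expression
floor discards a (sample, feature, class) whose strand-summed CPM is below
25; a feature at exactly 25 CPM is retained. Floored entries are marked
*absent*, distinct from zero, so that downstream fold-change logic can
skip features absent on both sides and zero-fill one-sided absences. The
floor is applied per element (strand-summed), not per strand, reading
"per transposon" as per-element.

## Ping-pong signature

For one feature's piRNAs, every (sense, antisense) pair of 5' ends
contributes `weight_sense × weight_antisense` to the overlap bin
`d = a − s + 1` (both coordinates plus-strand), for `d` in 1..20. The
ping-pong signal is bin 10. The z-score compares bin 10 against the mean
and SD of the other 19 bins; a zero-variance background (e.g. no pairs at
all) is flagged degenerate and reported as `NA`, never as infinity.
Because "number of ping-pong pairs" is ambiguous between weighting
schemes, both are reported: the weighted pair mass at overlap 10 and the
count of distinct (sense 5', antisense 5') position pairs. The 1U bias is
the weighted fraction of antisense piRNA reads beginning with T (U in
RNA), the 10A bias the fraction of sense piRNA reads with A at position
10; these are the nucleotide hallmarks of the slicer-guided ping-pong
cycle. The aggregation is position-indexed (masses summed per unique 5'
position before pairing) for speed; the test suite checks it against the
literal all-pairs enumeration.

## Divergence profile and coverage

Each read is assigned its minimal achievable Hamming distance to the
feature consensus over all windows and both strands: stratum 0, 1, 2, 3 or
`unmapped_at_3`. The profile is split by orientation (strand of the
minimal-distance placement) and reports `fraction_perfect` (stratum 0) and
`fraction_modern` (strata 0–3) — the report layer, not the profiler,
decides which cut-off means "modern active copy", since the full stratum
distribution is what the data support. Indels are not modeled; distances
are Hamming-only. Coverage tracks accumulate alignment weight at every
covered position, sense and antisense separately, scaled per million
mapped reads.

## Strain comparison

Fold changes use strand-summed, class-restricted CPM with a pseudocount:
`fold = (cpm_a + ε)/(cpm_b + ε)`, ε = 1 CPM by default, keeping folds
finite when one side is floored or zero. Calls are inclusive:
`fold ≥ 10` → higher in a, `fold ≤ 0.1` → higher in b, so a feature
exactly on the 10-fold line counts as exceeding it. Venn-style
intersections enumerate all `2^k − 1` exclusive regions of the called
sets. Spearman correlation (average ranks for ties, via `stats::cor`) is
computed over features expressed in at least one of the two samples, with
floored values treated as 0; scatter output uses `log10(CPM + ε)`, but
ranks make the correlation itself ε-insensitive for positive data.
Constant vectors yield a flagged degenerate result.

## qPCR and ChIP-qPCR calculators

Relative expression: `ΔCt = target − reference (rp49)` per record,
`ΔΔCt = ΔCt_sample − ΔCt_calibrator`, fold `= 2^−ΔΔCt`, with amplification
efficiency fixed at 2 (the assumption built into the formula). ChIP
percent-input: the input Ct is first corrected for the input dilution,
`adjusted = input_ct − log2(1/input_fraction)`, then
`percent_input = 100 × 2^(adjusted − ip_ct)`; enrichment is the target's
percent-input over the control locus (rp49). Replicate vectors return the
mean and the standard error of the mean. The input fraction is a required
user parameter — it cannot be inferred from Ct values.

# The synthetic-data generator

`simulate_strain_reads()` emulates the statistical structure the analysis
assumes, with a per-read truth table (feature, strand, 5' position,
planted mismatches, ping-pong flag, contaminant flag):

* **Composition.** TE-derived reads are drawn per the profile's abundance
  map, size distribution (defaults span 21 and 23–29 nt with a
  piRNA-heavy mix), and sense fraction. A configurable fraction of reads
  are exact substrings of a bundled contaminant set — 20 synthetic
  stand-ins for rRNA/tRNA/snRNA/miRNA shipped as
  `ncrna_synthetic.fasta`; no external database is used or implied. An
  optional "junk" fraction is emitted with qualities guaranteed to fail
  the 80%-at-Q20 filter (it defaults to 0).
* **Ping-pong pairs** are built on the same consensus with sense 5' at
  `s` and antisense 5' at `s + 9`, i.e. overlap exactly 10. Partner sense
  reads are drawn from the sense pool rather than added on top, so the
  realized strand balance matches `sense_fraction`.
* **1U/10A biases by placement, not mutation.** Antisense 5' ends are
  sampled, with probability 0.8, from consensus positions carrying `A`
  (so the read starts with T/U). For a ping-pong pair this single choice
  simultaneously creates the partner's 10A bias, because position 10 of
  the sense partner is the complement of the antisense read's first base
  — as in the real biology. Implementing the bias as base substitution
  would have corrupted the planted mismatch counts in the truth table.
* **Divergence.** Planted substitutions per the divergence mix; the
  `"diverged"` category plants 7 substitutions, which at read lengths
  21–29 against i.i.d. consensus sequence exceeds the 3-mismatch mapping
  ceiling with overwhelming probability.
* **Qualities** are Phred+33; non-junk bases are Q30 with a 5% sprinkling
  of Q10, keeping reads comfortably above the quality filter.
* **Determinism.** A fixed (library, profile) pair reproduces
  byte-identical FASTQ and truth output; the generator saves and restores
  the caller's RNG state.

What the simulator does *not* emulate: genomic insertion context (reads
come from consensuses, not from a genome assembly), indels and
position-dependent sequencing error, ligation biases, and realistic ncRNA
sequence families. Consequently, passing truth-recovery tests demonstrates
that the pipeline's operators are correct on data with the assumed
structure — not that the biological conclusions from any real library
would be reproduced.

# Problem sizes and numerical choices

The validation studies are scaled down from real library depths (millions
of reads) to desk scale. The planted-asymmetry study uses 62 TE families
(12 planted ≥ 20-fold piRNA deficits per M-like strain against 50
background families, 10 deficits shared between the two M-like strains)
at 40,000 reads per strain. That depth is a power choice: a 30-fold
abundance deficit on a family in the upper half of a log-normal abundance
distribution leaves an expected M-strain piRNA count high enough that
Poisson noise cannot push the observed fold change below the 10-fold call
line, so the planted sets are recovered exactly rather than
probabilistically. Deficit families are drawn from the upper 40% of the
abundance distribution, matching the fact that dysgenesis-implicated TE
families are well expressed in inducer strains. Ping-pong recovery uses
5,000 piRNA-only reads on a 1-kb element (planted pairing fraction 0.5);
the null condition uses uniform placement with the 1U placement bias
disabled, since the bias itself concentrates 5' ends non-uniformly.
Divergence recovery plants 10% perfect-match / 90% diverged antisense
reads at n = 5,000, where the binomial standard error (~0.4 points) sits
well inside the ±3-point check.

Numerical details worth knowing:

* Count tables serialize numbers with 7 significant digits, so a
  write→read round trip agrees within 1e-6 relative.
* The quality-fraction comparison subtracts 1e-12 before testing ≥, so
  exact-boundary reads (16/20 bases at Q20) are kept regardless of binary
  representation.
* The ping-pong z-score background excludes only bin 10; this follows the
  standard practice of the technique and is configurable in principle via
  the histogram itself.
* Ties in the mapper are impossible to break "correctly": all
  best-stratum placements are reported, deterministically ordered by
  (read, feature, strand, position).
* The pipeline's outputs are byte-identical across re-runs on identical
  inputs; the manifest logs the package version, thresholds, and a config
  hash.

# Known limitations

* Consensus-level mapping cannot attribute reads to individual genomic
  insertions; "modern vs ancestral copy" attribution is by sequence
  similarity only.
* Hamming-only alignment misses piRNAs whose divergence from the
  consensus includes indels; such reads inflate the `unmapped_at_3`
  stratum.
* CPM with a library-level denominator is the only normalization offered;
  no between-sample scaling factors (TMM/median-of-ratios) are computed,
  as cross-strain comparisons in this analysis are fold-change based.
* The ping-pong z-score treats the 19 background bins as exchangeable;
  with very few distinct piRNA 5' positions the background SD is unstable
  (the degenerate flag covers the extreme case only).
* No formal differential-expression statistics are attached to asymmetry
  calls; the ≥ 10-fold rule is a descriptive threshold, as in the
  analyses this package reproduces.
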