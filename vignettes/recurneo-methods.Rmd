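---
title: "Methods: identifying and ranking recurrent neo-epitope candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and ranking recurrent neo-epitope candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recurneo)
```

## Scope and model

`recurneo` takes cohort-level somatic variant tables (the tab-delimited MAF
dialect used by GDC/TCGA), identifies amino-acid exchanges that recur
within cancer-entity cohorts, derives MHC class I neo-epitope candidates
from them, and ranks the candidates by the expected number of newly
diagnosed patients who would carry both the mutation and a presenting HLA
allele. The intended use is triage: an objective ordering of reusable
("off-the-shelf") T-cell therapy targets for wet-lab validation, not a
claim of immunogenicity. The package also quantifies how patient coverage
degrades when most candidates turn out to be ineffective, and screens
variant calls for homopolymer-context sequencing artifacts.

This vignette explains each stage's model, its tunable parameters and
defaults, the numerical conventions, what the synthetic-data generator does
and does not emulate, and the design decisions made where more than one
reading was defensible.

## Variant filtering

A record survives only if it passes, in order:

1. **Read stage** — all required MAF columns present and non-empty; rows
   with a missing field are rejected with a reason (an empty
   `Transcript_ID` is rejected as "no valid ENSEMBL transcript ID"), never
   imputed. A *missing column* is a hard error; a missing *value* is a
   per-row rejection.
2. **Consistency** — `Mutation_Status` equals "somatic" case-insensitively
   (the one deliberately case-insensitive comparison; all other fields are
   matched exactly), `t_depth = t_ref_count + t_alt_count`, and both
   alleles are single A/C/G/T bases. A depth mismatch is rejected, not
   repaired: it indicates an upstream accounting problem we must not guess
   around.
3. **Missense selection** — `Variant_Type == "SNP"`,
   `Variant_Classification == "Missense_Mutation"`, and `HGVSp_Short`
   parses as `p.<ref><pos><alt>` with single-letter codes from the standard
   20-letter alphabet. Frameshifts, stop gains and synonymous annotations
   are rejections by construction.
4. **Support** — `t_alt_count >= 5` and VAF `>= 0.10`, both inclusive
   ("at least"). The 5-read requirement applies to *alternate* reads: a
   total-depth reading would pass single-read variants whenever depth ≥ 5,
   defeating the false-positive rationale of the filter. A zero-depth
   record reaching this stage is a hard error (pipeline misordering), since
   such records must already have failed consistency.
5. **Population filter** — records whose `max_pop_af` annotation (the
   maximum allele frequency over reference populations, precomputed
   upstream; genome-liftover and database lookup are a documented
   preprocessing contract, not part of this package) is *strictly* greater
   than 1% are dropped. Equality at 1% is kept ("more than 1%"), and
   records without the annotation are kept: absence of evidence.

Every stage reports (in, out, rejected) with in = out + rejected; each
filter is idempotent. Thresholds live in `filter_config()` and are the
package defaults everywhere.

Patient identity is taken from `Tumor_Sample_Barcode` matched exactly
against the clinical table; multi-sample donors are outside the package's
scope and should be collapsed upstream.

## Recurrence calling

Recurrence is defined strictly at the protein level: distinct genomic SNVs
producing the same amino-acid exchange in the same patient collapse to one
carrier pair before counting. Per study, a change is recurrent when

  carriers / cohort size ≥ 1% (inclusive),

with the *full clinical-patient count* as denominator — including patients
with zero surviving variants — which is the conservative choice. Only
cohorts with **more than 100** patients are eligible (`min_patients = 101`).
A cutoff of "at least 100" would be the other defensible convention; we
default to the strict rule because it is the only one under which every
recurrent call is mathematically guaranteed to have at least 2 carriers
(1/101 ≈ 0.99% < 1% ≤ 2/101), and the threshold is configurable for users
who prefer the alternative.

Carrier counts are kept as integers; the threshold comparison is performed
as `n ≥ t·size − 1e-9`. The epsilon guards against binary-float artifacts
(`0.01 * 200` is not exactly `2` in doubles) while leaving genuinely
sub-threshold cases (1/101) untouched; frequencies are converted to floats
only for output.

Changes recurrent in several studies are deduplicated into unique changes;
changes hitting the same (gene, codon) merge into codon groups — the unit
comparable to external hotspot lists — and `hotspot_overlap()` counts plain
matches and matches against entries flagged as presumptive false positives.
Sorted outputs break ties lexicographically (study, frequency descending,
gene, position, alternate residue) so runs are diffable.

## Neo-epitope candidate generation

For each unique recurrent change the mutant protein is built (a reference
residue mismatch against the supplied proteome is a hard error naming
expected vs found), and **all** windows of length 9, 10 and 11 that lie
inside the protein and contain the exchanged residue are enumerated — up to
9 + 10 + 11 = 30 for interior positions, fewer near the termini. Windows
are scored against the HLA panel through a predictor interface; for each
(change, allele) only the window with the lowest predicted *mutant* IC50 is
retained, which removes both size redundancy and non-overlapping secondary
epitopes. IC50 ties (possible with coarse tabulated predictor output) break
deterministically: shortest peptide, then leftmost, then lexicographic. The
wild-type peptide — the same coordinates sliced from the unmutated sequence
— is scored with the same predictor for reference. Binder classes
(non/weak/strong) come from the predictor, following the rank-based
convention of the NetMHC family; candidate retention defaults to strong
binders, with `keep = c("strong", "weak")` available.

Sequences are matched to variants by gene symbol against the FASTA id;
isoform selection is the caller's responsibility. The default allele panel
is the 11 frequent HLA class I types shipped with the U.S. tables.

Two predictors ship:

* `table_predictor()` / `read_netmhccons_table()` — an adapter over
  whitespace/tab-delimited output of an external predictor, with
  configurable column and binder-level mappings; querying a pair absent
  from the table is a hard error carrying the pair.
* `toy_binding_predictor()` — a deterministic stand-in for synthetic runs.
  IC50 is a pure function of (peptide, allele, seed): a polynomial string
  hash (modulo 2³¹−1, two multiplicative scrambling rounds; exact in
  doubles) mapped log-uniformly onto [1, 50000] nM, divided by a bonus
  factor (default 50) when the peptide matches an allele-specific anchor
  motif at position 2 and the C terminus. Classes are per-allele quantiles
  of the predictor's own score distribution — strong below the 0.5%
  quantile, weak below 2% — estimated once from a seeded reference sample
  of 10,000 uniform-random 9–11-mers. Calibrating on the predictor's own
  distribution makes the class rates correct by construction; the reference
  sample is drawn with a private RNG stream because hash-generated
  reference peptides proved measurably non-uniform, biasing the thresholds.

## Expected-patient ranking and coverage

The ranking statistic for a candidate (change, allele *h*) is

  n_h = f_h · Σ_d r_d · N_d,

with f_h the population allele frequency, r_d the *observed* carrier
fraction in disease d, and N_d the annual incidence. Three conventions
matter:

* The sum runs over diseases present in **both** the incidence and
  variant-frequency tables.
* r_d is the observed fraction in every cohort with data, **including
  cohorts where the change is below the recurrence threshold** — the
  recurrence call decides which changes become candidates at all, not which
  diseases contribute patients.
* f_h is used directly, as the statistic defines it; the diploid carrier
  alternative 1 − (1 − f_h)² gives systematically larger numbers and is
  available via the `diploid = TRUE` flag of the ranking and coverage
  functions.

Coverage cells combine candidates under an independence assumption —
`cell(d, h) = N_d · f_h · (1 − Π_v (1 − r_vd))` over candidate changes v
binding h — with column totals and per-allele candidate counts. The cells
obey the union bound (equality iff at most one non-zero frequency), are
monotone in candidates and in every r, and scale linearly in incidence;
these properties are enforced by tests. Expected counts are reported as
reals; any rounding is display-only.

The shipped U.S. fixture holds 11 allele frequencies and 18 disease
incidences (total 1,161,958 annual cases); study-to-disease mapping is
identity on the table keys. Users supply their own tables for other
populations.

## Robustness to false-positive candidates

Because binding prediction over-calls, most candidates may fail wet-lab
validation. The resampling procedure treats a fraction of candidates as
ineffective: for each fraction (default 0.5, 0.8, 0.9, 0.95), `round(total
× fraction)` candidates are flagged uniformly at random without
replacement, and the fraction of patients still *matched* — carrying at
least one retained candidate's mutation **and** its HLA allele — is
recorded over 1000 iterations. Half-up rounding of the flagged count is
used because it is the only convention consistent with flagging 337, 539,
607 and 640 of 674 candidates at those four fractions. The 95% interval is
the empirical 2.5/97.5 percentile with linear interpolation between order
statistics (`quantile` type 7); a retained set of size zero scores 0 by
definition. One flagging draw is made per (iteration, fraction) and reused
for per-study breakdowns, so entities are compared on identical retained
sets; with the same config, the per-study run shares its draws with the
global one. All randomness comes from a private, seed-owned stream — the
caller's RNG state is saved and restored.

## Homopolymer QC and enrichment

Each call carries an 11-base reference context (variant base centered,
window configurable but always odd). A call is "in a repeat" when the
maximal run of identical bases *covering the center* has length ≥ 6;
adjacent runs that do not cover the variant do not count, since the claim
is that the variant itself sits in the artifact-prone run. Both "longer
than 6" and "at least 6" are common readings of a run-length rule; we
default to ≥ 6 (`min_run = 6`), configurable. The reference (pre-mutation)
context is used because alignment artifacts are reference-defined.

Under the null that all 11-mers are equiprobable, the probability of a
center-covering run ≥ m has a closed form: the run decomposes into
truncated-geometric left and right extensions (success probability 1/4,
truncated at the 5-base flank), summed over the 6×6 extension grid. For
the default (m = 6, window 11) this gives 0.00463867…; the implementation
is verified against full 4^window enumeration for windows 3–11. Each
study's observed repeat count is tested with the *exact* upper binomial
tail (no normal approximation), separately for singleton variants (one
patient in the cohort) and multi-occurrence variants, and
Benjamini–Hochberg corrected across studies within each branch at
α = 0.05.

Oncogene/tumor-suppressor enrichment uses Pearson's χ² without continuity
correction on set-by-class contingency tables (`gene_class_table()` counts
genes absent from the class list as "other"); a zero margin is a hard error
rather than a NaN.

## Synthetic data: what it emulates, and what it does not

The generator produces the full input surface with ground-truth labels:

* **Cohorts** — configurable studies and sizes; planted changes either with
  *exact* carrier counts or Binomial(n, f) carriers (stochastic mode);
  background passenger changes per patient ~ Poisson (default mean 2, and
  0.5 in the bundled examples to keep them small). In exact mode,
  background (gene, position) slots are drawn *without replacement across
  the whole run*, so a birthday collision can never push a background
  change over the recurrence threshold — planted-change recovery with zero
  false calls is deterministic, and tests rely on that.
* **Read support** — depth ~ negative binomial (mean 80, dispersion 10,
  floored at 50), VAF ~ Beta(8, 12) (mean 0.4, mimicking impure tumors),
  truncated so intended-pass records do pass the support filter.
* **Contaminants** — labelled records violating exactly one filter each
  (e.g. 4 alternate reads; VAF 6%; population AF 2%; classification
  "Silent"; a stop-gain annotation; a depth that does not add up), used to
  verify that each stage rejects precisely its own records.
* **HLA genotypes** — per locus, two independent draws from the allele
  frequency distribution (Hardy–Weinberg), remainder mass emitted as an
  out-of-panel placeholder allele.
* **Proteome** — uniform-random 20-letter sequences, minimum length 23 so
  interior positions admit all 11-mers.

Synthetic MAF coordinates are fabricated consistently (one gene per
contig-like chromosome label, nucleotide position = 3 × residue position)
because downstream stages use only protein-level identity. The generator
does **not** emulate mutational signatures, germline contamination,
transcript isoforms, expression, or realistic codon-to-nucleotide maps —
so green tests demonstrate the pipeline's logic and arithmetic, not
performance on real tumors. Every generator is a pure function of
(config, seed).

## Numerical conventions and degenerate inputs

* Recurrence threshold comparison: integer carriers vs `t·size − 1e-9`
  (see above).
* IC50 tie-breaks: shortest, leftmost, lexicographic.
* Ranking ties: lexicographic (gene, position, alternate, allele).
* Percentiles: `stats::quantile` type 7.
* Empty inputs: an empty MAF data section, an empty candidate list for an
  allele, an empty frequency list (union probability 0) and an empty
  hotspot list are all valid and return empty/zero results; empty *patient*
  sets for a match fraction are a hard error (the denominator is
  undefined).
* Problem sizes in the bundled tests and the acceptance script are chosen
  so the whole suite exercises every stage on cohorts of 100–400 patients,
  1000-iteration resampling, and full 4^11 enumeration of the homopolymer
  null — the scale at which all the checked identities are exact or have
  well-defined Monte-Carlo error.

## Known limitations

* Desk-scale synthetic cohorts cannot reproduce consortium-scale counts
  (millions of filtered variants, hundreds of recurrent calls across
  dozens of entities); what is reproduced exactly is the method's
  arithmetic (flagged/retained counts, the ≥ 2-carrier floor, the null
  repeat fraction) and every stated model property.
* The toy predictor is calibrated, not trained: it reproduces the *shape*
  of a rank-classified predictor, not real binding chemistry.
* HLA typing of real patients, expression filtering, proteasomal
  processing and class II prediction are out of scope.
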