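---
title: "Determining heat-inducible Hsp70s from sequence evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining heat-inducible Hsp70s from sequence evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsp70typer)
```

## The problem

The Hsp/Hsc70 chaperone family mixes constitutively expressed cognate
forms (Hsc70), heat-inducible forms (Hsp70) and intermediate
cognate-inducible forms, often as near-identical paralogs within one
genome. In non-model taxa such as amphipods, deciding *which* family
member is the heat-inducible one matters for using *hsp70* expression as
an environmental-stress biomarker, but expression experiments are slow
and transcriptome assemblies conflate paralogs. This package implements a
sequence-first determination: short diagnostic protein signatures
separate the inducible and cognate forms, promoter heat shock elements
(HSEs) corroborate heat inducibility at the gene level, and a small
expression toolkit (differential-expression candidate filtering and a
qPCR ΔCq pipeline) closes the loop where expression data exist.

## Signature model and classifier

A signature is a short degenerate pattern over the amino-acid alphabet:
`X` is a wildcard and a parenthesized letter is an alternative to the
preceding position, so `S(A)EAYLGK(G)E(A)` is eight positions with
two-residue sets at positions 1, 7 and 8. The built-in set
(`hsp70_signatures()`) contains:

* family-wide signatures: `IDLGTTYS`, `TVPAYFND`, `NEPTAA` and the
  phosphate-binding site `IFDLGGGTFDVSIL`;
* the putative nuclear localization signal `KK`-X9-`RRLRT`;
* cytosolic-localization evidence: C-terminal `GPTIEEVD` and the `EEVD`
  tail, plus `RARFEEL`/`RARFEEM`;
* inducibility diagnostics: the ATP/GTP-site variants
  `S(A)EAYLGK(G)E(A)` (heat-inducible) versus `ADAYLGTN` (cognate), the
  N-terminal hexamers `MRAKST` (heat-inducible) versus `MSKATA`
  (cognate), and the `RARFEEM`/`RARFEEL` final-residue contrast.

`classify_hsp70()` applies ordered, conflict-aware rules: family
membership needs at least two of the four family signatures; the `EEVD`
tail decides cytosolic versus non-cytosolic localization; inducibility is
called heat-inducible or cognate-like only when the diagnostic evidence
is one-sided, and any contradiction (for example both ATP-site variants
present) yields `undetermined` with the conflict recorded. The score
counts concordant diagnostics (ATP site, N-terminal hexamer, RARFEE
variant; maximum 3). We never break ties by majority vote: a sequence
with contradictory diagnostics is exactly the case a curator should see.

Design choices worth making explicit:

* The parenthesized-alternative grammar binds `(Y)` to the immediately
  preceding position only; this reproduces the conventional 8-residue
  ATP-site length.
* The N-terminal hexamer is compared over residues 1–6 including the
  initiator methionine, and is anchored: it only matches at the start.
* `EEVD` (four residues, C-anchored) carries the localization decision;
  `GPTIEEVD` is supporting evidence only, so sequences with slightly
  truncated C-termini still classify.
* Every signature defaults to a mismatch budget of 0; budgets are
  per-signature configurable for relaxed, "signature-like" searches in
  more divergent taxa. The default is strict because the diagnostics are
  short: at 8 residues a single allowed mismatch already erodes the
  inducible/cognate contrast.

## Domain coordinates

The reference layout is a 641-residue protein with the nucleotide
binding domain (NBD) at 1–390, the substrate binding domain (SBD) at
397–560 and the C-terminal domain at 561–641; the 391–396 linker belongs
to no domain. `map_domains()` transfers these boundaries to a query via
global pairwise alignment (BLOSUM62, affine gaps, opening 10 ≫ extension
0.5 — standard protein-alignment defaults, configurable because the
boundaries, not the aligner, are the content) and reports per-domain
coverage; alignments below 30% identity are flagged rather than refused.
`extract_region()` uses the same machinery to cut query residues aligned
to a reference interval, e.g. the 217–514 window (298 residues) used for
cross-species comparisons. Since no curated reference protein ships with
the package, the reference is constructed synthetically by
`gen_protein()` with the canonical signature layout; users with a real
reference supply it to `reference_model()`.

## Heat shock elements

An HSE is a run of contiguous, strictly alternating `NTTCN`/`NGAAN`
pentamers; heat shock factor trimers need at least three units, so
`min_units = 3` is the canonical threshold. Only the central
trinucleotide is informative — the flanking positions are free by
definition — and the two cores differ at all three positions, so a core
is never ambiguous between classes within a one-mismatch budget.
`find_hse()` scans all five pentamer phases and reports maximal,
non-extendable runs per phase; overlapping runs in different phases are
all reported.

"HSE-like" has no settled definition; the one adopted here is a run of
at least three units carrying exactly one core mismatch in total (which
includes the case of two perfect units flanked by a one-mismatch unit).
A bare two-perfect-unit run is reported as `hse_like` only when the
caller lowers `min_units` to 2 — this is how truncated printed elements
that end mid-unit can still be inspected. This definition is a
documented heuristic: published promoter scans sometimes label runs
HSE-like whose cores are not even 5-bp periodic, and no pentamer-grammar
definition can reproduce those.

Two conventions are fixed and documented rather than inferred: the
upstream distance is the number of bases strictly between the element's
last base and the A of the start ATG; and because the reverse complement
of `NGAAN` is `NTTCN`, every HSE interval is strand-symmetric, so each
interval is reported once on the forward strand (minus-strand scanning
is retained as an internal consistency check). When a run has one
mismatch budget left at both ends, the 5' extension is preferred for
determinism.

## Expression evidence

`filter_de()` flags candidate transcripts from an upstream
differential-expression table with strict inequalities: significant when
|log2 fold change| > 1 and adjusted p < 0.001, abundant when mean TPM
across conditions > 200, candidate when both. Missing adjusted p-values
are never significant (warned, not dropped). The thresholds are the
standard candidate criteria for this analysis and are surfaced in
`filter_config()`.

The qPCR pipeline mirrors bench practice: samples are discarded when the
reference gene (*gapdh* by default) has Cq > 30 or is undetected, or
when its minus-RT control sits below 30 (genomic contamination); ΔCq is
target minus reference per sample; groups are compared with a
Wilcoxon–Mann–Whitney test and Holm correction across the target genes
of a run. Undetectable target reactions are censored and counted, never
imputed — with strong induction the control group is often largely
undetectable, and imputation would manufacture effect size.

The exact test enumerates all `choose(n+m, n)` labelings for combined
sizes up to 12, uses midranks for ties, and defines the two-sided
p-value as the null probability of a U at least as far from `nm/2` as
observed — a deviation-based rule, not doubling of one tail, because
doubling can exceed 1 and misbehaves under asymmetric tie patterns. For
larger samples a tie-corrected, continuity-corrected normal
approximation is used and the method applied is reported. Two numerical
notes: the exact p-value is discrete, so at nominal α = 0.05 the
*attained* size is below 0.05 (0.041 for 6 vs 6, 0.032 for 5 vs 5); the
calibration tests therefore compare the Monte-Carlo rejection rate with
the attained size derived from the exact null distribution, and
additionally require the rate never to exceed the nominal level. Holm
adjustment delegates to `stats::p.adjust`; it is conservative and
rank-monotone but, like any step-down procedure, not idempotent.

## Synthetic data: what it emulates, and what it does not

The generators make the whole workflow testable without downloads, and
their defaults are the study conditions:

* `gen_protein()` — 641-residue backbones (uniform residue composition)
  with the signature layout planted at domain-consistent positions;
  types `inducible`, `cognate`, `noncytosolic`. Backbones are resampled
  (capped retries, loud failure) if an opposing diagnostic motif arises
  by chance, so zero-mutation fixtures classify as planted by
  construction; optional point mutations inside motifs degrade recovery.
* `gen_promoter()` — planted canonical/HSE-like elements at exact
  upstream distances on rejection-sampled backgrounds guaranteed free of
  accidental runs.
* `gen_de_table()` — exactly `n_pass` rows jointly passing the filter
  (defaults 23 of 155; 19 of 108 mirrors the second study species), with
  failing rows cycling through every single-failure mode.
* `gen_cq_table()` — two groups of at least four replicates, reference
  Cq centred at 20 (SD 0.3 cycles, typical technical spread), control
  ΔCq of 5, and a heat-shock shift of −6 cycles (about 64-fold
  induction, the order of magnitude qPCR validation targets); optional
  planted QC failures.

Identical seeds give byte-identical outputs, and each fixture carries a
`truth` attribute sufficient to score recovery without re-derivation.
What the fixtures do *not* emulate: phylogenetic correlation between
sequences, compositional bias, assembly artifacts (chimeric or
reverse-complement transcripts), or qPCR efficiency differences between
primer pairs. Passing on fixtures therefore demonstrates that the
scanners and rules are implemented correctly, not that the diagnostics
themselves generalize beyond the taxa they were derived from.

## Problem sizes and other numerical choices

Property tests run the scanners against naive brute-force oracles on 200
random motif cases and 100 random 1-kb promoter sequences; classifier
recovery uses 200 fixture proteins; the null calibration of the exact
test uses 10,000 replicates at 6 vs 6. Consensus ties break
alphabetically with an explicit tie flag. Pairwise identity of
equal-length sequences is positionwise; unequal lengths are globally
aligned first, terminal-gap columns are excluded from the denominator
and internal gaps count as mismatches — conventions differ between
alignment viewers, so ours is fixed and stated. ORFs are complete
ATG-to-stop units only (no open-ended ORFs); every qualifying ATG is
reported, so nested starts sharing a stop are all visible; codons
containing N translate to X, and N-containing start/stop codons are not
accepted.

## A worked example

```{r example}
prot <- gen_protein(7, "inducible", id = "TR_0001")
cls <- classify_hsp70(profile_signatures(prot))
cls

prom <- gen_promoter(8, distances = 1187, id = "TR_0001")
hits <- find_hse(prom)
upstream_distance(hits[1, ], attr(prom, "truth")$orf_start)

de <- gen_de_table(9, n_total = 155, n_pass = 23)
sum(filter_de(de)$candidate)

cq <- gen_cq_table(10, effect_size = -6)
qpcr_analysis(cq)
```

## Known limitations

The classifier encodes diagnostics derived from amphipod Hsp/Hsc70
sequences; in other taxa the hexamer and ATP-site contrasts may not
hold, and the configurable mismatch budgets only partially compensate.
The HSE-like definition is a heuristic (see above). Domain-boundary
transfer is only as good as a global pairwise alignment; for distant
homologs a profile-based alignment would be preferable. The qPCR module
deliberately stops at ΔCq — no efficiency correction or ΔΔCq — and the
DE filter consumes an upstream quantification/testing pipeline's output
rather than re-modelling counts.
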