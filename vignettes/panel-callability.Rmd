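---
title: "Auditing amplicon-panel callability: model, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing amplicon-panel callability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callaudit)
```

## What the audit measures

A targeted amplicon panel can only report a variant if the assay can
*evaluate* the variant's locus at all. Callability is a property of the
locus and the chemistry, not of whether the variant is present in a given
patient: a hotspot can be uncallable because no amplicon covers it, or
because the local sequence context makes the signal uninterpretable.
`callaudit` forces an evaluation at every locus of a knowledge-base
catalogue ("hotspot-forced calling"): the caller must answer REFERENCE,
VARIANT, or NOCALL with a machine-readable reason, and the audit assigns
every catalogue variant to one of three tiers — AUTOMATIC, REVIEW (the
in-silico stand-in for visual inspection of the alignment), or UNCALLABLE.
Panel **sensitivity** is the callable fraction,
$100\,(N - N_{\mathrm{unc}})/N$; **specificity** is used in the
orthogonal-confirmation sense (fraction of reported variants confirmed by
an independent method), not as a true-negative rate — the report header
states this.

## The decision cascade

`evaluate_hotspot()` applies rules in a fixed order; the first match wins.

1. **Uncovered** locus (not fully inside the union of amplicon inserts)
   → NOCALL, UNCALLABLE (`not_covered`). No assay output can exist here.
2. **Homopolymer indel**: an insertion or deletion of at most
   `max_hp_indel_len` (default 2) bases, whose inserted/deleted sequence
   is a pure repeat of one base, overlapping or directly abutting a
   maximal run of that base of length ≥ `min_homopolymer_len` (default 4)
   → NOCALL, UNCALLABLE (`homopolymer_indel`). This mirrors the error
   mechanism of flow/semiconductor chemistry, where run length is read
   out as a (noisy) signal intensity: neither software nor a human looking
   at the alignment can distinguish a true ±1 bp change of a long run from
   the chemistry's own error mode. A mixed-sequence indel beside a run
   (say an `AC` insertion next to an A-run) does **not** trigger the rule —
   it does not reproduce that mechanism.
3. **Pileup failures** → NOCALL, REVIEW, with every applicable reason:
   depth `< min_depth`; alternate reads confined to one strand or a
   significant two-sided Fisher strand-balance test; mean base or mapping
   quality below threshold; alternate VAF inside the noise band.
4. **Context demotion**: within `proximity_window` of a homopolymer run
   (overlap counts as distance 0, so in-run SNVs are included) or within
   `amplicon_end_margin` of the boundary of every covering insert → the
   VAF-based status is kept but the tier is REVIEW.
5. Otherwise AUTOMATIC: VARIANT if the alternate VAF reaches `min_vaf`,
   REFERENCE below it.

Across samples the panel-level tier of a variant is the worst observed
(UNCALLABLE > REVIEW > AUTOMATIC), reasons are the union, and the no-call
frequency is recorded — an audit run over a cohort records how often each
hotspot failed, but reports one classification per variant.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `min_homopolymer_len` (H) | 4 | bp | shortest run treated as a homopolymer stretch; 2–3 bp repeats are handled well by the chemistry |
| `proximity_window` (D) | 3 | bp | flow-signal spill-over is very local; 3 intervening bases is a conservative neighbourhood |
| `amplicon_end_margin` (E) | 5 | bp | primer-proximal bases are artefact-prone (end-repair, primer mispriming) |
| `max_hp_indel_len` | 2 | bp | the uncallable error mode concerns single/double base insertions or deletions |
| `min_depth` | 100 | reads | matches the panel operating regime in which essentially all target bases exceed 100× |
| `min_vaf` | 0.05 | fraction | conventional reporting floor for somatic assays |
| `min_base_quality`, `min_mapping_quality` | 20 | phred | Q20: 1% error |
| `strand_bias_alpha` | 0.001 | – | two-sided Fisher level; strict because thousands of loci × samples are tested |
| `noise_vaf_band` | [0.02, 0.05) | fraction | too much signal for clean reference, below the calling floor |
| `germline_min_normal_vaf` | 0.20 | fraction | well below the heterozygous expectation 0.5, robust to sampling noise |
| `somatic_max_normal_vaf` | 0.05 | fraction | sequencing-noise ceiling in the normal |
| `homozygous_min_tumour_vaf` | 0.85 | fraction | between heterozygous-with-purity and LOH expectations |
| `reaction_len` | 150 | bp | readable target of one Sanger reaction |

The one-strand rule carries a minimal-support guard (at least 2 alternate
reads): a single stray read is below the noise band and should not force
review on its own.

## Pathogenicity and origin rules

Mutation types are read off protein HGVS (`fs` → frameshift, substitution
to `Ter` → nonsense, `del` without `fs` → in-frame deletion, single-residue
substitution → missense, `=` → synonymous), falling back to coding HGVS
length-modulo-3 arithmetic when no protein annotation exists. The parser
covers the constructs of this problem space (substitutions, fs, del, dup,
delins, `=`) and errors loudly on anything else rather than guessing.

Classification applies five rules in order, forming a total function:

1. a catalogue record whose submitter entries are majority-pathogenic
   (strictly more pathogenic than benign entries) → **pathogenic**;
2. frameshift or nonsense → **pathogenic** (premature stop codon);
3. an unrecorded missense sharing its codon with a recorded pathogenic
   missense → **likely_pathogenic_same_codon**;
4. population frequency ≥ 1% with majority-benign entries → **benign**;
5. otherwise **VUS**.

Rule 1 precedes the structural rules so that a recorded-pathogenic
missense or in-frame deletion is called pathogenic. "Majority" is a strict
count comparison of submitter entries; a single dissenting pathogenic
entry against eight benign ones does not flip a common polymorphism.

Origin comes from the matched normal: normal VAF ≥ 0.20 → germline,
≤ 0.05 → somatic, in between (or missing normal) → undetermined, which is
monotone in the normal VAF by construction. Tumour VAF ≥ 0.85 marks
homozygosity or loss of the wild-type allele (LOH) — the signature of a
germline-heterozygous variant whose tumour lost the other allele.

## Sanger planning

Whole-gene workload follows the per-exon rule: one reaction per 150 bp,
one per exon if the exon is shorter. Blind-spot rescue is a minimum
fixed-length window cover of point loci; the left-to-right greedy (open a
window at each leftmost uncovered locus) is exact for this problem, and
the test suite verifies it against exhaustive search. Rescue windows are
placed on genomic coordinates without exon-boundary constraints; the
per-exon regime applies only to the whole-gene estimate, where reaction
setup is per-exon in practice.

## The synthetic study

The generator's defaults are the study conditions the package is
validated under, not tuning knobs:

* two genes with coding sizes 5,659 and 10,262 bp over 24 and 27 exons
  (near-equal exon split; real exon size distributions are not modelled,
  so whole-gene Sanger counts differ from any particular real transcript);
* catalogue geometry 2,522/398 germline/somatic entries with 79 shared,
  and 3,584/673 with 145 shared (union 6,953, raw sum 7,177, overlap 224);
* planted tiers 2,520/320/1 and 3,539/509/64, the second gene's 64
  uncallable split into 12 homopolymer blind spots and 52 variants inside
  2 unamplifiable windows. The blind-spot geometry (12 isolated runs plus
  2 windows, all farther apart than one reaction) mirrors the reported
  per-gene rescue workload of 1 + 14 reactions;
* 47 samples at mean hotspot depth 500 (Poisson), three multiplex pools,
  tumour purity 0.8 — manual microdissection guarantees at least 70%
  neoplastic cellularity, and 0.8 is a realistic post-enrichment mean that
  keeps the LOH allele fraction (1 + p)/2 = 0.9 clearly above the 0.85
  zygosity threshold;
* homopolymer indel error rate `min(0.01·L, 0.2)` per read — the simplest
  model that is linear in run length with saturation, making long runs
  uninterpretable while leaving short runs reviewable;
* a cohort of 13 mutated samples (8 + 5, mutually exclusive) with
  frameshift/nonsense/in-frame-deletion/missense composition, three LOH
  cases, plus common benign polymorphisms in up to 24/3/2 carriers.

Randomness is one master seed; each top-level generator draws from a
stream seeded at a fixed offset (reference +0, catalogues +1, pileups +2,
cohort +3), so generators are reproducible standalone and composed, and
adding a generator never perturbs earlier output.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: read-level alignment and realignment artefacts,
flow-space signal values, FFPE deamination damage (available only as an
optional strand-bias artefact channel, default off), PCR duplicate
structure, pool-imbalance coverage waves, and real exon/amplicon
coordinate distributions. The audit's context rules are exercised exactly;
the pileup-failure rules are exercised through planted artefact channels
with known truth.

## Numerical choices

* **Coordinates**: 0-based half-open internally; VCF (1-based) and BED
  (0-based half-open) converted at the I/O boundary only.
* **Canonical variant form**: indels are left-aligned and trimmed to the
  VCF-anchored form (one shared leading base; SNVs fully trimmed), the
  form in which two databases' representations of the same indel unify.
  An indel equivalent to a placement at the very start of a contig keeps
  its anchor at position 0. Normalization is idempotent, and two
  representations merge iff their implied haplotypes are identical
  (property-tested against a haplotype-equality oracle).
* **Rounding**: half-up everywhere (1 decimal for rates, integers for
  cohort percentages), with a 1e-9 epsilon against binary representation
  of decimal halves. Published tables of this kind are not always
  internally consistent under a single rounding rule (e.g. 2,840/2,841
  printed as 99.9, or 829/6,953 printed as 12.0, where half-up gives
  100.0 and 11.9); the report documents the convention and applies it
  uniformly.
* **Strand balance**: `stats::fisher.test`, two-sided; the suite checks it
  exhaustively against a hypergeometric tail enumeration for all tables
  with row margins ≤ 20 and on 1,000 random tables with margins up to 60 —
  sizes chosen to keep the enumeration exact yet fast.
* **Degenerate inputs**: depth 0 at a covered locus is a reviewable
  low-depth no-call, never an error; a missing pileup at a covered locus
  is the same plus a warning; an all-zero strand table is an error; a
  zero-denominator specificity is "not applicable" (`NA`), not 0 or 100.
* **Problem sizes** in the property suite (500 random rescue sets ≤ 12
  loci, 1,000 random indel normalizations, 100 random panels for the
  audit invariants, study-sized recovery at depth 500 over 47 samples)
  were chosen to exercise each combinatorial regime while keeping the
  default test run in minutes.

## Design choices where the design was open

* Visual inspection cannot be automated faithfully; it is modelled as the
  REVIEW tier plus an optional two-column override table merged at report
  time, preserving the three-way outcome while keeping the pipeline
  runnable unattended.
* The worst-tier-across-samples aggregation reflects how a panel-level
  claim must hold for every sample in which the locus was assayed.
* "Artefact-prone regions" are operationalized as amplicon-end margins
  plus an optional user-supplied blacklist, since the concept has no
  standard definition.
* Unamplifiable regions are a property of the supplied panel BED, not
  fixed knowledge: the audit discovers them as coverage gaps.
* Strand is ignored throughout: panel and catalogue are genomic-coordinate
  based.
* Out-of-design catalogue variants (outside exons ± 50 bp junctions) are
  flagged but retained, so the audit's denominator is explicit.

## Known limitations

The package audits *evaluability*, not caller accuracy: it does not
realign reads, model flow-space signals, or discover non-hotspot variants.
HGVS strings are taken as given (no transcript projection), splice-effect
prediction and full ACMG/AMP criteria are out of scope, and origin
thresholds are validated on synthetic data only — per-case VAF
distributions of real FFPE cohorts vary with fixation quality and should
be re-examined before clinical use.
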