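---
title: "Second-hit analysis of TSC1/TSC2-driven tumors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Second-hit analysis of TSC1/TSC2-driven tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secondhit)
```

## The scientific problem

Renal angiomyolipoma and lymphangioleiomyomatosis (LAM) are PEComa-family
proliferations driven by loss of the TSC1/TSC2 tumor suppressor complex and
consequent mTORC1 hyperactivation. Under Knudson's two-hit model a first
(often germline) inactivating mutation must be followed by a somatic
"second hit" that removes the remaining wild-type allele. In these tumors
the second hit is usually one of three events:

* a second, independent small mutation (point mutation or indel);
* **copy-neutral loss of heterozygosity (CN-LOH)** — mitotic recombination
  replaces the wild-type haplotype with the mutant one, leaving total copy
  number at 2 so that ordinary coverage-based copy-number analysis sees
  nothing;
* a genomic deletion removing both copies (homozygous deletion).

`secondhit` implements the complete analysis path from tumor/normal exome
variant tables to per-specimen inactivation verdicts, cohort burden
statistics, and patient-level clonal phylogenies of multifocal tumors, and
ships a synthetic-data generator with full truth records so that every
stage is testable without access to patient data.

## The allele-fraction mixture model

All quantitative reasoning rests on one piece of arithmetic. A specimen
with tumor purity $p$ (fraction of cells that are tumor) is a mixture of
tumor cells carrying $m_T$ mutant copies (out of 2, copy-neutral by
assumption) and normal cells carrying $m_N$. The expected variant allele
fraction is

$$\mathrm{AF}(p) \;=\; \frac{p\, m_T + (1-p)\, m_N}{2}.$$

The five genotype configurations the package models:

| model                         | $m_T$ | $m_N$ | AF$(p)$     |
|-------------------------------|-------|-------|-------------|
| `germline_het_no_loh`         | 1     | 1     | $1/2$       |
| `germline_het_cnloh_retained` | 2     | 1     | $(1+p)/2$   |
| `germline_het_cnloh_lost`     | 0     | 1     | $(1-p)/2$   |
| `somatic_het_no_loh`          | 1     | 0     | $p/2$       |
| `somatic_cnloh`               | 2     | 0     | $p$         |

`expected_af()` evaluates the map and `estimate_purity()` inverts it,
pushing an exact binomial confidence interval on the observed AF through
the inverse. Estimates outside $[0,1]$ — expected at low depth — are
clipped and flagged rather than refused. Two standing assumptions are made
explicit: total tumor copy number is 2 (the CN-LOH mechanism preserves
diploidy, and no other gains/losses are modelled), and events are clonal
(cancer cell fraction 1); a subclonal event biases the estimate downward.
The `germline_het_no_loh` map is constant and therefore refused as
uninformative for purity.

```{r purity}
expected_af("germline_het_cnloh_retained", purity = 0.44)
estimate_purity(0.72, "germline_het_cnloh_retained", depth = 116)
```

## LOH mapping from SNP allele fractions

CN-LOH is invisible to coverage but visible in the B-allele frequency of
germline heterozygous SNPs: in the LOH segment, a SNP's AF is displaced
from $1/2$ to $(1\pm p)/2$, the sign depending on which haplotype carries
its alternate allele. The mapping procedure:

1. **Informative SNPs** (`identify_het_snps`): normal-sample depth at
   least 20 (i.e. "> 19") and normal AF in $[0.40, 0.60]$, inclusive.
   Without a matched normal, `identify_candidate_snps_unpaired` keeps
   tumor AF in $[0.05, 0.95]$.
2. **Skew calls** (`call_skew`): a SNP is *skewed* when tumor AF is
   strictly below 0.40 or strictly above 0.60. AF exactly at a threshold
   is *normal*: the boundary is unclaimed by either definition, and
   assigning it to normal is the conservative choice (fewer false LOH
   calls). All threshold comparisons are done on the count scale with a
   `1e-9` epsilon so that exact boundaries land on the documented side
   regardless of binary floating-point representation.
3. **Region delineation** (`delineate_loh_regions`): maximal runs of
   skewed SNPs become regions. Isolated interior normal-AF SNPs do not
   split a region; they are counted (`n_discordant_interior`) under a
   global budget (`max_interior_discordant_frac`, default 0.1). A second,
   *local* gate requires every bridge crossed during merging (the next
   skewed run plus the normal SNPs separating it) to remain
   majority-skewed (discordance $\le 1/3$). Without the local gate a long
   region's global budget would let the scan chain out to isolated
   false-skew SNPs megabases beyond the true breakpoint; with it, the
   confident end stays pinned near the last genuine LOH SNP. Runs with
   fewer than `min_skewed` (default 10) skewed SNPs are reported as
   unassigned rather than called.
4. **Confident span vs uncertainty flanks**: the confident span runs from
   the first to the last skewed SNP; each flank extends to the nearest
   normal-AF SNP (the true breakpoint lies somewhere in that flank), or to
   the end of the observed track, in which case the boundary is marked
   *censored*. "Telomere-anchored" is defined relative to the observed
   track, since exome capture rarely reaches the physical telomere.
5. **Copy status** (`assess_copy_neutrality`): the median log2
   tumor/normal depth ratio over windows overlapping the confident span,
   with a neutral band of $\pm 0.3$ (tolerant of exome capture noise),
   single-copy loss down to $-1.5$, homozygous loss at or below $-1.5$,
   and `indeterminate` below 5 windows. This windowed-ratio scheme is a
   deliberate simplification of panel-of-normals exon-level segmentation.
   `detect_homozygous_deletion` applies the same thresholds to find focal
   deletions, reporting a mixed run as a single-copy-loss interval with
   homozygous sub-intervals nested inside it — the geometry of a focal
   homozygous deletion with hemizygous flanks.

`min_skewed = 10` and the discordance budgets are configuration, not
biology: the published analysis had dense exome SNPs and visual curation,
so these defaults encode "at least ten concordant markers, at most one
discordant in ten" as a reasonable automated surrogate.

### Detection power

The per-SNP skew call is a binomial tail event. At purity $p$ and depth
$d$, an LOH SNP on the retained haplotype has AF $(1+p)/2$ and is called
skewed with probability $P(\hat{\mathrm{AF}} > 0.6)$, computable directly
from the binomial distribution (the package's property tests verify the
empirical call rate against this tail probability). Two consequences are
worth knowing:

* at purity 0.5 and depth 80 the per-SNP miss rate is below 1%, and
  simulated breakpoints are recovered within twice the local SNP spacing
  in well over 95% of runs;
* at purity 0.3 the displaced AF is 0.65 and roughly a fifth of LOH SNPs
  read as normal-AF at depth 80 — more than the default interior
  discordance budget. Regions then fragment and mapping fails. This is a
  genuine detection floor of the thresholded method, not a tuning issue;
  the cohort's own low-purity specimen (~10%) was flagged as uncertain by
  the original analysis for exactly this reason.

## Two-hit mechanism classification

`classify_variant_type` types variants from their HGVS strings: stop
gains are nonsense; deletions/insertions are frameshift or in-frame by
length modulo 3; substitutions with intronic offsets are splice only at
the canonical $\pm 1/\pm 2$ positions — a deeper offset (e.g. $-15$)
requires either a `_splice` protein annotation or an explicit declared
type, which always overrides inference (logged). This mirrors curated
practice, where an extended splice-region variant is typed by functional
evidence rather than by position alone.

`classify_sample_status` applies a strict precedence:

1. homozygous deletion covering the locus;
2. two or more distinct inactivating variants at one locus
   (germline + somatic counts, as do two somatic);
3. one variant plus CN-LOH whose *confident span* covers the locus
   (a locus inside only the uncertainty flank is demoted with a warning);
4. CN-LOH with no detected variant (`cnloh_only` — LOH of a wild-type
   locus is not biallelic inactivation);
5. `none`.

Mechanisms 1–3 are biallelic. "Distinct" means distinct cDNA strings:
phasing is unknowable from short reads, and the trans configuration is an
assumption, stated here once. A homozygous deletion counts as two hits
(both alleles removed) in all tallies.

## Burden statistics and the mechanism contingency

Somatic coding mutations outside TSC1/TSC2 are counted per tumor-normal
pair (uncovered calls excluded, zeros filled for pairs with no calls),
summarised as median, range and median/territory rate (default territory
33 Mb, the exome capture size). The mutation *spectrum* is computed over
the patient-level unique set (`dedup_unique_mutations`: a mutation shared
by several tumors of one patient is one event; identical mutations in
different patients stay separate; literal duplicate rows collapse).

Both denominators — covered calls and patient-level unique mutations —
are computed and reported, because published tallies use both without
defining either and the two differ exactly when truncal mutations recur
across a patient's tumors. Subclonality tallies (fraction of mutations
below AF 0.15 and 0.10) are likewise reported under both denominators
with the choice echoed in the output.

The two-event-mechanism-by-cohort contingency (two small-scale hits vs
other, sporadic vs TSC) is tested with a Fisher exact test authored in
log space: the two-sided p-value is the sum of probabilities of all
hypergeometric outcomes no more likely than the observed table
(point-probability definition, with a $1+10^{-7}$ relative tie guard),
computed via `lchoose` so large margins cannot overflow. A doubling
variant (twice the smaller tail) is available for comparison. The
implementation is verified against a full enumeration oracle over every
2×2 table with margins up to 20.

## Clonality of multifocal tumors

The clone tree is event-set logic, not sequence phylogenetics. Evidence
tiers, strongest first:

* **definite_shared** — two or more identical somatic non-TSC mutations
  shared by a sample set. One shared mutation is reported as a *possible
  link* but never groups samples: a single recurrent artifact could
  explain it.
* **independent** — a unique TSC2 second-hit variant or a unique LOH
  region within the patient.
* **possible_shared** — linked only by an identical LOH boundary. Two
  regions match when their breakpoint-uncertainty intervals (confident to
  uncertain boundary) overlap on both comparable sides; telomere-anchored
  regions share their telomeric side by construction and are compared
  centromerically. Boundary identity alone never upgrades to definite:
  at exome SNP resolution, two independent recombination events can be
  indistinguishable.
* **unresolved** — no usable second-hit or sharing evidence (including
  the low-purity specimen whose LOH extent is uncertain).

When mutation sharing and LOH boundaries disagree, the mutation evidence
wins and the group carries a conflict flag — point-mutation identity is
far stronger evidence than boundary concordance. Trees export as newick
(internal nodes labelled with truncal event counts; round-trips through
`ape::read.tree`) and as JSON with full event lists.

## The synthetic-data generator

`simulate_snp_track` emulates exactly the data structure the mapper
consumes: germline het SNPs along a chromosome arm (36 Mb, the size of
16p), negative-binomial depths (default mean 80, variance twice the mean
— overdispersion stresses boundary detection the way uneven exome capture
does), normal alt counts Binomial$(d, 1/2)$, and tumor alt counts
Binomial$(d, \mathrm{AF}(p))$ where the genotype model inside the
telomere-anchored LOH segment is chosen per SNP by a simulated phase, so
skew direction alternates while its magnitude is set by purity — the
two-sided scatter seen in real B-allele plots. Defaults (purity 0.5,
breakpoint 10 Mb within the published 3–30 Mb size range, ~800
informative SNPs) describe a realistic mid-cohort specimen and are fixed
once, here.

`simulate_patient` adds variant tables (germline first hit, configured
second-hit mechanism, Poisson(4) private mutations from a synthetic gene
vocabulary) and truncal architecture. Presets:

* `p13_like` — 16 tumors: a 3-tumor truncal group sharing 2 somatic
  mutations and one CN-LOH breakpoint, 2 point-second-hit tumors, 9
  CN-LOH tumors with distinct breakpoints, 2 with no second hit.
* `sporadic_two_hit` — one tumor, two somatic TSC2 variants, no LOH.
* `homozygous_del` — a 50 kb homozygous dip nested in a 150 kb
  single-copy-loss interval. This preset defaults to purity 0.8: a
  homozygous deletion at purity $p$ leaves $2(1-p)$ mixture copies, and
  only around 80% purity does the depression reach the ~0.3–0.45-copy
  level actually observed for such events — at purity 0.5 the dip (1.0
  copies) is indistinguishable from hemizygous loss, which is a fact
  about the assay, not the simulator.

What the generator does **not** emulate: read-level errors, mapping
artifacts, GC waves, subclonal copy-number states, or germline structural
variation. A green simulation test therefore establishes that the
algorithms are correct under binomial sampling noise at stated purity and
depth — not that the thresholds are robust to every artifact of real
capture data.

## Numerical and design choices

* Boundary semantics are inclusive where the filter text says "at least"
  (3 mutant reads kept, AF 0.05 kept, normal AF 0.40/0.60 kept) and
  strict where it says "beyond" (skew requires AF strictly outside
  $[0.40, 0.60]$); epsilon-guarded count-scale comparisons make these
  exact.
* The packaged cohort tables are shipped as checksummed transcriptions;
  the loader refuses a modified file. Allele fractions are always
  recomputed from read counts, never trusted from a printed AF column
  (the transcription's printed AFs are retained as annotations and agree
  with recomputation to one unit in the second decimal — the printing's
  own rounding granularity).
* The cohort tables are already review-filtered; burden statistics use
  them as printed (excluding only no-coverage rows) rather than
  re-applying `filter_variant_calls`, which exists for raw caller output
  and synthetic data. One printed call sits below the nominal 5% AF
  filter (it was orthogonally validated); re-filtering would silently
  change the per-sample counts.
* Zero-depth calls have no allele fraction (`NA`, flagged uncovered) and
  are excluded from every statistic.
* Purity clipping, censored LOH flanks, demotion of flank-only LOH, and
  the single-window low-confidence flag in deletion detection all favour
  explicit flags over silent failure or silent confidence.

## Limitations

* The LOH mapper is thresholded, not probabilistic: no HMM/CBS
  segmentation, no allele-specific integer copy-number inference, no
  phasing. Below roughly purity 0.35–0.4 at depth 80 the per-SNP signal
  is too weak for the default thresholds (see detection power above).
* The purity estimator is single-variant and closed-form; it does not
  jointly fit multiple variants or deconvolute subclones.
* Clone trees are two-level event-set summaries; they do not infer
  mutation order beyond truncal vs private.
* The optional VCF importer maps only AD depth fields; annotation
  (genes, HGVS) must come from upstream tools.
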