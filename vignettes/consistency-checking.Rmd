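---
title: "Mendelian consistency checking on genotyped pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mendelian consistency checking on genotyped pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedsandwich)
```

## The problem

Livestock mapping populations — hundreds to thousands of related animals
genotyped at tens to hundreds of thousands of markers — invariably contain
errors: misrecorded parentage, swapped samples, failed assays, sex-linked
markers scored as if autosomal. Under Mendelian transmission each parent
contributes exactly one allele to an offspring's genotype, so such errors
surface as *inheritance inconsistencies*: offspring genotypes that cannot be
reconciled with the genotypes their recorded parents could have transmitted.
Downstream linkage and association analyses are highly sensitive to these
inconsistencies, so they must be found and understood before any analysis.

`pedsandwich` implements the checking engine for this task: pedigree and
genotype data models, set-based genotype inference over missing data, a
three-way error taxonomy, a simulation and error-injection suite with ground
truth, and a structural model of the generational "sandwich" layout used to
present the results.

## Data model

A **pedigree** is a table of individuals with optional sire and dam links, a
recorded sex (`male`, `female`, `unknown`) and an optional litter tag.
Validation reports duplicate ids, unknown parents, ancestry cycles,
individuals referenced as both sire and dam, and sex-role conflicts (an
individual recorded female but referenced as a sire, or vice versa).
Unsexed individuals may serve in either parental role without conflict: real
fowl pedigrees leave up to ~98% of non-breeders unsexed, and refusing them
as parents would make such files uncheckable. Generations are assigned by
longest path from the founders; a founder introduced mid-program is lifted
to one level above its earliest child, so every parent–offspring sandwich is
well formed without inventing ancestry.

A **genotype matrix** holds one unordered call per (individual, marker)
cell: diploid calls like `C/T`, hemizygous calls like `C/-` (the `-` is the
null allele carried by the heterogametic sex at sex-linked loci: XY males,
ZW females), partial calls like `T/?`, and missing calls `?/?`. Marker
alphabets are inferred from the data (the usual case: bi-allelic SNPs) or
declared in a sidecar, which also carries the linkage mode (`A`/`X`/`Z`).
Parental origin of the two alleles is unobservable in the data, so calls are
stored canonically (alleles sorted, `-` last, `?` last of all); origin
reasoning lives only inside the inference engine.

## Inference: nuclear-family genotype elimination

Missing data is the rule, not the exception — whole intermediate
generations are often left ungenotyped. The engine therefore infers, per
marker, a **candidate set** of genotypes for every individual:

1. initialize to the observed call (a singleton), to the legal genotypes
   consistent with a partial call, or to all legal genotypes for the
   individual's sex when the call is missing;
2. sweep the nuclear families in sorted (sire, dam) key order, deleting any
   member's candidate that takes part in no jointly consistent
   (sire, dam, child) assignment with the other members' current sets;
3. repeat until a full sweep deletes nothing.

This is classical genotype elimination, and on loop-free pedigrees the
fixpoint is exact: the test suite verifies equality with brute-force
whole-pedigree enumeration on hundreds of randomly generated small
pedigrees. Two design choices matter:

* **Inference is bidirectional.** Observed children constrain an
  ungenotyped parent exactly as parents constrain children. This is what
  lets an error travel: a corrupted genotype in one individual can narrow
  the candidate set of its ungenotyped mate and surface as flags in the
  mate's other offspring.
* **Observed genotypes are immutable facts.** They are never deleted, even
  when they are themselves the error — facts must constrain their
  neighbours for the contradiction to surface somewhere.

**Conflicts.** When facts are contradictory, some individual's candidate
set empties. That individual is marked `conflicted`, its set is reset to
the subset of its initial set compatible with its own parents' current
sets (its initial set if even that is empty), and it is exempted from
further deletion. Anchoring the reset to the parental side is deliberate:
the silent intermediate then *carries its ancestors' story downward*, and
its observed descendants — not the intermediate itself — fail to reconcile
and get flagged. A fully lenient reset (to all legal genotypes) was
rejected because it absorbs the contradiction: children of a wholly
ungenotyped generation could then never be flagged, and the
checker would go blind exactly in the datasets (50–100% erased
generations) where inference matters most. The exactness guarantee above is
claimed only for conflict-free data; conflicted individuals are reported as
such.

Candidate sets render back to the partially resolved labels used in
single-marker displays: `C/T`, `T/?`, `-/?`, or the bracketed multi-allelic
forms such as `[A or T]/[A or C or T]` (smallest covering slot pair,
smaller slot printed first, ties broken lexicographically).

## The error taxonomy

Every fully observed call of every non-founder is classified against the
**transmissible allele sets** of its parents' candidate sets (absent
parents contribute the full legal set; an x-linked sire transmits his X to
daughters and the Y-null to sons, a z-linked dam mirrors this):

* `nil_from_sire` — no child allele is in the sire's transmissible set;
* `nil_from_dam` — no child allele is in the dam's transmissible set;
* `novel_allele` — some child allele is in neither set.

Six of the eight flag combinations are attainable; "nil from both parents
but no novel allele" is logically impossible (if no allele matches either
side, every allele is novel), and the suite fuzzes this invariant.
Founders and cells that are missing or partial are never flagged: *a
genotype cannot be both inferred and incorrect*. One consequence worth
spelling out: errors are reported as low down the pedigree as the observed
data allows, so with an erased generation the flags appear in the
generation below the actual mistake.

Counts aggregate per individual, per marker and per family (family counts
are sums over members), together with incompleteness fractions. Severity
is binned to four levels — 0 for zero, then thirds of the view maximum —
because displays need a small ordinal palette, not raw counts; any
monotone four-level scheme would do, and the choice is isolated in
`severity_bin()`.

Markers are independent throughout: each marker's result depends only on
its own column, fully observed columns skip the (trivial) fixpoint
iteration through a vectorized path, and a ~100,000-marker dataset is
simply 100,000 independent single-marker problems.

## The simulator and what it does (not) emulate

`sim_pedigree()` generates breeding designs with controlled generations,
families per generation and family sizes; sires take roughly two partners
each, future breeders are designated interleaved across families (so both
full-sib and paternal half-sib breeder pairs exist) and force-sexed, and a
configurable fraction of non-breeders is left unsexed. `chicken_pedigree()`
reproduces the composition of a real anonymized chicken F2 population
(28♂+48♀ founders, 16♂+102♀ F1, 1598 all-female F2; 1792 in all) that sets
the shape — a heavily female-skewed final generation — many scenario tests
assume.

`gene_drop()` seeds each of seven marker templates a configurable number of
times (7, 70 or 350 markers for 1, 10, 50 copies): five autosomal C/T
markers with founder C:T ratios 1:1 … 1:5, plus one x-linked (Y-null) and
one z-linked (W-null) template. The ratio `1:k` is applied as founder
allele frequencies, `P(C) = 1/(1+k)`, so drawn allele counts approximate
the stated ratio; founder draws are binomial and non-founders receive one
allele per parent by fair draw under the linkage rules. Output is
consistent by construction — the suite checks zero flags across a hundred
random designs. `erase_generation()` removes an exact count
(`round(fraction × cells)`) of a generation's cells rather than flipping a
per-cell coin, so completeness fractions are deterministic.

The injection catalogue implements 11 pedigree corruptions (re-assigning
sires, dams or both for individuals, families, litters and whole sire-sib
sets, plus sex flips) and 14 genotype corruptions (copying, swapping and
randomizing calls; re-genotyping groups from a simulated "novel father";
scoring a sex-linked marker as homozygous; and identity swaps at four
relatedness levels). Every injection returns a ground-truth record whose
inverse restores the input exactly. Two interpretation choices: "some
genotypes" defaults to a 0.5 fraction (no fraction is canonical), and the
sex-linked-as-homozygous category also relabels the marker autosomal,
because the scenario it models is an *unrecognized* sex-linked marker — the
relabel is what produces its signature pattern of nil-from-sire flags
confined to hemizygous-sex individuals.

What the simulator does **not** emulate: linkage between markers,
recombination and genetic maps, mutation, genotyping-error rates with
realistic per-assay structure, or population-genetic allele-frequency
spectra. Passing the scenario suite therefore shows that the *engine*
exposes each error class with the expected spatial pattern; it does not
certify performance on real data where errors overlap and interfere.

## Scenario manifests

Each packaged scenario pairs an injected dataset with a machine-checkable
predicate over the resulting report — set containment over flagged
individuals rather than exact counts, because flag counts depend on the
random allele draws. The headline displacement trio re-assigns two breeding
full sisters to a wrong sire and checks: with complete data, flags exactly
at the sisters; at 50% F1 erasure, flags confined to the sisters and their
offspring; at 100% erasure, no F1 flags at all and the errors pushed down
to the sisters' F2 offspring. The sex-flip scenario must instead be caught
at validation (a breeding sire recorded female is a structural error, not
an inheritance error).

## Layout model

`build_layout()` emits the sandwich view as a structural document: one
sandwich per consecutive generation pair, sires on top, dams below,
children between, families read vertically; a parent with k families in a
sandwich appears k times joined by k−1 arcs. Offspring cells carry a
hexagon glyph state — sire-pointing tip, dam-pointing tip and mid-stripe
leveled by the three error counts — plus an incompleteness level (absolute
thirds of [0, 1], a fixed scale so the same fraction always shows the same
shade). Offspring can be split into male / unknown / female sub-rows, and
an optional focal marker switches cells to the mutually exclusive
error / inferred / clean states with rendered genotype labels. Cells
narrower than a pixel threshold are marked `label_suppressed` rather than
judged readable. Exports are JSON (round-trips structurally) and
deterministic static SVG. Interactivity — tooltips, cross-highlighting,
zooming, preference persistence — is explicitly out of scope, so every
display claim is restated as an assertion on this structure.

## Numerical and scale choices

* Family sweep order is sorted by (sire, dam) key: the fixpoint is
  order-independent, but the order pins down `pass_count` and makes runs
  bit-reproducible.
* All randomness (simulation, erasure, injection target choice) is
  seed-scoped; identical inputs give byte-identical outputs on any
  platform.
* Test problem sizes: oracle equivalence uses 200 pedigrees of ≤ 8
  individuals (kept small so brute-force enumeration stays exact and
  fast); clean-by-construction uses 100 designs of 100–500 individuals at
  70 markers; the scale check runs 97 individuals × 100,002 markers
  (2 × 7 × 14,286 template copies) and completes in well under a minute on
  one CPU, reporting wall-clock and memory rather than asserting them.

## Limitations

* Genotype elimination is exact only on loop-free pedigrees; inbreeding
  loops are handled by the conflict-reset rule but without the exactness
  guarantee (no loop-breaking search is attempted).
* No probabilistic imputation or phasing: candidate sets are possibilistic,
  so a single surviving wrong candidate suppresses a flag that a
  likelihood-based method might still raise.
* Error *sites* are observed child genotypes; parent-row colour in the
  layout derives from flags on their own child-role cells and their
  offspring's cells, an interpretation rather than a second primary flag.
* Data cleaning (masking bad cells and re-checking) is out of scope here;
  the report and ground-truth structures are designed so such a loop can be
  layered on top.
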