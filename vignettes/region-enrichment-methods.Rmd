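---
title: "Mapping lysine acetylation onto membrane-interaction regions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping lysine acetylation onto membrane-interaction regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirenrich)
```

## The question the package addresses

Peripheral membrane proteins dock onto bilayers through dedicated
membrane-binding domains — BAR, PX, C2 and EHD domains are four
structurally well-characterized families. Binding is largely
electrostatic: lysine and arginine side chains on the membrane-facing
surface contact negatively charged lipids. Lysine acetylation removes a
lysine's positive charge, so an acetylation site that falls on the
membrane-binding surface is positioned to switch membrane affinity off.

`mirenrich` asks, quantitatively: *are acetylation sites enriched in the
membrane-interaction region (MIR) of these domains relative to the rest of
the domain (the non-binding region, NBR)?* The package takes curated MIR
definitions on template domains, transfers them to homologous family
members by sequence or structural alignment, intersects the transferred
regions with an acetylation-site table, and reports region-wise enrichment
statistics.

## The statistics

For each region $r \in \{\mathrm{MIR}, \mathrm{NBR}\}$ of a domain we
tally the residue count $N_r$, the lysine count $K_r$ and the
acetyl-lysine count $K^{AC}_r$, and form two frequencies:

* per residue: $\%K_{AC}(r) = 100 \cdot K^{AC}_r / N_r$ — sensitive to
  lysine composition;
* per lysine: $\%K_{AC}/K(r) = 100 \cdot K^{AC}_r / K_r$ — controls for
  the fact that MIRs are themselves lysine-rich.

The enrichment ratio divides the MIR value by the NBR value; a ratio above
one means acetylation favours the membrane-binding surface. Ratios with a
zero NBR denominator are flagged undefined and excluded from pooled
summaries (the count of exclusions is reported) rather than imputed.
Family summaries pool raw counts across domains *before* normalizing, so
large domains weigh more than small ones; this is deliberate — the
alternative (averaging per-domain ratios) is dominated by small-count
noise. Each domain is also classified by where its sites fall: majority
(MIR vs NBR, by raw counts, ties reported separately) and exclusivity
(all sites in one region). Raw counts rather than frequencies decide the
majority; a frequency-based variant would reclassify domains whose regions
differ greatly in size, and is intentionally not the default.

Printed-precision comparisons use half-away-from-zero decimal rounding
(`round_half_up()`); IEEE banker's rounding would turn 2.05 into 2.0 and
break agreement with conventionally rounded published tables.

## Annotation transfer

Templates are family members whose MIR is known from direct experiment;
their MIR intervals arrive as a curated config (1-based, closed intervals,
declared explicitly in every file header). Other members receive their
annotation through an alignment to the template:

* **Sequence path** — global Needleman–Wunsch alignment with affine gaps
  (BLOSUM62, gap open 10, gap extend 0.5; the EMBOSS NEEDLE protein
  defaults). A gap run of length $L$ costs $\mathrm{open} + \mathrm{ext}
  \cdot L$ and end gaps are penalized. Traceback ties are broken
  deterministically (aligned pair, then gap in the second sequence, then
  gap in the first), so identical inputs always give byte-identical
  output.
* **Structural path** — preferred whenever both records carry Cα
  coordinates. A sequence alignment of the structure-derived sequences
  seeds the correspondence, a Kabsch superposition fits it, pairs with a
  residual above 5 Å are dropped, and the fit is repeated once on the
  survivors. Fewer than 20 surviving pairs is treated as failure rather
  than returning an unreliable map. The 5 Å cutoff and single refinement
  round mirror common superposition-refinement practice; both are
  parameters of `align_params()`.
* **Segment-wise path** — some domains (kinked F-BARs) are two rigid
  bodies joined by a hinge and superpose poorly as a whole. When a
  template declares kink segments, each segment is aligned independently
  and the maps concatenated; later pairs that would break strict
  monotonicity are dropped.

A target residue aligned to a template MIR residue becomes MIR; aligned to
NBR, NBR. Insertions (target residues with no template partner) become MIR
only when **both** nearest aligned flanking residues are MIR: an insertion
inside a membrane-binding surface most plausibly stays on that surface,
while an insertion at a region boundary defaults to the conservative NBR
label. This rule is the largest open choice in the procedure, so the
per-residue provenance (aligned vs insertion) is attached to every
transferred annotation for audit. The target's analysis range is the span
of mapped positions — curated ranges, when present in the config, take
precedence.

### Filters

Members under 50% sequence identity to their template cluster are excluded
(`cluster_by_identity()`; single-linkage by default, so a member may join
through an intermediate, with a template-only mode behind a switch because
the choice is genuinely open). C2 family members are assigned to a
C2A-like or C2B-like template by percent similarity; below 50% similarity
to both they are flagged degenerate and excluded. Similarity counts
alignment columns with a positive substitution score over all columns
between the first and last aligned pair, identity counts exact matches
over the same denominator — terminal overhangs are excluded so a short
construct aligned inside a long full-length sequence is not penalized for
length difference.

### N-terminal amphipathic helices

N-BAR domains carry an N-terminal amphipathic helix (H0) that inserts
into the membrane in situ but is usually unresolved in crystal structures;
it belongs in the MIR. Curated H0 intervals in the region config are the
primary path. When none is given, `detect_nterm_helix()` scans the
sequence upstream of the domain with an 11-residue sliding window of the
mean hydrophobic moment (Eisenberg consensus scale, 100°/residue) and
returns the maximal run of windows with $\mu_H \ge 0.25$. This is a
deliberately simple screen: it captures strongly amphipathic stretches
and ignores marginal ones, and its window, threshold and twist are all
exposed. A basic-residue density helper (`region_charge_density()`)
supports sanity-checking MIR definitions, which in these families should
be visibly K/R-enriched.

## Site mapping

Acetylation-site tables (protein id, 1-based position, residue,
modification) are deduplicated on (protein, position). A site whose stated
residue disagrees with the sequence, or that lands on a non-lysine, is
quarantined with a reason — never silently dropped — and sites outside the
domain range are tallied separately, so for every protein
`in-domain + outside + quarantined = input rows` holds exactly. An
optional `min_evidence` column passes through unfiltered by default,
since no evidence-count filter is part of the core procedure.

## Boundary sensitivity and significance

Because curated MIR boundaries carry uncertainty, `sensitivity_sweep()`
re-runs the whole tally with every MIR interval expanded or contracted by
1–2 residues (grown intervals merge, collapsed ones vanish, everything is
clipped to the domain). The delta-0 row is bit-identical to the base run
by construction. Deltas beyond ±2 error by default; the ±2 band is the
validated range of this control.

`permutation_enrichment_test()` is an optional audit: under the null the
observed number of acetyl-lysines is reassigned uniformly among the
domain's lysines, the statistic is the MIR acetyl count, and the one-sided
p-value uses add-one smoothing. On a two-region domain this null is
exactly hypergeometric, which the tests exploit as an oracle. When run
across many domains, Benjamini–Hochberg adjustment is available but off by
default, as no significance testing is part of the core procedure.

## The synthetic generator

Real inputs for this analysis are a PhosphoSitePlus-style export and PDB
structures, neither of which ships with the package. The generator
(`synthetic_family_spec()`, `generate_family()`, `emit_bundle()`) creates
families whose ground truth is known, so every stage is testable offline:

* **Template**: i.i.d. sequence with a target lysine fraction (default
  0.12, the composition regime of lysine-rich membrane-binding domains),
  default length 250 (a typical domain size in these families), with
  three planted MIR intervals covering ~26% of the domain — comparable to
  curated MIR fractions. Optional toy Cα coordinates trace an ideal helix
  with exact 3.8 Å consecutive spacing; they exercise the superposition
  and segment logic without claiming realistic folds.
* **Homologs**: point substitutions plus single-residue indels (default
  rate 0.02/residue) retried with an adapted substitution rate until the
  identity measured by `global_align()` lands within ±3 points of the
  target. Ground-truth labels ride along through every edit under the
  same insertion rule the transfer uses.
* **Sites**: every MIR lysine is acetylated independently with probability
  `base_rate * rho`, every NBR lysine with `base_rate` (defaults 0.15 and
   5). `rho` is the planted enrichment the pipeline should recover;
  `rho = 1` is the null.

Each generator operation derives its RNG stream deterministically from
the spec seed (template, per-homolog and site-planting draws use distinct
fixed offsets), so bundles are byte-identical across runs and individual
members are reproducible in isolation.

What the generator does **not** emulate: real fold geometry, covariation
and conserved motifs within families, database biases of acetylome
coverage (cell type, abundance, detectability), and clustering of sites
around specific binding pockets. Passing the recovery tests therefore
shows the machinery is correct and unbiased under the planted model — it
does not by itself validate conclusions about any particular real
proteome snapshot.

## Validation and problem sizes

The test suite checks, among others:

* alignment score and traceback against exhaustive enumeration of all
  global alignments on random short pairs, and score agreement with an
  independent alignment implementation on longer random pairs;
* Kabsch RMSD against direct numerical minimization over rotations,
  zero RMSD on rigid copies, invariance under common rigid transforms,
  determinant +1 always;
* partition/conservation invariants (MIR ∪ NBR = domain, site
  bookkeeping) on 1,000 randomized domains;
* transfer idempotence through an identity alignment and ≥95% pooled
  recovery of planted MIR residues at 60% identity;
* recovery of planted ρ ∈ {1, 2, 5} by the pooled per-lysine ratio within
  two standard errors over 20 seeds (50 domains × 250 residues each), and
  absence of systematic MIR bias at ρ = 1 against a permutation null band;
* agreement of the permutation p-value with the exact hypergeometric tail
  on all small two-region toys;
* bit-identity of the sweep's delta-0 row with the base run, and
  persistence of planted enrichment across all deltas.

These sizes (50 domains of ~250 residues, 20 seeds) were chosen to give
the recovery checks a standard error well under the effect sizes probed
while keeping a full run of suite plus acceptance script in single-digit
minutes on one core.

## Known limitations

* Pairwise template alignment replaces a progressive multiple alignment:
  annotation transfer only needs the template↔member correspondence, and
  pairwise alignment is exactly specifiable and oracle-testable. Members
  aligned through different templates are never compared column-wise.
* The structural path is rigid (plus the segment-wise variant); no
  flexible alignment.
* H0 detection is a single-scale hydrophobic-moment screen, not a full
  interfacial-hydrophobicity analysis; curated intervals should be
  preferred when available.
* The homology filter operates on percent identity of a pairwise
  alignment; profile or HMM-based homology detection is out of scope.
* The generator's identity targeting is approximate (±3 points) and its
  indel model is single-residue only.
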