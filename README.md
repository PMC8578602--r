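# mirenrich

Region-wise enrichment of lysine acetylation in peripheral membrane-binding
domains.

## The problem

Peripheral membrane proteins bind bilayers through dedicated domains — the
BAR, PX, C2 and EHD families are classic examples — and the binding is
largely carried by lysine/arginine contacts with negatively charged lipids.
Acetylation neutralizes a lysine's charge, so acetylation sites that fall on
the membrane-binding surface are positioned to regulate membrane binding.
`mirenrich` quantifies whether acetylation sites are enriched in the
**membrane-interaction region (MIR)** of a domain relative to its complement,
the **non-binding region (NBR)**.

Curated MIR definitions exist only for a few well-studied template domains.
The package transfers them to homologous family members by global sequence
alignment (Needleman–Wunsch, affine gaps, EMBOSS-NEEDLE-style defaults) or —
preferred when coordinates are available — by Cα structural alignment (Kabsch
superposition with residual-based pair filtering, segment-wise across
declared kinks). Acetylation-site tables are then mapped onto the transferred
regions and tallied.

For each region $r$ with $N_r$ residues, $K_r$ lysines and $K^{AC}_r$
acetyl-lysines it reports

- $\%K_{AC}(r) = 100\,K^{AC}_r / N_r$ (per residue),
- $\%K_{AC}/K(r) = 100\,K^{AC}_r / K_r$ (per lysine, controls for lysine
  abundance),

their MIR/NBR **enrichment ratios**, per-domain classifications
(MIR-majority / MIR-only / ties), family summaries pooled over raw counts,
a ±2-residue boundary-sensitivity sweep, and an optional permutation test of
MIR enrichment. A synthetic-family generator with planted region-biased
acetylation rates makes the whole pipeline testable offline, with known
ground truth.

Intended users: structural bioinformaticians and PTM researchers who have a
site table (e.g. a PhosphoSitePlus-style export), FASTA sequences, optional
PDB/mmCIF structures, and curated template region definitions.

## Worked example

Generate a small synthetic bundle with a 5-fold planted MIR:NBR acetylation
rate ratio and run the full pipeline on it:

```r
library(mirenrich)

dir <- file.path(tempdir(), "demo")
specs <- list(
  synthetic_family_spec(family = "BAR", n_domains = 6, domain_length = 200,
                        rho = 5, base_rate = 0.15, seed = 42,
                        with_structure = TRUE),
  synthetic_family_spec(family = "PX", n_domains = 5, domain_length = 150,
                        mir_intervals = intervals(c(30, 90), c(55, 115)),
                        rho = 5, base_rate = 0.15, seed = 43))
emit_bundle(specs, dir)

res <- run_pipeline(file.path(dir, "config.yaml"))
res$family_summary[, c("family", "n_domains", "mir_ack", "nbr_ack",
                       "pct_kac_per_k_mir", "pct_kac_per_k_nbr",
                       "ratio_kac_per_k", "fraction_mir_majority",
                       "fraction_mir_only")]
```

```
  family n_domains mir_ack nbr_ack pct_kac_per_k_mir pct_kac_per_k_nbr
     BAR         6      17       9              65.4              11.4
      PX         5      30      10              75.0              23.3
 Average        11      47      19              71.2              15.6
 ratio_kac_per_k fraction_mir_majority fraction_mir_only
            5.74                 0.833             0.000
            3.23                 0.800             0.400
            4.57                 0.818             0.182
```

Reading the `Average` row: across the 11 domains, 47 acetyl-lysines fall in
MIRs and 19 in NBRs; 71.2% of MIR lysines are acetylated versus 15.6% of NBR
lysines, a pooled per-lysine enrichment ratio of 4.6 (the planted ratio is 5;
pooling noise and transfer at ~70% identity account for the difference).
81.8% of domains have most of their acetylation in the MIR. The BAR family
ran through the structural path (toy Cα traces are emitted for it), PX
through the sequence path; `res$per_domain$path` records the choice per
domain, and `manifest.json` in the output directory records every per-domain
decision, exclusion and failure.

Per-domain objects support the optional significance audit:

```r
cts <- res$analyzed[["BAR_1"]]$counts
cts
#>     n_residues n_lysines n_ack region
#> MIR         63         3     2    MIR
#> NBR        139         8     1    NBR
permutation_enrichment_test(cts, n_perm = 10000, seed = 1)$p_value
#> [1] 0.1504
```

A thin CLI over the same functions lives at `inst/cli/mirenrich.R`
(`run`, `simulate`, `sweep`, `validate-config` subcommands).

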