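---
title: "Methods: tiered protein allergenicity screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiered protein allergenicity screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allerscreen)
```

## The problem and the model

Proteins intended for consumer products are screened for the risk of
triggering an IgE-mediated (Type I) allergic response. The classical
computational criteria — any shared hexamer with a known allergen, or 35%
identity over an 80-residue window — are extremely sensitive but flag a
large fraction of harmless proteins. `allerscreen` implements a tiered
cascade that keeps the sensitivity-first safety rationale while attacking
the two main sources of false positives: random short-peptide matches and
fold-level similarity without surface similarity.

Each query receives one of three verdicts — **strong**, **weak** or **no
evidence** of allergenic potential — from the first of four stages that
fires:

1. **Gluten-like Q-repeat fingerprint** (strong). A composition-only
   log-odds score over 9-residue windows, trained on Celiac-associated
   peptides. Evaluated first because these low-complexity repeats are
   deliberately removed from the hexamer stage (stage 4) by the entropy
   filter, and they matter clinically regardless of any other similarity.
2. **3D surface-epitope similarity** (strong or weak). If the query has a
   significant local-alignment hit (E < 0.001) among structure
   representatives of the allergen database, the query and its best
   allergen hit are mapped onto that representative and compared over
   every epitope-sized surface patch. Identity ≥ 93% on the best patch is
   strong evidence; any fold-level hit below that is weak evidence.
3. **Linear 80-residue window** (strong). The classical FAO/WHO rule,
   applied when no structure representative matches: ≥ 35% identity over
   an 80-column window of the global alignment with any known allergen.
4. **Entropy-filtered triple-hexamer rule** (weak). At least three
   distinct shared hexamers with one allergen, after removing hexamers
   containing ambiguity codes (B, J, O, U, X, Z) and hexamers with
   composition entropy < 0.34 bits. Three consecutive hexamer hits span
   exactly eight shared residues, making this a relaxed 8-mer match.

If no stage fires the verdict is *no evidence*. Earlier stages shadow
later ones, so a fold-level (weak) epitope call deliberately suppresses a
would-be linear-window hit: the 3D comparison is considered the more
relevant signal where a structure exists.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `entropy_min` | 0.34 bits | minimum hexamer composition entropy |
| `kmer_min_hits` | 3 | distinct shared hexamers required |
| `qrepeat_window` | 9 residues | fingerprint window |
| `qrepeat_sd_multiplier` | 1 | hit threshold = training mean − k·SD |
| `probe` | 1.4 Å | solvent probe radius |
| `surface_cutoff` | 2.55 Å | residue-to-surface distance for "surface" |
| `epitope_radius` | 12 Å | patch radius around each center residue |
| `epitope_min_size` | 13 residues | minimum patch size |
| `e_max` | 0.001 | E-value cutoff for similarity searches |
| `epitope_strong_identity` | 0.93 | strong-evidence epitope identity |
| `window_len` / `window_min_identity` | 80 / 0.35 | linear-window rule |
| `cluster_identity` | 0.70 | reference clustering identity |
| `max_batch` | 50 | batch size limit |
| `min_query_len` | 8 residues | minimum evaluable query length |

All of these are fields of `workflow_config()` and can be overridden from
a flat `key = value` file (`read_workflow_config()`).

Notes on the defaults:

* **0.34 bits** is applied to the raw (not length-normalized) base-2
  entropy of the hexamer's residue composition. For hexamers the only
  achievable entropy below 0.34 is exactly 0 (homopolymers); the
  next-lowest composition (5+1 of two residues) already has ≈ 0.65 bits.
  The filter's effective reach at k = 6 is therefore precisely the
  homopolymer repeats — users changing `kmer_k` should re-derive the
  threshold's meaning.
* **min_query_len = 8** is this package's own floor: eight residues is
  the span of three consecutive hexamer hits, and reference workflows
  report ultra-short entries (length 5) as "too short to be evaluated".
  Without a floor the linear-window rule (which treats a short alignment
  as a single window) would let any sequence self-match, which is not a
  meaningful assessment. Queries under the floor return *no evidence*
  with an explanatory note rather than an error, so batches never die on
  a stray peptide.
* **One-sided Q-repeat threshold.** "Within one standard deviation of the
  training average" is implemented as `score ≥ mean − 1·SD`: windows
  scoring *above* the training mean are the strongest possible signal and
  must not be excluded by a two-sided band. The multiplier is
  configurable.

## Numerical and algorithmic choices

**Alignment.** All pairwise alignment is Needleman–Wunsch (global, with
end-gap penalties) or Smith–Waterman (local) under BLOSUM62 with affine
gap cost 11 + 1·L, delegated to `Biostrings::pairwiseAlignment`, which is
deterministic. Significance of local hits uses the Karlin–Altschul
formula `E = K·m·n·exp(−λS)` with the published gapped BLOSUM62 constants
λ = 0.267, K = 0.041 and the pairwise lengths `m`, `n`. Unlike BLASTP no
database-size correction is applied: E-values near the 0.001 cutoff can
therefore differ from BLASTP's, and the effective hit set near the
boundary with it. Residues J, O and U, which have no BLOSUM62 row, are
treated as X inside the aligner only.

**Identity definitions.** Clustering identity and linear-window identity
both count identical columns with gap columns in the denominator
(conservative). Epitope identity divides by the *full* epitope size, so
surface regions that fail to align dilute identity — again conservative
for the ≥ 93% strong-evidence call. Ties in the best epitope are broken
by larger patch, then smaller center index; ties in best windows are
leftmost; tied hit rankings are broken by target id.

**Surface geometry.** The solvent-accessible surface is a Shrake–Rupley
style point cloud: a deterministic Fibonacci-spiral point set (no RNG) on
each atom's probe-expanded sphere, filtered against all overlapping
neighbour spheres. A residue's surface distance is the minimum over its
atoms of (distance to the nearest surviving surface point − the atom's
van der Waals radius), so a fully exposed atom sits exactly one probe
radius (1.4 Å) from the surface and the 2.55 Å cutoff classifies it as
surface. The 12 Å patch membership uses minimum heavy-atom distance
between residues (not CA–CA), matching the antibody-interface rationale
for the radius; both choices are configurable. Sphere sampling density
(default 256 points/atom) is validated by convergence tests: doubling the
density changes no surface flag on the fixtures.

**Window-rule edge cases.** The 80-residue window slides over alignment
columns; alignments shorter than 80 columns are evaluated as a single
window, which lets short known allergens self-match. A caution for
property-minded users: the intuitive claim "best window identity ≥
overall identity" is false in general — matches concentrated in the first
or last `w − 1` columns are covered by fewer windows. The exact
pigeonhole statement, which the test suite asserts, is
`best window matches ≥ total matches / ceiling(L / w)`.

**Window-scan implementation.** The database-wide window scan does not
materialize aligned strings (which dominates runtime at reference-set
scale); it reconstructs the alignment-column positions of identical
residue pairs from the alignment's compact representation (aligned
ranges, indel ranges, mismatch table) and slides the window over match
positions. The test suite asserts exact agreement with the literal
padded-string column scan on randomized gappy alignments.

**Greedy clustering.** Reference clustering is cd-hit-like greedy
incremental clustering (longest first, first-founded cluster wins ties)
but uses exact global alignment identity instead of word-count screens;
at desk-scale database sizes exactness is affordable and removes a
heuristic parameter. Published cd-hit cluster counts will therefore not
be reproduced exactly.

## The synthetic data, and what a green test establishes

The fixture generators (`make_synthetic_db()`, `mutate_homolog()`,
`reverse_db()`, `make_helix_structure()`, `make_qrich_peptides()`) are
seed-deterministic and emit standard formats (FASTA, PDB, plain peptide
lists). They emulate:

* i.i.d. sequences from a UniProt-like residue composition (or any
  supplied table) — realistic composition, no domain structure, no
  homologous families beyond the explicitly derived `mutate_homolog()`
  mutants;
* reversed-sequence negative controls, which preserve length and
  composition while destroying natural order — the cheap stand-in for a
  non-allergen proteome when measuring false-positive rates;
* idealized α-helix structures (1.5 Å rise, 100° twist, backbone plus one
  pseudo-side-chain atom), which exercise every geometric code path
  (surface detection, patch enumeration, PDB round trips) but are *thin*:
  every residue is solvent accessible, so buried-core behaviour is tested
  with a purpose-built dense-shell fixture instead;
* Q/P-enriched training peptides standing in for the Celiac peptide set.

A green suite therefore establishes internal correctness (each rule
agrees with independent brute-force oracles), the cascade's decision
logic, and the *directional* benchmark property that the entropy-filtered
triple-hexamer rule yields a false-positive rate on reversed controls no
higher than the classical single-hit rule at near-equal recall on 90%
homologs. It does **not** establish the published headline accuracies of
any reference implementation: those depend on curated allergen databases,
homology-modelled structure sets and benchmark lists that are not
reproducible offline at desk scale. No numeric acceptance targets are
defined for this package for exactly that reason.

## Known limitations

* Structures are consumed as ready-made single-chain PDB files; homology
  modelling, model quality control and mmCIF input are out of scope.
* E-values are per-pair Karlin–Altschul estimates, not BLASTP
  database-corrected values; hit sets near `e_max` may differ.
* The Q-repeat model ships with defaults (pseudocount 0.5/N, base-2
  logs, one-sided threshold, bundled UniProt-like background) that the
  original description leaves open; all four are configurable.
* Whether the historical FAO/WHO window slid over ungapped query windows
  or alignment columns is ambiguous; alignment columns are used here.
* `greedy_cluster()` membership near the identity threshold depends on
  alignment parameters and will not exactly match word-based tools.
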