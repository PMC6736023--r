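# allerscreen

Tiered screening of proteins for allergenic potential, from sequence (and,
where available, 3D structure) similarity to a reference set of known
allergens.

## Who this is for

Safety assessors and bioinformaticians who need a conservative,
reproducible desk assessment of whether a novel protein resembles known
IgE-binding allergens — without web services, external aligners or
reference downloads. Every rule is implemented in-process and every input
can be generated synthetically for testing.

## The method

Each query receives **strong**, **weak** or **no evidence** of allergenic
potential from the first stage of a fixed cascade that fires:

1. **Gluten-like Q-repeat** (strong): a composition-only log-odds
   fingerprint over 9-mers, `score(w) = Σ_a n_a(w)·log2(f_a/b_a)`, trained
   on Celiac-associated peptides; a hit is any window scoring at least
   `mean − 1·SD` of the training windows. Evaluated first because the
   hexamer stage's low-complexity filter deliberately discards these
   repeats.
2. **3D surface-epitope similarity** (strong/weak): if the query matches a
   structure representative (Smith–Waterman, Karlin–Altschul
   `E = K·m·n·e^{−λS} < 0.001`), query and best allergen hit are mapped
   onto that structure and compared over every surface patch (surface =
   residues < 2.55 Å from the solvent-accessible surface; patch = surface
   residues within 12 Å of a center, ≥ 13 residues). Best-patch identity
   ≥ 93% ⇒ strong, otherwise weak (same fold).
3. **FAO/WHO linear window** (strong): ≥ 35% identity over an 80-column
   window of the global alignment against any known allergen.
4. **Triple-hexamer rule** (weak): ≥ 3 distinct shared 6-mers with one
   allergen, after removing 6-mers with ambiguity codes (BJOUXZ) or
   composition entropy < 0.34 bits (`H = −Σ f·log2 f`).

The package also provides the supporting infrastructure: FASTA and PDB
IO, 100%-identity merge/dedup of allergen databases, cd-hit-style greedy
clustering at 70% identity, a Shrake–Rupley style surface computation,
and seed-deterministic synthetic fixtures (sequence sets, homologs at a
target identity, reversed-sequence negative controls, idealized helix
structures, Q/P-rich training peptides).

## Worked example

```r
library(allerscreen)

dir <- "demo_bundle"
make_fixture_bundle(dir, seed = 42)         # writes FASTA/PDB/JSON fixtures
refs    <- load_fixture_bundle(dir)         # 20 allergens, 5 structures
queries <- read_fasta(file.path(dir, "queries.fasta"))
calls   <- run_batch(queries, refs, out = file.path(dir, "calls.csv"))
calls[, c("query_id", "evidence", "basis", "best_allergen",
          "epitope_identity", "notes")]
```

```
   query_id evidence     basis best_allergen epitope_identity
1 homolog_q   strong epitope3d        alg001                1
2 qrepeat_q   strong   qrepeat                             NA
3  random_q     none      none                             NA
                                         notes
1      epitope center 9 size 17 (17 identical)
2 Q-repeat window QPPQQQQQQ at 31 (31.52 bits)
3
```

Reading the output: `homolog_q` (a 95% homolog of allergen `alg001`,
which has a structure) matches the structure representative and shows a
17-residue surface patch with all 17 residues identical between query and
allergen — identity 1.0 ≥ 0.93, hence strong evidence via the 3D stage.
`qrepeat_q` carries a glutamine/proline repeat: its best 9-mer scores
31.5 bits, above the training threshold, so it is strong evidence by the
Q-repeat rule no matter what the other stages would say. `random_q`
matches nothing at any stage: no evidence.

The Q-repeat model and the reference clustering can be inspected
directly:

```r
refs$qrepeat_model
#> QRepeatModel: window 9, 665 training window(s), mean 20.99, sd 7.03 bits
#>   top log-odds: Q=3.77, P=2.56, C=-0.77
greedy_cluster(refs$allergens, 0.70)
#> ClusterSet: 20 cluster(s) at >= 70% identity
```

All thresholds live in `workflow_config()` and can be overridden there or
from a `key = value` file. A command-line interface with the same
functionality is installed as `exec/allerscreen` (subcommands `assess`,
`build-index`, `build-epitopes`, `train-qrepeat`, `self-screen`,
`make-fixtures`).

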