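# capscore

Computer-aided pattern scoring for ligand-based virtual screening at
sparsely annotated ("orphan") targets.

Most disease-relevant proteins have no known ligands to seed a screening
campaign. This package implements the pattern-scoring strategy developed
for one such target, the cholesterol efflux transporter ABCA1: collect
every compound with any evidence of interaction with the target family
into a curated multitarget dataset (a *direct* group of proven/strongly
suggested interactors and an *inconclusive* group), dissect the dataset
into a catalog of substructure patterns, measure each pattern's occurrence
per group, extract a rule-defined focused fingerprint, and use it to
filter and score a large screening library.

## The model

Patterns are SMILES-like strings that may carry defined-hydrogen tokens
(`[H]`, the mapped position must bear a hydrogen) and attachment points
(`[R]`, not counted as an atom). For a pattern *p* and compound group *g*,

```
pct_g(p) = 100 x |{ m in g : p ⊆ m }| / |g|
```

with presence-only, stereo-blind matching (⊆ is substructure containment).
The fingerprint has four components, all thresholds inclusive:

* **Primary Positive**: `pct_direct >= 40` — used as a conjunctive library
  filter (every hit must contain every primary pattern);
* **4-Atom-focused**: `pct_all >= 20`, at least 4 counted atoms (defined H
  counts, `[R]` does not) and at least 2 distinct elements — the
  per-molecule count of these patterns is the score;
* **Basic Scaffolds**: heteroaromatic ring systems, frequency-blind;
* **Secondary Positive**: present in >= 5 inconclusive compounds under the
  same 4-atom scheme, disjoint from the rest — manual-triage support.

Candidates are ranked by score and triaged into scaffold classes
(pyrroles without indoles, pyridines without quinolines but with
isoquinolines, furans without benzofurans, ...) with inclusive score
windows. Two-concentration screens are summarized by threshold hit calling
(`mean + SEM >= 20%`) and closed-form IC50 estimation under the
three-parameter logistic `y = 100 / (1 + (IC50/x)^h)`, which two points
determine exactly.

SMILES parsing, canonicalization, SMARTS evaluation and descriptor
primitives are delegated to Open Babel through `ChemmineR`/`ChemmineOB`;
the pattern dialect, counting rules, extraction rules, scoring and the
two-point estimator are implemented here, and the matcher is cross-checked
in the tests against a brute-force subgraph-isomorphism oracle.

## Worked example

A deterministic synthetic study with known ground truth (40 direct + 10
inconclusive compounds, a 100-molecule library, five planted fragments):

```r
library(capscore)

planted <- data.frame(
  frag_id        = c("pyridine", "furan", "thiophene", "oxazole", "amide"),
  n_direct       = c(16L, 15L, 8L, 9L, 20L),
  n_inconclusive = c(0L,  0L,  2L, 0L,  4L),
  n_library      = c(60L, 45L, 30L, 15L, 70L))
study <- generateCompoundSet(
  fixtureSpec(seed = 1L, nDirect = 40L, nInconclusive = 10L,
              nLibrary = 100L, planted = planted))

tab <- collectivePatternAnalysis(study$catalog,
  study$set[compoundGroups(study$set) != "library"])
head(tab[, c("pattern_id", "count_all", "count_direct", "pct_all", "pct_direct")])
#>   pattern_id count_all count_direct pct_all pct_direct
#> 1      amide        24           20      48       50.0
#> 2   pyridine        16           16      32       40.0
#> 3      furan        15           15      30       37.5
#> 4  thiophene        10            8      20       20.0
#> 5    oxazole         9            9      18       22.5
#> 6   alkyne_d         0            0       0        0.0
```

Amide (50%) and pyridine (exactly 40%, the inclusive boundary) become
Primary Positive; furan (37.5%) does not. Pyridine, furan and thiophene
(20%, again the boundary) pass the 4-atom rule; oxazole at 18% does not,
but stays a Basic Scaffold because that rule never consults frequency:

```r
fp <- extractFingerprint(tab, study$catalog)
fp
#> FocusedFingerprint
#>   primary:        2 pattern(s)
#>   4-atom:         3 pattern(s)
#>   basic scaffold: 5 pattern(s)
#>   secondary:      0 pattern(s)

lib  <- study$set[compoundGroups(study$set) == "library"]
hits <- conjunctiveFilter(lib, study$catalog, requiredIds = primaryIds(fp))
length(hits)          # molecules containing both primary patterns
#> [1] 39

bm <- buildBinaryMatrix(hits, fp, study$catalog)
head(rankCandidates(bm), 3)   # score = number of 4-Atom patterns present
#>   compound_id score
#> 1    FIX_0052     3
#> 2    FIX_0065     3
#> 3    FIX_0085     3
```

Potency from a two-concentration screen (35% inhibition at 10 uM, 78% at
50 uM):

```r
estimateIC50TwoPoint(yLow = 35, yHigh = 78)
#>     ic50     hill flag
#> 1 16.966 1.171033   ok
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/capscore.R`
(`Rscript capscore.R run --config cfg.json --out-dir run/`).

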