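---
title: "Pattern scoring for ligand discovery at sparsely annotated targets"
author: "capscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern scoring for ligand discovery at sparsely annotated targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(capscore))
```

## The problem

Most disease-relevant proteins are "orphan targets": no intrinsic ligands,
substrates or modulators are known, so the structure-activity knowledge that
normally seeds a screening campaign does not exist. The cholesterol efflux
transporter ABCA1 is a canonical example — a handful of inhibitors, almost
none with quantified potency. `capscore` implements a ligand-based strategy
for exactly this situation: pool every compound with *any* evidence of
interaction with the target family, dissect that pool into substructure
patterns, learn which patterns are over-represented, and use them as a
conjunctive filter plus an additive score over a large vendor library.

The workflow has seven computational steps, each its own module surface:

1. **Curation** (`readCompounds`, `canonicalizeSmiles`, `deduplicate`) — a
   multitarget dataset of interactors split into a *direct* group
   (proven/strongly suggested direct interactors) and an *inconclusive*
   group.
2. **Catalog** (`parsePattern`, `enumerateSubstitutions`, `catalogDedup`)
   — substructure patterns in a SMILES dialect, extended by a heavy-atom
   substitution scheme.
3. **Collective pattern analysis** (`collectivePatternAnalysis`,
   `classifyActive`) — per-group presence counts and percentages.
4. **Fingerprint extraction** (`extractFingerprint`) — four rule-defined
   pattern sets.
5. **Screening** (`conjunctiveFilter`, `buildBinaryMatrix`,
   `rankCandidates`) — conjunctive filtering and binary pattern scoring.
6. **Selection** (`classSelect`, `summarizeSelection`) — scaffold-class
   triage; physicochemical annotation (`computeDescriptors`,
   `groupStatistics`).
7. **Biological validation bookkeeping** (`callHits`, `hitRate`,
   `estimateIC50TwoPoint`, `potencySummary`).

## The pattern dialect and its counting rule

Catalog patterns are SMILES-like strings with two extra tokens:

* `[H]` — a **defined (irreplaceable) hydrogen**: the mapped position must
  carry a hydrogen. `O[H]` is a free hydroxy; anisole does not match it.
* `[R]` — an **attachment point**: marks a bond to "the rest of the
  molecule" and never counts as an atom.

The counted-atom statistics that drive the extraction rules follow one
rule: heavy atoms **and** defined hydrogens count, attachment points do
not; distinct elements are counted over the counted atoms (hydrogen
included). So `O[H]` has 2 counted atoms and 2 elements, and
`[R]c1ccc(O[H])cc1` has 8 counted atoms and 3 elements.

```{r counting}
parsePattern("0044", "hydroxy-H, defined", "O[H]")[
  , c("counted_atoms", "defined_h", "distinct_elements")]
```

### Match semantics

Matching is **presence-only** (a pattern occurring twice counts once) and
**stereo-blind** (stereo descriptors of the molecule are ignored). Patterns
are translated to SMARTS and evaluated by Open Babel (via `ChemmineOB`), so
a single aromaticity and valence model applies to both the library
molecules and the patterns; aromatic/aliphatic distinctions in the catalog
are honored as written. Defined hydrogens become minimum H-count
constraints. The original study used a commercial query engine whose
perception model cannot be cloned; we fix one open model and apply it
consistently, which is why pattern-matching-dependent counts on external
data can differ slightly from published ones while all internal relations
(thresholds, monotonicity, score identities) are exact.

Two readings of `[R]` are defensible, and the sources do not define it. The
default (`rMatchesH = TRUE`) lets an attachment point be unsubstituted —
maximizing recall — while `rMatchesH = FALSE` requires a heavy-atom
substituent. The choice is fixed per catalog at parse time.

The matcher is continuously cross-checked in the test suite against an
independent brute-force subgraph-isomorphism oracle (exhaustive
backtracking over injective atom maps) on a panel of molecules and
patterns; agreement is required to be exact.

## The four extraction rules

With `n_all` compounds split into `n_direct` + `n_inconclusive`, and a
percentage defined as `100 x (compounds containing the pattern) / (group
size)`:

| Component | Rule | Default |
|---|---|---|
| Primary Positive | `pct_direct >= threshold` | 40% |
| 4-Atom-focused | `pct_all >= threshold` and `counted_atoms >= 4` and `distinct_elements >= 2` | 20% |
| Basic Scaffold | heteroaromatic ring present; frequency **not** consulted | — |
| Secondary Positive | `count_inconclusive >= 5`, same 4-atom scheme, disjoint from the other three | 5 |

All thresholds are inclusive ("at least"). Three numerical choices matter:

* The secondary rule is an **absolute count** (>= 5), not a percentage: the
  source equates "40%" of the 12-compound inconclusive group with 5
  compounds, although 40% of 12 is 4.8 — the printed count wins, because a
  percentage reading would silently change the rule for other group sizes.
* The 20% denominator of the 4-atom rule is the **full set** (the literal
  reading); `extractFourAtom(group = "direct")` switches to the direct
  group where a reproduction needs it.
* Percentages are carried at full precision; rounding is display-only, so
  no boundary decision can depend on formatting.

Ties are broken everywhere by descending statistic, then ascending pattern
id — outputs are byte-stable across runs.

A pattern may legitimately satisfy both the 4-Atom and the Basic Scaffold
rule. In the binary matrix such a pattern appears once, in the scoring
(4-Atom) block, so column sets stay disjoint and the score is well defined.

## Screening and scoring

The Primary Positive set is a **conjunctive** filter: a library molecule
must contain *every* required pattern. Individual patterns can be lifted
from the requirement (`excludedIds`) — the published campaign dropped its
defined-hydroxy pattern because requiring it left too few molecules; the
filter is monotone in the required set, which the tests assert on synthetic
libraries. The surviving molecules get a 0/1 row over the 4-Atom then Basic
Scaffold columns (each ordered by occurrence); the **score** is the number
of 4-Atom patterns present. Scaffold-class selection then takes each class
(pyrroles-no-indoles, pyridines-no-quinolines-but-isoquinolines, furans-no-
benzofurans, quinazolines-no-quinazolinones, ...) as an include query plus
exclude queries plus an inclusive score window; the top-score pseudo-class
uses no structural query at all. Class definitions ship as JSON
(`defaultScaffoldClasses()`) and are data, not code. The pyridyl-cation
class is retained for completeness although neutral vendor libraries leave
it empty. The published workflow's subsequent manual visual triage is out
of the algorithmic path by design; it can be reproduced declaratively by
subsetting selections with an explicit id list, keeping the step auditable.

## Physicochemical bookkeeping

`computeDescriptors` returns CLogP, MW, MR, TPSA, HBD, HBA, rotatable
bonds and heavy atoms. HBD/HBA use the Lipinski conventions (OH+NH
hydrogens; N+O atoms) because the drug-likeness fractions (CLogP <= 5,
MW <= 500, HBD <= 5, HBA <= 10, all inclusive) are rule-of-five
bookkeeping. MW and the counts are implementation-independent;
CLogP/MR/TPSA come from Open Babel's published atom-contribution models and
are **not** expected to match commercial estimators digit-for-digit, so
conclusions should rest on MW/HBD/HBA-based figures where possible.
Calculated solubility (CLogS) is not provided: there is no open
implementation of the estimator the field's commercial suites use, and a
look-alike would invite false comparisons.

## Two-point IC50 estimation

Screening used two concentrations (10 and 50 uM) with 0% and 100% anchors
from vehicle and a reference inhibitor. With bottom and top fixed, the
three-parameter logistic

$$y = \frac{100}{1 + (IC_{50}/x)^h}$$

is exactly determined by the two points, giving the closed form

$$h = \frac{\ln\left[(100/y_1 - 1)/(100/y_2 - 1)\right]}{\ln(x_2/x_1)},
\qquad IC_{50} = x_1\,(100/y_1 - 1)^{1/h}.$$

The closed form is the primary path (no optimizer nondeterminism); an
iterative least-squares fit serves as a test oracle only, with required
agreement to 1e-6 relative. Degenerate inputs are flagged, never
extrapolated: both responses <= 0 is `no_inhibition`; any response outside
(0, 100), or a non-increasing pair, is `out_of_range`. Hit calling reads
the published "+ SEM" convention literally — `mean + SEM >= 20%` — as the
most inclusive rule; `mean` and `mean - SEM` are configuration options
because the convention is stated ambiguously. The printed uncertainty of a
two-point estimate has no defined error model here and is deliberately not
reproduced.

```{r ic50}
estimateIC50TwoPoint(50, 250/3, 10, 50)   # anchors force IC50 = 10, h = 1
```

## What the synthetic fixtures emulate — and what they do not

`generateCompoundSet` assembles molecules from an all-carbon backbone plus
attachable heteroatom-bearing fragments, planting each fragment in an
exact, seeded subset of each compound group. Exact-count planting (not
Bernoulli sampling) is the point: rule-boundary behavior is the riskiest
code, so fixtures must be able to sit a pattern at exactly 40.0% and one
compound below. The generator refuses frequencies that are not
integer-feasible and refuses fragment panels that cross-match, so its
incidence map is exact ground truth. Group sizes in the boundary fixtures
(40 direct + 10 inconclusive, and 1,000-molecule libraries for the
screening identities) are chosen to make every threshold integer-exact
while keeping the full suite in tens of seconds; they emulate the
*structure* of a curated multitarget dataset (101 + 12 compounds and a
38M-compound vendor library in the motivating study), not its scale.

What fixtures do **not** emulate: medicinal-chemistry diversity (real
molecules are not alkane backbones with pendant heterocycles), correlated
pattern co-occurrence, tautomerism, salts, or property-matched decoys.
Passing fixture tests therefore demonstrates that the *rules and
arithmetic* are implemented exactly, not that the fingerprint would enrich
actives on a particular vendor library.

Assay fixtures simulate replicate inhibition values from each compound's
true logistic curve plus seeded Gaussian noise (default SD 2% inhibition,
3 replicates — the scale of the published SEM bars), reporting mean and
SEM = SD/sqrt(n).

## Curation conventions

Structures are kept exactly as written (no salt stripping by default);
deduplication keys on canonical **isomeric** SMILES, so stereoisomers are
distinct records even though pattern matching is stereo-blind. The
first occurrence wins and every removal is reported. Unparseable rows are
collected into a failure report, never dropped silently. Readers accept
CSV, `.smi` and SDF; the deposited-workbook format of the motivating study
is positional prose rather than a machine schema, and no xlsx reader is a
package dependency, so workbook sheets should be exported to CSV for
ingestion.

## Known limitations

* Pattern-matching counts depend on the aromaticity model; parity with
  commercial engines is approximate (the reason published pattern counts
  carry a documented tolerance while MW-based statistics are exact).
* The heavy-atom substitution scheme defaults (aromatic C<->N, O<->S,
  single substitution) are configuration, not chemistry dogma; the full
  published scheme lives in supplementary material not machine-readable
  here.
* Two-point IC50 values are exactly-determined estimates, not fits with
  residual degrees of freedom; they carry no uncertainty and should be
  read as ranking values near the tested concentrations.
* The `[R]`-semantics question (may an attachment point be unsubstituted?)
  is decided permissively and exposed as a flag; both readings are
  internally consistent.

## Reproducing a full run

```{r pipeline, eval = FALSE}
cfg <- defaultRunConfig(
  fixture = list(seed = 1L, nDirect = 40L, nInconclusive = 10L,
                 nLibrary = 100L,
                 planted = data.frame(
                   frag_id = c("pyridine", "furan", "amide"),
                   n_direct = c(16L, 15L, 20L),
                   n_inconclusive = c(0L, 0L, 4L),
                   n_library = c(60L, 40L, 70L))),
  seed = 1L)
runPipeline(cfg, outDir = "capscore_run")
```

Every artifact carries a config-hash/seed header line; reruns under the
same configuration are byte-identical, which the test suite enforces.
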