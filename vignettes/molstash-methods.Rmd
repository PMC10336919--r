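---
title: "molstash: models, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{molstash: models, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. Everything stated here is either a definition
or a property that the test suite and `scripts/acceptance.R` themselves
verify; no empirical claim beyond those is made.

## The data model

A **project** is an ordered list of molecule entries plus an ordered
property schema, persisted as a folder:

```
project/
  project.json        name, schema, entries (id, input SMILES, canonical
                      SMILES, property strings, highlight, attachment names)
  attachments/<id>/   files attached to one molecule
  lock.json           owner, ISO-8601 timestamp, mode
```

JSON was chosen over a binary table because a folder synced through a
file-sharing service should diff cleanly, survive partial syncs visibly,
and be readable without this package. Entry order is part of the model and
survives save/load byte-for-byte.

**Canonicalization.** Every structure is stored twice: the user's SMILES
verbatim and the OpenBabel canonical spelling. All matching, deduplication
and descriptor work uses the canonical form, so `OCC` and `CCO` are the
same molecule everywhere; the input spelling is never lost. One
canonicalizer (OpenBabel) is used for every structure-touching path —
queries, targets, fingerprints, descriptors — so aromaticity is perceived
by a single model and never compared across engines.

**Property values are strings.** Chemistry tables mix numbers, formulas
and free text in one column; forcing types at storage time loses data.
Numeric interpretation happens at query/sort time instead (see below).

**Locking.** The first opener of a shared folder writes `lock.json` and
holds Read/Write; later openers get read-only plus the owner's identity.
A lock older than 24 h (configurable) is treated as stale — the original
tool never says what happens when a writer crashes, so a TTL plus an
explicit `steal` override is this package's choice: long enough for a
workday, short enough that a crashed laptop does not wedge the folder
forever. Lock release is explicit (`ms_release()`); there is no heartbeat.

**Duplicate IDs.** Imports keep only the first instance of an ID — whether
the clash is within the file or against entries already in the project —
and report every skipped `(id, row)` pair. The interactive
`ms_add_molecule()` goes one step further and refuses outright: silently
dropping a molecule a user typed in is worse than an error. This
distinction (import skips and reports; interactive add errors) is a
deliberate resolution of a case the original description leaves open.

## Queries

Eight comparators: `GE`, `GT`, `LT`, `LE` parse **both** the cell and the
reference as decimal numbers, and a parse failure on either side makes the
filter false rather than an error — mixed string/number columns are the
norm, and a query should never die on row 517 of someone's inventory.
`EQ`/`NE` compare exact strings; `CONTAINS`/`NOT_CONTAINS` are
case-sensitive substring tests (case-folding would merge the aromatic/
aliphatic distinction in SMILES columns). An **absent** cell is false for
every comparator except `NE` and `NOT_CONTAINS`: absence differs from any
value. Filters AND-combine; OR and nesting are out of scope. Queries
return a *new*, unsaved project and never touch the source.

Sorting parses numerically on request; entries whose value is missing or
unparsable go last in stable input order, so a half-filled column still
sorts usefully.

## Structural matching

A structural query is entered as SMILES (not SMARTS). The query is
canonicalized and then used as a SMARTS pattern against the targets, with
one adjustment: explicit hydrogen counts are stripped from bracket atoms.
Canonicalization fills in implicit hydrogens — a lone nitro fragment
becomes `O=[NH+][O-]` — and a literal `H` in SMARTS would demand that
hydrogen on the target, turning "contains this group" into "contains this
group with a spare H". Substructure containment here means containment of
the heavy-atom graph. Superstructure is the same test with the roles
swapped, which makes the two modes exact duals (a property the suite
checks).

The test suite cross-checks every substructure decision against an
independent backtracking subgraph-isomorphism matcher over element- and
ring-membership-labelled graphs with bond orders ignored. Ignoring orders
makes the oracle immune to Kekulé alternation; labelling by ring
membership reproduces the aromatic/aliphatic distinction within the
fixture grammar, where every ring atom is aromatic and every acyclic atom
is not. That equivalence is a property of the generated fixtures, not of
chemistry at large — molecules with aliphatic rings would need a true
aromaticity perception in the oracle.

**Fingerprints.** Similarity uses a 2048-bit, radius-2 circular
(Morgan-style) fingerprint computed on the canonical graph: the initial
atom invariant hashes element, heavy-atom degree, bond-order sum and ring
membership; two neighbourhood-hashing rounds follow, and every environment
from every round sets one bit. Formal charge is *not* part of the
invariant — a charged and a neutral spelling of the same group may
collide; acceptable for a similarity screen, documented as a limit. The
hash is a plain polynomial string hash kept below 2^26 so all arithmetic
is exact in doubles and bit-identical across platforms. Tanimoto is
`|A∩B|/|A∪B|`, defined as 1 when both sets are empty. The default
similarity threshold is 0.7 — the conventional "looks similar" cut for
2048-bit circular fingerprints — and the score is always written to a
`Similarity` column (4 decimals), so the threshold choice stays visible
and revisable.

## Descriptors

Nine descriptors, all computed by OpenBabel on the canonical graph:
molecular weight (average, not monoisotopic, atomic masses — inventory
convention), Hill-order formula, heavy-atom count, Wildman–Crippen
atomic-contribution logP, H-bond donors and acceptors (OpenBabel's
acceptor definition), rotatable bonds (the standard non-ring single bond
between non-terminal, non-triple-bond atoms SMARTS), smallest-set ring
count (cyclomatic number), and Ertl TPSA in Å². Cells are written as
strings — 2 decimals for MW/logP/TPSA, bare integers for counts — and stay
editable; recomputation overwrites a column the package created (including
manual edits of those cells, which is the point of recomputation) but
refuses to fill a column the *user* created under the same name unless
explicitly told to. `ms_formula_mass()` recomputes mass from the emitted
formula string with IUPAC standard atomic weights, which is the
self-consistency cross-check the acceptance script runs (agreement within
0.01 g/mol).

## Toxicity scoring

The scoring contract: each endpoint has an ensemble of probabilistic
classifiers over the package's fingerprints, and the reported value is
`round(100 · mean pᵢ)`, rounded half-up, an integer in 0–100. Mean
probability is the simplest consensus satisfying the printed range and
makes "m copies of one model" exactly equal the single model — a property
the suite asserts. Whether a deployed consensus scorer uses mean
probability, vote fractions or something else is not specified by the
interface this package emulates; the rule here is a declared stand-in.

The bundled ensembles are **placeholders**: five bootstrap-resampled
random forests per endpoint, trained at first use on the package's own
synthetic structure–toxicity data (a fixed seed per endpoint) and memoised
for the session. Training at first use rather than shipping weights keeps
the repository plain text and makes the models exactly reproducible from
source. They recover the planted structural signal (held-out separation
≥ 20 score points is asserted) and carry no toxicological meaning
whatsoever.

## The synthetic-library generator

Libraries are assembled from a scaffold × substituent grammar — benzene,
pyridine, coumarin and indole cores; methyl, hydroxy, methoxy, halogen,
amino and nitro substituents on 0–2 template positions. Grammar assembly
(rather than random strings or perturbed real molecules) guarantees every
SMILES parses and makes the planted facts — which molecules carry the
coumarin core, any nitrogen, a nitro group — true by construction and
independently checkable by the subgraph oracle. Requested fractions are
hit exactly after rounding; the whole library is a pure function of
`(n, seed, fractions)`, and generation restores the caller's RNG state.

Defaults: 20% coumarin cores (a planted-retrieval query then has a
meaningful positive set of 20 in a 100-molecule library), 50% nitrogen,
25% nitro. The toxicity dataset uses 50% nitro so the binary label is
balanced, flips 5% of labels as noise (enough to punish memorisation,
small enough that signal recovery is expected), and refuses n < 20.

What the generator does **not** emulate: stereochemistry, charged
scaffolds beyond the nitro group, aliphatic rings, tautomerism, molecular
weights beyond ~350 g/mol, or the property distributions of a real
screening collection. Green tests therefore demonstrate that the machinery
is correct on structures whose ground truth is known exactly — not that
retrieval or scoring performance transfers to a vendor library.

## Problem sizes and numerics

The suite and acceptance script run at sizes chosen to exercise every code
path at desk scale: 500 molecules for the four-format round-trip, 200 rows
with 10 planted duplicates for the import policy, 200 random query
specifications over 1000 molecules against the row-scan oracle, 100
molecules with 20 planted cores for structural retrieval, 10,000 random
fingerprint pairs for the Tanimoto properties, 200/100 train/held-out for
toxicity, and a 10,000-molecule library for the substructure sweep (a
desk-scale stand-in for the ~100k regime the folder format targets).

Numerical conventions: CAS checksum weights count right-to-left from the
digit before the check digit; consensus rounding is half-up
(`floor(100p + 0.5)`), not banker's; descriptor count columns are
integers; XLSX is written as a minimal single-sheet inline-string workbook
(no R package on the stack writes XLSX) and read back with readxl; SDF
records are passed to and from OpenBabel as raw text so that formal-charge
columns survive untouched, and the V2000 dialect only is supported.
Attachment name collisions get `_1`, `_2`, … suffixes — user data is never
overwritten. Empty import cells become *absent* values, not empty strings,
preserving the "no data" / "empty text" distinction.

## Known limitations

* Aromaticity is whatever OpenBabel perceives; no alternative models.
* Fingerprints ignore formal charge and stereochemistry.
* The live CAS client takes the first record when a number maps to several
  and notes nothing else; it is rate-limited (200 ms, 3 retries) and is
  never exercised by the tests — the recorded-fixture client is the tested
  path.
* Grid reports render structures as SMILES text; no 2-D depiction backend
  is wired in.
* Lock arbitration is advisory (a cooperating-clients protocol), not an
  OS-level lock.
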