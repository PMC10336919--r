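# molstash

A headless, folder-based compound-library manager for medicinal chemistry
and chemical-biology groups.

Bench chemists accumulate molecules in spreadsheets: structures as SMILES,
assay values, provenance notes, attached spectra. Those spreadsheets do not
know what a molecule *is* — they cannot tell you that `OCC` and `CCO` are
the same compound, find every entry containing a coumarin core, or compute a
logP. molstash stores a compound collection as a **project**: a plain folder
holding a JSON table of molecules, an `attachments/` tree for per-molecule
files (spectra, PDFs, notebook scans), and a `lock.json` record that
arbitrates write access when the folder is shared through a sync service —
the first user to open the project holds Read/Write; everyone else is
dropped to read-only and told who the writer is.

On top of that store the package provides:

* **Import/export** of CSV (comma/semicolon/tab), XLSX and V2000 SDF
  compound tables with free column-to-field mapping. Repeated IDs are never
  silently merged: only the first instance is kept and every duplicate is
  reported with its row number, as are rows whose SMILES does not parse.
* **CAS-number resolution** — turn a text file of CAS registry numbers into
  structures plus IUPAC names through a PubChem-style REST client (the
  checksum `Σ i·dᵢ mod 10` is verified before any lookup), with a
  recorded-fixture client so everything runs offline.
* **Descriptors** — MW (average atomic masses), Hill-order formula, heavy
  atoms, Wildman–Crippen logP, H-bond donors/acceptors, rotatable bonds,
  ring count and TPSA, computed on the canonical molecular graph by
  OpenBabel and written into editable table columns.
* **Property queries** with the eight comparators ≥, >, <, ≤, =, ≠,
  *contains*, *not-contains*, AND-combined, returning a new project.
* **Structural queries** — substructure, superstructure, or Tanimoto
  similarity `T(A,B) = |A∩B| / |A∪B|` over 2048-bit radius-2 circular
  (Morgan-style) fingerprints, with the score written into a `Similarity`
  column.
* **Consensus toxicity scores** for four endpoints (mutagenicity,
  carcinogenicity, estrogenicity, hepatotoxicity): an ensemble of
  fingerprint-based classifiers is averaged and scaled to the 0–100 range,
  `score = round(100 · mean pᵢ)`. The bundled ensembles are *placeholder*
  models trained on this package's synthetic data — they demonstrate the
  scoring pipeline and carry no toxicological validity.
* A **synthetic-library generator** (scaffold × substituent grammar with
  planted coumarin/nitrogen/nitro ground truth) and a **command-line
  interface** covering every operation.

## Worked example

```r
library(molstash)

p <- ms_create("mylib", "kinase-fragments")
p <- ms_add_molecule(p, "frag-1", "Oc1ccc2ccccc2c1", list(Source = "bench"))
p <- ms_add_molecule(p, "frag-2", "O=c1ccc2ccccc2o1", list(Source = "vendor"))
p <- ms_add_molecule(p, "frag-3", "Nc1ccc(Cl)cc1")
p <- ms_compute_properties(p, c("molecular_weight", "logp", "molecular_formula"))
p <- ms_predict_tox(p, "mutagenicity")
ms_save(p)
as.data.frame(p)
#>       ID             SMILES     # Source     MW LogP Formula Tox_Mutagenicity
#> 1 frag-1  Oc1ccc2c(c1)cccc2 FALSE  bench 144.17 2.55  C10H8O               10
#> 2 frag-2 O=c1ccc2c(o1)cccc2 FALSE vendor 146.14 1.79  C9H6O2                2
#> 3 frag-3      Nc1ccc(cc1)Cl FALSE   <NA> 127.57 2.50 C6H6ClN                1
```

Each molecule was canonicalized on entry (`SMILES` shows the canonical
spelling; the input spelling is kept too), `#` is the attachment flag, `MW`
is in g/mol, `LogP` the atomic-contribution octanol–water estimate, and
`Tox_Mutagenicity` the 0–100 consensus score of the bundled placeholder
ensemble — here all three fragments score low.

```r
ms_ids(ms_query(p, list(ms_filter("MW", "GE", "140"),
                        ms_filter("LogP", "LE", "2.0"))))
#> [1] "frag-2"
ms_ids(ms_structural_query(p, "substructure", "O=c1ccc2ccccc2o1"))
#> [1] "frag-2"
```

The property query keeps molecules with MW ≥ 140 **and** logP ≤ 2.0; the
structural query retrieves the entries containing the coumarin core —
both single out the chromen-2-one fragment.

The same flows from a shell:

```sh
exec/molstash new ./mylib --name kinase-fragments
exec/molstash add ./mylib --id frag-2 --smiles 'O=c1ccc2ccccc2o1'
exec/molstash props ./mylib --set MW,LogP,Formula
exec/molstash query ./mylib --where 'MW>=140' --where 'LogP<=2.0' --out ./hits --json
```

## Scope

No GUI or structure sketcher (SMILES text stands in for both), no SMARTS
query language, no OR/nested boolean filters, no external database
sampling, and no claim that the bundled toxicity models predict real
toxicity. The methods vignette (`vignettes/molstash-methods.Rmd`)
documents the model, the numerical conventions and the design decisions.
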