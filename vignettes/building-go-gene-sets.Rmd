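---
title: "Building GO-derived gene set collections: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building GO-derived gene set collections: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gosets)
```

## The procedure

`gosets` turns a Gene Ontology release (an OBO 1.2 flat file) and a gene–GO
association source into an MSigDB-format gene set collection. The pipeline
has four phases, executed in a fixed order by `build_genesets()`:

1. **Ontology.** The OBO file is parsed into a DAG of current terms; obsolete
   terms and `alt_id` synonyms are recorded in side tables. Acyclicity, the
   existence of exactly one root per namespace, and the absence of
   cross-namespace parent edges are *asserted*, not assumed — a malformed
   ontology fails loudly with a classified error rather than producing a
   subtly wrong collection. The parsed DAG can be cached
   (`cache_dag()`/`load_cached()`) behind a format-versioned contract: a
   stale or foreign cache is an explicit error instructing a re-parse, never
   a silent partial load.
2. **Associations.** One of three reader dialects (NCBI gene2go, GAF 2.x,
   Affymetrix/Agilent array annotations) produces a uniform
   `(gene_id, term_id, evidence)` table. Evidence filtering, optional
   identifier remapping and GO accession resolution follow, in that order, so
   evidence codes are interpreted on the source's own identifiers before any
   remapping can merge records.
3. **Propagation.** The true-path rule is applied: each term's member set
   becomes the union of its direct members and those of all its descendants
   through propagating edges. Depths (shortest edge distance to the namespace
   root) are computed on the same DAG.
4. **Output.** Size filtering, duplicate collapsing, and `.gmt`/`.gmx`
   serialization.

### Assumptions

* The ontology is a rooted DAG per namespace; parents of current terms are
  current terms.
* An association's meaning is fully captured by (gene, term, evidence):
  associations differing only in evidence code collapse to one membership,
  and evidence matters only at filter time.
* A `NOT`-qualified annotation asserts non-membership. These rows are
  excluded by every reader: propagating a negated annotation upward would
  poison every ancestor set. (The qualifier's other values — `contributes_to`
  and friends — do not negate and are kept.)

## Propagating relationships

GO relationship types differ in whether the true-path rule is sound across
them. `gosets` follows `is_a` and `part_of` edges by default — the convention
shared by the widely used GO set-building and enrichment tools — and does
*not* follow `regulates`-type edges (a regulator of a process is not part of
it). The allow-list is a parameter of `parse_obo(relations = )` for users who
disagree. In valid GO releases `part_of` never crosses namespaces; a file
where it does is rejected rather than reinterpreted.

The traversal itself is a memoized accumulation in reverse topological order:
each term's propagated set is computed exactly once from its children's final
sets, so the cost is linear in the total size of the propagated sets, rather
than one upward DAG walk per association. Terms left with no members are
dropped from the index — an empty set can never pass a minimum size filter of
at least one, so this is observationally equivalent and keeps the index
small.

## Resolution of stale accessions

Association sources routinely lag (or lead) the ontology release. Three
anomalies are handled in-band, counted, and reported on standard error rather
than raised:

* a **synonymous** accession (`alt_id`) is rewritten to the preferred
  accession;
* an **obsolete** accession is dropped — including the corner case of a
  synonym whose preferred accession is itself obsolete, which is treated as
  obsolete (the conservative reading: there is no current term to credit);
* an **unknown** accession (absent entirely, possible when the term source is
  older than the association source) is dropped.

An obsolete term's `replaced_by` pointer is recorded when it names exactly
one replacement, but associations to obsolete terms are *not* silently
re-annotated to the replacement: curation practice treats `replaced_by` as a
hint for curators, not a semantic equivalence. Multiple `replaced_by` targets
or `consider`-only stanzas are treated as obsolete with no replacement.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `min_size`, `max_size` | 10, 700 (inclusive) | Sets below ~10 genes cannot reach significance in set-based tests; sets above ~700 are too general to interpret. These are the conventional bounds for GO-derived GSEA collections, and "between 10 and 700" is read inclusively. |
| `evidence` | `"high_quality"` | All codes except IEA (electronic, uncurated), ND (no data) and NAS (non-traceable statement). The historical curated-human-collection subset was never published, so this profile is a documented convention; `"all"` (no filtering) or any explicit code vector can be given instead. Sources without evidence codes (array files) require `"all"`, since an unknown support level cannot pass a filter. |
| `relations` | `is_a`, `part_of` | See above. |
| `map_mode` | `keep_unmapped` | With a partial identifier map, unmapped identifiers pass through verbatim; `drop_unmapped` instead restricts output to mapped genes (e.g. one species out of a multi-species array annotation). |
| `url_template` | AmiGO term page | `%s` is replaced by the representative accession. |

## Duplicate collapsing and naming

Propagation guarantees duplicate content: any parent whose annotated
descendants cover all its genes ends up identical to the union of its
children. Duplicate sets distort FDR estimation in GSEA, so each distinct
gene content is emitted once. Unlike builds that silently discard the
duplicates, the description field enumerates *every* term with that content,
each with its depth:

```
GO:0000002 muscle system process [level 1]|GO:0000003 muscle contraction [level 2]
```

The grammar (`|`-separated entries, `[level D]` suffix) is this package's
choice; what is essential is that all terms and their per-term depths are
recoverable — the test suite includes an inverse parser that reconstructs the
term list from the description. The representative term (set name, URL) is
the minimum-depth, i.e. most general, term; equal depths break the tie by
lexicographically smallest accession, making output independent of input
order. Set names follow the MSigDB c5 style — uppercase, non-alphanumeric
runs collapsed to `_` — with `_2`, `_3`... suffixes on collisions.

The `.gmt` description column is a single free-text field, but both a URL
and the term list are wanted; the default emits `"URL<space>description"` in
that one field, and `description = "url_only"` gives strict MSigDB mimicry.
`.gmx` is the exact field-by-field transpose, short columns padded with empty
fields.

## Numerical and degenerate-input choices

* Depth follows the recurrence `depth(root) = 0`,
  `depth(t) = 1 + min(depth(parents(t)))`, evaluated in topological order;
  no floating point is involved anywhere in the pipeline.
* Output ordering is deterministic end to end: member lists are sorted,
  collections are ordered by representative accession, and two runs on the
  same inputs are byte-identical.
* Accessions are compared case-sensitively after trimming surrounding
  whitespace; gene identifier case is preserved as read.
* Empty inputs degrade explicitly: an empty association table gives an empty
  collection and a zero-column `.gmx`; `propagated_fraction()` of an empty
  index is `NA` with a warning rather than `0/0`.
* Readers keep an accounting attribute
  (`rows = emitted + skipped + excluded`) so row conservation is testable.
* The output file is written to a temporary name and renamed, so a failing
  run never leaves a partial collection behind.

## What the synthetic fixtures do and do not establish

`fixture_spec()`/`make_ontology()`/`make_associations()` generate a seeded
random single-namespace ontology (acyclic by construction: parents are drawn
only from earlier terms) and association files in all three dialects, with
controlled injections of the hostile cases — NOT-qualified rows, synonymous,
obsolete and unknown accessions, a decoy taxon — together with ground truth
for each. Defaults (50 terms, 100 genes, 200 associations, ~5% synonym and
obsolete rates, a 50/30/20 IEA/IDA/TAS evidence mix) reflect the anomaly
rates seen when an association source is about a year newer than the
ontology release; sizes are kept small because the tests sweep many seeds.

The generator emulates file syntax and DAG structure, not biology: term-size
distributions are uniform rather than the heavy-tailed distributions of real
GO, all three namespaces are not represented simultaneously, and gene
identifiers are synthetic. A green test establishes that parsing,
resolution, propagation, collapsing and serialization are correct on
arbitrary DAGs — it does not certify any statement about real GO releases,
whose content changes with every release. The canned `sarcomere_fixture()`
reconstructs only the arithmetic of the classic motivating example (16
directly annotated genes, 81 more on child terms, 97 after propagation), not
the real mouse annotations.

## Known limitations

* Flat files only: no live GO/MySQL database or NCBI E-utilities backends.
* No cross-species ortholog mapping; identifier remapping is a plain lookup.
* The Agilent cell grammar (`GO:NNNNNNN(name)` entries, `|`-separated) is a
  documented assumption with column-name overrides, as manufacturer formats
  vary between array generations.
* Enrichment statistics themselves are out of scope; the package builds the
  input collections.
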