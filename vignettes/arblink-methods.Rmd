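---
title: "Linking desktop curation to outsourced phylogenetics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking desktop curation to outsourced phylogenetics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arblink)
```

## The procedure

`arblink` implements a round trip between a locally curated sequence
database and remote computation:

```
meta-labels ──> GenBank extraction ──> custom database ──> bare-ID FASTA ──> (cloud)
     │                 │                     │                                  │
     └──> import filter┘                     └───────────<── Newick tree <──────┘
                                                   link by unique ID, relabel
```

The pivot of the whole design is the **unique ID**. Every record is
assigned a short identifier at extraction time; that identifier is
simultaneously (a) the first header cell of the custom database, (b) the
value the generated import filter writes into ARB's per-species `name`
field, (c) the only content of the exported FASTA headers, and (d) the
leaf name of any tree built externally from that export. Because all
four roles carry the same token, a tree returned from a remote service
can always be reunited with the metadata it was stripped of, and new
metadata can later be attached to existing records.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `prefix` (ID minting) | `"sq"` | — | 1–2 lowercase alphanumerics; distinguishes extraction batches. |
| `start` (ID minting) | `1` | counter | First base-36 counter value; reruns with the same `(prefix, start)` reproduce identical IDs. |
| ID counter width | 6 | base-36 digits | Capacity 36^6 ≈ 2.2e9 per prefix; total ID length ≤ 8 characters, a size ARB's short `name` key handles comfortably. |
| `strip_gaps` (export) | `TRUE` | — | External aligners expect unaligned input; set `FALSE` to ship an existing alignment. |
| Sequence wrap width | 70 | columns | Cosmetic only; the reader accepts any wrapping. |
| `sep` (relabel) | `" "` | — | Joins multiple metadata fields into one display label. |

Meta-label normalization (trim, lowercase, runs of whitespace/hyphens to
`_`) exists because ARB database field names are conventionally lowercase
identifiers while users write display names like "Gene Product". A
single deterministic, idempotent mapping keeps the database header, the
filter's `WRITE` targets and the relabeling lookups consistent. The
unique-ID column is deliberately *not* part of the schema: it is implicit
column 0 of every header.

## Field resolution from GenBank records

Requested fields resolve through a fixed chain: built-in resolvers for
well-known names (accession, version, GI, definition, organism/species,
genus, phylum, product, gene, locus tag, date, author, journal), then
source-feature qualifiers, then qualifiers pooled over all other
features (first occurrence wins, in file order), then the empty string.
Missing data is *never* an error: realistic schemas include environmental
fields (pH, salinity, temperature) that most GenBank records simply lack,
and hard-failing would make such schemas unusable.

Two rank lookups are heuristic by default: `genus` is the first
whitespace token of the organism name, and `phylum` is the second
lineage token (NCBI lineages open superkingdom; phylum; ...). An
optional offline taxdump mode (`load_taxdump()` on `names.dmp` /
`nodes.dmp`) replaces the positional guess with rank-resolved names when
a dump is available; no network access is ever attempted.

Values are sanitized at extraction: tabs and newlines collapse to a
single space, because the database header is tab-delimited. The mapping
is lossy by design and applied exactly once.

## The import-filter dialect and its reference interpreter

ARB ingests flat files through declarative `.ift` filters. The emitter
produces a conservative subset of the directive language — `AUTODETECT`,
`KEYWIDTH`, `BEGIN`, one `MATCH`/`TABCOLUMN`/`WRITE` block per field,
`SEQUENCEAFTER`, `SEQUENCEEND`, `END` — in which the entire
column-extraction step is the single directive `TABCOLUMN i`: split the
text matched by the `*` of the `MATCH` pattern on tabs, take zero-based
column *i*. ARB's full search-replace (SRT) micro-syntax is intentionally
abstracted behind this one directive. The reasons:

* filter correctness must be testable without an ARB installation, so
  the package ships `apply_filter()`, a reference interpreter that
  defines the directive semantics and is held to a 100%-recovery
  standard against databases the package itself wrote;
* the extraction expression is isolated in one place, so a bit-exact
  SRT backend can replace it later without touching the filter model.

One `MATCH` block per field (rather than one mega-expression) keeps the
rendering, the interpreter and textual diffs simple. Byte-compatibility
with a specific ARB release's SRT parser is explicitly not guaranteed
and must be validated against a live ARB; this is a documented
limitation, not an oversight.

Strictness choices worth noting: on read, a header whose cell count does
not equal `1 + length(schema)` is an error, never padded — silent
padding would mask schema drift between the meta-labels file and the
database, which is exactly the failure mode the unique-ID system exists
to prevent. Duplicate unique IDs are likewise fatal everywhere they can
be detected.

## Tree linking and relabeling

The Newick reader/writer is small and exact: quoted labels (`'...'`,
with `''` escaping), no underscore-to-space munging, branch-length
tokens kept as text so they round-trip exactly as printed. Linking
requires every leaf to match a database uid; leaves may be a strict
subset of the database (users prune before tree building), but the
converse is an error that names every unmatched leaf, because a leaf
without a record severs the linkage guarantee. Duplicate display labels
after relabeling are allowed — display names need not be unique — and
`keep_uid = TRUE` is the documented way to restore uniqueness. The
relabeled tree is for viewers; the uid-labeled tree remains the
canonical artifact imported into ARB.

## What the synthetic data emulates — and what it does not

`generate_genbank()` emits structurally faithful flat files: fixed-column
LOCUS lines, wrapped DEFINITION and lineage continuations, reference
blocks, a feature table with source and CDS features at the canonical
indentation, and a coordinate-grouped ORIGIN block. Planted values echo
the motivating domain (bacterial/fungal sugar transporters and
polymer-degradation enzymes). Deliberately awkward cases exercise
documented decisions: every fifth record carries a tab inside its
`product` qualifier (sanitization), environmental qualifiers appear in
only every third record (missing-field totality), lineages end with a
trailing period (lineage parsing), definitions wrap (continuation
joining). The generator's ground truth is the parser's oracle, and an
independent cross-check against a second, unrelated GenBank parser on
the same fixture guards against the generator and parser sharing a
blind spot.

The generator does not attempt multi-feature gene models, join()
locations, CON/contig records, EMBL dialects, or the full zoo of
qualifier types — real GenBank files are messier than any fixture. A
green suite therefore demonstrates correctness of the pipeline's
contracts, not robustness to every upstream format quirk.

Randomized databases (`generate_database()`) draw field values from a
character pool that includes spaces, quotes, commas, parentheses and
colons — everything header-hostile except the structurally forbidden tab
and newline — plus ~10% empty cells, and sequences of 50–200 residues.
Test problem sizes were chosen to exercise the contracts at scale while
keeping the default suite fast: the round-trip corpora use 200 databases
of 1–500 records and 1–12 fields; linkage and relabeling properties run
on 10–100 random trees of 3–40 leaves; the acceptance script uses 60
databases per corpus.

## Numerical and representational choices

* **Base-36 counters, not random IDs**: determinism makes reruns
  reproducible and collisions structurally impossible within a prefix;
  capacity overflow is a hard error.
* **Branch lengths as text**: numbers parsed to double and reformatted
  would drift (`0.05` → `0.050000000000000003` in unlucky formatters);
  storing the token sidesteps the issue entirely.
* **Exact pair counts**: `n(n−1)/2` is computed in doubles, exact for
  every n below 2^26.5; at the motivating n = 10,752 the count is
  57,797,376 and, at 0.019 s per pair, ≈ 12.7 days of local compute.
* **Gap alphabet**: `-` and `.` both accepted on read (ARB uses
  dot-gaps in places); `-` is canonical on write; gap stripping at
  export is the default.
* **Tie-breaks**: first qualifier occurrence wins, scan order is file
  order; first reference block feeds author/journal fields.

## Known limitations

* The emitted `.ift` has not been validated against a live ARB; the
  reference interpreter defines the dialect's semantics.
* Rank assignment without a taxdump is positional and can be wrong for
  unusual lineages; supply a taxdump for authoritative ranks.
* Tab/newline sanitization of metadata values is lossy.
* One tree per Newick file; Nexus is out of scope, as are running
  aligners/tree builders and any network retrieval.
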