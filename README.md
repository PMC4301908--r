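# arblink

Middleware between the ARB desktop phylogenetics environment and
outsourced (cloud) alignment and tree-building services.

## The problem

Molecular ecologists curate, explore and annotate sequence data
interactively in ARB — but alignment and phylogeny scale nonlinearly with
dataset size. An all-against-all alignment of *n* sequences performs

```
n (n − 1) / 2
```

pairwise alignments: for a ten-thousand-sequence gene family that is tens
of millions of pairs, days of local compute, versus minutes on a remote
gateway running MAFFT/RAxML. Outsourcing, however, breaks the connection
between sequences and their curated metadata: external services accept a
bare FASTA and return a Newick tree whose leaves know nothing about your
species names, gene products, pH measurements or publication dates.

`arblink` keeps that connection intact. It:

1. parses a user-authored **meta-labels** file — one metadata field name
   per line — defining the schema of the whole pipeline;
2. extracts those fields (identification, taxonomy, environmental,
   functional, publication) from **GenBank flat files** and mints a short
   stable **unique ID** per record (`sq000001`, ... — a 2-character
   prefix plus a fixed-width base-36 counter, at most 8 characters, the
   ARB per-species `name` key);
3. writes the **custom database**: a FASTA dialect whose header line is a
   tab-delimited row of unique ID followed by the metadata values in
   schema order;
4. generates the matching **ARB import filter**
   (`custom_import_filter.ift`) automatically from the schema, plus a
   reference interpreter of the emitted directive subset so the filter is
   testable without an ARB installation;
5. exports the **bare-ID FASTA** handed to external alignment / tree
   services;
6. **links the returned Newick tree** back to the database by unique ID
   and relabels leaves with any metadata field (e.g. view gene products
   on the leaves when choosing product-discriminative primer targets).

A deterministic synthetic-data generator (GenBank records, databases,
trees — all with known ground truth) makes the entire pipeline testable
offline.

## Worked example

```r
library(arblink)

schema <- parse_meta_labels("Accession\nSpecies\nGene Product\n")
gb     <- generate_genbank(4, seed = 7)          # synthetic GenBank records
db     <- build_records(parse_genbank(gb$text), schema)
db
#> <custom_database> 4 record(s), schema: accession, species, gene_product

cat(write_database(db))
#> >sq000001	SY000001	Bacillus subtilis	sugar:proton symporter
#> TGTTCGTGCTGTTCGGCTCGATGCCGCTCTGTTAGCTAGAATAACTAGAGCTTATCGTCCCTGTCGATCG
#> ...
```

Each header row is `uid TAB accession TAB species TAB gene_product`; the
unique ID (`sq000001`) is the join key everything else hangs off.

```r
cat(render_ift(build_import_filter(schema)))
#> AUTODETECT	">*"
#> KEYWIDTH	12
#> BEGIN	">*"
#> MATCH	">*"
#> 	TABCOLUMN	0
#> 	WRITE	"name"
#> MATCH	">*"
#> 	TABCOLUMN	1
#> 	WRITE	"accession"
#> ...
```

One `MATCH`/`TABCOLUMN`/`WRITE` block per field: column 0 feeds ARB's
reserved `name` field, column *i* feeds the *i*-th meta-label. Install
the file into `/arb/lib/import/` and import the database with ARB's
standard new-database procedure.

```r
cat(export_sequences(db))                 # bare-ID FASTA for the cloud
#> >sq000001
#> TGTTCGTGCTGTTCGGCTCGATGCCGCTCTGTT...

tree <- generate_tree(db$uid, seed = 7)   # stands in for the returned tree
lt   <- link_tree(tree, db)
lt
#> <linked_tree> 4/4 leaves linked to database of 4 record(s)

cat(write_newick(relabel_leaves(lt, "gene_product")))
#> (('major facilitator superfamily protein':0.34,'MFS transporter':0.97):0.79,
#>  ('sugar transporter':0.46,'sugar:proton symporter':0.17):0.17);
```

`link_tree()` fails loudly, naming every offender, if any leaf is not a
database uid — the guarantee that outsourced results can always be
reunited with their metadata. Relabeled trees are for viewers; the
uid-labeled tree remains the canonical artifact imported into ARB
(`Tree/Tree Admin/Import`).

```r
estimate_pairwise_alignments(10752, t_per_pair = 0.019)
#> $n_pairs       57797376
#> $total_seconds 1098150
#> $total_days    12.71
```

## Command line

A launcher script ships in `inst/cli/arblink`
(`system.file("cli", "arblink", package = "arblink")`):

```sh
arblink extract      --meta-labels meta_labels.txt --genbank records.gb --out-dir out/
arblink build-filter --meta-labels meta_labels.txt --out-dir out/
arblink export       --meta-labels meta_labels.txt --database out/custom_database.fasta --out sequences.fasta
arblink check-tree   --meta-labels meta_labels.txt --database out/custom_database.fasta --tree tree.nwk
arblink relabel      --meta-labels meta_labels.txt --database out/custom_database.fasta \
                     --tree tree.nwk --fields gene_product --out relabeled.nwk
arblink estimate     --n 10752 --t-per-pair 0.019
arblink make-fixtures --out-dir demo/
```

Exit codes: 0 success, 2 validation error, 3 I/O error. Flags may come
from `--config file` (`key = value` lines); explicit flags win.

## Scope

`arblink` prepares inputs for, and consumes outputs of, external tools.
It does not run ARB, submit jobs to any gateway, execute aligners or
tree builders, or download records from NCBI; byte-compatibility of the
emitted filter with a specific ARB release's SRT parser is not
guaranteed (see the methods vignette).
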