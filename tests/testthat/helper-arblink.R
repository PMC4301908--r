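# Shared fixtures for the suite. Everything is generated in code; no test
# reads the network or the wall clock.

`%||%` <- function(a, b) if (is.null(a)) b else a

demo_schema <- function() {
  meta_labels(c("accession", "species", "gene_product", "ph"))
}

# Equality of database content (ignores the provenance manifest).
db_content <- function(db) {
  list(schema = as.character(db$schema), uid = db$uid,
       meta = unname(db$meta), seq = db$seq)
}

expect_db_equal <- function(a, b) {
  expect_identical(db_content(a), db_content(b))
}

# A literal record, hand-written so parser expectations are independent of
# the generator.
literal_genbank_record <- function() {
  paste(c(
    "LOCUS       AB123456                  24 bp    DNA     linear   BCT 02-MAR-2013",
    "DEFINITION  Escherichia coli xylE gene for sugar transporter, complete",
    "            cds.",
    "ACCESSION   AB123456",
    "VERSION     AB123456.1  GI:123456789",
    "SOURCE      Escherichia coli",
    "  ORGANISM  Escherichia coli",
    "            Bacteria; Proteobacteria; Gammaproteobacteria;",
    "            Enterobacterales; Enterobacteriaceae; Escherichia.",
    "REFERENCE   1  (bases 1 to 24)",
    "  AUTHORS   Garcia,M. and Chen,L.",
    "  TITLE     Sugar transport in enteric bacteria",
    "  JOURNAL   J. Bacteriol. 181 (2), 334-341 (2012)",
    "FEATURES             Location/Qualifiers",
    "     source          1..24",
    "                     /organism=\"Escherichia coli\"",
    "                     /mol_type=\"genomic DNA\"",
    "                     /ph=\"7.2\"",
    "     CDS             1..24",
    "                     /gene=\"xylE\"",
    "                     /locus_tag=\"ECX_0001\"",
    "                     /product=\"sugar transporter\"",
    "ORIGIN      ",
    "        1 acgtacgtac gtacgtacgt acgt",
    "//"), collapse = "\n")
}
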