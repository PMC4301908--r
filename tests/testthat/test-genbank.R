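test_that("a hand-written record parses field by field", {
  entries <- parse_genbank(literal_genbank_record())
  expect_length(entries, 1L)
  e <- entries[[1]]
  expect_identical(e$locus, "AB123456")
  expect_identical(e$accession, "AB123456")
  expect_identical(e$version, "AB123456.1")
  expect_identical(e$gi, "123456789")
  expect_identical(e$date, "02-MAR-2013")
  expect_identical(e$definition,
                   "Escherichia coli xylE gene for sugar transporter, complete cds.")
  expect_identical(e$organism, "Escherichia coli")
  expect_identical(e$taxonomy_lineage,
                   c("Bacteria", "Proteobacteria", "Gammaproteobacteria",
                     "Enterobacterales", "Enterobacteriaceae", "Escherichia"))
  expect_identical(e$source_qualifiers$ph, "7.2")
  expect_identical(e$feature_qualifiers$product, "sugar transporter")
  expect_identical(e$feature_qualifiers$gene, "xylE")
  expect_identical(e$references[[1]]$authors, "Garcia,M. and Chen,L.")
  expect_identical(e$references[[1]]$journal,
                   "J. Bacteriol. 181 (2), 334-341 (2012)")
  expect_identical(e$references[[1]]$date, "2012")
  # ORIGIN coordinates and spacing stripped, residues uppercased
  expect_identical(e$sequence, "ACGTACGTACGTACGTACGTACGT")
})

test_that("multi-record files keep file order; malformed input is rejected", {
  two <- paste0(literal_genbank_record(), "\n",
                sub("AB123456", "XY999999", literal_genbank_record()), "\n")
  entries <- parse_genbank(two)
  expect_length(entries, 2L)
  expect_identical(vapply(entries, `[[`, "", "locus"),
                   c("AB123456", "XY999999"))

  expect_error(parse_genbank(""), class = "arblink_empty_input")
  expect_error(parse_genbank("LOCUS       X\nORIGIN\n        1 acgt\n"),
               class = "arblink_truncated_record")
  no_origin <- sub("ORIGIN.*//", "//", literal_genbank_record())
  err <- expect_error(parse_genbank(no_origin),
                      class = "arblink_malformed_record")
  expect_match(conditionMessage(err), "AB123456")
})

test_that("parser agrees with Biopython on a synthetic flat file", {
  gb <- generate_genbank(4, seed = 99)
  gb_path <- tempfile(fileext = ".gb")
  writeLines(gb$text, gb_path, sep = "")
  py <- paste(
    "import sys",
    "from Bio import SeqIO",
    "for r in SeqIO.parse(sys.argv[1], 'genbank'):",
    "    prod = ''",
    "    for f in r.features:",
    "        if f.type != 'source' and 'product' in f.qualifiers:",
    "            prod = f.qualifiers['product'][0]; break",
    "    print('\\t'.join([r.name, r.annotations['organism'], prod, str(r.seq).upper()]))",
    sep = "\n")
  py_path <- tempfile(fileext = ".py")
  writeLines(py, py_path)
  out <- system2("python", c(py_path, gb_path), stdout = TRUE)
  expect_length(out, 4L)
  mine <- parse_genbank(gb$text)
  for (i in seq_along(mine)) {
    ref <- strsplit(out[i], "\t", fixed = TRUE)[[1]]
    expect_identical(mine[[i]]$locus, ref[1])
    expect_identical(mine[[i]]$organism, ref[2])
    expect_identical(mine[[i]]$feature_qualifiers$product, ref[3])
    expect_identical(mine[[i]]$sequence, ref[4])
  }
})
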