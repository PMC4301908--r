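test_that("field resolution follows the documented lookup chain", {
  e <- parse_genbank(literal_genbank_record())[[1]]
  expect_identical(extract_field(e, "accession"), "AB123456")
  expect_identical(extract_field(e, "gi"), "123456789")
  expect_identical(extract_field(e, "species"), "Escherichia coli")
  expect_identical(extract_field(e, "organism"), "Escherichia coli")
  expect_identical(extract_field(e, "genus"), "Escherichia")
  expect_identical(extract_field(e, "phylum"), "Proteobacteria")
  expect_identical(extract_field(e, "gene_product"), "sugar transporter")
  expect_identical(extract_field(e, "product"), "sugar transporter")
  expect_identical(extract_field(e, "gene"), "xylE")
  expect_identical(extract_field(e, "locus_tag"), "ECX_0001")
  expect_identical(extract_field(e, "date"), "02-MAR-2013")
  expect_identical(extract_field(e, "author"), "Garcia,M. and Chen,L.")
  expect_identical(extract_field(e, "ph"), "7.2")          # source qualifier
  expect_identical(extract_field(e, "mol_type"), "genomic DNA")
})

test_that("missing metadata resolves to empty string, never an error", {
  e <- parse_genbank(literal_genbank_record())[[1]]
  for (lab in c("salinity", "temperature", "isolation_source", "pfam",
                "no_such_field")) {
    expect_identical(extract_field(e, lab), "")
  }
})

test_that("extracted values are always tab- and newline-free", {
  gb <- generate_genbank(10, seed = 5)   # record 5 and 10 plant a tab
  entries <- parse_genbank(gb$text)
  expect_true(grepl("\t", entries[[5]]$feature_qualifiers$product))
  for (e in entries) {
    for (lab in c("gene_product", "definition", "journal", "species")) {
      expect_false(grepl("[\t\r\n]", extract_field(e, lab)))
    }
  }
})

test_that("unique IDs follow the fixed-width base-36 counter scheme", {
  expect_identical(mint_unique_ids(3, "sq", 1),
                   c("sq000001", "sq000002", "sq000003"))
  expect_identical(mint_unique_ids(1, "sq", 36), "sq000010")
  # independent decode oracle: strtoi base 36 recovers the counter
  set.seed(7)
  for (rep in 1:20) {
    start <- sample.int(1000000L, 1)
    ids <- mint_unique_ids(5, "ab", start)
    expect_true(all(nchar(ids) == 8L))
    decoded <- strtoi(substring(ids, 3L), base = 36L)
    expect_identical(decoded, start + 0:4)
  }
  ids <- mint_unique_ids(10000, "x", 1)
  expect_identical(anyDuplicated(ids), 0L)
})

test_that("unique ID minting validates its inputs and capacity", {
  expect_error(mint_unique_ids(0), class = "arblink_bad_argument")
  expect_error(mint_unique_ids(1, prefix = "ABC"),
               class = "arblink_bad_argument")
  expect_error(mint_unique_ids(2, start = 36^6 - 1),
               class = "arblink_capacity_error")
  expect_identical(mint_unique_ids(1, start = 36^6 - 1), "sqzzzzzz")
})

test_that("build_records assembles the database deterministically", {
  schema <- demo_schema()
  gb <- generate_genbank(6, seed = 11)
  entries <- parse_genbank(gb$text)
  db <- build_records(entries, schema)
  expect_s3_class(db, "custom_database")
  expect_length(db, 6L)
  expect_identical(dim(db$meta), c(6L, 4L))
  # metadata values resolved in schema order
  expect_identical(unname(db$meta[1, 1]), gb$ground_truth[[1]]$accession)
  expect_identical(unname(db$meta[1, 2]), gb$ground_truth[[1]]$species)
  # manifest retains the uid -> accession correspondence
  man <- db_manifest(db)
  expect_identical(man$uid, db$uid)
  expect_identical(man$accession,
                   vapply(gb$ground_truth, `[[`, "", "accession"))
  # same input and id settings give an identical database
  db2 <- build_records(parse_genbank(gb$text), schema)
  expect_db_equal(db, db2)
  # tabs planted in qualifier values are sanitized to a single space
  gb5 <- generate_genbank(5, seed = 11)
  db5 <- build_records(parse_genbank(gb5$text), schema)
  expect_false(any(grepl("\t", db5$meta)))
})

test_that("an offline taxdump refines rank lookups", {
  dir <- tempfile("taxdump")
  dir.create(dir)
  writeLines(c(
    "1\t|\tBacteria\t|\t\t|\tscientific name\t|",
    "2\t|\tProteobacteria\t|\t\t|\tscientific name\t|",
    "3\t|\tEscherichia\t|\t\t|\tscientific name\t|",
    "4\t|\tE. coli synonym\t|\t\t|\tsynonym\t|"),
    file.path(dir, "names.dmp"))
  writeLines(c(
    "1\t|\t1\t|\tsuperkingdom\t|",
    "2\t|\t1\t|\tphylum\t|",
    "3\t|\t2\t|\tgenus\t|"),
    file.path(dir, "nodes.dmp"))
  td <- load_taxdump(dir)
  e <- parse_genbank(literal_genbank_record())[[1]]
  expect_identical(extract_field(e, "phylum", taxdump = td), "Proteobacteria")
  expect_identical(extract_field(e, "genus", taxdump = td), "Escherichia")
  expect_error(load_taxdump(tempfile()), class = "arblink_missing_file")
})
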