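test_that("the tab-delimited-header dialect renders exactly as specified", {
  schema <- meta_labels(c("accession", "species"))
  db <- custom_database(schema, "sq000001",
                        matrix(c("AB123456", "Escherichia coli"), nrow = 1),
                        "ACGT")
  expect_identical(write_database(db),
                   ">sq000001\tAB123456\tEscherichia coli\nACGT\n")
  # empty metadata values render as empty tab-delimited cells
  db2 <- custom_database(schema, c("sq000001", "sq000002"),
                         matrix(c("AB123456", "", "Escherichia coli",
                                  "Bacillus sp."), nrow = 2),
                         c("ACGT", "GGCC"))
  expect_identical(
    write_database(db2),
    ">sq000001\tAB123456\tEscherichia coli\nACGT\n>sq000002\t\tBacillus sp.\nGGCC\n")
})

test_that("sequences wrap at 70 columns on write; any wrapping reads back", {
  schema <- meta_labels("species")
  s <- paste(rep("ACGTACGTAC", 15), collapse = "")  # 150 residues
  db <- custom_database(schema, "sq000001", matrix("x", 1), s)
  lines <- strsplit(write_database(db), "\n")[[1]]
  expect_identical(nchar(lines[-1]), c(70L, 70L, 10L))
  # single-line and oddly wrapped forms parse identically
  one_line <- paste0(">sq000001\tx\n", s, "\n")
  odd_wrap <- paste0(">sq000001\tx\n", substr(s, 1, 7), "\n",
                     substr(s, 8, 150), "\n")
  expect_db_equal(read_database(one_line, schema),
                  read_database(odd_wrap, schema))
  expect_db_equal(read_database(one_line, schema), db)
})

test_that("read after write is the identity on randomized databases", {
  for (k in 1:15) {
    db <- generate_database(sample(1:40, 1), sample(1:8, 1), seed = 100 + k)
    expect_db_equal(read_database(write_database(db), db$schema), db)
  }
})

test_that("header cell-count mismatches and duplicate uids fail loudly", {
  schema <- meta_labels(c("a", "b", "c"))
  err <- expect_error(read_database(">sq000001\tonly_one\nACGT\n", schema),
                      class = "arblink_schema_mismatch")
  expect_match(conditionMessage(err), "sq000001")
  dup <- ">sq000001\tx\ty\tz\nACGT\n>sq000001\tx\ty\tz\nGGCC\n"
  expect_error(read_database(dup, schema), class = "arblink_duplicate_id")
})

test_that("bare-ID export is a uid bijection and handles gaps", {
  schema <- meta_labels("species")
  db <- custom_database(schema, c("sq000001", "sq000002", "sq000003"),
                        matrix(c("a", "b", "c"), 3),
                        c("AC-GT", "AC.GT", "ACGT"))
  fa <- export_sequences(db, strip_gaps = TRUE)
  tf <- tempfile(fileext = ".fasta")
  writeLines(fa, tf, sep = "")
  back <- Biostrings::readBStringSet(tf)   # independent FASTA reader
  expect_identical(names(back), db$uid)    # bijection, order preserved
  expect_identical(as.character(back[[1]]), "ACGT")
  expect_identical(as.character(back[[2]]), "ACGT")
  kept <- export_sequences(db, strip_gaps = FALSE)
  expect_match(kept, "AC-GT", fixed = TRUE)
  expect_match(kept, "AC.GT", fixed = TRUE)
})

test_that("aligned FASTA imports keep gaps, shapes and existing uids", {
  schema <- meta_labels(c("accession", "species"))
  fa <- paste0(">CDD001\nAC-GTACGTA\n>CDD002\nACGG-ACGTA\n>CDD003\nACGTTACG-A\n")
  meta_src <- list(CDD001 = c("CDD001", "Escherichia coli"),
                   CDD002 = c("CDD002", "Bacillus subtilis"))
  db <- import_aligned_fasta(fa, schema, metadata_source = meta_src)
  expect_length(db, 3L)
  expect_true(all(nchar(db$seq) == 10L))
  expect_match(db$seq[1], "-", fixed = TRUE)
  expect_identical(unname(db$meta[1, ]), c("CDD001", "Escherichia coli"))
  expect_identical(unname(db$meta[3, ]), c("", ""))   # unmatched -> empty row

  ragged <- ">a\nACGTACGTAC\n>b\nACGTACGTA\n"
  expect_error(import_aligned_fasta(ragged, schema),
               class = "arblink_alignment_shape")

  # headers that already are uids survive re-import unchanged
  already <- ">sq000001\nAC-GT\n>sq000002\nA-CGT\n"
  db2 <- import_aligned_fasta(already, schema)
  expect_identical(db2$uid, c("sq000001", "sq000002"))
})

test_that("ungapped residues are conserved through import and export", {
  schema <- meta_labels("species")
  fa <- ">seqA\nAC-GTA-CGT\n>seqB\n-CGTACGTA-\n"
  db <- import_aligned_fasta(fa, schema)
  exported <- export_sequences(db, strip_gaps = TRUE)
  tf <- tempfile(fileext = ".fasta")
  writeLines(exported, tf, sep = "")
  back <- Biostrings::readBStringSet(tf)
  expect_identical(unname(as.character(back)),
                   gsub("[-.]", "", c("AC-GTA-CGT", "-CGTACGTA-")))
})
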