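make_linked_fixture <- function(n = 6, seed = 2) {
  db <- build_records(parse_genbank(generate_genbank(n, seed = seed)$text),
                      demo_schema())
  tree <- generate_tree(db$uid, seed = seed)
  list(db = db, tree = tree, lt = link_tree(tree, db))
}

test_that("linking binds every leaf to a record by exact uid match", {
  fx <- make_linked_fixture()
  expect_identical(fx$lt$n_leaves, 6L)
  expect_identical(fx$lt$n_matched, 6L)
  for (uid in tree_leaf_labels(fx$tree)) {
    rec <- db_record(fx$db, uid)
    expect_identical(rec$uid, uid)
  }
  # the tree may cover a subset of the database
  sub <- generate_tree(fx$db$uid[1:3], seed = 4)
  lt <- link_tree(sub, fx$db)
  expect_identical(lt$n_matched, 3L)
})

test_that("foreign and duplicate leaves are rejected with names", {
  fx <- make_linked_fixture()
  txt <- write_newick(fx$tree)
  foreign <- sub(fx$db$uid[2], "sq999999", txt, fixed = TRUE)
  err <- expect_error(link_tree(parse_newick(foreign), fx$db),
                      class = "arblink_link_error")
  expect_match(conditionMessage(err), "sq999999")
  expect_identical(err$unmatched, "sq999999")

  dup <- sub(fx$db$uid[2], fx$db$uid[1], txt, fixed = TRUE)
  expect_error(link_tree(parse_newick(dup), fx$db),
               class = "arblink_duplicate_leaf")
})

test_that("relabeling swaps leaf labels for metadata and nothing else", {
  fx <- make_linked_fixture()
  out <- relabel_leaves(fx$lt, "gene_product")
  labs <- tree_leaf_labels(out)
  uid_order <- tree_leaf_labels(fx$tree)
  expect_identical(labs,
                   vapply(uid_order, function(u)
                     unname(db_record(fx$db, u)$metadata["gene_product"]),
                     character(1), USE.NAMES = FALSE))
  # multiword products are emitted quoted
  expect_match(write_newick(out), "'[a-z]+ [a-z]", perl = TRUE)
  # topology, lengths and internal labels untouched
  expect_identical(tree_shape_distance(fx$tree, out), 0L)
  strip_labels <- function(txt) gsub("'[^']*'|[A-Za-z0-9_.-]+(?=[:,);])", "",
                                     txt, perl = TRUE)
  expect_identical(strip_labels(write_newick(out)),
                   strip_labels(write_newick(fx$tree)))
})

test_that("relabel by uid is the identity; keep_uid restores uniqueness", {
  fx <- make_linked_fixture()
  expect_identical(write_newick(relabel_leaves(fx$lt, "uid")),
                   write_newick(fx$tree))
  kept <- relabel_leaves(fx$lt, "gene_product", sep = "|", keep_uid = TRUE)
  labs <- tree_leaf_labels(kept)
  expect_identical(anyDuplicated(labs), 0L)
  expect_true(all(grepl("^sq[0-9a-z]{6}\\|", labs)))
})

test_that("multiple fields join in order with the separator", {
  fx <- make_linked_fixture()
  out <- relabel_leaves(fx$lt, c("species", "gene_product"), sep = " / ")
  first_uid <- tree_leaf_labels(fx$tree)[1]
  rec <- db_record(fx$db, first_uid)
  expect_identical(tree_leaf_labels(out)[1],
                   paste(rec$metadata["species"],
                         rec$metadata["gene_product"], sep = " / "))
  expect_error(relabel_leaves(fx$lt, "no_such_field"),
               class = "arblink_field_error")
})
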