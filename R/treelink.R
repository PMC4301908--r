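#' Link an externally built tree to a custom database
#'
#' Trees built by outsourced services (e.g. RAxML on a remote gateway)
#' come back with leaf names equal to the unique IDs exported by
#' [export_sequences()]. Linking binds every leaf to its database record
#' by exact unique-ID match. Leaves may be a strict subset of the database
#' (records are often pruned before tree building), but a leaf absent
#' from the database breaks the linkage guarantee and is an error that
#' names every unmatched label.
#'
#' @param tree A `newick_tree` (or Newick text, which is parsed first).
#' @param db A `custom_database`.
#' @return An object of class `linked_tree`: the tree, the database, and
#'   the counts `n_leaves` and `n_matched` (equal after success).
#' @export
link_tree <- function(tree, db) {
  if (is.character(tree)) tree <- parse_newick(tree)
  stopifnot(inherits(tree, "newick_tree"), inherits(db, "custom_database"))
  leaves <- tree_leaf_labels(tree)
  if (anyDuplicated(leaves)) {
    abort_arblink(
      sprintf("duplicate leaf label(s): %s",
              paste(unique(leaves[duplicated(leaves)]), collapse = ", ")),
      "arblink_duplicate_leaf")
  }
  unmatched <- setdiff(leaves, db$uid)
  if (length(unmatched) > 0L) {
    abort_arblink(
      sprintf("leaf label(s) not found in database: %s",
              paste(unmatched, collapse = ", ")),
      "arblink_link_error", unmatched = unmatched)
  }
  structure(list(tree = tree, db = db,
                 n_leaves = length(leaves), n_matched = length(leaves)),
            class = "linked_tree")
}

#' @export
print.linked_tree <- function(x, ...) {
  cat(sprintf("<linked_tree> %d/%d leaves linked to database of %d record(s)\n",
              x$n_matched, x$n_leaves, length(x$db)))
  invisible(x)
}

#' Relabel tree leaves with metadata fields
#'
#' Replaces each leaf's unique ID with the joined values of the requested
#' metadata fields — e.g. relabel by `gene_product` to view protein
#' products on the leaves when picking product-discriminative primer
#' targets, or by `date` to follow discovery order. Topology, branch
#' lengths and internal labels are untouched; new labels are
#' Newick-quoted when needed on write. Duplicate display labels are
#' allowed (set `keep_uid = TRUE` to restore uniqueness). The pseudo-field
#' `uid` names the unique ID itself; `fields = "uid"` is the identity
#' relabeling.
#'
#' @param lt A `linked_tree` from [link_tree()].
#' @param fields Ordered character vector of schema field names (or
#'   `"uid"`).
#' @param sep Separator joining multiple field values (default `" "`).
#' @param keep_uid Prepend the unique ID to each label (default `FALSE`).
#' @return A `newick_tree` with relabeled leaves.
#' @export
relabel_leaves <- function(lt, fields, sep = " ", keep_uid = FALSE) {
  stopifnot(inherits(lt, "linked_tree"))
  known <- c("uid", as.character(lt$db$schema))
  bad <- setdiff(fields, known)
  if (length(bad) > 0L) {
    abort_arblink(
      sprintf("unknown relabel field(s): %s (schema: %s)",
              paste(bad, collapse = ", "), paste(known, collapse = ", ")),
      "arblink_field_error")
  }
  db <- lt$db
  new_label <- function(uid) {
    i <- match(uid, db$uid)
    vals <- vapply(fields, function(f) {
      if (f == "uid") uid else db$meta[i, f]
    }, character(1))
    lab <- paste(vals, collapse = sep)
    if (keep_uid) lab <- paste(c(uid, lab), collapse = sep)
    lab
  }
  walk <- function(node) {
    if (length(node$children) == 0L) {
      node$label <- new_label(node$label)
      return(node)
    }
    node$children <- lapply(node$children, walk)
    node
  }
  structure(list(root = walk(lt$tree$root)), class = "newick_tree")
}
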