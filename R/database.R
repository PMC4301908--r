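#' Custom database container
#'
#' A custom database binds an ordered set of sequence records to one
#' meta-labels schema. On disk it is a FASTA dialect where each header line
#' is a tab-delimited row: the unique ID first, then the metadata values in
#' schema order. Invariants enforced here: unique IDs are pairwise
#' distinct, every record carries exactly `length(schema)` metadata values,
#' values are tab- and newline-free, and sequences are non-empty.
#'
#' @param schema A `meta_labels` object.
#' @param uid Character vector of unique IDs.
#' @param meta Character matrix, one row per record, one column per label.
#' @param seq Character vector of residue strings (gaps `-`/`.` allowed).
#' @param manifest Optional data frame retaining provenance (uid,
#'   accession).
#' @return An object of class `custom_database`.
#' @export
custom_database <- function(schema, uid, meta, seq, manifest = NULL) {
  stopifnot(inherits(schema, "meta_labels"))
  uid <- as.character(uid)
  seq <- as.character(seq)
  if (!is.matrix(meta)) meta <- matrix(as.character(meta), nrow = length(uid))
  storage.mode(meta) <- "character"
  n <- length(uid)
  if (nrow(meta) != n || length(seq) != n) {
    abort_arblink("uid, metadata and sequence lengths differ",
                  "arblink_shape_error")
  }
  if (ncol(meta) != length(schema)) {
    abort_arblink(
      sprintf("metadata has %d column(s) but schema has %d label(s)",
              ncol(meta), length(schema)),
      "arblink_schema_mismatch")
  }
  if (anyDuplicated(uid)) {
    abort_arblink(
      sprintf("duplicate unique ID(s): %s",
              paste(unique(uid[duplicated(uid)]), collapse = ", ")),
      "arblink_duplicate_id")
  }
  if (any(!nzchar(seq))) {
    abort_arblink("empty sequence(s) in database", "arblink_shape_error")
  }
  if (any(grepl("[\t\r\n]", meta))) {
    abort_arblink("metadata values must not contain tabs or newlines",
                  "arblink_shape_error")
  }
  colnames(meta) <- as.character(schema)
  structure(list(schema = schema, uid = uid, meta = meta, seq = seq),
            manifest = manifest, class = "custom_database")
}

#' @export
print.custom_database <- function(x, ...) {
  cat(sprintf("<custom_database> %d record(s), schema: %s\n",
              length(x$uid), paste(as.character(x$schema), collapse = ", ")))
  invisible(x)
}

#' @export
length.custom_database <- function(x) length(x$uid)

#' Retrieve the uid-to-accession manifest of a database
#' @param db A `custom_database`.
#' @return A data frame (`uid`, `accession`) or `NULL` when the database
#'   was not built from GenBank entries.
#' @export
db_manifest <- function(db) attr(db, "manifest")

#' Fetch one record by unique ID
#' @param db A `custom_database`.
#' @param uid A single unique ID present in `db`.
#' @return List with `uid`, `metadata` (named character vector) and
#'   `sequence`.
#' @export
db_record <- function(db, uid) {
  i <- match(uid, db$uid)
  if (is.na(i)) {
    abort_arblink(sprintf("unique ID not in database: %s", uid),
                  "arblink_link_error")
  }
  list(uid = db$uid[i], metadata = db$meta[i, , drop = TRUE],
       sequence = db$seq[i])
}

#' Write a custom database to its tab-delimited-header FASTA form
#'
#' Each record renders as `>`uid TAB value1 TAB ... TAB valueN on one
#' header line, followed by the sequence wrapped at 70 columns. Record
#' order is preserved; the output ends with a newline. The rendering is a
#' pure function of the database, so identical databases produce
#' byte-identical files.
#'
#' @param db A `custom_database`.
#' @param path Optional output path; when given the content is also
#'   written to disk.
#' @return The file content as a single string (invisibly when `path` is
#'   given).
#' @export
write_database <- function(db, path = NULL) {
  stopifnot(inherits(db, "custom_database"))
  headers <- paste0(">", db$uid,
                    apply_header_cells(db$meta))
  body <- vapply(db$seq, wrap_seq, character(1), USE.NAMES = FALSE)
  content <- paste0(paste(rbind(headers, body), collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(content, path, sep = "")
    return(invisible(content))
  }
  content
}

apply_header_cells <- function(meta) {
  if (ncol(meta) == 0L) return(rep("", nrow(meta)))
  apply(meta, 1L, function(r) paste0("\t", paste(r, collapse = "\t")))
}

wrap_seq <- function(s, width = 70L) {
  n <- nchar(s)
  starts <- seq(1L, n, by = width)
  paste(substring(s, starts, pmin(starts + width - 1L, n)), collapse = "\n")
}

#' Read a custom database written by [write_database()]
#'
#' Exact inverse of [write_database()] on its image. Any sequence-line
#' wrapping is accepted. Each header must split into exactly
#' `1 + length(schema)` tab-delimited cells (the unique ID plus one cell
#' per label); a mismatch is an error rather than silent padding, because
#' padding would mask schema drift between the meta-labels file and the
#' database.
#'
#' @param text File content (single string or vector of lines), or use
#'   `path`.
#' @param schema The `meta_labels` schema the file must conform to.
#' @param path Optional file path, used when `text` is missing.
#' @return A `custom_database`.
#' @export
read_database <- function(text, schema, path = NULL) {
  stopifnot(inherits(schema, "meta_labels"))
  if (missing(text)) {
    if (is.null(path) || !file.exists(path)) {
      abort_arblink(sprintf("database file not found: %s", path %||% "<none>"),
                    "arblink_missing_file", category = "arblink_io")
    }
    text <- readLines(path, warn = FALSE)
  }
  lines <- if (length(text) == 1L) {
    strsplit(gsub("\r\n?", "\n", text), "\n", fixed = TRUE)[[1]]
  } else {
    sub("\r$", "", text)
  }
  hdr_i <- which(startsWith(lines, ">"))
  if (length(hdr_i) == 0L) {
    abort_arblink("no FASTA headers found in database file",
                  "arblink_empty_input")
  }
  ends <- c(hdr_i[-1L] - 1L, length(lines))
  n <- length(hdr_i)
  uid <- character(n)
  meta <- matrix("", nrow = n, ncol = length(schema))
  seqs <- character(n)
  for (k in seq_len(n)) {
    cells <- split_keep_empty(substring(lines[hdr_i[k]], 2L), "\t")
    if (length(cells) != 1L + length(schema)) {
      abort_arblink(
        sprintf("schema mismatch at line %d (record '%s'): header has %d cell(s), schema requires %d",
                hdr_i[k], cells[1L], length(cells), 1L + length(schema)),
        "arblink_schema_mismatch")
    }
    uid[k] <- cells[1L]
    if (length(schema) > 0L) meta[k, ] <- cells[-1L]
    body <- if (ends[k] > hdr_i[k]) lines[(hdr_i[k] + 1L):ends[k]] else character(0)
    seqs[k] <- paste(trimws(body), collapse = "")
  }
  if (anyDuplicated(uid)) {
    abort_arblink(
      sprintf("duplicate unique ID(s) in database file: %s",
              paste(unique(uid[duplicated(uid)]), collapse = ", ")),
      "arblink_duplicate_id")
  }
  custom_database(schema, uid, meta, seqs)
}

#' Export the bare-ID FASTA for outsourced computation
#'
#' Writes plain FASTA whose headers carry only the unique ID, in database
#' order — the file handed to external alignment/tree services (e.g. a
#' MAFFT + RAxML pipeline on a remote gateway). The returned tree's leaf
#' names are then exactly the database's unique IDs, which is what makes
#' re-linking ([link_tree()]) lossless.
#'
#' @param db A `custom_database`.
#' @param strip_gaps Remove alignment gaps (`-` and `.`) from the
#'   sequences (default `TRUE`: external aligners expect unaligned input).
#' @param path Optional output path.
#' @return FASTA content as a single string (invisibly when `path` is
#'   given).
#' @export
export_sequences <- function(db, strip_gaps = TRUE, path = NULL) {
  stopifnot(inherits(db, "custom_database"))
  seqs <- db$seq
  if (strip_gaps) seqs <- gsub("[-.]", "", seqs)
  if (any(!nzchar(seqs))) {
    abort_arblink("record became empty after gap stripping",
                  "arblink_shape_error")
  }
  body <- vapply(seqs, wrap_seq, character(1), USE.NAMES = FALSE)
  content <- paste0(paste(rbind(paste0(">", db$uid), body), collapse = "\n"),
                    "\n")
  if (!is.null(path)) {
    writeLines(content, path, sep = "")
    return(invisible(content))
  }
  content
}

#' Import a pre-aligned FASTA (e.g. a curated CDD family export)
#'
#' Builds a custom database from an externally aligned FASTA file, keeping
#' the gaps. All sequences must share one aligned length. Headers that are
#' already valid unique IDs of this toolkit are preserved (re-minting
#' would sever previously exported trees from the database); otherwise
#' fresh IDs are minted and the original header is kept in the manifest.
#' Metadata rows come from `metadata_source`, keyed by the full header
#' word; unmatched headers get an empty metadata row.
#'
#' @param text Aligned FASTA content (single string or lines), or use
#'   `path`.
#' @param schema A `meta_labels` schema.
#' @param metadata_source Optional named list/matrix lookup: header (or
#'   uid) to character vector of metadata values in schema order.
#' @param prefix,start Passed to [mint_unique_ids()] for headers that are
#'   not already unique IDs.
#' @param path Optional file path, used when `text` is missing.
#' @return A `custom_database` whose sequences retain their gaps.
#' @export
import_aligned_fasta <- function(text, schema, metadata_source = NULL,
                                 prefix = "sq", start = 1, path = NULL) {
  stopifnot(inherits(schema, "meta_labels"))
  if (missing(text)) {
    if (is.null(path) || !file.exists(path)) {
      abort_arblink(sprintf("FASTA file not found: %s", path %||% "<none>"),
                    "arblink_missing_file", category = "arblink_io")
    }
    fa <- Biostrings::readBStringSet(path)
  } else {
    tf <- tempfile(fileext = ".fasta")
    on.exit(unlink(tf), add = TRUE)
    writeLines(if (length(text) == 1L) text else paste(text, collapse = "\n"),
               tf, sep = if (length(text) == 1L) "" else "\n")
    fa <- Biostrings::readBStringSet(tf)
  }
  if (length(fa) == 0L) {
    abort_arblink("no sequences in aligned FASTA", "arblink_empty_input")
  }
  lens <- Biostrings::width(fa)
  if (length(unique(lens)) != 1L) {
    abort_arblink(
      sprintf("ragged alignment: sequence lengths %s are not all equal",
              paste(sort(unique(lens)), collapse = ", ")),
      "arblink_alignment_shape")
  }
  headers <- sub("\\s.*$", "", names(fa))
  is_uid <- grepl("^[a-z0-9]{1,2}[0-9a-z]{6}$", headers) & nchar(headers) <= 8L
  uids <- headers
  n_new <- sum(!is_uid)
  if (n_new > 0L) {
    uids[!is_uid] <- mint_unique_ids(n_new, prefix = prefix, start = start)
  }
  meta <- matrix("", nrow = length(fa), ncol = length(schema))
  if (!is.null(metadata_source)) {
    for (k in seq_along(fa)) {
      row <- metadata_source[[headers[k]]] %||% metadata_source[[uids[k]]]
      if (!is.null(row)) {
        if (length(row) != length(schema)) {
          abort_arblink(
            sprintf("metadata for '%s' has %d value(s), schema requires %d",
                    headers[k], length(row), length(schema)),
            "arblink_schema_mismatch")
        }
        meta[k, ] <- sanitize_value(as.character(row))
      }
    }
  }
  custom_database(schema, uids, meta, as.character(fa),
                  manifest = data.frame(uid = uids, accession = headers,
                                        stringsAsFactors = FALSE))
}
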