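#' Meta-labels: the metadata schema of the pipeline
#'
#' A meta-labels file is a plain-text file with one metadata field name per
#' line (blank lines and `#` comments are ignored). It defines, in order, the
#' metadata columns of the custom database header, the fields written by the
#' generated ARB import filter, and the fields available for tree leaf
#' relabeling. Field names are normalized to ARB-safe identifiers (lowercase
#' letters, digits and underscores, starting with a letter) before
#' validation; order is preserved exactly as read.
#'
#' @param text Character. Raw file content, or a character vector of lines.
#' @param path Optional path of the source file (stored for provenance; when
#'   given and `text` is missing, the file is read).
#'
#' @return An object of class `meta_labels`: a character vector of normalized
#'   labels with attribute `source_path`.
#'
#' @examples
#' parse_meta_labels("Accession\nSpecies\nGene Product\n")
#'
#' @export
parse_meta_labels <- function(text, path = NULL) {
  if (missing(text)) {
    if (is.null(path)) {
      abort_arblink("either `text` or `path` must be supplied",
                    "arblink_schema_empty")
    }
    if (!file.exists(path)) {
      abort_arblink(sprintf("meta-labels schema file not found: %s", path),
                    "arblink_missing_file", category = "arblink_io")
    }
    text <- readLines(path, warn = FALSE)
  }
  lines <- if (length(text) == 1L) {
    strsplit(gsub("\r\n?", "\n", text), "\n", fixed = TRUE)[[1]]
  } else {
    sub("\r$", "", text)
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    abort_arblink("meta-labels schema is empty (no field names found)",
                  "arblink_schema_empty")
  }
  labels <- vapply(lines, normalize_label, character(1), USE.NAMES = FALSE)
  dup <- labels[duplicated(labels)]
  if (length(dup) > 0L) {
    abort_arblink(
      sprintf("duplicate meta-label(s) after normalization: %s",
              paste(unique(dup), collapse = ", ")),
      "arblink_duplicate_label")
  }
  meta_labels(labels, source_path = path)
}

#' @rdname parse_meta_labels
#' @param labels Character vector of already-normalized labels.
#' @param source_path Optional provenance string.
#' @export
meta_labels <- function(labels, source_path = NULL) {
  if (length(labels) == 0L) {
    abort_arblink("meta-labels schema is empty", "arblink_schema_empty")
  }
  bad <- labels[!grepl("^[a-z][a-z0-9_]*$", labels)]
  if (length(bad) > 0L) {
    abort_arblink(
      sprintf("illegal meta-label(s): %s (must be lowercase identifier starting with a letter)",
              paste(bad, collapse = ", ")),
      "arblink_illegal_label")
  }
  if (anyDuplicated(labels)) {
    abort_arblink(
      sprintf("duplicate meta-label(s): %s",
              paste(unique(labels[duplicated(labels)]), collapse = ", ")),
      "arblink_duplicate_label")
  }
  structure(as.character(labels), source_path = source_path,
            class = "meta_labels")
}

#' Normalize a metadata field name to an ARB-safe identifier
#'
#' Trims, lowercases, and collapses runs of whitespace and hyphens to a
#' single underscore. The mapping is idempotent. Names that normalize to
#' something other than `[a-z][a-z0-9_]*` (e.g. starting with a digit, or
#' empty after trimming) are rejected.
#'
#' @param raw A single field name as written by the user (e.g. "Gene Product").
#' @return The normalized name (e.g. "gene_product").
#' @export
normalize_label <- function(raw) {
  if (length(raw) != 1L || is.na(raw)) {
    abort_arblink("label must be a single string", "arblink_illegal_label")
  }
  x <- trimws(raw)
  if (!nzchar(x)) {
    abort_arblink("empty meta-label", "arblink_illegal_label")
  }
  x <- tolower(x)
  x <- gsub("[[:space:]-]+", "_", x)
  if (!grepl("^[a-z][a-z0-9_]*$", x)) {
    abort_arblink(
      sprintf("illegal meta-label %s (normalizes to '%s'; must start with a letter and contain only a-z, 0-9, _)",
              dQuote(raw, q = FALSE), x),
      "arblink_illegal_label")
  }
  x
}

#' @export
print.meta_labels <- function(x, ...) {
  cat(sprintf("<meta_labels> %d field(s): %s\n",
              length(x), paste(unclass(x), collapse = ", ")))
  invisible(x)
}

#' @export
format.meta_labels <- function(x, ...) paste0(unclass(x), collapse = "\n")

#' Render a meta-labels schema back to file form (one label per line)
#' @param x A `meta_labels` object.
#' @return A single string, one label per line, trailing newline.
#' @export
render_meta_labels <- function(x) {
  stopifnot(inherits(x, "meta_labels"))
  paste0(paste(unclass(x), collapse = "\n"), "\n")
}
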