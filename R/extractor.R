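#' Resolve a metadata field from a GenBank entry
#'
#' Resolution follows a fixed lookup chain and never fails; missing data is
#' the empty string by contract (environmental fields such as pH or salinity
#' are simply absent from most GenBank records):
#' \enumerate{
#'   \item built-in resolvers for well-known labels: `accession`, `gi`,
#'     `version`, `definition`, `locus`, `organism`/`species`, `genus`
#'     (first whitespace token of the organism name), `phylum` (second
#'     lineage token by position, refined when a taxdump is supplied),
#'     `product`/`gene_product`, `gene`, `locus_tag`, `date` (LOCUS line),
#'     `author`/`authors`, `journal`, `title`;
#'   \item source-feature qualifiers (e.g. `ph`, `salinity`, `temperature`,
#'     `isolation_source` when present);
#'   \item qualifiers pooled over all non-source features;
#'   \item otherwise `""`.
#' }
#' Returned values are always tab- and newline-free (runs collapse to a
#' single space) because the database header is tab-delimited.
#'
#' @param entry A `genbank_entry` from [parse_genbank()].
#' @param label A normalized field name (see [normalize_label()]).
#' @param taxdump Optional taxonomy table from [load_taxdump()], used to
#'   refine rank-based labels (`genus`, `phylum`).
#' @return A single string; `""` when the field is not present.
#' @export
extract_field <- function(entry, label, taxdump = NULL) {
  stopifnot(inherits(entry, "genbank_entry"))
  val <- switch(label,
    accession  = entry$accession,
    gi         = entry$gi,
    version    = entry$version,
    definition = entry$definition,
    locus      = entry$locus,
    organism   = ,
    species    = entry$organism,
    genus      = resolve_rank(entry, "genus", taxdump),
    phylum     = resolve_rank(entry, "phylum", taxdump),
    product    = ,
    gene_product = entry$feature_qualifiers[["product"]] %||% "",
    gene       = entry$feature_qualifiers[["gene"]] %||% "",
    locus_tag  = entry$feature_qualifiers[["locus_tag"]] %||% "",
    date       = entry$date,
    author     = ,
    authors    = if (length(entry$references)) entry$references[[1L]]$authors else "",
    journal    = if (length(entry$references)) entry$references[[1L]]$journal else "",
    title      = if (length(entry$references)) entry$references[[1L]]$title else "",
    NULL)
  if (is.null(val)) val <- entry$source_qualifiers[[label]]
  if (is.null(val)) val <- entry$feature_qualifiers[[label]]
  if (is.null(val) || length(val) == 0L || is.na(val)) val <- ""
  sanitize_value(val)
}

# Tab/newline sanitization: header cells must be tab- and newline-free.
sanitize_value <- function(x) {
  gsub("[\t\r\n]+", " ", x)
}

resolve_rank <- function(entry, rank, taxdump = NULL) {
  if (!is.null(taxdump)) {
    hit <- taxdump_rank(taxdump, entry$organism, entry$taxonomy_lineage, rank)
    if (nzchar(hit)) return(hit)
  }
  if (rank == "genus") {
    if (!nzchar(entry$organism)) return("")
    return(strsplit(trimws(entry$organism), "\\s+")[[1L]][1L])
  }
  if (rank == "phylum") {
    # position-based default: superkingdom; phylum; ... in NCBI lineage order
    if (length(entry$taxonomy_lineage) >= 2L) {
      return(entry$taxonomy_lineage[2L])
    }
    return("")
  }
  ""
}

#' Mint deterministic unique sequence identifiers
#'
#' IDs are a short lowercase prefix followed by a zero-padded base-36
#' counter of fixed width 6 (digits `0-9a-z`), e.g. `sq000001`. The total
#' length never exceeds 8 characters, matching ARB's convention of a short
#' unique key in the per-species `name` field. The scheme is a pure
#' function of `(prefix, start)`, so reruns of an extraction are
#' reproducible and previously exported trees stay linked.
#'
#' @param n Number of IDs to mint (>= 1).
#' @param prefix Lowercase alphanumeric prefix, at most 2 characters.
#' @param start First counter value (>= 0).
#' @return Character vector of `n` distinct IDs for counters
#'   `start, start+1, ..., start+n-1`.
#' @examples
#' mint_unique_ids(3)                 # sq000001 sq000002 sq000003
#' mint_unique_ids(1, start = 36)     # sq000010
#' @export
mint_unique_ids <- function(n, prefix = "sq", start = 1) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    abort_arblink("`n` must be a positive integer", "arblink_bad_argument")
  }
  if (!grepl("^[a-z0-9]{1,2}$", prefix)) {
    abort_arblink("`prefix` must be 1-2 lowercase alphanumeric characters",
                  "arblink_bad_argument")
  }
  if (!is.numeric(start) || start < 0 || start != floor(start)) {
    abort_arblink("`start` must be a non-negative integer", "arblink_bad_argument")
  }
  width <- 6L
  cap <- 36^width
  if (start + n - 1 >= cap) {
    abort_arblink(
      sprintf("unique-ID capacity exceeded: counter %s does not fit in %d base-36 digits",
              format(start + n - 1, scientific = FALSE), width),
      "arblink_capacity_error")
  }
  paste0(prefix, vapply(start + seq_len(n) - 1, encode_base36, character(1),
                        width = width))
}

encode_base36 <- function(x, width = 6L) {
  digits36 <- c(0:9, letters)
  out <- character(width)
  for (i in seq_len(width)) {
    out[width - i + 1L] <- digits36[(x %% 36) + 1L]
    x <- x %/% 36
  }
  paste(out, collapse = "")
}

#' Build a custom database from parsed GenBank entries
#'
#' Mints unique IDs in entry order, resolves every schema field via
#' [extract_field()], and assembles a [custom_database()]. The ID-to-
#' accession correspondence is retained in the database manifest
#' (`db_manifest()`), so metadata can later be added to existing records.
#'
#' @param entries List of `genbank_entry` objects (non-empty).
#' @param schema A `meta_labels` schema.
#' @param prefix,start Passed to [mint_unique_ids()].
#' @param taxdump Optional taxonomy table from [load_taxdump()].
#' @return A `custom_database`.
#' @export
build_records <- function(entries, schema, prefix = "sq", start = 1,
                          taxdump = NULL) {
  stopifnot(inherits(schema, "meta_labels"))
  if (length(entries) == 0L) {
    abort_arblink("no entries to build records from", "arblink_empty_input")
  }
  uids <- mint_unique_ids(length(entries), prefix = prefix, start = start)
  meta <- matrix("", nrow = length(entries), ncol = length(schema),
                 dimnames = list(NULL, as.character(schema)))
  seqs <- character(length(entries))
  acc <- character(length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    for (j in seq_along(schema)) {
      meta[i, j] <- extract_field(e, schema[[j]], taxdump = taxdump)
    }
    seqs[i] <- e$sequence
    acc[i] <- e$accession
  }
  custom_database(schema, uids, meta, seqs,
                  manifest = data.frame(uid = uids, accession = acc,
                                        stringsAsFactors = FALSE))
}

#' Load an offline NCBI taxdump for rank refinement
#'
#' Reads `names.dmp` and `nodes.dmp` (pipe-delimited NCBI taxonomy dump
#' dialect) and returns a lookup table mapping scientific names to ranks.
#' Entirely optional: without it, `genus` and `phylum` fall back to the
#' positional heuristics documented in [extract_field()].
#'
#' @param dir Directory containing `names.dmp` and `nodes.dmp`.
#' @return An object of class `arblink_taxdump` (a data frame of
#'   `name`, `rank`).
#' @export
load_taxdump <- function(dir) {
  names_f <- file.path(dir, "names.dmp")
  nodes_f <- file.path(dir, "nodes.dmp")
  if (!file.exists(names_f) || !file.exists(nodes_f)) {
    abort_arblink(sprintf("taxdump directory %s must contain names.dmp and nodes.dmp", dir),
                  "arblink_missing_file", category = "arblink_io")
  }
  parse_dmp <- function(path) {
    rows <- readLines(path, warn = FALSE)
    rows <- sub("\\s*\\|\\s*$", "", rows)
    do.call(rbind, strsplit(rows, "\\s*\\|\\s*"))
  }
  nm <- parse_dmp(names_f)   # taxid | name | unique name | name class
  nd <- parse_dmp(nodes_f)   # taxid | parent | rank | ...
  nm <- nm[nm[, 4L] == "scientific name", , drop = FALSE]
  rank <- nd[match(nm[, 1L], nd[, 1L]), 3L]
  structure(data.frame(name = nm[, 2L], rank = rank,
                       stringsAsFactors = FALSE),
            class = c("arblink_taxdump", "data.frame"))
}

taxdump_rank <- function(taxdump, organism, lineage, rank) {
  candidates <- c(lineage, organism,
                  if (nzchar(organism)) strsplit(trimws(organism), "\\s+")[[1L]][1L])
  hits <- taxdump$name[taxdump$rank == rank]
  found <- candidates[candidates %in% hits]
  if (length(found) > 0L) found[1L] else ""
}
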