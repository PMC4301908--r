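#' ARB import filter generation and reference interpretation
#'
#' ARB ingests flat files through declarative import filters (`.ift`
#' files). The dialect emitted here is a conservative, documented subset
#' of ARB's directives — `AUTODETECT`, `KEYWIDTH`, `BEGIN`, one
#' `MATCH`/`TABCOLUMN`/`WRITE` block per field, `SEQUENCEAFTER`,
#' `SEQUENCEEND`, `END` — in which the column-extraction step is a single
#' `TABCOLUMN <i>` directive: split the text matched by the `*` of the
#' `MATCH` pattern on tabs and take the zero-based column `i`. ARB's full
#' search-replace (SRT) micro-syntax is deliberately abstracted behind
#' this directive so a bit-exact SRT backend can be swapped in later; the
#' reference interpreter [apply_filter()] defines the semantics and makes
#' filter correctness testable without an ARB installation.
#'
#' The first rule always writes ARB's reserved per-species key field
#' `name` from column 0 (the unique ID); rule `i > 1` writes schema label
#' `i - 1` from column `i - 1`. ARB's tree import matches tree leaves
#' against `name`, which is exactly the unique-ID linkage this toolkit
#' relies on.
#'
#' @name iftgen
NULL

#' Build the import filter for a meta-labels schema
#'
#' @param schema A `meta_labels` object.
#' @return An object of class `import_filter` with exactly
#'   `1 + length(schema)` field rules. Equal schemas render to
#'   byte-identical filters.
#' @export
build_import_filter <- function(schema) {
  stopifnot(inherits(schema, "meta_labels"))
  fields <- c("name", as.character(schema))
  rules <- lapply(seq_along(fields) - 1L, function(i) {
    field_rule(match_pattern = ">*", column = i, target_field = fields[i + 1L])
  })
  import_filter(
    autodetect_pattern = ">*",
    keywidth = max(nchar(fields)),
    begin_pattern = ">*",
    rules = rules,
    sequence_after = ">*",
    sequence_end = ">*",
    end_pattern = "//"
  )
}

#' @rdname build_import_filter
#' @param match_pattern Glob pattern a header line must match (`*` is the
#'   wildcard; the text it captures feeds the column extraction).
#' @param column Zero-based tab-column index extracted from the matched
#'   text.
#' @param target_field ARB database field written by the rule.
#' @export
field_rule <- function(match_pattern, column, target_field) {
  stopifnot(is.character(match_pattern), length(match_pattern) == 1L)
  if (!grepl("^[a-z][a-z0-9_]*$", target_field)) {
    abort_arblink(
      sprintf("unsafe WRITE target field: '%s'", target_field),
      "arblink_illegal_label")
  }
  structure(list(match_pattern = match_pattern, column = as.integer(column),
                 target_field = target_field),
            class = "field_rule")
}

#' @rdname build_import_filter
#' @param autodetect_pattern,keywidth,begin_pattern,rules,sequence_after,sequence_end,end_pattern
#'   Filter components; see [iftgen].
#' @export
import_filter <- function(autodetect_pattern, keywidth, begin_pattern, rules,
                          sequence_after, sequence_end, end_pattern) {
  cols <- vapply(rules, function(r) r$column, integer(1))
  tgts <- vapply(rules, function(r) r$target_field, character(1))
  if (anyDuplicated(cols) || anyDuplicated(tgts)) {
    abort_arblink("field rules must have unique columns and target fields",
                  "arblink_schema_mismatch")
  }
  if (length(rules) == 0L || tgts[1L] != "name") {
    abort_arblink("the first filter rule must write the reserved field 'name'",
                  "arblink_schema_mismatch")
  }
  structure(list(autodetect_pattern = autodetect_pattern,
                 keywidth = as.integer(keywidth),
                 begin_pattern = begin_pattern,
                 rules = rules,
                 sequence_after = sequence_after,
                 sequence_end = sequence_end,
                 end_pattern = end_pattern),
            class = "import_filter")
}

#' @export
print.import_filter <- function(x, ...) {
  cat(sprintf("<import_filter> %d field rule(s): %s\n", length(x$rules),
              paste(vapply(x$rules, `[[`, character(1), "target_field"),
                    collapse = ", ")))
  invisible(x)
}

#' Render an import filter to .ift text
#'
#' Rendering is a pure function of the filter: equal filters give
#' byte-identical text. The conventional output file name is
#' `custom_import_filter.ift`, to be placed in ARB's import-filter
#' directory `/arb/lib/import/`.
#'
#' @param filter An `import_filter`.
#' @param path Optional output path.
#' @return The .ift content as a single string (invisibly when `path` is
#'   given).
#' @export
render_ift <- function(filter, path = NULL) {
  stopifnot(inherits(filter, "import_filter"))
  q <- function(x) paste0("\"", x, "\"")
  lines <- c(
    "# custom_import_filter.ift",
    "# import filter for a tab-delimited-header FASTA custom database",
    "# install into /arb/lib/import/",
    paste0("AUTODETECT\t", q(filter$autodetect_pattern)),
    paste0("KEYWIDTH\t", filter$keywidth),
    "",
    paste0("BEGIN\t", q(filter$begin_pattern))
  )
  for (r in filter$rules) {
    lines <- c(lines,
               "",
               paste0("MATCH\t", q(r$match_pattern)),
               paste0("\tTABCOLUMN\t", r$column),
               paste0("\tWRITE\t", q(r$target_field)))
  }
  lines <- c(lines,
             "",
             paste0("SEQUENCEAFTER\t", q(filter$sequence_after)),
             paste0("SEQUENCEEND\t", q(filter$sequence_end)),
             paste0("END\t", q(filter$end_pattern)))
  content <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(content, path, sep = "")
    return(invisible(content))
  }
  content
}

#' Parse .ift text back into an import filter
#'
#' Inverse of [render_ift()] on its image ( `parse_ift(render_ift(f))`
#' equals `f` ). Comment lines (`#`) and blank lines are ignored.
#'
#' @param text .ift content (single string or vector of lines).
#' @return An `import_filter`.
#' @export
parse_ift <- function(text) {
  lines <- if (length(text) == 1L) {
    strsplit(gsub("\r\n?", "\n", text), "\n", fixed = TRUE)[[1]]
  } else {
    sub("\r$", "", text)
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unq <- function(x) sub("^\"(.*)\"$", "\\1", x)
  vals <- list()
  rules <- list()
  cur <- NULL
  push_rule <- function() {
    if (!is.null(cur)) {
      if (is.null(cur$column) || is.null(cur$target_field)) {
        abort_arblink("incomplete MATCH block in .ift (needs TABCOLUMN and WRITE)",
                      "arblink_ift_parse_error")
      }
      rules[[length(rules) + 1L]] <<- field_rule(cur$match_pattern,
                                                 cur$column, cur$target_field)
    }
    cur <<- NULL
  }
  for (ln in lines) {
    toks <- strsplit(ln, "\t+|\\s{2,}|\t| ")[[1]]
    toks <- toks[nzchar(toks)]
    key <- toks[1L]
    arg <- if (length(toks) > 1L) paste(toks[-1L], collapse = " ") else ""
    switch(key,
      AUTODETECT = { vals$autodetect_pattern <- unq(arg) },
      KEYWIDTH = { vals$keywidth <- as.integer(arg) },
      BEGIN = { vals$begin_pattern <- unq(arg) },
      MATCH = { push_rule(); cur <- list(match_pattern = unq(arg)) },
      TABCOLUMN = {
        if (is.null(cur)) abort_arblink("TABCOLUMN outside MATCH block",
                                        "arblink_ift_parse_error")
        cur$column <- as.integer(arg)
      },
      WRITE = {
        if (is.null(cur)) abort_arblink("WRITE outside MATCH block",
                                        "arblink_ift_parse_error")
        cur$target_field <- unq(arg)
      },
      SEQUENCEAFTER = { vals$sequence_after <- unq(arg) },
      SEQUENCEEND = { vals$sequence_end <- unq(arg) },
      END = { vals$end_pattern <- unq(arg) },
      abort_arblink(sprintf("unknown .ift directive: %s", key),
                    "arblink_ift_parse_error")
    )
  }
  push_rule()
  need <- c("autodetect_pattern", "keywidth", "begin_pattern",
            "sequence_after", "sequence_end", "end_pattern")
  missing_d <- setdiff(need, names(vals))
  if (length(missing_d) > 0L) {
    abort_arblink(sprintf("missing .ift directive(s): %s",
                          paste(toupper(sub("_pattern$|_after$|_end$", "",
                                            missing_d)), collapse = ", ")),
                  "arblink_ift_parse_error")
  }
  import_filter(vals$autodetect_pattern, vals$keywidth, vals$begin_pattern,
                rules, vals$sequence_after, vals$sequence_end,
                vals$end_pattern)
}

#' Reference interpreter: apply an import filter to flat-file text
#'
#' Stands in for ARB's importer so the generated filter can be validated
#' end-to-end: for each entry delimited by the `BEGIN` pattern, every
#' field rule's tab-column extraction is evaluated on the header and bound
#' to its target field; the lines up to the next entry are collected as
#' the sequence.
#'
#' @param filter An `import_filter`.
#' @param text Custom-database file content (single string or lines).
#' @return A list with one element per entry: `fields` (named character
#'   vector, including `name`) and `sequence`.
#' @export
apply_filter <- function(filter, text) {
  stopifnot(inherits(filter, "import_filter"))
  lines <- if (length(text) == 1L) {
    strsplit(gsub("\r\n?", "\n", text), "\n", fixed = TRUE)[[1]]
  } else {
    sub("\r$", "", text)
  }
  rx <- utils::glob2rx(filter$begin_pattern)
  hdr_i <- which(grepl(rx, lines))
  if (length(hdr_i) == 0L) return(list())
  ends <- c(hdr_i[-1L] - 1L, length(lines))
  max_col <- max(vapply(filter$rules, function(r) r$column, integer(1)))
  headers <- lines[hdr_i]

  # rules sharing a MATCH pattern share one extraction pass over the headers
  patterns <- vapply(filter$rules, function(r) r$match_pattern, character(1))
  cell_sets <- lapply(unique(patterns), function(p) {
    captured <- vapply(headers, glob_capture, character(1),
                       pattern = p, USE.NAMES = FALSE)
    n_cells <- nchar(captured) -
      nchar(gsub("\t", "", captured, fixed = TRUE)) + 1L
    short <- which(n_cells <= max_col)
    if (length(short) > 0L) {
      k <- short[1L]
      first_cell <- strsplit(captured[k], "\t", fixed = TRUE)[[1]][1L]
      abort_arblink(
        sprintf("import error at entry '%s' (line %d): header has %d tab column(s), filter requires %d",
                first_cell %||% "", hdr_i[k], n_cells[k], max_col + 1L),
        "arblink_import_error")
    }
    parts <- strsplit(captured, "\t", fixed = TRUE)
    lapply(seq_along(parts), function(k) {
      c(parts[[k]], rep("", n_cells[k] - length(parts[[k]])))
    })
  })
  names(cell_sets) <- unique(patterns)

  out <- vector("list", length(hdr_i))
  targets <- vapply(filter$rules, function(r) r$target_field, character(1))
  cols <- vapply(filter$rules, function(r) r$column, integer(1))
  for (k in seq_along(hdr_i)) {
    fields <- vapply(seq_along(filter$rules), function(j) {
      cell_sets[[patterns[j]]][[k]][cols[j] + 1L]
    }, character(1))
    names(fields) <- targets
    body <- if (ends[k] > hdr_i[k]) lines[(hdr_i[k] + 1L):ends[k]] else character(0)
    out[[k]] <- list(fields = fields,
                     sequence = paste(trimws(body), collapse = ""))
  }
  out
}

# Text captured by the single '*' of a glob pattern: strip the literal
# prefix (before '*') and suffix (after '*') from the line.
glob_capture <- function(pattern, line) {
  star <- regexpr("*", pattern, fixed = TRUE)
  if (star == -1L) return(line)
  prefix <- substr(pattern, 1L, star - 1L)
  suffix <- substr(pattern, star + 1L, nchar(pattern))
  if (nzchar(prefix) && startsWith(line, prefix)) {
    line <- substr(line, nchar(prefix) + 1L, nchar(line))
  }
  if (nzchar(suffix) && endsWith(line, suffix)) {
    line <- substr(line, 1L, nchar(line) - nchar(suffix))
  }
  line
}
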