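#' Parse GenBank flat files
#'
#' Parses one or more concatenated GenBank records (`LOCUS` ... `//`) from
#' text. Each record yields a `genbank_entry`: identification fields, the
#' organism and its taxonomy lineage, source-feature qualifiers, pooled
#' qualifiers from all other features (first occurrence wins, in file
#' order), references, and the residue string with the `ORIGIN` block's
#' coordinates and spacing stripped.
#'
#' @param text Character. Flat-file content (single string or vector of
#'   lines), or use `path` to read a file.
#' @param path Optional file path; used when `text` is missing.
#'
#' @return A list of `genbank_entry` objects, in file order. Each entry has
#'   elements `locus`, `accession`, `version`, `gi`, `definition`, `date`,
#'   `organism`, `taxonomy_lineage`, `source_qualifiers`,
#'   `feature_qualifiers`, `references`, `sequence`.
#' @export
parse_genbank <- function(text, path = NULL) {
  if (missing(text)) {
    if (is.null(path) || !file.exists(path)) {
      abort_arblink(sprintf("GenBank file not found: %s", path %||% "<none>"),
                    "arblink_missing_file", category = "arblink_io")
    }
    text <- readLines(path, warn = FALSE)
  }
  lines <- if (length(text) == 1L) {
    strsplit(gsub("\r\n?", "\n", text), "\n", fixed = TRUE)[[1]]
  } else {
    sub("\r$", "", text)
  }

  term <- which(trimws(lines) == "//")
  if (length(term) == 0L) {
    if (all(!nzchar(trimws(lines)))) {
      abort_arblink("no GenBank records found in input", "arblink_empty_input")
    }
    abort_arblink("truncated GenBank input: no record terminator '//' found",
                  "arblink_truncated_record")
  }
  tail_lines <- if (max(term) < length(lines)) lines[(max(term) + 1L):length(lines)] else character(0)
  if (any(nzchar(trimws(tail_lines)))) {
    abort_arblink("truncated GenBank input: content after last '//' lacks a terminator",
                  "arblink_truncated_record")
  }

  starts <- c(1L, head(term, -1L) + 1L)
  entries <- vector("list", length(term))
  for (k in seq_along(term)) {
    chunk <- lines[starts[k]:(term[k] - 1L)]
    entries[[k]] <- parse_genbank_record(chunk)
  }
  if (length(entries) == 0L) {
    abort_arblink("no GenBank records found in input", "arblink_empty_input")
  }
  entries
}

# One record (lines between LOCUS and the terminator, exclusive).
parse_genbank_record <- function(lines) {
  # top-level sections start at column 1
  is_kw <- nzchar(lines) & !startsWith(lines, " ")
  kw_idx <- which(is_kw)
  if (length(kw_idx) == 0L) {
    abort_arblink("malformed GenBank record: no keywords found",
                  "arblink_malformed_record")
  }

  entry <- list(locus = "", accession = "", version = "", gi = "",
                definition = "", date = "", organism = "",
                taxonomy_lineage = character(0),
                source_qualifiers = list(), feature_qualifiers = list(),
                references = list(), sequence = "")

  sec_starts <- kw_idx
  sec_ends <- c(kw_idx[-1L] - 1L, length(lines))
  for (s in seq_along(sec_starts)) {
    sec <- lines[sec_starts[s]:sec_ends[s]]
    kw <- sub("^(\\S+).*$", "\\1", sec[1L])
    body_first <- trimws(sub("^\\S+\\s*", "", sec[1L]))
    cont <- if (length(sec) > 1L) trimws(sec[-1L]) else character(0)

    if (kw == "LOCUS") {
      toks <- strsplit(trimws(sec[1L]), "\\s+")[[1]]
      entry$locus <- if (length(toks) >= 2L) toks[2L] else ""
      last <- toks[length(toks)]
      if (grepl("^\\d{2}-[A-Z]{3}-\\d{4}$", last)) entry$date <- last
    } else if (kw == "DEFINITION") {
      entry$definition <- paste(c(body_first, cont), collapse = " ")
    } else if (kw == "ACCESSION") {
      entry$accession <- strsplit(body_first, "\\s+")[[1]][1L] %||% ""
    } else if (kw == "VERSION") {
      toks <- strsplit(body_first, "\\s+")[[1]]
      entry$version <- toks[1L] %||% ""
      gi <- grep("^GI:", toks, value = TRUE)
      if (length(gi) > 0L) entry$gi <- sub("^GI:", "", gi[1L])
    } else if (kw == "SOURCE") {
      org_i <- grep("^\\s*ORGANISM\\b", sec)
      if (length(org_i) > 0L) {
        entry$organism <- trimws(sub("^\\s*ORGANISM\\s*", "", sec[org_i[1L]]))
        if (org_i[1L] < length(sec)) {
          lin <- paste(trimws(sec[(org_i[1L] + 1L):length(sec)]), collapse = " ")
          lin <- sub("\\.\\s*$", "", lin)
          parts <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
          entry$taxonomy_lineage <- parts[nzchar(parts)]
        }
      }
    } else if (kw == "REFERENCE") {
      entry$references <- c(entry$references, list(parse_reference(sec)))
    } else if (kw == "FEATURES") {
      quals <- parse_feature_table(sec[-1L])
      entry$source_qualifiers <- quals$source
      entry$feature_qualifiers <- quals$other
    } else if (kw == "ORIGIN") {
      seq_txt <- paste(sec[-1L], collapse = "")
      seq_txt <- gsub("[0-9[:space:]]", "", seq_txt)
      entry$sequence <- toupper(seq_txt)
    }
  }

  if (!nzchar(entry$sequence)) {
    abort_arblink(
      sprintf("malformed GenBank record '%s': no ORIGIN sequence",
              if (nzchar(entry$locus)) entry$locus else "<unnamed>"),
      "arblink_malformed_record")
  }
  if (grepl("[^A-Z]", entry$sequence)) {
    abort_arblink(
      sprintf("malformed GenBank record '%s': sequence contains non-IUPAC characters",
              entry$locus),
      "arblink_malformed_record")
  }
  structure(entry, class = "genbank_entry")
}

parse_reference <- function(sec) {
  ref <- list(authors = "", title = "", journal = "", date = "")
  sub_i <- grep("^\\s{1,4}(AUTHORS|TITLE|JOURNAL)\\b", sec)
  if (length(sub_i) > 0L) {
    ends <- c(sub_i[-1L] - 1L, length(sec))
    for (j in seq_along(sub_i)) {
      block <- sec[sub_i[j]:ends[j]]
      key <- tolower(sub("^\\s*(\\S+).*$", "\\1", block[1L]))
      val <- paste(trimws(c(sub("^\\s*\\S+\\s*", "", block[1L]), block[-1L])),
                   collapse = " ")
      val <- trimws(val)
      if (key %in% names(ref)) ref[[key]] <- val
    }
  }
  yr <- regmatches(ref$journal, regexpr("\\((\\d{4})\\)", ref$journal))
  if (length(yr) == 1L) ref$date <- gsub("[()]", "", yr)
  ref
}

# FEATURES table: feature keys start at column 6, qualifiers ("/key=value",
# values possibly quoted and wrapped) at column 22. First occurrence of a
# qualifier wins, scan order = file order.
parse_feature_table <- function(lines) {
  source_q <- list()
  other_q <- list()
  cur_feature <- NA_character_
  cur_key <- NA_character_
  cur_val <- NULL
  in_quote <- FALSE

  flush_qual <- function() {
    if (!is.na(cur_key)) {
      val <- paste(cur_val, collapse = " ")
      if (identical(cur_feature, "source")) {
        if (is.null(source_q[[cur_key]])) source_q[[cur_key]] <<- val
      } else {
        if (is.null(other_q[[cur_key]])) other_q[[cur_key]] <<- val
      }
    }
    cur_key <<- NA_character_; cur_val <<- NULL; in_quote <<- FALSE
  }

  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    key_field <- trimws(substr(ln, 1L, 20L))
    rest <- trimws(substr(ln, 21L, nchar(ln)))
    if (nzchar(key_field) && !startsWith(key_field, "/")) {
      flush_qual()
      cur_feature <- key_field
      next
    }
    txt <- trimws(ln)
    if (startsWith(txt, "/") && !in_quote) {
      flush_qual()
      m <- regexec("^/([A-Za-z0-9_]+)(=(.*))?$", txt)[[1]]
      if (m[1L] == -1L) next
      cur_key <- sub("^/([A-Za-z0-9_]+).*$", "\\1", txt)
      has_val <- grepl("=", txt, fixed = TRUE)
      if (!has_val) {
        cur_val <- "true"   # flag qualifier, e.g. /environmental_sample
        flush_qual()
        next
      }
      val <- sub("^/[A-Za-z0-9_]+=", "", txt)
      if (startsWith(val, "\"")) {
        if (nchar(val) > 1L && endsWith(val, "\"")) {
          cur_val <- substr(val, 2L, nchar(val) - 1L)
          flush_qual()
        } else {
          in_quote <- TRUE
          cur_val <- substr(val, 2L, nchar(val))
        }
      } else {
        cur_val <- val
        flush_qual()
      }
    } else if (!is.na(cur_key) && in_quote) {
      if (endsWith(txt, "\"")) {
        cur_val <- c(cur_val, substr(txt, 1L, nchar(txt) - 1L))
        flush_qual()
      } else {
        cur_val <- c(cur_val, txt)
      }
    }
  }
  flush_qual()
  list(source = source_q, other = other_q)
}

#' @export
print.genbank_entry <- function(x, ...) {
  cat(sprintf("<genbank_entry> %s (%s) %s, %d bp/aa\n",
              x$accession, x$organism, x$locus, nchar(x$sequence)))
  invisible(x)
}
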