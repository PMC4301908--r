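#' Parse a Newick tree
#'
#' A small exact Newick reader used for tree linking and relabeling. Leaf
#' and internal labels, optional branch lengths and internal support
#' labels are preserved verbatim; quoted labels (`'...'`, with `''`
#' escaping an embedded quote) are unescaped per the Newick rules.
#' Unquoted labels are kept as written (no underscore-to-space
#' conversion). Branch-length tokens are stored as text so they survive a
#' parse/write round trip exactly as printed.
#'
#' @param text A single Newick statement ending in `;` (or a vector of
#'   lines that concatenate to one).
#' @return An object of class `newick_tree`.
#' @export
parse_newick <- function(text) {
  s <- paste(text, collapse = "")
  s <- gsub("[\r\n]", "", s)
  env <- new.env(parent = emptyenv())
  env$s <- s
  env$i <- 1L
  env$n <- nchar(s)

  peek <- function() if (env$i > env$n) "" else substr(env$s, env$i, env$i)
  advance <- function() env$i <- env$i + 1L
  skip_ws <- function() while (env$i <= env$n && grepl("^\\s$", peek())) advance()
  fail <- function(msg) {
    abort_arblink(sprintf("Newick parse error at character %d: %s", env$i, msg),
                  "arblink_newick_parse_error", offset = env$i)
  }

  read_quoted <- function() {
    advance()  # opening quote
    out <- character(0)
    repeat {
      if (env$i > env$n) fail("unterminated quoted label")
      ch <- peek()
      advance()
      if (ch == "'") {
        if (peek() == "'") { out <- c(out, "'"); advance() } else break
      } else {
        out <- c(out, ch)
      }
    }
    paste(out, collapse = "")
  }

  read_unquoted <- function() {
    start <- env$i
    while (env$i <= env$n && !grepl("[\\s,():;\\[\\]']", peek(), perl = TRUE)) {
      advance()
    }
    substr(env$s, start, env$i - 1L)
  }

  read_label <- function() {
    skip_ws()
    if (peek() == "'") read_quoted() else read_unquoted()
  }

  read_length <- function() {
    skip_ws()
    if (peek() != ":") return(NA_character_)
    advance()
    skip_ws()
    start <- env$i
    while (env$i <= env$n && grepl("[-+0-9.eE]", peek())) advance()
    tok <- substr(env$s, start, env$i - 1L)
    if (!nzchar(tok) || is.na(suppressWarnings(as.numeric(tok)))) {
      fail("invalid branch length")
    }
    tok
  }

  read_subtree <- function() {
    skip_ws()
    if (peek() == "(") {
      advance()
      children <- list(read_subtree())
      repeat {
        skip_ws()
        ch <- peek()
        if (ch == ",") {
          advance()
          children <- c(children, list(read_subtree()))
        } else if (ch == ")") {
          advance()
          break
        } else {
          fail("expected ',' or ')'")
        }
      }
      label <- read_label()
      len <- read_length()
      list(children = children,
           label = if (nzchar(label)) label else NA_character_,
           length_txt = len)
    } else {
      label <- read_label()
      if (!nzchar(label)) fail("expected a leaf label")
      len <- read_length()
      list(children = list(), label = label, length_txt = len)
    }
  }

  skip_ws()
  if (env$i > env$n) fail("empty input")
  root <- read_subtree()
  skip_ws()
  if (peek() != ";") fail("expected ';' terminating the tree")
  advance()
  skip_ws()
  if (env$i <= env$n) fail("trailing content after ';'")
  structure(list(root = root), class = "newick_tree")
}

#' Serialize a tree to Newick text
#'
#' Inverse of [parse_newick()] up to whitespace: labels and branch lengths
#' round-trip exactly. Labels containing spaces, parentheses, brackets,
#' commas, colons, semicolons or quotes are emitted quoted, with embedded
#' quotes doubled.
#'
#' @param tree A `newick_tree`.
#' @param path Optional output path.
#' @return Newick text (single statement ending in `;` plus newline);
#'   invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "newick_tree"))
  content <- paste0(render_node(tree$root), ";\n")
  if (!is.null(path)) {
    writeLines(content, path, sep = "")
    return(invisible(content))
  }
  content
}

render_node <- function(node) {
  lab <- if (is.na(node$label)) "" else quote_label(node$label)
  len <- if (is.na(node$length_txt)) "" else paste0(":", node$length_txt)
  if (length(node$children) == 0L) {
    paste0(lab, len)
  } else {
    inner <- vapply(node$children, render_node, character(1))
    paste0("(", paste(inner, collapse = ","), ")", lab, len)
  }
}

quote_label <- function(x) {
  if (grepl("[\\s,():;\\[\\]']", x, perl = TRUE) || !nzchar(x)) {
    paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
  } else {
    x
  }
}

#' @export
print.newick_tree <- function(x, ...) {
  cat(sprintf("<newick_tree> %d leaves, %d internal node(s)\n",
              length(tree_leaf_labels(x)), count_internal(x$root)))
  invisible(x)
}

count_internal <- function(node) {
  if (length(node$children) == 0L) return(0L)
  1L + sum(vapply(node$children, count_internal, integer(1)))
}

#' Leaf labels of a tree, in serialization order
#' @param tree A `newick_tree`.
#' @return Character vector of leaf labels.
#' @export
tree_leaf_labels <- function(tree) {
  stopifnot(inherits(tree, "newick_tree"))
  collect <- function(node) {
    if (length(node$children) == 0L) return(node$label)
    unlist(lapply(node$children, collect))
  }
  collect(tree$root)
}

# Shape of a tree ignoring labels and branch lengths; child order is
# preserved by every operation here, so ordered comparison suffices.
tree_shape <- function(node) {
  if (length(node$children) == 0L) return("()")
  paste0("(", paste(vapply(node$children, tree_shape, character(1)),
                    collapse = ","), ")")
}

#' Structural tree distance ignoring labels
#'
#' Compares the shapes (child-list structure) of two trees, ignoring all
#' labels and branch lengths. Returns 0 when the shapes are identical and
#' 1 otherwise; relabeling must never change it.
#'
#' @param a,b `newick_tree` objects.
#' @return 0L or 1L.
#' @export
tree_shape_distance <- function(a, b) {
  stopifnot(inherits(a, "newick_tree"), inherits(b, "newick_tree"))
  if (identical(tree_shape(a$root), tree_shape(b$root))) 0L else 1L
}
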