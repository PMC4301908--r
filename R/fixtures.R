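#' Deterministic synthetic data for offline pipeline testing
#'
#' Every downstream module is exercised against synthetic GenBank
#' records, databases and trees generated here with known ground truth,
#' so no network access or reference download is ever needed. Generation
#' is a pure function of its arguments (the seed included): identical
#' calls yield byte-identical artifacts. The value pools echo the
#' toolkit's motivating use case — bacterial and fungal sugar-transporter
#' and polymer-degradation gene families — without copying any real
#' record.
#'
#' @name fixtures
NULL

# Run code under a seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

fixture_organisms <- function() {
  list(
    list(name = "Escherichia coli",
         lineage = c("Bacteria", "Proteobacteria", "Gammaproteobacteria",
                     "Enterobacterales", "Enterobacteriaceae", "Escherichia")),
    list(name = "Bacillus subtilis",
         lineage = c("Bacteria", "Bacillota", "Bacilli", "Bacillales",
                     "Bacillaceae", "Bacillus")),
    list(name = "Pseudomonas fluorescens",
         lineage = c("Bacteria", "Proteobacteria", "Gammaproteobacteria",
                     "Pseudomonadales", "Pseudomonadaceae", "Pseudomonas")),
    list(name = "Streptomyces coelicolor",
         lineage = c("Bacteria", "Actinomycetota", "Actinomycetes",
                     "Kitasatosporales", "Streptomycetaceae", "Streptomyces")),
    list(name = "Saccharomyces cerevisiae",
         lineage = c("Eukaryota", "Ascomycota", "Saccharomycetes",
                     "Saccharomycetales", "Saccharomycetaceae",
                     "Saccharomyces")),
    list(name = "Aspergillus niger",
         lineage = c("Eukaryota", "Ascomycota", "Eurotiomycetes",
                     "Eurotiales", "Aspergillaceae", "Aspergillus"))
  )
}

fixture_products <- function() {
  c("sugar transporter", "MFS transporter", "sugar:proton symporter",
    "ABC sugar transporter permease", "major facilitator superfamily protein",
    "cellulase", "beta-glucosidase", "xylanase")
}

fixture_genes <- function() {
  c("xylE", "araE", "galP", "malE", "bglB", "celA", "xynA", "mfsT")
}

fixture_authors <- function() {
  c("Garcia,M. and Chen,L.", "Okafor,A.", "Nilsson,K. and Petrov,D.",
    "Silva,R., Tanaka,H. and Mora,E.")
}

fixture_journals <- function() {
  c("J. Bacteriol. 181 (2), 334-341 (2012)",
    "Appl. Environ. Microbiol. 77 (4), 1122-1130 (2013)",
    "Mol. Ecol. 22 (9), 2501-2515 (2014)",
    "FEMS Microbiol. Lett. 301 (1), 44-52 (2011)")
}

#' Generate synthetic GenBank records with known ground truth
#'
#' Produces syntactically valid multi-record GenBank flat-file text plus
#' the per-record field values that were planted, so the parser can be
#' verified against the generator's own ground truth. Deliberately
#' awkward cases are included: every fifth record carries a tab inside
#' its `product` qualifier, environmental qualifiers (`ph`, `salinity`,
#' `temperature`) are present in only some records, lineages end with a
#' period, and definitions wrap over continuation lines.
#'
#' @param n_records Number of records (>= 1).
#' @param seed Integer seed; output is a pure function of the arguments.
#' @param seq_length_range Length range (min, max) of the generated
#'   nucleotide sequences.
#' @return List with `text` (the flat file as one string) and
#'   `ground_truth` (one named list per record with every planted value,
#'   as the parser should recover it).
#' @export
generate_genbank <- function(n_records, seed = 1,
                             seq_length_range = c(120L, 360L)) {
  if (n_records < 1) {
    abort_arblink("n_records must be >= 1", "arblink_bad_argument")
  }
  stopifnot(length(seq_length_range) == 2L,
            seq_length_range[1L] <= seq_length_range[2L])
  with_seed(seed, {
    orgs <- fixture_organisms()
    recs <- vector("list", n_records)
    truths <- vector("list", n_records)
    for (i in seq_len(n_records)) {
      org <- orgs[[sample.int(length(orgs), 1L)]]
      product <- sample(fixture_products(), 1L)
      if (i %% 5L == 0L) {
        product <- sub(" ", "\t", product)  # awkward: tab inside the value
      }
      gene <- sample(fixture_genes(), 1L)
      acc <- sprintf("SY%06d", i)
      gi <- as.character(100000 + i)
      date <- sprintf("%02d-%s-%d", sample.int(28, 1L),
                      sample(c("JAN", "MAR", "JUN", "SEP", "NOV"), 1L),
                      sample(2008:2015, 1L))
      author <- sample(fixture_authors(), 1L)
      journal <- sample(fixture_journals(), 1L)
      seq_len_i <- sample(seq(seq_length_range[1L], seq_length_range[2L]), 1L)
      sequence <- paste(sample(c("A", "C", "G", "T"), seq_len_i,
                               replace = TRUE), collapse = "")
      has_env <- i %% 3L == 0L
      ph <- if (has_env) sprintf("%.1f", round(runif(1, 4, 9), 1)) else NULL
      temperature <- if (has_env) sprintf("%d C", sample(10:60, 1L)) else NULL
      definition <- sprintf("%s %s (%s) gene for %s, complete cds.",
                            org$name, gene, acc, gsub("\t", " ", product))
      locus_tag <- sprintf("SYN_%04d", i)
      recs[[i]] <- render_genbank_record(
        locus = acc, accession = acc, version = paste0(acc, ".1"), gi = gi,
        date = date, definition = definition, organism = org$name,
        lineage = org$lineage, product = product, gene = gene,
        locus_tag = locus_tag, ph = ph, temperature = temperature,
        author = author, journal = journal,
        title = sprintf("Diversity of %s genes in environmental isolates",
                        gene),
        sequence = sequence)
      truths[[i]] <- list(
        locus = acc, accession = acc, version = paste0(acc, ".1"), gi = gi,
        date = date, definition = definition, organism = org$name,
        species = org$name,
        genus = strsplit(org$name, " ")[[1L]][1L],
        phylum = org$lineage[2L],
        taxonomy_lineage = org$lineage,
        product = product, gene = gene, locus_tag = locus_tag,
        ph = if (has_env) ph else "",
        temperature = if (has_env) temperature else "",
        author = author, journal = journal,
        sequence = sequence)
    }
    list(text = paste0(paste(unlist(recs), collapse = ""), ""),
         ground_truth = truths)
  })
}

# GenBank layout: keywords in a 12-column field, feature keys at column 6,
# qualifiers at column 22, ORIGIN in 60-residue lines of 10-residue groups.
render_genbank_record <- function(locus, accession, version, gi, date,
                                  definition, organism, lineage, product,
                                  gene, locus_tag, ph, temperature, author,
                                  journal, title, sequence) {
  kw <- function(key, value) sprintf("%-12s%s", key, value)
  wrap_at <- function(text, first_prefix, cont_prefix, width = 79L) {
    words <- strsplit(text, " ", fixed = TRUE)[[1]]
    lines <- character(0)
    cur <- first_prefix
    body_start <- TRUE
    for (w in words) {
      cand <- if (body_start) paste0(cur, w) else paste(cur, w)
      if (nchar(cand) > width && !body_start) {
        lines <- c(lines, cur)
        cur <- paste0(cont_prefix, w)
      } else {
        cur <- cand
      }
      body_start <- FALSE
    }
    c(lines, cur)
  }
  qual <- function(key, value, quoted = TRUE) {
    v <- if (quoted) paste0("\"", value, "\"") else value
    sprintf("%21s/%s=%s", "", key, v)
  }
  lineage_txt <- paste0(paste(lineage, collapse = "; "), ".")
  lines <- c(
    sprintf("LOCUS       %-16s%12d bp    DNA     linear   BCT %s",
            locus, nchar(sequence), date),
    wrap_at(definition, kw("DEFINITION", ""), strrep(" ", 12L)),
    kw("ACCESSION", accession),
    kw("VERSION", sprintf("%s  GI:%s", version, gi)),
    kw("SOURCE", organism),
    sprintf("  ORGANISM  %s", organism),
    wrap_at(lineage_txt, strrep(" ", 12L), strrep(" ", 12L)),
    kw("REFERENCE", sprintf("1  (bases 1 to %d)", nchar(sequence))),
    sprintf("  AUTHORS   %s", author),
    wrap_at(title, "  TITLE     ", strrep(" ", 12L)),
    sprintf("  JOURNAL   %s", journal),
    sprintf("%-21s%s", "FEATURES", "Location/Qualifiers"),
    sprintf("     %-16s%s", "source", sprintf("1..%d", nchar(sequence))),
    qual("organism", organism),
    qual("mol_type", "genomic DNA"),
    if (!is.null(ph)) qual("ph", ph),
    if (!is.null(temperature)) qual("temperature", temperature),
    sprintf("     %-16s%s", "gene", sprintf("1..%d", nchar(sequence))),
    qual("gene", gene),
    qual("locus_tag", locus_tag),
    sprintf("     %-16s%s", "CDS", sprintf("1..%d", nchar(sequence))),
    qual("gene", gene),
    qual("locus_tag", locus_tag),
    qual("product", product),
    kw("ORIGIN", ""),
    render_origin(sequence),
    "//"
  )
  paste0(paste(unlist(lines), collapse = "\n"), "\n")
}

render_origin <- function(sequence) {
  s <- tolower(sequence)
  n <- nchar(s)
  starts <- seq(1L, n, by = 60L)
  vapply(starts, function(st) {
    chunk <- substr(s, st, min(st + 59L, n))
    groups <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(1L, nchar(chunk), by = 10L) + 9L,
                             nchar(chunk)))
    sprintf("%9d %s", st, paste(groups, collapse = " "))
  }, character(1))
}

#' Generate a randomized custom database
#'
#' Builds a valid database directly (no GenBank intermediary) with random
#' field values, including empty cells and values containing spaces,
#' quotes, commas and other header-hostile characters (never tabs or
#' newlines, which the format forbids). Used for round-trip and
#' filter-emulation testing at scale.
#'
#' @param n_records Number of records.
#' @param n_fields Number of metadata fields (a schema `f1..fN` is made
#'   unless `schema` is given).
#' @param seed Integer seed.
#' @param schema Optional `meta_labels` overriding `n_fields`.
#' @return A `custom_database`.
#' @export
generate_database <- function(n_records, n_fields = 3L, seed = 1,
                              schema = NULL) {
  if (is.null(schema)) {
    schema <- meta_labels(paste0("f", seq_len(n_fields)))
  }
  with_seed(seed, {
    uids <- mint_unique_ids(n_records, prefix = "sq",
                            start = sample.int(1000L, 1L))
    pool <- c(letters, LETTERS, 0:9, " ", ".", ",", ";", "'", "\"", "(",
              ")", ":", "-", "/")
    rand_strings <- function(n, alphabet, len_min, len_max) {
      lens <- sample.int(len_max - len_min + 1L, n, replace = TRUE) +
        len_min - 1L
      chars <- sample(alphabet, sum(lens), replace = TRUE)
      grp <- factor(rep.int(seq_len(n), lens), levels = seq_len(n))
      vapply(split(chars, grp), paste, character(1), collapse = "")
    }
    n_cells <- n_records * length(schema)
    # leading/trailing spaces would not survive ARB fields, hence trimws
    vals <- trimws(rand_strings(n_cells, pool, 1L, 24L))
    vals[runif(n_cells) < 0.1] <- ""
    meta <- matrix(vals, nrow = n_records, ncol = length(schema))
    seqs <- rand_strings(n_records, c("A", "C", "G", "T"), 50L, 200L)
    custom_database(schema, uids, meta, seqs)
  })
}

#' Generate a random binary tree over given unique IDs
#'
#' Random topology with positive branch lengths, deterministic per seed —
#' a stand-in for the Newick tree an external tree-building service
#' returns for the exported sequences.
#'
#' @param uids Character vector of at least two leaf names.
#' @param seed Integer seed.
#' @return A `newick_tree` whose leaf set equals `uids`.
#' @export
generate_tree <- function(uids, seed = 1) {
  if (length(uids) < 2L) {
    abort_arblink("at least 2 unique IDs are required to build a tree",
                  "arblink_bad_argument")
  }
  with_seed(seed, {
    phy <- ape::rtree(length(uids), tip.label = uids)
    parse_newick(ape::write.tree(phy))
  })
}

#' Pairwise-alignment cost of an all-against-all multiple alignment
#'
#' An all-against-all alignment of `n` sequences performs `n(n-1)/2`
#' pairwise alignments; at a measured per-pair time this gives the total
#' local cost — the quantity that motivates outsourcing in the first
#' place (tens of millions of pairs for a ten-thousand-sequence family).
#'
#' @param n Number of sequences (>= 1).
#' @param t_per_pair Optional seconds per pairwise alignment (>= 0).
#' @return List with `n_pairs` (exact integer-valued count) and, when
#'   `t_per_pair` is given, `total_seconds` and `total_days`.
#' @examples
#' estimate_pairwise_alignments(10752, 0.019)
#' @export
estimate_pairwise_alignments <- function(n, t_per_pair = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    abort_arblink("n must be a positive integer", "arblink_bad_argument")
  }
  n_pairs <- n * (n - 1) / 2
  out <- list(n_pairs = n_pairs)
  if (!is.null(t_per_pair)) {
    if (t_per_pair < 0) {
      abort_arblink("t_per_pair must be >= 0", "arblink_bad_argument")
    }
    out$total_seconds <- n_pairs * t_per_pair
    out$total_days <- out$total_seconds / 86400
  }
  out
}

#' Write a self-contained demo fixture directory
#'
#' Creates a directory with a meta-labels file, a synthetic GenBank flat
#' file, and the expected pipeline outputs (custom database, bare-ID
#' FASTA, import filter, tree), mirroring the step-by-step tutorial flow.
#'
#' @param dir Output directory (created if absent).
#' @param n_records Number of synthetic records.
#' @param seed Integer seed.
#' @return Invisibly, a named list of the written paths.
#' @export
make_fixture_dir <- function(dir, n_records = 8L, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- c("accession", "species", "gene_product", "ph")
  schema <- meta_labels(labels)
  paths <- list(
    meta_labels = file.path(dir, "meta_labels.txt"),
    genbank = file.path(dir, "records.gb"),
    database = file.path(dir, "custom_database.fasta"),
    sequences = file.path(dir, "sequences.fasta"),
    filter = file.path(dir, "custom_import_filter.ift"),
    tree = file.path(dir, "tree.nwk")
  )
  writeLines(labels, paths$meta_labels)
  gb <- generate_genbank(n_records, seed = seed)
  writeLines(gb$text, paths$genbank, sep = "")
  db <- build_records(parse_genbank(gb$text), schema)
  write_database(db, paths$database)
  export_sequences(db, path = paths$sequences)
  render_ift(build_import_filter(schema), path = paths$filter)
  write_newick(generate_tree(db$uid, seed = seed), path = paths$tree)
  invisible(paths)
}
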