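# Parsing and serialization of reaction SMILES and fingerprint matrices.

strip_atom_maps <- function(s) gsub(":[0-9]+\\]", "]", s)

split_molecules <- function(field, what, raw) {
  if (!nzchar(field)) return(character(0))
  parts <- strsplit(field, ".", fixed = TRUE)[[1]]
  if (any(!nzchar(parts)))
    drfp_error("drfp_unparsable_molecule",
               sprintf("empty molecule in the %s field of '%s'", what, raw))
  parts
}

#' Parse a reaction SMILES
#'
#' Splits `REACTANTS>REAGENTS>PRODUCTS` into its three dot-separated molecule
#' lists, strips atom-map numbers, and validates every molecule against the
#' chemistry backend. The reagent field may be empty (`A>>B`).
#'
#' @param s a single reaction SMILES string with exactly two `>` separators.
#' @return an object of class `reaction_record` with fields `reactants`,
#'   `reagents`, `products` (character vectors of molecule SMILES, atom maps
#'   removed) and `raw` (the input string).
#' @examples
#' parse_reaction("CCO.CC(=O)O>[H+]>CCOC(=O)C")
#' @export
parse_reaction <- function(s) {
  stopifnot(is.character(s), length(s) == 1, !is.na(s))
  seps <- gregexpr(">", s, fixed = TRUE)[[1]]
  n_sep <- if (seps[1] == -1L) 0L else length(seps)
  if (n_sep != 2L)
    drfp_error("drfp_malformed_reaction",
               sprintf("expected 2 '>' separators, found %d in '%s'", n_sep, s))
  fields <- c(substr(s, 1L, seps[1] - 1L),
              substr(s, seps[1] + 1L, seps[2] - 1L),
              substr(s, seps[2] + 1L, nchar(s)))
  fields <- strip_atom_maps(trimws(fields))
  reactants <- split_molecules(fields[1], "reactant", s)
  reagents <- split_molecules(fields[2], "reagent", s)
  products <- split_molecules(fields[3], "product", s)
  if (length(reactants) + length(reagents) == 0L)
    drfp_error("drfp_empty_side", sprintf("no reactant or reagent molecules in '%s'", s))
  if (length(products) == 0L)
    drfp_error("drfp_empty_side", sprintf("no product molecules in '%s'", s))
  mols <- c(reactants, reagents, products)
  can <- canonical_smiles(mols)
  if (anyNA(can)) {
    bad <- mols[which(is.na(can))[1]]
    drfp_error("drfp_unparsable_molecule",
               sprintf("molecule SMILES rejected by the chemistry backend: '%s' (in '%s')", bad, s),
               component = bad)
  }
  structure(list(reactants = reactants, reagents = reagents,
                 products = products, raw = s),
            class = "reaction_record",
            canonical = list(reactants = can[seq_along(reactants)],
                             reagents = can[length(reactants) + seq_along(reagents)],
                             products = can[length(reactants) + length(reagents) +
                                              seq_along(products)]))
}

#' @export
print.reaction_record <- function(x, ...) {
  cat("reaction:", reaction_string(x), "\n")
  cat(sprintf("  %d reactant(s), %d reagent(s), %d product(s)\n",
              length(x$reactants), length(x$reagents), length(x$products)))
  invisible(x)
}

#' Render a reaction record back to a reaction SMILES string
#'
#' @param rec a `reaction_record`.
#' @return a single reaction SMILES string.
#' @export
reaction_string <- function(rec) {
  stopifnot(inherits(rec, "reaction_record"))
  paste(paste(rec$reactants, collapse = "."),
        paste(rec$reagents, collapse = "."),
        paste(rec$products, collapse = "."), sep = ">")
}

#' Merge reagents into the reactants
#'
#' The fingerprint does not distinguish reactants from reagents: the left
#' side of the encoded reaction is reactants followed by reagents, the right
#' side the products. No deduplication is performed here.
#'
#' @param rec a `reaction_record`.
#' @return list with character vectors `left` and `right`.
#' @export
merge_sides <- function(rec) {
  stopifnot(inherits(rec, "reaction_record"))
  list(left = c(rec$reactants, rec$reagents), right = rec$products)
}

# -- labeled reaction sets ----------------------------------------------------

#' Construct a labeled reaction set
#'
#' @param reactions character vector of reaction SMILES.
#' @param labels optional vector: a factor/character for class labels, or a
#'   numeric vector of percent yields in `[0, 100]`.
#' @param label_kind `"class"`, `"yield"` or `"none"`; inferred from `labels`
#'   when `NULL`.
#' @return an object of class `labeled_reactions`.
#' @export
labeled_reactions <- function(reactions, labels = NULL, label_kind = NULL) {
  stopifnot(is.character(reactions))
  if (is.null(label_kind))
    label_kind <- if (is.null(labels)) "none" else if (is.numeric(labels)) "yield" else "class"
  if (label_kind != "none") {
    stopifnot(length(labels) == length(reactions))
    if (label_kind == "class") labels <- as.factor(labels)
  } else labels <- NULL
  structure(list(reactions = reactions, labels = labels, label_kind = label_kind),
            class = "labeled_reactions")
}

#' @export
print.labeled_reactions <- function(x, ...) {
  cat(sprintf("%d reactions, labels: %s\n", length(x$reactions), x$label_kind))
  if (x$label_kind == "class")
    print(table(x$labels))
  invisible(x)
}

#' Read reactions from a text file or delimited table
#'
#' With `smiles_column = NULL` the file is read as plain text, one reaction
#' SMILES per line. Otherwise it is read as a delimited table with a header
#' and the named column holds the reaction SMILES; `label_column` optionally
#' attaches class labels or yields. In strict mode (default) the first
#' invalid row aborts with its 1-based row number; in lenient mode invalid
#' rows are skipped with a warning.
#'
#' @param path file path.
#' @param smiles_column name of the reaction SMILES column, or `NULL`.
#' @param label_column optional name of a label column.
#' @param sep field separator; inferred from the extension when `NULL`
#'   (`.csv` comma, `.tsv` tab, otherwise comma).
#' @param lenient skip invalid rows instead of aborting.
#' @return a [labeled_reactions()] object; skipped row indices (lenient mode)
#'   are in `$skipped`.
#' @export
read_reaction_table <- function(path, smiles_column = NULL, label_column = NULL,
                                sep = NULL, lenient = FALSE) {
  if (!file.exists(path))
    drfp_error("drfp_io_failure", sprintf("file not found: '%s'", path))
  if (is.null(smiles_column)) {
    lines <- readLines(path, warn = FALSE)
    reactions <- trimws(lines)
    reactions <- reactions[nzchar(reactions)]
    labels <- NULL
  } else {
    if (is.null(sep))
      sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            comment.char = "")
    if (!smiles_column %in% names(df))
      drfp_error("drfp_missing_column",
                 sprintf("column '%s' not found in '%s'", smiles_column, path))
    if (!is.null(label_column) && !label_column %in% names(df))
      drfp_error("drfp_missing_column",
                 sprintf("column '%s' not found in '%s'", label_column, path))
    reactions <- as.character(df[[smiles_column]])
    labels <- if (is.null(label_column)) NULL else df[[label_column]]
  }
  keep <- logical(length(reactions))
  for (i in seq_along(reactions)) {
    ok <- tryCatch({ parse_reaction(reactions[i]); TRUE },
                   drfp_error = function(e) {
                     if (!lenient)
                       drfp_error(class(e)[1],
                                  sprintf("row %d: %s", i, conditionMessage(e)), row = i)
                     warning(sprintf("skipping row %d: %s", i, conditionMessage(e)),
                             call. = FALSE)
                     FALSE
                   })
    keep[i] <- ok
  }
  out <- labeled_reactions(reactions[keep],
                           if (is.null(labels)) NULL else labels[keep])
  out$skipped <- which(!keep)
  out
}

# -- fingerprint serialization ------------------------------------------------

fp_matrix <- function(x) {
  if (inherits(x, "drfp_fingerprints")) x$bits
  else if (inherits(x, "drfp_fingerprint")) matrix(x$bits, nrow = 1)
  else as.matrix(x)
}

#' Write a fingerprint matrix to disk
#'
#' Three lossless formats: `"dense"` (CSV of 0/1), `"sparse"` (one row per
#' reaction listing the 0-based indices of the set bits, preceded by a header
#' line carrying the dimensions), and `"packed"` (binary bit-packed matrix
#' with a small header). Optionally serializes bit provenance maps to a JSON
#' sidecar.
#'
#' @param x an n-by-d binary matrix, or a `drfp_fingerprints` object.
#' @param path output file path.
#' @param format one of `"dense"`, `"sparse"`, `"packed"`.
#' @param bit_map_path optional path for the JSON bit-to-fragment sidecar
#'   (requires `x` to be a `drfp_fingerprints` object or `bit_maps` given).
#' @param bit_maps optional list of per-reaction bit maps for the sidecar.
#' @return invisibly, `path`.
#' @export
write_fingerprints <- function(x, path, format = c("dense", "sparse", "packed"),
                               bit_map_path = NULL, bit_maps = NULL) {
  format <- match.arg(format)
  m <- fp_matrix(x)
  storage.mode(m) <- "integer"
  if (format == "dense") {
    utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  } else if (format == "sparse") {
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines(sprintf("# drfp sparse n=%d d=%d", nrow(m), ncol(m)), con)
    for (i in seq_len(nrow(m)))
      writeLines(paste(which(m[i, ] == 1L) - 1L, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(charToRaw("DRFP"), con)
    writeBin(c(nrow(m), ncol(m)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(m)))
      writeBin(packBits(c(as.logical(m[i, ]),
                          rep(FALSE, (8 - ncol(m) %% 8) %% 8)), "raw"), con)
  }
  if (!is.null(bit_map_path)) {
    if (is.null(bit_maps) && inherits(x, "drfp_fingerprints")) bit_maps <- x$bit_maps
    if (is.null(bit_maps) && inherits(x, "drfp_fingerprint")) bit_maps <- list(x$bit_map)
    write_bit_maps(bit_maps, bit_map_path)
  }
  invisible(path)
}

#' Read a fingerprint matrix written by [write_fingerprints()]
#'
#' @param path file path.
#' @param format one of `"dense"`, `"sparse"`, `"packed"`.
#' @return integer matrix of 0/1.
#' @export
read_fingerprints <- function(path, format = c("dense", "sparse", "packed")) {
  format <- match.arg(format)
  if (!file.exists(path))
    drfp_error("drfp_io_failure", sprintf("file not found: '%s'", path))
  if (format == "dense") {
    m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
    dimnames(m) <- NULL
    storage.mode(m) <- "integer"
    m
  } else if (format == "sparse") {
    lines <- readLines(path)
    hdr <- regmatches(lines[1],
                      regexec("^# drfp sparse n=([0-9]+) d=([0-9]+)$", lines[1]))[[1]]
    if (length(hdr) != 3)
      drfp_error("drfp_io_failure", sprintf("'%s' is not a drfp sparse file", path))
    n <- as.integer(hdr[2]); d <- as.integer(hdr[3])
    m <- matrix(0L, n, d)
    for (i in seq_len(n)) {
      row <- lines[i + 1L]
      if (nzchar(trimws(row))) {
        idx <- as.integer(strsplit(trimws(row), " +")[[1]])
        m[i, idx + 1L] <- 1L
      }
    }
    m
  } else {
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    magic <- rawToChar(readBin(con, "raw", 4))
    if (magic != "DRFP")
      drfp_error("drfp_io_failure", sprintf("'%s' is not a drfp packed file", path))
    dims <- readBin(con, "integer", 2, size = 4, endian = "little")
    n <- dims[1]; d <- dims[2]
    bytes_per_row <- ceiling(d / 8)
    m <- matrix(0L, n, d)
    for (i in seq_len(n)) {
      bits <- as.integer(rawToBits(readBin(con, "raw", bytes_per_row)))
      m[i, ] <- bits[seq_len(d)]
    }
    m
  }
}

#' Serialize bit-to-fragment maps as JSON
#'
#' @param bit_maps a single bit map (named list: 0-based bit index as
#'   character, value a character vector of fragment SMILES) or a list of
#'   such maps.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bit_maps <- function(bit_maps, path) {
  jsonlite::write_json(bit_maps, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
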