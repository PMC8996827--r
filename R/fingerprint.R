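# The fingerprint pipeline: symmetric difference of the two shinglings,
# 32-bit hashing with provenance, and folding modulo the dimension.

#' Symmetric difference of two fragment sets
#'
#' Fragments present in exactly one of the two shinglings: the substructures
#' changed by the reaction.
#'
#' @param r,p character vectors (fragment sets).
#' @return sorted character vector of the strings occurring in exactly one of
#'   the two sets.
#' @export
shingling_difference <- function(r, p) {
  r <- unique(r); p <- unique(p)
  sort(c(setdiff(r, p), setdiff(p, r)))
}

#' Hash a fragment set to unsigned 32-bit integers
#'
#' Each fragment string is hashed with a stable, platform- and
#' process-independent 32-bit FNV-1a over its UTF-8 bytes. Provenance records
#' every fragment per hash value; fragments colliding at 32 bits share a key.
#'
#' @param fragments character vector of fragment SMILES.
#' @return object of class `drfp_hashed`: list with `hashes` (sorted numeric
#'   vector of values in `[0, 2^32)`) and `provenance` (named list keyed by
#'   the decimal hash value).
#' @export
hash_shingling <- function(fragments) {
  fragments <- unique(as.character(fragments))
  if (length(fragments) == 0)
    return(structure(list(hashes = numeric(0), provenance = list()),
                     class = "drfp_hashed"))
  h <- fnv1a_hash32(fragments)
  key <- sprintf("%.0f", h)
  prov <- lapply(split(fragments, key), function(x) sort(unique(x)))
  hashes <- sort(unique(h))
  structure(list(hashes = hashes, provenance = prov[sprintf("%.0f", hashes)]),
            class = "drfp_hashed")
}

#' Fold a hashed fragment set into a binary fingerprint
#'
#' Bit `i` (0-based) is set iff some hash `k` satisfies `k mod d == i`. The
#' bit map unions the provenance of all hashes landing on the bit.
#'
#' @param hashed a `drfp_hashed` object.
#' @param n_bits fingerprint dimension `d` (positive integer).
#' @return object of class `drfp_fingerprint`: list with `bits` (integer 0/1
#'   vector of length `d`) and `bit_map` (named list, 0-based bit index as
#'   character -> sorted fragment SMILES).
#' @export
fold_hashes <- function(hashed, n_bits) {
  stopifnot(inherits(hashed, "drfp_hashed"))
  n_bits <- as.integer(n_bits)
  stopifnot(length(n_bits) == 1, n_bits >= 1)
  bits <- integer(n_bits)
  bit_map <- list()
  if (length(hashed$hashes)) {
    residue <- hashed$hashes %% n_bits
    ures <- sort(unique(residue))
    bits[ures + 1L] <- 1L
    bit_map <- lapply(ures, function(rr)
      sort(unique(unlist(hashed$provenance[residue == rr], use.names = FALSE))))
    names(bit_map) <- sprintf("%d", as.integer(ures))
  }
  structure(list(bits = bits, bit_map = bit_map, n_bits = n_bits),
            class = "drfp_fingerprint")
}

#' Encode a reaction SMILES as a differential reaction fingerprint
#'
#' Runs the full pipeline: parse, merge reagents into reactants, extract the
#' shinglings of both sides, take their symmetric difference, hash, and fold.
#' The output is deterministic: identical input and configuration give a
#' byte-identical fingerprint across processes and platforms.
#'
#' @param reaction a reaction SMILES string or a `reaction_record`.
#' @param config a [drfp_config()].
#' @return a `drfp_fingerprint`; besides `bits` and `bit_map` it carries the
#'   input string and the configuration.
#' @examples
#' fp <- drfp_encode("CCO.CC(=O)O>[H+]>CCOC(=O)C", drfp_config(n_bits = 256))
#' sum(fp$bits)
#' @export
drfp_encode <- function(reaction, config = drfp_config()) {
  stopifnot(inherits(config, "drfp_config"))
  rec <- if (inherits(reaction, "reaction_record")) reaction
         else parse_reaction(reaction)
  sides <- merge_sides(rec)
  r <- side_shingling(sides$left, config)
  p <- side_shingling(sides$right, config)
  s <- shingling_difference(r, p)
  fp <- fold_hashes(hash_shingling(s), config$n_bits)
  fp$config <- config
  fp$reaction <- rec$raw
  fp
}

#' @export
print.drfp_fingerprint <- function(x, ...) {
  cat(sprintf("drfp fingerprint: %d / %d bits set\n", sum(x$bits), x$n_bits))
  if (!is.null(x$reaction)) cat("  reaction:", x$reaction, "\n")
  invisible(x)
}

#' @export
summary.drfp_fingerprint <- function(object, n = 5, ...) {
  print(object)
  on_bits <- names(object$bit_map)
  for (b in head(on_bits, n))
    cat(sprintf("  bit %s <- %s\n", b,
                paste(object$bit_map[[b]], collapse = ", ")))
  if (length(on_bits) > n) cat(sprintf("  ... and %d more bits\n", length(on_bits) - n))
  invisible(object)
}

#' Fragments behind a fingerprint bit
#'
#' @param fp a `drfp_fingerprint`.
#' @param i 0-based bit index, `0 <= i < d`.
#' @return sorted character vector of fragment SMILES (empty if the bit is
#'   unset).
#' @export
explain_bit <- function(fp, i) {
  stopifnot(inherits(fp, "drfp_fingerprint"))
  i <- as.integer(i)
  if (length(i) != 1 || is.na(i) || i < 0L || i >= fp$n_bits)
    drfp_error("drfp_index_error",
               sprintf("bit index %s out of range [0, %d)", i, fp$n_bits))
  frags <- fp$bit_map[[as.character(i)]]
  if (is.null(frags)) character(0) else frags
}

#' Encode many reactions into a fingerprint matrix
#'
#' @param reactions character vector of reaction SMILES.
#' @param config a [drfp_config()].
#' @param lenient if `TRUE`, rows that fail to encode become all-zero rows
#'   and their indices are reported in `$failed`; if `FALSE` (default) the
#'   first failure aborts with its row number.
#' @return object of class `drfp_fingerprints`: list with `bits` (n-by-d
#'   integer matrix), `bit_maps` (per-row provenance), `failed` (integer
#'   row indices), `config`, `reactions`.
#' @export
drfp_encode_many <- function(reactions, config = drfp_config(), lenient = FALSE) {
  stopifnot(is.character(reactions), inherits(config, "drfp_config"))
  n <- length(reactions)
  bits <- matrix(0L, n, config$n_bits)
  bit_maps <- vector("list", n)
  failed <- integer(0)
  for (i in seq_len(n)) {
    fp <- tryCatch(drfp_encode(reactions[i], config), drfp_error = function(e) {
      if (!lenient)
        drfp_error(class(e)[1],
                   sprintf("reaction %d: %s", i, conditionMessage(e)), row = i)
      NULL
    })
    if (is.null(fp)) {
      failed <- c(failed, i)
      bit_maps[[i]] <- list()
    } else {
      bits[i, ] <- fp$bits
      bit_maps[[i]] <- fp$bit_map
    }
  }
  if (length(failed))
    warning(sprintf("%d reaction(s) failed to encode: rows %s",
                    length(failed), paste(failed, collapse = ", ")), call. = FALSE)
  structure(list(bits = bits, bit_maps = bit_maps, failed = failed,
                 config = config, reactions = reactions),
            class = "drfp_fingerprints")
}

#' @export
print.drfp_fingerprints <- function(x, ...) {
  cat(sprintf("drfp fingerprints: %d reactions x %d bits (mean %.1f bits set)\n",
              nrow(x$bits), ncol(x$bits), mean(rowSums(x$bits))))
  if (length(x$failed)) cat(sprintf("  %d failed row(s)\n", length(x$failed)))
  invisible(x)
}

#' @export
as.matrix.drfp_fingerprints <- function(x, ...) x$bits
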