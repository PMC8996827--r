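# SMILES handling: backend canonicalization via Open Babel (ChemmineOB) and
# an internal reader that turns the backend's canonical SMILES into a
# molecular graph (atoms, bonds, aromaticity, charges, stereo marks).
#
# All molecules are canonicalized on entry, so every downstream step sees one
# fixed atom ordering per molecule regardless of how the input was written.

#' Canonical SMILES of one or more molecules
#'
#' Validates and canonicalizes molecule SMILES through the Open Babel
#' backend. Results are memoised. Invalid molecules yield `NA`.
#'
#' @param smiles character vector of single-molecule SMILES (no `.`, no `>`).
#' @return character vector of canonical SMILES, `NA` where the backend
#'   rejects the input.
#' @examples
#' canonical_smiles(c("OCC", "C1=CC=CC=C1"))
#' @export
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  lookup <- function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    v <- the$canonical[[s]]
    if (is.null(v)) NULL else v           # cached value may itself be NA
  }
  resolved <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    v <- lookup(smiles[i])
    if (is.null(v)) next
    out[i] <- v
    resolved[i] <- TRUE
  }
  todo <- unique(smiles[!resolved])
  if (length(todo)) {
    res <- ob_canonical_batch(todo)
    res[!is.na(res) & !nzchar(res)] <- NA_character_
    for (i in seq_along(todo)) the$canonical[[todo[i]]] <- res[i]
    for (i in which(!resolved)) out[i] <- res[match(smiles[i], todo)]
  }
  out
}

# one batch call; Open Babel stops emitting at the first bad line, so fall
# back to per-molecule conversion when the line counts disagree
ob_canonical_batch <- function(smiles) {
  conv <- function(x) {
    ChemmineOB::convertFormat("SMI", "CAN", paste0(paste(x, collapse = "\n"), "\n"))
  }
  lines <- strsplit(conv(smiles), "\n", fixed = TRUE)[[1]]
  lines <- sub("[ \t\r]+$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == length(smiles)) return(lines)
  vapply(smiles, function(s) {
    one <- sub("[ \t\r\n]+$", "", conv(s))
    if (nzchar(one)) one else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

# -- canonical-SMILES reader --------------------------------------------------

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

capitalize_element <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

# Parse one canonical single-component SMILES into a graph. Only the dialect
# Open Babel emits needs to be covered; atom maps are stripped upstream.
# Neighbour order per atom is recorded (0 = in-bracket implicit H) because
# tetrahedral parity is defined relative to it.
smiles_graph <- function(s) {
  n_at <- 0L
  element <- character(); aromatic <- logical(); charge <- integer()
  isotope <- integer(); hcount <- integer(); stereo <- character()
  nbr_order <- list()
  b_a1 <- integer(); b_a2 <- integer(); b_order <- integer()
  b_arom <- logical(); b_dir <- character()

  prev <- NA_integer_
  stack <- integer(0)
  pend_sym <- ""            # pending bond symbol ("", "-", "=", "#", "$", ":", "/", "\\")
  open_rings <- list()      # digit -> list(atom, sym, pos)

  add_atom <- function(el, arom, chg, iso, hc, st) {
    n_at <<- n_at + 1L
    element[n_at] <<- el; aromatic[n_at] <<- arom; charge[n_at] <<- chg
    isotope[n_at] <<- iso; hcount[n_at] <<- hc; stereo[n_at] <<- st
    nbr_order[[n_at]] <<- integer(0)
    if (!is.na(prev)) {
      add_bond(prev, n_at, pend_sym)
      nbr_order[[prev]] <<- c(nbr_order[[prev]], n_at)
      nbr_order[[n_at]] <<- c(nbr_order[[n_at]], prev)
    }
    pend_sym <<- ""
    if (!is.na(hc) && hc > 0L)
      nbr_order[[n_at]] <<- c(nbr_order[[n_at]], rep(0L, hc))
    prev <<- n_at
    n_at
  }

  add_bond <- function(a1, a2, sym) {
    k <- length(b_a1) + 1L
    b_a1[k] <<- a1; b_a2[k] <<- a2
    b_dir[k] <<- ""
    if (sym == "" ) {
      if (aromatic[a1] && aromatic[a2]) { b_order[k] <<- 1L; b_arom[k] <<- TRUE }
      else { b_order[k] <<- 1L; b_arom[k] <<- FALSE }
    } else if (sym == ":") { b_order[k] <<- 1L; b_arom[k] <<- TRUE }
    else if (sym == "-") { b_order[k] <<- 1L; b_arom[k] <<- FALSE }
    else if (sym == "=") { b_order[k] <<- 2L; b_arom[k] <<- FALSE }
    else if (sym == "#") { b_order[k] <<- 3L; b_arom[k] <<- FALSE }
    else if (sym == "$") { b_order[k] <<- 4L; b_arom[k] <<- FALSE }
    else if (sym == "/" || sym == "\\") {
      b_order[k] <<- 1L; b_arom[k] <<- FALSE; b_dir[k] <<- sym
    } else drfp_error("drfp_unparsable_molecule", sprintf("unknown bond symbol '%s' in '%s'", sym, s))
    k
  }

  i <- 1L
  nc <- nchar(s)
  while (i <= nc) {
    ch <- substr(s, i, i)
    ch2 <- if (i < nc) substr(s, i, i + 1L) else ""
    if (ch == "[") {
      j <- regexpr("]", substr(s, i + 1L, nc), fixed = TRUE)
      if (j < 0) drfp_error("drfp_unparsable_molecule", sprintf("unclosed bracket in '%s'", s))
      content <- substr(s, i + 1L, i + j - 1L)
      m <- regmatches(content,
        regexec("^([0-9]+)?([A-Za-z][a-z]?|\\*)(@{1,2})?(H([0-9]+)?)?(\\++|-+|[+-][0-9]+)?$", content))[[1]]
      if (length(m) == 0)
        drfp_error("drfp_unparsable_molecule", sprintf("cannot read bracket atom [%s] in '%s'", content, s))
      iso <- if (nzchar(m[2])) as.integer(m[2]) else 0L
      sym <- m[3]
      arom <- substr(sym, 1, 1) %in% letters
      el <- if (sym == "*") "*" else capitalize_element(sym)
      st <- m[4]
      hc <- if (nzchar(m[5])) { if (nzchar(m[6])) as.integer(m[6]) else 1L } else 0L
      chg_s <- m[7]
      chg <- if (!nzchar(chg_s)) 0L
        else if (grepl("^\\++$", chg_s)) nchar(chg_s)
        else if (grepl("^-+$", chg_s)) -nchar(chg_s)
        else as.integer(chg_s)
      add_atom(el, arom, as.integer(chg), iso, hc, st)
      i <- i + j + 1L
    } else if (ch2 %in% c("Cl", "Br")) {
      add_atom(ch2, FALSE, 0L, 0L, NA_integer_, "")
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch, FALSE, 0L, 0L, NA_integer_, "")
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE, 0L, 0L, NA_integer_, "")
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", "$", ":", "/", "\\")) {
      pend_sym <- ch
      i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0)
        drfp_error("drfp_unparsable_molecule", sprintf("unbalanced ')' in '%s'", s))
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (ch == "%") {
        digit <- substr(s, i + 1L, i + 2L)
        i <- i + 3L
      } else {
        digit <- ch
        i <- i + 1L
      }
      if (is.na(prev))
        drfp_error("drfp_unparsable_molecule", sprintf("ring digit before any atom in '%s'", s))
      key <- digit
      if (!is.null(open_rings[[key]])) {
        op <- open_rings[[key]]
        open_rings[[key]] <- NULL
        sym <- if (nzchar(op$sym)) op$sym else pend_sym
        if (sym %in% c("/", "\\") && !nzchar(op$sym)) {
          # direction written at the closing atom applies closing->opening;
          # normalise to a1->a2 (opening->closing) by flipping
          sym_store <- if (sym == "/") "\\" else "/"
          k <- add_bond(op$atom, prev, sym_store)
        } else {
          k <- add_bond(op$atom, prev, sym)
        }
        # patch the placeholder left at the opening atom, append at closer
        nbr_order[[op$atom]][op$pos] <- prev
        nbr_order[[prev]] <- c(nbr_order[[prev]], op$atom)
      } else {
        nbr_order[[prev]] <- c(nbr_order[[prev]], -1L)
        open_rings[[key]] <- list(atom = prev, sym = pend_sym,
                                  pos = length(nbr_order[[prev]]))
      }
      pend_sym <- ""
    } else if (ch == ".") {
      prev <- NA_integer_
      i <- i + 1L
    } else if (ch %in% c(" ", "\t")) {
      i <- i + 1L
    } else {
      drfp_error("drfp_unparsable_molecule", sprintf("unexpected character '%s' in '%s'", ch, s))
    }
  }
  if (length(open_rings))
    drfp_error("drfp_unparsable_molecule", sprintf("unclosed ring bond in '%s'", s))
  if (length(stack))
    drfp_error("drfp_unparsable_molecule", sprintf("unbalanced '(' in '%s'", s))

  adj <- vector("list", n_at)
  for (k in seq_along(b_a1)) {
    adj[[b_a1[k]]] <- c(adj[[b_a1[k]]], k)
    adj[[b_a2[k]]] <- c(adj[[b_a2[k]]], k)
  }
  list(n = n_at, element = element, aromatic = aromatic, charge = charge,
       isotope = isotope, hcount = hcount, stereo = stereo,
       nbr_order = nbr_order,
       bond_a1 = b_a1, bond_a2 = b_a2, bond_order = b_order,
       bond_arom = b_arom, bond_dir = b_dir,
       adj = adj, smiles = s)
}

# canonicalize + parse, memoised on the raw input string
mol_graph <- function(smiles) {
  g <- the$graphs[[smiles]]
  if (!is.null(g)) return(g)
  can <- canonical_smiles(smiles)
  if (is.na(can))
    drfp_error("drfp_unparsable_molecule",
               sprintf("molecule SMILES rejected by the chemistry backend: '%s'", smiles),
               component = smiles)
  g <- the$graphs[[can]]
  if (is.null(g)) {
    g <- smiles_graph(can)
    the$graphs[[can]] <- g
  }
  the$graphs[[smiles]] <- g
  g
}

other_end <- function(g, bond, atom) {
  ifelse(g$bond_a1[bond] == atom, g$bond_a2[bond], g$bond_a1[bond])
}

# single-source BFS over the bond graph; returns integer distances (Inf-free,
# NA for unreachable, 0 at the root)
atom_distances <- function(g, root) {
  d <- rep(NA_integer_, g$n)
  d[root] <- 0L
  frontier <- root
  while (length(frontier)) {
    nxt <- integer(0)
    for (a in frontier) {
      for (k in g$adj[[a]]) {
        b <- other_end(g, k, a)
        if (is.na(d[b])) {
          d[b] <- d[a] + 1L
          nxt <- c(nxt, b)
        }
      }
    }
    frontier <- nxt
  }
  d
}
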