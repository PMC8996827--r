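# Molecular n-grams: the set of canonical fragment SMILES of all circular
# substructures (radius 0..r around every heavy atom) plus the SSSR rings.

#' Fingerprint configuration
#'
#' @param radius maximum circular-substructure radius in bonds. Radius 0 is
#'   the single root atom. Default 3.
#' @param n_bits fingerprint dimension `d` (length of the folded binary
#'   vector). Default 2048.
#' @param include_rings also extract every ring of the SSSR (smallest set of
#'   smallest rings) as a fragment. Default `TRUE`.
#' @return an object of class `drfp_config`.
#' @examples
#' drfp_config(radius = 2, n_bits = 512)
#' @export
drfp_config <- function(radius = 3, n_bits = 2048, include_rings = TRUE) {
  radius <- as.integer(radius)
  n_bits <- as.integer(n_bits)
  stopifnot(length(radius) == 1, !is.na(radius), radius >= 0,
            length(n_bits) == 1, !is.na(n_bits), n_bits >= 1,
            is.logical(include_rings), length(include_rings) == 1)
  structure(list(radius = radius, n_bits = n_bits,
                 include_rings = isTRUE(include_rings)),
            class = "drfp_config")
}

#' @export
print.drfp_config <- function(x, ...) {
  cat(sprintf("drfp configuration: radius = %d, n_bits = %d, include_rings = %s\n",
              x$radius, x$n_bits, x$include_rings))
  invisible(x)
}

# -- SSSR ---------------------------------------------------------------------

# Minimum cycle basis of the molecular graph (Horton-style): shortest cycle
# through every bond, sorted by size, kept greedily while linearly
# independent over GF(2) on the bond incidence vectors. Molecules are tiny,
# so the cubic-ish cost is irrelevant.
sssr <- function(g) {
  nb <- length(g$bond_a1)
  n_rings <- nb - g$n + 1L   # single connected component per molecule
  if (n_rings <= 0L) return(list())

  shortest_cycle_through <- function(k) {
    src <- g$bond_a1[k]; dst <- g$bond_a2[k]
    pred_atom <- rep(NA_integer_, g$n)
    pred_bond <- rep(NA_integer_, g$n)
    seen <- logical(g$n); seen[src] <- TRUE
    frontier <- src
    while (length(frontier) && !seen[dst]) {
      nxt <- integer(0)
      for (a in frontier) {
        for (kk in g$adj[[a]]) {
          if (kk == k) next
          b <- other_end(g, kk, a)
          if (!seen[b]) {
            seen[b] <- TRUE
            pred_atom[b] <- a; pred_bond[b] <- kk
            nxt <- c(nxt, b)
          }
        }
      }
      frontier <- nxt
    }
    if (!seen[dst]) return(NULL)  # bridge bond
    path <- integer(0)
    at <- dst
    while (at != src) {
      path <- c(path, pred_bond[at])
      at <- pred_atom[at]
    }
    sort(c(path, k))
  }

  cand <- Filter(Negate(is.null), lapply(seq_len(nb), shortest_cycle_through))
  if (!length(cand)) return(list())
  key <- vapply(cand, function(x) paste(x, collapse = ","), character(1))
  cand <- cand[!duplicated(key)]
  sizes <- vapply(cand, length, integer(1))
  keys <- vapply(cand, function(x) paste(sprintf("%04d", x), collapse = ","), character(1))
  cand <- cand[order(sizes, keys)]

  basis <- list()
  pivots <- integer(0)
  chosen <- list()
  for (cyc in cand) {
    v <- logical(nb); v[cyc] <- TRUE
    for (i in seq_along(basis)) {
      if (v[pivots[i]]) v <- xor(v, basis[[i]])
    }
    if (any(v)) {
      basis[[length(basis) + 1L]] <- v
      pivots[length(basis)] <- which(v)[1]
      chosen[[length(chosen) + 1L]] <- cyc
      if (length(chosen) == n_rings) break
    }
  }
  lapply(chosen, function(cyc) {
    list(atoms = sort(unique(c(g$bond_a1[cyc], g$bond_a2[cyc]))), bonds = cyc)
  })
}

# bonds of the circular environment of bond-radius rho rooted at `root`:
# every bond within rho steps, i.e. whose nearer endpoint is < rho away
environment_bonds <- function(g, dist, rho) {
  if (rho <= 0L || length(g$bond_a1) == 0L) return(integer(0))
  d1 <- dist[g$bond_a1]; d2 <- dist[g$bond_a2]
  near <- pmin(d1, d2)
  which(!is.na(near) & near <= rho - 1L)
}

#' Molecular shingling: circular substructures and SSSR rings as SMILES
#'
#' Iterates over the heavy atoms of a molecule and renders, for every radius
#' 0..`radius`, the circular substructure rooted at the atom as a canonical
#' fragment SMILES (radius 0 is the bare atom). With `include_rings`, every
#' SSSR ring (ring atoms and ring bonds only) is rendered as well. The result
#' is the set of distinct fragment strings.
#'
#' @param mol a single molecule SMILES string.
#' @param config a [drfp_config()]; only `radius` and `include_rings` are used.
#' @return sorted character vector of canonical fragment SMILES (a set).
#' @examples
#' molecule_shingling("CCO", drfp_config(radius = 1))
#' @export
molecule_shingling <- function(mol, config = drfp_config()) {
  stopifnot(inherits(config, "drfp_config"), is.character(mol), length(mol) == 1)
  g <- mol_graph(mol)
  key <- paste0(g$smiles, "\r", config$radius, "\r", config$include_rings)
  hit <- the$shinglings[[key]]
  if (!is.null(hit)) return(hit)

  frags <- character(0)
  heavy <- which(g$element != "H")
  for (a in heavy) {
    frags <- c(frags, fragment_smiles(g, a))
    if (config$radius >= 1L && length(g$adj[[a]])) {
      dist <- atom_distances(g, a)
      prev_n <- -1L
      for (rho in seq_len(config$radius)) {
        bonds <- environment_bonds(g, dist, rho)
        if (length(bonds) == prev_n) break   # environment exhausted the molecule
        prev_n <- length(bonds)
        atoms <- unique(c(a, g$bond_a1[bonds], g$bond_a2[bonds]))
        frags <- c(frags, fragment_smiles(g, atoms, bonds))
      }
    }
  }
  if (config$include_rings) {
    for (ring in sssr(g))
      frags <- c(frags, fragment_smiles(g, ring$atoms, ring$bonds))
  }
  out <- sort(unique(frags))
  the$shinglings[[key]] <- out
  out
}

#' Shingling of one side of a reaction
#'
#' Set union of [molecule_shingling()] over a list of molecules; the result
#' does not depend on molecule order or multiplicity.
#'
#' @param mols character vector of molecule SMILES.
#' @param config a [drfp_config()].
#' @return sorted character vector of canonical fragment SMILES.
#' @export
side_shingling <- function(mols, config = drfp_config()) {
  stopifnot(is.character(mols))
  out <- character(0)
  for (i in seq_along(mols)) {
    frags <- tryCatch(molecule_shingling(mols[i], config), drfp_error = function(e) {
      drfp_error(class(e)[1], sprintf("molecule %d: %s", i, conditionMessage(e)),
                 component = mols[i], index = i)
    })
    out <- c(out, frags)
  }
  sort(unique(out))
}
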