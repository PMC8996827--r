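# Independent oracles used across the suite. These deliberately take
# different computational routes from the package internals they check.

# --- brute-force shingling oracle -------------------------------------------
# Enumerates every (atom, radius) bond neighbourhood by literal frontier
# expansion (the package filters bonds on precomputed BFS distances) and the
# ring basis from ALL simple cycles (the package only considers shortest
# cycles through each bond).

oracle_environment <- function(g, root, rho) {
  atoms <- root
  bonds <- integer(0)
  if (rho > 0) {
    for (step in seq_len(rho)) {
      new_bonds <- unique(unlist(g$adj[atoms]))
      if (length(new_bonds) == 0) break
      bonds <- sort(unique(c(bonds, new_bonds)))
      atoms <- sort(unique(c(atoms, g$bond_a1[bonds], g$bond_a2[bonds])))
    }
  }
  list(atoms = atoms, bonds = bonds)
}

oracle_all_cycles <- function(g) {
  cycles <- list()
  seen <- character(0)
  nbrs <- function(u) {
    ks <- g$adj[[u]]
    cbind(ks, ifelse(g$bond_a1[ks] == u, g$bond_a2[ks], g$bond_a1[ks]))
  }
  extend <- function(path_atoms, path_bonds) {
    u <- path_atoms[length(path_atoms)]
    nb <- nbrs(u)
    if (length(nb) == 0) return(invisible())
    for (r in seq_len(nrow(nb))) {
      k <- nb[r, 1]; v <- nb[r, 2]
      if (length(path_bonds) && k == path_bonds[length(path_bonds)]) next
      if (v == path_atoms[1] && length(path_atoms) >= 3) {
        key <- paste(sort(c(path_bonds, k)), collapse = ",")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          cycles[[length(cycles) + 1L]] <<- sort(c(path_bonds, k))
        }
      } else if (!(v %in% path_atoms) && v > path_atoms[1]) {
        extend(c(path_atoms, v), c(path_bonds, k))
      }
    }
  }
  for (s in seq_len(g$n)) extend(s, integer(0))
  cycles
}

oracle_ring_basis <- function(g) {
  nb <- length(g$bond_a1)
  dim_cycle <- nb - g$n + 1L
  if (dim_cycle <= 0) return(list())
  cycles <- oracle_all_cycles(g)
  sizes <- vapply(cycles, length, integer(1))
  keys <- vapply(cycles, function(x) paste(sprintf("%04d", x), collapse = ","), character(1))
  cycles <- cycles[order(sizes, keys)]
  basis <- list(); pivots <- integer(0); chosen <- list()
  for (cyc in cycles) {
    v <- logical(nb); v[cyc] <- TRUE
    for (i in seq_along(basis)) if (v[pivots[i]]) v <- xor(v, basis[[i]])
    if (any(v)) {
      basis[[length(basis) + 1L]] <- v
      pivots[length(basis)] <- which(v)[1]
      chosen[[length(chosen) + 1L]] <- cyc
      if (length(chosen) == dim_cycle) break
    }
  }
  chosen
}

oracle_shingling <- function(mol, radius, include_rings = TRUE) {
  g <- drfp:::mol_graph(mol)
  frags <- character(0)
  for (a in which(g$element != "H")) {
    for (rho in 0:radius) {
      env <- oracle_environment(g, a, rho)
      frags <- c(frags, drfp:::fragment_smiles(g, env$atoms, env$bonds))
    }
  }
  if (include_rings) {
    for (cyc in oracle_ring_basis(g)) {
      atoms <- sort(unique(c(g$bond_a1[cyc], g$bond_a2[cyc])))
      frags <- c(frags, drfp:::fragment_smiles(g, atoms, cyc))
    }
  }
  sort(unique(frags))
}

# --- independent 32-bit FNV-1a in pure R ------------------------------------
# Double-precision arithmetic with a 16-bit split so every intermediate stays
# exact; checks the compiled implementation.

r_fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  h
}

bitwXor_dbl <- function(a, b) {
  # xor of doubles holding 32-bit unsigned values
  hi_a <- floor(a / 2^16); lo_a <- a %% 2^16
  hi_b <- floor(b / 2^16); lo_b <- b %% 2^16
  bitwXor(hi_a, hi_b) * 2^16 + bitwXor(lo_a, lo_b)
}

# --- independent classification metrics -------------------------------------
# MCC via the Pearson-correlation form on one-hot indicator matrices; CEN by
# a naive double loop straight from its published definition.

ref_mcc <- function(cm) {
  cm <- as.matrix(cm)
  lev <- seq_len(nrow(cm))
  # expand label vectors from the matrix: cell (i,j) contributes cm[i,j] pairs
  truth <- unlist(lapply(lev, function(i) rep(i, times = sum(cm[i, ]))))
  pred <- unlist(lapply(lev, function(i) {
    unlist(lapply(lev, function(j) rep(j, times = cm[i, j])))
  }))
  X <- outer(truth, lev, "==") * 1
  Y <- outer(pred, lev, "==") * 1
  num <- sum(diag(crossprod(scale(X, scale = FALSE), scale(Y, scale = FALSE))))
  den <- sqrt(sum(diag(crossprod(scale(X, scale = FALSE)))) *
              sum(diag(crossprod(scale(Y, scale = FALSE)))))
  if (den == 0) return(0)
  num / den
}

ref_cen <- function(cm) {
  cm <- as.matrix(cm)
  n <- nrow(cm)
  if (n < 2) return(0)
  total <- sum(cm)
  out <- 0
  for (j in seq_len(n)) {
    pj <- (sum(cm[j, ]) + sum(cm[, j])) / (2 * total)
    denom <- sum(cm[j, ]) + sum(cm[, j])
    if (denom == 0) next
    cenj <- 0
    for (k in seq_len(n)) {
      if (k == j) next
      for (p in list(cm[j, k] / denom, cm[k, j] / denom)) {
        if (p > 0) cenj <- cenj - p * log(p, base = 2 * (n - 1))
      }
    }
    out <- out + pj * cenj
  }
  out
}

random_confusion <- function(n_class, max_count = 40) {
  matrix(sample.int(max_count + 1L, n_class^2, replace = TRUE) - 1L,
         n_class, n_class)
}
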