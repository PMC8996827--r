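# Molecule panels and a randomized SMILES writer used by the invariance and
# oracle tests. The panel stays at <= 8 heavy atoms so brute-force oracles
# remain exhaustive; it covers alkanes, unsaturation, aromatics,
# heteroaromatics, rings (incl. fused), chiral and charged species, isotopes
# and cis/trans pairs.

small_molecule_panel <- function() {
  c("C", "CC", "CCC", "CCCC", "CC(C)C", "CC(C)(C)C",
    "C=C", "C#C", "CC=CC", "C=CC=C", "C#N", "N#CC",
    "CCO", "CO", "C=O", "CC(=O)O", "CC(=O)OC", "CCN",
    "CC(=O)N", "OCC(=O)O", "NCC(=O)O", "CS(=O)(=O)O",
    "c1ccccc1", "c1ccncc1", "c1cc[nH]c1", "c1ccoc1", "c1ccsc1", "Cc1ccccc1",
    "C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1", "C1CCOC1", "C1CCNC1",
    "CC1CC1", "C1CC2CCC1C2",
    "C[C@H](N)C(=O)O", "C[C@@H](N)C(=O)O", "C[C@@H](O)CC",
    "F/C=C/F", "F/C=C\\F",
    "[NH4+]", "[Cl-]", "CC(=O)[O-]", "C[N+](C)(C)C",
    "FC(F)(F)C", "ClCCBr", "[13CH4]")
}

# panel members safe for the randomized-rendering generator (no stereo marks,
# whose parity bookkeeping the simple test writer does not implement)
achiral_panel <- function() {
  p <- small_molecule_panel()
  p[!grepl("@|/|\\\\", p)]
}

# Write a molecule graph as SMILES in a random atom order. Stereo and
# direction marks are dropped (use achiral molecules). Relies only on the
# parsed graph structure, not on the package's canonical writer.
random_rendering <- function(mol, seed) {
  g <- drfp:::mol_graph(mol)
  stopifnot(all(g$stereo == ""), all(g$bond_dir == ""))
  drfp:::with_seed(seed, {
    visited <- logical(g$n)
    digit_pool <- rep(TRUE, 9)
    open_digit <- integer(length(g$bond_a1))
    ring_at <- vector("list", g$n)   # precomputed ring bonds per atom
    children <- vector("list", g$n)
    parentb <- rep(NA_integer_, g$n)
    # random DFS to classify edges
    order_seen <- integer(0)
    stack <- list(list(a = sample.int(g$n, 1), pb = NA_integer_))
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (visited[fr$a]) next
      visited[fr$a] <- TRUE
      parentb[fr$a] <- fr$pb
      order_seen <- c(order_seen, fr$a)
      ks <- g$adj[[fr$a]]
      if (length(ks)) for (k in ks[sample.int(length(ks))]) {
        v <- drfp:::other_end(g, k, fr$a)
        if (!is.na(fr$pb) && k == fr$pb) next
        stack[[length(stack) + 1L]] <- list(a = v, pb = k)
      }
    }
    disc <- match(seq_len(g$n), order_seen)
    for (a in seq_len(g$n)) {
      ks <- g$adj[[a]]
      if (!length(ks)) next
      for (k in ks[sample.int(length(ks))]) {
        v <- drfp:::other_end(g, k, a)
        if (!is.na(parentb[v]) && parentb[v] == k && disc[v] > disc[a]) {
          children[[a]] <- c(children[[a]], list(c(k, v)))
        } else if ((is.na(parentb[a]) || parentb[a] != k) &&
                   !(!is.na(parentb[v]) && parentb[v] == k) &&
                   disc[v] > disc[a]) {
          ring_at[[a]] <- c(ring_at[[a]], k)   # record at earlier atom only
        }
      }
    }
    atom_tok <- function(a) {
      sym <- g$element[a]
      if (g$aromatic[a]) sym <- tolower(sym)
      if (g$element[a] %in% drfp:::ORGANIC_SUBSET && g$isotope[a] == 0L &&
          g$charge[a] == 0L && is.na(g$hcount[a]) &&
          (!g$aromatic[a] || g$element[a] %in% c("B", "C", "N", "O", "P", "S")))
        return(sym)
      hc <- g$hcount[a]
      paste0("[", if (g$isotope[a] > 0) g$isotope[a] else "", sym,
             if (!is.na(hc) && hc > 0) paste0("H", if (hc > 1) hc else "") else "",
             drfp:::charge_token(g$charge[a]), "]")
    }
    bond_tok <- function(k) {
      if (g$bond_arom[k]) return("")
      switch(g$bond_order[k], "1" = {
        if (g$aromatic[g$bond_a1[k]] && g$aromatic[g$bond_a2[k]]) "-" else ""
      }, "2" = "=", "3" = "#", "$")
    }
    write_atom <- function(a) {
      out <- atom_tok(a)
      for (k in g$adj[[a]]) {
        # closures for ring bonds opened at the partner
        partner <- drfp:::other_end(g, k, a)
        if (k %in% ring_at[[partner]] && disc[partner] < disc[a]) {
          out <- paste0(out, open_digit[k])
          digit_pool[open_digit[k]] <<- TRUE
        }
      }
      for (k in ring_at[[a]]) {
        d <- which(digit_pool)[1]
        digit_pool[d] <<- FALSE
        open_digit[k] <<- d
        out <- paste0(out, bond_tok(k), d)
      }
      kids <- children[[a]]
      if (length(kids)) {
        parts <- vapply(kids, function(kv)
          paste0(bond_tok(kv[1]), write_atom(kv[2])), character(1))
        if (length(parts) > 1)
          out <- paste0(out, paste0("(", parts[-length(parts)], ")", collapse = ""),
                        parts[length(parts)])
        else out <- paste0(out, parts)
      }
      out
    }
    write_atom(order_seen[1])
  })
}

# molecule SMILES appearing in the synthetic reaction corpus, for seeded
# random-molecule draws
fixture_molecules <- function() {
  set_ <- generate_template_reactions(5, 20, seed = 99)
  mols <- unlist(lapply(set_$reactions, function(rx) {
    rec <- parse_reaction(rx)
    c(rec$reactants, rec$reagents, rec$products)
  }))
  sort(unique(mols))
}
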