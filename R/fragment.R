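# Canonical rendering of molecular fragments (subgraphs) as SMILES strings.
#
# Fragments must render to the same string no matter which molecule or atom
# ordering they were extracted from, otherwise substructures shared by the
# two sides of a reaction would fail to cancel in the symmetric difference.
# Canonical atom ranks are computed by iterative partition refinement over
# atom/bond invariants with deterministic tie-breaking, and the string is
# written by a DFS that visits neighbours in rank order. Tetrahedral parity
# is recomputed against the written neighbour order; cis/trans marks are kept
# only when the defining bonds are wholly inside the fragment.

# ranks: iterative refinement, then symmetry tie-breaks until discrete
fragment_ranks <- function(el, arom, chg, iso, hc, adjb, bond_lab, bond_other) {
  la <- length(el)
  base <- paste(el, arom, chg, iso, ifelse(is.na(hc), "x", hc),
                vapply(adjb, length, integer(1)))
  tb <- rep(0L, la)
  refine <- function(inv) {
    ranks <- match(inv, sort(unique(inv)))
    repeat {
      # zero-padded old rank as key prefix: refinement only ever splits
      # classes, so the loop terminates at the stable partition
      keys <- vapply(seq_len(la), function(a) {
        nb <- adjb[[a]]
        env <- if (length(nb))
          paste(sort(paste0(bond_lab[nb], ".", sprintf("%06d", ranks[bond_other[[a]]]))),
                collapse = "|")
        else ""
        paste0(sprintf("%06d", ranks[a]), "#", env)
      }, character(1))
      new <- match(keys, sort(unique(keys)))
      if (identical(new, ranks)) break
      ranks <- new
    }
    ranks
  }
  ranks <- refine(paste(base, tb))
  counter <- 0L
  while (anyDuplicated(ranks)) {
    dup <- sort(unique(ranks[duplicated(ranks)]))[1]
    member <- which(ranks == dup)[1]
    counter <- counter + 1L
    tb[member] <- counter
    ranks <- refine(paste(base, tb))
  }
  ranks
}

perm_parity_even <- function(p) {
  # TRUE if permutation p (a rearrangement of 1..n) is even
  n <- length(p)
  seen <- logical(n)
  sign <- TRUE
  for (i in seq_len(n)) {
    if (seen[i]) next
    j <- i
    len <- 0L
    while (!seen[j]) {
      seen[j] <- TRUE
      j <- p[j]
      len <- len + 1L
    }
    if (len %% 2L == 0L) sign <- !sign
  }
  sign
}

charge_token <- function(chg) {
  if (chg == 0L) ""
  else if (chg == 1L) "+"
  else if (chg == -1L) "-"
  else if (chg > 1L) paste0("+", chg)
  else paste0("-", abs(chg))
}

#' @keywords internal
#' @noRd
fragment_smiles <- function(g, atoms, bonds = integer(0)) {
  atoms <- sort(unique(as.integer(atoms)))
  bonds <- sort(unique(as.integer(bonds)))
  la <- length(atoms)
  gl <- integer(g$n); gl[atoms] <- seq_len(la)

  el <- g$element[atoms]; arom <- g$aromatic[atoms]
  chg <- g$charge[atoms]; iso <- g$isotope[atoms]; hc <- g$hcount[atoms]

  lb_a1 <- gl[g$bond_a1[bonds]]; lb_a2 <- gl[g$bond_a2[bonds]]
  lb_order <- g$bond_order[bonds]; lb_arom <- g$bond_arom[bonds]
  bond_lab <- ifelse(lb_arom, ":", as.character(lb_order))

  adjb <- vector("list", la)       # local bond ids per local atom
  bond_other <- vector("list", la) # partner local atom per entry of adjb
  for (k in seq_along(bonds)) {
    adjb[[lb_a1[k]]] <- c(adjb[[lb_a1[k]]], k)
    bond_other[[lb_a1[k]]] <- c(bond_other[[lb_a1[k]]], lb_a2[k])
    adjb[[lb_a2[k]]] <- c(adjb[[lb_a2[k]]], k)
    bond_other[[lb_a2[k]]] <- c(bond_other[[lb_a2[k]]], lb_a1[k])
  }

  ranks <- fragment_ranks(el, arom, chg, iso, hc, adjb, bond_lab, bond_other)

  # --- stereo retention -----------------------------------------------------
  in_frag_bond <- logical(length(g$bond_a1)); in_frag_bond[bonds] <- TRUE
  keep_stereo <- vapply(seq_len(la), function(a) {
    ga <- atoms[a]
    if (!nzchar(g$stereo[ga])) return(FALSE)
    nb <- g$nbr_order[[ga]]
    heavy <- nb[nb > 0L]
    if (!(length(nb) %in% c(3L, 4L))) return(FALSE)
    if (sum(nb == 0L) > 1L) return(FALSE)
    if (!all(gl[heavy] > 0L)) return(FALSE)
    all(in_frag_bond[g$adj[[ga]]])
  }, logical(1))

  # cis/trans: keep direction marks only around double bonds that still have
  # at least one in-fragment marked single bond on each end
  kept_dir <- logical(length(bonds))
  dbl <- which(lb_order == 2L & !lb_arom)
  for (k in dbl) {
    ends <- c(atoms[lb_a1[k]], atoms[lb_a2[k]])
    side_ok <- logical(2)
    side_bonds <- vector("list", 2)
    for (e in 1:2) {
      kb <- g$adj[[ends[e]]]
      kb <- kb[g$bond_dir[kb] != "" & g$bond_order[kb] == 1L]
      inside <- kb[in_frag_bond[kb]]
      side_ok[e] <- length(kb) > 0L && length(inside) > 0L
      side_bonds[[e]] <- inside
    }
    if (all(side_ok)) {
      loc <- match(unique(unlist(side_bonds)), bonds)
      kept_dir[loc[!is.na(loc)]] <- TRUE
    }
  }

  # --- DFS (neighbours in rank order) ---------------------------------------
  root <- which.min(ranks)
  disc <- rep(NA_integer_, la)
  parent_bond <- rep(NA_integer_, la)
  children <- vector("list", la)   # list of (bond, atom) in visit order
  ring_open <- vector("list", la)  # bonds opening at this atom, partner later
  ring_close <- vector("list", la) # bonds closing at this atom, partner earlier
  clock <- 0L
  # iterative DFS to avoid R recursion limits on long chains
  stack <- list(list(a = root, pb = NA_integer_))
  seen_bond <- logical(length(bonds))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    a <- fr$a
    if (!is.na(disc[a])) next
    clock <- clock + 1L
    disc[a] <- clock
    parent_bond[a] <- fr$pb
    if (!is.na(fr$pb)) seen_bond[fr$pb] <- TRUE
    nb <- adjb[[a]]
    if (length(nb)) {
      ord <- order(ranks[bond_other[[a]]])
      # push in reverse so lowest-rank neighbour is visited first
      for (idx in rev(ord)) {
        k <- nb[idx]; v <- bond_other[[a]][idx]
        if (!is.na(fr$pb) && k == fr$pb) next
        stack[[length(stack) + 1L]] <- list(a = v, pb = k)
      }
    }
  }
  # classify edges now that discovery times are fixed
  for (a in seq_len(la)) {
    nb <- adjb[[a]]
    if (!length(nb)) next
    ord <- order(ranks[bond_other[[a]]])
    for (idx in ord) {
      k <- nb[idx]; v <- bond_other[[a]][idx]
      if (!is.na(parent_bond[v]) && parent_bond[v] == k && disc[v] > disc[a]) {
        children[[a]] <- c(children[[a]], list(c(k, v)))
      } else if ((is.na(parent_bond[a]) || parent_bond[a] != k) &&
                 !(!is.na(parent_bond[v]) && parent_bond[v] == k)) {
        # ring bond; record at both ends once
        if (disc[v] > disc[a]) ring_open[[a]] <- c(ring_open[[a]], k)
        else ring_close[[a]] <- c(ring_close[[a]], k)
      }
    }
  }
  if (any(is.na(disc)))
    drfp_error("drfp_internal", "fragment subgraph is not connected")

  # ring openings at an atom ordered by partner discovery time
  for (a in seq_len(la)) {
    if (length(ring_open[[a]]) > 1L) {
      partners <- vapply(ring_open[[a]], function(k)
        disc[if (lb_a1[k] == a) lb_a2[k] else lb_a1[k]], integer(1))
      ring_open[[a]] <- ring_open[[a]][order(partners)]
    }
  }

  # --- write ----------------------------------------------------------------
  open_digit <- integer(length(bonds))  # digit currently assigned to bond
  open_seq <- integer(length(bonds))    # global order in which digit opened
  digit_used <- logical(99)
  seq_counter <- 0L

  alloc_digit <- function() {
    d <- which(!digit_used)[1]
    digit_used[d] <<- TRUE
    d
  }
  digit_str <- function(d) if (d < 10L) as.character(d) else sprintf("%%%02d", d)

  bond_token <- function(k, from) {
    # from = local atom the traversal leaves
    if (lb_arom[k]) return("")
    if (lb_order[k] == 2L) return("=")
    if (lb_order[k] == 3L) return("#")
    if (lb_order[k] == 4L) return("$")
    gk <- bonds[k]
    if (kept_dir[k]) {
      d <- g$bond_dir[gk]
      if (g$bond_a1[gk] != atoms[from]) d <- if (d == "/") "\\" else "/"
      return(d)
    }
    if (arom[lb_a1[k]] && arom[lb_a2[k]]) return("-")
    ""
  }

  atom_token <- function(a, written_nbrs) {
    sym <- el[a]
    if (arom[a]) sym <- tolower(sym)
    st <- ""
    if (keep_stereo[a]) {
      ga <- atoms[a]
      parsed <- g$nbr_order[[ga]]
      parsed_l <- ifelse(parsed == 0L, 0L, gl[parsed])
      pos <- match(parsed_l, written_nbrs)
      # repeated 0 impossible here (<=1 bracket H when stereo kept)
      st <- g$stereo[ga]
      if (!anyNA(pos) && !perm_parity_even(pos))
        st <- if (st == "@") "@@" else "@"
    }
    bare <- el[a] %in% ORGANIC_SUBSET && iso[a] == 0L && chg[a] == 0L &&
      !nzchar(st) && is.na(hc[a]) &&
      (!arom[a] || el[a] %in% c("B", "C", "N", "O", "P", "S"))
    if (bare) return(sym)
    hctok <- ""
    if (!is.na(hc[a]) && hc[a] > 0L)
      hctok <- if (hc[a] == 1L) "H" else paste0("H", hc[a])
    paste0("[", if (iso[a] > 0L) iso[a] else "", sym, st, hctok,
           charge_token(chg[a]), "]")
  }

  write_atom <- function(a) {
    written <- integer(0)
    if (!is.na(parent_bond[a])) {
      pb <- parent_bond[a]
      written <- c(written, if (lb_a1[pb] == a) lb_a2[pb] else lb_a1[pb])
    }
    nH <- if (!is.na(hc[a])) hc[a] else 0L
    if (nH > 0L) written <- c(written, rep(0L, nH))

    ring_toks <- character(0)
    # closures first (digits already known), ordered by opening sequence
    cl <- ring_close[[a]]
    if (length(cl)) {
      cl <- cl[order(open_seq[cl])]
      for (k in cl) {
        ring_toks <- c(ring_toks, digit_str(open_digit[k]))
        digit_used[open_digit[k]] <<- FALSE
        written <- c(written, if (lb_a1[k] == a) lb_a2[k] else lb_a1[k])
      }
    }
    for (k in ring_open[[a]]) {
      d <- alloc_digit()
      open_digit[k] <<- d
      seq_counter <<- seq_counter + 1L
      open_seq[k] <<- seq_counter
      ring_toks <- c(ring_toks, paste0(bond_token(k, a), digit_str(d)))
      written <- c(written, if (lb_a1[k] == a) lb_a2[k] else lb_a1[k])
    }

    kids <- children[[a]]
    for (kv in kids) written <- c(written, kv[2])

    out <- paste0(atom_token(a, written), paste(ring_toks, collapse = ""))
    if (length(kids)) {
      parts <- vapply(seq_along(kids), function(i) {
        k <- kids[[i]][1]; v <- kids[[i]][2]
        paste0(bond_token(k, a), write_atom(v))
      }, character(1))
      if (length(parts) > 1L)
        out <- paste0(out, paste0("(", parts[-length(parts)], ")", collapse = ""), parts[length(parts)])
      else out <- paste0(out, parts)
    }
    out
  }

  write_atom(root)
}
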