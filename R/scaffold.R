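#' Murcko scaffold of a molecule
#'
#' The union of ring systems plus the acyclic linkers connecting them;
#' terminal side chains (including exocyclic substituents) are removed by
#' iterative pruning of degree-1 heavy atoms. An acyclic molecule has an
#' empty scaffold. The operation is idempotent.
#'
#' @param m an `lk_mol`.
#' @return an `lk_mol` (possibly with zero atoms).
#' @export
murcko_scaffold <- function(m) {
  m <- strip_hydrogens(m)
  repeat {
    deg <- tabulate(c(m$bonds$a1, m$bonds$a2), nbins = nrow(m$atoms))
    drop <- which(deg <= 1)
    if (nrow(m$atoms) == 0 || length(drop) == 0) break
    m <- subset_molecule(m, setdiff(seq_len(nrow(m$atoms)), drop))
  }
  m
}

# A cleavable bond under the configured retrosynthetic rules: acyclic single
# non-aromatic covalent bonds in chemically meaningful environments.
default_brics_rules <- function() {
  list(
    amide   = function(env) env$carbonyl1 && env$el2 == "N",
    ester   = function(env) env$carbonyl1 && env$el2 == "O",
    ether   = function(env) env$el1 == "O" && env$deg1 >= 2 && env$el2 == "C" &&
      !env$ring2 && !env$carbonyl2,
    ring_chain = function(env) env$ring1 && env$el2 == "C" && !env$ring2 &&
      env$deg2 >= 2
  )
}

#' Fragment a molecule with BRICS-style retrosynthetic rules
#'
#' Cleaves every acyclic single bond whose environment matches one of the
#' configured bond-environment rules (amide, ester, ether and ring-to-chain
#' by default), replacing each cut end with an attachment marker atom
#' (`"*"`). A molecule with no cleavable bond is returned as a singleton
#' set. The heavy-atom multiset of all fragments (attachment markers
#' excluded) equals the parent's.
#'
#' @param m an `lk_mol`.
#' @param rules named list of predicates over bond environments; see
#'   `default_brics_rules`.
#' @return list of `lk_mol` fragments.
#' @export
brics_fragments <- function(m, rules = default_brics_rules()) {
  m <- strip_hydrogens(m)
  if (nrow(m$atoms) == 0) return(list(m))
  rb <- ring_bonds(m)
  inring <- ring_atoms(m)
  nb <- neighbours(m)
  deg <- lengths(nb)
  bidx <- atom_bond_index(m)
  has_carbonyl <- vapply(seq_len(nrow(m$atoms)), function(i) {
    m$atoms$element[i] == "C" &&
      any(m$bonds$order[bidx[[i]]] == 2 &
            m$atoms$element[ifelse(m$bonds$a1[bidx[[i]]] == i,
                                   m$bonds$a2[bidx[[i]]],
                                   m$bonds$a1[bidx[[i]]])] == "O")
  }, TRUE)
  env_of <- function(i, j) list(
    el1 = m$atoms$element[i], el2 = m$atoms$element[j],
    deg1 = deg[i], deg2 = deg[j],
    ring1 = inring[i], ring2 = inring[j],
    carbonyl1 = has_carbonyl[i], carbonyl2 = has_carbonyl[j])
  cut <- logical(nrow(m$bonds))
  for (k in seq_len(nrow(m$bonds))) {
    b <- m$bonds[k, ]
    if (rb[k] || b$order != 1L || b$aromatic || b$dative) next
    e12 <- env_of(b$a1, b$a2); e21 <- env_of(b$a2, b$a1)
    cut[k] <- any(vapply(rules, function(r) isTRUE(r(e12)) || isTRUE(r(e21)), TRUE))
  }
  if (!any(cut)) return(list(m))

  # remove cut bonds, add a "*" marker bonded to each cut end
  atoms <- m$atoms
  bonds <- m$bonds[!cut, , drop = FALSE]
  for (k in which(cut)) {
    for (endp in c(m$bonds$a1[k], m$bonds$a2[k])) {
      atoms <- rbind(atoms, data.frame(atom_id = NA_character_, element = "*",
                                       charge = 0L, x = NA_real_, y = NA_real_,
                                       z = NA_real_, x2 = NA_real_, y2 = NA_real_))
      bonds <- rbind(bonds, data.frame(a1 = endp, a2 = nrow(atoms), order = 1L,
                                       aromatic = FALSE, dative = FALSE))
    }
  }
  whole <- molecule(atoms, bonds, name = m$name)
  lapply(mol_components(whole), function(idx) subset_molecule(whole, idx))
}
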