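#' PARITY similarity between two molecules
#'
#' Atom-level maximum-common-substructure similarity. The common
#' substructure (connected or disconnected) is found as a maximum clique on
#' the modular product of the two heavy-atom graphs: product vertices are
#' element-matching atom pairs, and two vertices are compatible when the
#' corresponding atom pairs agree on bond existence (and, in strict mode,
#' bond order and aromaticity). The score is the Jaccard ratio over atoms:
#'
#' \deqn{score = matched / (n_A + n_B - matched)}
#'
#' so identical heavy-atom graphs score 1 and element-disjoint molecules 0.
#' The clique search is exact up to a node-expansion budget; if the budget
#' is exhausted the best substructure found so far is returned with
#' `timed_out = TRUE`.
#'
#' @param a,b `lk_mol` objects (hydrogens are ignored).
#' @param strict_bonds if `TRUE`, matched bonds must agree on order and
#'   aromatic flag; by default only bond existence matters, which is robust
#'   to tautomer and charge-state drawing differences.
#' @param budget node-expansion budget for the clique search.
#' @return an `lk_parity` list: `score`, `matched_atoms`, `mapping`
#'   (data.frame query/target atom indices), `timed_out`.
#' @examples
#' \dontrun{
#' parity_score(fixture_mol("benzene"), fixture_mol("ethylbenzene"))
#' }
#' @export
parity_score <- function(a, b, strict_bonds = FALSE, budget = 1e6) {
  a <- strip_hydrogens(a); b <- strip_hydrogens(b)
  nA <- nrow(a$atoms); nB <- nrow(b$atoms)
  empty <- structure(list(score = 0, matched_atoms = 0L,
                          mapping = data.frame(query = integer(), target = integer()),
                          timed_out = FALSE), class = "lk_parity")
  if (nA == 0 || nB == 0) return(empty)

  pairs <- element_pairs(a, b)
  if (nrow(pairs) == 0) return(empty)

  adj <- product_adjacency(a, b, pairs, strict_bonds)
  res <- .lk_max_clique(adj, budget)
  matched <- length(res$clique)
  mapping <- data.frame(query = pairs$i[res$clique], target = pairs$j[res$clique])
  mapping <- mapping[order(mapping$query), , drop = FALSE]
  rownames(mapping) <- NULL
  structure(list(score = matched / (nA + nB - matched),
                 matched_atoms = matched,
                 mapping = mapping,
                 timed_out = res$timed_out), class = "lk_parity")
}

#' @export
print.lk_parity <- function(x, ...) {
  cat(sprintf("<PARITY %.4f: %d matched atom(s)%s>\n", x$score, x$matched_atoms,
              if (x$timed_out) ", budget exhausted" else ""))
  invisible(x)
}

element_pairs <- function(a, b) {
  out <- list()
  for (el in intersect(unique(a$atoms$element), unique(b$atoms$element))) {
    ia <- which(a$atoms$element == el)
    ib <- which(b$atoms$element == el)
    out[[el]] <- expand.grid(i = ia, j = ib, KEEP.OUT.ATTRS = FALSE)
  }
  if (length(out) == 0) return(data.frame(i = integer(), j = integer()))
  pairs <- do.call(rbind, out)
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

# bond matrix: 0 = none; else order (aromatic encoded as 1.5)
bond_matrix <- function(m) {
  n <- nrow(m$atoms)
  M <- matrix(0, n, n)
  b <- m$bonds
  if (nrow(b)) {
    v <- ifelse(b$aromatic, 1.5, b$order)
    M[cbind(b$a1, b$a2)] <- v
    M[cbind(b$a2, b$a1)] <- v
  }
  M
}

product_adjacency <- function(a, b, pairs, strict_bonds) {
  BA <- bond_matrix(a); BB <- bond_matrix(b)
  np <- nrow(pairs)
  i <- pairs$i; j <- pairs$j
  Ai <- BA[i, i, drop = FALSE]   # np x np: bond between a-atoms of vertex pairs
  Bj <- BB[j, j, drop = FALSE]
  diff_i <- outer(i, i, "!=")
  diff_j <- outer(j, j, "!=")
  if (strict_bonds) {
    compat <- (Ai == Bj)
  } else {
    compat <- (Ai > 0) == (Bj > 0)
  }
  adj <- diff_i & diff_j & compat
  diag(adj) <- FALSE
  adj
}

#' Check whether two molecules are stereoisomers
#'
#' True when the InChI formula, connectivity and hydrogen layers agree but
#' the stereo layers (double-bond and tetrahedral) differ. A molecule is
#' never a stereoisomer of itself, and constitutional isomers are rejected
#' by the connectivity layer.
#'
#' @param a,b `lk_mol` objects (3D coordinates drive stereo perception).
#' @return logical.
#' @export
stereoisomer_check <- function(a, b) {
  la <- inchi_layers(mol_inchi(a))
  lb <- inchi_layers(mol_inchi(b))
  la$formula == lb$formula && la$connect == lb$connect &&
    la$hydrogens == lb$hydrogens && la$stereo != lb$stereo
}

#' Group reference ligands by their relation to a query ligand
#'
#' Reference ligands are partitioned into three disjoint groups, in priority
#' order: stereoisomers of the query, ligands sharing the query's (non-empty)
#' scaffold, and ligands with PARITY similarity at or above `t_related`.
#'
#' @param query an `lk_mol`.
#' @param reference_set list of entries, each a list with `id`, `mol`, and
#'   optionally precomputed `scaffold_smiles` and `inchi`.
#' @param t_related similarity threshold (inclusive), default 0.6.
#' @param budget clique-search budget passed to [parity_score()].
#' @return an `lk_related_report` list: `stereoisomers`, `same_scaffold`
#'   (character id vectors), `similar` (data.frame id/score), `t_related`.
#' @export
related_ligands <- function(query, reference_set, t_related = 0.6, budget = 1e6) {
  qs <- murcko_scaffold(query)
  q_scaf <- if (nrow(qs$atoms)) mol_cansmiles(qs) else ""
  q_inchi <- mol_inchi(query)
  stereo <- character(); scaf <- character()
  sim_id <- character(); sim_score <- numeric()
  for (ref in reference_set) {
    is_stereo <- {
      li <- inchi_layers(if (!is.null(ref$inchi)) ref$inchi else mol_inchi(ref$mol))
      lq <- inchi_layers(q_inchi)
      li$formula == lq$formula && li$connect == lq$connect &&
        li$hydrogens == lq$hydrogens && li$stereo != lq$stereo
    }
    if (is_stereo) { stereo <- c(stereo, ref$id); next }
    r_scaf <- if (!is.null(ref$scaffold_smiles)) ref$scaffold_smiles else {
      rs <- murcko_scaffold(ref$mol)
      if (nrow(rs$atoms)) mol_cansmiles(rs) else ""
    }
    if (nzchar(q_scaf) && identical(q_scaf, r_scaf)) { scaf <- c(scaf, ref$id); next }
    sc <- parity_score(query, ref$mol, budget = budget)$score
    if (sc >= t_related) { sim_id <- c(sim_id, ref$id); sim_score <- c(sim_score, sc) }
  }
  structure(list(stereoisomers = stereo, same_scaffold = scaf,
                 similar = data.frame(id = sim_id, score = sim_score),
                 t_related = t_related), class = "lk_related_report")
}

#' @export
print.lk_related_report <- function(x, ...) {
  cat(sprintf("<related ligands: %d stereoisomer(s), %d same-scaffold, %d similar (>= %.2f)>\n",
              length(x$stereoisomers), length(x$same_scaffold), nrow(x$similar),
              x$t_related))
  invisible(x)
}
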