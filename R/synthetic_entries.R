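# Synthetic stand-in entries for two well-known archive situations, built
# entirely in code so no download is ever needed:
#
#  * a Chromomycin-like entry: two copies of a six-component ligand
#    (tri-saccharide arm + di-saccharide arm covalently joined to an
#    aromatic chromophore) plus a coordinated Mg ion;
#  * an NAD-cofactor entry: many copies of NAD bound to a dehydrogenase-like
#    protein, plus a smaller cryoprotectant-like ligand.
#
# The component graphs are synthetic look-alikes, not dictionary copies.

embed_random_walk <- function(m, seed) {
  set.seed(seed)
  n <- nrow(m$atoms)
  pos <- matrix(0, n, 3)
  nb <- neighbours(m)
  placed <- logical(n)
  # BFS from atom 1 through bonds; isolated atoms drop on a line
  queue <- 1L; placed[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in nb[[v]]) {
      if (placed[w]) next
      repeat {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        p <- pos[v, ] + 1.5 * u
        if (all(rowSums((pos[placed, , drop = FALSE] -
                           matrix(p, sum(placed), 3, byrow = TRUE))^2) > 0.81)) break
      }
      pos[w, ] <- p; placed[w] <- TRUE; queue <- c(queue, w)
    }
    if (!length(queue) && any(!placed)) {
      k <- which(!placed)[1]; pos[k, ] <- c(5 * k, 0, 0); placed[k] <- TRUE
      queue <- k
    }
  }
  m$atoms$x <- pos[, 1]; m$atoms$y <- pos[, 2]; m$atoms$z <- pos[, 3]
  m
}

smiles_component <- function(id, smiles, seed) {
  m <- ensure_atom_ids(mol_from_smiles(smiles, name = id))
  m <- sanitize(m)$mol
  component_record(id, embed_random_walk(m, seed))
}

#' Synthetic Chromomycin-like entry
#'
#' A two-chain assembly in which each chain carries a six-component ligand:
#' two copies of a deoxy-sugar (CDR) and one acetylated sugar (ERI) form one
#' covalently linked arm, a second arm joins two further sugars (ARI, 1GL),
#' and both arms attach to an aromatic chromophore core (CPH). A single Mg
#' ion is metal-coordinated (not covalently bonded) to one chromophore.
#' Correct bound-molecule inference therefore yields one six-component
#' molecule per chain plus a separate Mg.
#'
#' @return list: `assembly`, `components` (named list of `lk_component`).
#' @export
synthetic_chromomycin_entry <- function() {
  smis <- c(
    CDR = "CC1OC(O)CC(O)C1O",
    ERI = "CC1OC(O)CC(OC(C)=O)C1O",
    ARI = "CC1OC(O)CC(O)C1OC(C)=O",
    `1GL` = "CC1OC(O)C(O)C(O)C1O",
    CPH = "CCC(O)C(=O)c1c(O)cc2cc3cc(OC)c(O)c(C)c3c(O)c2c1O")
  comps <- list()
  for (i in seq_along(smis)) {
    comps[[names(smis)[i]]] <- smiles_component(names(smis)[i], smis[[i]], 400 + i)
  }
  comps[["MG"]] <- component_record("MG", molecule(
    data.frame(atom_id = "MG", element = "Mg", x = 0, y = 0, z = 0)))

  instances <- NULL; sites <- NULL; links <- NULL
  add <- function(comp, chain, resnum, offset) {
    rec <- comps[[comp]]
    instances <<- rbind(instances, data.frame(
      component_id = comp, chain = chain, resnum = resnum,
      kind = "non-polymer", stringsAsFactors = FALSE))
    ii <- nrow(instances)
    sites <<- rbind(sites, data.frame(
      instance = ii, atom_id = rec$mol$atoms$atom_id,
      element = rec$mol$atoms$element,
      x = rec$mol$atoms$x + offset[1], y = rec$mol$atoms$y + offset[2],
      z = rec$mol$atoms$z + offset[3], stringsAsFactors = FALSE))
    ii
  }
  link <- function(i1, a1, i2, a2, kind = "covalent") {
    links <<- rbind(links, data.frame(inst1 = i1, atom1 = a1, inst2 = i2,
                                      atom2 = a2, kind = kind,
                                      stringsAsFactors = FALSE))
  }
  first_o <- function(comp) {
    a <- comps[[comp]]$mol$atoms
    a$atom_id[a$element == "O"][1]
  }
  anomeric_c <- function(comp) comps[[comp]]$mol$atoms$atom_id[1]

  for (ch in c("E", "F")) {
    base <- if (ch == "E") 0 else 60
    cdr1 <- add("CDR", ch, 101L, c(base, 0, 0))
    cdr2 <- add("CDR", ch, 102L, c(base + 8, 0, 0))
    eri  <- add("ERI", ch, 103L, c(base + 16, 0, 0))
    ari  <- add("ARI", ch, 104L, c(base, 10, 0))
    gl1  <- add("1GL", ch, 105L, c(base + 8, 10, 0))
    cph  <- add("CPH", ch, 106L, c(base + 8, 5, 8))
    link(cdr1, anomeric_c("CDR"), cdr2, first_o("CDR"))
    link(cdr2, anomeric_c("CDR"), eri, first_o("ERI"))
    link(ari, anomeric_c("ARI"), gl1, first_o("1GL"))
    link(cph, first_o("CPH"), cdr1, first_o("CDR"))
    link(cph, anomeric_c("CPH"), ari, first_o("ARI"))
  }
  mg <- add("MG", "G", 201L, c(30, 5, 4))
  link(mg, "MG", 6L, first_o("CPH"), kind = "metal-coordination")

  list(assembly = assembly_structure(instances, sites, links),
       components = comps)
}

#' Synthetic NAD-cofactor entry
#'
#' A dehydrogenase-like assembly carrying `n_nad` copies of NAD and
#' `n_other` copies of a small diol ligand (EDO), with a toy pocket of
#' protein residues around the first NAD. Intended for end-to-end runs of
#' the pipeline with the shipped cofactor classes: NAD classifies as
#' cofactor-like under an oxidoreductase EC annotation, the diol does not.
#'
#' @param n_nad number of NAD instances (default 12).
#' @param n_other number of diol instances (default 6).
#' @param pocket_residues toy pocket size.
#' @return list: `assembly`, `components`, `references` (protein accession,
#'   entry ECs and the shipped cofactor classes).
#' @export
synthetic_cofactor_entry <- function(n_nad = 12, n_other = 6,
                                     pocket_residues = 4) {
  comps <- list(
    NAD = smiles_component(
      "NAD",
      "NC(=O)c1ccc[n+](c1)C1OC(COP(O)(=O)OP(O)(=O)OCC2OC(n3cnc4c(N)ncnc34)C(O)C2O)C(O)C1O",
      501),
    EDO = smiles_component("EDO", "OCCO", 502))
  instances <- NULL; sites <- NULL
  add <- function(comp, chain, resnum, kind, offset, rec = comps[[comp]]) {
    instances <<- rbind(instances, data.frame(
      component_id = comp, chain = chain, resnum = resnum, kind = kind,
      stringsAsFactors = FALSE))
    ii <- nrow(instances)
    sites <<- rbind(sites, data.frame(
      instance = ii, atom_id = rec$mol$atoms$atom_id,
      element = rec$mol$atoms$element,
      x = rec$mol$atoms$x + offset[1], y = rec$mol$atoms$y + offset[2],
      z = rec$mol$atoms$z + offset[3], stringsAsFactors = FALSE))
    ii
  }
  for (i in seq_len(n_nad)) add("NAD", "B", 300L + i, "non-polymer", c(25 * i, 0, 0))
  for (i in seq_len(n_other)) add("EDO", "C", 400L + i, "non-polymer", c(25 * i, 30, 0))
  # toy pocket near the first NAD
  builtin <- builtin_components()
  set.seed(503)
  aa <- sample(c("SER", "ASP", "PHE", "LYS"), pocket_residues, replace = TRUE)
  ctr <- c(25, 0, 0)
  for (r in seq_len(pocket_residues)) {
    rec <- builtin[[aa[r]]]
    v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
    rc <- ctr + stats::runif(1, 4.5, 7) * v
    na <- nrow(rec$mol$atoms)
    mr <- rec$mol
    mr$atoms$x <- rc[1] + stats::rnorm(na); mr$atoms$y <- rc[2] + stats::rnorm(na)
    mr$atoms$z <- rc[3] + stats::rnorm(na)
    add(aa[r], "A", r, "polymer", c(0, 0, 0), rec = component_record(aa[r], mr))
  }
  list(assembly = assembly_structure(instances, sites, NULL),
       components = comps,
       references = list(
         protein_accessions = "P0A9Q7",
         entry_ecs = c("1.2.1.10", "1.1.1.1"),
         cofactor_classes = load_cofactor_classes()))
}
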