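# Built-in component definitions: heavy-atom graphs of the standard amino
# acids (backbone + side chain, side-chain charges at physiological pH) and
# water. Used to type protein atoms for contact detection and to rebuild
# bound-molecule graphs when the caller supplies no dictionary.

aa_def <- function(id, atoms, bonds) {
  # atoms: c("N","CA",...) elements inferred from the first character
  # (OG/OD/OE/OH -> O, ND/NE/NZ/NH -> N, SG/SD -> S, else C); bonds: list of
  # c(a, b, order) triples, order defaults 1; "a:b:2" shorthand not used.
  el <- substr(atoms, 1, 1)
  charge <- integer(length(atoms))
  bdf <- do.call(rbind, lapply(bonds, function(b) {
    data.frame(a1 = match(b[[1]], atoms), a2 = match(b[[2]], atoms),
               order = if (length(b) >= 3) as.integer(b[[3]]) else 1L,
               aromatic = length(b) >= 4 && isTRUE(b[[4]]))
  }))
  list(id = id, atoms = atoms, el = el, bonds = bdf)
}

backbone <- list(c("N", "CA"), c("CA", "C"), c("C", "O", 2))

builtin_component_defs <- local({
  ar <- function(a, b) c(a, b, 1, TRUE)   # aromatic ring bond
  defs <- list(
    aa_def("GLY", c("N", "CA", "C", "O"), backbone),
    aa_def("ALA", c("N", "CA", "C", "O", "CB"), c(backbone, list(c("CA", "CB")))),
    aa_def("VAL", c("N", "CA", "C", "O", "CB", "CG1", "CG2"),
           c(backbone, list(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2")))),
    aa_def("LEU", c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
           c(backbone, list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2")))),
    aa_def("ILE", c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1"),
           c(backbone, list(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2"), c("CG1", "CD1")))),
    aa_def("SER", c("N", "CA", "C", "O", "CB", "OG"),
           c(backbone, list(c("CA", "CB"), c("CB", "OG")))),
    aa_def("THR", c("N", "CA", "C", "O", "CB", "OG1", "CG2"),
           c(backbone, list(c("CA", "CB"), c("CB", "OG1"), c("CB", "CG2")))),
    aa_def("CYS", c("N", "CA", "C", "O", "CB", "SG"),
           c(backbone, list(c("CA", "CB"), c("CB", "SG")))),
    aa_def("MET", c("N", "CA", "C", "O", "CB", "CG", "SD", "CE"),
           c(backbone, list(c("CA", "CB"), c("CB", "CG"), c("CG", "SD"), c("SD", "CE")))),
    aa_def("PRO", c("N", "CA", "C", "O", "CB", "CG", "CD"),
           c(backbone, list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "N")))),
    aa_def("ASP", c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
           c(backbone, list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1", 2), c("CG", "OD2")))),
    aa_def("GLU", c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
           c(backbone, list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                            c("CD", "OE1", 2), c("CD", "OE2")))),
    aa_def("ASN", c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"),
           c(backbone, list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1", 2), c("CG", "ND2")))),
    aa_def("GLN", c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2"),
           c(backbone, list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                            c("CD", "OE1", 2), c("CD", "NE2")))),
    aa_def("LYS", c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
           c(backbone, list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                            c("CD", "CE"), c("CE", "NZ")))),
    aa_def("ARG", c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
           c(backbone, list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                            c("CD", "NE"), c("NE", "CZ"), c("CZ", "NH1", 2),
                            c("CZ", "NH2")))),
    aa_def("PHE", c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
           c(backbone, list(c("CA", "CB"), c("CB", "CG"),
                            ar("CG", "CD1"), ar("CD1", "CE1"), ar("CE1", "CZ"),
                            ar("CZ", "CE2"), ar("CE2", "CD2"), ar("CD2", "CG")))),
    aa_def("TYR", c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
           c(backbone, list(c("CA", "CB"), c("CB", "CG"),
                            ar("CG", "CD1"), ar("CD1", "CE1"), ar("CE1", "CZ"),
                            ar("CZ", "CE2"), ar("CE2", "CD2"), ar("CD2", "CG"),
                            c("CZ", "OH")))),
    aa_def("HIS", c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
           c(backbone, list(c("CA", "CB"), c("CB", "CG"),
                            c("CG", "ND1"), c("ND1", "CE1", 2), c("CE1", "NE2"),
                            c("NE2", "CD2"), c("CD2", "CG", 2)))),
    aa_def("TRP", c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1",
                    "CE2", "CE3", "CZ2", "CZ3", "CH2"),
           c(backbone, list(c("CA", "CB"), c("CB", "CG"),
                            c("CG", "CD1", 2), c("CD1", "NE1"), c("NE1", "CE2"),
                            ar("CE2", "CD2"), c("CD2", "CG"),
                            ar("CD2", "CE3"), ar("CE3", "CZ3"), ar("CZ3", "CH2"),
                            ar("CH2", "CZ2"), ar("CZ2", "CE2"))))
  )
  names(defs) <- vapply(defs, `[[`, "", "id")
  defs
})

# side-chain charges at physiological pH
builtin_charges <- list(
  ASP = c(OD2 = -1L), GLU = c(OE2 = -1L), LYS = c(NZ = 1L), ARG = c(NH2 = 1L))

#' Built-in component records
#'
#' Heavy-atom component definitions for the 20 standard amino acids and
#' water, used for protein-side atom typing and bound-molecule assembly
#' when no external dictionary is supplied.
#' @return named list of `lk_component`.
#' @export
builtin_components <- function() {
  out <- lapply(builtin_component_defs, function(d) {
    charge <- integer(length(d$atoms))
    ch <- builtin_charges[[d$id]]
    if (!is.null(ch)) charge[match(names(ch), d$atoms)] <- ch
    m <- molecule(data.frame(atom_id = d$atoms, element = d$el, charge = charge,
                             stringsAsFactors = FALSE),
                  d$bonds, name = d$id)
    component_record(d$id, m)
  })
  out$HOH <- component_record("HOH", molecule(
    data.frame(atom_id = "O", element = "O", stringsAsFactors = FALSE)))
  out
}
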