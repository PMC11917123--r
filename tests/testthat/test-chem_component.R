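# descriptors, scaffolds, fragmentation, substructure search, depiction

test_that("descriptors carry formula, weight and well-formed identifiers", {
  d <- compute_descriptors(fixture_mol("water"))
  expect_equal(d$formula, "H2O")
  expect_equal(d$weight, 18.015, tolerance = 1e-3)
  expect_equal(d$inchi, "InChI=1S/H2O/h1H2")
  expect_equal(nchar(d$inchikey), 27)
  expect_equal(lengths(regmatches(d$inchikey, gregexpr("-", d$inchikey))), 2,
               ignore_attr = TRUE)
  expect_error(compute_descriptors(molecule(data.frame(element = character()))),
               "empty")
})

test_that("canonical SMILES is invariant under atom relabeling", {
  m <- gen_molecule(21)
  set.seed(9)
  for (k in 1:2) {
    perm <- sample(nrow(m$atoms))
    m2 <- ligandkit:::subset_molecule(m, perm)
    expect_equal(compute_descriptors(m2)$smiles, compute_descriptors(m)$smiles)
  }
})

test_that("InChI of reference molecules matches the frozen external values", {
  # generated once with an independent implementation (RDKit 2024.09)
  expect_equal(compute_descriptors(fixture_mol("benzene"))$inchi,
               "InChI=1S/C6H6/c1-2-4-6-5-3-1/h1-6H")
  expect_equal(compute_descriptors(fixture_mol("isobutane"))$inchi,
               "InChI=1S/C4H10/c1-4(2)3/h4H,1-3H3")
})

test_that("Murcko scaffold keeps rings and linkers, drops side chains", {
  expect_equal(n_atoms(murcko_scaffold(fixture_mol("propane"))), 0)
  bz <- murcko_scaffold(fixture_mol("benzene"))
  expect_equal(sort(bz$atoms$element), rep("C", 6))
  eb <- murcko_scaffold(fixture_mol("ethylbenzene"))
  expect_equal(sort(eb$atoms$element), rep("C", 6))
  expect_equal(nrow(eb$bonds), 6)
})

test_that("Murcko scaffold is idempotent and matches the pruning oracle", {
  for (seed in 1:30) {
    m <- gen_molecule(seed, ring_prob = 0.6)
    s1 <- murcko_scaffold(m)
    expect_identical(sort(murcko_scaffold(s1)$atoms$element),
                     sort(s1$atoms$element), info = paste("seed", seed))
    expect_identical(sort(s1$atoms$element), oracle_scaffold_elements(m),
                     info = paste("seed", seed))
  }
})

test_that("BRICS-style fragmentation cleaves configured environments", {
  expect_length(brics_fragments(fixture_mol("methane")), 1)
  fr <- brics_fragments(fixture_mol("ethyl_phenyl_ether"))
  expect_gte(length(fr), 2)
  has_ring <- vapply(fr, function(f) any(ligandkit:::ring_bonds(f)), TRUE)
  expect_true(any(has_ring))
})

test_that("fragment heavy atoms are conserved (markers aside)", {
  mols <- c(lapply(c(5, 8, 13, 21), gen_molecule),
            list(fixture_mol("ethyl_phenyl_ether"), fixture_mol("toluene")))
  for (m in mols) {
    fr <- brics_fragments(m)
    got <- sort(unname(unlist(lapply(fr, function(f) f$atoms$element))))
    got <- got[got != "*"]
    expect_equal(got, sort(strip_hydrogens(m)$atoms$element))
  }
})

test_that("substructure search returns witnesses and respects bond orders", {
  m <- fixture_mol("ethylbenzene")
  hits <- substructure_search(m, list(m))
  expect_equal(hits$library_index, 1)
  expect_length(hits$mapping[[1]], n_atoms(m))
  expect_equal(nrow(substructure_search(m, list())), 0)
  lib <- list(fixture_mol("benzene"), fixture_mol("cyclohexane"))
  hits <- substructure_search(m, lib)
  expect_equal(hits$library_index, 1)   # aromatic ring matches, saturated no
})

test_that("substructure search agrees with the brute-force oracle", {
  set.seed(3)
  mols <- lapply(1:14, function(s) gen_molecule(s, n_range = c(3, 8)))
  for (i in seq_along(mols)) {
    qs <- sample(seq_along(mols), 3)
    for (j in qs) {
      got <- nrow(substructure_search(mols[[i]], mols[j])) > 0
      expect_equal(got, oracle_has_substructure(mols[[j]], mols[[i]]),
                   info = paste("pattern", j, "target", i))
    }
  }
})

test_that("depiction penalty counts crossings and overlaps exactly", {
  expect_equal(depiction_penalty(fixture_mol("benzene"))$penalty, 0)
  # two bonds forced to cross: X layout
  crossed <- molecule(
    data.frame(element = rep("C", 4),
               x2 = c(0, 1, 0, 1), y2 = c(0, 1, 1, 0)),
    data.frame(a1 = c(1, 3), a2 = c(2, 4)))
  sc <- depiction_penalty(crossed)
  expect_equal(sc$crossings, 1)
  expect_gt(sc$penalty, 0)
  expect_error(depiction_penalty(fixture_mol("cyclohexane")), "2D")
})

test_that("select_depiction picks the argmin, first on ties, scale-invariant", {
  clean <- fixture_mol("benzene")
  crossed <- clean
  crossed$atoms$x2[c(1, 4)] <- crossed$atoms$x2[c(4, 1)]  # scramble the hexagon
  expect_gt(depiction_penalty(crossed)$penalty, 0)
  expect_identical(select_depiction(list(crossed, clean)), clean)
  expect_identical(select_depiction(list(clean, clean, crossed)), clean)
  expect_error(select_depiction(list()), "no depiction")
  scaled <- crossed; scaled$atoms$x2 <- scaled$atoms$x2 * 3
  scaled$atoms$y2 <- scaled$atoms$y2 * 3
  expect_equal(depiction_penalty(scaled)$crossings,
               depiction_penalty(crossed)$crossings)
})
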