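chain_of <- function(n) molecule(data.frame(element = rep("C", n)),
                                 data.frame(a1 = seq_len(n - 1), a2 = 2:n))

test_that("identity pairs score 1 and element-disjoint pairs 0", {
  for (nm in c("benzene", "ethyl_phenyl_ether", "imidazole")) {
    m <- fixture_mol(nm)
    p <- parity_score(m, m)
    expect_equal(p$score, 1.0, info = nm)
    expect_equal(p$matched_atoms, n_atoms(m, heavy = TRUE), info = nm)
  }
  expect_equal(parity_score(fixture_mol("methane"), fixture_mol("water"))$score, 0)
  empty <- molecule(data.frame(element = character()))
  expect_equal(parity_score(empty, fixture_mol("benzene"))$score, 0)
})

test_that("score is exact on nucleotide-like fixtures", {
  adp <- ligandkit:::fixture_nucleotide_like(2)
  atp <- ligandkit:::fixture_nucleotide_like(3)
  expect_lte(n_atoms(atp, heavy = TRUE), 31)
  p <- parity_score(adp, atp)
  expect_false(p$timed_out)
  # the smaller graph embeds completely, so the true MCS size is nA (the
  # hard upper bound min(nA, nB)); verify the returned mapping really is a
  # full common-subgraph witness, independently of the search
  na <- n_atoms(adp, heavy = TRUE); nb <- n_atoms(atp, heavy = TRUE)
  expect_equal(p$matched_atoms, na)
  expect_equal(p$score, na / (na + nb - na))
  mp <- p$mapping
  expect_equal(sort(mp$query), seq_len(na))
  expect_equal(anyDuplicated(mp$target), 0)
  expect_equal(adp$atoms$element[mp$query], atp$atoms$element[mp$target])
  bnd <- function(m) {
    M <- matrix(FALSE, nrow(m$atoms), nrow(m$atoms))
    M[cbind(m$bonds$a1, m$bonds$a2)] <- TRUE
    M | t(M)
  }
  BA <- bnd(adp); BB <- bnd(atp)
  tgt <- integer(na); tgt[mp$query] <- mp$target
  for (i in seq_len(na - 1)) for (j in (i + 1):na) {
    expect_equal(BA[i, j], BB[tgt[i], tgt[j]],
                 info = sprintf("pair %d-%d", i, j))
  }
  # exhaustive oracle agreement on truncated (<= 12-atom) sub-fixtures
  sub_a <- ligandkit:::subset_molecule(adp, 1:10)
  sub_b <- ligandkit:::subset_molecule(atp, 1:12)
  ps <- parity_score(sub_a, sub_b)
  expect_equal(ps$matched_atoms, oracle_mcs_size(sub_a, sub_b))
  expect_equal(ps$score, oracle_parity_score(sub_a, sub_b))
})

test_that("parity agrees with the independent clique oracle on small pairs", {
  mols <- lapply(1:12, function(s) gen_molecule(s, n_range = c(3, 10)))
  for (i in 1:6) {
    for (j in (i + 1):7) {
      p <- parity_score(mols[[i]], mols[[j]])
      expect_equal(p$matched_atoms, oracle_mcs_size(mols[[i]], mols[[j]]),
                   info = paste(i, j))
    }
  }
})

test_that("parity is symmetric and bounded in [0, 1]", {
  set.seed(42)
  mols <- lapply(100 + 1:24, function(s) gen_molecule(s, n_range = c(3, 10)))
  for (k in 1:40) {
    ij <- sample(length(mols), 2)
    p1 <- parity_score(mols[[ij[1]]], mols[[ij[2]]])
    p2 <- parity_score(mols[[ij[2]]], mols[[ij[1]]])
    expect_equal(p1$score, p2$score)
    expect_gte(p1$score, 0); expect_lte(p1$score, 1)
  }
})

test_that("mapping is a valid partial injection respecting elements", {
  a <- gen_molecule(301, n_range = c(6, 10))
  b <- gen_molecule(302, n_range = c(6, 10))
  p <- parity_score(a, b)
  mp <- p$mapping
  expect_equal(nrow(mp), p$matched_atoms)
  expect_false(anyDuplicated(mp$query) > 0)
  expect_false(anyDuplicated(mp$target) > 0)
  ah <- strip_hydrogens(a); bh <- strip_hydrogens(b)
  expect_equal(ah$atoms$element[mp$query], bh$atoms$element[mp$target])
})

test_that("adding atoms to one side never raises the score", {
  base <- fixture_mol("benzene")
  grown <- fixture_mol("toluene")     # benzene + one carbon
  other <- fixture_mol("imidazole")
  s1 <- parity_score(base, other)$score
  s2 <- parity_score(grown, other)$score
  expect_lte(s2, s1 + 1e-12)
})

test_that("budget exhaustion returns best-so-far with timed_out", {
  a <- gen_molecule(401, n_range = c(12, 12))
  b <- gen_molecule(402, n_range = c(12, 12))
  p <- parity_score(a, b, budget = 3)
  expect_true(p$timed_out)
  expect_gte(p$matched_atoms, 0)
  full <- parity_score(a, b)
  expect_lte(p$matched_atoms, full$matched_atoms)
})

test_that("stereoisomer check distinguishes enantiomers from isomers", {
  mk <- function(mirror) molecule(
    data.frame(element = c("C", "F", "Cl", "Br"),
               x = c(0, -0.36, -0.36, -0.54), y = c(0, 1.03, -0.51, -0.61),
               z = c(0, 0, 0.89 * mirror, -1.2 * mirror)),
    data.frame(a1 = 1, a2 = 2:4))
  expect_true(stereoisomer_check(mk(1), mk(-1)))
  expect_false(stereoisomer_check(mk(1), mk(1)))
  expect_false(stereoisomer_check(fixture_mol("butane"), fixture_mol("isobutane")))
})

test_that("related-ligand grouping applies priorities and the 0.6 threshold", {
  query <- fixture_mol("toluene")
  refs <- list(
    list(id = "SELF", mol = fixture_mol("toluene")),
    list(id = "SCAF", mol = fixture_mol("ethylbenzene")),   # same benzene scaffold
    list(id = "SIM", mol = fixture_mol("benzene")),          # 0.857 but also same scaffold
    list(id = "FAR", mol = fixture_mol("propane")))          # score 0
  rep <- related_ligands(query, refs)
  expect_true(all(c("SELF", "SCAF", "SIM") %in% rep$same_scaffold))
  expect_false("FAR" %in% c(rep$same_scaffold, rep$similar$id, rep$stereoisomers))
  # the three groups are disjoint
  all_ids <- c(rep$stereoisomers, rep$same_scaffold, rep$similar$id)
  expect_equal(anyDuplicated(all_ids), 0)
})

test_that("similarity threshold is inclusive at exactly 0.6", {
  # construct scores around the threshold: pentane vs heptane-like chains
  # C5 vs C7 chain: MCS 5 -> 5/(5+7-5) = 0.714; C3 vs C7: 3/7 = 0.429
  c5 <- chain_of(5); c7 <- chain_of(7); c3 <- chain_of(3)
  r <- related_ligands(c7, list(list(id = "C5", mol = c5),
                                list(id = "C3", mol = c3)), t_related = 0.6)
  expect_true("C5" %in% r$similar$id)
  expect_false("C3" %in% r$similar$id)
  # exact boundary: score == t_related is included
  c6 <- chain_of(6)
  r2 <- related_ligands(c6, list(list(id = "C4", mol = chain_of(4))),
                        t_related = 2 / 3)
  expect_true("C4" %in% r2$similar$id)   # 4/(4+6-4) = 2/3 exactly
})

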