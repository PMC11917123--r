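chain_of2 <- function(n) molecule(data.frame(element = rep("C", n)),
                                  data.frame(a1 = seq_len(n - 1), a2 = 2:n))

# tiny molecules with fully controllable similarities
mol_a <- function() fixture_mol("benzene")       # "the ligand"
mol_b <- function() fixture_mol("imidazole")     # dissimilar to benzene (N-ring)

make_class <- function(stage1_pass, stage2_pass, ec) {
  list(name = "X",
       template = if (stage1_pass) mol_a() else mol_b(),
       representative = if (stage2_pass) mol_a() else mol_b(),
       threshold = 0.99,
       ec = ec)
}

test_that("the cofactor decision table covers all eight combinations", {
  for (s1 in c(TRUE, FALSE)) for (s2 in c(TRUE, FALSE)) for (ecm in c(TRUE, FALSE)) {
    cl <- make_class(s1, s2, if (ecm) "1.1.1.-" else "9.9.9.9")
    res <- classify_cofactor(mol_a(), entry_ecs = "1.1.1.1", classes = list(cl))
    expect_equal(res$cofactor_like, s1 && s2 && ecm,
                 info = sprintf("s1=%s s2=%s ec=%s", s1, s2, ecm))
    expect_equal(res$manual_review, s1 && s2 && !ecm,
                 info = sprintf("s1=%s s2=%s ec=%s", s1, s2, ecm))
  }
})

test_that("EC matching is prefix-aware", {
  expect_true(ligandkit:::ec_matches("1.1.1.-", "1.1.1.42"))
  expect_true(ligandkit:::ec_matches("1.1.1", "1.1.1.42"))
  expect_true(ligandkit:::ec_matches("1.6.-.-", "1.6.5.3"))
  expect_false(ligandkit:::ec_matches("1.1.1.-", "1.1.2.1"))
  expect_false(ligandkit:::ec_matches("1.1.1.42", "1.1.1"))
})

test_that("empty class list is simply not-cofactor", {
  res <- classify_cofactor(mol_a(), "1.1.1.1", list())
  expect_false(res$cofactor_like)
  expect_false(res$manual_review)
})

test_that("cofactor evidence is sufficient to recompute the decision", {
  cl <- make_class(TRUE, TRUE, "1.1.1.-")
  res <- classify_cofactor(mol_a(), "1.1.1.1", list(cl))
  ev <- res$evidence
  expect_true(ev$stage1 >= cl$threshold && ev$stage2 >= cl$threshold && ev$ec_match)
  expect_equal(ev$outcome, "cofactor-like")
})

test_that("reactant threshold 0.7 is inclusive; 0.6999 is rejected", {
  # chains give exact rational scores: C7 vs C3 -> 3/7 = 0.4286;
  # identical -> 1.0; boundary probed by adjusting the threshold around a
  # fixed exact score of 0.7 = 7/10 (C7 ligand vs C10 participant)
  c7 <- chain_of2(7); c10 <- chain_of2(10)
  rx <- list(list(id = "R", participants = list(c10), accessions = "P1"))
  t_at <- modifyList(default_rellig_thresholds(), list(t_reactant = 0.7))
  res <- classify_reactant(c7, "P1", rx, t_at)
  expect_equal(res$evidence$score, 0.7)
  expect_true(res$reactant_like)
  # a score of 0.6999 (just under) must be rejected at t = 0.7
  res2 <- classify_reactant(c7, "P1", rx,
                            modifyList(t_at, list(t_reactant = 0.70000001)))
  expect_false(res2$reactant_like)
  # identical participant scores 1.0
  res3 <- classify_reactant(c7, "P1",
                            list(list(id = "R2", participants = list(chain_of2(7)),
                                      accessions = "P1")), t_at)
  expect_true(res3$reactant_like)
  expect_equal(res3$evidence$score, 1.0)
})

test_that("proteins without mapped reactions are never reactant-like", {
  rx <- list(list(id = "R", participants = list(mol_a()), accessions = "P2"))
  expect_false(classify_reactant(mol_a(), "P1", rx)$reactant_like)
})

test_that("raising the reactant threshold never adds annotations", {
  c7 <- chain_of2(7)
  rx <- list(list(id = "R", participants = list(chain_of2(10)), accessions = "P1"))
  ts <- seq(0.3, 1.0, by = 0.1)
  hits <- vapply(ts, function(t) {
    classify_reactant(c7, "P1", rx,
                      modifyList(default_rellig_thresholds(),
                                 list(t_reactant = t)))$reactant_like
  }, TRUE)
  expect_true(all(diff(as.integer(hits)) <= 0))
})

test_that("drug classification is strict target-set membership", {
  tbl <- list(list(drug_id = "STI", targets = c("P1", "P2")))
  expect_true(classify_drug("STI", NULL, "P1", tbl)$drug_like)
  expect_false(classify_drug("STI", NULL, "P9", tbl)$drug_like)
  expect_false(classify_drug("ZZZ", NULL, "P1", tbl)$drug_like)
  # InChIKey route
  ik <- ligandkit:::mol_inchikey(mol_a())
  tbl2 <- list(list(drug_id = "DRG", inchikey = ik, targets = "P1"))
  expect_true(classify_drug("OTHER", mol_a(), "P1", tbl2)$drug_like)
})

test_that("entry annotation unions roles and is idempotent", {
  ne <- synthetic_cofactor_entry(n_nad = 2, n_other = 1, pocket_residues = 2)
  bs <- infer_bound_molecules(ne$assembly, ne$components)
  refs <- ne$references
  refs$drug_table <- list(list(drug_id = "EDO", targets = "P0A9Q7"))
  ann1 <- annotate_entry(bs, refs$protein_accessions, refs$entry_ecs, refs)
  ann2 <- annotate_entry(bs, refs$protein_accessions, refs$entry_ecs, refs)
  expect_equal(as.data.frame(ann1)[1:5], as.data.frame(ann2)[1:5])
  roles <- stats::setNames(ann1$roles, ann1$ligand)
  expect_true(all(roles[names(roles) == "NAD"] == "cofactor-like"))
  expect_true(all(roles[names(roles) == "EDO"] == "drug-like"))
})

test_that("entries with no ligands give an empty annotation table", {
  empty_set <- structure(list(bound = list(), polymer_attached = list()),
                         class = "lk_bound_set")
  ann <- annotate_entry(empty_set, "P1", "1.1.1.1",
                        list(cofactor_classes = list()))
  expect_equal(nrow(ann), 0)
})

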