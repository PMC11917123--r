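fake_contacts <- function(atoms, comps = "ALA", subtypes = "hbond") {
  data.frame(lig_atom = atoms,
             env_comp = rep_len(comps, length(atoms)),
             subtype = rep_len(subtypes, length(atoms)),
             stringsAsFactors = FALSE)
}

test_that("a single contact puts its atom at 100%", {
  ft <- aggregate_atom_frequencies(fake_contacts("C1"))
  expect_equal(unname(ft$atom_pct), 100)
})

test_that("counts 2/1/1 yield 50/25/25", {
  ft <- aggregate_atom_frequencies(fake_contacts(c("a", "a", "b", "c")))
  expect_equal(ft$atom_pct[c("a", "b", "c")], c(a = 50, b = 25, c = 25))
})

test_that("atom percentages always sum to 100; amino-acid columns too", {
  set.seed(77)
  for (k in 1:50) {
    n <- sample(1:40, 1)
    ct <- fake_contacts(sample(letters[1:6], n, replace = TRUE),
                        comps = sample(c("ALA", "SER", "HIS"), n, replace = TRUE),
                        subtypes = sample(c("hbond", "vdw"), n, replace = TRUE))
    ft <- aggregate_atom_frequencies(ct)
    expect_equal(sum(ft$atom_pct), 100, tolerance = 1e-9)
    expect_true(all(abs(colSums(ft$atom_aa_pct) - 100) < 1e-9))
  }
})

test_that("subtype filters restrict before counting; empty filter empties", {
  ct <- rbind(fake_contacts(c("a", "b"), subtypes = "hbond"),
              fake_contacts("c", subtypes = "vdw"))
  ft <- aggregate_atom_frequencies(ct, filter = "hbond")
  expect_equal(sort(names(ft$atom_pct)), c("a", "b"))
  expect_equal(sum(ft$atom_pct), 100)
  ft0 <- aggregate_atom_frequencies(ct, filter = "halogen")
  expect_length(ft0$atom_pct, 0)
})

test_that("aggregation over merged entries equals aggregating the merge", {
  a <- fake_contacts(c("a", "a", "b"))
  b <- fake_contacts(c("b", "c"), comps = "SER")
  direct <- aggregate_atom_frequencies(rbind(a, b))
  expect_equal(direct$counts[c("a", "b", "c")], c(a = 2L, b = 2L, c = 1L))
  expect_equal(sum(direct$atom_pct), 100)
})

test_that("Z-score outliers use strict |Z| > 2.0", {
  gr <- geometry_flags(zscores = list(bonds = c(0, 1.5, 2.0, -2.0, 2.01, -2.5)))
  expect_equal(gr$outliers$bonds, c(5L, 6L))
  expect_equal(gr$rmsz$bonds, sqrt(mean(c(0, 1.5, 2.0, 2.0, 2.01, 2.5)^2)))
  clean <- geometry_flags(zscores = list(bonds = rep(0, 4)))
  expect_equal(clean$rmsz$bonds, 0)
  expect_length(clean$outliers$bonds, 0)
  expect_true(is.na(geometry_flags(zscores = list(bonds = numeric()))$rmsz$bonds))
})

test_that("torsion and ring flags use strict boundaries", {
  gr <- geometry_flags(torsion_densities = c(4.9, 5.0, 5.1),
                       ring_rmsds = c(59, 60, 61))
  expect_equal(gr$torsion_flags, 1L)
  expect_equal(gr$ring_flags, 3L)
})

test_that("geometry flagging is monotone in added Z values", {
  z <- c(0.5, 1.0, 2.5)
  n1 <- length(geometry_flags(zscores = list(b = z))$outliers$b)
  n2 <- length(geometry_flags(zscores = list(b = c(z, 3.0)))$outliers$b)
  expect_gte(n2, n1)
})

test_that("density fit flags follow the strict RSCC/RSR boundaries", {
  expect_true(density_flags(0.79, 0.2)$flagged)
  expect_false(density_flags(0.80, 0.2)$flagged)
  expect_true(density_flags(0.9, 0.41)$flagged)
  expect_false(density_flags(0.9, 0.40)$flagged)
  expect_false(density_flags(0.8, 0.4)$flagged)
  expect_error(density_flags(1.2, 0.2), "RSCC")
})
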