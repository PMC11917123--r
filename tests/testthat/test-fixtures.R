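test_that("generators are deterministic per seed", {
  expect_identical(gen_molecule(99), gen_molecule(99))
  g1 <- gen_assembly(12); g2 <- gen_assembly(12)
  expect_identical(g1$assembly$sites, g2$assembly$sites)
  expect_identical(g1$partition, g2$partition)
  expect_error(gen_molecule(1, n_range = c(0, 0)), "size range")
})

test_that("generated molecules are valence-correct by construction", {
  for (seed in 1:60) {
    s <- sanitize(gen_molecule(seed))
    expect_equal(nrow(s$report$actions), 0, info = paste("seed", seed))
  }
})

test_that("generated molecule sizes respect the requested range", {
  for (seed in 1:20) {
    n <- n_atoms(gen_molecule(seed, n_range = c(5, 9)))
    expect_gte(n, 5); expect_lte(n, 9)
  }
})

test_that("chain topologies give the expected partition counts", {
  # k components joined by a chain of k-1 covalent links -> one molecule
  k <- 4
  ga <- gen_assembly(201, n_nonpoly = k, n_covalent = 0, n_metal = 0)
  a <- ga$assembly
  for (i in seq_len(k - 1)) {
    i1 <- ga$ligand_instances[i]; i2 <- ga$ligand_instances[i + 1]
    a$links <- rbind(a$links, data.frame(
      inst1 = i1, atom1 = a$sites$atom_id[a$sites$instance == i1][1],
      inst2 = i2, atom2 = a$sites$atom_id[a$sites$instance == i2][1],
      kind = "covalent"))
  }
  bs <- infer_bound_molecules(a, ga$components)
  expect_length(bs$bound, 1)
  expect_length(bs$bound[[1]]$instances, k)
  # zero links -> k molecules
  bs0 <- infer_bound_molecules(ga$assembly, ga$components)
  expect_length(bs0$bound, k)
})

test_that("the pipeline runs end-to-end and reproduces byte-identical JSON", {
  ga <- gen_assembly(77, n_nonpoly = 3, n_covalent = 1, n_metal = 1)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  run_pipeline(ga$assembly, ga$components, out = f1)
  run_pipeline(ga$assembly, ga$components, out = f2)
  expect_identical(readLines(f1), readLines(f2))
  rep <- jsonlite::fromJSON(f1, simplifyVector = FALSE)
  expect_gte(length(rep$bound_molecules), 1)
  expect_true(all(vapply(rep$bound_molecules,
                         function(b) nzchar(b$identifier), TRUE)))
})

test_that("pipeline stage errors carry the stage name", {
  bad <- tempfile(fileext = ".cif")
  writeLines("data_x\n_cell.length_a 1.0", bad)
  expect_error(run_pipeline(bad), "stage 'read'")
})

test_that("pipeline matches composed per-stage results", {
  ga <- gen_assembly(78, n_nonpoly = 2, n_covalent = 1, n_metal = 0)
  rep <- run_pipeline(ga$assembly, ga$components)
  bs <- infer_bound_molecules(ga$assembly,
                              lapply(ga$components, function(r) {
                                component_record(r$component_id,
                                                 sanitize(r$mol)$mol, r$name)
                              }))
  expect_equal(length(rep$bound_molecules), length(bs$bound))
  expect_equal(lapply(rep$bound_molecules, function(b) unlist(b$components)),
               lapply(bs$bound, `[[`, "component_multiset"),
               ignore_attr = TRUE)
})
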