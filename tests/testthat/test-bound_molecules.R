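test_that("unlinked instances each form their own bound molecule", {
  ga <- gen_assembly(11, n_nonpoly = 3, n_covalent = 0, n_metal = 0)
  bs <- infer_bound_molecules(ga$assembly, ga$components)
  expect_length(bs$bound, 3)
  expect_true(all(lengths(lapply(bs$bound, `[[`, "instances")) == 1))
  expect_equal(vapply(bs$bound, `[[`, "", "bmID"), paste0("bm", 1:3))
})

test_that("Chromomycin-like entry unifies six components, Mg stays apart", {
  ce <- synthetic_chromomycin_entry()
  bs <- infer_bound_molecules(ce$assembly, ce$components)
  sizes <- sort(lengths(lapply(bs$bound, `[[`, "instances")))
  expect_equal(sizes, c(1, 6, 6))
  big <- bs$bound[lengths(lapply(bs$bound, `[[`, "instances")) == 6]
  for (bm in big) {
    expect_equal(bm$component_multiset,
                 sort(c("1GL", "ARI", "CPH", "CDR", "CDR", "ERI")))
  }
  mg <- bs$bound[lengths(lapply(bs$bound, `[[`, "instances")) == 1][[1]]
  expect_equal(mg$component_multiset, "MG")
})

test_that("inference matches the union-find oracle across seeds", {
  for (seed in 1:20) {
    ga <- gen_assembly(seed, n_nonpoly = sample(2:6, 1),
                       n_covalent = sample(0:4, 1), n_metal = sample(0:2, 1))
    bs <- infer_bound_molecules(ga$assembly, ga$components)
    got <- partition_key(c(lapply(bs$bound, `[[`, "instances"),
                           lapply(bs$polymer_attached, `[[`, "instances")))
    expect_equal(got, partition_key(oracle_partition(ga$assembly)),
                 info = paste("seed", seed, "(oracle)"))
    expect_equal(got, partition_key(ga$partition),
                 info = paste("seed", seed, "(generator truth)"))
  }
})

test_that("metal links never merge; adding a covalent link merges exactly two", {
  ga <- gen_assembly(31, n_nonpoly = 4, n_covalent = 0, n_metal = 2)
  bs0 <- infer_bound_molecules(ga$assembly, ga$components)
  n0 <- length(bs0$bound)
  # every molecule is a singleton despite the metal-coordination links
  expect_true(all(lengths(lapply(bs0$bound, `[[`, "instances")) == 1))
  # add one covalent link between the first two ligand instances
  a <- ga$assembly
  i1 <- ga$ligand_instances[1]; i2 <- ga$ligand_instances[2]
  at1 <- a$sites$atom_id[a$sites$instance == i1][1]
  at2 <- a$sites$atom_id[a$sites$instance == i2][1]
  a$links <- rbind(a$links, data.frame(inst1 = i1, atom1 = at1,
                                       inst2 = i2, atom2 = at2,
                                       kind = "covalent"))
  bs1 <- infer_bound_molecules(a, ga$components)
  expect_equal(length(bs1$bound), n0 - 1)
  merged <- Filter(function(b) length(b$instances) == 2, bs1$bound)
  expect_length(merged, 1)
  expect_setequal(merged[[1]]$instances, c(i1, i2))
})

test_that("every non-polymer, non-water instance lands in exactly one molecule", {
  for (seed in c(3, 17, 29)) {
    ga <- gen_assembly(seed, n_nonpoly = 5, n_covalent = 3, n_metal = 1)
    bs <- infer_bound_molecules(ga$assembly, ga$components)
    inst <- unlist(c(lapply(bs$bound, `[[`, "instances"),
                     lapply(bs$polymer_attached, `[[`, "instances")))
    nonpoly <- which(ga$assembly$instances$kind == "non-polymer")
    expect_setequal(inst, nonpoly)
    expect_equal(anyDuplicated(inst), 0)
  }
})

test_that("components covalently bound to the polymer are flagged", {
  ga <- gen_assembly(41, n_nonpoly = 2, n_covalent = 0, n_metal = 0)
  a <- ga$assembly
  poly <- which(a$instances$kind == "polymer")[1]
  lig <- ga$ligand_instances[1]
  a$links <- rbind(a$links, data.frame(
    inst1 = lig, atom1 = a$sites$atom_id[a$sites$instance == lig][1],
    inst2 = poly, atom2 = a$sites$atom_id[a$sites$instance == poly][1],
    kind = "covalent"))
  bs <- infer_bound_molecules(a, ga$components)
  expect_length(bs$polymer_attached, 1)
  expect_true(bs$polymer_attached[[1]]$polymer_attached)
  expect_equal(bs$polymer_attached[[1]]$instances, lig)
  expect_length(bs$bound, 1)
})

test_that("identifier assignment: CCD for singletons, PRD precedence, CLC mint", {
  ga <- gen_assembly(51, n_nonpoly = 4, n_covalent = 2, n_metal = 0)
  bs <- infer_bound_molecules(ga$assembly, ga$components)
  reg <- clc_registry()
  singles <- Filter(function(b) length(b$instances) == 1, bs$bound)
  for (b in singles) {
    expect_equal(assign_identifier(b, reg), b$component_multiset)
  }
  multi <- Filter(function(b) length(b$instances) > 1, bs$bound)
  if (length(multi)) {
    key <- paste(sort(multi[[1]]$component_multiset), collapse = "+")
    prd <- stats::setNames("PRD_000123", key)
    expect_equal(assign_identifier(multi[[1]], reg, prd), "PRD_000123")
    id1 <- assign_identifier(multi[[1]], reg)
    expect_match(id1, "^CLC_\\d{6}$")
    expect_equal(assign_identifier(multi[[1]], reg), id1)  # stable lookup
  }
})

test_that("fresh registry mints sequential zero-padded ordinals", {
  reg <- clc_registry()
  id1 <- ligandkit:::registry_lookup(reg, "AAAAAAAAAAAAAA-AAAAAAAAAA-N")
  id2 <- ligandkit:::registry_lookup(reg, "BBBBBBBBBBBBBB-BBBBBBBBBB-N")
  expect_equal(id1, "CLC_000001")
  expect_equal(id2, "CLC_000002")
  expect_equal(ligandkit:::registry_lookup(reg, "AAAAAAAAAAAAAA-AAAAAAAAAA-N"),
               "CLC_000001")
})

test_that("registry save/load preserves all assignments", {
  reg <- clc_registry()
  ligandkit:::registry_lookup(reg, "AAAAAAAAAAAAAA-AAAAAAAAAA-N")
  ligandkit:::registry_lookup(reg, "BBBBBBBBBBBBBB-BBBBBBBBBB-N")
  f <- tempfile(fileext = ".json")
  save_registry(reg, f)
  reg2 <- load_registry(f)
  expect_equal(reg2$map, reg$map)
  expect_equal(reg2$next_ordinal, reg$next_ordinal)
  expect_equal(ligandkit:::registry_lookup(reg2, "CCCCCCCCCCCCCC-CCCCCCCCCC-N"),
               "CLC_000003")
})
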