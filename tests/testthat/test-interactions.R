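# helpers to build tiny hand-positioned scenes ------------------------------

scene <- function(lig_atoms, env_comp, env_atoms, links = NULL,
                  env_kind = "polymer") {
  # lig_atoms/env_atoms: data.frame(atom_id, element, x, y, z)
  instances <- data.frame(
    component_id = c("LIG", env_comp), chain = c("B", "A"),
    resnum = c(101L, 1L), kind = c("non-polymer", env_kind))
  sites <- rbind(cbind(instance = 1L, lig_atoms),
                 cbind(instance = 2L, env_atoms))
  assembly_structure(instances, sites, links)
}

lig_component <- function(mol) list(LIG = component_record("LIG", mol))

test_that("atoms far apart yield no contacts", {
  lig <- data.frame(atom_id = "C1", element = "C", x = 0, y = 0, z = 0)
  env <- data.frame(atom_id = "CA", element = "C", x = 10, y = 0, z = 0)
  a <- scene(lig, "GLY", env)
  bm <- infer_bound_molecules(a)$bound[[1]]
  ct <- compute_contacts(a, bm, mode = "distance")
  expect_equal(nrow(ct), 0)
})

test_that("constructed N-H...O=C geometry is a hydrogen bond", {
  # ligand N at origin with an H pointing at the acceptor; carbonyl O at 2.9 A
  lig <- data.frame(atom_id = c("N1", "C2"), element = c("N", "C"),
                    x = c(0, -1.4), y = 0, z = 0)
  lig_mol <- molecule(data.frame(atom_id = c("N1", "C2"),
                                 element = c("N", "C")),
                      data.frame(a1 = 1, a2 = 2))
  env <- data.frame(atom_id = c("O", "C"), element = c("O", "C"),
                    x = c(2.9, 3.8), y = c(0, 0.9), z = 0)
  a <- scene(lig, "GLY", env)
  a <- add_polar_hydrogens(a, lig_component(lig_mol))
  bm <- infer_bound_molecules(a, lig_component(lig_mol))$bound[[1]]
  ct <- compute_contacts(a, bm, components = lig_component(lig_mol))
  hb <- ct[ct$subtype == "hbond", ]
  expect_equal(nrow(hb), 1)
  expect_equal(hb$lig_atom, "N1")
  expect_equal(hb$env_atom, "O")
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
  expect_gte(hb$angle, 120)
  # vdw/proximal multiplicity is allowed alongside
  expect_true(any(ct$subtype %in% c("vdw", "proximal")))
})

test_that("two parallel stacked rings classify as pi-pi-FF", {
  bz <- fixture_mol("benzene")
  lig <- data.frame(atom_id = paste0("C", 1:6), element = "C",
                    x = bz$atoms$x, y = bz$atoms$y, z = 0)
  env <- data.frame(atom_id = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                    element = "C", x = bz$atoms$x, y = bz$atoms$y, z = 3.8)
  lig_mol <- molecule(data.frame(atom_id = paste0("C", 1:6), element = "C"),
                      bz$bonds)
  a <- scene(lig, "PHE", env)
  # restrict to a PHE ring-only component record so planes are detected
  bm <- infer_bound_molecules(a, lig_component(lig_mol))$bound[[1]]
  ct <- compute_contacts(a, bm, components = lig_component(lig_mol),
                         mode = "distance")
  pp <- ct[ct$category == "plane-plane", ]
  expect_gte(nrow(pp), 1)
  expect_true(all(pp$subtype == "pi-pi-FF"))
  expect_equal(pp$distance[1], 3.8, tolerance = 1e-6)
})

test_that("ring planes require planarity: benzene yes, chair no", {
  bz <- fixture_mol("benzene")
  pl <- detect_ring_planes(cbind(bz$atoms$x, bz$atoms$y, bz$atoms$z), bz)
  expect_length(pl, 1)
  expect_lt(pl[[1]]$rmsd, 1e-6)
  expect_equal(sqrt(sum(pl[[1]]$normal^2)), 1, tolerance = 1e-9)
  ch <- fixture_mol("cyclohexane")
  expect_length(detect_ring_planes(cbind(ch$atoms$x, ch$atoms$y, ch$atoms$z), ch), 0)
  im <- fixture_mol("imidazole")
  expect_length(detect_ring_planes(cbind(im$atoms$x, im$atoms$y, im$atoms$z), im), 1)
})

test_that("polar-hydrogen placement is selective, geometric and idempotent", {
  # serine-like hydroxyl gets exactly one H at the O-H bond length;
  # the backbone carbonyl O (acceptor, no implicit H) gets none
  ga <- gen_assembly(13, n_nonpoly = 1, n_covalent = 0, n_metal = 0,
                     pocket_residues = 3)
  a1 <- add_polar_hydrogens(ga$assembly, ga$components)
  s <- a1$sites
  ser_o <- which(s$atom_id == "OG")
  if (length(ser_o)) {
    h <- s[s$element == "H" & !is.na(s$parent) & s$parent == "OG", ]
    expect_equal(nrow(h), length(ser_o))
    d <- sqrt((h$x[1] - s$x[ser_o[1]])^2 + (h$y[1] - s$y[ser_o[1]])^2 +
                (h$z[1] - s$z[ser_o[1]])^2)
    expect_equal(d, 0.96, tolerance = 1e-9)
  }
  carbonyl_o <- which(s$atom_id == "O" & s$element == "O")
  expect_false(any(!is.na(s$parent) & s$parent == "O"))
  expect_true(length(carbonyl_o) > 0)
  a2 <- add_polar_hydrogens(a1, ga$components)
  expect_equal(nrow(a2$sites), nrow(a1$sites))
})

test_that("angle mode requires hydrogens", {
  lig <- data.frame(atom_id = "C1", element = "C", x = 0, y = 0, z = 0)
  env <- data.frame(atom_id = "CA", element = "C", x = 4, y = 0, z = 0)
  a <- scene(lig, "GLY", env)
  bm <- infer_bound_molecules(a)$bound[[1]]
  expect_error(compute_contacts(a, bm, mode = "angles"), "hydrogens")
})

test_that("contacts match the brute-force all-pairs oracle on random scenes", {
  rules <- default_interaction_rules()
  for (seed in c(2, 9, 23, 37)) {
    ga <- gen_assembly(seed, n_nonpoly = 3, n_covalent = 1, n_metal = 1,
                       pocket_residues = 6)
    bs <- infer_bound_molecules(ga$assembly, ga$components)
    for (bm in bs$bound) {
      got <- compute_contacts(ga$assembly, bm, rules, ga$components,
                              mode = "distance")
      got_aa <- got[got$category == "atom-atom", ]
      want <- oracle_atom_contacts(ga$assembly, bm, rules, ga$components)
      got_key <- sort(paste(got_aa$lig_instance, got_aa$lig_atom,
                            got_aa$env_atom, got_aa$subtype))
      want_key <- sort(paste(want$lig_instance, want$lig_atom,
                             want$env_atom, want$subtype))
      expect_equal(got_key, want_key,
                   info = paste("seed", seed, bm$bmID))
    }
  }
})

test_that("enlarging a distance cutoff never removes contacts of that subtype", {
  ga <- gen_assembly(5, n_nonpoly = 2, n_covalent = 0, n_metal = 0,
                     pocket_residues = 6)
  bm <- infer_bound_molecules(ga$assembly, ga$components)$bound[[1]]
  r1 <- default_interaction_rules()
  r2 <- r1; r2$hydrophobic_dist_max <- r1$hydrophobic_dist_max + 1
  c1 <- compute_contacts(ga$assembly, bm, r1, ga$components, mode = "distance")
  c2 <- compute_contacts(ga$assembly, bm, r2, ga$components, mode = "distance")
  k1 <- with(c1[c1$subtype == "hydrophobic", ],
             paste(lig_atom, env_chain, env_resnum, env_atom))
  k2 <- with(c2[c2$subtype == "hydrophobic", ],
             paste(lig_atom, env_chain, env_resnum, env_atom))
  expect_true(all(k1 %in% k2))
})

test_that("interaction report accounts for every contact and round-trips", {
  ga <- gen_assembly(19, n_nonpoly = 2, n_covalent = 1, n_metal = 0)
  bs <- infer_bound_molecules(ga$assembly, ga$components)
  rep <- interactions_report(ga$assembly, bs, components = ga$components,
                             mode = "distance")
  for (bm in bs$bound) {
    ct <- compute_contacts(ga$assembly, bm, components = ga$components,
                           mode = "distance")
    expect_equal(rep[[bm$bmID]]$n_contacts, nrow(ct))
    expect_equal(sum(lengths(rep[[bm$bmID]]$atoms)), nrow(ct))
  }
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(rep, f, auto_unbox = TRUE, digits = NA)
  rep2 <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(names(rep2), names(rep))
  expect_equal(rep2[[1]]$n_contacts, rep[[1]]$n_contacts)
})

test_that("empty-ligand entries give an empty report", {
  ga <- gen_assembly(8, n_nonpoly = 2, n_covalent = 0, n_metal = 0)
  empty_set <- structure(list(bound = list(), polymer_attached = list()),
                         class = "lk_bound_set")
  expect_length(interactions_report(ga$assembly, empty_set), 0)
})
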