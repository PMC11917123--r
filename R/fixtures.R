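# Deterministic synthetic fixtures: named reference molecules with known
# properties, a random valence-correct molecule generator, and a random
# assembly generator that returns its own ground-truth bound-molecule
# partition. Everything is seeded; identical seeds give identical objects.

#' Named fixture molecules
#'
#' Small reference molecules used throughout the documentation and tests:
#' `water`, `methane`, `propane`, `butane`, `isobutane`, `benzene` (with a
#' clean hexagonal 2D/3D layout), `toluene`, `ethylbenzene`,
#' `ethyl_phenyl_ether`, `cyclohexane` (3D chair), `imidazole` (planar) and
#' `ammonium_n` (a nitrogen drawn with four single bonds and no charge).
#'
#' @param name fixture name.
#' @return an `lk_mol`.
#' @export
fixture_mol <- function(name) {
  hex <- function(r = 1.39) {
    th <- pi / 3 * (0:5) + pi / 6
    cbind(r * cos(th), r * sin(th))
  }
  aromatic_ring_bonds <- data.frame(a1 = 1:6, a2 = c(2:6, 1),
                                    order = c(2L, 1L, 2L, 1L, 2L, 1L),
                                    aromatic = TRUE)
  switch(name,
    water = molecule(data.frame(element = c("O", "H", "H"),
                                x = c(0, 0.96, -0.24), y = c(0, 0, 0.93),
                                z = 0),
                     data.frame(a1 = c(1, 1), a2 = c(2, 3)), name = "water"),
    methane = molecule(data.frame(element = "C", x = 0, y = 0, z = 0), name = "methane"),
    propane = chain_alkane(3, "propane"),
    butane = chain_alkane(4, "butane"),
    isobutane = molecule(data.frame(element = rep("C", 4),
                                    x = c(0, 1.5, -0.75, -0.75),
                                    y = c(0, 0, 1.3, -1.3), z = 0),
                         data.frame(a1 = 1, a2 = 2:4), name = "isobutane"),
    benzene = {
      p <- hex()
      molecule(data.frame(element = rep("C", 6), x = p[, 1], y = p[, 2], z = 0,
                          x2 = p[, 1], y2 = p[, 2]),
               aromatic_ring_bonds, name = "benzene")
    },
    toluene = {
      p <- hex()
      molecule(data.frame(element = rep("C", 7),
                          x = c(p[, 1], 2.85 * cos(pi / 6)),
                          y = c(p[, 2], 2.85 * sin(pi / 6)), z = 0,
                          x2 = c(p[, 1], 2.85 * cos(pi / 6)),
                          y2 = c(p[, 2], 2.85 * sin(pi / 6))),
               rbind(aromatic_ring_bonds,
                     data.frame(a1 = 1, a2 = 7, order = 1L, aromatic = FALSE)),
               name = "toluene")
    },
    ethylbenzene = {
      p <- hex()
      molecule(data.frame(element = rep("C", 8),
                          x = c(p[, 1], 2.85 * cos(pi / 6), 4.0 * cos(pi / 6)),
                          y = c(p[, 2], 2.85 * sin(pi / 6), 4.2 * sin(pi / 6)),
                          z = 0),
               rbind(aromatic_ring_bonds,
                     data.frame(a1 = c(1, 7), a2 = c(7, 8), order = 1L,
                                aromatic = FALSE)),
               name = "ethylbenzene")
    },
    ethyl_phenyl_ether = {
      p <- hex()
      molecule(data.frame(element = c(rep("C", 6), "O", "C", "C"),
                          x = c(p[, 1], 2.8, 4.2, 5.5),
                          y = c(p[, 2], 1.5, 1.6, 2.4), z = 0),
               rbind(aromatic_ring_bonds,
                     data.frame(a1 = c(1, 7, 8), a2 = c(7, 8, 9), order = 1L,
                                aromatic = FALSE)),
               name = "ethyl_phenyl_ether")
    },
    cyclohexane = {
      th <- pi / 3 * (0:5)
      molecule(data.frame(element = rep("C", 6),
                          x = 1.25 * cos(th), y = 1.25 * sin(th),
                          z = 0.25 * (-1)^(0:5)),
               data.frame(a1 = 1:6, a2 = c(2:6, 1)), name = "cyclohexane")
    },
    imidazole = {
      th <- 2 * pi / 5 * (0:4) + pi / 2
      molecule(data.frame(element = c("N", "C", "N", "C", "C"),
                          x = 1.17 * cos(th), y = 1.17 * sin(th), z = 0),
               data.frame(a1 = 1:5, a2 = c(2:5, 1),
                          order = c(2L, 1L, 1L, 2L, 1L)), name = "imidazole")
    },
    ammonium_n = molecule(data.frame(element = c("N", "C", "C", "C", "C")),
                          data.frame(a1 = 1, a2 = 2:5), name = "ammonium_n"),
    stop("unknown fixture molecule: ", name))
}

chain_alkane <- function(n, name) {
  molecule(data.frame(element = rep("C", n), x = 1.5 * seq_len(n) * 0.87,
                      y = rep(c(0, 0.5), length.out = n), z = 0),
           data.frame(a1 = seq_len(n - 1), a2 = 2:n), name = name)
}

# toy ADP/ATP-like graphs: a purine-like bicycle, a five-ring, and a chain
# of 2 (resp. 3) phosphate-like units. Small enough for exhaustive
# common-substructure enumeration, large enough to exercise the search.
fixture_nucleotide_like <- function(n_phosphates) {
  atoms <- data.frame(element = c("N", "C", "N", "C", "C",      # 5-ring part
                                  "C", "N", "C", "N", "C",      # 6-ring part
                                  "O", "C", "C", "C"),          # sugar-ish link
                      stringsAsFactors = FALSE)
  bonds <- data.frame(
    a1 = c(1, 2, 3, 4, 5, 5, 6, 7, 8, 9, 10, 1, 11, 12, 13),
    a2 = c(2, 3, 4, 5, 1, 6, 7, 8, 9, 10, 4, 11, 12, 13, 14),
    order = c(1L, 2L, 1L, 2L, 1L, 1L, 2L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L))
  np <- nrow(atoms)
  for (k in seq_len(n_phosphates)) {
    # each unit: P with two terminal O and one bridging O
    atoms <- rbind(atoms, data.frame(element = c("P", "O", "O", "O")))
    p <- np + 1; o1 <- np + 2; o2 <- np + 3; ob <- np + 4
    prev <- if (k == 1) 14L else np  # previous bridging O (or chain C)
    bonds <- rbind(bonds, data.frame(a1 = c(prev, p, p, p),
                                     a2 = c(p, o1, o2, ob),
                                     order = c(1L, 2L, 1L, 1L)))
    np <- np + 4L
  }
  molecule(atoms, bonds, name = sprintf("nucleotide_like_%dP", n_phosphates))
}

#' Generate a random valence-correct molecule
#'
#' Builds a random spanning tree over `n` heavy atoms (elements drawn from
#' the palette), optionally closes rings, and raises bond orders only where
#' both endpoints have spare valence, so the result sanitizes with an empty
#' report by construction. Atoms receive rough 3D coordinates (random-walk
#' embedding with ~1.5 A bonds). Deterministic per seed.
#'
#' @param seed integer seed.
#' @param n_range inclusive heavy-atom count range.
#' @param ring_prob probability of attempting one extra ring closure.
#' @param elements element palette.
#' @param element_probs sampling weights.
#' @return an `lk_mol` with atom_ids `A1..An`.
#' @export
gen_molecule <- function(seed, n_range = c(4, 12), ring_prob = 0.3,
                         elements = c("C", "N", "O", "S"),
                         element_probs = c(0.65, 0.15, 0.15, 0.05)) {
  if (n_range[1] < 1) stop("molecule size range must start at 1")
  set.seed(seed)
  n <- if (n_range[1] == n_range[2]) n_range[1] else
    sample(n_range[1]:n_range[2], 1)
  el <- sample(elements, n, replace = TRUE, prob = element_probs)
  cap <- vapply(el, function(e) max(allowed_valences(default_valence_table(), e, 0L)), 0L)
  used <- integer(n)
  bonds <- NULL
  if (n > 1) {
    for (i in 2:n) {
      open <- which(used[seq_len(i - 1)] < cap[seq_len(i - 1)])
      if (!length(open)) open <- seq_len(i - 1)  # fall back (H-poor palettes)
      parent <- if (length(open) == 1) open else sample(open, 1)
      bonds <- rbind(bonds, data.frame(a1 = parent, a2 = i, order = 1L))
      used[parent] <- used[parent] + 1L; used[i] <- used[i] + 1L
    }
  }
  # optional ring closure between non-adjacent atoms with spare valence
  if (n >= 4 && stats::runif(1) < ring_prob) {
    spare <- which(used < cap)
    if (length(spare) >= 2) {
      cand <- utils::combn(spare, 2)
      adj <- paste(bonds$a1, bonds$a2)
      ok <- !(paste(cand[1, ], cand[2, ]) %in% adj)
      if (any(ok)) {
        pick <- which(ok)[sample(sum(ok), 1)]
        i <- cand[1, pick]; j <- cand[2, pick]
        bonds <- rbind(bonds, data.frame(a1 = i, a2 = j, order = 1L))
        used[i] <- used[i] + 1L; used[j] <- used[j] + 1L
      }
    }
  }
  # raise some bond orders within remaining valence
  if (!is.null(bonds)) {
    for (k in sample(nrow(bonds))) {
      i <- bonds$a1[k]; j <- bonds$a2[k]
      if (used[i] < cap[i] && used[j] < cap[j] && stats::runif(1) < 0.3) {
        bonds$order[k] <- bonds$order[k] + 1L
        used[i] <- used[i] + 1L; used[j] <- used[j] + 1L
      }
    }
  }
  # random-walk embedding
  pos <- matrix(0, n, 3)
  if (n > 1) {
    for (i in 2:n) {
      parent <- bonds$a1[bonds$a2 == i][1]
      repeat {
        v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
        p <- pos[parent, ] + 1.5 * v
        if (all(rowSums((pos[seq_len(i - 1), , drop = FALSE] -
                           matrix(p, i - 1, 3, byrow = TRUE))^2) > 0.81)) break
      }
      pos[i, ] <- p
    }
  }
  molecule(data.frame(atom_id = paste0("A", seq_len(n)), element = el,
                      x = pos[, 1], y = pos[, 2], z = pos[, 3]),
           bonds, name = sprintf("gen%d", seed))
}

#' Generate a random assembly with known bound-molecule partition
#'
#' Places randomly generated non-polymer components in space, adds declared
#' covalent and metal-coordination links, surrounds the first ligand with a
#' toy protein pocket, and returns the ground-truth partition of instances
#' into bound molecules (computed by an independent union-find over the
#' covalent links), for oracle tests of the inference step.
#'
#' @param seed integer seed.
#' @param n_nonpoly number of non-polymer component instances.
#' @param n_covalent number of covalent links drawn between random instance
#'   pairs.
#' @param n_metal number of metal ions, each coordinated (not covalently
#'   bonded) to a random instance.
#' @param pocket_residues number of toy protein residues around ligand 1.
#' @param mol_size heavy-atom range for generated components.
#' @return list: `assembly` (`lk_assembly`), `components` (named list of
#'   `lk_component`), `partition` (list of instance-index vectors, the
#'   ground truth), `ligand_instances` (indices of non-polymer instances).
#' @export
gen_assembly <- function(seed, n_nonpoly = 4, n_covalent = 2, n_metal = 1,
                         pocket_residues = 5, mol_size = c(4, 10)) {
  set.seed(seed)
  n_comp <- max(2L, ceiling(n_nonpoly * 0.7))
  comps <- list()
  # sub-seeds stay below .Machine$integer.max for any integer seed
  sub_seed <- (as.numeric(seed) %% 1000000) * 1000
  for (k in seq_len(n_comp)) {
    comps[[sprintf("LG%d", k)]] <- component_record(
      sprintf("LG%d", k),
      gen_molecule(sub_seed + k, n_range = mol_size))
  }
  set.seed(seed)  # component identities drawn from the caller's seed stream
  comp_of_inst <- sample(names(comps), n_nonpoly, replace = TRUE)

  instances <- NULL; sites <- NULL
  aa_pool <- c("ALA", "SER", "ASP", "LYS", "PHE", "GLY", "THR", "ASN", "LEU", "ARG")
  aa <- sample(aa_pool, pocket_residues, replace = TRUE)
  builtin <- builtin_components()

  add_instance <- function(component_id, chain, resnum, kind, atom_ids, els, xyz) {
    instances <<- rbind(instances, data.frame(
      component_id = component_id, chain = chain, resnum = resnum,
      kind = kind, stringsAsFactors = FALSE))
    ii <- nrow(instances)
    sites <<- rbind(sites, data.frame(
      instance = ii, atom_id = atom_ids, element = els,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
    ii
  }

  # ligands on chain B, spaced 15 A apart
  lig_inst <- integer(n_nonpoly)
  for (i in seq_len(n_nonpoly)) {
    rec <- comps[[comp_of_inst[i]]]
    m <- rec$mol
    off <- c(15 * i, 0, 0)
    lig_inst[i] <- add_instance(rec$component_id, "B", 100L + i, "non-polymer",
                                m$atoms$atom_id, m$atoms$element,
                                cbind(m$atoms$x + off[1], m$atoms$y + off[2],
                                      m$atoms$z + off[3]))
  }

  # covalent links between random distinct instance pairs
  links <- NULL
  if (n_covalent > 0 && n_nonpoly >= 2) {
    for (k in seq_len(n_covalent)) {
      pr <- sample(n_nonpoly, 2)
      m1 <- comps[[comp_of_inst[pr[1]]]]$mol; m2 <- comps[[comp_of_inst[pr[2]]]]$mol
      links <- rbind(links, data.frame(
        inst1 = lig_inst[pr[1]], atom1 = sample(m1$atoms$atom_id, 1),
        inst2 = lig_inst[pr[2]], atom2 = sample(m2$atoms$atom_id, 1),
        kind = "covalent", stringsAsFactors = FALSE))
    }
  }

  # metal ions on chain M, coordinated to a random ligand atom
  if (n_metal > 0) {
    comps[["MG"]] <- component_record("MG", molecule(
      data.frame(atom_id = "MG", element = "Mg", x = 0, y = 0, z = 0)))
    for (k in seq_len(n_metal)) {
      tgt <- sample(n_nonpoly, 1)
      mt <- comps[[comp_of_inst[tgt]]]$mol
      ctr <- c(15 * tgt + 3, 3, 0)
      mi <- add_instance("MG", "M", 200L + k, "non-polymer", "MG", "Mg",
                         matrix(ctr, 1, 3))
      links <- rbind(links, data.frame(
        inst1 = mi, atom1 = "MG",
        inst2 = lig_inst[tgt], atom2 = sample(mt$atoms$atom_id, 1),
        kind = "metal-coordination", stringsAsFactors = FALSE))
    }
  }

  # toy pocket on chain A around ligand 1: residue centres 4.5-7 A away,
  # atoms scattered ~1 A around the centre
  lig1 <- sites[sites$instance == lig_inst[1], ]
  ctr1 <- c(mean(lig1$x), mean(lig1$y), mean(lig1$z))
  for (r in seq_len(pocket_residues)) {
    rec <- builtin[[aa[r]]]
    v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
    rc <- ctr1 + stats::runif(1, 4.5, 7) * v
    na <- nrow(rec$mol$atoms)
    xyz <- matrix(rc, na, 3, byrow = TRUE) + matrix(stats::rnorm(na * 3, 0, 1.0), na, 3)
    add_instance(aa[r], "A", r, "polymer", rec$mol$atoms$atom_id,
                 rec$mol$atoms$element, xyz)
  }

  assembly <- assembly_structure(instances, sites, links)

  # independent ground truth: union-find over covalent links
  parent <- seq_len(n_nonpoly)
  findp <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (!is.null(links)) {
    cov <- links[links$kind == "covalent", , drop = FALSE]
    for (k in seq_len(nrow(cov))) {
      a <- match(cov$inst1[k], lig_inst); b <- match(cov$inst2[k], lig_inst)
      if (is.na(a) || is.na(b)) next
      ra <- findp(a); rb <- findp(b)
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n_nonpoly), findp, 0L)
  partition <- lapply(split(seq_len(n_nonpoly), roots), function(ix) sort(lig_inst[ix]))
  # metal ions never merge: each is its own bound molecule
  metal_inst <- which(instances$component_id == "MG")
  partition <- c(partition, lapply(metal_inst, identity))
  names(partition) <- NULL

  list(assembly = assembly, components = comps, partition = partition,
       ligand_instances = lig_inst)
}
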