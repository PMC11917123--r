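#' Default geometric interaction rules
#'
#' Distance/angle thresholds and the van der Waals radii used by
#' [compute_contacts()]. The values follow the conventions of
#' protein-ligand interaction databases (CREDO-style); every threshold is a
#' plain list entry the caller can edit. Distances in Angstrom, angles in
#' degrees.
#'
#' @return named list of thresholds.
#' @export
default_interaction_rules <- function() {
  list(
    vdw_tolerance = 0.1,
    clash_tolerance = 0.6,
    proximal_max = 5.0,
    hbond_dist_max = 3.5,
    hbond_angle_min = 120,
    weak_hbond_dist_max = 3.8,
    ionic_dist_max = 4.0,
    metal_dist_max = 3.0,
    hydrophobic_dist_max = 4.5,
    halogen_dist_max = 4.0,
    aromatic_centroid_max = 6.0,
    cationpi_dist_max = 4.5,
    donorpi_dist_max = 4.0,
    plane_angle_ff_max = 30,
    plane_angle_ee_min = 60,
    ring_planarity_rmsd_max = 0.1,
    oh_bond_length = 0.96,
    nh_bond_length = 1.01
  )
}

rules_global_cutoff <- function(rules) {
  max(rules$proximal_max, rules$hbond_dist_max, rules$weak_hbond_dist_max,
      rules$ionic_dist_max, rules$metal_dist_max, rules$hydrophobic_dist_max,
      rules$halogen_dist_max, rules$aromatic_centroid_max,
      rules$cationpi_dist_max, rules$donorpi_dist_max)
}

# --- atom typing ------------------------------------------------------------

# Per-site typing flags derived from the component dictionary graphs.
# Returns a data.frame aligned with assembly$sites rows.
type_assembly_atoms <- function(assembly, components = list()) {
  comp_lib <- c(components, builtin_components())
  s <- assembly$sites
  n <- nrow(s)
  out <- data.frame(
    donor = logical(n), weak_donor = logical(n), acceptor = logical(n),
    cation = logical(n), anion = logical(n), hydrophobe = logical(n),
    halogen = logical(n), metal = logical(n), n_h = integer(n))
  for (ii in seq_len(nrow(assembly$instances))) {
    rows <- which(s$instance == ii & s$element != "H")
    if (!length(rows)) next
    rec <- comp_lib[[assembly$instances$component_id[ii]]]
    el <- s$element[rows]
    out$halogen[rows] <- el %in% c("F", "Cl", "Br", "I")
    out$metal[rows] <- is_metal(el)
    out$cation[rows] <- out$cation[rows] | is_metal(el)
    if (is.null(rec)) {
      # no dictionary graph: element-level fallback
      out$acceptor[rows] <- el %in% c("O", "N")
      out$donor[rows] <- el %in% c("O", "N")
      out$n_h[rows] <- ifelse(el %in% c("O", "N"), 1L, 0L)
      out$hydrophobe[rows] <- el %in% c("C", "S")
      next
    }
    rm <- rec$mol
    mi <- match(s$atom_id[rows], rm$atoms$atom_id)
    nh <- implicit_hydrogens(rm)
    nbl <- neighbours(rm)
    for (k in seq_along(rows)) {
      j <- mi[k]
      if (is.na(j)) next
      e <- rm$atoms$element[j]; q <- rm$atoms$charge[j]
      row <- rows[k]
      nb_el <- rm$atoms$element[nbl[[j]]]
      nhj <- nh[j] + sum(nb_el == "H")
      out$n_h[row] <- nhj
      if (e %in% c("N", "O")) {
        out$donor[row] <- nhj >= 1
        out$acceptor[row] <- q <= 0
      }
      if (e == "C") {
        out$weak_donor[row] <- nhj >= 1
        out$hydrophobe[row] <- all(nb_el %in% c("C", "H", "S", "*"))
      }
      if (e == "S") out$hydrophobe[row] <- TRUE
      if (q > 0) out$cation[row] <- TRUE
      if (q < 0) out$anion[row] <- TRUE
      # carboxylate/phosphate terminal oxygens are anionic even when drawn
      # uncharged with one C=O / P=O
      if (e == "O" && length(nbl[[j]]) == 1 &&
          rm$atoms$element[nbl[[j]]] %in% c("P", "S")) {
        out$anion[row] <- TRUE
      }
    }
  }
  out
}

#' Add polar hydrogens to an assembly
#'
#' A naive geometric protonation step for structures deposited without
#' hydrogens: one hydrogen is placed on each typed donor (N/O with at least
#' one implicit hydrogen) that lacks an explicit one, along the negated sum
#' of the unit vectors to its bonded heavy neighbours (O-H 0.96, N-H 1.01
#' by default). Existing hydrogens are untouched, so the operation is
#' idempotent. Pass the result to [compute_contacts()] for angle-aware
#' hydrogen-bond detection.
#'
#' @param assembly an `lk_assembly`.
#' @param components named list of `lk_component` dictionary records.
#' @param rules rule list providing the bond lengths.
#' @return the protonated `lk_assembly`.
#' @export
add_polar_hydrogens <- function(assembly, components = list(),
                                rules = default_interaction_rules()) {
  comp_lib <- c(components, builtin_components())
  typing <- type_assembly_atoms(assembly, components)
  s <- assembly$sites
  new_h <- list()
  for (row in which(typing$donor & s$element %in% c("N", "O"))) {
    ii <- s$instance[row]
    # explicit H already attached to this atom?
    has_h <- any(s$instance == ii & s$element == "H" &
                   (!is.na(s$parent) & s$parent == s$atom_id[row]))
    if (!has_h) {
      rec <- comp_lib[[assembly$instances$component_id[ii]]]
      if (!is.null(rec)) {
        j <- match(s$atom_id[row], rec$mol$atoms$atom_id)
        if (!is.na(j)) {
          hn <- rec$mol$atoms$atom_id[neighbours(rec$mol)[[j]]]
          hn <- hn[rec$mol$atoms$element[match(hn, rec$mol$atoms$atom_id)] == "H"]
          has_h <- any(s$instance == ii & s$atom_id %in% hn)
        }
      }
    }
    if (has_h) next
    pos <- c(s$x[row], s$y[row], s$z[row])
    nb_rows <- heavy_neighbour_rows(assembly, comp_lib, row)
    dirv <- c(1, 0, 0)
    if (length(nb_rows)) {
      vs <- vapply(nb_rows, function(r) {
        v <- c(s$x[r], s$y[r], s$z[r]) - pos
        v / max(sqrt(sum(v^2)), 1e-9)
      }, numeric(3))
      v <- -rowSums(matrix(vs, nrow = 3))
      nv <- sqrt(sum(v^2))
      if (nv > 1e-6) dirv <- v / nv
    }
    len <- if (s$element[row] == "O") rules$oh_bond_length else rules$nh_bond_length
    hp <- pos + len * dirv
    new_h[[length(new_h) + 1L]] <- data.frame(
      instance = ii, atom_id = paste0("H", s$atom_id[row]), element = "H",
      x = hp[1], y = hp[2], z = hp[3], parent = s$atom_id[row],
      stringsAsFactors = FALSE)
  }
  if (length(new_h)) {
    assembly$sites <- rbind(s, do.call(rbind, new_h))
  }
  assembly
}

# site rows of bonded heavy neighbours (dictionary bonds within the
# instance, plus inter-instance links)
heavy_neighbour_rows <- function(assembly, comp_lib, row) {
  s <- assembly$sites
  ii <- s$instance[row]; aid <- s$atom_id[row]
  out <- integer()
  rec <- comp_lib[[assembly$instances$component_id[ii]]]
  if (!is.null(rec)) {
    j <- match(aid, rec$mol$atoms$atom_id)
    if (!is.na(j)) {
      nb_ids <- rec$mol$atoms$atom_id[neighbours(rec$mol)[[j]]]
      out <- which(s$instance == ii & s$atom_id %in% nb_ids & s$element != "H")
    }
  }
  l <- assembly$links
  hit1 <- l$inst1 == ii & l$atom1 == aid
  hit2 <- l$inst2 == ii & l$atom2 == aid
  for (k in which(hit1)) out <- c(out, which(s$instance == l$inst2[k] & s$atom_id == l$atom2[k]))
  for (k in which(hit2)) out <- c(out, which(s$instance == l$inst1[k] & s$atom_id == l$atom1[k]))
  unique(out)
}

# --- ring planes ------------------------------------------------------------

#' Detect planar rings in a set of positioned atoms
#'
#' Rings of 5-7 members (from the component dictionary graph) whose atom
#' coordinates fit a plane with RMSD at or below the planarity threshold
#' become ring planes with a centroid and unit normal (smallest principal
#' axis of the centred coordinates).
#'
#' @param coords numeric matrix (n x 3) of the instance's heavy-atom
#'   coordinates.
#' @param mol the instance's dictionary graph (`lk_mol`) aligned with
#'   `coords` rows.
#' @param rmsd_max planarity threshold in Angstrom.
#' @return list of ring planes: `members` (atom indices), `centroid`,
#'   `normal` (unit), `rmsd`.
#' @export
detect_ring_planes <- function(coords, mol, rmsd_max = 0.1) {
  rings <- find_rings(mol, min_size = 5, max_size = 7)
  out <- list()
  for (r in rings) {
    p <- coords[r, , drop = FALSE]
    if (any(is.na(p))) next
    ctr <- colMeans(p)
    cc <- sweep(p, 2, ctr)
    sv <- svd(cc)
    normal <- sv$v[, 3]
    rmsd <- sqrt(mean((cc %*% normal)^2))
    if (rmsd <= rmsd_max) {
      out[[length(out) + 1L]] <- list(members = r, centroid = ctr,
                                      normal = normal / sqrt(sum(normal^2)),
                                      rmsd = rmsd)
    }
  }
  out
}

# ring planes per instance: list of (instance, rows(site rows), centroid, normal)
assembly_ring_planes <- function(assembly, comp_lib, instance_ids, rules) {
  s <- assembly$sites
  out <- list()
  for (ii in instance_ids) {
    rec <- comp_lib[[assembly$instances$component_id[ii]]]
    if (is.null(rec)) next
    rows <- which(s$instance == ii & s$element != "H")
    mi <- match(rec$mol$atoms$atom_id, s$atom_id[rows])
    # atoms absent from the model get NA coordinates; rings touching them
    # are skipped inside detect_ring_planes
    coords <- cbind(s$x[rows][mi], s$y[rows][mi], s$z[rows][mi])
    planes <- detect_ring_planes(coords, rec$mol, rules$ring_planarity_rmsd_max)
    for (p in planes) {
      p$instance <- ii
      p$rows <- rows[mi[p$members]]
      p$atom_ids <- paste(s$atom_id[p$rows], collapse = "|")
      out[[length(out) + 1L]] <- p
    }
  }
  out
}

# planar amide groups (C(=O)-N) per instance, from the dictionary graph
assembly_amide_groups <- function(assembly, comp_lib, instance_ids) {
  s <- assembly$sites
  out <- list()
  for (ii in instance_ids) {
    rec <- comp_lib[[assembly$instances$component_id[ii]]]
    if (is.null(rec)) next
    rm <- rec$mol
    bidx <- atom_bond_index(rm)
    for (c_at in which(rm$atoms$element == "C")) {
      bs <- rm$bonds[bidx[[c_at]], , drop = FALSE]
      partners <- ifelse(bs$a1 == c_at, bs$a2, bs$a1)
      o_at <- partners[bs$order == 2 & rm$atoms$element[partners] == "O"]
      n_at <- partners[bs$order == 1 & rm$atoms$element[partners] == "N"]
      if (length(o_at) >= 1 && length(n_at) >= 1) {
        ids <- rm$atoms$atom_id[c(c_at, o_at[1], n_at[1])]
        rows <- which(s$instance == ii & s$atom_id %in% ids)
        if (length(rows) == 3) {
          out[[length(out) + 1L]] <- list(
            instance = ii, rows = rows,
            centroid = c(mean(s$x[rows]), mean(s$y[rows]), mean(s$z[rows])),
            atom_ids = paste(s$atom_id[rows], collapse = "|"))
        }
      }
    }
  }
  out
}

# --- contact computation ----------------------------------------------------

#' Compute typed contacts between a bound molecule and its environment
#'
#' Evaluates every (ligand atom, environment atom) pair within the global
#' cutoff against the rule table and emits all satisfied subtypes, in four
#' categories: atom-atom (clash, vdw, proximal, hbond, weak-hbond, ionic,
#' metal, hydrophobic, halogen), atom-plane (cation-pi, donor-pi),
#' plane-plane (pi-pi-FF / OF / EE by normal angle band) and plane-group
#' (amide-ring). Covalently linked pairs are excluded; a clashing pair
#' carries no bonding subtype. Output ordering is deterministic.
#'
#' @param assembly a (preferably protonated) `lk_assembly`.
#' @param bm an `lk_bound_molecule` from [infer_bound_molecules()].
#' @param rules rule list, see [default_interaction_rules()].
#' @param components named list of `lk_component` dictionary records.
#' @param mode `"auto"` uses hydrogen-aware hydrogen-bond angles when the
#'   assembly carries hydrogens, otherwise distance-only; `"angles"` insists
#'   on hydrogens (error without them); `"distance"` ignores angles.
#' @return data.frame of contacts (class `lk_contacts`): category, subtype,
#'   ligand instance/atom, partner chain/residue/component/atom, distance,
#'   angle.
#' @export
compute_contacts <- function(assembly, bm, rules = default_interaction_rules(),
                             components = list(),
                             mode = c("auto", "angles", "distance")) {
  mode <- match.arg(mode)
  s <- assembly$sites
  has_h <- any(s$element == "H")
  if (mode == "angles" && !has_h) {
    stop("angle-dependent mode requires hydrogens; run add_polar_hydrogens() first")
  }
  use_angles <- (mode == "angles") || (mode == "auto" && has_h)

  comp_lib <- c(components, builtin_components())
  typing <- type_assembly_atoms(assembly, components)
  inst <- assembly$instances

  lig_rows <- which(s$instance %in% bm$instances & s$element != "H")
  env_rows <- which(!s$instance %in% bm$instances & s$element != "H")
  if (!length(lig_rows) || !length(env_rows)) {
    return(empty_contacts())
  }

  # covalently linked (ligand, environment) site pairs are excluded
  l <- assembly$links[assembly$links$kind == "covalent", , drop = FALSE]
  excluded <- character()
  for (k in seq_len(nrow(l))) {
    r1 <- which(s$instance == l$inst1[k] & s$atom_id == l$atom1[k])
    r2 <- which(s$instance == l$inst2[k] & s$atom_id == l$atom2[k])
    excluded <- c(excluded, paste(r1, r2), paste(r2, r1))
  }

  cutoff <- rules_global_cutoff(rules)
  cand <- grid_pairs(s, lig_rows, env_rows, cutoff)
  out <- list()
  emit <- function(category, subtype, lrow, partner_desc, dist, angle = NA_real_) {
    out[[length(out) + 1L]] <<- data.frame(
      category = category, subtype = subtype,
      lig_instance = s$instance[lrow],
      lig_atom = s$atom_id[lrow],
      env_chain = partner_desc$chain, env_resnum = partner_desc$resnum,
      env_comp = partner_desc$comp, env_atom = partner_desc$atom,
      distance = dist, angle = angle, stringsAsFactors = FALSE)
  }
  partner_of <- function(erow) {
    ei <- s$instance[erow]
    list(chain = inst$chain[ei], resnum = inst$resnum[ei],
         comp = inst$component_id[ei], atom = s$atom_id[erow])
  }

  for (k in seq_len(nrow(cand))) {
    i <- cand$lig[k]; j <- cand$env[k]
    if (paste(i, j) %in% excluded) next
    d <- cand$dist[k]
    pj <- partner_of(j)
    ri <- vdw_radius(s$element[i]); rj <- vdw_radius(s$element[j])
    clash <- d < (ri + rj - rules$clash_tolerance)
    if (clash) {
      emit("atom-atom", "clash", i, pj, d)
      next   # clash excludes all bonding subtypes
    }
    if (d <= ri + rj + rules$vdw_tolerance) {
      emit("atom-atom", "vdw", i, pj, d)
    } else if (d <= rules$proximal_max) {
      emit("atom-atom", "proximal", i, pj, d)
    }
    ti <- typing[i, ]; tj <- typing[j, ]
    # hydrogen bond (either direction)
    if (d <= rules$hbond_dist_max) {
      for (dir in list(c(i, j), c(j, i))) {
        drow <- dir[1]; arow <- dir[2]
        if (typing$donor[drow] && typing$acceptor[arow]) {
          ang <- NA_real_
          ok <- TRUE
          if (use_angles) {
            ang <- best_dha_angle(s, drow, arow)
            ok <- is.na(ang) || ang >= rules$hbond_angle_min
          }
          if (ok) { emit("atom-atom", "hbond", i, pj, d, ang); break }
        }
      }
    }
    if (d <= rules$weak_hbond_dist_max &&
        ((ti$weak_donor && tj$acceptor) || (tj$weak_donor && ti$acceptor))) {
      emit("atom-atom", "weak-hbond", i, pj, d)
    }
    if (d <= rules$ionic_dist_max &&
        ((ti$cation && tj$anion) || (tj$cation && ti$anion))) {
      emit("atom-atom", "ionic", i, pj, d)
    }
    if (d <= rules$metal_dist_max &&
        ((ti$metal && (tj$acceptor || tj$anion)) ||
         (tj$metal && (ti$acceptor || ti$anion)))) {
      emit("atom-atom", "metal", i, pj, d)
    }
    if (d <= rules$hydrophobic_dist_max && ti$hydrophobe && tj$hydrophobe &&
        s$element[i] %in% c("C", "S") && s$element[j] %in% c("C", "S")) {
      emit("atom-atom", "hydrophobic", i, pj, d)
    }
    if (d <= rules$halogen_dist_max &&
        ((ti$halogen && tj$acceptor) || (tj$halogen && ti$acceptor))) {
      emit("atom-atom", "halogen", i, pj, d)
    }
  }

  # plane categories
  lig_planes <- assembly_ring_planes(assembly, comp_lib, bm$instances, rules)
  env_inst <- setdiff(seq_len(nrow(inst)), bm$instances)
  env_planes <- assembly_ring_planes(assembly, comp_lib, env_inst, rules)
  env_amides <- assembly_amide_groups(assembly, comp_lib, env_inst)
  lig_amides <- assembly_amide_groups(assembly, comp_lib, bm$instances)

  plane_partner <- function(p) list(chain = inst$chain[p$instance],
                                    resnum = inst$resnum[p$instance],
                                    comp = inst$component_id[p$instance],
                                    atom = p$atom_ids)
  emit_plane <- function(category, subtype, lig_desc, partner, dist, angle = NA_real_) {
    out[[length(out) + 1L]] <<- data.frame(
      category = category, subtype = subtype,
      lig_instance = lig_desc$instance, lig_atom = lig_desc$atom,
      env_chain = partner$chain, env_resnum = partner$resnum,
      env_comp = partner$comp, env_atom = partner$atom,
      distance = dist, angle = angle, stringsAsFactors = FALSE)
  }

  # plane-plane (pi stacking)
  for (lp in lig_planes) {
    for (ep in env_planes) {
      d <- sqrt(sum((lp$centroid - ep$centroid)^2))
      if (d > rules$aromatic_centroid_max) next
      th <- plane_angle(lp$normal, ep$normal)
      subtype <- if (th <= rules$plane_angle_ff_max) "pi-pi-FF"
        else if (th >= rules$plane_angle_ee_min) "pi-pi-EE" else "pi-pi-OF"
      emit_plane("plane-plane", subtype,
                 list(instance = lp$instance, atom = lp$atom_ids),
                 plane_partner(ep), d, th)
    }
  }
  # atom-plane: environment atoms onto ligand rings, ligand atoms onto
  # environment rings
  atom_plane <- function(arow, plane, ligand_side) {
    d <- sqrt(sum((c(s$x[arow], s$y[arow], s$z[arow]) - plane$centroid)^2))
    tt <- typing[arow, ]
    hits <- character()
    if (tt$cation && d <= rules$cationpi_dist_max) hits <- c(hits, "cation-pi")
    if (tt$donor && d <= rules$donorpi_dist_max) hits <- c(hits, "donor-pi")
    for (h in hits) {
      if (ligand_side) {
        emit_plane("atom-plane", h,
                   list(instance = s$instance[arow], atom = s$atom_id[arow]),
                   plane_partner(plane), d)
      } else {
        emit_plane("atom-plane", h,
                   list(instance = plane$instance, atom = plane$atom_ids),
                   partner_of(arow), d)
      }
    }
  }
  for (lp in lig_planes) for (j in env_rows) atom_plane(j, lp, ligand_side = FALSE)
  for (ep in env_planes) for (i in lig_rows) atom_plane(i, ep, ligand_side = TRUE)

  # plane-group: rings vs amide groups
  for (lp in lig_planes) {
    for (g in env_amides) {
      d <- sqrt(sum((lp$centroid - g$centroid)^2))
      if (d <= rules$aromatic_centroid_max) {
        emit_plane("plane-group", "amide-ring",
                   list(instance = lp$instance, atom = lp$atom_ids),
                   list(chain = inst$chain[g$instance], resnum = inst$resnum[g$instance],
                        comp = inst$component_id[g$instance], atom = g$atom_ids), d)
      }
    }
  }
  for (la in lig_amides) {
    for (ep in env_planes) {
      d <- sqrt(sum((la$centroid - ep$centroid)^2))
      if (d <= rules$aromatic_centroid_max) {
        emit_plane("plane-group", "amide-ring",
                   list(instance = la$instance, atom = la$atom_ids),
                   plane_partner(ep), d)
      }
    }
  }

  res <- if (length(out)) do.call(rbind, out) else empty_contacts()
  res <- res[order(res$lig_instance, res$lig_atom, res$env_chain,
                   res$env_resnum, res$env_atom, res$subtype), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("lk_contacts", "data.frame")
  res
}

empty_contacts <- function() {
  structure(data.frame(
    category = character(), subtype = character(), lig_instance = integer(),
    lig_atom = character(), env_chain = character(), env_resnum = integer(),
    env_comp = character(), env_atom = character(), distance = numeric(),
    angle = numeric(), stringsAsFactors = FALSE),
    class = c("lk_contacts", "data.frame"))
}

# acute angle between two plane normals, degrees in [0, 90]
plane_angle <- function(n1, n2) {
  ct <- abs(sum(n1 * n2)) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  acos(min(1, ct)) * 180 / pi
}

# best D-H...A angle over the donor's attached hydrogens (NA if none)
best_dha_angle <- function(s, drow, arow) {
  hs <- which(s$instance == s$instance[drow] & s$element == "H" &
                !is.na(s$parent) & s$parent == s$atom_id[drow])
  if (!length(hs)) return(NA_real_)
  a <- c(s$x[arow], s$y[arow], s$z[arow])
  best <- -Inf
  for (h in hs) {
    hp <- c(s$x[h], s$y[h], s$z[h])
    dv <- c(s$x[drow], s$y[drow], s$z[drow]) - hp
    av <- a - hp
    ct <- sum(dv * av) / (sqrt(sum(dv^2)) * sqrt(sum(av^2)))
    ang <- acos(max(-1, min(1, ct))) * 180 / pi
    if (ang > best) best <- ang
  }
  best
}

# uniform spatial grid of cell size = cutoff; returns candidate pairs with
# distances (exact filter applied)
grid_pairs <- function(s, lig_rows, env_rows, cutoff) {
  cell <- function(rows) {
    data.frame(row = rows,
               cx = floor(s$x[rows] / cutoff),
               cy = floor(s$y[rows] / cutoff),
               cz = floor(s$z[rows] / cutoff))
  }
  eg <- cell(env_rows)
  ekey <- paste(eg$cx, eg$cy, eg$cz)
  emap <- split(eg$row, ekey)
  lg <- cell(lig_rows)
  lig <- integer(); env <- integer()
  for (k in seq_len(nrow(lg))) {
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      key <- paste(lg$cx[k] + dx, lg$cy[k] + dy, lg$cz[k] + dz)
      cand <- emap[[key]]
      if (!is.null(cand)) { lig <- c(lig, rep(lg$row[k], length(cand))); env <- c(env, cand) }
    }
  }
  if (!length(lig)) return(data.frame(lig = integer(), env = integer(), dist = numeric()))
  d <- sqrt((s$x[lig] - s$x[env])^2 + (s$y[lig] - s$y[env])^2 + (s$z[lig] - s$z[env])^2)
  keep <- d <= cutoff
  data.frame(lig = lig[keep], env = env[keep], dist = d[keep])
}

#' Per-entry interaction report
#'
#' Contacts for every bound molecule of an entry, grouped per bmID and per
#' ligand atom, as a JSON-ready list.
#'
#' @param assembly an `lk_assembly`.
#' @param bound_set an `lk_bound_set` from [infer_bound_molecules()].
#' @param rules,components,mode passed to [compute_contacts()].
#' @return list: one element per bmID, each a list with `components` and
#'   `atoms` (per ligand atom: list of contact records).
#' @export
interactions_report <- function(assembly, bound_set,
                                rules = default_interaction_rules(),
                                components = list(), mode = "auto") {
  out <- list()
  for (bm in bound_set$bound) {
    cts <- compute_contacts(assembly, bm, rules, components, mode)
    atoms <- split(cts, cts$lig_atom)
    out[[bm$bmID]] <- list(
      components = as.list(bm$component_multiset),
      n_contacts = nrow(cts),
      atoms = lapply(atoms, function(df) {
        lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
      }))
  }
  out
}
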