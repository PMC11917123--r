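# Independent oracles used by the property suites. These deliberately share
# no search code with the package: the modular product is rebuilt here from
# scratch and maximum cliques are taken from igraph's exact enumeration;
# partitions come from a plain union-find; contacts from a direct all-pairs
# rule evaluation.

# exact maximum-common-substructure size via igraph's clique number on an
# independently built modular product graph
oracle_mcs_size <- function(a, b) {
  a <- strip_hs(a); b <- strip_hs(b)
  na <- nrow(a$atoms); nb <- nrow(b$atoms)
  if (na == 0 || nb == 0) return(0L)
  pairs <- expand.grid(i = seq_len(na), j = seq_len(nb))
  pairs <- pairs[a$atoms$element[pairs$i] == b$atoms$element[pairs$j], , drop = FALSE]
  if (nrow(pairs) == 0) return(0L)
  bm <- function(m) {
    M <- matrix(FALSE, nrow(m$atoms), nrow(m$atoms))
    if (nrow(m$bonds)) {
      M[cbind(m$bonds$a1, m$bonds$a2)] <- TRUE
      M[cbind(m$bonds$a2, m$bonds$a1)] <- TRUE
    }
    M
  }
  BA <- bm(a); BB <- bm(b)
  np <- nrow(pairs)
  edges <- NULL
  for (u in seq_len(np - 1)) {
    for (v in (u + 1):np) {
      i <- pairs$i[u]; k <- pairs$i[v]; j <- pairs$j[u]; l <- pairs$j[v]
      if (i != k && j != l && BA[i, k] == BB[j, l]) {
        edges <- rbind(edges, c(u, v))
      }
    }
  }
  if (is.null(edges)) return(1L)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, np - igraph::vcount(g)))
  igraph::clique_num(g)
}

strip_hs <- function(m) {
  keep <- which(m$atoms$element != "H")
  map <- integer(nrow(m$atoms)); map[keep] <- seq_along(keep)
  b <- m$bonds[m$bonds$a1 %in% keep & m$bonds$a2 %in% keep, , drop = FALSE]
  if (nrow(b)) { b$a1 <- map[b$a1]; b$a2 <- map[b$a2] }
  molecule(m$atoms[keep, , drop = FALSE], b)
}

oracle_parity_score <- function(a, b) {
  m <- oracle_mcs_size(a, b)
  na <- sum(a$atoms$element != "H"); nb <- sum(b$atoms$element != "H")
  if (na == 0 || nb == 0) return(0)
  m / (na + nb - m)
}

# union-find partition of non-polymer, non-water instances over covalent links
oracle_partition <- function(assembly) {
  inst <- assembly$instances
  nodes <- which(inst$kind == "non-polymer")
  parent <- seq_along(nodes)
  findp <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  l <- assembly$links[assembly$links$kind == "covalent", , drop = FALSE]
  for (k in seq_len(nrow(l))) {
    a <- match(l$inst1[k], nodes); b <- match(l$inst2[k], nodes)
    if (is.na(a) || is.na(b)) next
    ra <- findp(a); rb <- findp(b)
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_along(nodes), findp, 0L)
  unname(lapply(split(nodes, roots), sort))
}

partition_key <- function(groups) {
  sort(vapply(groups, function(g) paste(sort(g), collapse = ","), ""))
}

# direct all-pairs atom-atom contact evaluation (no spatial grid), using the
# package's typing but its own geometry logic
oracle_atom_contacts <- function(assembly, bm, rules, components = list()) {
  s <- assembly$sites
  typing <- ligandkit:::type_assembly_atoms(assembly, components)
  inst <- assembly$instances
  lig <- which(s$instance %in% bm$instances & s$element != "H")
  env <- which(!s$instance %in% bm$instances & s$element != "H")
  l <- assembly$links[assembly$links$kind == "covalent", , drop = FALSE]
  excl <- character()
  for (k in seq_len(nrow(l))) {
    r1 <- which(s$instance == l$inst1[k] & s$atom_id == l$atom1[k])
    r2 <- which(s$instance == l$inst2[k] & s$atom_id == l$atom2[k])
    excl <- c(excl, paste(r1, r2), paste(r2, r1))
  }
  rows <- list()
  for (i in lig) for (j in env) {
    if (paste(i, j) %in% excl) next
    d <- sqrt((s$x[i] - s$x[j])^2 + (s$y[i] - s$y[j])^2 + (s$z[i] - s$z[j])^2)
    ri <- ligandkit:::vdw_radius(s$element[i]); rj <- ligandkit:::vdw_radius(s$element[j])
    sub <- character()
    if (d < ri + rj - rules$clash_tolerance) {
      sub <- "clash"
    } else {
      if (d <= ri + rj + rules$vdw_tolerance) sub <- c(sub, "vdw")
      else if (d <= rules$proximal_max) sub <- c(sub, "proximal")
      ti <- typing[i, ]; tj <- typing[j, ]
      if (d <= rules$hbond_dist_max &&
          ((ti$donor && tj$acceptor) || (tj$donor && ti$acceptor))) sub <- c(sub, "hbond")
      if (d <= rules$weak_hbond_dist_max &&
          ((ti$weak_donor && tj$acceptor) || (tj$weak_donor && ti$acceptor))) sub <- c(sub, "weak-hbond")
      if (d <= rules$ionic_dist_max &&
          ((ti$cation && tj$anion) || (tj$cation && ti$anion))) sub <- c(sub, "ionic")
      if (d <= rules$metal_dist_max &&
          ((ti$metal && (tj$acceptor || tj$anion)) ||
           (tj$metal && (ti$acceptor || ti$anion)))) sub <- c(sub, "metal")
      if (d <= rules$hydrophobic_dist_max && ti$hydrophobe && tj$hydrophobe) sub <- c(sub, "hydrophobic")
      if (d <= rules$halogen_dist_max &&
          ((ti$halogen && tj$acceptor) || (tj$halogen && ti$acceptor))) sub <- c(sub, "halogen")
    }
    for (st in sub) {
      rows[[length(rows) + 1L]] <- data.frame(
        subtype = st, lig_atom = s$atom_id[i], lig_instance = s$instance[i],
        env_atom = s$atom_id[j], env_instance = s$instance[j],
        distance = d, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subtype = character(), lig_atom = character(),
               lig_instance = integer(), env_atom = character(),
               env_instance = integer(), distance = numeric())
  out[order(out$lig_instance, out$lig_atom, out$env_instance, out$env_atom,
            out$subtype), , drop = FALSE]
}

contact_key <- function(df) {
  if (nrow(df) == 0) return(character())
  sort(paste(df$lig_instance, df$lig_atom, df$env_instance %||% "",
             df$env_atom, df$subtype))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# iterative terminal-atom pruning, an independent scaffold oracle
oracle_scaffold_elements <- function(m) {
  m <- strip_hs(m)
  repeat {
    deg <- tabulate(c(m$bonds$a1, m$bonds$a2), nbins = nrow(m$atoms))
    drop <- which(deg <= 1)
    if (nrow(m$atoms) == 0 || length(drop) == 0) break
    keep <- setdiff(seq_len(nrow(m$atoms)), drop)
    map <- integer(nrow(m$atoms)); map[keep] <- seq_along(keep)
    b <- m$bonds[m$bonds$a1 %in% keep & m$bonds$a2 %in% keep, , drop = FALSE]
    if (nrow(b)) { b$a1 <- map[b$a1]; b$a2 <- map[b$a2] }
    m <- molecule(m$atoms[keep, , drop = FALSE], b)
  }
  sort(m$atoms$element)
}

# naive subgraph-monomorphism existence check by full permutation search
oracle_has_substructure <- function(pattern, target) {
  pattern <- strip_hs(pattern); target <- strip_hs(target)
  np <- nrow(pattern$atoms); nt <- nrow(target$atoms)
  if (np > nt) return(FALSE)
  tkey <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(target$bonds))) {
    b <- target$bonds[k, ]
    tkey[[paste(min(b$a1, b$a2), max(b$a1, b$a2))]] <- c(b$order, b$aromatic)
  }
  ok_mapping <- function(map) {
    for (k in seq_len(nrow(pattern$bonds))) {
      b <- pattern$bonds[k, ]
      t1 <- map[b$a1]; t2 <- map[b$a2]
      tb <- tkey[[paste(min(t1, t2), max(t1, t2))]]
      if (is.null(tb) || tb[1] != b$order || tb[2] != b$aromatic) return(FALSE)
    }
    TRUE
  }
  rec <- function(pos, map, used) {
    if (pos > np) return(ok_mapping(map))
    for (t in seq_len(nt)) {
      if (used[t]) next
      if (target$atoms$element[t] != pattern$atoms$element[pos]) next
      map[pos] <- t; used[t] <- TRUE
      if (rec(pos + 1, map, used)) return(TRUE)
      used[t] <- FALSE
    }
    FALSE
  }
  rec(1, integer(np), logical(nt))
}
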