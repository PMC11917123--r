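#' Construct a molecule
#'
#' The universal chemical object of the toolkit: an attributed graph of atoms
#' (element, formal charge, optional 2D and 3D coordinates, optional source
#' atom name) and bonds (order, aromatic flag, dative flag). Hydrogens may be
#' explicit or implicit; most operations work on the heavy-atom graph and
#' complete hydrogens against the valence table when needed.
#'
#' @param atoms data.frame with columns `element` (chemical symbol) and
#'   optionally `atom_id` (source atom name), `charge` (integer, default 0),
#'   `x`,`y`,`z` (3D coordinates, Angstrom), `x2`,`y2` (2D depiction
#'   coordinates).
#' @param bonds data.frame with columns `a1`, `a2` (1-based atom indices) and
#'   optionally `order` (1, 2 or 3; default 1), `aromatic` (logical),
#'   `dative` (logical; dative/coordination bonds do not count towards
#'   valence).
#' @param name optional molecule name/identifier.
#' @return An object of class `lk_mol`.
#' @examples
#' m <- molecule(
#'   atoms = data.frame(element = c("O", "H", "H")),
#'   bonds = data.frame(a1 = c(1, 1), a2 = c(2, 3))
#' )
#' n_atoms(m)
#' @export
molecule <- function(atoms, bonds = NULL, name = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) > 0 && is.null(atoms$element)) {
    stop("atoms must have an 'element' column")
  }
  for (col in c("x", "y", "z", "x2", "y2")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- rep(NA_real_, nrow(atoms))
    atoms[[col]] <- as.numeric(atoms[[col]])
  }
  if (is.null(atoms$atom_id)) atoms$atom_id <- rep(NA_character_, nrow(atoms))
  if (is.null(atoms$charge)) atoms$charge <- rep(0L, nrow(atoms))
  atoms$charge[is.na(atoms$charge)] <- 0L
  atoms$charge <- as.integer(atoms$charge)
  atoms$element <- as.character(atoms$element)
  atoms <- atoms[, c("atom_id", "element", "charge", "x", "y", "z", "x2", "y2")]
  rownames(atoms) <- NULL

  if (is.null(bonds) || NROW(bonds) == 0) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer(),
                        aromatic = logical(), dative = logical())
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    if (is.null(bonds$order)) bonds$order <- 1L
    if (is.null(bonds$aromatic)) bonds$aromatic <- FALSE
    if (is.null(bonds$dative)) bonds$dative <- FALSE
    bonds$a1 <- as.integer(bonds$a1)
    bonds$a2 <- as.integer(bonds$a2)
    bonds$order <- as.integer(bonds$order)
    bonds$aromatic <- as.logical(bonds$aromatic)
    bonds$dative <- as.logical(bonds$dative)
    bonds <- bonds[, c("a1", "a2", "order", "aromatic", "dative")]
    # canonical endpoint order a1 < a2
    flip <- bonds$a1 > bonds$a2
    tmp <- bonds$a1[flip]; bonds$a1[flip] <- bonds$a2[flip]; bonds$a2[flip] <- tmp
    rownames(bonds) <- NULL
  }

  m <- structure(list(atoms = atoms, bonds = bonds, name = name),
                 class = "lk_mol")
  validate_molecule(m)
  m
}

validate_molecule <- function(m) {
  a <- m$atoms; b <- m$bonds
  n <- nrow(a)
  if (nrow(b) > 0) {
    if (any(b$a1 < 1 | b$a2 < 1 | b$a1 > n | b$a2 > n)) {
      stop("bond references an atom index outside 1..", n)
    }
    if (any(b$a1 == b$a2)) stop("self-loop bond not allowed")
    key <- paste(b$a1, b$a2)
    if (anyDuplicated(key)) stop("duplicate bond between atoms ",
                                 key[duplicated(key)][1])
    if (any(!b$order %in% 1:3)) stop("bond order must be 1, 2 or 3")
  }
  bad <- !a$element %in% periodic_table$symbol
  if (any(bad)) stop("unknown element symbol: ", paste(unique(a$element[bad]), collapse = ", "))
  if (any(abs(a$charge) > 4)) stop("formal charge out of range [-4, 4]")
  invisible(m)
}

#' @export
print.lk_mol <- function(x, ...) {
  cat(sprintf("<molecule%s: %d atoms (%d heavy), %d bonds>\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              nrow(x$atoms), sum(x$atoms$element != "H"), nrow(x$bonds)))
  f <- tryCatch(molecular_formula(x), error = function(e) NULL)
  if (!is.null(f)) cat("  formula:", f, "\n")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param m an `lk_mol`.
#' @param heavy if `TRUE`, count heavy (non-hydrogen) atoms only.
#' @return integer count.
#' @export
n_atoms <- function(m, heavy = FALSE) {
  if (heavy) sum(m$atoms$element != "H") else nrow(m$atoms)
}

#' Drop explicit hydrogens
#'
#' Returns the heavy-atom graph; bonds to hydrogens are removed and the
#' remaining atoms are re-indexed.
#' @param m an `lk_mol`.
#' @return an `lk_mol` with hydrogens removed.
#' @export
strip_hydrogens <- function(m) {
  keep <- which(m$atoms$element != "H")
  subset_molecule(m, keep)
}

# Induced subgraph on atom indices `keep` (in the order given).
subset_molecule <- function(m, keep) {
  map <- integer(nrow(m$atoms)); map[keep] <- seq_along(keep)
  b <- m$bonds
  b <- b[b$a1 %in% keep & b$a2 %in% keep, , drop = FALSE]
  if (nrow(b) > 0) { b$a1 <- map[b$a1]; b$a2 <- map[b$a2] }
  molecule(m$atoms[keep, , drop = FALSE], b, name = m$name)
}

# Per-atom bond-order sum. Aromatic bonds count 1.5, dative bonds 0.
valence_sums <- function(m) {
  n <- nrow(m$atoms)
  v <- numeric(n)
  b <- m$bonds
  if (nrow(b) == 0) return(v)
  contrib <- ifelse(b$dative, 0, ifelse(b$aromatic, 1.5, b$order))
  for (i in seq_len(nrow(b))) {
    v[b$a1[i]] <- v[b$a1[i]] + contrib[i]
    v[b$a2[i]] <- v[b$a2[i]] + contrib[i]
  }
  v
}

# Adjacency list: for each atom, the bond row indices touching it.
atom_bond_index <- function(m) {
  n <- nrow(m$atoms)
  idx <- vector("list", n)
  b <- m$bonds
  for (i in seq_len(nrow(b))) {
    idx[[b$a1[i]]] <- c(idx[[b$a1[i]]], i)
    idx[[b$a2[i]]] <- c(idx[[b$a2[i]]], i)
  }
  idx
}

# Neighbour list (atom indices).
neighbours <- function(m) {
  n <- nrow(m$atoms)
  nb <- vector("list", n)
  b <- m$bonds
  for (i in seq_len(nrow(b))) {
    nb[[b$a1[i]]] <- c(nb[[b$a1[i]]], b$a2[i])
    nb[[b$a2[i]]] <- c(nb[[b$a2[i]]], b$a1[i])
  }
  nb
}

as_igraph <- function(m) {
  igraph::graph_from_data_frame(
    d = if (nrow(m$bonds)) m$bonds[, c("a1", "a2")] else data.frame(a1 = integer(), a2 = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(m$atoms))))
}

# Logical vector: is each bond part of a cycle (i.e. not a bridge)?
ring_bonds <- function(m) {
  nb <- nrow(m$bonds)
  if (nb == 0) return(logical(0))
  g <- as_igraph(m)
  br <- igraph::bridges(g)
  res <- rep(TRUE, nb)
  res[as.integer(br)] <- FALSE
  res
}

# Logical vector: is each atom part of a cycle?
ring_atoms <- function(m) {
  inring <- logical(nrow(m$atoms))
  rb <- ring_bonds(m)
  if (any(rb)) {
    b <- m$bonds[rb, , drop = FALSE]
    inring[unique(c(b$a1, b$a2))] <- TRUE
  }
  inring
}

# All simple cycles of length min_size..max_size, as atom-index vectors.
# Each cycle reported once, rotated/reflected to a canonical form.
find_rings <- function(m, min_size = 3, max_size = 7) {
  nb <- neighbours(m)
  n <- nrow(m$atoms)
  seen <- new.env(parent = emptyenv())
  out <- list()
  path <- integer(max_size)
  visit <- function(start, v, depth, onpath) {
    for (w in nb[[v]]) {
      if (w == start && depth >= min_size) {
        cyc <- path[seq_len(depth)]
        # canonical: rotate so min first, then direction with smaller second
        i0 <- which.min(cyc)
        k <- length(cyc)
        rot <- cyc[((seq_len(k) + i0 - 2) %% k) + 1]
        rev2 <- c(rot[1], rev(rot[-1]))
        canon <- if (paste(rot, collapse = ",") <= paste(rev2, collapse = ",")) rot else rev2
        key <- paste(canon, collapse = ",")
        if (is.null(seen[[key]])) { seen[[key]] <- TRUE; out[[length(out) + 1L]] <<- canon }
      } else if (depth < max_size && w > start && !onpath[w]) {
        path[depth + 1L] <<- w
        onpath[w] <- TRUE
        visit(start, w, depth + 1L, onpath)
        onpath[w] <- FALSE
      }
    }
  }
  for (s in seq_len(n)) {
    onpath <- logical(n); onpath[s] <- TRUE
    path[1L] <- s
    visit(s, s, 1L, onpath)
  }
  out
}

# Connected components of the heavy-atom graph; list of atom-index vectors.
mol_components <- function(m) {
  g <- as_igraph(m)
  comp <- igraph::components(g)
  split(seq_len(nrow(m$atoms)), comp$membership)
}

#' Combine several molecules into one disconnected graph
#' @param mols list of `lk_mol`.
#' @param name optional name of the combined molecule.
#' @return an `lk_mol` whose components are the inputs, in order.
#' @export
combine_molecules <- function(mols, name = NULL) {
  atoms <- do.call(rbind, lapply(mols, function(m) m$atoms))
  off <- cumsum(c(0, vapply(mols, function(m) nrow(m$atoms), 0)))
  bonds <- do.call(rbind, lapply(seq_along(mols), function(i) {
    b <- mols[[i]]$bonds
    if (nrow(b)) { b$a1 <- b$a1 + off[i]; b$a2 <- b$a2 + off[i] }
    b
  }))
  molecule(atoms, bonds, name = name)
}
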