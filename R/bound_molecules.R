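#' Infer complete bound molecules from assembly connectivity
#'
#' Builds a graph whose nodes are the non-polymer, non-water component
#' instances of the assembly and whose edges are the links of kind
#' `"covalent"` only — metal-coordination links never merge components, so
#' a coordinated metal ion stays a separate bound molecule. Each connected
#' component becomes one bound molecule with a `bmID` assigned in order of
#' the (chain, residue number) of its first member. Components covalently
#' linked into a polymer chain are reported separately as polymer-attached
#' (modified-residue-like) rather than as free ligands.
#'
#' @param assembly an `lk_assembly`.
#' @param components optional named list of `lk_component` records used to
#'   rebuild each bound molecule's chemical graph (atoms without a record
#'   contribute element-only atoms). Built-in residue/water definitions are
#'   always available.
#' @param merge_metal if `TRUE`, metal-coordination links also merge
#'   (default `FALSE`).
#' @return an `lk_bound_set`: list with `bound` (list of `lk_bound_molecule`)
#'   and `polymer_attached` (same shape, for flagged components).
#' @export
infer_bound_molecules <- function(assembly, components = list(),
                                  merge_metal = FALSE) {
  inst <- assembly$instances
  nodes <- which(inst$kind == "non-polymer")
  if (length(nodes) == 0) {
    return(structure(list(bound = list(), polymer_attached = list()),
                     class = "lk_bound_set"))
  }
  links <- assembly$links
  kinds <- "covalent"
  if (merge_metal) kinds <- c(kinds, "metal-coordination")
  el <- links[links$kind %in% kinds, , drop = FALSE]

  # edges among non-polymer instances
  both <- el$inst1 %in% nodes & el$inst2 %in% nodes
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = match(el$inst1[both], nodes),
                   to = match(el$inst2[both], nodes)),
    directed = FALSE,
    vertices = data.frame(name = seq_along(nodes)))
  comp <- igraph::components(g)$membership
  groups <- split(nodes, comp)

  # polymer attachment: any covalent link between a member and a polymer residue
  poly <- which(inst$kind == "polymer")
  attached_nodes <- unique(c(el$inst1[el$inst2 %in% poly], el$inst2[el$inst1 %in% poly]))

  # discovery order: (chain, resnum) of each group's first member
  first <- t(vapply(groups, function(g0) {
    o <- order(inst$chain[g0], inst$resnum[g0])
    c(inst$chain[g0[o[1]]], sprintf("%09d", inst$resnum[g0[o[1]]]))
  }, c("", "")))
  groups <- groups[order(first[, 1], first[, 2])]

  bound <- list(); attached <- list()
  for (g0 in groups) {
    bm <- build_bound_molecule(assembly, sort(g0), components)
    if (any(g0 %in% attached_nodes)) {
      bm$polymer_attached <- TRUE
      attached[[length(attached) + 1L]] <- bm
    } else {
      bound[[length(bound) + 1L]] <- bm
    }
  }
  for (i in seq_along(bound)) bound[[i]]$bmID <- paste0("bm", i)
  for (i in seq_along(attached)) attached[[i]]$bmID <- paste0("att", i)
  structure(list(bound = bound, polymer_attached = attached),
            class = "lk_bound_set")
}

#' @export
print.lk_bound_set <- function(x, ...) {
  cat(sprintf("<bound molecules: %d free, %d polymer-attached>\n",
              length(x$bound), length(x$polymer_attached)))
  for (bm in x$bound) {
    cat(sprintf("  %s: {%s}\n", bm$bmID,
                paste(sort(bm$component_multiset), collapse = ",")))
  }
  invisible(x)
}

# Assemble one bound molecule: atoms/bonds of every member instance (bonds
# from the component dictionary, matched by atom_id), fused at covalent
# link atoms.
build_bound_molecule <- function(assembly, instance_ids, components) {
  inst <- assembly$instances
  comp_lib <- c(components, builtin_components())
  atoms <- list(); bonds <- list()
  offset <- 0L
  index_of <- list()  # instance -> named map atom_id -> global index
  for (ii in instance_ids) {
    s <- assembly$sites[assembly$sites$instance == ii & assembly$sites$element != "H", , drop = FALSE]
    rec <- comp_lib[[inst$component_id[ii]]]
    at <- data.frame(atom_id = s$atom_id, element = s$element,
                     charge = 0L, x = s$x, y = s$y, z = s$z,
                     x2 = NA_real_, y2 = NA_real_, stringsAsFactors = FALSE)
    if (!is.null(rec)) {
      mi <- match(s$atom_id, rec$mol$atoms$atom_id)
      at$charge <- ifelse(is.na(mi), 0L, rec$mol$atoms$charge[mi])
      rb <- rec$mol$bonds
      if (nrow(rb)) {
        id1 <- rec$mol$atoms$atom_id[rb$a1]; id2 <- rec$mol$atoms$atom_id[rb$a2]
        k1 <- match(id1, s$atom_id); k2 <- match(id2, s$atom_id)
        keep <- !is.na(k1) & !is.na(k2)
        if (any(keep)) {
          bonds[[length(bonds) + 1L]] <- data.frame(
            a1 = k1[keep] + offset, a2 = k2[keep] + offset,
            order = rb$order[keep], aromatic = rb$aromatic[keep],
            dative = rb$dative[keep])
        }
      }
    }
    index_of[[as.character(ii)]] <- stats::setNames(seq_len(nrow(at)) + offset, at$atom_id)
    atoms[[length(atoms) + 1L]] <- at
    offset <- offset + nrow(at)
  }
  # fuse at covalent link atoms
  l <- assembly$links
  l <- l[l$kind == "covalent" & l$inst1 %in% instance_ids & l$inst2 %in% instance_ids, , drop = FALSE]
  for (k in seq_len(nrow(l))) {
    i1 <- unname(index_of[[as.character(l$inst1[k])]][l$atom1[k]])
    i2 <- unname(index_of[[as.character(l$inst2[k])]][l$atom2[k]])
    if (!is.na(i1) && !is.na(i2)) {
      bonds[[length(bonds) + 1L]] <- data.frame(a1 = i1, a2 = i2, order = 1L,
                                                aromatic = FALSE, dative = FALSE)
    }
  }
  allb <- if (length(bonds)) do.call(rbind, bonds) else NULL
  if (!is.null(allb)) {
    # canonicalize endpoints, then drop duplicates (a link may repeat or
    # mirror an existing bond)
    flip <- allb$a1 > allb$a2
    tmp <- allb$a1[flip]; allb$a1[flip] <- allb$a2[flip]; allb$a2[flip] <- tmp
    allb <- allb[!duplicated(paste(allb$a1, allb$a2)), , drop = FALSE]
  }
  mol <- molecule(do.call(rbind, atoms), allb)
  structure(list(
    bmID = NA_character_,
    instances = instance_ids,
    component_multiset = sort(inst$component_id[instance_ids]),
    mol = mol,
    polymer_attached = FALSE,
    identifier = NA_character_,
    inchikey = NA_character_), class = "lk_bound_molecule")
}

#' @export
print.lk_bound_molecule <- function(x, ...) {
  cat(sprintf("<%s: {%s}%s%s>\n", x$bmID,
              paste(x$component_multiset, collapse = ","),
              if (!is.na(x$identifier)) paste0(" = ", x$identifier) else "",
              if (x$polymer_attached) " [polymer-attached]" else ""))
  invisible(x)
}

# --- CLC registry -----------------------------------------------------------

#' Create a CLC identifier registry
#'
#' An ordered InChIKey -> identifier map handing out `CLC_` + zero-padded
#' 6-digit ordinals. Identifiers are never reassigned; looking up the same
#' InChIKey twice returns the same id. The registry is a mutable environment
#' so assignments persist across calls; use [save_registry()] /
#' [load_registry()] to persist it as JSON.
#'
#' @return an `lk_clc_registry`.
#' @export
clc_registry <- function() {
  e <- new.env(parent = emptyenv())
  e$map <- character()       # named: inchikey -> clc id
  e$next_ordinal <- 1L
  class(e) <- "lk_clc_registry"
  e
}

#' @export
print.lk_clc_registry <- function(x, ...) {
  cat(sprintf("<CLC registry: %d assignment(s), next ordinal %d>\n",
              length(x$map), x$next_ordinal))
  invisible(x)
}

registry_lookup <- function(registry, inchikey) {
  hit <- registry$map[inchikey]
  if (!is.na(hit)) return(unname(hit))
  id <- sprintf("CLC_%06d", registry$next_ordinal)
  registry$map[inchikey] <- id
  registry$next_ordinal <- registry$next_ordinal + 1L
  id
}

#' Persist a CLC registry as JSON
#' @param registry an `lk_clc_registry`.
#' @param path output file path.
#' @export
save_registry <- function(registry, path) {
  jsonlite::write_json(list(map = as.list(registry$map),
                            next_ordinal = registry$next_ordinal),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Load a CLC registry from JSON
#' @param path file written by [save_registry()].
#' @return an `lk_clc_registry`.
#' @export
load_registry <- function(path) {
  o <- jsonlite::fromJSON(path)
  r <- clc_registry()
  r$map <- unlist(o$map) %||% character()
  if (is.null(r$map)) r$map <- character()
  r$next_ordinal <- as.integer(o$next_ordinal)
  r
}

#' Assign the reference identifier of a bound molecule
#'
#' A single-component bound molecule keeps its component (CCD) identifier.
#' Multi-component molecules whose component multiset appears in the curated
#' reference table get that PRD identifier (curation takes precedence over
#' automatic assignment); otherwise the molecule's InChIKey is looked up in
#' the CLC registry, minting a new sequential `CLC_` id on first sight.
#'
#' @param bm an `lk_bound_molecule`.
#' @param registry an `lk_clc_registry` (updated in place).
#' @param prd_table optional named character vector: sorted component
#'   multiset key (components joined by `"+"`) -> PRD identifier.
#' @return the identifier string.
#' @export
assign_identifier <- function(bm, registry, prd_table = character()) {
  comps <- bm$component_multiset
  if (length(comps) == 1) return(comps)
  key <- paste(sort(comps), collapse = "+")
  if (key %in% names(prd_table)) return(unname(prd_table[key]))
  ik <- tryCatch(mol_inchikey(bm$mol), error = function(e) NULL)
  if (is.null(ik) || !nzchar(ik)) {
    cond <- structure(class = c("lk_unidentified_molecule", "error", "condition"),
                      list(message = paste0(
                        "could not compute InChIKey for bound molecule {",
                        paste(comps, collapse = ","), "}"),
                        call = sys.call(-1), component_multiset = comps))
    stop(cond)
  }
  registry_lookup(registry, ik)
}
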