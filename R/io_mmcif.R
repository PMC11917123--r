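# Minimal mmCIF-dialect reader/writer.
#
# Only the categories the toolkit interprets are materialized:
#   components : _chem_comp, _chem_comp_atom, _chem_comp_bond
#   assemblies : _atom_site, _struct_conn
# Every other category is tokenized and ignored. Values "?" and "." are
# missing-value markers. Parsing is insensitive to row order and to the
# order of columns inside a loop.

# --- generic tokenizer ------------------------------------------------------

cif_tokenize_line <- function(line) {
  # split one line into tokens respecting '...' and "..." quoting
  out <- character()
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1L
      while (j <= n && substr(line, j, j) != ch) j <- j + 1L
      out <- c(out, substr(line, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1L
      out <- c(out, substr(line, i, j - 1L))
      i <- j
    }
  }
  out
}

# Parse mmCIF text into a list: category name -> data.frame (columns = item
# names without the category prefix, all character). Single key-value items
# become one-row data.frames.
cif_parse <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- lines[trimws(lines) != ""]
  cats <- list()
  add_value <- function(cat, item, value) {
    df <- cats[[cat]]
    if (is.null(df)) df <- list()
    df[[item]] <- value
    cats[[cat]] <<- df
  }
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "data_") || startsWith(ln, "#")) { i <- i + 1L; next }
    if (ln == "loop_") {
      i <- i + 1L
      items <- character()
      while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
        items <- c(items, trimws(lines[i])); i <- i + 1L
      }
      rows <- list()
      while (i <= length(lines)) {
        l2 <- trimws(lines[i])
        if (l2 == "" || startsWith(l2, "_") || l2 == "loop_" ||
            startsWith(l2, "data_")) break
        toks <- cif_tokenize_line(lines[i])
        if (length(toks)) rows[[length(rows) + 1L]] <- toks
        i <- i + 1L
      }
      if (length(items) == 0) next
      cat <- sub("\\..*$", "", items[1])
      cols <- sub("^[^.]*\\.", "", items)
      bad <- which(vapply(rows, length, 0L) != length(items))
      if (length(bad)) {
        stop(sprintf("malformed mmCIF loop row %d in %s: expected %d values, got %d",
                     bad[1], cat, length(items), length(rows[[bad[1]]])))
      }
      mat <- do.call(rbind, rows)
      df <- as.data.frame(mat, stringsAsFactors = FALSE)
      names(df) <- cols
      # merge with an existing block of the same category
      if (!is.null(cats[[cat]]) && is.data.frame(cats[[cat]])) {
        common <- intersect(names(cats[[cat]]), names(df))
        cats[[cat]] <- rbind(cats[[cat]][common], df[common])
      } else {
        cats[[cat]] <- df
      }
    } else if (startsWith(ln, "_")) {
      toks <- cif_tokenize_line(ln)
      item <- toks[1]
      val <- if (length(toks) >= 2) paste(toks[-1], collapse = " ") else NA_character_
      cat <- sub("\\..*$", "", item)
      col <- sub("^[^.]*\\.", "", item)
      if (is.null(cats[[cat]]) || !is.data.frame(cats[[cat]])) {
        add_value(cat, col, val)
      }
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  lapply(cats, function(x) if (is.data.frame(x)) x else as.data.frame(x, stringsAsFactors = FALSE))
}

cif_missing <- function(x) is.na(x) | x %in% c("?", ".")

cif_quote <- function(x) {
  x <- as.character(x)
  needs <- grepl("[ '\"]", x) | x == ""
  x[needs] <- paste0('"', x[needs], '"')
  x
}

# --- component records ------------------------------------------------------

#' Create a chemical-component record
#'
#' A component record couples a short component identifier (the dictionary
#' id, e.g. `"ATP"`) and free-text name with the component's molecular graph
#' and optional precomputed descriptors.
#'
#' @param component_id short identifier token (stored uppercase).
#' @param mol an [molecule()] whose atoms carry `atom_id` names.
#' @param name free-text component name.
#' @param descriptors optional named list (smiles/inchi/inchikey).
#' @return an object of class `lk_component`.
#' @export
component_record <- function(component_id, mol, name = component_id,
                             descriptors = NULL) {
  stopifnot(inherits(mol, "lk_mol"))
  if (any(is.na(mol$atoms$atom_id))) stop("component atoms must carry atom_id names")
  if (anyDuplicated(mol$atoms$atom_id)) stop("duplicate atom_id within component")
  structure(list(component_id = toupper(component_id), name = name,
                 mol = mol, descriptors = descriptors),
            class = "lk_component")
}

#' @export
print.lk_component <- function(x, ...) {
  cat(sprintf("<component %s (%s): %d atoms, %d bonds>\n", x$component_id,
              x$name, nrow(x$mol$atoms), nrow(x$mol$bonds)))
  invisible(x)
}

order_to_cif <- c(`1` = "SING", `2` = "DOUB", `3` = "TRIP")
cif_to_order <- c(SING = 1L, DOUB = 2L, TRIP = 3L, AROM = 1L)

#' Read a component definition from mmCIF-dialect text
#'
#' Interprets the `_chem_comp`, `_chem_comp_atom` and `_chem_comp_bond`
#' categories; everything else in the block is ignored. Missing-value
#' markers (`?`, `.`) map to absent fields and charges default to 0.
#'
#' @param text character scalar (or vector of lines) with one component block.
#' @return an `lk_component`.
#' @export
read_component <- function(text) {
  if (length(text) > 1) text <- paste(text, collapse = "\n")
  cats <- cif_parse(text)
  at <- cats[["_chem_comp_atom"]]
  if (is.null(at)) stop("no _chem_comp_atom table in component block")
  comp_id <- if (!is.null(cats[["_chem_comp"]]$id)) cats[["_chem_comp"]]$id[1] else
    if (!is.null(at$comp_id)) at$comp_id[1] else "UNL"
  comp_name <- if (!is.null(cats[["_chem_comp"]]$name)) cats[["_chem_comp"]]$name[1] else comp_id
  num <- function(x) ifelse(cif_missing(x), NA_real_, suppressWarnings(as.numeric(x)))
  charge <- if (is.null(at$charge)) 0L else ifelse(cif_missing(at$charge), 0L,
                                                  suppressWarnings(as.integer(at$charge)))
  atoms <- data.frame(
    atom_id = at$atom_id,
    element = at$type_symbol,
    charge = charge,
    x = if (is.null(at$model_Cartn_x)) NA_real_ else num(at$model_Cartn_x),
    y = if (is.null(at$model_Cartn_y)) NA_real_ else num(at$model_Cartn_y),
    z = if (is.null(at$model_Cartn_z)) NA_real_ else num(at$model_Cartn_z),
    x2 = if (is.null(at$x2d)) NA_real_ else num(at$x2d),
    y2 = if (is.null(at$y2d)) NA_real_ else num(at$y2d),
    stringsAsFactors = FALSE)
  bd <- cats[["_chem_comp_bond"]]
  bonds <- NULL
  if (!is.null(bd) && nrow(bd)) {
    i1 <- match(bd$atom_id_1, atoms$atom_id)
    i2 <- match(bd$atom_id_2, atoms$atom_id)
    if (anyNA(i1) || anyNA(i2)) {
      missing_id <- c(bd$atom_id_1[is.na(i1)], bd$atom_id_2[is.na(i2)])[1]
      stop(sprintf("bond references unknown atom_id '%s'", missing_id))
    }
    ord <- toupper(bd$value_order %||% rep("SING", nrow(bd)))
    unknown <- !ord %in% names(cif_to_order)
    if (any(unknown)) stop("unknown bond order: ", ord[unknown][1])
    bonds <- data.frame(a1 = i1, a2 = i2, order = unname(cif_to_order[ord]),
                        aromatic = ord == "AROM")
  }
  desc <- NULL
  dsc <- cats[["_pdbx_chem_comp_descriptor"]]
  if (!is.null(dsc) && all(c("type", "descriptor") %in% names(dsc))) {
    desc <- as.list(stats::setNames(dsc$descriptor, tolower(dsc$type)))
  }
  component_record(comp_id, molecule(atoms, bonds, name = comp_id),
                   name = comp_name, descriptors = desc)
}

#' Write a component record as component-mmCIF text
#' @param record an `lk_component`.
#' @return character scalar of mmCIF text.
#' @export
write_component_cif <- function(record) {
  a <- record$mol$atoms; b <- record$mol$bonds
  fmt <- function(x) ifelse(is.na(x), "?", sprintf("%.4f", x))
  has2d <- any(!is.na(a$x2))
  hdr <- c(sprintf("data_%s", record$component_id),
           "#",
           sprintf("_chem_comp.id %s", record$component_id),
           sprintf("_chem_comp.name %s", cif_quote(record$name)),
           "#", "loop_",
           "_chem_comp_atom.comp_id", "_chem_comp_atom.atom_id",
           "_chem_comp_atom.type_symbol", "_chem_comp_atom.charge",
           "_chem_comp_atom.model_Cartn_x", "_chem_comp_atom.model_Cartn_y",
           "_chem_comp_atom.model_Cartn_z",
           if (has2d) c("_chem_comp_atom.x2d", "_chem_comp_atom.y2d"))
  atom_rows <- paste(record$component_id, a$atom_id, a$element, a$charge,
                     fmt(a$x), fmt(a$y), fmt(a$z),
                     if (has2d) paste(fmt(a$x2), fmt(a$y2)) else "")
  out <- c(hdr, trimws(atom_rows, which = "right"))
  if (nrow(b)) {
    ord <- ifelse(b$aromatic, "AROM", order_to_cif[as.character(b$order)])
    out <- c(out, "#", "loop_",
             "_chem_comp_bond.comp_id", "_chem_comp_bond.atom_id_1",
             "_chem_comp_bond.atom_id_2", "_chem_comp_bond.value_order",
             paste(record$component_id, a$atom_id[b$a1], a$atom_id[b$a2], ord))
  }
  if (!is.null(record$descriptors) && length(record$descriptors)) {
    out <- c(out, "#", "loop_",
             "_pdbx_chem_comp_descriptor.comp_id",
             "_pdbx_chem_comp_descriptor.type",
             "_pdbx_chem_comp_descriptor.descriptor",
             paste(record$component_id, toupper(names(record$descriptors)),
                   cif_quote(unlist(record$descriptors))))
  }
  paste(c(out, "#"), collapse = "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- assemblies -------------------------------------------------------------

#' Standard polymer component identifiers
#'
#' The 20 canonical amino acids plus the standard nucleotides; atom-site
#' instances whose component id appears in this list are classified as
#' polymer residues by [read_assembly()].
#' @return character vector of component ids.
#' @export
default_polymer_components <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
    "A", "C", "G", "U", "DA", "DC", "DG", "DT")
}

#' Create an assembly structure
#'
#' Atom sites grouped into component instances (polymer residue /
#' non-polymer / water) plus typed inter-instance links. This is the input
#' to bound-molecule inference and contact typing.
#'
#' @param instances data.frame: `component_id`, `chain`, `resnum`, `kind`
#'   (one of `"polymer"`, `"non-polymer"`, `"water"`).
#' @param sites data.frame: `instance` (row index into `instances`),
#'   `atom_id`, `element`, `x`, `y`, `z` and optionally `parent` (atom_id of
#'   the heavy atom a placed hydrogen belongs to).
#' @param links data.frame (may be empty): `inst1`, `atom1`, `inst2`,
#'   `atom2`, `kind` (`"covalent"`, `"metal-coordination"` or `"other"`).
#' @return an object of class `lk_assembly`.
#' @export
assembly_structure <- function(instances, sites, links = NULL) {
  instances <- as.data.frame(instances, stringsAsFactors = FALSE)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (is.null(links) || NROW(links) == 0) {
    links <- data.frame(inst1 = integer(), atom1 = character(),
                        inst2 = integer(), atom2 = character(),
                        kind = character(), stringsAsFactors = FALSE)
  }
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  instances$resnum <- as.integer(instances$resnum)
  stopifnot(all(instances$kind %in% c("polymer", "non-polymer", "water")))
  key <- paste(instances$component_id, instances$chain, instances$resnum)
  if (anyDuplicated(key)) stop("duplicate instance key: ", key[duplicated(key)][1])
  if (nrow(sites) == 0) stop("assembly has no atom sites")
  if (is.null(sites$parent)) sites$parent <- NA_character_
  sites$instance <- as.integer(sites$instance)
  if (any(sites$instance < 1 | sites$instance > nrow(instances))) {
    stop("atom site references unknown instance")
  }
  if (any(!is.finite(sites$x) | !is.finite(sites$y) | !is.finite(sites$z))) {
    stop("non-finite atom-site coordinates")
  }
  if (nrow(links)) {
    links$inst1 <- as.integer(links$inst1); links$inst2 <- as.integer(links$inst2)
    ok <- function(inst, atom) {
      inst >= 1 & inst <= nrow(instances) &
        mapply(function(i, a) any(sites$instance == i & sites$atom_id == a), inst, atom)
    }
    if (!all(ok(links$inst1, links$atom1)) || !all(ok(links$inst2, links$atom2))) {
      stop("link endpoint references a missing instance/atom")
    }
    unknown <- !links$kind %in% c("covalent", "metal-coordination", "other")
    if (any(unknown)) {
      warning("unknown link kind recorded as 'other': ",
              paste(unique(links$kind[unknown]), collapse = ", "))
      links$kind[unknown] <- "other"
    }
  }
  structure(list(instances = instances, sites = sites, links = links),
            class = "lk_assembly")
}

#' @export
print.lk_assembly <- function(x, ...) {
  k <- table(factor(x$instances$kind, c("polymer", "non-polymer", "water")))
  cat(sprintf("<assembly: %d sites; %d polymer / %d non-polymer / %d water instances; %d links>\n",
              nrow(x$sites), k[["polymer"]], k[["non-polymer"]], k[["water"]],
              nrow(x$links)))
  invisible(x)
}

conn_type_map <- c(covale = "covalent", metalc = "metal-coordination",
                   hydrog = "other", disulf = "covalent")

#' Read an assembly from mmCIF-dialect text
#'
#' Interprets `_atom_site` (required) and `_struct_conn` (optional);
#' instances are partitioned into polymer / non-polymer / water by component
#' identity against `polymer_components`, waters by the `HOH`/`WAT`/`DOD`
#' ids. Unknown `_struct_conn` types are kept as kind `"other"` with a
#' warning.
#'
#' @param text character scalar or vector of lines.
#' @param polymer_components component ids treated as polymer residues.
#' @return an `lk_assembly`.
#' @export
read_assembly <- function(text, polymer_components = default_polymer_components()) {
  if (length(text) > 1) text <- paste(text, collapse = "\n")
  cats <- cif_parse(text)
  at <- cats[["_atom_site"]]
  if (is.null(at) || nrow(at) == 0) stop("assembly contains no atom sites")
  chain <- at$label_asym_id %||% at$auth_asym_id
  seqid <- at$label_seq_id %||% at$auth_seq_id
  seqid <- ifelse(cif_missing(seqid), "0", seqid)
  comp <- at$label_comp_id
  key <- paste(comp, chain, seqid)
  uk <- !duplicated(key)
  instances <- data.frame(
    component_id = comp[uk], chain = chain[uk],
    resnum = as.integer(seqid[uk]),
    kind = ifelse(comp[uk] %in% c("HOH", "WAT", "DOD"), "water",
                  ifelse(comp[uk] %in% polymer_components, "polymer", "non-polymer")),
    stringsAsFactors = FALSE)
  inst_of <- match(key, key[uk])
  sites <- data.frame(
    instance = inst_of,
    atom_id = at$label_atom_id,
    element = at$type_symbol,
    x = as.numeric(at$Cartn_x), y = as.numeric(at$Cartn_y),
    z = as.numeric(at$Cartn_z), stringsAsFactors = FALSE)
  links <- NULL
  sc <- cats[["_struct_conn"]]
  if (!is.null(sc) && nrow(sc)) {
    ikey <- paste(instances$component_id, instances$chain, instances$resnum)
    i1 <- match(paste(sc$ptnr1_label_comp_id, sc$ptnr1_label_asym_id, sc$ptnr1_label_seq_id), ikey)
    i2 <- match(paste(sc$ptnr2_label_comp_id, sc$ptnr2_label_asym_id, sc$ptnr2_label_seq_id), ikey)
    if (anyNA(i1) || anyNA(i2)) stop("_struct_conn references a missing instance")
    kind <- unname(conn_type_map[tolower(sc$conn_type_id)])
    kind[is.na(kind)] <- sc$conn_type_id[is.na(kind)]  # validated downstream
    links <- data.frame(inst1 = i1, atom1 = sc$ptnr1_label_atom_id,
                        inst2 = i2, atom2 = sc$ptnr2_label_atom_id,
                        kind = kind, stringsAsFactors = FALSE)
  }
  assembly_structure(instances, sites, links)
}

#' Write an assembly as mmCIF-dialect text
#' @param assembly an `lk_assembly`.
#' @param entry_id data-block name.
#' @return character scalar of mmCIF text.
#' @export
write_assembly <- function(assembly, entry_id = "entry") {
  inst <- assembly$instances; s <- assembly$sites
  grp <- ifelse(inst$kind[s$instance] == "polymer", "ATOM", "HETATM")
  out <- c(sprintf("data_%s", entry_id), "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.label_atom_id", "_atom_site.label_comp_id",
           "_atom_site.label_asym_id", "_atom_site.label_seq_id",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           paste(grp, seq_len(nrow(s)), s$element, s$atom_id,
                 inst$component_id[s$instance], inst$chain[s$instance],
                 inst$resnum[s$instance],
                 sprintf("%.3f", s$x), sprintf("%.3f", s$y), sprintf("%.3f", s$z)))
  if (nrow(assembly$links)) {
    l <- assembly$links
    rev_map <- c(covalent = "covale", `metal-coordination` = "metalc", other = "other")
    out <- c(out, "#", "loop_",
             "_struct_conn.id", "_struct_conn.conn_type_id",
             "_struct_conn.ptnr1_label_comp_id", "_struct_conn.ptnr1_label_asym_id",
             "_struct_conn.ptnr1_label_seq_id", "_struct_conn.ptnr1_label_atom_id",
             "_struct_conn.ptnr2_label_comp_id", "_struct_conn.ptnr2_label_asym_id",
             "_struct_conn.ptnr2_label_seq_id", "_struct_conn.ptnr2_label_atom_id",
             paste(paste0("conn", seq_len(nrow(l))), rev_map[l$kind],
                   inst$component_id[l$inst1], inst$chain[l$inst1],
                   inst$resnum[l$inst1], l$atom1,
                   inst$component_id[l$inst2], inst$chain[l$inst2],
                   inst$resnum[l$inst2], l$atom2))
  }
  paste(c(out, "#"), collapse = "\n")
}
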