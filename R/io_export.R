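# Chemical-format export: SDF V2000, XYZ, JSON, component-mmCIF, plus an
# SDF reader used by the command-line front end and the fixtures.

mol_to_molblock <- function(m, title = m$name %||% "", dim = c("3D", "2D")) {
  dim <- match.arg(dim)
  a <- m$atoms; b <- m$bonds
  if (dim == "3D") {
    if (any(is.na(a$x) | is.na(a$y) | is.na(a$z))) {
      stop("molecule lacks 3D coordinates required for SDF/molblock export")
    }
    xyz <- cbind(a$x, a$y, a$z)
  } else {
    if (any(is.na(a$x2) | is.na(a$y2))) stop("molecule lacks 2D coordinates")
    xyz <- cbind(a$x2, a$y2, 0)
  }
  hdr <- c(substr(title, 1, 80), sprintf(" ligandkit%s", if (dim == "3D") "        3D" else "        2D"), "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   xyz[, 1], xyz[, 2], xyz[, 3], a$element)
  ord <- ifelse(b$aromatic, 4L, b$order)
  bonds <- if (nrow(b)) sprintf("%3d%3d%3d  0", b$a1, b$a2, ord) else character()
  chg <- which(a$charge != 0)
  props <- character()
  if (length(chg)) {
    # M CHG lines hold at most 8 (atom, charge) pairs each
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      props <- c(props, paste0("M  CHG", sprintf("%3d", length(grp)),
                               paste0(sprintf("%4d%4d", grp, a$charge[grp]), collapse = "")))
    }
  }
  paste(c(hdr, counts, atoms, bonds, props, "M  END"), collapse = "\n")
}

#' Export a molecule or component in a standard chemical format
#'
#' @param record an `lk_component` or bare `lk_mol`.
#' @param format one of `"sdf"`, `"xyz"`, `"json"`, `"cif"` (component-mmCIF).
#' @return character scalar with the serialized record.
#' @details SDF and XYZ require 3D coordinates. JSON is loss-less on all
#'   record fields and can be read back with [read_component_json()].
#' @export
write_component <- function(record, format = c("sdf", "xyz", "json", "cif")) {
  format <- match.arg(tolower(format), c("sdf", "xyz", "json", "cif"))
  if (inherits(record, "lk_mol")) {
    record <- component_record(
      if (is.null(record$name)) "UNL" else record$name,
      ensure_atom_ids(record))
  }
  stopifnot(inherits(record, "lk_component"))
  m <- record$mol
  switch(format,
    sdf = paste0(mol_to_molblock(m, title = record$component_id), "\n$$$$\n"),
    xyz = {
      a <- m$atoms
      if (any(is.na(a$x))) stop("molecule lacks 3D coordinates required for XYZ export")
      paste(c(nrow(a), record$component_id,
              sprintf("%-3s %12.6f %12.6f %12.6f", a$element, a$x, a$y, a$z)),
            collapse = "\n")
    },
    json = jsonlite::toJSON(list(
      component_id = record$component_id, name = record$name,
      atoms = m$atoms, bonds = m$bonds,
      descriptors = record$descriptors), dataframe = "columns",
      auto_unbox = TRUE, digits = NA, null = "null"),
    cif = write_component_cif(record))
}

# give atoms positional atom_id names when the source had none
ensure_atom_ids <- function(m) {
  if (any(is.na(m$atoms$atom_id))) {
    el <- m$atoms$element
    idx <- stats::ave(seq_along(el), el, FUN = seq_along)
    m$atoms$atom_id <- ifelse(is.na(m$atoms$atom_id),
                              paste0(toupper(el), idx), m$atoms$atom_id)
  }
  m
}

#' Read a component back from its JSON export
#' @param text JSON text produced by `write_component(..., "json")`.
#' @return an `lk_component`.
#' @export
read_component_json <- function(text) {
  o <- jsonlite::fromJSON(text)
  atoms <- as.data.frame(o$atoms, stringsAsFactors = FALSE)
  bonds <- if (length(o$bonds) && NROW(as.data.frame(o$bonds))) as.data.frame(o$bonds) else NULL
  desc <- if (is.null(o$descriptors) || length(o$descriptors) == 0) NULL else as.list(o$descriptors)
  component_record(o$component_id, molecule(atoms, bonds, name = o$component_id),
                   name = o$name, descriptors = desc)
}

#' Read molecules from SDF (V2000) text
#' @param text SDF text (one or more records separated by `$$$$`).
#' @return list of `lk_mol` (coordinates become NA when every atom sits at
#'   the origin, i.e. the writer had no geometry).
#' @export
read_sdf <- function(text) {
  if (length(text) > 1) text <- paste(text, collapse = "\n")
  recs <- strsplit(text, "\\$\\$\\$\\$")[[1]]
  recs <- recs[vapply(recs, function(r) grepl("V2000", r), TRUE)]
  lapply(recs, read_molblock)
}

read_molblock <- function(block) {
  lines <- unlist(strsplit(block, "\n", fixed = TRUE))
  ci <- grep("V2000", lines)[1]            # counts line anchors the header
  if (is.na(ci)) stop("not a V2000 molblock")
  title <- if (ci >= 4) trimws(lines[ci - 3]) else ""
  counts <- lines[ci]
  na <- as.integer(substr(counts, 1, 3)); nb <- as.integer(substr(counts, 4, 6))
  al <- lines[(ci + 1):(ci + na)]
  atoms <- data.frame(
    element = trimws(substr(al, 32, 34)),
    x = as.numeric(substr(al, 1, 10)),
    y = as.numeric(substr(al, 11, 20)),
    z = as.numeric(substr(al, 21, 30)),
    stringsAsFactors = FALSE)
  bonds <- NULL
  if (nb > 0) {
    bl <- lines[(ci + na + 1):(ci + na + nb)]
    ord <- as.integer(substr(bl, 7, 9))
    bonds <- data.frame(a1 = as.integer(substr(bl, 1, 3)),
                        a2 = as.integer(substr(bl, 4, 6)),
                        order = ifelse(ord == 4L, 1L, ord),
                        aromatic = ord == 4L)
  }
  charges <- integer(na)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    k <- toks[1]
    for (p in seq_len(k)) charges[toks[2 * p]] <- toks[2 * p + 1]
  }
  atoms$charge <- charges
  if (all(abs(atoms$x) < 1e-9 & abs(atoms$y) < 1e-9 & abs(atoms$z) < 1e-9)) {
    atoms$x <- atoms$y <- atoms$z <- NA_real_
  }
  molecule(atoms, bonds, name = if (nzchar(title)) title else NULL)
}
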