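# Chemical descriptors. Formula and molecular weight come from the graph
# (implicit hydrogens completed against the valence table); canonical
# SMILES, InChI and InChIKey are generated with OpenBabel's `obabel` CLI,
# which perceives stereo from 3D coordinates when present.

obabel_available <- function() nzchar(Sys.which("obabel"))

obabel_convert <- function(input, in_fmt, out_fmt, args = character()) {
  if (!obabel_available()) {
    stop("the 'obabel' executable is required for ", out_fmt,
         " generation but was not found on PATH")
  }
  fin <- tempfile(fileext = paste0(".", in_fmt))
  on.exit(unlink(fin), add = TRUE)
  writeLines(input, fin)
  out <- suppressWarnings(system2("obabel", c(fin, paste0("-o", out_fmt), args),
                                  stdout = TRUE, stderr = FALSE))
  out <- out[nzchar(trimws(out))]
  if (length(out) == 0) stop("obabel produced no ", out_fmt, " output")
  trimws(out[1])
}

mol_to_obabel_input <- function(m) {
  # prefer a 3D molblock (keeps stereo); fall back to a coordinate-free one
  has3d <- nrow(m$atoms) > 0 && all(!is.na(m$atoms$x))
  if (!has3d) { m$atoms$x <- 0; m$atoms$y <- 0; m$atoms$z <- 0 }
  mol_to_molblock(m)
}

#' Compute chemical descriptors for a molecule
#'
#' @param m a sanitized `lk_mol`.
#' @param vt valence table used to complete implicit hydrogens.
#' @return an `lk_descriptors` list: `formula` (Hill order), `weight`
#'   (g/mol), `smiles` (canonical), `inchi`, `inchikey`.
#' @examples
#' \dontrun{
#' compute_descriptors(fixture_mol("water"))
#' }
#' @export
compute_descriptors <- function(m, vt = default_valence_table()) {
  if (nrow(m$atoms) == 0) stop("empty molecule")
  inp <- mol_to_obabel_input(m)
  first_field <- function(x) strsplit(x, "[ \t]")[[1]][1]
  structure(list(
    formula = molecular_formula(m, vt),
    weight = molecular_weight(m, vt),
    smiles = first_field(obabel_convert(inp, "sdf", "can")),
    inchi = first_field(obabel_convert(inp, "sdf", "inchi")),
    inchikey = first_field(obabel_convert(inp, "sdf", "inchikey"))
  ), class = "lk_descriptors")
}

#' @export
print.lk_descriptors <- function(x, ...) {
  cat(sprintf("%s  MW %.2f\n  SMILES   %s\n  InChI    %s\n  InChIKey %s\n",
              x$formula, x$weight, x$smiles, x$inchi, x$inchikey))
  invisible(x)
}

# InChIKey of a molecule (helper used by identifier assignment).
mol_inchikey <- function(m) {
  obabel_convert(mol_to_obabel_input(m), "sdf", "inchikey")
}

mol_inchi <- function(m) {
  strsplit(obabel_convert(mol_to_obabel_input(m), "sdf", "inchi"), "[ \t]")[[1]][1]
}

# Canonical SMILES (helper; empty molecule -> "").
mol_cansmiles <- function(m) {
  if (nrow(m$atoms) == 0) return("")
  strsplit(obabel_convert(mol_to_obabel_input(m), "sdf", "can"), "[ \t]")[[1]][1]
}

#' Build a molecule from a SMILES string
#'
#' Materializes the heavy-atom graph via OpenBabel (kekulized bond orders,
#' formal charges preserved). Coordinates are not generated.
#'
#' @param smiles a SMILES string.
#' @param name optional molecule name.
#' @return an `lk_mol`.
#' @export
mol_from_smiles <- function(smiles, name = NULL) {
  if (!obabel_available()) stop("the 'obabel' executable is required to parse SMILES")
  fin <- tempfile(fileext = ".smi"); on.exit(unlink(fin), add = TRUE)
  writeLines(smiles, fin)
  out <- suppressWarnings(system2("obabel", c(fin, "-osdf"), stdout = TRUE, stderr = FALSE))
  if (!any(grepl("V2000", out))) stop("could not parse SMILES: ", smiles)
  m <- read_sdf(paste(out, collapse = "\n"))[[1]]
  m$name <- name
  m
}

# InChI layer decomposition: returns list(formula, connect, hydrogens, stereo)
inchi_layers <- function(inchi) {
  body <- sub("^InChI=1S?/", "", inchi)
  parts <- strsplit(body, "/", fixed = TRUE)[[1]]
  formula <- parts[1]
  get <- function(prefix) {
    hit <- grep(paste0("^", prefix), parts[-1], value = TRUE)
    if (length(hit)) hit[1] else ""
  }
  list(formula = formula,
       connect = get("c"),
       hydrogens = get("h"),
       stereo = paste(get("b"), get("t"), get("m"), get("s"), sep = ";"))
}
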