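# Periodic-table data used across the toolkit: symbols, standard atomic
# weights (g/mol), van der Waals radii (Angstrom, Bondi/Alvarez values for
# the elements the contact rules touch), and a metal flag.
periodic_table <- local({
  df <- data.frame(
    symbol = c("H", "B", "C", "N", "O", "F", "Na", "Mg", "Al", "Si", "P",
               "S", "Cl", "K", "Ca", "Cr", "Mn", "Fe", "Co", "Ni", "Cu",
               "Zn", "As", "Se", "Br", "Mo", "Cd", "I", "W", "Hg", "Li",
               "*"),  # "*" = attachment-point marker used by fragmentation
    weight = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998, 22.990, 24.305,
               26.982, 28.085, 30.974, 32.06, 35.45, 39.098, 40.078, 51.996,
               54.938, 55.845, 58.933, 58.693, 63.546, 65.38, 74.922, 78.971,
               79.904, 95.95, 112.414, 126.904, 183.84, 200.592, 6.94, 0),
    vdw = c(1.20, 1.92, 1.70, 1.55, 1.52, 1.47, 2.27, 1.73, 1.84, 2.10, 1.80,
            1.80, 1.75, 2.75, 2.31, 2.00, 2.00, 2.00, 2.00, 1.63, 1.40,
            1.39, 1.85, 1.90, 1.85, 2.00, 1.58, 1.98, 2.00, 1.55, 1.82, 0),
    metal = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE,
              FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
              TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE,
              TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  rownames(df) <- df$symbol
  df
})

is_metal <- function(element) {
  m <- periodic_table[element, "metal"]
  m[is.na(m)] <- FALSE
  m
}

atomic_weight <- function(element) periodic_table[element, "weight"]

vdw_radius <- function(element) {
  r <- periodic_table[element, "vdw"]
  r[is.na(r)] <- 2.0
  r
}

#' Default valence table
#'
#' Allowed total bond-order sums per (element, formal charge). Used by
#' [sanitize()] to detect over-valent atoms and by the implicit-hydrogen
#' model. Metals are not listed: they form coordination (dative) bonds and
#' are exempt from valence checks. The table is an ordinary nested list and
#' can be edited or replaced wholesale by the caller.
#'
#' @return named list: element -> named list mapping formal charge (as
#'   character) to an integer vector of allowed valences.
#' @export
default_valence_table <- function() {
  list(
    H  = list(`0` = 1L),
    B  = list(`0` = 3L, `-1` = 4L),
    C  = list(`0` = 4L, `1` = 3L, `-1` = 3L),
    N  = list(`0` = 3L, `1` = 4L, `-1` = 2L),
    O  = list(`0` = 2L, `1` = 3L, `-1` = 1L),
    P  = list(`0` = c(3L, 5L), `1` = 4L),
    S  = list(`0` = c(2L, 4L, 6L), `1` = 3L, `-1` = 1L),
    Se = list(`0` = c(2L, 4L, 6L)),
    F  = list(`0` = 1L, `-1` = 0L),
    Cl = list(`0` = 1L, `-1` = 0L),
    Br = list(`0` = 1L, `-1` = 0L),
    I  = list(`0` = 1L, `-1` = 0L),
    Si = list(`0` = 4L),
    As = list(`0` = c(3L, 5L))
  )
}

allowed_valences <- function(vt, element, charge) {
  e <- vt[[element]]
  if (is.null(e)) return(NULL)
  v <- e[[as.character(charge)]]
  if (is.null(v)) integer(0) else v
}

# Implicit hydrogen count per atom: smallest allowed valence that is >= the
# explicit bond-order sum, minus that sum. Metals, atoms of unknown
# valence, and explicit hydrogens get 0.
implicit_hydrogens <- function(m, vt = default_valence_table()) {
  vs <- valence_sums(m)
  n <- nrow(m$atoms)
  h <- integer(n)
  for (i in seq_len(n)) {
    el <- m$atoms$element[i]
    if (el == "H" || is_metal(el)) next
    av <- allowed_valences(vt, el, m$atoms$charge[i])
    if (is.null(av) || length(av) == 0) next
    ok <- av[av >= vs[i]]
    if (length(ok)) h[i] <- as.integer(min(ok) - ceiling(vs[i]))
  }
  # explicit hydrogens already bonded reduce nothing further: bond sums
  # include them, so the formula above is already net of explicit H.
  h
}

#' Molecular formula in Hill order
#'
#' Counts explicit atoms plus implicit hydrogens completed against the
#' valence table. Hill convention: C first, H second, all other elements
#' alphabetically (no C: all elements alphabetical).
#'
#' @param m an `lk_mol`.
#' @param vt valence table, see [default_valence_table()].
#' @return a single string such as `"C6H6"` or `"H2O"`.
#' @export
molecular_formula <- function(m, vt = default_valence_table()) {
  if (nrow(m$atoms) == 0) stop("empty molecule")
  counts <- table(m$atoms$element)
  nh <- sum(implicit_hydrogens(m, vt)) + if ("H" %in% names(counts)) counts[["H"]] else 0
  counts <- counts[names(counts) != "H"]
  els <- names(counts)
  if ("C" %in% els) {
    ord <- c("C", if (nh > 0) "H", sort(setdiff(els, "C")))
  } else {
    els2 <- c(els, if (nh > 0) "H")
    ord <- sort(unique(els2))
  }
  paste0(vapply(ord, function(e) {
    k <- if (e == "H") nh else counts[[e]]
    paste0(e, if (k > 1) k else "")
  }, ""), collapse = "")
}

# Molecular weight (g/mol), implicit hydrogens included.
molecular_weight <- function(m, vt = default_valence_table()) {
  sum(atomic_weight(m$atoms$element)) + 1.008 * sum(implicit_hydrogens(m, vt))
}

# Element count vector (implicit H included), for formula-conservation checks.
element_counts <- function(m, vt = default_valence_table()) {
  cnt <- table(m$atoms$element)
  out <- as.integer(cnt); names(out) <- names(cnt)
  nh <- sum(implicit_hydrogens(m, vt))
  if (nh > 0) out["H"] <- (if ("H" %in% names(out)) out[["H"]] else 0L) + nh
  out[order(names(out))]
}
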