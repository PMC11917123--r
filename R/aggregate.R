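#' Aggregate per-atom interaction frequencies
#'
#' From a contact table spanning one or many entries, computes the relative
#' interaction frequency (%) of every ligand atom with respect to the
#' ligand's total interactions, and of every (ligand atom, amino-acid type)
#' pair with respect to that amino acid's total interactions. An optional
#' subtype filter restricts the contacts before counting.
#'
#' @param contacts an `lk_contacts` data.frame (or any data.frame with
#'   `lig_atom`, `env_comp`, `subtype` columns); concatenate entries with
#'   `rbind` before aggregating.
#' @param filter optional character vector of subtypes to keep (e.g.
#'   `c("hbond")`).
#' @return an `lk_frequency_table`: `atom_pct` (named percentages summing to
#'   100), `atom_aa_pct` (matrix atoms x amino acids, each column summing to
#'   100), `counts` (raw per-atom counts), `filter`.
#' @export
aggregate_atom_frequencies <- function(contacts, filter = NULL) {
  if (!is.null(filter)) contacts <- contacts[contacts$subtype %in% filter, , drop = FALSE]
  if (nrow(contacts) == 0) {
    return(structure(list(atom_pct = numeric(0),
                          atom_aa_pct = matrix(numeric(0), 0, 0),
                          counts = integer(0), filter = filter),
                     class = "lk_frequency_table"))
  }
  counts <- table(contacts$lig_atom)
  atom_pct <- 100 * as.numeric(counts) / sum(counts)
  names(atom_pct) <- names(counts)
  cross <- table(contacts$lig_atom, contacts$env_comp)
  col_tot <- colSums(cross)
  atom_aa_pct <- sweep(cross, 2, ifelse(col_tot > 0, col_tot, 1), "/") * 100
  structure(list(atom_pct = atom_pct,
                 atom_aa_pct = as.matrix(atom_aa_pct),
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 filter = filter),
            class = "lk_frequency_table")
}

#' @export
print.lk_frequency_table <- function(x, ...) {
  cat(sprintf("<interaction frequencies: %d atom(s)%s>\n", length(x$atom_pct),
              if (!is.null(x$filter)) paste0(", filter ", paste(x$filter, collapse = "/")) else ""))
  if (length(x$atom_pct)) print(round(x$atom_pct, 2))
  invisible(x)
}

#' Default ligand-quality thresholds
#'
#' Geometric Z-scores above 2.0 (absolute) are outliers; torsion angles are
#' flagged when their local density measure falls below 5%; rings when their
#' torsion-angle RMSD exceeds 60 degrees; density fit is flagged for RSCC
#' below 0.8 or RSR above 0.4. All boundaries are strict, and the RMSZ of a
#' well-refined ligand ideally lies in [0, 1].
#' @return named list of thresholds.
#' @export
default_validation_thresholds <- function() {
  list(z_outlier = 2.0, torsion_density_min = 5, ring_rmsd_max = 60,
       rscc_min = 0.8, rsr_max = 0.4, rmsz_ideal = c(0, 1))
}

#' Flag geometric quality issues of a ligand
#'
#' Z-scores are consumed as supplied (computed upstream against
#' small-molecule reference geometry); this function applies the outlier
#' rule |Z| > 2.0 (strict), summarizes each category by its RMSZ
#' (sqrt(mean(Z^2))), and applies the torsion-density and ring-RMSD flags.
#'
#' @param zscores named list of numeric vectors per feature category
#'   (e.g. `list(bonds = ..., angles = ...)`).
#' @param torsion_densities numeric vector of local density measures (%).
#' @param ring_rmsds numeric vector of ring torsion RMSDs (degrees).
#' @param thresholds see [default_validation_thresholds()].
#' @return an `lk_geometry_report`: per-category `rmsz` (NA when a category
#'   is empty) and `outliers` (indices), `torsion_flags`, `ring_flags`,
#'   `any_flag`.
#' @export
geometry_flags <- function(zscores = list(), torsion_densities = numeric(),
                           ring_rmsds = numeric(),
                           thresholds = default_validation_thresholds()) {
  rmsz <- lapply(zscores, function(z) if (length(z)) sqrt(mean(z^2)) else NA_real_)
  outliers <- lapply(zscores, function(z) which(abs(z) > thresholds$z_outlier))
  torsion_flags <- which(torsion_densities < thresholds$torsion_density_min)
  ring_flags <- which(ring_rmsds > thresholds$ring_rmsd_max)
  structure(list(rmsz = rmsz, outliers = outliers,
                 torsion_flags = torsion_flags, ring_flags = ring_flags,
                 any_flag = any(lengths(outliers) > 0) ||
                   length(torsion_flags) > 0 || length(ring_flags) > 0),
            class = "lk_geometry_report")
}

#' @export
print.lk_geometry_report <- function(x, ...) {
  cat("<geometry report>\n")
  for (cat_name in names(x$rmsz)) {
    cat(sprintf("  %s: RMSZ %s, %d outlier(s)\n", cat_name,
                if (is.na(x$rmsz[[cat_name]])) "n/a" else sprintf("%.2f", x$rmsz[[cat_name]]),
                length(x$outliers[[cat_name]])))
  }
  cat(sprintf("  torsion flags: %d; ring flags: %d\n",
              length(x$torsion_flags), length(x$ring_flags)))
  invisible(x)
}

#' Flag poor ligand fit to electron density
#'
#' A ligand is highlighted for scrutiny when its real-space correlation
#' coefficient falls below 0.8 or its real-space R-value rises above 0.4
#' (both strict).
#'
#' @param rscc real-space correlation coefficient, in [0, 1].
#' @param rsr real-space R-value.
#' @param thresholds see [default_validation_thresholds()].
#' @return list: `flagged`, `rscc_flag`, `rsr_flag`.
#' @export
density_flags <- function(rscc, rsr, thresholds = default_validation_thresholds()) {
  if (is.na(rscc) || rscc < 0 || rscc > 1) stop("RSCC must lie in [0, 1]")
  rscc_flag <- rscc < thresholds$rscc_min
  rsr_flag <- rsr > thresholds$rsr_max
  list(flagged = rscc_flag || rsr_flag, rscc_flag = rscc_flag, rsr_flag = rsr_flag)
}
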