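# Functional-role classification of bound ligands: cofactor-like (two-stage
# similarity against curated cofactor classes gated by enzyme EC numbers),
# reactant-like (similarity to reaction participants mapped to the catalysing
# protein), and drug-like (membership of a drug -> pharmacologically active
# target table).

#' Default classification thresholds
#' @return list with `t_reactant` (0.7, inclusive) and `budget` (similarity
#'   search budget used by the classifiers).
#' @export
default_rellig_thresholds <- function() list(t_reactant = 0.7, budget = 5e4)

#' Load cofactor classes from a JSON reference file
#'
#' Each class carries a name, a template molecule and a representative
#' molecule (as SMILES), a per-class minimum similarity threshold, and the
#' set of enzyme EC numbers (possibly partial, e.g. `"1.1.1.-"`) associated
#' with the class.
#'
#' @param path JSON file; defaults to the small curated set shipped with
#'   the package.
#' @return list of cofactor classes with materialized molecules.
#' @export
load_cofactor_classes <- function(path = system.file("extdata", "cofactor_classes.json",
                                                     package = "ligandkit")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(cl) {
    list(name = cl$name,
         template = mol_from_smiles(cl$template_smiles, name = cl$name),
         representative = mol_from_smiles(cl$representative_smiles),
         threshold = cl$threshold,
         ec = unlist(cl$ec))
  })
}

# EC prefix matching: "1.1.1.-" or "1.1.1" matches "1.1.1.42".
ec_matches <- function(class_ec, entry_ec) {
  fields <- function(x) {
    f <- strsplit(x, ".", fixed = TRUE)[[1]]
    f[f != "-"]
  }
  cf <- fields(class_ec); ef <- fields(entry_ec)
  length(cf) <= length(ef) && all(cf == ef[seq_along(cf)])
}

any_ec_match <- function(class_ecs, entry_ecs) {
  for (ce in class_ecs) for (ee in entry_ecs) if (ec_matches(ce, ee)) return(TRUE)
  FALSE
}

# similarity with an identical-graph shortcut: equal InChIKey connectivity
# blocks mean equal heavy-atom graphs, which PARITY scores 1 by definition
role_similarity <- function(a, b, budget = 1e6) {
  ka <- tryCatch(substr(mol_inchikey(a), 1, 14), error = function(e) NULL)
  kb <- tryCatch(substr(mol_inchikey(b), 1, 14), error = function(e) NULL)
  if (!is.null(ka) && !is.null(kb) && nchar(ka) == 14 && identical(ka, kb)) return(1.0)
  parity_score(a, b, budget = budget)$score
}

#' Classify a ligand as cofactor-like
#'
#' Two-stage decision: similarity against each class template must meet the
#' class threshold; classes passing advance to the representative molecule,
#' whose similarity must also meet the threshold. A stage-2 pass additionally
#' requires the structure's EC annotation to intersect the class EC set
#' (prefix matching); a similarity pass without an EC match is flagged for
#' manual review instead of being annotated.
#'
#' @param ligand sanitized `lk_mol`.
#' @param entry_ecs character vector of EC numbers annotated on the entry.
#' @param classes cofactor classes, see [load_cofactor_classes()].
#' @param budget similarity search budget.
#' @return list: `cofactor_like` (logical), `manual_review` (logical),
#'   `evidence` (data.frame of per-class stage scores).
#' @export
classify_cofactor <- function(ligand, entry_ecs, classes, budget = 5e4) {
  ev <- list()
  cofactor <- FALSE; review <- FALSE
  for (cl in classes) {
    s1 <- role_similarity(ligand, cl$template, budget)
    if (s1 < cl$threshold) {
      ev[[length(ev) + 1L]] <- data.frame(class = cl$name, stage1 = s1,
                                          stage2 = NA_real_, ec_match = NA,
                                          outcome = "below-threshold")
      next
    }
    s2 <- role_similarity(ligand, cl$representative, budget)
    if (s2 < cl$threshold) {
      ev[[length(ev) + 1L]] <- data.frame(class = cl$name, stage1 = s1,
                                          stage2 = s2, ec_match = NA,
                                          outcome = "representative-fail")
      next
    }
    ecm <- any_ec_match(cl$ec, entry_ecs)
    if (ecm) {
      cofactor <- TRUE
      ev[[length(ev) + 1L]] <- data.frame(class = cl$name, stage1 = s1,
                                          stage2 = s2, ec_match = TRUE,
                                          outcome = "cofactor-like")
    } else {
      review <- TRUE
      ev[[length(ev) + 1L]] <- data.frame(class = cl$name, stage1 = s1,
                                          stage2 = s2, ec_match = FALSE,
                                          outcome = "manual-review")
    }
  }
  list(cofactor_like = cofactor, manual_review = review && !cofactor,
       evidence = if (length(ev)) do.call(rbind, ev) else
         data.frame(class = character(), stage1 = numeric(), stage2 = numeric(),
                    ec_match = logical(), outcome = character()))
}

#' Classify a ligand as reactant-like
#'
#' Over the reactions catalysed by the given protein, the ligand is compared
#' to every reaction participant; a maximum similarity at or above
#' `t_reactant` (default 0.7, inclusive) makes it reactant-like.
#'
#' @param ligand sanitized `lk_mol`.
#' @param protein_accession protein accession string.
#' @param reactions list of reaction records: each a list with `id`,
#'   `participants` (list of `lk_mol`), `accessions` (character).
#' @param thresholds see [default_rellig_thresholds()].
#' @param budget similarity search budget.
#' @return list: `reactant_like`, `evidence` (best reaction/participant/score).
#' @export
classify_reactant <- function(ligand, protein_accession, reactions,
                              thresholds = default_rellig_thresholds(),
                              budget = thresholds$budget) {
  best <- list(score = -Inf, reaction = NA_character_, participant = NA_integer_)
  for (rx in reactions) {
    if (!protein_accession %in% rx$accessions) next
    for (pi in seq_along(rx$participants)) {
      sc <- role_similarity(ligand, rx$participants[[pi]], budget)
      if (sc > best$score) best <- list(score = sc, reaction = rx$id, participant = pi)
    }
  }
  hit <- is.finite(best$score) && best$score >= thresholds$t_reactant
  list(reactant_like = hit,
       evidence = data.frame(reaction = best$reaction,
                             participant = best$participant,
                             score = if (is.finite(best$score)) best$score else NA_real_))
}

#' Classify a ligand as drug-like
#'
#' True when the ligand maps to a drug (by InChIKey, falling back to exact
#' identifier) whose pharmacologically-active target set contains the
#' protein accession.
#'
#' @param ligand_id ligand identifier (component id).
#' @param ligand optional `lk_mol` for InChIKey matching.
#' @param protein_accession protein accession string.
#' @param drug_table list of drug records: each a list with `drug_id`,
#'   optional `inchikey`, and `targets` (character accessions).
#' @return list: `drug_like`, `evidence` (matched drug).
#' @export
classify_drug <- function(ligand_id, ligand = NULL, protein_accession, drug_table) {
  lig_ik <- if (!is.null(ligand)) tryCatch(mol_inchikey(ligand), error = function(e) NA_character_)
            else NA_character_
  for (dr in drug_table) {
    matched <- (!is.na(lig_ik) && !is.null(dr$inchikey) && identical(dr$inchikey, lig_ik)) ||
      identical(dr$drug_id, ligand_id)
    if (matched && protein_accession %in% unlist(dr$targets)) {
      return(list(drug_like = TRUE,
                  evidence = data.frame(drug = dr$drug_id, target = protein_accession)))
    }
  }
  list(drug_like = FALSE,
       evidence = data.frame(drug = character(), target = character()))
}

#' Annotate every bound molecule of an entry with functional roles
#'
#' Runs the cofactor, reactant and drug classifiers for each (bound
#' molecule, protein accession) pair and unions the roles; roles are
#' non-exclusive. Output ordering follows bmID then accession.
#'
#' @param bound_set an `lk_bound_set`.
#' @param protein_accessions character vector of protein accessions in the
#'   entry.
#' @param entry_ecs character vector of entry EC annotations.
#' @param references list with `cofactor_classes`, `reactions`, `drug_table`
#'   (any may be empty lists).
#' @param budget similarity search budget.
#' @return data.frame (class `lk_annotations`): bmID, identifier, accession,
#'   roles (comma-joined), manual_review, plus a list-column `evidence`.
#' @export
annotate_entry <- function(bound_set, protein_accessions, entry_ecs,
                           references, budget = 5e4) {
  rows <- list()
  cache <- new.env(parent = emptyenv())   # one decision per unique ligand type
  for (bm in bound_set$bound) {
    lig <- bm$mol
    lig_id <- if (length(bm$component_multiset) == 1) bm$component_multiset else bm$identifier
    for (acc in protein_accessions) {
      key <- paste(c(lig_id, paste(bm$component_multiset, collapse = "+"), acc),
                   collapse = "|")
      hit <- cache[[key]]
      if (is.null(hit)) {
        co <- classify_cofactor(lig, entry_ecs, references$cofactor_classes %||% list(), budget)
        re <- classify_reactant(lig, acc, references$reactions %||% list(),
                                thresholds = modifyList(default_rellig_thresholds(),
                                                        list(budget = budget)))
        dr <- classify_drug(lig_id, lig, acc, references$drug_table %||% list())
        hit <- list(co = co, re = re, dr = dr)
        cache[[key]] <- hit
      }
      co <- hit$co; re <- hit$re; dr <- hit$dr
      roles <- character(); review <- FALSE
      ev <- list()
      if (co$cofactor_like) roles <- c(roles, "cofactor-like")
      review <- review || co$manual_review
      ev$cofactor <- co$evidence
      if (re$reactant_like) roles <- c(roles, "reactant-like")
      ev$reactant <- re$evidence
      if (dr$drug_like) roles <- c(roles, "drug-like")
      ev$drug <- dr$evidence
      rows[[length(rows) + 1L]] <- data.frame(
        bmID = bm$bmID,
        ligand = paste(bm$component_multiset, collapse = "+"),
        accession = acc,
        roles = paste(roles, collapse = ","),
        manual_review = review,
        evidence = I(list(ev)), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    bmID = character(), ligand = character(), accession = character(),
    roles = character(), manual_review = logical(), evidence = I(list()))
  class(out) <- c("lk_annotations", "data.frame")
  out
}
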