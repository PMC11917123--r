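#' Run the full entry-level analysis pipeline
#'
#' Desk-scale analogue of an archive processing run for one entry:
#' sanitize the component dictionary, infer bound molecules from assembly
#' connectivity, assign reference identifiers (CCD / PRD / CLC), add polar
#' hydrogens, compute typed contacts per bound molecule, classify functional
#' roles against the supplied reference tables, and aggregate per-atom
#' interaction frequencies. The returned report is a plain list ready for
#' JSON serialization; rerunning with identical inputs reproduces it
#' byte-identically.
#'
#' @param assembly an `lk_assembly` (or path to an assembly-mmCIF file).
#' @param components named list of `lk_component` (or path to a directory of
#'   component-mmCIF files).
#' @param references optional list with `cofactor_classes`, `reactions`,
#'   `drug_table`, `protein_accessions`, `entry_ecs`, `prd_table`.
#' @param registry an `lk_clc_registry` (fresh one by default).
#' @param rules interaction rules, see [default_interaction_rules()].
#' @param out optional path: write the report as JSON.
#' @return the report list (invisibly when `out` is given).
#' @export
run_pipeline <- function(assembly, components = list(), references = list(),
                         registry = clc_registry(),
                         rules = default_interaction_rules(), out = NULL) {
  stage <- "read"
  result <- tryCatch({
    if (is.character(assembly)) assembly <- read_assembly(readLines(assembly))
    if (is.character(components)) {
      files <- list.files(components, pattern = "\\.cif$", full.names = TRUE)
      components <- Filter(Negate(is.null), lapply(files, function(f) {
        tryCatch(read_component(readLines(f)), error = function(e) NULL)
      }))
      names(components) <- vapply(components, `[[`, "", "component_id")
    }

    stage <- "sanitize"
    sanitization <- lapply(components, function(rec) {
      s <- sanitize(rec$mol)
      list(record = component_record(rec$component_id, s$mol, rec$name,
                                     rec$descriptors),
           actions = nrow(s$report$actions))
    })
    components <- lapply(sanitization, `[[`, "record")

    stage <- "infer-bound-molecules"
    bound_set <- infer_bound_molecules(assembly, components)

    stage <- "identifiers"
    for (i in seq_along(bound_set$bound)) {
      bound_set$bound[[i]]$identifier <-
        assign_identifier(bound_set$bound[[i]], registry,
                          references$prd_table %||% character())
    }

    stage <- "protonate"
    prepared <- add_polar_hydrogens(assembly, components, rules)

    stage <- "contacts"
    contacts <- interactions_report(prepared, bound_set, rules, components)

    stage <- "classify"
    annotations <- if (length(references$cofactor_classes %||% list()) ||
                       length(references$reactions %||% list()) ||
                       length(references$drug_table %||% list())) {
      annotate_entry(bound_set, references$protein_accessions %||% character(),
                     references$entry_ecs %||% character(), references)
    } else NULL

    stage <- "aggregate"
    all_contacts <- do.call(rbind, lapply(bound_set$bound, function(bm) {
      compute_contacts(prepared, bm, rules, components)
    }))
    freq <- if (!is.null(all_contacts) && nrow(all_contacts)) {
      aggregate_atom_frequencies(all_contacts)
    } else NULL

    list(
      bound_molecules = lapply(bound_set$bound, function(bm) list(
        bmID = bm$bmID, components = as.list(bm$component_multiset),
        identifier = bm$identifier)),
      polymer_attached = lapply(bound_set$polymer_attached, function(bm) list(
        bmID = bm$bmID, components = as.list(bm$component_multiset))),
      sanitization_actions = lapply(sanitization, `[[`, "actions"),
      interactions = contacts,
      annotations = if (!is.null(annotations)) {
        lapply(seq_len(nrow(annotations)), function(i) list(
          bmID = annotations$bmID[i], ligand = annotations$ligand[i],
          accession = annotations$accession[i], roles = annotations$roles[i],
          manual_review = annotations$manual_review[i]))
      } else list(),
      atom_frequencies = if (!is.null(freq)) as.list(freq$atom_pct) else list())
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  if (!is.null(out)) {
    jsonlite::write_json(result, out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(result))
  }
  result
}
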