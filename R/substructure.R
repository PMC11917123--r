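#' Search a fragment library against a molecule
#'
#' Returns every library member that occurs as a subgraph of `m` under
#' element and bond-order matching (aromatic bonds only match aromatic
#' bonds), together with one witness atom mapping. Matching is a subgraph
#' monomorphism: the molecule may carry extra bonds between matched atoms.
#' Attachment markers (`"*"`) in library fragments match any heavy atom.
#'
#' @param m the query `lk_mol`.
#' @param library list of `lk_mol` fragments.
#' @return data.frame with columns `library_index` and a list-column
#'   `mapping` (integer vector: fragment atom i -> molecule atom
#'   `mapping[i]`). Zero rows when nothing matches or the library is empty.
#' @export
substructure_search <- function(m, library) {
  m <- strip_hydrogens(m)
  hits <- list()
  for (k in seq_along(library)) {
    map <- find_monomorphism(strip_hydrogens(library[[k]]), m)
    if (!is.null(map)) hits[[length(hits) + 1L]] <- list(library_index = k, mapping = map)
  }
  data.frame(
    library_index = vapply(hits, `[[`, 0L, "library_index"),
    mapping = I(lapply(hits, `[[`, "mapping")))
}

# One subgraph monomorphism pattern -> target, or NULL. Deterministic:
# pattern atoms are matched in a connectivity-first order and target
# candidates tried in index order.
find_monomorphism <- function(pattern, target) {
  np <- nrow(pattern$atoms)
  if (np == 0 || np > nrow(target$atoms)) return(NULL)
  # order pattern atoms so each (after the first per component) touches an
  # earlier one where possible
  nbp <- neighbours(pattern)
  ordr <- integer(0); left <- seq_len(np)
  while (length(left)) {
    nxt <- left[vapply(left, function(v) any(nbp[[v]] %in% ordr), TRUE)]
    pick <- if (length(nxt)) nxt[1] else left[1]
    ordr <- c(ordr, pick); left <- setdiff(left, pick)
  }
  tb <- bond_lookup(target)
  pb <- pattern$bonds
  nbt_used <- logical(nrow(target$atoms))
  assign_map <- integer(np)
  el_ok <- function(pe, te) pe == "*" || pe == te
  try_at <- function(pos) {
    if (pos > np) return(TRUE)
    v <- ordr[pos]
    for (t in seq_len(nrow(target$atoms))) {
      if (nbt_used[t]) next
      if (!el_ok(pattern$atoms$element[v], target$atoms$element[t])) next
      if (pattern$atoms$element[v] != "*" &&
          pattern$atoms$charge[v] != target$atoms$charge[t]) next
      ok <- TRUE
      for (bi in which((pb$a1 == v & pb$a2 %in% ordr[seq_len(pos - 1)]) |
                       (pb$a2 == v & pb$a1 %in% ordr[seq_len(pos - 1)]))) {
        w <- if (pb$a1[bi] == v) pb$a2[bi] else pb$a1[bi]
        tw <- assign_map[w]
        key <- paste(min(t, tw), max(t, tw))
        tbond <- tb[[key]]
        if (is.null(tbond) ||
            (pattern$atoms$element[v] != "*" && pattern$atoms$element[w] != "*" &&
             (tbond$order != pb$order[bi] || tbond$aromatic != pb$aromatic[bi]))) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      assign_map[v] <<- t; nbt_used[t] <<- TRUE
      if (try_at(pos + 1)) return(TRUE)
      nbt_used[t] <<- FALSE; assign_map[v] <<- 0L
    }
    FALSE
  }
  if (try_at(1)) assign_map else NULL
}

bond_lookup <- function(m) {
  out <- new.env(parent = emptyenv(), size = max(16L, nrow(m$bonds)))
  b <- m$bonds
  for (i in seq_len(nrow(b))) {
    out[[paste(b$a1[i], b$a2[i])]] <- list(order = b$order[i], aromatic = b$aromatic[i])
  }
  out
}
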