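#' Sanitize a molecule against a valence table
#'
#' Iteratively detects atoms whose explicit bond-order sum exceeds every
#' allowed valence for their (element, formal charge) and repairs them, one
#' action per offending atom per iteration, until the graph is valence-clean
#' or `max_iter` is reached. Repairs, in order of preference:
#'
#' 1. **bond-retyped** — if the over-valent atom has a covalent bond to a
#'    metal, that bond is retyped to a dative (coordination) bond, which no
#'    longer counts towards valence. This is how haem-like fragments (Fe
#'    bonded to four pyrrole nitrogens) resolve without inventing charges.
#' 2. **charge-set** — a formal charge for which the valence table allows
#'    the observed bond sum (e.g. a tetravalent neutral N becomes N+).
#'    Charges are tried in order of increasing magnitude, positive first.
#' 3. **bond-order-lowered** — the atom's highest-order bond is demoted by
#'    one (ties broken by lowest partner atom index).
#'
#' Metals themselves are exempt from valence checks. The function is
#' idempotent: sanitizing its own output is a no-op.
#'
#' @param m an `lk_mol`.
#' @param vt valence table, see [default_valence_table()].
#' @param max_iter maximum repair sweeps before giving up.
#' @return list with elements `mol` (repaired `lk_mol`) and `report`
#'   (an `lk_sanitization_report`: data.frame of actions, `converged` flag,
#'   `iterations` count).
#' @examples
#' # ammonium drawn uncharged: N with four single bonds
#' m <- molecule(data.frame(element = c("N", "H", "H", "H", "H")),
#'               data.frame(a1 = 1, a2 = 2:5))
#' s <- sanitize(m)
#' s$mol$atoms$charge[1]  # +1
#' @export
sanitize <- function(m, vt = default_valence_table(), max_iter = 10L) {
  validate_molecule(m)
  actions <- list()
  iter <- 0L
  repeat {
    offending <- over_valent_atoms(m, vt)
    if (length(offending) == 0 || iter >= max_iter) break
    iter <- iter + 1L
    applied <- FALSE
    for (i in offending) {
      # re-check: an earlier repair this sweep may have fixed this atom
      if (!is_over_valent(m, i, vt)) next
      act <- repair_atom(m, i, vt)
      if (is.null(act)) next
      m <- act$mol
      actions[[length(actions) + 1L]] <- act$action
      applied <- TRUE
    }
    if (!applied) break   # nothing applicable: stuck
  }
  converged <- length(over_valent_atoms(m, vt)) == 0
  report <- structure(list(
    actions = if (length(actions)) do.call(rbind, actions) else
      data.frame(atom = integer(), action = character(),
                 before = character(), after = character()),
    converged = converged,
    iterations = iter), class = "lk_sanitization_report")
  if (!converged) {
    cond <- structure(class = c("lk_unsanitizable", "error", "condition"),
                      list(message = sprintf(
                        "sanitization did not converge after %d iteration(s)", iter),
                        call = sys.call(-1), report = report))
    stop(cond)
  }
  list(mol = m, report = report)
}

over_valent_atoms <- function(m, vt) {
  which(vapply(seq_len(nrow(m$atoms)), function(i) is_over_valent(m, i, vt), TRUE))
}

is_over_valent <- function(m, i, vt) {
  el <- m$atoms$element[i]
  if (is_metal(el)) return(FALSE)
  av <- allowed_valences(vt, el, m$atoms$charge[i])
  if (is.null(av)) return(FALSE)          # element not governed by the table
  vs <- valence_sums(m)[i]
  length(av) > 0 && all(vs > av)
}

repair_atom <- function(m, i, vt) {
  el <- m$atoms$element[i]
  vs <- valence_sums(m)[i]
  bidx <- atom_bond_index(m)[[i]]

  # 1. retype a covalent bond to a metal as dative
  if (length(bidx)) {
    partners <- ifelse(m$bonds$a1[bidx] == i, m$bonds$a2[bidx], m$bonds$a1[bidx])
    metal_b <- bidx[is_metal(m$atoms$element[partners]) & !m$bonds$dative[bidx]]
    if (length(metal_b)) {
      j <- metal_b[order(m$bonds$a1[metal_b], m$bonds$a2[metal_b])][1]
      m$bonds$dative[j] <- TRUE
      return(list(mol = m, action = data.frame(
        atom = i, action = "bond-retyped",
        before = "covalent", after = "dative")))
    }
  }

  # 2. formal charge consistent with the table
  charges <- vt[[el]]
  if (!is.null(charges)) {
    cand <- as.integer(names(charges))
    cand <- cand[cand != m$atoms$charge[i]]
    cand <- cand[order(abs(cand), -sign(cand))]  # small magnitude, + before -
    for (q in cand) {
      av <- allowed_valences(vt, el, q)
      if (length(av) && any(av >= vs)) {
        before <- m$atoms$charge[i]
        m$atoms$charge[i] <- q
        return(list(mol = m, action = data.frame(
          atom = i, action = "charge-set",
          before = as.character(before), after = as.character(q))))
      }
    }
  }

  # 3. lower the highest-order bond (lowest partner index tie-break)
  if (length(bidx)) {
    cand <- bidx[m$bonds$order[bidx] > 1 & !m$bonds$aromatic[bidx] & !m$bonds$dative[bidx]]
    if (length(cand)) {
      partners <- ifelse(m$bonds$a1[cand] == i, m$bonds$a2[cand], m$bonds$a1[cand])
      j <- cand[order(-m$bonds$order[cand], partners)][1]
      before <- m$bonds$order[j]
      m$bonds$order[j] <- m$bonds$order[j] - 1L
      return(list(mol = m, action = data.frame(
        atom = i, action = "bond-order-lowered",
        before = as.character(before), after = as.character(before - 1L))))
    }
  }
  NULL
}

#' @export
print.lk_sanitization_report <- function(x, ...) {
  cat(sprintf("<sanitization report: %d action(s), %s after %d iteration(s)>\n",
              nrow(x$actions),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  if (nrow(x$actions)) print(x$actions)
  invisible(x)
}
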