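#' Score a 2D depiction
#'
#' The depiction penalty counts bond-line crossings (exact segment
#' intersection over non-adjacent bond pairs) and atom overlaps (pairs
#' closer than `min_sep` times the median 2D bond length) and combines
#' them as `penalty = w_cross * crossings + w_overlap * overlaps`. A clean
#' layout therefore scores exactly 0.
#'
#' @param m an `lk_mol` with 2D coordinates.
#' @param w_cross weight per bond crossing.
#' @param w_overlap weight per overlapping atom pair.
#' @param min_sep overlap threshold as a fraction of the median bond length.
#' @return an `lk_depiction_score` list: `penalty`, `crossings`, `overlaps`.
#' @export
depiction_penalty <- function(m, w_cross = 1.0, w_overlap = 0.5, min_sep = 0.5) {
  a <- m$atoms
  if (nrow(a) == 0) stop("empty molecule")
  if (any(is.na(a$x2) | is.na(a$y2))) stop("molecule lacks 2D coordinates")
  b <- m$bonds
  p <- cbind(a$x2, a$y2)

  crossings <- 0L
  if (nrow(b) >= 2) {
    for (i in seq_len(nrow(b) - 1)) {
      for (j in (i + 1):nrow(b)) {
        if (length(intersect(c(b$a1[i], b$a2[i]), c(b$a1[j], b$a2[j])))) next
        if (segments_cross(p[b$a1[i], ], p[b$a2[i], ], p[b$a1[j], ], p[b$a2[j], ])) {
          crossings <- crossings + 1L
        }
      }
    }
  }

  overlaps <- 0L
  if (nrow(b) > 0 && nrow(a) >= 2) {
    blen <- sqrt((p[b$a1, 1] - p[b$a2, 1])^2 + (p[b$a1, 2] - p[b$a2, 2])^2)
    thr <- min_sep * stats::median(blen)
    d <- as.matrix(stats::dist(p))
    overlaps <- sum(d[upper.tri(d)] < thr)
  }

  structure(list(penalty = w_cross * crossings + w_overlap * overlaps,
                 crossings = crossings, overlaps = overlaps),
            class = "lk_depiction_score")
}

#' @export
print.lk_depiction_score <- function(x, ...) {
  cat(sprintf("<depiction penalty %.2f: %d crossing(s), %d overlap(s)>\n",
              x$penalty, x$crossings, x$overlaps))
  invisible(x)
}

# strict segment crossing (shared endpoints excluded by the caller)
segments_cross <- function(p1, p2, p3, p4) {
  o <- function(a, b, c) sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  d1 <- o(p3, p4, p1); d2 <- o(p3, p4, p2); d3 <- o(p1, p2, p3); d4 <- o(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Select the best 2D depiction among candidates
#'
#' Returns the candidate layout with the smallest depiction penalty; ties go
#' to the earliest candidate in input order.
#'
#' @param candidates non-empty list of `lk_mol` with 2D coordinates.
#' @param ... passed to [depiction_penalty()].
#' @return the winning `lk_mol`.
#' @export
select_depiction <- function(candidates, ...) {
  if (length(candidates) == 0) stop("no depiction candidates supplied")
  pen <- vapply(candidates, function(m) depiction_penalty(m, ...)$penalty, 0)
  candidates[[which.min(pen)]]
}
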