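## superpose: least-squares rigid superposition and RMSD over selections.

#' Atom selection for superposition
#'
#' @param chain Chain id.
#' @param ranges Inclusive author residue-number ranges: a two-column
#'   matrix/list of `c(first, last)` pairs, or a single `c(first, last)`.
#'   `NULL` selects the whole chain.
#' @param atoms One of `"CA"` (C-alpha only), `"backbone"` (N, CA, C, O)
#'   or `"heavy"` (all non-hydrogen atoms).
#' @return A `selection` object.
#' @export
selection <- function(chain, ranges = NULL, atoms = c("CA", "backbone", "heavy")) {
  atoms <- match.arg(atoms)
  if (!is.null(ranges)) {
    if (is.numeric(ranges) && length(ranges) == 2) ranges <- list(ranges)
    ranges <- lapply(ranges, function(r) {
      if (length(r) != 2 || r[2] < r[1]) stop("invalid residue range")
      as.integer(r)
    })
  }
  structure(list(chain = chain, ranges = ranges, atoms = atoms), class = "selection")
}

#' Parse a selection string `chain:first-last:subset`
#'
#' Mini-grammar, e.g. `"A:90-141:CA"`; subset one of CA/backbone/heavy,
#' ranges inclusive; `"A::heavy"` selects the whole chain.
#' @param text Selection string.
#' @return A [selection()].
#' @export
parse_selection <- function(text) {
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  if (length(parts) < 1 || nchar(parts[1]) == 0) stop("selection must name a chain")
  rng <- if (length(parts) >= 2 && nzchar(parts[2])) {
    lapply(strsplit(parts[2], ",")[[1]], function(p) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      if (length(ab) == 1) c(ab, ab) else ab
    })
  } else NULL
  atoms <- if (length(parts) >= 3 && nzchar(parts[3])) parts[3] else "CA"
  selection(parts[1], rng, atoms)
}

BACKBONE_NAMES <- c("N", "CA", "C", "O")

## Atom table for a selection, ordered by residue then a fixed atom-name order.
selection_atoms <- function(s, sel) {
  a <- s$atoms
  a <- a[a$chain == sel$chain & !a$het, , drop = FALSE]
  if (!nrow(a)) stop("selection matches no atoms (chain '", sel$chain, "')")
  if (!is.null(sel$ranges)) {
    keep <- Reduce(`|`, lapply(sel$ranges, function(r) a$resno >= r[1] & a$resno <= r[2]))
    a <- a[keep, , drop = FALSE]
  }
  a$elety <- trimws(a$elety)
  if (sel$atoms == "CA") a <- a[a$elety == "CA", , drop = FALSE]
  else if (sel$atoms == "backbone") a <- a[a$elety %in% BACKBONE_NAMES, , drop = FALSE]
  else a <- a[a$elem != "H", , drop = FALSE]
  ## stable order: residue order in file, then atom name
  rk <- paste(a$resno, a$insert, sep = "|")
  ord <- order(match(rk, unique(rk)), a$elety)
  a[ord, , drop = FALSE]
}

#' Kabsch least-squares superposition of paired point sets
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' `P` (mobile) and `Q` (fixed), with the standard SVD sign correction
#' guarding against reflections.
#'
#' @param P,Q n x 3 coordinate matrices, paired by row; n >= 3.
#' @return A `superposition`: list with `rotation` (3x3, det +1),
#'   `translation`, `rmsd` (Angstrom) and `n_atoms`. The transform maps P
#'   onto Q as `P %*% t(rotation) + translation`.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3 || ncol(Q) != 3)
    stop("P and Q must be paired n x 3 matrices")
  n <- nrow(P)
  if (n < 3) stop("need at least 3 paired points")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- t(P0) %*% Q0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  if (min(sv$d) < 1e-8 * max(sv$d, 1e-12))
    warning("degenerate (near-collinear) point set; solution may not be unique")
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tr <- as.numeric(cq - R %*% cp)
  Pf <- transform_xyz(P, R, tr)
  rmsd <- sqrt(sum((Pf - Q)^2) / n)
  structure(list(rotation = R, translation = tr, rmsd = rmsd, n_atoms = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.4f A over %d atoms\n", x$rmsd, x$n_atoms))
  invisible(x)
}

## Pair atoms of two selections by (residue order, atom name); unpaired dropped.
pair_selection_atoms <- function(sA, selA, sB, selB) {
  a <- selection_atoms(sA, selA)
  b <- selection_atoms(sB, selB)
  rka <- match(paste(a$resno, a$insert, sep = "|"),
               unique(paste(a$resno, a$insert, sep = "|")))
  rkb <- match(paste(b$resno, b$insert, sep = "|"),
               unique(paste(b$resno, b$insert, sep = "|")))
  ka <- paste(rka, a$elety)
  kb <- paste(rkb, b$elety)
  hit <- match(ka, kb)
  ok <- !is.na(hit)
  dropped <- sum(!ok) + sum(!(kb %in% ka))
  list(A = as.matrix(a[ok, c("x", "y", "z")]),
       B = as.matrix(b[hit[ok], c("x", "y", "z")]),
       n_dropped = dropped)
}

#' RMSD between two structures over selections
#'
#' Atoms are paired by residue order within each selection and atom name;
#' unpaired atoms are dropped (never imputed) and reported.
#'
#' @param sA,sB `bh3_structure` objects.
#' @param selA,selB [selection()]s (or selection strings).
#' @return A `superposition` with an extra `n_dropped` field.
#' @export
rmsd_between <- function(sA, selA, sB, selB) {
  if (is.character(selA)) selA <- parse_selection(selA)
  if (is.character(selB)) selB <- parse_selection(selB)
  pr <- pair_selection_atoms(sA, selA, sB, selB)
  if (nrow(pr$A) == 0) stop("zero paired atoms between selections")
  fit <- kabsch(pr$A, pr$B)
  fit$n_dropped <- pr$n_dropped
  fit
}
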