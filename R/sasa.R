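## Solvent-accessible surface area by deterministic sphere-dot integration.

## Deterministic quasi-uniform unit sphere points (Fibonacci spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area
#'
#' Classic Shrake-Rupley style numerical SASA: dots are placed on each
#' atom's solvent-accessible sphere (vdW radius + probe) and counted
#' accessible when outside every neighbor's accessible sphere.
#'
#' @param atoms data.frame with columns x, y, z, elem (heavy atoms).
#' @param probe Probe radius in Angstrom.
#' @param n_dots Dots per atom (default 960).
#' @return Numeric vector of per-atom SASA (A^2).
#' @export
atom_sasa <- function(atoms, probe = 1.4, n_dots = 960) {
  n <- nrow(atoms)
  if (!n) return(numeric())
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- vdw_radius(atoms$elem) + probe
  dots <- fibonacci_sphere(n_dots)
  out <- numeric(n)
  maxr <- max(rad)
  for (i in seq_len(n)) {
    d2i <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2i < (rad[i] + maxr)^2 & d2i > 1e-12)
    nb <- nb[sqrt(d2i[nb]) < rad[i] + rad[nb]]
    pts <- sweep(dots * rad[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      buried <- rep(FALSE, n_dots)
      for (j in nb) {
        if (all(buried)) break
        dj2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
        buried <- buried | dj2 < rad[j]^2
      }
      acc <- sum(!buried)
    } else acc <- n_dots
    out[i] <- 4 * pi * rad[i]^2 * acc / n_dots
  }
  out
}

#' Per-residue side-chain SASA
#'
#' Side-chain accessibility used by the design-position selector: SASA is
#' summed over side-chain heavy atoms (everything beyond N, CA, C, O; the
#' CA stands proxy for glycine), computed in the context of all atoms of
#' the supplied structure. The default probe of 2.2 A is deliberately
#' larger than the water probe; it is the surface-selection probe of the
#' design protocol (burial for H-bond satisfaction uses 1.4 A).
#'
#' @param s A `bh3_structure` (typically the isolated binder monomer).
#' @param probe Probe radius (A), default 2.2.
#' @param n_dots Dots per atom.
#' @return Named numeric vector: per-residue side-chain SASA (A^2), names
#'   `chain:resno`.
#' @export
sidechain_sasa <- function(s, probe = 2.2, n_dots = 960) {
  a <- s$atoms[!s$atoms$het & s$atoms$elem != "H", , drop = FALSE]
  a$elety <- trimws(a$elety)
  sas <- atom_sasa(a, probe = probe, n_dots = n_dots)
  is_sc <- !(a$elety %in% c("N", "CA", "C", "O"))
  gly_proxy <- a$resid == "GLY" & a$elety == "CA"
  use <- is_sc | gly_proxy
  key <- paste(a$chain, a$resno, sep = ":")
  res_keys <- unique(key)
  out <- vapply(res_keys, function(k) sum(sas[use & key == k]), 0)
  stats::setNames(out, res_keys)
}
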