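## Coarse united-atom side-chain model.
##
## Side chains are built from an internal-coordinate table: each heavy atom
## is placed by NeRF from three predecessors with an ideal bond length and
## angle, and a torsion that is either a sampled chi angle (possibly with a
## fixed branch offset) or a fixed ring/planar value. No hydrogens. This is
## a deliberately coarse geometry -- adequate for steric/H-bond/burial
## scoring of designed interfaces, not for rotamer-accurate refinement.

## Element vdW radii (Angstrom), standard heavy-atom values.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

vdw_radius <- function(elem) {
  r <- VDW_RADII[elem]
  r[is.na(r)] <- 1.70
  unname(r)
}

## Side-chain topology. Each atom: name, elem, prev3 (names of the three
## reference atoms a,b,c; bonded to c), len, ang (new-c-b), chi (index of the
## sampled torsion, NA for fixed), off (added to the chi, or the fixed
## torsion when chi is NA).
sc_atom <- function(name, elem, prev3, len, ang, chi = NA, off = 0) {
  list(name = name, elem = elem, prev3 = prev3, len = len, ang = ang,
       chi = chi, off = off)
}

SIDECHAIN_TOPOLOGY <- list(
  GLY = list(),
  ALA = list(),
  SER = list(sc_atom("OG",  "O", c("N", "CA", "CB"), 1.42, 110.8, 1)),
  CYS = list(sc_atom("SG",  "S", c("N", "CA", "CB"), 1.81, 113.8, 1)),
  THR = list(sc_atom("OG1", "O", c("N", "CA", "CB"), 1.43, 109.6, 1),
             sc_atom("CG2", "C", c("N", "CA", "CB"), 1.52, 110.5, 1, -120)),
  VAL = list(sc_atom("CG1", "C", c("N", "CA", "CB"), 1.52, 110.5, 1),
             sc_atom("CG2", "C", c("N", "CA", "CB"), 1.52, 110.5, 1, 122)),
  LEU = list(sc_atom("CG",  "C", c("N", "CA", "CB"), 1.53, 116.3, 1),
             sc_atom("CD1", "C", c("CA", "CB", "CG"), 1.52, 110.7, 2),
             sc_atom("CD2", "C", c("CA", "CB", "CG"), 1.52, 110.7, 2, 120)),
  ILE = list(sc_atom("CG1", "C", c("N", "CA", "CB"), 1.53, 110.4, 1),
             sc_atom("CG2", "C", c("N", "CA", "CB"), 1.52, 110.5, 1, -122),
             sc_atom("CD1", "C", c("CA", "CB", "CG1"), 1.52, 113.8, 2)),
  MET = list(sc_atom("CG",  "C", c("N", "CA", "CB"), 1.52, 114.1, 1),
             sc_atom("SD",  "S", c("CA", "CB", "CG"), 1.81, 112.7, 2),
             sc_atom("CE",  "C", c("CB", "CG", "SD"), 1.79, 100.9, 3)),
  PRO = list(sc_atom("CG",  "C", c("N", "CA", "CB"), 1.50, 104.5, 1),
             sc_atom("CD",  "C", c("CA", "CB", "CG"), 1.51, 106.1, 2)),
  PHE = list(sc_atom("CG",  "C", c("N", "CA", "CB"), 1.50, 113.8, 1),
             sc_atom("CD1", "C", c("CA", "CB", "CG"), 1.39, 120.8, 2),
             sc_atom("CD2", "C", c("CA", "CB", "CG"), 1.39, 120.8, 2, 180),
             sc_atom("CE1", "C", c("CB", "CG", "CD1"), 1.39, 120.0, NA, 180),
             sc_atom("CE2", "C", c("CB", "CG", "CD2"), 1.39, 120.0, NA, 180),
             sc_atom("CZ",  "C", c("CG", "CD1", "CE1"), 1.39, 120.0, NA, 0)),
  TYR = list(sc_atom("CG",  "C", c("N", "CA", "CB"), 1.51, 113.9, 1),
             sc_atom("CD1", "C", c("CA", "CB", "CG"), 1.39, 120.8, 2),
             sc_atom("CD2", "C", c("CA", "CB", "CG"), 1.39, 120.8, 2, 180),
             sc_atom("CE1", "C", c("CB", "CG", "CD1"), 1.39, 120.0, NA, 180),
             sc_atom("CE2", "C", c("CB", "CG", "CD2"), 1.39, 120.0, NA, 180),
             sc_atom("CZ",  "C", c("CG", "CD1", "CE1"), 1.39, 120.0, NA, 0),
             sc_atom("OH",  "O", c("CD1", "CE1", "CZ"), 1.38, 119.9, NA, 180)),
  TRP = list(sc_atom("CG",  "C", c("N", "CA", "CB"), 1.50, 113.6, 1),
             sc_atom("CD1", "C", c("CA", "CB", "CG"), 1.37, 126.9, 2),
             sc_atom("CD2", "C", c("CA", "CB", "CG"), 1.43, 126.7, 2, 180),
             sc_atom("NE1", "N", c("CB", "CG", "CD1"), 1.38, 110.2, NA, 180),
             sc_atom("CE2", "C", c("CB", "CG", "CD2"), 1.41, 107.2, NA, 180),
             sc_atom("CZ2", "C", c("CG", "CD2", "CE2"), 1.40, 122.4, NA, 180)),
  ASP = list(sc_atom("CG",  "C", c("N", "CA", "CB"), 1.52, 113.1, 1),
             sc_atom("OD1", "O", c("CA", "CB", "CG"), 1.25, 118.4, 2),
             sc_atom("OD2", "O", c("CA", "CB", "CG"), 1.25, 118.4, 2, 180)),
  ASN = list(sc_atom("CG",  "C", c("N", "CA", "CB"), 1.52, 112.7, 1),
             sc_atom("OD1", "O", c("CA", "CB", "CG"), 1.23, 120.8, 2),
             sc_atom("ND2", "N", c("CA", "CB", "CG"), 1.33, 116.5, 2, 180)),
  GLU = list(sc_atom("CG",  "C", c("N", "CA", "CB"), 1.52, 114.1, 1),
             sc_atom("CD",  "C", c("CA", "CB", "CG"), 1.52, 112.6, 2),
             sc_atom("OE1", "O", c("CB", "CG", "CD"), 1.25, 118.4, 3),
             sc_atom("OE2", "O", c("CB", "CG", "CD"), 1.25, 118.4, 3, 180)),
  GLN = list(sc_atom("CG",  "C", c("N", "CA", "CB"), 1.52, 114.1, 1),
             sc_atom("CD",  "C", c("CA", "CB", "CG"), 1.52, 112.6, 2),
             sc_atom("OE1", "O", c("CB", "CG", "CD"), 1.23, 120.8, 3),
             sc_atom("NE2", "N", c("CB", "CG", "CD"), 1.33, 116.5, 3, 180)),
  LYS = list(sc_atom("CG",  "C", c("N", "CA", "CB"), 1.52, 114.1, 1),
             sc_atom("CD",  "C", c("CA", "CB", "CG"), 1.52, 111.3, 2),
             sc_atom("CE",  "C", c("CB", "CG", "CD"), 1.52, 111.3, 3),
             sc_atom("NZ",  "N", c("CG", "CD", "CE"), 1.49, 111.9, 4)),
  ARG = list(sc_atom("CG",  "C", c("N", "CA", "CB"), 1.52, 114.1, 1),
             sc_atom("CD",  "C", c("CA", "CB", "CG"), 1.52, 111.3, 2),
             sc_atom("NE",  "N", c("CB", "CG", "CD"), 1.46, 112.0, 3),
             sc_atom("CZ",  "C", c("CG", "CD", "NE"), 1.33, 124.2, 4),
             sc_atom("NH1", "N", c("CD", "NE", "CZ"), 1.33, 120.0, NA, 0),
             sc_atom("NH2", "N", c("CD", "NE", "CZ"), 1.33, 120.0, NA, 180)),
  HIS = list(sc_atom("CG",  "C", c("N", "CA", "CB"), 1.50, 113.8, 1),
             sc_atom("ND1", "N", c("CA", "CB", "CG"), 1.38, 122.7, 2),
             sc_atom("CD2", "C", c("CA", "CB", "CG"), 1.36, 131.0, 2, 180),
             sc_atom("CE1", "C", c("CB", "CG", "ND1"), 1.32, 109.3, NA, 180),
             sc_atom("NE2", "N", c("CB", "CG", "CD2"), 1.37, 107.2, NA, 180))
)

## Number of sampled chi angles per residue type.
n_chi <- function(resid) {
  topo <- SIDECHAIN_TOPOLOGY[[resid]]
  if (is.null(topo) || !length(topo)) return(0L)
  mx <- suppressWarnings(max(vapply(topo, function(a) {
    if (is.na(a$chi)) 0L else as.integer(a$chi)
  }, 0L)))
  max(mx, 0L)
}

## H-bond chemistry by (residue, atom name). Backbone: N donor, O acceptor.
polar_role <- function(resid, elety) {
  elety <- trimws(elety)
  if (elety == "N") return("donor")
  if (elety == "O") return("acceptor")
  don <- list(SER = "OG", THR = "OG1", TYR = "OH", LYS = "NZ", TRP = "NE1",
              ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"),
              ARG = c("NE", "NH1", "NH2"))
  acc <- list(SER = "OG", THR = "OG1", TYR = "OH", ASP = c("OD1", "OD2"),
              GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1", HIS = "ND1")
  d <- elety %in% (don[[resid]] %||% character())
  a <- elety %in% (acc[[resid]] %||% character())
  if (d && a) "both" else if (d) "donor" else if (a) "acceptor" else "none"
}

## Place CB from backbone N, CA, C (L-amino-acid chirality).
place_cb <- function(N, CA, C) {
  place_atom(C, N, CA, 1.53, 110.5, -122.5)
}

#' Build side-chain atoms for one residue
#'
#' @param resid 3-letter residue type.
#' @param N,CA,C Backbone coordinates (3-vectors).
#' @param chi Numeric vector of chi angles (degrees); recycled/padded with
#'   defaults (-60 for chi1/chi2, 180 beyond) if shorter than required.
#' @return data.frame of atoms (name, elem, x, y, z); includes CB for all
#'   types except GLY.
#' @keywords internal
build_sidechain <- function(resid, N, CA, C, chi = numeric()) {
  if (resid == "GLY") return(data.frame(name = character(), elem = character(),
                                        x = numeric(), y = numeric(), z = numeric()))
  need <- n_chi(resid)
  defaults <- c(-60, -60, 180, 180)
  if (length(chi) < need)
    chi <- c(chi, defaults[seq(length(chi) + 1, need)])
  cb <- place_cb(N, CA, C)
  coords <- list(N = N, CA = CA, C = C, CB = cb)
  topo <- SIDECHAIN_TOPOLOGY[[resid]]
  if (is.null(topo)) topo <- list()
  for (a in topo) {
    tor <- if (is.na(a$chi)) a$off else chi[a$chi] + a$off
    p <- coords[a$prev3]
    coords[[a$name]] <- place_atom(p[[1]], p[[2]], p[[3]], a$len, a$ang, tor)
  }
  nm <- setdiff(names(coords), c("N", "CA", "C"))
  elems <- vapply(nm, function(n) {
    if (n == "CB") "C" else topo[[which(vapply(topo, function(t) t$name == n, TRUE))]]$elem
  }, "")
  m <- do.call(rbind, coords[nm])
  data.frame(name = nm, elem = unname(elems),
             x = m[, 1], y = m[, 2], z = m[, 3], stringsAsFactors = FALSE)
}

## Coarse backbone-independent chi grid for the rotamer library.
CHI_GRID <- c(-60, 60, 180)
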