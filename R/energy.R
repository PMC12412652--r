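## The simplified pairwise interface potential.
##
## A declared 4-term surrogate, not a reimplementation of any production
## force field: (1) softened steric (12-6 with a hard inner floor so every
## rotamer pair scores finite), (2) a distance/angle hydrogen-bond well on
## heavy-atom donor/acceptor geometry, (3) a burial-of-polar penalty for
## polar atoms buried without a partner, (4) per-residue-type reference
## energies. All terms are pairwise- or single-decomposable; bonded
## exclusions: within-residue pairs and adjacent-residue backbone-backbone
## pairs are never scored sterically.

#' Simplified interface energy model
#'
#' @param eps_steric Well depth of the 12-6 steric term (model units).
#' @param soft_floor Fraction of contact distance below which repulsion is
#'   clamped (keeps all states finite).
#' @param steric_cutoff_pad Steric interactions beyond `r_i+r_j+pad` are 0.
#' @param w_hb Hydrogen-bond well depth.
#' @param hb_d0,hb_sigma H-bond distance optimum and Gaussian width (A).
#' @param hb_dmax Maximum donor-acceptor heavy-atom distance (A).
#' @param hb_angle_min Minimum base-donor-acceptor angle (degrees).
#' @param w_bury Penalty per buried unsatisfied polar atom.
#' @param burial_radius,burial_min_neighbors Burial proxy: a polar atom with
#'   at least this many heavy neighbors within the radius counts as buried.
#' @param ref Named per-residue-type reference energies (3-letter codes).
#' @return An `energy_model` list.
#' @export
energy_model <- function(eps_steric = 0.05, soft_floor = 0.6,
                         steric_cutoff_pad = 2.5,
                         w_hb = 2.0, hb_d0 = 2.9, hb_sigma = 0.3,
                         hb_dmax = 3.5, hb_angle_min = 90,
                         w_bury = 1.0, burial_radius = 5.5,
                         burial_min_neighbors = 14,
                         ref = NULL) {
  if (is.null(ref)) {
    ref <- stats::setNames(rep(0, 20), names(AA321)[1:20])
    ref[c("TRP", "TYR", "PHE", "ARG", "MET")] <- 0.3
    ref[c("LYS", "GLU", "GLN", "ILE", "LEU", "HIS")] <- 0.15
    ref["ALA"] <- 0
  }
  structure(as.list(environment()), class = "energy_model")
}

## Atom records: coordinates plus H-bond chemistry (role, base atom coords).
## `is_bb` marks backbone N/CA/C/O.
atom_records <- function(s) {
  a <- s$atoms[!s$atoms$het & s$atoms$elem != "H", , drop = FALSE]
  a$elety <- trimws(a$elety)
  a$is_bb <- a$elety %in% BACKBONE_NAMES
  n <- nrow(a)
  a$role <- "none"
  a$bx <- a$by <- a$bz <- NA_real_
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  for (i in seq_len(n)) {
    role <- polar_role(a$resid[i], a$elety[i])
    a$role[i] <- role
    if (role == "none") next
    base_name <- if (a$elety[i] == "N") "CA"
    else if (a$elety[i] == "O") "C"
    else {
      topo <- SIDECHAIN_TOPOLOGY[[a$resid[i]]]
      hit <- Filter(function(t) t$name == a$elety[i], topo %||% list())
      if (length(hit)) hit[[1]]$prev3[3] else "CB"
    }
    j <- which(key == key[i] & a$elety == base_name)
    if (length(j)) {
      a$bx[i] <- a$x[j[1]]; a$by[i] <- a$y[j[1]]; a$bz[i] <- a$z[j[1]]
    }
  }
  a
}

## Steric 12-6 with inner clamp; E(d) for contact distance r0.
steric_energy_vec <- function(d, r0, model) {
  d <- pmax(d, model$soft_floor * r0)
  out <- numeric(length(d))
  inr <- d < r0 + model$steric_cutoff_pad
  x <- (r0[inr] / d[inr])
  out[inr] <- model$eps_steric * (x^12 - 2 * x^6)
  out
}

## H-bond energy between donor rows (of A) and acceptor rows (of B).
hbond_energy_pairs <- function(don, acc, model) {
  if (!nrow(don) || !nrow(acc)) return(0)
  D <- as.matrix(don[, c("x", "y", "z")])
  A <- as.matrix(acc[, c("x", "y", "z")])
  B <- as.matrix(don[, c("bx", "by", "bz")])
  d2 <- cross_dist2(D, A)
  E <- 0
  hits <- which(d2 < model$hb_dmax^2 & d2 > 2.4^2, arr.ind = TRUE)
  for (r in seq_len(nrow(hits))) {
    i <- hits[r, 1]; j <- hits[r, 2]
    if (!is.finite(B[i, 1])) next
    ang <- bond_angle(B[i, ], D[i, ], A[j, ])
    if (ang < model$hb_angle_min) next
    d <- sqrt(d2[i, j])
    fa <- min(1, (ang - model$hb_angle_min) / 60)
    E <- E - model$w_hb * exp(-((d - model$hb_d0)^2) / (2 * model$hb_sigma^2)) * fa
  }
  E
}

## Pairwise (steric + H-bond) energy between two atom-record sets belonging
## to different residues. `exclude_bb_bb` drops backbone-backbone pairs
## (used for adjacent residues).
pair_interaction <- function(ra, rb, model, exclude_bb_bb = FALSE) {
  if (!nrow(ra) || !nrow(rb)) return(0)
  A <- as.matrix(ra[, c("x", "y", "z")])
  B <- as.matrix(rb[, c("x", "y", "z")])
  d2 <- cross_dist2(A, B)
  r0 <- outer(vdw_radius(ra$elem), vdw_radius(rb$elem), "+")
  mask <- d2 < (r0 + model$steric_cutoff_pad)^2
  if (exclude_bb_bb) mask <- mask & !outer(ra$is_bb, rb$is_bb, "&")
  E <- 0
  if (any(mask)) {
    d <- sqrt(pmax(d2[mask], 0))
    E <- E + sum(steric_energy_vec(d, r0[mask], model))
  }
  da <- ra[ra$role %in% c("donor", "both"), , drop = FALSE]
  ab <- rb[rb$role %in% c("acceptor", "both"), , drop = FALSE]
  db <- rb[rb$role %in% c("donor", "both"), , drop = FALSE]
  aa <- ra[ra$role %in% c("acceptor", "both"), , drop = FALSE]
  if (exclude_bb_bb) {
    ## adjacent-residue backbone H-bonds are covalent-adjacent artifacts
    da <- da[!da$is_bb, , drop = FALSE]; ab <- ab[!ab$is_bb, , drop = FALSE]
    db <- db[!db$is_bb, , drop = FALSE]; aa <- aa[!aa$is_bb, , drop = FALSE]
  }
  E + hbond_energy_pairs(da, ab, model) + hbond_energy_pairs(db, aa, model)
}

## Buried-unsatisfied-polar penalty of records `rp` in environment `env`.
burial_penalty <- function(rp, env, model) {
  rp <- rp[rp$role != "none", , drop = FALSE]
  if (!nrow(rp) || !nrow(env)) return(0)
  P <- as.matrix(rp[, c("x", "y", "z")])
  Ev <- as.matrix(env[, c("x", "y", "z")])
  d2 <- cross_dist2(P, Ev)
  pen <- 0
  for (i in seq_len(nrow(rp))) {
    nb <- sum(d2[i, ] < model$burial_radius^2)
    if (nb < model$burial_min_neighbors) next
    comp <- if (rp$role[i] %in% c("donor", "both")) c("acceptor", "both") else c("donor", "both")
    if (rp$role[i] == "both") comp <- c("donor", "acceptor", "both")
    partners <- env$role %in% comp & d2[i, ] < model$hb_dmax^2 & d2[i, ] > 2.4^2
    if (!any(partners)) pen <- pen + model$w_bury
  }
  pen
}

## Residue adjacency: consecutive resno in the same chain.
residues_adjacent <- function(c1, r1, c2, r2) c1 == c2 & abs(r1 - r2) == 1

#' Total energy of a structure under the simplified model
#'
#' Sum of per-residue reference energies, all residue-pair steric/H-bond
#' interactions (within-residue excluded; adjacent-residue backbone pairs
#' excluded), and the burial-of-polar penalty of each residue's polar atoms
#' against the rest of the structure.
#'
#' @param s A `bh3_structure`.
#' @param model An [energy_model()].
#' @param terms Return the per-term breakdown.
#' @return Total energy (model units), or a list when `terms = TRUE`.
#' @export
total_energy <- function(s, model = energy_model(), terms = FALSE) {
  rec <- atom_records(s)
  key <- paste(rec$chain, rec$resno, rec$insert, sep = "|")
  ukeys <- unique(key)
  by_res <- split(seq_len(nrow(rec)), factor(key, levels = ukeys))
  nres <- length(ukeys)
  chains <- vapply(by_res, function(ix) rec$chain[ix[1]], "")
  resnos <- vapply(by_res, function(ix) rec$resno[ix[1]], 0)
  resids <- vapply(by_res, function(ix) rec$resid[ix[1]], "")
  E_pair <- 0
  cax <- t(vapply(by_res, function(ix) {
    ca <- ix[rec$elety[ix] == "CA"]
    if (length(ca)) as.numeric(rec[ca[1], c("x", "y", "z")])
    else as.numeric(rec[ix[1], c("x", "y", "z")])
  }, numeric(3)))
  for (i in seq_len(nres - 1)) {
    for (j in (i + 1):nres) {
      if (sum((cax[i, ] - cax[j, ])^2) > 400) next
      adj <- residues_adjacent(chains[i], resnos[i], chains[j], resnos[j])
      E_pair <- E_pair + pair_interaction(rec[by_res[[i]], ], rec[by_res[[j]], ],
                                          model, exclude_bb_bb = adj)
    }
  }
  E_ref <- sum(model$ref[resids], na.rm = TRUE)
  E_bury <- 0
  for (i in seq_len(nres)) {
    ri <- rec[by_res[[i]], , drop = FALSE]
    env <- rec[-by_res[[i]], , drop = FALSE]
    E_bury <- E_bury + burial_penalty(ri, env, model)
  }
  tot <- E_pair + E_ref + E_bury
  if (terms) list(total = tot, pair = E_pair, reference = E_ref, burial = E_bury)
  else tot
}
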