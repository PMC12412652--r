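## filters: design-selection metrics -- predicted binding energy, shape
## complementarity, buried unsatisfied polar atoms, omega geometry -- and
## threshold gating.

#' Filter thresholds
#'
#' Gate values are user-supplied (the design protocol templates them);
#' only the omega cutoff has a stated default of 150 degrees.
#'
#' @param ddg_max Maximum predicted binding energy (model units).
#' @param sc_min Minimum shape complementarity.
#' @param unsat_max Maximum buried unsatisfied polar atoms.
#' @param omega_cutoff Degrees; residues with |omega| below this fail.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(ddg_max = 0, sc_min = 0.5, unsat_max = 1,
                              omega_cutoff = 150) {
  stopifnot(omega_cutoff > 90, omega_cutoff < 180)
  structure(list(ddg_max = ddg_max, sc_min = sc_min, unsat_max = unsat_max,
                 omega_cutoff = omega_cutoff), class = "filter_thresholds")
}

## Split a complex into two partner structures by chain sets. `split` is
## either a character vector of binder chains or "B/A"-style text.
partner_split <- function(complex, split) {
  all_ch <- chain_ids(complex)
  if (is.character(split) && length(split) == 1 && grepl("/", split)) {
    parts <- strsplit(split, "/", fixed = TRUE)[[1]]
    ch1 <- strsplit(parts[1], "")[[1]]
    ch2 <- strsplit(parts[2], "")[[1]]
  } else {
    ch1 <- split
    ch2 <- setdiff(all_ch, ch1)
  }
  if (!length(ch2)) stop("partner split leaves one side empty (single-chain input?)")
  list(A = subset_chains(complex, intersect(all_ch, ch1)),
       B = subset_chains(complex, intersect(all_ch, ch2)))
}

#' Predicted binding energy of a two-body complex
#'
#' In the default (`repack = FALSE`) mode this is the exact sum of
#' inter-partner pairwise terms of the simplified model -- zero whenever
#' the partners make no contact. With `repack = TRUE` each partner is
#' additionally repacked alone (fixed seed) and the energy difference
#' E(complex) - [E(A repacked) + E(B repacked)] is reported, emulating a
#' bound-minus-unbound estimate.
#'
#' @param complex A `bh3_structure` with at least two chains.
#' @param model An [energy_model()].
#' @param split Binder chain id(s) or `"B/A"` split text; default: last chain.
#' @param repack Repack partners alone before differencing.
#' @param cfg [design_config()] used for the repack pass.
#' @return Binding energy in model units (negative = favorable).
#' @export
binding_energy <- function(complex, model = energy_model(), split = NULL,
                           repack = FALSE, cfg = design_config()) {
  ch <- chain_ids(complex)
  if (length(ch) < 2) stop("binding energy needs a two-body complex")
  if (is.null(split)) split <- ch[length(ch)]
  ps <- partner_split(complex, split)
  if (!repack) {
    recA <- atom_records(ps$A)
    recB <- atom_records(ps$B)
    return(pair_interaction(recA, recB, model) +
             inter_burial_delta(recA, recB, model))
  }
  ## repack-only (identity-fixed) relaxation of each partner alone at the
  ## former interface, fixed seed
  repack_alone <- function(s, other) {
    sa <- s$atoms[s$atoms$elem != "H" & !s$atoms$het, , drop = FALSE]
    oa <- other$atoms[other$atoms$elem != "H" & !other$atoms$het, , drop = FALSE]
    d2 <- cross_dist2(as.matrix(sa[, c("x", "y", "z")]),
                      as.matrix(oa[, c("x", "y", "z")]))
    iface <- unique(sa$resno[apply(d2 < 64, 1, any)])
    best <- s
    for (ch in chain_ids(s)) {
      pos <- intersect(iface, unique(sa$resno[sa$chain == ch]))
      if (!length(pos)) next
      ids <- lapply(stats::setNames(pos, pos), function(p) {
        unname(AA321[sa$resid[sa$chain == ch & sa$resno == p][1]])
      })
      rot <- build_rotamer_set(best, ch, pos, cfg, identities = ids)
      best <- mc_design(best, pos, rot, model, cfg, ch)$complex
    }
    total_energy(best, model)
  }
  total_energy(complex, model) - repack_alone(ps$A, ps$B) -
    repack_alone(ps$B, ps$A)
}

## Burial-penalty change upon complexation (polar atoms of one partner
## buried by the other). Zero when partners are far apart.
inter_burial_delta <- function(recA, recB, model) {
  d <- 0
  d <- d + burial_penalty(recA, rbind(recA, recB), model) -
    burial_penalty(recA, recA, model)
  d <- d + burial_penalty(recB, rbind(recA, recB), model) -
    burial_penalty(recB, recB, model)
  d
}

## Dot surface of a partner: accessible dots on vdW spheres with outward
## normals (deterministic Fibonacci dots).
molecular_surface_dots <- function(atoms, n_dots = 180) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- vdw_radius(atoms$elem)
  dots <- fibonacci_sphere(n_dots)
  res <- vector("list", nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    pts <- sweep(dots * rad[i], 2, xyz[i, ], "+")
    keep <- rep(TRUE, n_dots)
    d2i <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2i < (rad[i] + max(rad))^2 & d2i > 1e-12)
    for (j in nb) {
      if (!any(keep)) break
      keep <- keep & rowSums(sweep(pts, 2, xyz[j, ])^2) > rad[j]^2
    }
    if (any(keep))
      res[[i]] <- cbind(pts[keep, , drop = FALSE], dots[keep, , drop = FALSE])
  }
  m <- do.call(rbind, res)
  if (is.null(m)) m <- matrix(numeric(), 0, 6)
  list(points = m[, 1:3, drop = FALSE], normals = m[, 4:6, drop = FALSE])
}

#' Shape complementarity statistic
#'
#' Lawrence-Colman-style Sc: dots are sampled on each partner's vdW
#' surface and restricted to the interface band (dots within `band` A of
#' the other partner's surface). For each dot the nearest dot on the
#' opposing surface is found and scored by normal anti-alignment weighted
#' by `exp(-w d^2)` with w = 0.5 per A^2; Sc is the mean of the two
#' directional medians. Deterministic (fixed dot construction).
#'
#' @param complex A `bh3_structure`.
#' @param split Partner split (see [binding_energy()]).
#' @param n_dots Dots per atom.
#' @param band Interface band half-width (A).
#' @param w Gaussian distance weight (1/A^2).
#' @return Sc in `[-1, 1]`.
#' @export
shape_complementarity <- function(complex, split = NULL, n_dots = 180,
                                  band = 1.5, w = 0.5) {
  ch <- chain_ids(complex)
  if (is.null(split)) split <- ch[length(ch)]
  ps <- partner_split(complex, split)
  aA <- ps$A$atoms[ps$A$atoms$elem != "H", , drop = FALSE]
  aB <- ps$B$atoms[ps$B$atoms$elem != "H", , drop = FALSE]
  dmin2 <- min(cross_dist2(as.matrix(aA[, c("x", "y", "z")]),
                           as.matrix(aB[, c("x", "y", "z")])))
  if (dmin2 > 64) stop("no contact surface between partners")
  sA <- molecular_surface_dots(aA, n_dots)
  sB <- molecular_surface_dots(aB, n_dots)
  if (!nrow(sA$points) || !nrow(sB$points)) stop("no contact surface between partners")
  ## distance from each dot to the other partner's sphere surface
  surf_dist <- function(pts, atoms) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    rad <- vdw_radius(atoms$elem)
    d <- sqrt(pmax(cross_dist2(pts, xyz), 0))
    apply(sweep(d, 2, rad), 1, min)
  }
  inA <- surf_dist(sA$points, aB) <= band
  inB <- surf_dist(sB$points, aA) <= band
  if (!any(inA) || !any(inB)) stop("no contact surface between partners")
  score_dir <- function(P, NP, Q, NQ) {
    d2 <- cross_dist2(P, Q)
    j <- max.col(-d2, ties.method = "first")
    d2n <- d2[cbind(seq_len(nrow(P)), j)]
    align <- -rowSums(NP * NQ[j, , drop = FALSE])
    stats::median(align * exp(-w * pmax(d2n, 0)))
  }
  sAB <- score_dir(sA$points[inA, , drop = FALSE], sA$normals[inA, , drop = FALSE],
                   sB$points[inB, , drop = FALSE], sB$normals[inB, , drop = FALSE])
  sBA <- score_dir(sB$points[inB, , drop = FALSE], sB$normals[inB, , drop = FALSE],
                   sA$points[inA, , drop = FALSE], sA$normals[inA, , drop = FALSE])
  max(-1, min(1, (sAB + sBA) / 2))
}

#' Buried unsatisfied polar atoms at an interface
#'
#' Counts N/O donor/acceptor heavy atoms that are buried in the complex
#' (SASA < `burial_sasa` at probe 1.4 A), have no hydrogen-bond partner
#' under the heavy-atom criterion (donor-acceptor distance <= 3.5 A, base
#' angle >= 90 degrees), and whose burial state changes upon complexation
#' (isolated single chains therefore always count zero).
#'
#' @param complex A `bh3_structure`.
#' @param split Partner split; default last chain vs rest. A single-chain
#'   structure returns 0.
#' @param model [energy_model()] supplying the H-bond well geometry.
#' @param burial_sasa SASA threshold (A^2).
#' @param n_dots SASA dot density.
#' @return Integer count.
#' @export
buried_unsat_polar <- function(complex, split = NULL, model = energy_model(),
                               burial_sasa = 0.01, n_dots = 960) {
  ch <- chain_ids(complex)
  if (length(ch) < 2) return(0L)
  if (is.null(split)) split <- ch[length(ch)]
  ps <- partner_split(complex, split)
  rec <- atom_records(complex)
  sas_cx <- atom_sasa(rec, probe = 1.4, n_dots = n_dots)
  ## per-partner SASA (apo burial state)
  recA <- atom_records(ps$A); recB <- atom_records(ps$B)
  sasA <- atom_sasa(recA, probe = 1.4, n_dots = n_dots)
  sasB <- atom_sasa(recB, probe = 1.4, n_dots = n_dots)
  keyf <- function(r) paste(r$chain, r$resno, r$insert, r$elety, sep = "|")
  apo <- stats::setNames(c(sasA, sasB), c(keyf(recA), keyf(recB)))
  sas_apo <- apo[keyf(rec)]
  polar <- which(rec$role != "none")
  cnt <- 0L
  P <- as.matrix(rec[, c("x", "y", "z")])
  for (i in polar) {
    if (sas_cx[i] >= burial_sasa) next
    if (sas_apo[i] < burial_sasa) next  # buried already before complexation
    ## H-bond partner search among all polar atoms
    comp <- if (rec$role[i] == "donor") c("acceptor", "both")
    else if (rec$role[i] == "acceptor") c("donor", "both")
    else c("donor", "acceptor", "both")
    cand <- which(rec$role %in% comp)
    cand <- cand[cand != i]
    d <- sqrt(rowSums(sweep(P[cand, , drop = FALSE], 2, P[i, ])^2))
    cand <- cand[d <= model$hb_dmax & d >= 2.4]
    satisfied <- FALSE
    for (j in cand) {
      ## angle check at whichever side is the donor
      ok <- FALSE
      if (rec$role[i] %in% c("donor", "both") && is.finite(rec$bx[i])) {
        ang <- bond_angle(c(rec$bx[i], rec$by[i], rec$bz[i]), P[i, ], P[j, ])
        ok <- ok || ang >= model$hb_angle_min
      }
      if (rec$role[j] %in% c("donor", "both") && is.finite(rec$bx[j])) {
        ang <- bond_angle(c(rec$bx[j], rec$by[j], rec$bz[j]), P[j, ], P[i, ])
        ok <- ok || ang >= model$hb_angle_min
      }
      if (ok) { satisfied <- TRUE; break }
    }
    if (!satisfied) cnt <- cnt + 1L
  }
  cnt
}

#' Peptide-bond omega geometry check
#'
#' Residue i fails when |omega_i| < cutoff, i.e. the peptide bond to the
#' following residue deviates from trans (180 degrees) by more than
#' 180 - cutoff. Cis-proline (omega near 0 preceding a proline) is exempt
#' by default.
#'
#' @param s A `bh3_structure`.
#' @param cutoff_deg Cutoff in degrees (default 150).
#' @param exempt_cis_proline Exempt omega bonds preceding proline when
#'   |omega| < 30 (cis).
#' @param chains Chains to check (default all polymer chains).
#' @return data.frame of failing residues (chain, resno, omega).
#' @export
omega_check <- function(s, cutoff_deg = 150, exempt_cis_proline = TRUE,
                        chains = chain_ids(s)) {
  out <- list()
  for (ch in chains) {
    bd <- backbone_dihedrals(s, ch)
    om <- bd$omega
    fail <- !is.na(om) & abs(om) < cutoff_deg
    if (exempt_cis_proline) {
      nxt <- c(bd$resid[-1], NA)
      fail <- fail & !(abs(om) < 30 & !is.na(nxt) & nxt == "PRO")
    }
    if (any(fail))
      out[[ch]] <- data.frame(chain = ch, resno = bd$resno[fail],
                              omega = om[fail], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chain = character(), resno = integer(), omega = numeric()))
  do.call(rbind, out)
}

#' Compute all design filters and gate on thresholds
#'
#' @param complex A designed `bh3_structure` complex.
#' @param thresholds A [filter_thresholds()].
#' @param split Partner split for the interface metrics.
#' @param model An [energy_model()].
#' @return A `filter_report`: metrics plus per-filter and overall pass flags.
#' @export
filter_report <- function(complex, thresholds = filter_thresholds(),
                          split = NULL, model = energy_model()) {
  ddg <- binding_energy(complex, model, split)
  sc <- tryCatch(shape_complementarity(complex, split),
                 error = function(e) NA_real_)
  unsat <- buried_unsat_polar(complex, split, model)
  om <- omega_check(complex, thresholds$omega_cutoff)
  pass <- list(
    binding_energy = ddg <= thresholds$ddg_max,
    sc = !is.na(sc) && sc >= thresholds$sc_min,
    buried_unsat = unsat <= thresholds$unsat_max,
    omega = nrow(om) == 0
  )
  structure(list(binding_energy = ddg, sc = sc, buried_unsat = unsat,
                 omega_failures = nrow(om), pass = pass,
                 pass_all = all(unlist(pass))),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter report: ddG=%.3f sc=%.3f unsat=%d omega_fail=%d -> %s\n",
              x$binding_energy, x$sc, x$buried_unsat, x$omega_failures,
              if (x$pass_all) "PASS" else "FAIL"))
  invisible(x)
}
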