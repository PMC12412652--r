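## interface_design: SASA/shell selection of designable positions and
## Monte Carlo simulated-annealing sequence design over discrete rotamers.

#' Design configuration
#'
#' Defaults mirror the two-shell interface design protocol: consecutive
#' design at binder positions within 8 then 12 A of the target, surface
#' positions selected by side-chain SASA (probe 2.2 A, threshold 30 A^2)
#' on the isolated binder monomer, hotspots fixed, and Pro/Cys/Trp/Gly
#' never introduced at designed positions.
#'
#' @param shell_distances Increasing distance cutoffs (A).
#' @param sasa_probe_radius Surface-selection probe (A).
#' @param surface_asa_min Minimum side-chain SASA (A^2) for a designable
#'   surface position.
#' @param disallowed_types 1-letter codes never introduced by design.
#' @param hotspots_fixed Keep hotspot identities and conformers fixed.
#' @param mc_temp_start,mc_temp_end,mc_steps Annealing schedule.
#' @param seed Integer seed driving the single RNG stream of the packer.
#' @return A `design_config` list.
#' @export
design_config <- function(shell_distances = c(8, 12), sasa_probe_radius = 2.2,
                          surface_asa_min = 30,
                          disallowed_types = c("P", "C", "W", "G"),
                          hotspots_fixed = TRUE,
                          mc_temp_start = 3, mc_temp_end = 0.05,
                          mc_steps = 3000, seed = 1) {
  stopifnot(all(diff(shell_distances) > 0), mc_temp_start > 0, mc_temp_end > 0)
  structure(as.list(environment()), class = "design_config")
}

#' Select designable binder positions for a shell
#'
#' A binder position is designable when (a) its side-chain SASA in the
#' isolated binder monomer is at least `surface_asa_min` (probe
#' `sasa_probe_radius`) -- core positions never change identity, (b) any of
#' its heavy atoms lies within `shell` Angstrom of any target heavy atom,
#' and (c) it is not a hotspot.
#'
#' @param complex `bh3_structure` with binder and target chains.
#' @param binder_chain Binder chain id.
#' @param cfg A [design_config()].
#' @param shell Distance cutoff (A).
#' @param hotspots Author residue numbers on the binder excluded from design.
#' @return Integer vector of binder residue numbers.
#' @export
select_designable <- function(complex, binder_chain, cfg = design_config(),
                              shell = cfg$shell_distances[1], hotspots = integer()) {
  binder <- subset_chains(complex, binder_chain)
  sas <- sidechain_sasa(binder, probe = cfg$sasa_probe_radius)
  surf_resnos <- as.integer(sub("^.*:", "", names(sas)[sas >= cfg$surface_asa_min]))
  ba <- complex$atoms[complex$atoms$chain == binder_chain & !complex$atoms$het &
                        complex$atoms$elem != "H", , drop = FALSE]
  ta <- complex$atoms[complex$atoms$chain != binder_chain & !complex$atoms$het &
                        complex$atoms$elem != "H", , drop = FALSE]
  if (!nrow(ta)) stop("complex has no target chain")
  d2 <- cross_dist2(as.matrix(ba[, c("x", "y", "z")]),
                    as.matrix(ta[, c("x", "y", "z")]))
  near <- ba$resno[apply(d2 < shell^2, 1, any)]
  out <- sort(intersect(intersect(unique(near), surf_resnos),
                        setdiff(unique(ba$resno), hotspots)))
  if (!length(out)) warning("no designable positions selected; repack-only")
  out
}

## Build candidate atom records for one (identity, chi-tuple) at a position.
candidate_records <- function(chain, resno, resid, N, CA, C, chi) {
  sc <- build_sidechain(resid, N, CA, C, chi)
  if (!nrow(sc)) {
    return(data.frame(chain = character(), resno = integer(), insert = character(),
                      resid = character(), elety = character(), elem = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      is_bb = logical(), role = character(),
                      bx = numeric(), by = numeric(), bz = numeric()))
  }
  rec <- data.frame(chain = chain, resno = resno, insert = "", resid = resid,
                    elety = sc$name, elem = sc$elem, x = sc$x, y = sc$y, z = sc$z,
                    is_bb = FALSE, stringsAsFactors = FALSE)
  rec$role <- vapply(rec$elety, function(e) polar_role(resid, e), "")
  rec$bx <- rec$by <- rec$bz <- NA_real_
  topo <- SIDECHAIN_TOPOLOGY[[resid]] %||% list()
  for (i in which(rec$role != "none")) {
    hit <- Filter(function(t) t$name == rec$elety[i], topo)
    base <- if (length(hit)) hit[[1]]$prev3[3] else "CA"
    j <- which(rec$elety == base)
    bcoord <- if (length(j)) as.numeric(rec[j[1], c("x", "y", "z")])
    else if (base == "CA") CA else NA_real_
    if (all(is.finite(bcoord))) {
      rec$bx[i] <- bcoord[1]; rec$by[i] <- bcoord[2]; rec$bz[i] <- bcoord[3]
    }
  }
  rec
}

#' Build a rotamer set for designable positions
#'
#' Coarse backbone-independent library: chi1 and chi2 sampled on
#' (-60, 60, 180), deeper chis held at extended values. The native
#' identity and conformation (the atoms currently in the structure) are
#' always candidate 1. Identities default to all 20 minus the disallowed
#' set; hotspot-fixed positions get exactly their current identity.
#'
#' @param complex `bh3_structure`.
#' @param binder_chain Binder chain id.
#' @param positions Residue numbers to build candidates for.
#' @param cfg A [design_config()].
#' @param identities Optional character vector (1-letter) of allowed
#'   identities, or a named list per position.
#' @return A `rotamer_set`: list keyed by position with `candidates`.
#' @export
build_rotamer_set <- function(complex, binder_chain, positions,
                              cfg = design_config(), identities = NULL) {
  a <- complex$atoms
  a$elety <- trimws(a$elety)
  out <- list()
  allowed_default <- setdiff(unname(AA321[1:20]), cfg$disallowed_types)
  for (p in positions) {
    sel <- a$chain == binder_chain & a$resno == p & !a$het
    if (!any(sel)) stop("position ", p, " not found on binder chain")
    res <- a[sel, , drop = FALSE]
    native_resid <- res$resid[1]
    getc <- function(nm) as.numeric(res[res$elety == nm, c("x", "y", "z")][1, ])
    N <- getc("N"); CA <- getc("CA"); C <- getc("C")
    if (anyNA(c(N, CA, C))) stop("position ", p, " missing backbone atoms")
    ## native candidate: current side-chain atoms as-is
    nat <- res[!(res$elety %in% BACKBONE_NAMES), , drop = FALSE]
    natrec <- if (nrow(nat)) {
      r <- data.frame(chain = binder_chain, resno = p, insert = "",
                      resid = native_resid, elety = nat$elety, elem = nat$elem,
                      x = nat$x, y = nat$y, z = nat$z, is_bb = FALSE,
                      stringsAsFactors = FALSE)
      r$role <- vapply(r$elety, function(e) polar_role(native_resid, e), "")
      r$bx <- r$by <- r$bz <- NA_real_
      for (i in which(r$role != "none")) {
        topo <- SIDECHAIN_TOPOLOGY[[native_resid]] %||% list()
        hit <- Filter(function(t) t$name == r$elety[i], topo)
        base <- if (length(hit)) hit[[1]]$prev3[3] else "CA"
        j <- which(r$elety == base)
        bc <- if (length(j)) as.numeric(r[j[1], c("x", "y", "z")]) else CA
        r$bx[i] <- bc[1]; r$by[i] <- bc[2]; r$bz[i] <- bc[3]
      }
      r
    } else candidate_records(binder_chain, p, native_resid, N, CA, C, numeric())
    cands <- list(list(resid = native_resid, chi = NULL, records = natrec,
                       native = TRUE))
    ids <- if (is.null(identities)) allowed_default
    else if (is.list(identities)) identities[[as.character(p)]] %||% allowed_default
    else identities
    ids3 <- unname(AA123[union(ids, AA321[native_resid])])
    for (id3 in ids3) {
      nc <- n_chi(id3)
      chis <- if (nc == 0) list(numeric())
      else if (nc == 1) lapply(CHI_GRID, function(x) x)
      else {
        g <- expand.grid(chi1 = CHI_GRID, chi2 = CHI_GRID)
        lapply(seq_len(nrow(g)), function(i) c(g$chi1[i], g$chi2[i]))
      }
      for (chi in chis) {
        cands[[length(cands) + 1]] <- list(
          resid = id3, chi = chi,
          records = candidate_records(binder_chain, p, id3, N, CA, C, chi),
          native = FALSE)
      }
    }
    out[[as.character(p)]] <- list(position = p, native = native_resid,
                                   backbone = list(N = N, CA = CA, C = C),
                                   candidates = cands)
  }
  structure(out, class = "rotamer_set")
}

## Stack all candidates' atom records of one position; `cand` indexes them.
stack_candidates <- function(cands) {
  recs <- lapply(seq_along(cands), function(i) {
    r <- cands[[i]]$records
    if (nrow(r)) r$cand <- i
    r
  })
  df <- do.call(rbind, recs[vapply(recs, nrow, 0L) > 0])
  if (is.null(df)) df <- cands[[1]]$records[0, ]
  df
}

## Vectorized steric energy matrix between two record sets (0 beyond cutoff).
steric_matrix <- function(ra, rb, model) {
  d2 <- cross_dist2(as.matrix(ra[, c("x", "y", "z")]),
                    as.matrix(rb[, c("x", "y", "z")]))
  r0 <- outer(vdw_radius(ra$elem), vdw_radius(rb$elem), "+")
  E <- matrix(0, nrow(ra), nrow(rb))
  m <- d2 < (r0 + model$steric_cutoff_pad)^2
  if (any(m)) E[m] <- steric_energy_vec(sqrt(pmax(d2[m], 0)), r0[m], model)
  E
}

## Accumulate directional H-bond energies into a candidate-pair matrix.
accumulate_hbonds <- function(M, don, acc, don_cand, acc_cand, model,
                              transpose = FALSE) {
  if (!nrow(don) || !nrow(acc)) return(M)
  d2 <- cross_dist2(as.matrix(don[, c("x", "y", "z")]),
                    as.matrix(acc[, c("x", "y", "z")]))
  hits <- which(d2 < model$hb_dmax^2 & d2 > 2.4^2, arr.ind = TRUE)
  for (r in seq_len(nrow(hits))) {
    i <- hits[r, 1]; j <- hits[r, 2]
    if (!is.finite(don$bx[i])) next
    ang <- bond_angle(c(don$bx[i], don$by[i], don$bz[i]),
                      as.numeric(don[i, c("x", "y", "z")]),
                      as.numeric(acc[j, c("x", "y", "z")]))
    if (ang < model$hb_angle_min) next
    d <- sqrt(d2[i, j])
    fa <- min(1, (ang - model$hb_angle_min) / 60)
    e <- -model$w_hb * exp(-((d - model$hb_d0)^2) / (2 * model$hb_sigma^2)) * fa
    a <- don_cand[i]; b <- acc_cand[j]
    if (transpose) M[b, a] <- M[b, a] + e else M[a, b] <- M[a, b] + e
  }
  M
}

## Precompute single/pair energy tables for the packer (vectorized over
## the stacked candidate atoms of each position).
pack_tables <- function(complex, binder_chain, positions, rotamers, model) {
  rec <- atom_records(complex)
  movable <- rec$chain == binder_chain & rec$resno %in% positions & !rec$is_bb
  fixed <- rec[!movable, , drop = FALSE]
  np <- length(positions)
  singles <- vector("list", np)
  stacks <- lapply(as.character(positions),
                   function(p) stack_candidates(rotamers[[p]]$candidates))
  for (k in seq_len(np)) {
    cands <- rotamers[[as.character(positions[k])]]$candidates
    nc <- length(cands)
    same_res <- fixed$chain == binder_chain & fixed$resno == positions[k]
    env <- fixed[!same_res, , drop = FALSE]
    S <- stacks[[k]]
    e <- stats::setNames(unname(model$ref[vapply(cands, `[[`, "", "resid")]),
                         NULL)
    if (nrow(S) && nrow(env)) {
      Est <- steric_matrix(S, env, model)
      st_by_cand <- rep(0, nc)
      rs <- rowsum(rowSums(Est), S$cand)
      st_by_cand[as.integer(rownames(rs))] <- rs[, 1]
      M <- matrix(0, nc, 1)
      don <- S[S$role %in% c("donor", "both"), , drop = FALSE]
      accE <- env[env$role %in% c("acceptor", "both"), , drop = FALSE]
      donE <- env[env$role %in% c("donor", "both"), , drop = FALSE]
      acc <- S[S$role %in% c("acceptor", "both"), , drop = FALSE]
      M <- accumulate_hbonds(M, don, accE, don$cand, rep(1L, nrow(accE)), model)
      M <- accumulate_hbonds(M, donE, acc, rep(1L, nrow(donE)), acc$cand, model,
                             transpose = TRUE)
      ## burial of candidate polar atoms against the fixed environment
      bury <- vapply(seq_len(nc), function(ci)
        burial_penalty(S[S$cand == ci, , drop = FALSE], env, model), 0)
      e <- e + st_by_cand + M[, 1] + bury
    }
    singles[[k]] <- e
  }
  pairs <- list()
  if (np >= 2) {
    for (i in seq_len(np - 1)) for (j in (i + 1):np) {
      bbi <- rotamers[[as.character(positions[i])]]$backbone$CA
      bbj <- rotamers[[as.character(positions[j])]]$backbone$CA
      if (sqrt(sum((bbi - bbj)^2)) > 18) next
      ci <- rotamers[[as.character(positions[i])]]$candidates
      cj <- rotamers[[as.character(positions[j])]]$candidates
      Si <- stacks[[i]]; Sj <- stacks[[j]]
      M <- matrix(0, length(ci), length(cj))
      if (nrow(Si) && nrow(Sj)) {
        Est <- steric_matrix(Si, Sj, model)
        if (any(Est != 0)) {
          Ii <- outer(Si$cand, seq_along(ci), "==") * 1
          Ij <- outer(Sj$cand, seq_along(cj), "==") * 1
          M <- t(Ii) %*% Est %*% Ij
        }
        M <- accumulate_hbonds(M, Si[Si$role %in% c("donor", "both"), , drop = FALSE],
                               Sj[Sj$role %in% c("acceptor", "both"), , drop = FALSE],
                               Si$cand[Si$role %in% c("donor", "both")],
                               Sj$cand[Sj$role %in% c("acceptor", "both")], model)
        M <- accumulate_hbonds(M, Sj[Sj$role %in% c("donor", "both"), , drop = FALSE],
                               Si[Si$role %in% c("acceptor", "both"), , drop = FALSE],
                               Sj$cand[Sj$role %in% c("donor", "both")],
                               Si$cand[Si$role %in% c("acceptor", "both")], model,
                               transpose = TRUE)
      }
      if (any(M != 0)) pairs[[paste(i, j)]] <- M
    }
  }
  list(singles = singles, pairs = pairs, positions = positions)
}

state_energy <- function(tables, state) {
  e <- sum(vapply(seq_along(state), function(k) tables$singles[[k]][state[k]], 0))
  for (nm in names(tables$pairs)) {
    ij <- as.integer(strsplit(nm, " ")[[1]])
    e <- e + tables$pairs[[nm]][state[ij[1]], state[ij[2]]]
  }
  e
}

## Write a candidate's identity/atoms into the complex at a position.
install_candidate <- function(complex, binder_chain, position, cand) {
  a <- complex$atoms
  a$elety <- trimws(a$elety)
  sel <- a$chain == binder_chain & a$resno == position & !a$het
  bb <- a[sel & a$elety %in% BACKBONE_NAMES, , drop = FALSE]
  bb$resid <- cand$resid
  sc <- cand$records
  scdf <- if (nrow(sc)) data.frame(chain = binder_chain, resno = position,
                                   insert = "", resid = cand$resid,
                                   elety = sc$elety, elem = sc$elem,
                                   x = sc$x, y = sc$y, z = sc$z,
                                   occ = 1, b = 0, het = FALSE,
                                   stringsAsFactors = FALSE) else NULL
  a <- rbind(a[!sel, , drop = FALSE], bb, scdf)
  ord <- order(a$het, match(a$chain, unique(a$chain)), a$resno,
               match(a$elety, c(BACKBONE_NAMES, "CB")), a$elety)
  new_structure(a[ord, , drop = FALSE], complex$metadata)
}

#' Monte Carlo simulated-annealing sequence design
#'
#' Single-position substitution moves with Metropolis acceptance over a
#' geometric temperature schedule; energies come from precomputed
#' single/pair tables under the simplified model. Deterministic for a
#' fixed `cfg$seed`; the best-encountered state is returned. Hotspot
#' positions should simply not be in `positions`.
#'
#' @param complex `bh3_structure`.
#' @param positions Designable residue numbers on the binder chain
#'   (empty = repack-only no-op: input returned unchanged).
#' @param rotamers A [build_rotamer_set()] result covering `positions`.
#' @param model An [energy_model()].
#' @param cfg A [design_config()].
#' @param binder_chain Binder chain id (defaults to metadata, else "X").
#' @return List: `complex` (designed), `energy` (best), `initial_energy`,
#'   `trace` (data.frame step/current/best), `state`, `sequence` (per
#'   position identity).
#' @export
mc_design <- function(complex, positions, rotamers, model = energy_model(),
                      cfg = design_config(),
                      binder_chain = complex$metadata$binder_chain %||% "X") {
  if (!length(positions)) {
    return(list(complex = complex, energy = NA_real_, initial_energy = NA_real_,
                trace = data.frame(), state = integer(), sequence = character()))
  }
  positions <- sort(positions)
  for (p in positions) {
    if (is.null(rotamers[[as.character(p)]]) ||
        !length(rotamers[[as.character(p)]]$candidates))
      stop("empty rotamer set at position ", p)
  }
  tables <- pack_tables(complex, binder_chain, positions, rotamers, model)
  np <- length(positions)
  ncand <- vapply(as.character(positions),
                  function(p) length(rotamers[[p]]$candidates), 0L)
  state <- rep(1L, np)  # native conformers
  e_cur <- state_energy(tables, state)
  e_init <- e_cur
  best <- state; e_best <- e_cur
  steps <- cfg$mc_steps
  temps <- cfg$mc_temp_start * (cfg$mc_temp_end / cfg$mc_temp_start)^
    (seq_len(steps) / steps)
  trace <- matrix(NA_real_, nrow = steps, ncol = 2)
  with_seed(cfg$seed, {
    for (s in seq_len(steps)) {
      k <- sample.int(np, 1)
      c_new <- sample.int(ncand[k], 1)
      if (c_new != state[k]) {
        de <- tables$singles[[k]][c_new] - tables$singles[[k]][state[k]]
        for (nm in names(tables$pairs)) {
          ij <- as.integer(strsplit(nm, " ")[[1]])
          if (ij[1] == k) de <- de + tables$pairs[[nm]][c_new, state[ij[2]]] -
              tables$pairs[[nm]][state[k], state[ij[2]]]
          else if (ij[2] == k) de <- de + tables$pairs[[nm]][state[ij[1]], c_new] -
              tables$pairs[[nm]][state[ij[1]], state[k]]
        }
        if (de <= 0 || stats::runif(1) < exp(-de / temps[s])) {
          state[k] <- c_new
          e_cur <- e_cur + de
          if (e_cur < e_best) { e_best <- e_cur; best <- state }
        }
      }
      trace[s, ] <- c(e_cur, e_best)
    }
  })
  out <- complex
  seqs <- character(np)
  for (k in seq_len(np)) {
    cd <- rotamers[[as.character(positions[k])]]$candidates[[best[k]]]
    out <- install_candidate(out, binder_chain, positions[k], cd)
    seqs[k] <- cd$resid
  }
  list(complex = out, energy = e_best, initial_energy = e_init,
       trace = data.frame(step = seq_len(steps), current = trace[, 1],
                          best = trace[, 2]),
       state = best, sequence = stats::setNames(seqs, positions))
}

#' Two-shell design protocol with final repack
#'
#' Runs [mc_design()] at the first shell (default 8 A), then at the second
#' (12 A), then a repack-only pass (identities fixed to the designed
#' sequence, conformers re-optimized) standing in for gradient
#' minimization. Hotspots are never designable.
#'
#' @param complex Graft complex (`bh3_structure` with binder chain).
#' @param cfg A [design_config()].
#' @param model An [energy_model()].
#' @param binder_chain Binder chain id.
#' @param hotspots Hotspot residue numbers on the binder.
#' @param identities Optional allowed identities (see [build_rotamer_set()]).
#' @return List: `complex`, `record` (per-stage energies, designed
#'   sequence), `stages`.
#' @export
design_protocol <- function(complex, cfg = design_config(),
                            model = energy_model(),
                            binder_chain = complex$metadata$binder_chain %||% "X",
                            hotspots = integer(), identities = NULL) {
  stages <- list()
  cur <- complex
  for (si in seq_along(cfg$shell_distances)) {
    shell <- cfg$shell_distances[si]
    pos <- select_designable(cur, binder_chain, cfg, shell, hotspots)
    if (length(pos)) {
      rot <- build_rotamer_set(cur, binder_chain, pos, cfg, identities)
      res <- mc_design(cur, pos, rot, model, cfg, binder_chain)
      cur <- res$complex
      stages[[paste0("shell_", shell)]] <-
        res[c("energy", "initial_energy", "sequence")]
    } else {
      stages[[paste0("shell_", shell)]] <- list(energy = NA, sequence = character())
    }
  }
  ## final repack: identities fixed, conformers only
  pos <- select_designable(cur, binder_chain, cfg,
                           cfg$shell_distances[length(cfg$shell_distances)],
                           hotspots)
  if (length(pos)) {
    cur_ids <- lapply(stats::setNames(pos, pos), function(p) {
      r3 <- cur$atoms$resid[cur$atoms$chain == binder_chain &
                              cur$atoms$resno == p][1]
      unname(AA321[r3])
    })
    rot <- build_rotamer_set(cur, binder_chain, pos, cfg, identities = cur_ids)
    res <- mc_design(cur, pos, rot, model, cfg, binder_chain)
    cur <- res$complex
    stages$repack <- res[c("energy", "initial_energy")]
  }
  seqrec <- extract_sequence(cur, binder_chain)
  list(complex = cur,
       record = list(sequence = seqrec$residues, stages = stages,
                     final_energy = stages$repack$energy %||% NA_real_),
       stages = stages)
}
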