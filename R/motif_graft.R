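## motif_graft: scan a helical scaffold for segments geometrically
## compatible with a bound BH3-like motif, clash-test the docked scaffold,
## and thread hotspot identities onto accepted placements.

#' Grafting configuration
#'
#' Tolerances mirror the grafting protocol used for the binder designs:
#' full-backbone RMSD tolerance 3.0 A, endpoint (N/C points) tolerance
#' 2.0 A, clash cutoff 0 with the scaffold reduced to glycine (backbone
#' only) for the clash test, full-backbone alignment, and reversion of
#' non-hotspot positions to the scaffold's native sequence.
#'
#' @param full_bb_rmsd_tol Full-backbone RMSD tolerance (A).
#' @param endpoint_rmsd_tol N/C endpoint RMSD tolerance (A).
#' @param clash_cutoff Maximum allowed clash count.
#' @param clash_pad Soft tolerance subtracted from vdW contact distance (A).
#' @param cis_exempt Unused here; present for config round-trips.
#' @return A `graft_config` list.
#' @export
graft_config <- function(full_bb_rmsd_tol = 3.0, endpoint_rmsd_tol = 2.0,
                         clash_cutoff = 0, clash_pad = 0.6, cis_exempt = TRUE) {
  stopifnot(full_bb_rmsd_tol > 0, endpoint_rmsd_tol > 0, clash_cutoff >= 0)
  structure(list(full_bb_rmsd_tol = full_bb_rmsd_tol,
                 endpoint_rmsd_tol = endpoint_rmsd_tol,
                 clash_cutoff = clash_cutoff, clash_pad = clash_pad,
                 cis_exempt = cis_exempt),
            class = "graft_config")
}

#' Prepare context and motif from a bound complex
#'
#' Splits a target-peptide complex into the design context (target chains)
#' and a motif: the peptide span reduced to backbone plus beta carbon, with
#' every non-hotspot identity set to alanine and the hotspot identities
#' (default I, L, I, G, D at motif positions 1, 5, 8, 9, 10 -- the h1, h2,
#' h3, h3+1, h3+2 roles) preserved.
#'
#' @param complex A `bh3_structure` containing target and bound peptide.
#' @param peptide_chain Chain id of the bound helical peptide.
#' @param motif_span `c(first, last)` author residue numbers on the peptide.
#' @param hotspot_indices 1-based positions within the motif.
#' @return List with `context` (`bh3_structure`) and `motif` (a `bh3_motif`).
#' @export
prepare_context_motif <- function(complex, peptide_chain, motif_span,
                                  hotspot_indices = c(1, 5, 8, 9, 10)) {
  if (!peptide_chain %in% chain_ids(complex))
    stop("peptide chain '", peptide_chain, "' not in complex")
  hotspot_indices <- sort(as.integer(hotspot_indices))
  span <- seq(motif_span[1], motif_span[2])
  L <- length(span)
  if (L < max(hotspot_indices))
    stop("motif span (", L, " residues) shorter than max hotspot index (",
         max(hotspot_indices), ")")
  ctx <- subset_chains(complex, setdiff(chain_ids(complex, polymer = FALSE),
                                        peptide_chain))
  a <- complex$atoms
  a <- a[a$chain == peptide_chain & !a$het & a$resno %in% span, , drop = FALSE]
  a$elety <- trimws(a$elety)
  keep <- a$elety %in% c(BACKBONE_NAMES, "CB")
  a <- a[keep, , drop = FALSE]
  per_res <- split(a$elety, a$resno)
  bad <- names(per_res)[!vapply(per_res, function(e) all(c("N", "CA", "C") %in% e), TRUE)]
  if (length(bad))
    stop("motif residues missing backbone atoms: ", paste(bad, collapse = ","))
  idx <- match(a$resno, span)
  hot_id <- a$resid[match(hotspot_indices, idx)]
  is_hot <- idx %in% hotspot_indices
  a$resid[!is_hot] <- "ALA"
  ## renumber motif 1..L
  a$resno <- idx
  motif <- structure(list(
    structure = new_structure(a, metadata = list(origin = "prepare_context_motif")),
    length = L,
    hotspot_indices = hotspot_indices,
    hotspot_identities = hot_id,
    roles = c("h1", "h2", "h3", "h3+1", "h3+2")[seq_along(hotspot_indices)]
  ), class = "bh3_motif")
  list(context = ctx, motif = motif)
}

## Backbone (N,CA,C,O) coordinate block for residues of one chain, ordered
## residue-major then N,CA,C,O. Residues missing any of the four are an error.
backbone_block <- function(s, chain, resnos = NULL) {
  a <- s$atoms
  a <- a[a$chain == chain & !a$het, , drop = FALSE]
  a$elety <- trimws(a$elety)
  a <- a[a$elety %in% BACKBONE_NAMES, , drop = FALSE]
  if (!is.null(resnos)) a <- a[a$resno %in% resnos, , drop = FALSE]
  ord <- order(match(a$resno, if (is.null(resnos)) sort(unique(a$resno)) else resnos),
               match(a$elety, BACKBONE_NAMES))
  a <- a[ord, , drop = FALSE]
  n_res <- length(unique(a$resno))
  if (nrow(a) != 4 * n_res) stop("incomplete backbone in chain ", chain)
  as.matrix(a[, c("x", "y", "z")])
}

#' Scan a scaffold for graft-compatible windows
#'
#' For every contiguous window of the scaffold with the motif's length, the
#' window backbone (N, CA, C, O) is least-squares superposed onto the motif
#' backbone (full-backbone alignment). The endpoint RMSD is evaluated over
#' the first and last motif residues' backbone atoms under that same
#' transform. A window is accepted iff full-backbone RMSD and endpoint RMSD
#' are within tolerance and, with the whole scaffold posed into the context
#' frame, the glycine-reduced clash count against the context does not
#' exceed the cutoff.
#'
#' @param motif A `bh3_motif` from [prepare_context_motif()].
#' @param scaffold Single-chain `bh3_structure`.
#' @param cfg A [graft_config()].
#' @param context Optional context structure; when supplied, the clash test
#'   is applied (omitted otherwise, e.g. for geometry-only scans).
#' @return List of `graft_solution` objects sorted by ascending
#'   full-backbone RMSD (ties by window start).
#' @export
find_graft_sites <- function(motif, scaffold, cfg = graft_config(),
                             context = NULL) {
  sc_chain <- chain_ids(scaffold)
  if (length(sc_chain) != 1) stop("scaffold must be a single polymer chain")
  rt <- residue_table(scaffold, sc_chain)
  L <- motif$length
  if (nrow(rt) < L) {
    warning("scaffold shorter than motif; no graft windows")
    return(list())
  }
  mb <- backbone_block(motif$structure, chain_ids(motif$structure))
  endpoint_rows <- c(1:4, (4 * (L - 1) + 1):(4 * L))
  sols <- list()
  for (w in seq_len(nrow(rt) - L + 1)) {
    resnos <- rt$resno[w:(w + L - 1)]
    wb <- tryCatch(backbone_block(scaffold, sc_chain, resnos),
                   error = function(e) NULL)
    if (is.null(wb) || nrow(wb) != nrow(mb)) next
    fit <- suppressWarnings(kabsch(wb, mb))
    if (fit$rmsd > cfg$full_bb_rmsd_tol) next
    wbt <- transform_xyz(wb, fit$rotation, fit$translation)
    ep <- sqrt(mean(rowSums((wbt[endpoint_rows, ] - mb[endpoint_rows, ])^2)))
    if (ep > cfg$endpoint_rmsd_tol) next
    sol <- structure(list(window_start = w, window_resnos = resnos, length = L,
                          placement = fit, full_bb_rmsd = fit$rmsd,
                          endpoint_rmsd = ep, clash_score = NA_integer_),
                     class = "graft_solution")
    if (!is.null(context)) {
      posed <- rigid_place(scaffold, fit$rotation, fit$translation)
      sol$clash_score <- clash_score(context, posed, cfg,
                                     exclude_resnos = resnos)
      if (sol$clash_score > cfg$clash_cutoff) next
    }
    sols[[length(sols) + 1]] <- sol
  }
  ## deterministic ordering: RMSD rounded to 1e-6 A so numerically tied
  ## windows (e.g. ideal-helix repeats) sort stably by window start
  ord <- order(round(vapply(sols, `[[`, 0, "full_bb_rmsd"), 6),
               vapply(sols, `[[`, 0L, "window_start"))
  sols[ord]
}

#' Glycine-reduction clash count between context and a posed scaffold
#'
#' The scaffold is reduced to backbone N, CA, C, O (the glycine clash-test
#' semantics read literally: glycine has no beta carbon); heavy-atom pairs
#' (context atom, scaffold atom) closer than `r_i + r_j - clash_pad` count
#' as clashes. Backbone atoms of the grafted window are excluded -- they
#' replace the native bound peptide and legitimately occupy its groove.
#'
#' @param context,posed_scaffold `bh3_structure`s in a common frame.
#' @param cfg A [graft_config()] (supplies the 0.6 A soft pad).
#' @param exclude_resnos Scaffold residue numbers excluded from the count.
#' @return Integer clash count.
#' @export
clash_score <- function(context, posed_scaffold, cfg = graft_config(),
                        exclude_resnos = NULL) {
  ca <- context$atoms
  ca <- ca[ca$elem != "H", , drop = FALSE]
  sa <- posed_scaffold$atoms
  sa$elety <- trimws(sa$elety)
  sa <- sa[!sa$het & sa$elety %in% BACKBONE_NAMES, , drop = FALSE]
  if (!is.null(exclude_resnos)) sa <- sa[!sa$resno %in% exclude_resnos, , drop = FALSE]
  if (!nrow(ca) || !nrow(sa)) return(0L)
  d2 <- cross_dist2(as.matrix(ca[, c("x", "y", "z")]),
                    as.matrix(sa[, c("x", "y", "z")]))
  lim <- outer(vdw_radius(ca$elem), vdw_radius(sa$elem), "+") - cfg$clash_pad
  sum(d2 < lim^2 & d2 > 0)
}

#' Apply an accepted graft: pose the scaffold and thread hotspots
#'
#' Poses the whole scaffold into the context frame, writes the motif's
#' hotspot identities onto the corresponding window positions (side chains
#' beyond CB are trimmed at changed positions; a rebuild happens at design
#' time), reverts every other position to the scaffold's native sequence,
#' and merges with the context. Graft provenance (window, RMSDs, clash
#' score) is recorded in `metadata$remarks` and survives PDB round trips.
#'
#' @param sol An accepted `graft_solution`.
#' @param motif The `bh3_motif` grafted.
#' @param scaffold The unposed scaffold structure.
#' @param context The context structure.
#' @param binder_chain Chain id given to the posed scaffold in the output.
#' @return A `bh3_structure` complex (context + grafted binder).
#' @export
apply_graft <- function(sol, motif, scaffold, context, binder_chain = "X") {
  posed <- rigid_place(scaffold, sol$placement$rotation, sol$placement$translation)
  a <- posed$atoms
  a$chain <- binder_chain
  win_resnos <- sol$window_resnos
  for (k in seq_along(motif$hotspot_indices)) {
    rn <- win_resnos[motif$hotspot_indices[k]]
    ident <- motif$hotspot_identities[k]
    sel <- a$resno == rn
    if (!any(sel)) next
    if (a$resid[sel][1] != ident) {
      a$resid[sel] <- ident
      keepnm <- c(BACKBONE_NAMES, "CB")
      a <- a[!(sel & !(trimws(a$elety) %in% keepnm)), , drop = FALSE]
      sel <- a$resno == rn
      if (ident != "GLY" && !("CB" %in% trimws(a$elety[sel]))) {
        bb <- a[sel & trimws(a$elety) %in% c("N", "CA", "C"), ]
        getc <- function(nm) as.numeric(bb[trimws(bb$elety) == nm, c("x", "y", "z")])
        cb <- place_cb(getc("N"), getc("CA"), getc("C"))
        a <- rbind(a, data.frame(chain = binder_chain, resno = rn, insert = "",
                                 resid = ident, elety = "CB", elem = "C",
                                 x = cb[1], y = cb[2], z = cb[3],
                                 occ = 1, b = 0, het = FALSE))
      }
    }
  }
  a <- a[order(a$resno, match(trimws(a$elety), c(BACKBONE_NAMES, "CB")),
               trimws(a$elety)), , drop = FALSE]
  binder <- new_structure(a)
  cx <- merge_structures(context, binder)
  cx$metadata$remarks <- c(cx$metadata$remarks, sprintf(
    "GRAFT window=%d len=%d full_bb_rmsd=%.3f endpoint_rmsd=%.3f clash=%s",
    sol$window_start, sol$length, sol$full_bb_rmsd, sol$endpoint_rmsd,
    ifelse(is.na(sol$clash_score), "NA", sol$clash_score)))
  cx$metadata$graft <- sol[c("window_start", "window_resnos", "length",
                             "full_bb_rmsd", "endpoint_rmsd", "clash_score")]
  cx$metadata$binder_chain <- binder_chain
  cx
}
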