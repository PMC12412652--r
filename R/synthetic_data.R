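## synthetic_data: generators for every input class the pipeline consumes,
## each deterministic per seed and carrying its ground truth.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Build an ideal helical (or arbitrary-dihedral) peptide
#'
#' Generates a polypeptide backbone with standard bond lengths/angles by
#' sequential NeRF placement, at the requested per-residue dihedrals
#' (defaults: ideal alpha helix, phi -57, psi -47, omega 180), then attaches
#' coarse side chains at default chi angles.
#'
#' @param sequence One-letter sequence string (sets the length).
#' @param phi,psi,omega Dihedrals in degrees (scalar or per-residue vector).
#' @param chain Chain id for the output.
#' @param rotation,translation Optional rigid placement applied to the
#'   finished coordinates.
#' @param sidechains Attach side-chain atoms (default TRUE; FALSE gives
#'   backbone N, CA, C, O plus CB).
#' @return A `bh3_structure` with one chain.
#' @export
build_helix <- function(sequence, phi = -57, psi = -47, omega = 180,
                        chain = "A", rotation = NULL, translation = NULL,
                        sidechains = TRUE) {
  seqstr <- as_sequence_string(sequence)
  L <- nchar(seqstr)
  if (L < 4) stop("helix length must be >= 4")
  aa1 <- strsplit(seqstr, "")[[1]]
  if (any(aa1 == "X")) stop("cannot build coordinates for unknown residue X")
  aa3 <- unname(AA123[aa1])
  phi <- rep_len(phi, L); psi <- rep_len(psi, L); omega <- rep_len(omega, L)

  ## backbone internal geometry (standard values)
  b_n_ca <- 1.458; b_ca_c <- 1.525; b_c_n <- 1.329; b_c_o <- 1.231
  a_n_ca_c <- 111.2; a_ca_c_n <- 116.2; a_c_n_ca <- 121.7; a_ca_c_o <- 120.5

  N <- CA <- C <- O <- matrix(NA_real_, L, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_n_ca, 0, 0)
  C[1, ] <- place_atom(c(0, 1, 0), N[1, ], CA[1, ], b_ca_c, a_n_ca_c, phi[1])
  for (i in seq_len(L - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], b_c_n, a_ca_c_n, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], b_n_ca, a_c_n_ca, omega[i])
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], b_ca_c, a_n_ca_c, phi[i + 1])
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], b_c_o, a_ca_c_o, psi[i] + 180)
  }
  O[L, ] <- place_atom(N[L, ], CA[L, ], C[L, ], b_c_o, a_ca_c_o, psi[L] + 180)

  rows <- vector("list", L)
  for (i in seq_len(L)) {
    bb <- data.frame(name = c("N", "CA", "C", "O"),
                     elem = c("N", "C", "C", "O"),
                     rbind(N[i, ], CA[i, ], C[i, ], O[i, ]),
                     stringsAsFactors = FALSE)
    names(bb)[3:5] <- c("x", "y", "z")
    if (sidechains || aa3[i] != "GLY") {
      sc <- build_sidechain(aa3[i], N[i, ], CA[i, ], C[i, ])
      if (!sidechains) sc <- sc[sc$name == "CB", , drop = FALSE]
      if (nrow(sc)) {
        names(sc)[1] <- "name"
        bb <- rbind(bb, sc)
      }
    }
    rows[[i]] <- data.frame(chain = chain, resno = i, insert = "",
                            resid = aa3[i], elety = bb$name, elem = bb$elem,
                            x = bb$x, y = bb$y, z = bb$z,
                            occ = 1, b = 0, het = FALSE, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  if (!is.null(rotation) || !is.null(translation)) {
    R <- rotation %||% diag(3)
    tr <- translation %||% c(0, 0, 0)
    xyz <- transform_xyz(as.matrix(atoms[, c("x", "y", "z")]), R, tr)
    atoms[, c("x", "y", "z")] <- xyz
  }
  new_structure(atoms, metadata = list(generator = "build_helix"))
}

## Principal axis (unit vector) of a chain's CA trace.
helix_axis <- function(s, chain) {
  ca <- atom_coords(s, chain, "CA")
  ca <- ca[stats::complete.cases(ca), , drop = FALSE]
  unit(ca[nrow(ca), ] - ca[1, ])
}

rigid_place <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  a <- s$atoms
  a[, c("x", "y", "z")] <- transform_xyz(as.matrix(a[, c("x", "y", "z")]),
                                         rotation, translation)
  new_structure(a, s$metadata)
}

#' Build a toy groove-plus-motif complex
#'
#' Two flanking helices (chains A, B) form a hydrophobic cleft with a
#' 13-residue motif helix (chain C) docked in it, emulating a BH3 helix in
#' a groove. Hotspot-like large hydrophobics line the contact. Deterministic
#' per seed (the seed only jitters side-chain-free placement, never the
#' contact guarantee).
#'
#' @param seed Integer RNG seed.
#' @param motif_sequence Sequence of the docked helix (default carries
#'   I/L/I/G/D at positions 1, 5, 8, 9, 10).
#' @param groove_separation Distance between groove helix axes (Angstrom).
#' @param motif_height Height of the motif helix above the groove plane (default 7.5).
#' @return A 3-chain `bh3_structure`; attribute `contacts` gives the number
#'   of inter-chain heavy-atom contacts under 5 A.
#' @export
build_toy_complex <- function(seed = 1,
                              motif_sequence = "IAAALAAIGDAAA",
                              groove_separation = 10.5,
                              motif_height = 7.5) {
  with_seed(seed, {
    g_seq <- "ALALLALLALALLALA"
    g1 <- build_helix(g_seq, chain = "A")
    ## align helix axis to x for controlled placement
    ca <- atom_coords(g1, "A", "CA")
    fit <- suppressWarnings(
      kabsch(ca, cbind(seq(0, by = 1.5, length.out = nrow(ca)), 0, 0)))
    g1 <- rigid_place(g1, fit$rotation, fit$translation)
    g2 <- rigid_place(subset_chains(g1, "A"), diag(3), c(0, groove_separation, 0))
    g2$atoms$chain <- "B"
    m <- build_helix(motif_sequence, chain = "C")
    cam <- atom_coords(m, "C", "CA")
    fitm <- suppressWarnings(
      kabsch(cam, cbind(seq(2, by = 1.5, length.out = nrow(cam)),
                        groove_separation / 2, motif_height)))
    m <- rigid_place(m, fitm$rotation, fitm$translation)
    jitter <- stats::rnorm(3, 0, 0.05)
    m <- rigid_place(m, diag(3), jitter)
    cx <- merge_structures(g1, g2, m)
    ab <- cx$atoms[cx$atoms$chain %in% c("A", "B"), c("x", "y", "z")]
    cc <- cx$atoms[cx$atoms$chain == "C", c("x", "y", "z")]
    d2 <- cross_dist2(as.matrix(ab), as.matrix(cc))
    attr(cx, "contacts") <- sum(d2 < 25)
    cx$metadata$generator <- "build_toy_complex"
    cx
  })
}

#' Build a toy single-chain scaffold containing a helical graft window
#'
#' A helix-loop-helix-loop-helix chain whose final helix is ideal-helical
#' (hence graft-compatible with any ideal 13-residue motif helix).
#'
#' @param seed Integer seed (jitters loop dihedrals).
#' @param helix_lengths Lengths of the three helices.
#' @param sequence Optional full-length sequence; default poly-A with
#'   leucines spaced along the helices.
#' @return A single-chain (`S`) `bh3_structure`.
#' @export
build_toy_scaffold <- function(seed = 1, helix_lengths = c(14, 14, 16),
                               sequence = NULL) {
  with_seed(seed, {
    loop_len <- 4
    L <- sum(helix_lengths) + 2 * loop_len
    if (is.null(sequence)) {
      aa <- rep("A", L)
      aa[seq(3, L, by = 7)] <- "L"
      sequence <- paste0(aa, collapse = "")
    }
    phi <- rep(-57, L); psi <- rep(-47, L)
    l1 <- helix_lengths[1] + seq_len(loop_len)
    l2 <- helix_lengths[1] + loop_len + helix_lengths[2] + seq_len(loop_len)
    phi[c(l1, l2)] <- -75 + stats::rnorm(2 * loop_len, 0, 5)
    psi[c(l1, l2)] <- 145 + stats::rnorm(2 * loop_len, 0, 5)
    build_helix(sequence, phi = phi, psi = psi, chain = "S")
  })
}

#' Simulate site-saturation-mutagenesis sorted pools
#'
#' Emulates a naive yeast-display SSM pool and two sorted pools (affinity
#' and specificity conditions). Variant frequencies in the naive pool are
#' near-uniform over all single mutants; each sort reweights a variant by a
#' logistic function of its planted effect under that condition. Counts are
#' multinomial at the requested depth; the exact sampled tallies are the
#' ground truth.
#'
#' @param parent `protein_sequence` (or string).
#' @param true_effects data.frame with columns `position`, `to`,
#'   `aff_effect`, `spec_effect` (log-odds selection effects; 0 = neutral).
#' @param depth Reads per pool (>= 1000).
#' @param seed Integer seed.
#' @param gate Sort-gate stringency (log-odds): a variant survives the sort
#'   with probability `plogis(effect - gate)`, so neutral variants
#'   (effect 0) survive at `plogis(-gate)` (about 12 percent at the
#'   default 2) and strongly beneficial ones approach 1.
#' @return List of three `pool_counts` objects: `naive`, `affinity`,
#'   `specificity`, each with attribute `truth` (the sampling frequencies).
#' @export
simulate_ssm_pools <- function(parent, true_effects = NULL, depth = 1e5,
                               seed = 1, gate = 2) {
  pseq <- as_sequence_string(parent)
  L <- nchar(pseq)
  if (depth < 1e3) stop("depth must be >= 1000")
  paa <- strsplit(pseq, "")[[1]]
  AAs <- unname(AA321[1:20])
  vars <- expand.grid(position = seq_len(L), to = AAs, stringsAsFactors = FALSE)
  vars$from <- paa[vars$position]
  vars <- vars[vars$from != vars$to, c("position", "from", "to")]
  eff_a <- eff_s <- rep(0, nrow(vars))
  if (!is.null(true_effects)) {
    key <- paste(vars$position, vars$to)
    tkey <- paste(true_effects$position, true_effects$to)
    hit <- match(tkey, key)
    if (anyNA(hit)) stop("true_effects reference mutations absent from the SSM")
    eff_a[hit] <- true_effects$aff_effect
    eff_s[hit] <- true_effects$spec_effect
  }
  with_seed(seed, {
    base <- stats::rlnorm(nrow(vars), 0, 0.15)
    wt_w <- mean(base) * 5   # wild type over-represented, as in real pools
    draw <- function(w, wtw, id, condition) {
      p <- c(w, wtw) / sum(c(w, wtw))
      cnt <- as.integer(stats::rmultinom(1, depth, p))
      pool_counts(data.frame(position = vars$position, from = vars$from,
                             to = vars$to, count = cnt[seq_len(nrow(vars))],
                             stringsAsFactors = FALSE),
                  wt_count = cnt[length(cnt)], pool_id = id,
                  condition = condition, parent = pseq, truth = p)
    }
    surv_wt <- stats::plogis(-gate)
    list(naive = draw(base, wt_w, "naive", "naive"),
         affinity = draw(base * stats::plogis(eff_a - gate), wt_w * surv_wt,
                         "aff", "affinity_sort"),
         specificity = draw(base * stats::plogis(eff_s - gate), wt_w * surv_wt,
                            "spec", "specificity_sort"))
  })
}

#' Simulate liposome dye-release time courses
#'
#' Per binder dose, a fluorescence time course rising exponentially to the
#' endpoint implied by the equilibrium threshold mechanism
#' ([simulate_dose_response()]), plus buffer-only (Fmin) and detergent
#' (Fmax) control channels.
#'
#' @param params [mechanism_params()].
#' @param doses Binder doses (molar).
#' @param timepoints Times in seconds (default 2-min sampling over 120 min).
#' @param noise Gaussian noise SD in fluorescence units.
#' @param seed Integer seed.
#' @param Fmin,Fmax Control fluorescence levels.
#' @return List with `traces` (data.frame: dose_M, time_s, F), `Fmin`,
#'   `Fmax`, and `truth` (the noiseless endpoint release percentages).
#' @export
simulate_liposome_traces <- function(params, doses,
                                     timepoints = seq(0, 7200, by = 120),
                                     noise = 0, seed = 1,
                                     Fmin = 100, Fmax = 1100) {
  rel <- simulate_dose_response(params, doses)
  tau <- 1200
  with_seed(seed, {
    tr <- do.call(rbind, lapply(seq_along(doses), function(i) {
      endF <- Fmin + (Fmax - Fmin) * rel[i] / 100
      Ft <- Fmin + (endF - Fmin) * (1 - exp(-timepoints / tau)) /
        (1 - exp(-max(timepoints) / tau))
      data.frame(dose_M = doses[i], time_s = timepoints,
                 F = Ft + stats::rnorm(length(timepoints), 0, noise))
    }))
    list(traces = tr, Fmin = Fmin, Fmax = Fmax, truth = rel)
  })
}

#' Synthetic designed-binder lineage sequences
#'
#' Stand-in sequences (clearly synthetic, not the deposited constructs)
#' whose pairwise Hamming structure matches the published binder lineages:
#' a BAK lineage of length 118 (CDP02 -> aBAK1: 10 mutations, aBAK1 ->
#' aBAK2: 12, CDP02 -> aBAK2: 22) and a BAX lineage of length 117
#' (CDP01 -> aBAX1: 8, aBAX1 -> aBAX2: 10, CDP01 -> aBAX2: 18), at
#' non-overlapping positions so the counts add.
#'
#' @return Named list of `protein_sequence` objects: CDP02, aBAK1, aBAK2,
#'   CDP01, aBAX1, aBAX2.
#' @export
synthetic_lineage_sequences <- function() {
  with_seed(20240917, {
    AAs <- unname(AA321[1:20])
    mutate_at <- function(seqv, pos) {
      for (p in pos) seqv[p] <- sample(setdiff(AAs, seqv[p]), 1)
      seqv
    }
    mk_lineage <- function(len, n1, n2, names3) {
      base <- sample(AAs, len, replace = TRUE)
      pos <- sample(len, n1 + n2)
      v1 <- mutate_at(base, pos[seq_len(n1)])
      v2 <- mutate_at(v1, pos[n1 + seq_len(n2)])
      stats::setNames(list(
        protein_sequence(paste0(base, collapse = ""), names3[1]),
        protein_sequence(paste0(v1, collapse = ""), names3[2]),
        protein_sequence(paste0(v2, collapse = ""), names3[3])
      ), names3)
    }
    c(mk_lineage(118, 10, 12, c("CDP02", "aBAK1", "aBAK2")),
      mk_lineage(117, 8, 10, c("CDP01", "aBAX1", "aBAX2")))
  })
}
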