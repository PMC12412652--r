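# Fixtures built in code; no binary data.

# Minimal hand-written 3-residue PDB text (Ala-Gly-Ser), used by structio tests.
toy_pdb_text <- function() {
  c(
    "HEADER    TOY FIXTURE",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       2.000  -0.773  -1.207  1.00  0.00           C",
    "ATOM      6  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      7  CA  GLY A   2       3.989   2.839   0.000  1.00  0.00           C",
    "ATOM      8  C   GLY A   2       5.504   2.693   0.000  1.00  0.00           C",
    "ATOM      9  O   GLY A   2       6.030   1.580   0.000  1.00  0.00           O",
    "ATOM     10  N   SER A   3       6.235   3.803   0.000  1.00  0.00           N",
    "ATOM     11  CA  SER A   3       7.690   3.771   0.000  1.00  0.00           C",
    "ATOM     12  C   SER A   3       8.253   5.184   0.000  1.00  0.00           C",
    "ATOM     13  O   SER A   3       7.517   6.173   0.000  1.00  0.00           O",
    "ATOM     14  CB  SER A   3       8.225   2.985   1.207  1.00  0.00           C",
    "ATOM     15  OG  SER A   3       7.785   1.640   1.180  1.00  0.00           O",
    "END"
  )
}

write_toy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(toy_pdb_text(), path)
  path
}

# A flat wall of overlapping carbon spheres (near-analytic plane) at height z.
atom_wall <- function(z, n = 17, spacing = 1.0, chain = "A") {
  g <- expand.grid(x = seq(0, by = spacing, length.out = n),
                   y = seq(0, by = spacing, length.out = n))
  new_structure(data.frame(
    chain = chain, resno = seq_len(nrow(g)), insert = "", resid = "ALA",
    elety = "CB", elem = "C", x = g$x, y = g$y, z = z,
    occ = 1, b = 0, het = FALSE, stringsAsFactors = FALSE))
}

# Standard toy graft setting shared across tests (deterministic).
toy_graft_setting <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cx <- build_toy_complex(1)
      pm <- prepare_context_motif(cx, "C", c(1, 13))
      sc <- build_toy_scaffold(1)
      sols <- find_graft_sites(pm$motif, sc, graft_config(), context = pm$context)
      g <- apply_graft(sols[[1]], pm$motif, sc, pm$context, binder_chain = "X")
      cache <<- list(complex = cx, context = pm$context, motif = pm$motif,
                     scaffold = sc, solutions = sols, graft = g,
                     hotspots = sols[[1]]$window_resnos[pm$motif$hotspot_indices])
    }
    cache
  }
})

# Independent brute-force RMSD of a superposition candidate: evaluates the
# RMSD directly for a given rotation/translation.
direct_rmsd <- function(P, Q, R, tr) {
  Pf <- sweep(P %*% t(R), 2, tr, "+")
  sqrt(mean(rowSums((Pf - Q)^2)))
}

# Euler-angle rotation matrix (z-y-x convention) for oracle searches.
euler_rotation <- function(a, b, c) {
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), -sin(c), 0, sin(c), cos(c)), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# Brute-force minimum RMSD over rotations via multistart Euler optimization
# (independent of the SVD path).
bruteforce_min_rmsd <- function(P, Q, n_starts = 60, seed = 99) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  obj <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((P0 %*% t(R) - Q0)^2)))
  }
  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    a0 <- stats::runif(3, -pi, pi)
    o <- stats::optim(a0, obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
    if (o$value < best) best <- o$value
  }
  best
}

# Independent per-state design energy: rebuilds candidate placements and sums
# interactions directly (never touches the packer's tables).
oracle_state_energy <- function(complex, binder_chain, positions, rotamers,
                                state, model) {
  rec <- bh3forge:::atom_records(complex)
  movable <- rec$chain == binder_chain & rec$resno %in% positions & !rec$is_bb
  fixed <- rec[!movable, , drop = FALSE]
  cands <- lapply(seq_along(positions), function(k)
    rotamers[[as.character(positions[k])]]$candidates[[state[k]]])
  e <- 0
  for (k in seq_along(positions)) {
    cd <- cands[[k]]
    env <- fixed[!(fixed$chain == binder_chain &
                     fixed$resno == positions[k]), , drop = FALSE]
    e <- e + bh3forge:::pair_interaction(cd$records, env, model) +
      bh3forge:::burial_penalty(cd$records, env, model) +
      unname(model$ref[cd$resid])
  }
  if (length(positions) >= 2) {
    for (i in seq_len(length(positions) - 1))
      for (j in (i + 1):length(positions))
        e <- e + bh3forge:::pair_interaction(cands[[i]]$records,
                                             cands[[j]]$records, model)
  }
  e
}

# Enumerate all states of a rotamer problem and return the best by the oracle.
oracle_exhaustive_best <- function(complex, binder_chain, positions, rotamers,
                                   model) {
  ncand <- vapply(as.character(positions),
                  function(p) length(rotamers[[p]]$candidates), 0L)
  grid <- do.call(expand.grid, lapply(ncand, seq_len))
  energies <- apply(grid, 1, function(st)
    oracle_state_energy(complex, binder_chain, positions, rotamers,
                        as.integer(st), model))
  list(state = as.integer(grid[which.min(energies), ]),
       energy = min(energies), energies = energies)
}
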