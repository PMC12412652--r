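test_that("prepare_context_motif reduces to backbone+CB with hotspots preserved", {
  cx <- build_toy_complex(1)
  pm <- prepare_context_motif(cx, "C", c(1, 13))
  expect_equal(pm$motif$length, 13)
  expect_equal(pm$motif$hotspot_indices, c(1, 5, 8, 9, 10))
  expect_equal(pm$motif$hotspot_identities, c("ILE", "LEU", "ILE", "GLY", "ASP"))
  seqm <- extract_sequence(pm$motif$structure, "C")$residues
  expect_equal(sum(strsplit(seqm, "")[[1]] != "A"), 5)
  expect_true(all(trimws(pm$motif$structure$atoms$elety) %in%
                    c("N", "CA", "C", "O", "CB")))
  expect_false("C" %in% chain_ids(pm$context))
  ## span shorter than max hotspot index errors
  expect_error(prepare_context_motif(cx, "C", c(1, 8)), "hotspot")
  ## all-hotspot motif keeps the sequence unchanged
  pm2 <- prepare_context_motif(cx, "C", c(1, 13), hotspot_indices = 1:13)
  expect_equal(extract_sequence(pm2$motif$structure, "C")$residues,
               extract_sequence(cx, "C")$residues)
})

test_that("find_graft_sites accepts an embedded motif and rejects a beta strand", {
  st <- toy_graft_setting()
  sols <- find_graft_sites(st$motif, st$scaffold, graft_config())
  expect_gt(length(sols), 0)
  expect_lt(sols[[1]]$full_bb_rmsd, 1e-6)  # ideal helix contains the motif
  ## sorted ascending by full-backbone RMSD
  rm <- vapply(sols, `[[`, 0, "full_bb_rmsd")
  expect_true(all(diff(rm) >= -1e-12))
  ## extended strand: no helical window fits
  strand <- build_helix(paste0(rep("A", 20), collapse = ""),
                        phi = -120, psi = 120, chain = "S")
  expect_length(find_graft_sites(st$motif, strand, graft_config()), 0)
  short <- build_helix("AAAAA", chain = "S")
  expect_warning(out <- find_graft_sites(st$motif, short, graft_config()),
                 "shorter")
  expect_length(out, 0)
})

test_that("graft window scan equals brute-force enumeration on random scaffolds", {
  ## independent oracle: every window, direct kabsch + direct endpoint RMSD
  st <- toy_graft_setting()
  motif <- st$motif
  mb <- bh3forge:::backbone_block(motif$structure, "C")
  L <- motif$length
  ep_rows <- c(1:4, (4 * (L - 1) + 1):(4 * L))
  cfgs <- list(graft_config(), graft_config(1.5, 1.0), graft_config(0.5, 0.3))
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    phi <- -57 + rnorm(n, 0, sample(c(5, 25), 1))
    psi <- -47 + rnorm(n, 0, sample(c(5, 25), 1))
    sc <- build_helix(paste0(sample(c("A", "L", "S"), n, TRUE), collapse = ""),
                      phi = phi, psi = psi, chain = "S")
    prev_sets <- NULL
    for (cfg in cfgs) {
      sols <- find_graft_sites(motif, sc, cfg)
      got <- sort(vapply(sols, `[[`, 0L, "window_start"))
      expected <- integer()
      for (w in seq_len(n - L + 1)) {
        wb <- bh3forge:::backbone_block(sc, "S", w:(w + L - 1))
        fit <- suppressWarnings(kabsch(wb, mb))
        wbt <- bh3forge:::transform_xyz(wb, fit$rotation, fit$translation)
        ep <- sqrt(mean(rowSums((wbt[ep_rows, ] - mb[ep_rows, ])^2)))
        if (fit$rmsd <= cfg$full_bb_rmsd_tol && ep <= cfg$endpoint_rmsd_tol)
          expected <- c(expected, w)
      }
      expect_identical(got, expected)
      ## tightening tolerances never adds solutions
      if (!is.null(prev_sets)) expect_true(all(got %in% prev_sets))
      prev_sets <- got
    }
  }
})

test_that("graft acceptance is invariant under rigid transformation of the scaffold", {
  st <- toy_graft_setting()
  sols <- find_graft_sites(st$motif, st$scaffold, graft_config())
  set.seed(17)
  scT <- bh3forge:::rigid_place(st$scaffold, bh3forge:::random_rotation(),
                                rnorm(3, 0, 40))
  solsT <- find_graft_sites(st$motif, scT, graft_config())
  expect_equal(vapply(sols, `[[`, 0L, "window_start"),
               vapply(solsT, `[[`, 0L, "window_start"))
  expect_equal(vapply(sols, `[[`, 0, "full_bb_rmsd"),
               vapply(solsT, `[[`, 0, "full_bb_rmsd"), tolerance = 1e-6)
})

test_that("accepted solutions satisfy their tolerances under independent recomputation", {
  st <- toy_graft_setting()
  cfg <- graft_config()
  for (sol in st$solutions) {
    wb <- bh3forge:::backbone_block(st$scaffold, "S", sol$window_resnos)
    mb <- bh3forge:::backbone_block(st$motif$structure, "C")
    refit <- suppressWarnings(kabsch(wb, mb))
    expect_lte(refit$rmsd, cfg$full_bb_rmsd_tol)
    expect_equal(refit$rmsd, sol$full_bb_rmsd, tolerance = 1e-9)
    expect_lte(sol$endpoint_rmsd, cfg$endpoint_rmsd_tol)
    expect_lte(sol$clash_score, cfg$clash_cutoff)
  }
})

test_that("clash_score counts soft vdW overlaps and matches brute force", {
  st <- toy_graft_setting()
  cfg <- graft_config()
  ## far translation: zero clashes
  far <- bh3forge:::rigid_place(st$scaffold, diag(3), c(100, 0, 0))
  expect_equal(clash_score(st$context, far, cfg), 0L)
  ## scaffold posed onto the context chain itself: self-overlap
  ctxA <- subset_chains(st$context, "A")
  caA <- atom_coords(ctxA, "A", "CA")
  caS <- atom_coords(st$scaffold, "S", "CA")
  n <- min(nrow(caA), nrow(caS))
  fit <- kabsch(caS[1:n, ], caA[1:n, ])
  onto <- bh3forge:::rigid_place(st$scaffold, fit$rotation, fit$translation)
  expect_gt(clash_score(st$context, onto, cfg), 0L)
  ## brute-force O(n^2) oracle on a random pose
  set.seed(23)
  pose <- bh3forge:::rigid_place(st$scaffold, bh3forge:::random_rotation(),
                                 rnorm(3, 0, 6))
  got <- clash_score(st$context, pose, cfg)
  ctx <- st$context$atoms[st$context$atoms$elem != "H", ]
  sca <- pose$atoms[trimws(pose$atoms$elety) %in% c("N", "CA", "C", "O"), ]
  cnt <- 0L
  for (i in seq_len(nrow(ctx))) for (j in seq_len(nrow(sca))) {
    d <- sqrt(sum((as.numeric(ctx[i, c("x", "y", "z")]) -
                     as.numeric(sca[j, c("x", "y", "z")]))^2))
    lim <- bh3forge:::vdw_radius(ctx$elem[i]) +
      bh3forge:::vdw_radius(sca$elem[j]) - cfg$clash_pad
    if (d < lim) cnt <- cnt + 1L
  }
  expect_equal(got, cnt)
})

test_that("apply_graft threads hotspots, reverts the rest, and keeps provenance", {
  st <- toy_graft_setting()
  g <- st$graft
  nat <- strsplit(extract_sequence(st$scaffold, "S")$residues, "")[[1]]
  des <- strsplit(extract_sequence(g, "X")$residues, "")[[1]]
  diffs <- which(nat != des)
  expect_length(diffs, 5)  # exactly the hotspot positions
  expect_setequal(diffs, st$hotspots)
  ## idempotence: grafting onto a scaffold already carrying the hotspots
  sc2 <- st$scaffold
  for (k in seq_along(st$motif$hotspot_indices)) {
    rn <- st$solutions[[1]]$window_resnos[st$motif$hotspot_indices[k]]
    sel <- sc2$atoms$resno == rn
    sc2$atoms <- sc2$atoms[!(sel & !(trimws(sc2$atoms$elety) %in%
                                       c("N", "CA", "C", "O", "CB"))), ]
    sc2$atoms$resid[sc2$atoms$resno == rn] <- st$motif$hotspot_identities[k]
  }
  g2 <- apply_graft(st$solutions[[1]], st$motif, sc2, st$context, "X")
  expect_equal(extract_sequence(g2, "X")$residues,
               extract_sequence(sc2, "S")$residues)
  ## provenance survives a PDB round trip
  f <- tempfile(fileext = ".pdb")
  write_structure(g, f)
  back <- read_structure(f)
  expect_true(any(grepl("GRAFT window=", back$metadata$remarks)))
})
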