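test_that("side-chain SASA behaves at the exposure and burial limits", {
  ## single isolated residue: fully exposed side chain
  h <- build_helix("ALAA")
  one <- new_structure(h$atoms[h$atoms$resno == 2, ])  # a leucine
  sas <- sidechain_sasa(one, probe = 2.2)
  expect_gt(unname(sas["A:2"]), 30)
  ## residue enclosed in a synthetic cage: SASA ~ 0
  lys <- new_structure(h$atoms[h$atoms$resno == 2, ])
  ctr <- colMeans(as.matrix(lys$atoms[, c("x", "y", "z")]))
  dirs <- bh3forge:::fibonacci_sphere(200)
  cage <- data.frame(chain = "Z", resno = seq_len(200), insert = "",
                     resid = "ALA", elety = "CB", elem = "C",
                     x = ctr[1] + 7 * dirs[, 1], y = ctr[2] + 7 * dirs[, 2],
                     z = ctr[3] + 7 * dirs[, 3], occ = 1, b = 0, het = FALSE)
  caged <- new_structure(rbind(lys$atoms, cage))
  sas2 <- sidechain_sasa(caged, probe = 2.2)
  expect_lt(unname(sas2["A:2"]), 1)
})

test_that("default-density SASA agrees with a high-density evaluation", {
  pep <- build_helix("ASKLE")
  lo <- sidechain_sasa(pep, probe = 2.2, n_dots = 960)
  hi <- sidechain_sasa(pep, probe = 2.2, n_dots = 10000)
  rel <- abs(lo - hi) / pmax(hi, 1)
  expect_true(all(rel < 0.02))
})

test_that("designable selection gates on SASA, shell distance and hotspots", {
  st <- toy_graft_setting()
  g <- st$graft
  cfg <- design_config()
  p8 <- select_designable(g, "X", cfg, 8, hotspots = st$hotspots)
  p12 <- select_designable(g, "X", cfg, 12, hotspots = st$hotspots)
  expect_gt(length(p8), 0)
  expect_true(all(p8 %in% p12))            # shell monotonicity
  expect_true(!any(st$hotspots %in% p8))   # hotspots never designable
  ## far-displaced binder: empty selection with repack-only warning
  far <- g
  sel <- far$atoms$chain == "X"
  far$atoms[sel, c("x", "y", "z")] <- far$atoms[sel, c("x", "y", "z")] + 50
  expect_warning(p <- select_designable(far, "X", cfg, 8), "repack-only")
  expect_length(p, 0)
  ## brute-force oracle: double loop over atom pairs with the same SASA gate
  binder <- subset_chains(g, "X")
  sas <- sidechain_sasa(binder, probe = cfg$sasa_probe_radius)
  surf <- as.integer(sub("^.*:", "", names(sas)[sas >= cfg$surface_asa_min]))
  ba <- g$atoms[g$atoms$chain == "X" & g$atoms$elem != "H", ]
  ta <- g$atoms[g$atoms$chain != "X" & g$atoms$elem != "H", ]
  near <- integer()
  for (rn in unique(ba$resno)) {
    bi <- as.matrix(ba[ba$resno == rn, c("x", "y", "z")])
    hit <- FALSE
    for (j in seq_len(nrow(ta))) {
      if (any(sqrt(rowSums(sweep(bi, 2, as.numeric(ta[j, c("x", "y", "z")]))^2)) <= 8)) {
        hit <- TRUE; break
      }
    }
    if (hit) near <- c(near, rn)
  }
  oracle <- sort(setdiff(intersect(near, surf), st$hotspots))
  expect_identical(p8, oracle)
})

test_that("energy model terms are symmetric and pairwise-decomposable", {
  st <- toy_graft_setting()
  model <- energy_model()
  rec <- bh3forge:::atom_records(st$graft)
  key <- paste(rec$chain, rec$resno)
  ks <- unique(key)
  set.seed(31)
  for (rep in 1:10) {
    ij <- sample(ks, 2)
    ra <- rec[key == ij[1], ]; rb <- rec[key == ij[2], ]
    expect_equal(bh3forge:::pair_interaction(ra, rb, model),
                 bh3forge:::pair_interaction(rb, ra, model), tolerance = 1e-10)
  }
  ## packer tables: total equals sum of singles + pairs by recomputation
  pos <- select_designable(st$graft, "X", design_config(), 8,
                           hotspots = st$hotspots)[1:3]
  rot <- build_rotamer_set(st$graft, "X", pos, design_config(),
                           identities = c("A", "S", "L"))
  tables <- bh3forge:::pack_tables(st$graft, "X", pos, rot, model)
  st1 <- c(1L, 2L, 1L)
  e <- bh3forge:::state_energy(tables, st1)
  manual <- sum(vapply(1:3, function(k) tables$singles[[k]][st1[k]], 0))
  for (nm in names(tables$pairs)) {
    ij <- as.integer(strsplit(nm, " ")[[1]])
    manual <- manual + tables$pairs[[nm]][st1[ij[1]], st1[ij[2]]]
  }
  expect_equal(e, manual, tolerance = 1e-12)
})

test_that("mc_design equals exhaustive enumeration on small state spaces", {
  st <- toy_graft_setting()
  model <- energy_model()
  cfg <- design_config(mc_steps = 1200)
  all_pos <- select_designable(st$graft, "X", cfg, 12, hotspots = st$hotspots)
  set.seed(41)
  for (rep in 1:6) {
    np <- sample(1:3, 1)
    pos <- sort(sample(all_pos, np))
    ids <- sample(c("A", "S", "L", "K", "E", "V", "T"), sample(2:3, 1))
    rot <- build_rotamer_set(st$graft, "X", pos, cfg, identities = ids)
    ## truncate candidate lists to keep the state space tiny
    for (p in as.character(pos)) {
      nc <- length(rot[[p]]$candidates)
      keep <- unique(c(1, seq(2, nc, length.out = min(nc - 1, 5))))
      rot[[p]]$candidates <- rot[[p]]$candidates[sort(round(keep))]
    }
    cfg$seed <- rep
    res <- mc_design(st$graft, pos, rot, model, cfg, "X")
    oracle <- oracle_exhaustive_best(st$graft, "X", pos, rot, model)
    expect_equal(res$energy, oracle$energy, tolerance = 1e-8)
    ## packer and oracle agree on the energy of the packer's chosen state
    expect_equal(oracle_state_energy(st$graft, "X", pos, rot, res$state, model),
                 res$energy, tolerance = 1e-8)
  }
})

test_that("mc_design is deterministic, monotone, and respects constraints", {
  st <- toy_graft_setting()
  cfg <- design_config(mc_steps = 800, seed = 5)
  pos <- select_designable(st$graft, "X", cfg, 8, hotspots = st$hotspots)
  rot <- build_rotamer_set(st$graft, "X", pos, cfg)
  r1 <- mc_design(st$graft, pos, rot, energy_model(), cfg, "X")
  r2 <- mc_design(st$graft, pos, rot, energy_model(), cfg, "X")
  expect_identical(r1$state, r2$state)
  expect_identical(r1$complex$atoms, r2$complex$atoms)
  expect_lte(r1$energy, r1$initial_energy)
  ## disallowed types never introduced at designed positions
  seq_out <- r1$sequence
  expect_false(any(bh3forge:::AA321[seq_out] %in% c("P", "C", "W", "G")))
  ## hotspot identities unchanged in the output complex
  for (k in seq_along(st$hotspots)) {
    got <- r1$complex$atoms$resid[r1$complex$atoms$chain == "X" &
                                    r1$complex$atoms$resno == st$hotspots[k]][1]
    expect_equal(got, st$motif$hotspot_identities[k])
  }
  ## zero designable positions: identity operation
  r0 <- mc_design(st$graft, integer(), rot, energy_model(), cfg, "X")
  expect_identical(r0$complex$atoms, st$graft$atoms)
})

test_that("longer annealing schedules do at least as well on average", {
  st <- toy_graft_setting()
  pos <- select_designable(st$graft, "X", design_config(), 8,
                           hotspots = st$hotspots)[1:4]
  rot <- build_rotamer_set(st$graft, "X", pos, design_config(),
                           identities = c("A", "S", "L", "E", "K"))
  e_short <- e_long <- numeric(10)
  for (s in 1:10) {
    e_short[s] <- mc_design(st$graft, pos, rot, energy_model(),
                            design_config(mc_steps = 60, seed = s), "X")$energy
    e_long[s] <- mc_design(st$graft, pos, rot, energy_model(),
                           design_config(mc_steps = 1500, seed = s), "X")$energy
  }
  expect_lte(mean(e_long), mean(e_short) + 1e-9)
})

test_that("the two-shell protocol is deterministic and monotone in best energy", {
  st <- toy_graft_setting()
  cfg <- design_config(mc_steps = 600, seed = 7)
  d1 <- design_protocol(st$graft, cfg, binder_chain = "X", hotspots = st$hotspots,
                        identities = c("A", "S", "L", "E", "K", "T", "I"))
  d2 <- design_protocol(st$graft, cfg, binder_chain = "X", hotspots = st$hotspots,
                        identities = c("A", "S", "L", "E", "K", "T", "I"))
  expect_identical(d1$complex$atoms, d2$complex$atoms)
  expect_lte(d1$stages$shell_8$energy, d1$stages$shell_8$initial_energy)
  expect_lte(d1$stages$shell_12$energy, d1$stages$shell_12$initial_energy)
  expect_lte(d1$stages$repack$energy, d1$stages$repack$initial_energy + 1e-9)
  ## no disallowed types at designed positions
  seqv <- strsplit(d1$record$sequence, "")[[1]]
  pos <- select_designable(st$graft, "X", cfg, 12, hotspots = st$hotspots)
  expect_false(any(seqv[pos] %in% c("P", "C", "W", "G")))
})
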