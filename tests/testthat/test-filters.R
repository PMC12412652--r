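test_that("binding energy is zero for separated partners and negative for an ideal H-bond", {
  st <- toy_graft_setting()
  model <- energy_model()
  far <- st$graft
  sel <- far$atoms$chain == "X"
  far$atoms[sel, c("x", "y", "z")] <- far$atoms[sel, c("x", "y", "z")] + 100
  expect_equal(binding_energy(far, model, split = "X"), 0, tolerance = 1e-6)
  ## two single residues with one ideal serine-aspartate H-bond, no clashes
  ser <- build_helix("ASAA", chain = "A")
  serres <- new_structure(ser$atoms[ser$atoms$resno == 2, ])
  og <- as.numeric(serres$atoms[trimws(serres$atoms$elety) == "OG", c("x", "y", "z")])
  cb <- as.numeric(serres$atoms[trimws(serres$atoms$elety) == "CB", c("x", "y", "z")])
  dir <- (og - cb) / sqrt(sum((og - cb)^2))
  acc <- og + dir * 2.9   # acceptor opposite the donor base: angle 180
  accres <- new_structure(data.frame(
    chain = "B", resno = 1, insert = "", resid = "ASP", elety = "OD1",
    elem = "O", x = acc[1], y = acc[2], z = acc[3], occ = 1, b = 0, het = FALSE))
  cx <- merge_structures(serres, accres)
  expect_lt(binding_energy(cx, model, split = "B"), -0.5)
  expect_error(binding_energy(serres, model), "two-body")
})

test_that("binding energy equals a term-by-term inter-partner sum", {
  st <- toy_graft_setting()
  model <- energy_model()
  g <- st$graft
  got <- binding_energy(g, model, split = "X")
  recA <- bh3forge:::atom_records(subset_chains(g, c("A", "B")))
  recB <- bh3forge:::atom_records(subset_chains(g, "X"))
  ## brute-force inter-partner residue-pair sum
  keyA <- paste(recA$chain, recA$resno)
  keyB <- paste(recB$chain, recB$resno)
  e <- 0
  for (ka in unique(keyA)) for (kb in unique(keyB))
    e <- e + bh3forge:::pair_interaction(recA[keyA == ka, ], recB[keyB == kb, ],
                                         model)
  e <- e + bh3forge:::inter_burial_delta(recA, recB, model)
  expect_equal(got, e, tolerance = 1e-8)
  ## adding a pure steric clash strictly increases the binding energy
  clash <- g
  ca <- clash$atoms[clash$atoms$chain == "X" & trimws(clash$atoms$elety) == "CB", ][1, ]
  ctx <- clash$atoms[clash$atoms$chain == "A", ][10, ]
  extra <- ca
  extra[, c("x", "y", "z")] <- ctx[, c("x", "y", "z")] + c(0.8, 0, 0)
  extra$elety <- "CG"; extra$resid <- "LEU"
  clash$atoms <- rbind(clash$atoms, extra)
  expect_gt(binding_energy(clash, model, split = "X"), got)
})

test_that("shape complementarity is high for mating walls and lower for tilted ones", {
  w1 <- atom_wall(0, chain = "A")
  w2 <- atom_wall(3.4, chain = "B")
  sc_par <- shape_complementarity(merge_structures(w1, w2), split = "B")
  expect_gte(sc_par, 0.8)
  expect_lte(sc_par, 1)
  ## tilt the second wall: complementarity must drop strictly
  th <- 50 * pi / 180
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, byrow = TRUE)
  w2t <- atom_wall(0, chain = "B")
  xyz <- as.matrix(w2t$atoms[, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, c(0, 8, 0)) %*% t(R), 2, c(0, 8, 3.4), "+")
  w2t$atoms[, c("x", "y", "z")] <- xyz
  sc_tilt <- shape_complementarity(merge_structures(w1, w2t), split = "B")
  expect_lt(sc_tilt, sc_par)
  expect_gte(sc_tilt, -1)
  ## separated partners: no contact surface
  w2f <- atom_wall(103.4, chain = "B")
  expect_error(shape_complementarity(merge_structures(w1, w2f), split = "B"),
               "no contact surface")
})

test_that("sc stays within [-1, 1] across toy interfaces", {
  st <- toy_graft_setting()
  s <- shape_complementarity(st$graft, split = "X")
  expect_gte(s, -1)
  expect_lte(s, 1)
})

test_that("buried unsatisfied polar atoms: lysine burial toy with and without acceptor", {
  ## chain A: one lysine; chain B: a carbon cage burying NZ upon complexation
  h <- build_helix("AKAA", chain = "A")
  lys <- new_structure(h$atoms[h$atoms$resno == 2, ])
  nz <- as.numeric(lys$atoms[trimws(lys$atoms$elety) == "NZ", c("x", "y", "z")])
  ce <- as.numeric(lys$atoms[trimws(lys$atoms$elety) == "CE", c("x", "y", "z")])
  dirs <- bh3forge:::fibonacci_sphere(250)
  ## cage carbons at 4.5 A around NZ, skipping the side-chain direction
  keep <- apply(dirs, 1, function(d) sum(d * (ce - nz)) < 3.5)
  cage <- data.frame(chain = "B", resno = seq_len(sum(keep)), insert = "",
                     resid = "ALA", elety = "CB", elem = "C",
                     x = nz[1] + 4.5 * dirs[keep, 1],
                     y = nz[2] + 4.5 * dirs[keep, 2],
                     z = nz[3] + 4.5 * dirs[keep, 3],
                     occ = 1, b = 0, het = FALSE)
  cx <- merge_structures(lys, new_structure(cage))
  expect_equal(buried_unsat_polar(cx, split = "B"), 1L)
  ## isolated single chain: zero by definition
  expect_equal(buried_unsat_polar(lys), 0L)
  ## add a well-placed acceptor: satisfied, count drops to zero
  dir <- (nz - ce) / sqrt(sum((nz - ce)^2))
  acc <- nz + dir * 2.9
  cage2 <- rbind(cage, data.frame(chain = "B", resno = nrow(cage) + 1,
                                  insert = "", resid = "ASP", elety = "OD1",
                                  elem = "O", x = acc[1], y = acc[2], z = acc[3],
                                  occ = 1, b = 0, het = FALSE))
  cx2 <- merge_structures(lys, new_structure(cage2))
  expect_equal(buried_unsat_polar(cx2, split = "B"), 0L)
})

test_that("omega_check flags distorted peptide bonds and matches an independent oracle", {
  h <- build_helix(paste0(rep("A", 13), collapse = ""))
  expect_equal(nrow(omega_check(h)), 0)
  ## one distorted omega at residue 5
  h2 <- build_helix(paste0(rep("A", 13), collapse = ""),
                    omega = c(rep(180, 4), 120, rep(180, 8)))
  oc <- omega_check(h2)
  expect_equal(oc$resno, 5)
  expect_equal(abs(oc$omega), 120, tolerance = 1)
  ## randomized chains: failures equal direct dihedral recomputation (bio3d)
  set.seed(47)
  for (rep in 1:40) {
    n <- sample(5:12, 1)
    om <- sample(c(180, 175, 160, 150.5, 149, 120, 90, 30), n, TRUE)
    hc <- build_helix(paste0(rep("A", n), collapse = ""),
                      phi = -57 + rnorm(n, 0, 20), psi = -47 + rnorm(n, 0, 20),
                      omega = om)
    got <- omega_check(hc, 150)$resno
    N <- atom_coords(hc, "A", "N"); CA <- atom_coords(hc, "A", "CA")
    C <- atom_coords(hc, "A", "C")
    oracle <- integer()
    for (i in seq_len(n - 1)) {
      quad <- rbind(CA[i, ], C[i, ], N[i + 1, ], CA[i + 1, ])
      tors <- bio3d::torsion.xyz(as.numeric(t(quad)), atm.inc = 4)
      if (abs(tors[1]) < 150) oracle <- c(oracle, i)
    }
    expect_identical(got, oracle)
  }
  ## rigid invariance
  set.seed(48)
  h2T <- bh3forge:::rigid_place(h2, bh3forge:::random_rotation(), rnorm(3, 0, 30))
  expect_equal(omega_check(h2T)$resno, omega_check(h2)$resno)
  ## cis-proline exemption
  hp <- build_helix("AAPA", omega = c(180, 2, 180, 180))
  expect_equal(nrow(omega_check(hp)), 0)
  expect_equal(omega_check(hp, exempt_cis_proline = FALSE)$resno, 2)
})

test_that("filter_report gates each metric and the overall verdict", {
  st <- toy_graft_setting()
  rep_pass <- filter_report(st$graft, filter_thresholds(
    ddg_max = 1000, sc_min = -1, unsat_max = 100), split = "X")
  expect_true(rep_pass$pass_all)
  rep_fail <- filter_report(st$graft, filter_thresholds(
    ddg_max = 1000, sc_min = 1.01, unsat_max = 100), split = "X")
  expect_false(rep_fail$pass$sc)
  expect_false(rep_fail$pass_all)
  expect_error(filter_thresholds(omega_cutoff = 80), "omega_cutoff")
})
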