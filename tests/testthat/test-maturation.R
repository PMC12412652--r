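test_that("count_variants tallies singles, wild type, and discards the rest", {
  parent <- "MKTAYI"
  pc <- count_variants(rep(parent, 5), parent)
  expect_equal(pc$wt_count, 5L)
  expect_equal(nrow(pc$counts), 0)
  pc2 <- count_variants(c(parent, "MKTAYK", "MKTAYK", "MATAYK", "SHORT*"),
                        parent)
  expect_equal(pc2$wt_count, 1L)
  expect_equal(pc2$counts$count[pc2$counts$position == 6 &
                                  pc2$counts$to == "K"], 2L)
  expect_equal(pc2$discarded, 2L)  # double mutant + bad read
  expect_equal(pc2$total, 5L)
})

test_that("count_variants reproduces a simulated pool's exact tallies", {
  parent <- paste0(rep("A", 12), collapse = "")
  pools <- simulate_ssm_pools(parent, depth = 2e4, seed = 11)
  nv <- pools$naive
  ## reconstruct reads from the counts and re-count them
  pv <- strsplit(parent, "")[[1]]
  reads <- c(rep(parent, nv$wt_count),
             unlist(lapply(seq_len(nrow(nv$counts)), function(i) {
               v <- pv
               v[nv$counts$position[i]] <- nv$counts$to[i]
               rep(paste0(v, collapse = ""), nv$counts$count[i])
             })))
  rc <- count_variants(reads, parent)
  expect_equal(rc$wt_count, nv$wt_count)
  key <- function(df) paste(df$position, df$from, df$to)
  m <- match(key(nv$counts[nv$counts$count > 0, ]), key(rc$counts))
  expect_false(anyNA(m))
  expect_equal(rc$counts$count[m], nv$counts$count[nv$counts$count > 0])
})

test_that("enrichment has the identity, closed-form and antisymmetry properties", {
  parent <- paste0(rep("A", 10), collapse = "")
  pools <- simulate_ssm_pools(parent, depth = 5e4, seed = 2)
  ## identical pools: e = 0 everywhere
  e0 <- enrichment(pools$naive, pools$naive)
  expect_true(all(abs(e0$table$log2_enrichment) < 1e-12))
  ## closed form: doubling a mutation's frequency gives e -> 1 as p -> 0
  nv <- pools$naive
  sel <- nv
  i <- which.max(nv$counts$count)
  sel$counts$count[i] <- sel$counts$count[i] * 2
  sel$total <- sum(sel$counts$count) + sel$wt_count
  ## rescale totals so overall frequency normalization stays comparable
  e <- enrichment(nv, sel, pseudocount = 1e-9)
  expected <- log2(2 * nv$total / sel$total)
  expect_equal(e$table$log2_enrichment[i], expected, tolerance = 1e-6)
  ## antisymmetry: swapping pools negates every e_m
  ea <- enrichment(pools$naive, pools$affinity)
  eb <- enrichment(pools$affinity, pools$naive)
  expect_equal(ea$table$log2_enrichment, -eb$table$log2_enrichment,
               tolerance = 1e-9)
  expect_error(enrichment(nv, pool_counts(nv$counts[0, ], 0)), "zero-total")
})

test_that("planted affinity effects are recovered as the top enrichments", {
  parent <- paste0(rep("A", 20), collapse = "")
  eff <- data.frame(position = c(2, 5, 9, 13, 17),
                    to = c("K", "E", "R", "D", "Q"),
                    aff_effect = 3, spec_effect = 0)
  pools <- simulate_ssm_pools(parent, eff, depth = 1e5, seed = 3)
  ea <- enrichment(pools$naive, pools$affinity)
  top5 <- head(ea$table[order(-ea$table$log2_enrichment), ], 5)
  expect_setequal(paste(top5$position, top5$to),
                  paste(eff$position, eff$to))
})

test_that("dual_select returns exactly the shared planted effects", {
  parent <- paste0(rep("A", 20), collapse = "")
  eff <- data.frame(position = c(2, 5, 9, 3, 7, 11, 15),
                    to = c("K", "E", "R", "S", "T", "N", "H"),
                    aff_effect = c(3, 3, 3, 3, 3, 0, 0),
                    spec_effect = c(3, 3, 3, 0, 0, 3, 3))
  pools <- simulate_ssm_pools(parent, eff, depth = 1e5, seed = 3)
  ea <- enrichment(pools$naive, pools$affinity)
  es <- enrichment(pools$naive, pools$specificity)
  sel <- dual_select(ea, es)
  expect_setequal(paste(sel$position, sel$to), c("2 K", "5 E", "9 R"))
  ## subset property and threshold monotonicity
  ea2 <- enrichment(pools$naive, pools$affinity, threshold = 2.5)
  sel2 <- dual_select(ea2, es)
  expect_true(all(paste(sel2$position, sel2$to) %in% paste(sel$position, sel$to)))
  enr_a <- ea$table[ea$table$enriched, ]
  expect_true(all(paste(sel$position, sel$to) %in%
                    paste(enr_a$position, enr_a$to)))
  ## disjoint enriched sets: empty selection
  eaX <- ea; eaX$table$enriched <- ea$table$position %in% 3
  esX <- es; esX$table$enriched <- es$table$position %in% 11
  expect_equal(nrow(dual_select(eaX, esX)), 0)
  ## idempotence: identical flags select that set
  expect_setequal(paste(dual_select(ea, ea)$position, dual_select(ea, ea)$to),
                  paste(enr_a$position[enr_a$from != enr_a$to],
                        enr_a$to[enr_a$from != enr_a$to]))
})

test_that("degenerate codon algebra: NNK and minimal covers", {
  nnk <- degenerate_codon_aas("NNK")
  expect_length(nnk$aas, 20)
  expect_equal(nnk$n_codons, 32)
  expect_equal(nnk$n_stop, 1)  # amber TAG
  b <- best_degenerate_codon(c("A", "E", "K", "T"))
  expect_true(all(c("A", "E", "K", "T") %in% b$aas))
  ## minimality: no covering codon has fewer concrete codons
  tab <- bh3forge:::degenerate_codon_table()
  covers <- vapply(tab$aas, function(s) all(c("A", "E", "K", "T") %in% s), TRUE)
  expect_equal(b$n_codons, min(tab$n_codons[covers]))
  expect_error(best_degenerate_codon("Z"), "invalid|covers")
})

test_that("combinatorial library design covers selections and respects the cap", {
  parent <- paste0(rep("A", 20), collapse = "")
  ## empty selection: parent-only library
  lib0 <- design_combinatorial_library(parent, data.frame(position = integer(),
                                                          to = character()))
  expect_equal(library_diversity(lib0), list(dna = 1, protein = 1))
  ## two NNK-like positions: full coverage demanded
  sel <- data.frame(position = c(rep(3, 19), rep(8, 19)),
                    to = rep(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "A"),
                             length.out = 38),
                    min_e = 1)
  sel$to[1:19] <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "A")
  sel$to[20:38] <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "A")
  lib2 <- design_combinatorial_library(parent, sel)
  dv <- library_diversity(lib2)
  expect_equal(dv$protein, 400)   # 20 x 20, stops excluded
  expect_equal(dv$dna, 1024)      # 32 x 32
  expect_equal(lib2$positions[["3"]]$codon, "NNK")
  ## cap pruning: 20 positions x 4 AAs each = 4^20 >> cap
  big <- do.call(rbind, lapply(1:20, function(p)
    data.frame(position = p, to = c("K", "E", "S"), min_e = p + c(0.1, 0.2, 0.3))))
  libc <- design_combinatorial_library(parent, big, cap = 4e7)
  expect_lt(libc$protein_diversity, 4e7)
  expect_gt(nrow(libc$dropped), 0)
  ## every surviving mutation is encodable by its position's codon
  for (i in seq_len(nrow(libc$selected))) {
    p <- as.character(libc$selected$position[i])
    expect_true(libc$selected$to[i] %in% libc$positions[[p]]$aas)
  }
  ## parental identity always encodable
  for (p in libc$positions) expect_true(p$parent %in% p$aas)
  ## degenerate cap: parent-only output, everything dropped
  lib1 <- design_combinatorial_library(parent, big, cap = 1)
  expect_equal(lib1$protein_diversity, 1)
  expect_equal(nrow(lib1$dropped), nrow(big))
})

test_that("library diversity equals brute-force enumeration on small cases", {
  parent <- "MKTAYIAKQR"
  sel <- data.frame(position = c(2, 5, 5, 8), to = c("R", "F", "L", "E"),
                    min_e = c(2, 1.5, 1.2, 1))
  lib <- design_combinatorial_library(parent, sel)
  vars <- enumerate_library(lib)
  expect_equal(length(unique(vars)), lib$protein_diversity)
  ## parent present; every selected mutation represented in some variant
  expect_true(parent %in% vars)
  for (i in seq_len(nrow(sel))) {
    pv <- strsplit(parent, "")[[1]]
    pv[sel$position[i]] <- sel$to[i]
    hit <- vapply(vars, function(v)
      substr(v, sel$position[i], sel$position[i]) == sel$to[i], TRUE)
    expect_true(any(hit))
  }
})
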