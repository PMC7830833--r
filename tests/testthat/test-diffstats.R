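# Per-population frequencies and the pairwise Gst'' engine.

test_that("condition frequencies use haploid counts over scored individuals", {
  m <- fsm_from_rows(c("I", "I", "II", "IV"), rep("p1", 4))
  f <- condition_frequencies(m)
  expect_equal(unname(f$freqs$L1["p1", ]), c(0.5, 0.25, 0, 0.25))
  m2 <- fsm_from_rows(rep("III", 5), rep("p1", 5))
  expect_equal(unname(condition_frequencies(m2)$freqs$L1["p1", ]), c(0, 0, 1, 0))
})

test_that("a missing-coded individual reduces the denominator", {
  s <- matrix(c("I", "I", "II", NA), 4, 1,
              dimnames = list(paste0("i", 1:4), "L1"))
  f <- condition_frequencies(four_state_matrix(s, rep("p1", 4)))
  expect_equal(unname(f$freqs$L1["p1", ]), c(2 / 3, 1 / 3, 0, 0))
  expect_equal(unname(f$n["p1", "L1"]), 3)
})

test_that("genotype frequencies count allele copies and reject half-genotypes", {
  g <- geno_df(list(list("A/A"), list("A/B")), c("p1", "p1"))
  f <- genotype_frequencies(g)
  expect_equal(unname(f$freqs$loc1["p1", ]), c(0.75, 0.25))
  g2 <- geno_df(list(list("A/B"), list("A/B")), c("p1", "p1"))
  expect_equal(unname(genotype_frequencies(g2)$freqs$loc1["p1", ]), c(0.5, 0.5))
  g3 <- geno_df(list(list("A/A"), list("A/B"), list(NA)), rep("p1", 3))
  f3 <- genotype_frequencies(g3)
  expect_equal(unname(f3$n["p1", "loc1"]), 4)
  g4 <- geno_df(list(list("A/A")), "p1")
  g4$loc1_a2 <- NA_character_
  expect_error(genotype_frequencies(g4), "half-genotype")
})

test_that("Gst'' closed forms match the standardized-differentiation formula", {
  # identical populations -> 0
  f_id <- freq_table(list(L1 = rbind(p1 = c(0.3, 0.7), p2 = c(0.3, 0.7))))
  expect_equal(pairwise_gst(f_id)$gst["p1", "p2"], 0)
  # fixed difference at one locus -> exactly 1
  f_fix <- freq_table(list(L1 = rbind(p1 = c(1, 0), p2 = c(0, 1))))
  expect_equal(pairwise_gst(f_fix)$gst["p1", "p2"], 1, tolerance = 1e-12)
  # (0.8,0.2) vs (0.2,0.8): HS = 0.32, HT = 0.5 -> 0.36 / 0.4624
  f_mid <- freq_table(list(L1 = rbind(p1 = c(0.8, 0.2), p2 = c(0.2, 0.8))))
  g <- pairwise_gst(f_mid)
  expect_equal(g$gst["p1", "p2"], 0.36 / (0.68 * 0.68), tolerance = 1e-12)
  expect_equal(g$components$hs, 0.32, tolerance = 1e-12)
  expect_equal(g$components$ht, 0.5, tolerance = 1e-12)
})

test_that("Gst'' matrices are symmetric, zero-diagonal and in [0,1] (plugin)", {
  m <- random_fsm(30, 25, rep(paste0("p", 1:3), each = 10), seed = 11)
  g <- pairwise_gst(condition_frequencies(m))$gst
  expect_equal(g, t(g))
  expect_true(all(diag(g) == 0))
  expect_true(all(g >= -1e-12 & g <= 1 + 1e-12))
})

test_that("Gst'' is invariant under state relabeling", {
  m <- random_fsm(24, 15, rep(c("a", "b"), each = 12), seed = 13)
  g1 <- pairwise_gst(condition_frequencies(m))$gst
  relab <- c(I = "III", II = "IV", III = "I", IV = "II")
  m2 <- four_state_matrix(matrix(relab[m$states], nrow(m$states),
                                 dimnames = dimnames(m$states)),
                          m$populations)
  g2 <- pairwise_gst(condition_frequencies(m2))$gst
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("Gst'' increases with |p1 - p2| on a biallelic grid (oracle check)", {
  prev <- -Inf
  for (delta in seq(0.05, 0.45, by = 0.05)) {
    f <- freq_table(list(L1 = rbind(p1 = c(0.5 + delta, 0.5 - delta),
                                    p2 = c(0.5 - delta, 0.5 + delta))))
    g <- pairwise_gst(f)$gst["p1", "p2"]
    oracle <- gst_oracle_pair(list(rbind(c(0.5 + delta, 0.5 - delta),
                                         c(0.5 - delta, 0.5 + delta))))
    expect_equal(g, oracle, tolerance = 1e-12)
    expect_gt(g, prev)
    prev <- g
  }
})

test_that("HS/HT are averaged across loci before the ratio; per-locus mode differs", {
  # heterogeneous loci: one strongly differentiated, one weak
  freqs <- list(L1 = rbind(p1 = c(0.95, 0.05), p2 = c(0.05, 0.95)),
                L2 = rbind(p1 = c(0.55, 0.45), p2 = c(0.45, 0.55)))
  f <- freq_table(freqs)
  across <- pairwise_gst(f, average = "across_loci")$gst["p1", "p2"]
  expect_equal(across, gst_oracle_pair(freqs), tolerance = 1e-12)
  per_locus <- pairwise_gst(f, average = "per_locus_ratio")$gst["p1", "p2"]
  expect_false(isTRUE(all.equal(across, per_locus, tolerance = 1e-6)))
})

test_that("monomorphic-within-pair loci enter the averages; fully fixed pair warns", {
  freqs <- list(L1 = rbind(p1 = c(0.8, 0.2), p2 = c(0.2, 0.8)),
                L2 = rbind(p1 = c(1, 0), p2 = c(1, 0)))      # monomorphic pair
  g <- pairwise_gst(freq_table(freqs))$gst["p1", "p2"]
  expect_equal(g, gst_oracle_pair(freqs), tolerance = 1e-12)
  # diluting with a monomorphic locus changes the value
  g1 <- pairwise_gst(freq_table(freqs[1]))$gst["p1", "p2"]
  expect_false(isTRUE(all.equal(g, g1)))
  f_fix <- freq_table(list(L1 = rbind(p1 = c(1, 0), p2 = c(1, 0))))
  expect_warning(gfix <- pairwise_gst(f_fix), "degenerate")
  expect_equal(gfix$gst["p1", "p2"], 0)
})

test_that("nei_unbiased corrects small-sample bias and requires sample sizes", {
  f_nolen <- pool_frequencies(rbind(p1 = c(0.2, 0.6), p2 = c(0.8, 0.4)))
  expect_error(pairwise_gst(f_nolen, estimator = "nei_unbiased"),
               "frequency-only")
  # with sample sizes the correction shifts the plugin value
  f <- freq_table(list(L1 = rbind(p1 = c(0.8, 0.2), p2 = c(0.2, 0.8))),
                  n = rbind(p1 = 20, p2 = 20))
  plug <- pairwise_gst(f, "plugin")$gst["p1", "p2"]
  unb <- pairwise_gst(f, "nei_unbiased")$gst["p1", "p2"]
  expect_false(isTRUE(all.equal(plug, unb, tolerance = 1e-9)))
})

test_that("all three marker systems flow through the same engine", {
  ds <- simulate_riverscape(sim_config(n_sites = 4, n_individuals_per_site = 8,
                                       n_snps = 40, n_epiloci = 30),
                            seed = 21)
  sp <- ds$species$speciesA
  for (f in list(condition_frequencies(sp$epi),
                 genotype_frequencies(sp$genotypes),
                 pool_frequencies(sp$pools))) {
    g <- pairwise_gst(f)$gst
    expect_equal(dim(g), c(4, 4))
    expect_equal(g, t(g))
    expect_true(all(g >= -1e-12 & g <= 1 + 1e-12))
  }
})
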