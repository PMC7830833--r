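# Distance-based AMOVA: metrics, variance components, permutation test.

test_that("epi4 distances count per-locus condition mismatches", {
  m <- fsm_from_rows(c("I II III IV I II III IV I II",
                       "I II III IV I II III IV I II",
                       "I II III IV I II IV III II I"),
                     rep("p", 3))
  d2 <- epi_distances(m)
  expect_equal(d2["ind1", "ind2"], 0)
  expect_equal(d2["ind1", "ind3"], 4)
  expect_true(all(diag(d2) == 0))
})

test_that("epi4 distances rescale over comparable loci when cells are missing", {
  s <- rbind(ind1 = c("I", "II", "III", "IV"),
             ind2 = c("I", "I", NA, "IV"))
  colnames(s) <- paste0("L", 1:4)
  m <- four_state_matrix(s, c("p", "p"))
  d2 <- epi_distances(m)
  # 1 mismatch over 3 comparable loci, scaled to 4 loci
  expect_equal(d2["ind1", "ind2"], 1 / 3 * 4)
})

test_that("microsat distances count non-shared allele copies", {
  g <- geno_df(list(list("A/A", "A/B"), list("A/B", "A/B"),
                    list("B/B", "C/C")), rep("p", 3))
  d2 <- microsat_distances(g)
  expect_equal(d2["ind1", "ind2"], 1)       # (A/A) vs (A/B) -> 1; tie at loc2
  expect_equal(d2["ind1", "ind3"], 2 + 2)   # both loci fully distinct
  expect_equal(d2["ind2", "ind3"], 1 + 2)
})

test_that("SNP pools are rejected from the individual-distance path", {
  f <- pool_frequencies(rbind(p1 = c(0.2, 0.6), p2 = c(0.8, 0.4)))
  expect_error(individual_distance_matrix(f), "individual")
})

test_that("variance components equal a brute-force indicator-coded nested ANOVA", {
  m <- random_fsm(12, 10, rep(c("a", "b"), each = 6), seed = 31)
  res <- amova(epi_distances(m), m$populations, n_perm = 10, seed = 1)

  # Oracle: code each (locus, state) as an indicator / sqrt(2) and run a
  # one-way ANOVA per coordinate via stats::aov, then pool sums of squares.
  pops <- factor(m$populations)
  X <- do.call(cbind, lapply(seq_len(ncol(m$states)), function(j) {
    sapply(c("I", "II", "III", "IV"), function(st)
      as.numeric(m$states[, j] == st) / sqrt(2))
  }))
  ssa <- ssw <- 0
  for (k in seq_len(ncol(X))) {
    if (var(X[, k]) == 0) next
    sm <- summary(stats::aov(X[, k] ~ pops))[[1]]
    ssa <- ssa + sm["pops", "Sum Sq"]
    ssw <- ssw + sm["Residuals", "Sum Sq"]
  }
  N <- length(pops); P <- nlevels(pops)
  n_p <- table(pops)
  n0 <- (N - sum(n_p^2) / N) / (P - 1)
  sw <- ssw / (N - P)
  sa <- (ssa / (P - 1) - sw) / n0

  expect_equal(res$ss_among, ssa, tolerance = 1e-9)
  expect_equal(res$ss_within, ssw, tolerance = 1e-9)
  expect_equal(res$sigma2_among, sa, tolerance = 1e-9)
  expect_equal(res$sigma2_within, sw, tolerance = 1e-9)
  expect_equal(res$phi_st, sa / (sa + sw), tolerance = 1e-9)
})

test_that("unbalanced designs also match the oracle", {
  m <- random_fsm(15, 8, rep(c("a", "b", "c"), c(3, 5, 7)), seed = 32)
  res <- amova(epi_distances(m), m$populations, n_perm = 10, seed = 1)
  pops <- factor(m$populations)
  X <- do.call(cbind, lapply(seq_len(ncol(m$states)), function(j) {
    sapply(c("I", "II", "III", "IV"), function(st)
      as.numeric(m$states[, j] == st) / sqrt(2))
  }))
  tot <- colSums(sweep(X, 2, colMeans(X))^2)
  wit <- sapply(seq_len(ncol(X)), function(k)
    sum(unlist(tapply(X[, k], pops, function(v) sum((v - mean(v))^2)))))
  expect_equal(res$ss_within, sum(wit), tolerance = 1e-9)
  expect_equal(res$ss_among, sum(tot) - sum(wit), tolerance = 1e-9)
})

test_that("SS and df additivity hold exactly", {
  m <- random_fsm(20, 12, rep(paste0("p", 1:4), each = 5), seed = 33)
  res <- amova(epi_distances(m), m$populations, n_perm = 5, seed = 2)
  expect_equal(res$ss_among + res$ss_within, res$ss_total, tolerance = 1e-9)
  expect_equal(res$df_among + res$df_within, 19)
})

test_that("two internally monomorphic populations give Phi = 1, 100% among", {
  m <- fsm_from_rows(c(rep("I II III", 5), rep("IV I II", 5)),
                     rep(c("a", "b"), each = 5))
  res <- amova(epi_distances(m), m$populations, n_perm = 99, seed = 3)
  expect_equal(res$phi_st, 1, tolerance = 1e-12)
  expect_equal(res$pct_variation_among, 100, tolerance = 1e-9)
  expect_equal(res$ss_within, 0, tolerance = 1e-12)
})

test_that("scaling all squared distances scales SS but not Phi or p", {
  m <- random_fsm(18, 10, rep(c("a", "b", "c"), each = 6), seed = 34)
  d2 <- epi_distances(m)
  r1 <- amova(d2, m$populations, n_perm = 99, seed = 7)
  r2 <- amova(2 * d2, m$populations, n_perm = 99, seed = 7)
  expect_equal(r2$ss_total, 2 * r1$ss_total, tolerance = 1e-9)
  expect_equal(r2$sigma2_among, 2 * r1$sigma2_among, tolerance = 1e-9)
  expect_equal(r2$phi_st, r1$phi_st, tolerance = 1e-12)
  expect_equal(r2$p_value, r1$p_value)
})

test_that("Phi is invariant under relabeling populations and reordering individuals", {
  m <- random_fsm(16, 10, rep(c("a", "b"), each = 8), seed = 35)
  d2 <- epi_distances(m)
  r1 <- amova(d2, m$populations, n_perm = 5, seed = 1)
  perm <- sample(seq_len(16))
  relab <- c(a = "z", b = "y")[m$populations][perm]
  r2 <- amova(d2[perm, perm], relab, n_perm = 5, seed = 1)
  expect_equal(r2$phi_st, r1$phi_st, tolerance = 1e-12)
})

test_that("permutation p uses the +1 convention and guards degenerate input", {
  m <- random_fsm(12, 6, rep(c("a", "b"), each = 6), seed = 36)
  res <- amova(epi_distances(m), m$populations, n_perm = 19, seed = 5)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_true(res$p_value %in% ((1:20) / 20))
  expect_error(amova(epi_distances(m), c("a", rep("b", 11)), n_perm = 5),
               "size 1")
  flat <- fsm_from_rows(rep("I I I", 8), rep(c("a", "b"), each = 4))
  r <- amova(epi_distances(flat), flat$populations, n_perm = 9, seed = 1)
  expect_true(r$degenerate)
  expect_true(is.na(r$phi_st))
})
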