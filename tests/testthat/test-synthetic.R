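# Synthetic riverscape generator: determinism, designed structure, coupling
# dials.

test_that("same seed reproduces every table; different seed changes data only", {
  cfg <- sim_config(n_sites = 5, n_individuals_per_site = 6, n_snps = 50,
                    n_epiloci = 40, n_microsat_loci = 5)
  a <- simulate_riverscape(cfg, seed = 3)
  b <- simulate_riverscape(cfg, seed = 3)
  expect_identical(a$env, b$env)
  expect_identical(a$riparian, b$riparian)
  expect_identical(a$species$speciesA$genotypes, b$species$speciesA$genotypes)
  expect_identical(a$species$speciesA$pools, b$species$speciesA$pools)
  expect_identical(a$species$speciesA$epi$states, b$species$speciesA$epi$states)
  c <- simulate_riverscape(cfg, seed = 4)
  expect_identical(dim(c$env), dim(a$env))
  expect_false(identical(c$env, a$env))
  expect_false(identical(c$species$speciesA$pools, a$species$speciesA$pools))
})

test_that("with zero noise the environmental table has rank 3", {
  cfg <- sim_config(env_noise_sd = 0)
  e <- simulate_env(cfg, seed = 5)
  expect_equal(qr(scale(e$env, scale = FALSE))$rank, 3)
})

test_that("PCA of the default table recovers the three designed variable blocks", {
  e <- simulate_env(sim_config(), seed = 12)
  # independent eigen-oracle on the correlation matrix
  eg <- eigen(cor(e$env), symmetric = TRUE)
  expect_gte(sum(eg$values[1:3]) / sum(eg$values), 0.55)
  blocks <- list(
    eutro = c("oxygen", "conductivity", "nitrite", "nitrate", "oxygen_saturation"),
    updown = c("flow", "width", "pH"),
    altnut = c("orthophosphate", "slope", "altitude", "SM"))
  # each of the first three eigenvectors is dominated by one designed block
  tops <- lapply(1:3, function(k) {
    v <- abs(eg$vectors[, k])
    names(v) <- colnames(e$env)
    names(sort(v, decreasing = TRUE))[1:3]
  })
  hit <- vapply(blocks, function(b)
    any(vapply(tops, function(tp) mean(tp %in% b) >= 2 / 3, logical(1))),
    logical(1))
  expect_true(all(hit))
})

test_that("riparian distances are a metric from the river tree", {
  e <- simulate_env(sim_config(n_sites = 8), seed = 6)
  d <- e$riparian
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d[upper.tri(d)] > 0))
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
})

test_that("vanishing f_gen gives bias-corrected microsat Gst'' near zero", {
  cfg <- sim_config(n_sites = 4, n_individuals_per_site = 12,
                    n_microsat_loci = 8, n_snps = 10, n_epiloci = 10,
                    f_gen = 1e-4, gamma_env_gen = 0)
  vals <- vapply(1:30, function(i) {
    e <- simulate_env(cfg, seed = 100 + i)
    g <- simulate_genetics(cfg, e, seed = 100 + i)
    gst <- pairwise_gst(genotype_frequencies(g$genotypes),
                        estimator = "nei_unbiased")$gst
    mean(gst[lower.tri(gst)])
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 4 * se + 0.005)
})

test_that("rho = 1 with beta = 0 makes epigenetic site effects deterministic in G", {
  cfg <- sim_config(n_sites = 6, n_individuals_per_site = 60,
                    n_epiloci = 400, n_snps = 10, n_microsat_loci = 2,
                    rho_epi_gen = 1, beta_env = 0, epi_drift_sd = 0)
  e <- simulate_env(cfg, seed = 9)
  g <- simulate_genetics(cfg, e, seed = 9)
  epi <- simulate_epigenetics(cfg, e, g$site_factors, seed = 9)
  gst <- pairwise_gst(condition_frequencies(epi))$gst
  G <- g$site_factors
  dg <- abs(outer(G, G, "-"))[rownames(gst), rownames(gst)]
  # epigenetic differentiation tracks |G_a - G_b| tightly
  expect_gt(cor(gst[lower.tri(gst)], dg[lower.tri(dg)]), 0.8)
})

test_that("without site-level epigenetic effects Gst'' sits in a near-zero band", {
  cfg <- sim_config(n_sites = 5, n_individuals_per_site = 24, n_epiloci = 150,
                    n_snps = 10, n_microsat_loci = 2,
                    rho_epi_gen = 0, beta_env = 0,
                    epi_factor_sd = 0, epi_drift_sd = 0)
  vals <- vapply(1:10, function(i) {
    e <- simulate_env(cfg, seed = 300 + i)
    epi <- simulate_epigenetics(cfg, e, structure(rnorm(5), names = rownames(e$env)),
                                seed = 300 + i)
    gst <- pairwise_gst(condition_frequencies(epi),
                        estimator = "nei_unbiased")$gst
    mean(gst[lower.tri(gst)])
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 4 * se + 0.005)
})

test_that("strong direct environmental forcing is detected by the MRM env term", {
  cfg <- sim_config(rho_epi_gen = 0, beta_env = 2, gamma_env_gen = 0,
                    n_snps = 300, n_microsat_loci = 5)
  n_rep <- 40
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    e <- simulate_env(cfg, seed = 400 + i)
    g <- simulate_genetics(cfg, e, seed = 400 + i)
    epi <- simulate_epigenetics(cfg, e, g$site_factors, seed = 400 + i)
    p <- retain_components(env_pca(e$env), 3)
    ed <- all_component_distances(p)
    gst_epi <- pairwise_gst(condition_frequencies(epi))$gst
    gst_snp <- pairwise_gst(pool_frequencies(g$pools))$gst
    fit <- mrm(gst_epi, c(ed, list(riparian = e$riparian, snp = gst_snp)),
               n_perm = 99, seed = 400 + i)
    rej[i] <- fit$coefficients$p_value[fit$coefficients$term == "PC1"] <= 0.05
  }
  expect_gte(mean(rej), 0.9)
})

test_that("species share the environment but draw markers independently", {
  ds <- simulate_riverscape(sim_config(n_sites = 5, n_individuals_per_site = 6,
                                       n_snps = 30, n_epiloci = 20,
                                       n_microsat_loci = 4), seed = 17)
  expect_length(ds$species, 2)
  expect_false(identical(ds$species$speciesA$pools, ds$species$speciesB$pools))
  expect_identical(rownames(ds$species$speciesA$pools),
                   rownames(ds$species$speciesB$pools))
})
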