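# Synthetic riverscape generator. Emulates the sampling design the pipeline
# targets: ~13 sites on a dendritic river network, two sympatric species,
# 24 individuals per site, with three marker systems (four-state epiloci,
# diploid microsatellites, pooled biallelic SNPs) and 14 correlated
# environmental variables organized along three latent gradients
# (eutrophication, upstream-downstream, altitude/nutrient). Couplings are
# explicit dials: f_gen sets neutral genetic differentiation (F-model),
# gamma_env_gen pushes allele frequencies along the eutrophication gradient
# (selection proxy), rho_epi_gen ties epigenetic site effects to the same
# latent site factor that shifted allele frequencies, and beta_env adds a
# direct environment -> epigenome effect. This makes the causal structure of
# the data a known quantity, so the inference chain (Mantel vs MRM) can be
# validated against ground truth.

#' Simulation configuration
#'
#' @param n_sites number of sites; default 13.
#' @param n_individuals_per_site individuals sampled per site per species;
#'   default 24.
#' @param n_microsat_loci,n_alleles_per_microsat microsatellite panel size;
#'   defaults 15 loci x 8 alleles.
#' @param n_snps pooled biallelic SNP count; default 1500.
#' @param n_epiloci four-state epilocus count; default 260.
#' @param f_gen genetic differentiation intensity in (0, 1) (F-model
#'   Dirichlet uses concentration `(1 - f_gen) / f_gen`); default 0.1.
#' @param rho_epi_gen genetic -> epigenetic coupling in \[0, 1\]; default 0.8.
#' @param beta_env direct environment -> epigenetic effect size (per SD of
#'   the eutrophication gradient); default 0.
#' @param gamma_env_gen environment -> genetic (selection-proxy) effect
#'   size; default 1.
#' @param env_noise_sd residual SD of each environmental variable around its
#'   gradient structure (gradient loadings are order 0.55-0.9); default 0.5,
#'   which leaves roughly 70% of standardized variance on the first three
#'   axes.
#' @param epi_factor_sd scale of site-level epigenetic effects on the logit
#'   of state probabilities; default 1.0 (chosen so the emulated among-population
#'   epigenetic variance fraction sits near 20%). Zero removes all site
#'   structure
#'   from the epigenome.
#' @param epi_drift_sd SD of locus x site epigenetic drift noise unrelated
#'   to genetics or environment; default 0.15.
#' @param pool_depth optional binomial read depth for pooled SNP
#'   frequencies; `NULL` (default) reports exact site frequencies.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 13, n_individuals_per_site = 24,
                       n_microsat_loci = 15, n_alleles_per_microsat = 8,
                       n_snps = 1500, n_epiloci = 260,
                       f_gen = 0.1, rho_epi_gen = 0.8, beta_env = 0,
                       gamma_env_gen = 1, env_noise_sd = 0.5,
                       epi_factor_sd = 1.0, epi_drift_sd = 0.15,
                       pool_depth = NULL) {
  stopifnot(n_sites >= 3, n_individuals_per_site >= 2,
            n_microsat_loci >= 2, n_alleles_per_microsat >= 2,
            n_snps >= 2, n_epiloci >= 2,
            f_gen > 0, f_gen < 1,
            rho_epi_gen >= 0, rho_epi_gen <= 1,
            beta_env >= 0, gamma_env_gen >= 0,
            env_noise_sd >= 0, epi_factor_sd >= 0, epi_drift_sd >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# Gradient loading design: signs follow the field interpretation of the
# three axes (eutrophic sites: low oxygen, high conductivity/nitrogen).
env_loadings <- function() {
  L <- matrix(0, 14, 3, dimnames = list(ENV_VARIABLES,
                                        c("eutrophication", "updown", "altnutrient")))
  L[c("oxygen", "oxygen_saturation"), 1] <- c(-0.9, -0.85)
  L[c("conductivity", "nitrite", "nitrate", "BOD", "temperature"), 1] <-
    c(0.88, 0.85, 0.75, 0.55, 0.58)
  L[c("flow", "width", "pH"), 2] <- c(0.89, 0.86, 0.72)
  L[c("orthophosphate", "slope", "altitude", "SM"), 3] <-
    c(0.76, 0.61, 0.60, 0.53)
  L
}

# Typical scale/location used to put variables on realistic units.
env_units <- function() {
  data.frame(
    variable = ENV_VARIABLES,
    mean = c(8, 15, 1.5, 300, 0.35, 2, 12, 8, 0.15, 0.2, 8.5, 7.9, 95, 19),
    sd = c(6, 10, 1.2, 200, 0.15, 1, 8, 5, 0.1, 0.15, 1.5, 0.4, 10, 2.5)
  )
}

#' Simulate the environmental table and riparian distances
#'
#' Builds three latent standard-normal site gradients, mixes them into the
#' 14 named variables with the block loading structure described above plus
#' independent noise, and rescales to realistic units. Riparian distances
#' are path lengths (km) between leaves of a random bifurcating river tree.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `env` (sites x 14 matrix), `riparian` (site x site
#'   path-distance matrix), `gradients` (sites x 3 latent matrix) and
#'   `tree` (the `ape::phylo` river network).
#' @export
simulate_env <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(seed, "env"))
  S <- config$n_sites
  sites <- sprintf("site%02d", seq_len(S))
  z <- matrix(stats::rnorm(S * 3), S, 3,
              dimnames = list(sites, c("eutrophication", "updown", "altnutrient")))
  z <- scale(z)                         # exact zero mean / unit SD gradients
  attr(z, "scaled:center") <- attr(z, "scaled:scale") <- NULL
  L <- env_loadings()
  noise <- matrix(stats::rnorm(S * 14, sd = config$env_noise_sd), S, 14)
  std <- z %*% t(L) + noise
  u <- env_units()
  env <- sweep(sweep(std, 2, u$sd, "*"), 2, u$mean, "+")
  dimnames(env) <- list(sites, ENV_VARIABLES)

  tree <- ape::rtree(S, tip.label = sites)
  tree$edge.length <- stats::runif(length(tree$edge.length), 2, 40)  # km
  riparian <- ape::cophenetic.phylo(tree)[sites, sites]
  list(env = env, riparian = riparian, gradients = z, tree = tree)
}

# Logit-shift the first allele of a frequency vector by delta, rescaling the
# remaining alleles proportionally. Frequencies kept off the exact boundary.
logit_shift_first <- function(p, delta) {
  q1 <- stats::plogis(stats::qlogis(min(max(p[1], 1e-9), 1 - 1e-9)) + delta)
  rest <- p[-1]
  if (sum(rest) > 0) rest <- rest * (1 - q1) / sum(rest)
  c(q1, rest)
}

#' Simulate genetic markers along the riverscape
#'
#' F-model: per-locus site frequencies are drawn from a Dirichlet centered
#' on ancestral frequencies with concentration `(1 - f_gen) / f_gen`, then
#' logit-shifted along a site factor `G = g + gamma_env_gen * z1` (with `g`
#' standard-normal site effects and `z1` the eutrophication gradient) using
#' locus-specific response weights scaled by `sqrt(f_gen / (1 - f_gen))`.
#' Diploid microsatellite genotypes are sampled from the site frequencies;
#' the pooled SNP table reports the site frequencies exactly (or with
#' binomial read noise when `pool_depth` is set).
#'
#' @param config a [sim_config()].
#' @param env result of [simulate_env()].
#' @param seed integer seed.
#' @return list with `genotypes` (data frame in the genotype-table layout),
#'   `pools` (sites x SNPs reference-allele frequency matrix),
#'   `site_factors` (named vector `G`, the latent factor that shifted the
#'   frequencies) and `populations`.
#' @export
simulate_genetics <- function(config, env, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(seed, "genetics"))
  sites <- rownames(env$env)
  S <- length(sites)
  n_ind <- config$n_individuals_per_site
  f <- config$f_gen
  conc <- (1 - f) / f
  kappa <- sqrt(f / (1 - f))
  g <- stats::rnorm(S)
  G <- g + config$gamma_env_gen * env$gradients[, 1]
  names(G) <- sites

  rdirichlet <- function(alpha) {
    x <- stats::rgamma(length(alpha), shape = pmax(alpha, 1e-8))
    if (sum(x) == 0) x <- rep(1, length(alpha))
    x / sum(x)
  }

  # Microsatellites
  A <- config$n_alleles_per_microsat
  loci <- sprintf("ms%02d", seq_len(config$n_microsat_loci))
  geno <- data.frame(
    individual = sprintf("%s_i%02d", rep(sites, each = n_ind),
                         rep(seq_len(n_ind), S)),
    population = rep(sites, each = n_ind), stringsAsFactors = FALSE)
  for (lc in loci) {
    anc <- rdirichlet(rep(2, A))
    w <- stats::rnorm(1)
    a1 <- a2 <- character(S * n_ind)
    for (s in seq_len(S)) {
      q <- rdirichlet(anc * conc)
      q <- logit_shift_first(q, kappa * w * G[s])
      idx <- seq((s - 1) * n_ind + 1, s * n_ind)
      a1[idx] <- sample(paste0("A", seq_len(A)), n_ind, TRUE, prob = q)
      a2[idx] <- sample(paste0("A", seq_len(A)), n_ind, TRUE, prob = q)
    }
    geno[[paste0(lc, "_a1")]] <- a1
    geno[[paste0(lc, "_a2")]] <- a2
  }

  # Pooled SNPs
  nsnp <- config$n_snps
  anc <- stats::runif(nsnp, 0.05, 0.95)
  w <- stats::rnorm(nsnp)
  pools <- matrix(NA_real_, S, nsnp,
                  dimnames = list(sites, sprintf("snp%04d", seq_len(nsnp))))
  for (s in seq_len(S)) {
    q <- stats::rbeta(nsnp, anc * conc, (1 - anc) * conc)
    q <- stats::plogis(stats::qlogis(pmin(pmax(q, 1e-9), 1 - 1e-9)) +
                         kappa * w * G[s])
    if (!is.null(config$pool_depth))
      q <- stats::rbinom(nsnp, config$pool_depth, q) / config$pool_depth
    pools[s, ] <- q
  }

  list(genotypes = geno, pools = pools, site_factors = G,
       populations = geno$population)
}

#' Simulate the four-state epigenetic matrix
#'
#' Site-level epigenetic effects are
#' `E = rho_epi_gen * std(G) + sqrt(1 - rho^2) * e + beta_env * z1`,
#' where `G` is the latent site factor that shifted allele frequencies
#' (standardized across sites), `e` independent standard-normal site
#' effects, and `z1` the eutrophication gradient. Per epilocus, baseline
#' four-state probabilities are drawn from a Dirichlet and each site's
#' probability vector is a softmax logit shift by
#' `epi_factor_sd * w_l * E_s` plus `epi_drift_sd` locus x site drift.
#' Individual states are drawn independently from their site's vector;
#' Condition IV is an ordinary fourth state (restriction-site loss genetics
#' is not modeled).
#'
#' @param config a [sim_config()].
#' @param env result of [simulate_env()].
#' @param site_factors named latent site factor vector from
#'   [simulate_genetics()].
#' @param seed integer seed.
#' @return a [four_state_matrix()].
#' @export
simulate_epigenetics <- function(config, env, site_factors, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(seed, "epigenetics"))
  sites <- rownames(env$env)
  S <- length(sites)
  n_ind <- config$n_individuals_per_site
  rho <- config$rho_epi_gen
  Gs <- site_factors[sites]
  G_std <- if (stats::sd(Gs) > 0) (Gs - mean(Gs)) / stats::sd(Gs) else Gs * 0
  e <- stats::rnorm(S)
  E <- rho * G_std + sqrt(1 - rho^2) * e + config$beta_env * env$gradients[, 1]

  nloc <- config$n_epiloci
  pops <- rep(sites, each = n_ind)
  states <- matrix(NA_character_, S * n_ind, nloc,
                   dimnames = list(sprintf("%s_i%02d", pops,
                                           rep(seq_len(n_ind), S)),
                                   sprintf("epi%03d", seq_len(nloc))))
  for (j in seq_len(nloc)) {
    base <- stats::rgamma(4, shape = c(1.6, 1.0, 1.0, 1.4))
    base <- pmax(base / sum(base), 1e-4)
    w <- stats::rnorm(4); w <- w - mean(w)
    for (s in seq_len(S)) {
      lp <- log(base) + config$epi_factor_sd * w * E[s] +
        stats::rnorm(4, sd = config$epi_drift_sd)
      pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
      idx <- seq((s - 1) * n_ind + 1, s * n_ind)
      states[idx, j] <- sample(MSAFLP_STATES, n_ind, TRUE, prob = pr)
    }
  }
  four_state_matrix(states, pops)
}

#' Simulate a full two-species riverscape dataset
#'
#' Both species share the environmental table and river network; marker
#' data are independent draws with species-specific coupling parameters,
#' enabling comparative designs (e.g. one species environmentally coupled,
#' the other not).
#'
#' @param config a [sim_config()] (baseline shared by both species).
#' @param seed integer seed; the only source of randomness.
#' @param species_params named list of per-species overrides of config
#'   fields, e.g. `list(speciesA = list(), speciesB = list(gamma_env_gen =
#'   0, rho_epi_gen = 0.4))`. Default: two species, the second without
#'   environmental coupling.
#' @return object of class `synthetic_dataset`: `env`, `riparian`, `tree`,
#'   `gradients`, per-species list `species` (each with `genotypes`,
#'   `pools`, `epi` and `site_factors`), `config`, `seed`.
#' @export
simulate_riverscape <- function(config = sim_config(), seed = 1,
                                species_params = list(
                                  speciesA = list(),
                                  speciesB = list(gamma_env_gen = 0,
                                                  rho_epi_gen = 0.4))) {
  stopifnot(inherits(config, "sim_config"))
  envr <- simulate_env(config, seed)
  species <- lapply(seq_along(species_params), function(i) {
    cfg <- config
    for (nm in names(species_params[[i]])) cfg[[nm]] <- species_params[[i]][[nm]]
    sp_seed <- derive_seed(seed, names(species_params)[i])
    gen <- simulate_genetics(cfg, envr, sp_seed)
    epi <- simulate_epigenetics(cfg, envr, gen$site_factors, sp_seed)
    list(genotypes = gen$genotypes, pools = gen$pools, epi = epi,
         site_factors = gen$site_factors, params = cfg)
  })
  names(species) <- names(species_params)
  structure(list(env = envr$env, riparian = envr$riparian, tree = envr$tree,
                 gradients = envr$gradients, species = species,
                 config = config, seed = seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic riverscape: ", nrow(x$env), " sites, ",
      length(x$species), " species (seed ", x$seed, ")\n", sep = "")
  for (nm in names(x$species)) {
    sp <- x$species[[nm]]
    cat(" ", nm, ": ", ncol(sp$epi$states), " epiloci, ",
        length(genotype_loci(sp$genotypes)), " microsat loci, ",
        ncol(sp$pools), " SNPs\n", sep = "")
  }
  invisible(x)
}
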