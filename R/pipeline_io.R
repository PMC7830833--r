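# CSV readers/writers for every table dialect in the pipeline, plus the
# end-to-end orchestration producing the standard report bundle (AMOVA
# tables, pairwise Gst'' matrices, Mantel batteries, MRM table, PCA report,
# biplot exports). Dialect: comma separator, dot decimal, UTF-8, mandatory
# header; parsing is locale-independent.

#' Read a long-format peak table CSV
#'
#' Columns: `individual,locus_size,profile,rfu`.
#' @param path CSV path.
#' @return data frame suitable for [call_presence()].
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "locus_size", "profile", "rfu")
  if (!all(need %in% names(df)))
    stop("peak table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read / write a four-state matrix CSV
#'
#' Layout: first column `individual`, second `population`, remaining columns
#' one locus each with states written I/II/III/IV (empty = unscored).
#' @param path CSV path.
#' @return a [four_state_matrix()].
#' @export
read_four_state_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 3 || !identical(names(df)[1:2], c("individual", "population")))
    stop("four-state CSV must start with individual,population columns")
  s <- as.matrix(df[, -(1:2), drop = FALSE])
  s[s == ""] <- NA
  rownames(s) <- df$individual
  four_state_matrix(s, df$population)
}

#' @rdname read_four_state_matrix
#' @param m a `four_state_matrix`.
#' @export
write_four_state_matrix <- function(m, path) {
  stopifnot(inherits(m, "four_state_matrix"))
  df <- data.frame(individual = rownames(m$states),
                   population = m$populations,
                   m$states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a diploid genotype table CSV
#'
#' Columns: `individual,population`, then `<locus>_a1,<locus>_a2` pairs;
#' missing alleles as empty cells or `NA`.
#' @param path CSV path.
#' @return genotype data frame.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("NA", ""), colClasses = "character")
  genotype_loci(df)      # validates layout
  df
}

#' Read a pooled SNP frequency CSV
#'
#' First column `population`, remaining columns one SNP each with the
#' reference-allele frequency in \[0, 1\].
#' @param path CSV path.
#' @return a [freq_table()] with `marker = "snp_pool"`.
#' @export
read_pool_frequencies <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "population")
    stop("pool CSV must start with a population column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$population
  pool_frequencies(m)
}

#' Read a site x environmental-variable CSV
#'
#' First column `site`, header row with variable names.
#' @param path CSV path.
#' @return numeric matrix with site row names.
#' @export
read_env_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "site") stop("environment CSV must start with a site column")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("environmental variables must be numeric")
  rownames(m) <- df$site
  m
}

#' Read / write a labeled square distance matrix CSV
#'
#' First column holds row labels, header the (identical) column labels.
#' Validation: square, unique matching labels, non-negative, zero diagonal,
#' symmetric within 1e-9 (small asymmetries are averaged away, larger ones
#' are an error).
#' @param path CSV path.
#' @return validated matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  validate_distance_matrix(m)
}

#' @rdname read_distance_matrix
#' @param m square matrix.
#' @export
write_distance_matrix <- function(m, path) {
  m <- validate_distance_matrix(m)
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full riverscape analysis
#'
#' Per species: two-level AMOVA on epiloci and microsatellites (SNP pools
#' carry no individual level and are excluded by construction), pairwise
#' Gst'' for all three marker systems, the marker-vs-marker Mantel battery,
#' the marker-vs-environment/riparian Mantel battery, and an MRM with the
#' epigenetic Gst'' matrix as response and the three environmental axis
#' distances, riparian distance and the SNP Gst'' matrix as predictors
#' (optionally also the microsatellite Gst'' matrix). All randomized
#' procedures draw from independent named substreams of `seed`, so toggling
#' one analysis never perturbs another's p-values.
#'
#' @param data a [simulate_riverscape()] dataset, or a list with the same
#'   shape (`env`, `riparian`, and per-species `epi`, `genotypes`, `pools`).
#' @param n_perm permutations for every test; default 1000.
#' @param seed master seed; default 1.
#' @param retain number of environmental PCA axes retained; default 3.
#' @param scale_pca standardize environmental variables? Default `TRUE`.
#' @param include_microsat_in_mrm add the microsatellite Gst'' matrix as an
#'   MRM predictor? Default `FALSE`.
#' @return object of class `report_bundle`.
#' @export
run_full_analysis <- function(data, n_perm = 1000, seed = 1, retain = 3,
                              scale_pca = TRUE,
                              include_microsat_in_mrm = FALSE) {
  if (is.null(data$env) || is.null(data$riparian) || is.null(data$species))
    stop("missing input block: need env, riparian and species data")
  pca <- retain_components(env_pca(data$env, scale = scale_pca),
                           fixed_count = retain)
  env_d <- all_component_distances(pca)
  riparian <- validate_distance_matrix(data$riparian, what = "riparian")
  sites <- rownames(riparian)

  species_out <- lapply(names(data$species), function(sp) {
    d <- data$species[[sp]]
    if (is.null(d$epi) || is.null(d$genotypes) || is.null(d$pools))
      stop("missing input block for ", sp, ": need epi, genotypes, pools")

    # Pairwise differentiation, one engine for all three marker systems
    gst_epi <- pairwise_gst(condition_frequencies(d$epi))
    gst_ms <- pairwise_gst(genotype_frequencies(d$genotypes))
    gst_snp <- pairwise_gst(pool_frequencies(d$pools))
    gst <- list(epi = gst_epi$gst, microsat = gst_ms$gst, snp = gst_snp$gst)
    for (g in gst) align_matrix(g, sites, what = "Gst'' matrix")

    # AMOVA: individual-level markers only
    am_epi <- amova(epi_distances(d$epi), d$epi$populations, n_perm = n_perm,
                    seed = derive_seed(seed, paste0("amova_epi_", sp)))
    am_ms <- amova(microsat_distances(d$genotypes), d$genotypes$population,
                   n_perm = n_perm,
                   seed = derive_seed(seed, paste0("amova_ms_", sp)))
    amova_tab <- rbind(
      cbind(species = sp, marker = "epigenetic", amova_report_row(am_epi)),
      cbind(species = sp, marker = "microsatellite", amova_report_row(am_ms)))

    # Marker-vs-marker Mantel battery (r above diagonal, p below)
    mk <- c("microsat", "snp", "epi")
    mm <- matrix(NA_real_, 3, 3, dimnames = list(mk, mk))
    for (i in 1:2) for (j in seq(i + 1, 3)) {
      mt <- mantel_test(gst[[mk[i]]], gst[[mk[j]]], n_perm = n_perm,
                        seed = derive_seed(seed, paste("mantel", sp, mk[i], mk[j])))
      mm[i, j] <- mt$r
      mm[j, i] <- mt$p_value
    }

    # Marker-vs-environment/riparian battery
    preds <- c(env_d, list(riparian = riparian))
    me <- do.call(rbind, lapply(mk, function(k) {
      do.call(rbind, lapply(names(preds), function(pn) {
        mt <- mantel_test(gst[[k]], preds[[pn]], n_perm = n_perm,
                          seed = derive_seed(seed, paste("mantelenv", sp, k, pn)))
        data.frame(species = sp, marker = k, predictor = pn,
                   r = mt$r, p_value = mt$p_value)
      }))
    }))

    # MRM: epigenetic differentiation vs environment + space + genetics
    mrm_preds <- c(env_d, list(riparian = riparian, snp_gst = gst$snp))
    if (include_microsat_in_mrm) mrm_preds$microsat_gst <- gst$microsat
    mr <- mrm(gst$epi, mrm_preds, n_perm = n_perm,
              seed = derive_seed(seed, paste0("mrm_", sp)))

    biplot <- data.frame(
      pair = apply(utils::combn(sites, 2), 2, paste, collapse = "-"),
      snp_gst = lower_tri(gst$snp), epi_gst = lower_tri(gst$epi),
      env1_dist = lower_tri(env_d[[1]]))
    attr(biplot, "reference_line") <- TRUE

    list(gst = gst, gst_components = list(epi = gst_epi, microsat = gst_ms,
                                          snp = gst_snp),
         amova = list(epi = am_epi, microsat = am_ms),
         amova_table = amova_tab,
         mantel_markers = mm, mantel_env = me, mrm = mr, biplot = biplot)
  })
  names(species_out) <- names(data$species)

  structure(list(pca = pca, env_distances = env_d, riparian = riparian,
                 species = species_out,
                 meta = list(n_perm = n_perm, seed = seed,
                             retain = retain, scale_pca = scale_pca,
                             version = as.character(utils::packageVersion("episcape")),
                             timestamp = NA)),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Riverscape analysis report (", length(x$species), " species, seed ",
      x$meta$seed, ", ", x$meta$n_perm, " permutations)\n", sep = "")
  cat("Environmental PCA: first ", max(x$pca$retained), " axes = ",
      round(100 * sum(x$pca$var_fraction[x$pca$retained]), 2),
      "% of variance\n", sep = "")
  for (nm in names(x$species)) {
    sp <- x$species[[nm]]
    cat("\n== ", nm, " ==\n", sep = "")
    print(sp$amova_table[, c("marker", "variation_pct", "phi_st", "p_value")],
          row.names = FALSE)
    cat("Mantel r epi~snp: ", round(sp$mantel_markers["snp", "epi"], 3),
        " (p = ", round(sp$mantel_markers["epi", "snp"], 4), ")\n", sep = "")
    cat("MRM R2: ", round(sp$mrm$r_squared, 3), "\n", sep = "")
  }
  invisible(x)
}

#' Write a report bundle as CSV files
#'
#' Emits, under `dir`: the PCA loadings/scores, one AMOVA table, the
#' per-species Gst'' matrices, Mantel batteries, MRM tables, biplot data,
#' and a plain-text run log (version, seed, permutations, thresholds).
#'
#' @param bundle a [run_full_analysis()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, paste0(...))
  utils::write.csv(data.frame(variable = rownames(bundle$pca$loadings),
                              bundle$pca$loadings, check.names = FALSE),
                   fp("pca_loadings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(site = rownames(bundle$pca$scores),
                              bundle$pca$scores, check.names = FALSE),
                   fp("pca_scores.csv"), row.names = FALSE)
  amova_all <- do.call(rbind, lapply(bundle$species, `[[`, "amova_table"))
  utils::write.csv(amova_all, fp("amova.csv"), row.names = FALSE)
  for (nm in names(bundle$species)) {
    sp <- bundle$species[[nm]]
    for (k in names(sp$gst))
      write_distance_matrix(sp$gst[[k]], fp("gst_", k, "_", nm, ".csv"))
    utils::write.csv(data.frame(marker = rownames(sp$mantel_markers),
                                sp$mantel_markers, check.names = FALSE),
                     fp("mantel_markers_", nm, ".csv"), row.names = FALSE)
    utils::write.csv(sp$mantel_env, fp("mantel_env_", nm, ".csv"),
                     row.names = FALSE)
    co <- sp$mrm$coefficients
    co$r_squared <- sp$mrm$r_squared
    co$r_squared_p <- sp$mrm$r_squared_p
    utils::write.csv(co, fp("mrm_", nm, ".csv"), row.names = FALSE)
    utils::write.csv(sp$biplot, fp("biplot_", nm, ".csv"), row.names = FALSE)
  }
  writeLines(c(
    paste("episcape version:", bundle$meta$version),
    paste("seed:", bundle$meta$seed),
    paste("n_perm:", bundle$meta$n_perm),
    paste("pca axes retained:", bundle$meta$retain),
    paste("pca scaled:", bundle$meta$scale_pca)),
    fp("run_log.txt"))
  invisible(dir)
}

#' Write a synthetic dataset as the pipeline's CSV dialects
#'
#' One file per table (environment, riparian distances, and per-species
#' genotypes, pool frequencies, four-state matrix) plus a YAML echo of the
#' generating configuration.
#'
#' @param ds a [simulate_riverscape()] dataset.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, paste0(...))
  utils::write.csv(data.frame(site = rownames(ds$env), ds$env,
                              check.names = FALSE),
                   fp("environment.csv"), row.names = FALSE)
  write_distance_matrix(ds$riparian, fp("riparian.csv"))
  for (nm in names(ds$species)) {
    sp <- ds$species[[nm]]
    utils::write.csv(sp$genotypes, fp("genotypes_", nm, ".csv"),
                     row.names = FALSE, quote = FALSE, na = "")
    utils::write.csv(data.frame(population = rownames(sp$pools), sp$pools,
                                check.names = FALSE),
                     fp("pools_", nm, ".csv"), row.names = FALSE)
    write_four_state_matrix(sp$epi, fp("epi_", nm, ".csv"))
  }
  cfg <- ds$config
  cfg$pool_depth <- if (is.null(cfg$pool_depth)) "exact" else cfg$pool_depth
  yaml::write_yaml(c(unclass(cfg), list(seed = ds$seed)), fp("config.yaml"))
  invisible(dir)
}

#' Load a dataset written by [write_synthetic_dataset()]
#'
#' @param dir directory of CSV files.
#' @return list with the [run_full_analysis()] input shape.
#' @export
read_dataset_dir <- function(dir) {
  env <- read_env_table(file.path(dir, "environment.csv"))
  riparian <- read_distance_matrix(file.path(dir, "riparian.csv"))
  sp_files <- list.files(dir, "^epi_.*\\.csv$")
  species <- lapply(sp_files, function(f) {
    nm <- sub("^epi_(.*)\\.csv$", "\\1", f)
    list(epi = read_four_state_matrix(file.path(dir, f)),
         genotypes = read_genotypes(file.path(dir, paste0("genotypes_", nm, ".csv"))),
         pools = local({
           ft <- read_pool_frequencies(file.path(dir, paste0("pools_", nm, ".csv")))
           m <- do.call(cbind, lapply(ft$freqs, function(x) x[, "ref"]))
           colnames(m) <- names(ft$freqs)
           m
         }))
  })
  names(species) <- sub("^epi_(.*)\\.csv$", "\\1", sp_files)
  list(env = env, riparian = riparian, species = species)
}
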