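# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Long-format peak table from a compact spec: list of
# (individual, size, profile, rfu) rows.
peaks_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(individual = r[[1]], locus_size = as.integer(r[[2]]),
               profile = r[[3]], rfu = as.numeric(r[[4]]))
  }))
}

# Four-state matrix from a character vector per individual.
fsm_from_rows <- function(rows, populations) {
  s <- do.call(rbind, lapply(rows, function(r) unlist(strsplit(r, " "))))
  rownames(s) <- paste0("ind", seq_len(nrow(s)))
  four_state_matrix(s, populations)
}

# Random four-state matrix with uniform independent states.
random_fsm <- function(n_ind, n_loci, populations = NULL, seed = 1) {
  set.seed(seed)
  s <- matrix(sample(c("I", "II", "III", "IV"), n_ind * n_loci, TRUE),
              n_ind, n_loci)
  if (is.null(populations))
    populations <- rep(paste0("p", 1:2), length.out = n_ind)
  four_state_matrix(s, populations)
}

# Diploid genotype table from a list: one entry per individual, each a list
# of "A/B" strings per locus.
geno_df <- function(genos, populations, loci = NULL) {
  n_loci <- length(genos[[1]])
  if (is.null(loci)) loci <- paste0("loc", seq_len(n_loci))
  df <- data.frame(individual = paste0("ind", seq_along(genos)),
                   population = populations, stringsAsFactors = FALSE)
  for (j in seq_len(n_loci)) {
    al <- t(vapply(genos, function(g) {
      if (is.na(g[[j]])) c(NA_character_, NA_character_)
      else unlist(strsplit(g[[j]], "/"))
    }, character(2)))
    df[[paste0(loci[j], "_a1")]] <- al[, 1]
    df[[paste0(loci[j], "_a2")]] <- al[, 2]
  }
  df
}

# Symmetric labeled distance matrix from lower-triangle values.
dist_from_lower <- function(values, labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- values
  m + t(m)
}

# Independent Gst'' oracle: literal transcription of the standardized
# differentiation formula for two populations, one frequency matrix (2 x
# states) per locus. Kept separate from the package implementation.
gst_oracle_pair <- function(freq_list) {
  hs <- ht <- numeric(0)
  for (f in freq_list) {
    hs <- c(hs, mean(c(1 - sum(f[1, ]^2), 1 - sum(f[2, ]^2))))
    ht <- c(ht, 1 - sum(colMeans(f)^2))
  }
  HS <- mean(hs); HT <- mean(ht)
  2 * (HT - HS) / ((2 * HT - HS) * (1 - HS))
}

# Random labeled distance matrix (Euclidean from random points).
random_dist <- function(n, seed, labels = paste0("s", seq_len(n))) {
  set.seed(seed)
  x <- matrix(rnorm(n * 2), n, 2)
  m <- as.matrix(dist(x))
  dimnames(m) <- list(labels, labels)
  m
}
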