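# Per-population frequencies and pairwise standardized differentiation
# (Gst'') shared by the three marker systems: four-state epiloci (haploid
# treatment, one state per individual), codominant diploid microsatellites
# (allele-copy counting), and pooled-sequencing SNPs (frequency-only).
#
# The pairwise statistic is the standardized differentiation of Meirmans &
# Hedrick (2011):
#   Gst'' = k (HT - HS) / ((k HT - HS) (1 - HS)),   k = number of populations
# with per-locus HS the mean within-population gene diversity 1 - sum(p^2)
# and HT the gene diversity of the pooled mean frequencies; HS and HT are
# averaged across loci before the ratio. It equals 1 when populations are
# fixed for different alleles regardless of within-population diversity,
# which makes marker systems with very different heterozygosities (epiloci,
# microsatellites, SNPs) comparable on one scale.

#' Build a frequency table
#'
#' Container shared by all marker systems: a list of per-locus matrices of
#' state/allele frequencies (populations x states) plus sampled gene-copy
#' counts where available.
#'
#' @param freqs named list, one populations x states frequency matrix per
#'   locus; rows must sum to 1 (or be all-`NA` for a missing population).
#' @param n populations x loci matrix of sampled gene copies (`NA` for
#'   frequency-only data such as pools).
#' @param marker one of `"epi4"`, `"microsat"`, `"snp_pool"`.
#' @return object of class `freq_table`.
#' @export
freq_table <- function(freqs, n = NULL, marker = c("epi4", "microsat", "snp_pool")) {
  marker <- match.arg(marker)
  stopifnot(is.list(freqs), length(freqs) >= 1)
  pops <- rownames(freqs[[1]])
  for (l in seq_along(freqs)) {
    f <- freqs[[l]]
    if (!identical(rownames(f), pops))
      stop("population labels differ across loci")
    rs <- rowSums(f)
    ok <- is.na(rs) | abs(rs - 1) < 1e-9
    if (!all(ok)) stop("frequencies do not sum to 1 at locus ", l)
    if (any(f < -1e-12 | f > 1 + 1e-12, na.rm = TRUE))
      stop("frequencies outside [0, 1] at locus ", l)
  }
  if (is.null(names(freqs))) names(freqs) <- paste0("L", seq_along(freqs))
  if (!is.null(n)) {
    n <- as.matrix(n)
    stopifnot(nrow(n) == length(pops), ncol(n) == length(freqs))
    dimnames(n) <- list(pops, names(freqs))
  }
  structure(list(freqs = freqs, n = n, marker = marker, populations = pops),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("Frequency table (", x$marker, "): ", length(x$populations),
      " populations x ", length(x$freqs), " loci\n", sep = "")
  invisible(x)
}

#' Four-state condition frequencies per population
#'
#' Haploid treatment: each scored individual contributes one state per
#' epilocus; frequencies are counts over scored individuals. `NA` cells
#' (unscored) reduce the denominator; Condition IV counts as an ordinary
#' state.
#'
#' @param m a [four_state_matrix()].
#' @return a [freq_table()] with `marker = "epi4"`.
#' @export
condition_frequencies <- function(m) {
  stopifnot(inherits(m, "four_state_matrix"))
  pops <- sort(unique(m$populations))
  s <- m$states
  scored_any <- vapply(pops, function(p) {
    sum(!is.na(s[m$populations == p, , drop = FALSE]))
  }, numeric(1))
  if (any(scored_any == 0))
    stop("population with no scored individuals at any locus: ",
         pops[which(scored_any == 0)[1]])
  nmat <- matrix(NA_real_, length(pops), ncol(s),
                 dimnames = list(pops, colnames(s)))
  freqs <- vector("list", ncol(s))
  names(freqs) <- colnames(s)
  for (j in seq_len(ncol(s))) {
    f <- matrix(NA_real_, length(pops), 4,
                dimnames = list(pops, MSAFLP_STATES))
    for (i in seq_along(pops)) {
      v <- s[m$populations == pops[i], j]
      v <- v[!is.na(v)]
      nmat[i, j] <- length(v)
      if (length(v) > 0)
        f[i, ] <- tabulate(match(v, MSAFLP_STATES), 4) / length(v)
    }
    freqs[[j]] <- f
  }
  freq_table(freqs, nmat, "epi4")
}

#' Allele frequencies from a diploid genotype table
#'
#' Allele-copy counting: each fully scored individual contributes two copies
#' per locus. A genotype with exactly one recorded allele (half-genotype) is
#' rejected; fully missing genotypes reduce the denominator.
#'
#' @param g genotype data frame: columns `individual`, `population`, then
#'   two columns per locus named `<locus>_a1` and `<locus>_a2` (character or
#'   integer alleles, `NA` = missing).
#' @return a [freq_table()] with `marker = "microsat"`.
#' @export
genotype_frequencies <- function(g) {
  loci <- genotype_loci(g)
  pops <- sort(unique(as.character(g$population)))
  nmat <- matrix(NA_real_, length(pops), length(loci),
                 dimnames = list(pops, loci))
  freqs <- vector("list", length(loci))
  names(freqs) <- loci
  for (j in seq_along(loci)) {
    a1 <- as.character(g[[paste0(loci[j], "_a1")]])
    a2 <- as.character(g[[paste0(loci[j], "_a2")]])
    half <- xor(is.na(a1), is.na(a2))
    if (any(half))
      stop("half-genotype at locus ", loci[j], " for individual ",
           g$individual[which(half)[1]])
    alleles <- sort(unique(stats::na.omit(c(a1, a2))))
    f <- matrix(NA_real_, length(pops), length(alleles),
                dimnames = list(pops, alleles))
    for (i in seq_along(pops)) {
      sel <- as.character(g$population) == pops[i]
      copies <- c(a1[sel], a2[sel])
      copies <- copies[!is.na(copies)]
      nmat[i, j] <- length(copies)
      if (length(copies) > 0)
        f[i, ] <- tabulate(match(copies, alleles), length(alleles)) /
          length(copies)
    }
    freqs[[j]] <- f
  }
  freq_table(freqs, nmat, "microsat")
}

# Locus names of a genotype table (columns <locus>_a1 / <locus>_a2).
genotype_loci <- function(g) {
  stopifnot(is.data.frame(g), all(c("individual", "population") %in% names(g)))
  a1 <- sub("_a1$", "", grep("_a1$", names(g), value = TRUE))
  a2 <- sub("_a2$", "", grep("_a2$", names(g), value = TRUE))
  if (!setequal(a1, a2) || length(a1) == 0)
    stop("genotype table needs paired <locus>_a1 / <locus>_a2 columns")
  a1
}

#' Frequency table from pooled reference-allele frequencies
#'
#' Pooled sequencing yields population-level biallelic frequencies without
#' individual genotypes, so no sample-size correction is possible
#' (`n` stays `NA`).
#'
#' @param pool populations x loci matrix or data frame of reference-allele
#'   frequencies in \[0, 1\]; population labels as row names.
#' @return a [freq_table()] with `marker = "snp_pool"`.
#' @export
pool_frequencies <- function(pool) {
  pool <- as.matrix(pool)
  if (!is.numeric(pool)) stop("pool frequencies must be numeric")
  if (any(pool < 0 | pool > 1, na.rm = TRUE))
    stop("pool frequencies must lie in [0, 1]")
  if (is.null(rownames(pool))) rownames(pool) <- paste0("S", seq_len(nrow(pool)))
  if (is.null(colnames(pool))) colnames(pool) <- paste0("snp", seq_len(ncol(pool)))
  freqs <- lapply(seq_len(ncol(pool)), function(j) {
    f <- cbind(ref = pool[, j], alt = 1 - pool[, j])
    rownames(f) <- rownames(pool)
    f
  })
  names(freqs) <- colnames(pool)
  freq_table(freqs, NULL, "snp_pool")
}

#' Pairwise standardized differentiation (Gst'')
#'
#' Computes the Meirmans-Hedrick standardized differentiation for every pair
#' of populations, averaging the diversity components HS and HT across loci
#' before forming the ratio (the per-locus-ratio average is available as a
#' sensitivity mode). The default `plugin` estimator uses observed
#' frequencies directly so the three marker systems, including
#' frequency-only SNP pools, are computed identically; `nei_unbiased`
#' applies the small-sample gene-diversity correction (requires sample
#' sizes, so not available for pools).
#'
#' Loci monomorphic within a pair contribute HS = HT = 0 and stay in the
#' across-locus averages. A pair fixed for the same state at every locus has
#' no gene diversity at all; its Gst'' is reported as 0 with a warning.
#'
#' @param f a [freq_table()].
#' @param estimator `"plugin"` (default) or `"nei_unbiased"`.
#' @param average `"across_loci"` (HS, HT averaged before the ratio;
#'   default) or `"per_locus_ratio"` (mean of per-locus Gst'').
#' @return object of class `gst_result`: list with `gst` (symmetric
#'   zero-diagonal matrix), `components` (per-pair HS, HT, Gst'' data
#'   frame), `estimator`, `marker`.
#' @export
pairwise_gst <- function(f, estimator = c("plugin", "nei_unbiased"),
                         average = c("across_loci", "per_locus_ratio")) {
  stopifnot(inherits(f, "freq_table"))
  estimator <- match.arg(estimator)
  average <- match.arg(average)
  if (estimator == "nei_unbiased" && is.null(f$n))
    stop("nei_unbiased estimator needs sample sizes; pools are frequency-only")
  pops <- f$populations
  P <- length(pops)
  if (P < 2) stop("need at least two populations")
  G <- matrix(0, P, P, dimnames = list(pops, pops))
  comp <- NULL
  for (a in seq_len(P - 1)) {
    for (b in seq(a + 1, P)) {
      res <- gst_pair(f, a, b, estimator, average)
      G[a, b] <- G[b, a] <- res$gst
      comp <- rbind(comp, data.frame(pop1 = pops[a], pop2 = pops[b],
                                     hs = res$hs, ht = res$ht, k = 2,
                                     gst_dp = res$gst, n_loci = res$n_loci))
    }
  }
  structure(list(gst = G, components = comp, estimator = estimator,
                 average = average, marker = f$marker),
            class = "gst_result")
}

# Gst'' for one population pair. k = 2.
gst_pair <- function(f, a, b, estimator, average) {
  k <- 2
  hs_l <- ht_l <- numeric(0)
  for (j in seq_along(f$freqs)) {
    pa <- f$freqs[[j]][a, ]
    pb <- f$freqs[[j]][b, ]
    if (anyNA(pa) || anyNA(pb)) next
    hs_a <- 1 - sum(pa^2)
    hs_b <- 1 - sum(pb^2)
    hs <- (hs_a + hs_b) / 2
    ht <- 1 - sum(((pa + pb) / 2)^2)
    if (estimator == "nei_unbiased") {
      na <- f$n[a, j]; nb <- f$n[b, j]
      if (is.na(na) || is.na(nb) || na < 2 || nb < 2)
        stop("nei_unbiased needs >= 2 gene copies per population per locus")
      nh <- 2 / (1 / na + 1 / nb)          # harmonic mean gene copies
      hs <- nh / (nh - 1) * hs
      ht <- ht + hs / (nh * k)
    }
    hs_l <- c(hs_l, hs)
    ht_l <- c(ht_l, ht)
  }
  if (length(hs_l) == 0) stop("pair with no shared scored locus")
  gst_ratio <- function(hs, ht) {
    num <- k * (ht - hs)
    den <- (k * ht - hs) * (1 - hs)
    if (abs(den) < 1e-15) 0 else num / den
  }
  if (average == "across_loci") {
    hs <- mean(hs_l); ht <- mean(ht_l)
    if (ht < 1e-15) {
      warning("degenerate pair: no gene diversity at any locus; Gst'' = 0")
      g <- 0
    } else g <- gst_ratio(hs, ht)
  } else {
    poly <- ht_l > 1e-15
    if (!any(poly)) {
      warning("degenerate pair: no gene diversity at any locus; Gst'' = 0")
      hs <- mean(hs_l); ht <- mean(ht_l); g <- 0
    } else {
      g <- mean(mapply(gst_ratio, hs_l[poly], ht_l[poly]))
      hs <- mean(hs_l); ht <- mean(ht_l)
    }
  }
  list(gst = g, hs = hs, ht = ht, n_loci = length(hs_l))
}

#' @export
print.gst_result <- function(x, ...) {
  cat("Pairwise Gst'' (", x$marker, ", ", x$estimator, ", ", x$average,
      "): ", nrow(x$gst), " populations\n", sep = "")
  cat("Mean pairwise Gst'': ", round(mean(lower_tri(x$gst)), 4), "\n", sep = "")
  invisible(x)
}
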