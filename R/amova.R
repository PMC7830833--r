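# Two-level distance-based analysis of molecular variance (Excoffier-style),
# partitioning squared inter-individual molecular distances into among- and
# within-population variance components, with a one-tailed permutation test
# on Phi-st (individual population labels permuted).

#' Squared inter-individual distance matrix for epiloci
#'
#' Per-locus mismatch metric: a pair contributes 0 at a locus where both
#' individuals carry the same methylation condition and 1 otherwise, summed
#' over loci. On indicator-coded states this count is a squared Euclidean
#' distance, which is what the AMOVA decomposition expects. Pairs with
#' missing loci are rescaled: mean per-locus distance over comparable loci
#' times the total locus count.
#'
#' @param m a [four_state_matrix()].
#' @return individuals x individuals squared-distance matrix.
#' @export
epi_distances <- function(m) {
  stopifnot(inherits(m, "four_state_matrix"))
  s <- m$states
  N <- nrow(s)
  if (N < 2) stop("need at least 2 individuals")
  L <- ncol(s)
  if (!anyNA(s)) {
    match_ct <- matrix(0, N, N)
    for (st in MSAFLP_STATES) {
      x <- s == st
      match_ct <- match_ct + tcrossprod(x)
    }
    d2 <- L - match_ct
  } else {
    obs <- !is.na(s)
    comp <- tcrossprod(obs)                       # loci compared per pair
    if (any(lower_tri(comp) == 0))
      stop("individual pair with zero comparable loci")
    match_ct <- matrix(0, N, N)
    for (st in MSAFLP_STATES) {
      x <- !is.na(s) & s == st
      match_ct <- match_ct + tcrossprod(x)
    }
    d2 <- (comp - match_ct) / comp * L
  }
  diag(d2) <- 0
  dimnames(d2) <- list(rownames(s), rownames(s))
  d2
}

#' Squared inter-individual distance matrix for microsatellites
#'
#' Per-locus contribution is the number of non-shared allele copies between
#' two diploid genotypes (0, 1 or 2), i.e. half the L1 distance between
#' allele-count vectors, summed over loci. Missing genotypes are handled by
#' rescaling the mean per-locus distance to the total locus count.
#'
#' @param g genotype data frame (see [genotype_frequencies()]).
#' @return individuals x individuals squared-distance matrix.
#' @export
microsat_distances <- function(g) {
  loci <- genotype_loci(g)
  ids <- as.character(g$individual)
  if (anyDuplicated(ids)) stop("duplicate individual ids")
  N <- length(ids)
  if (N < 2) stop("need at least 2 individuals")
  d2 <- matrix(0, N, N)
  comp <- matrix(0, N, N)
  for (lc in loci) {
    a1 <- as.character(g[[paste0(lc, "_a1")]])
    a2 <- as.character(g[[paste0(lc, "_a2")]])
    half <- xor(is.na(a1), is.na(a2))
    if (any(half))
      stop("half-genotype at locus ", lc, " for individual ", ids[which(half)[1]])
    scored <- !is.na(a1)
    alleles <- sort(unique(c(a1[scored], a2[scored])))
    cnt <- matrix(0, N, length(alleles))
    cnt[cbind(which(scored), match(a1[scored], alleles))] <-
      cnt[cbind(which(scored), match(a1[scored], alleles))] + 1
    cnt[cbind(which(scored), match(a2[scored], alleles))] <-
      cnt[cbind(which(scored), match(a2[scored], alleles))] + 1
    dl <- matrix(0, N, N)
    for (k in seq_along(alleles))
      dl <- dl + abs(outer(cnt[, k], cnt[, k], "-"))
    dl <- dl / 2
    dl[!scored, ] <- 0; dl[, !scored] <- 0
    d2 <- d2 + dl
    comp <- comp + outer(scored, scored, "&")
  }
  if (any(lower_tri(comp) == 0)) stop("individual pair with zero comparable loci")
  d2 <- d2 / comp * length(loci)
  diag(d2) <- 0
  dimnames(d2) <- list(ids, ids)
  d2
}

#' Squared inter-individual distances for a marker set
#'
#' Dispatcher over the two individual-level marker types. SNP pools carry no
#' individual genotypes and are deliberately not accepted: AMOVA needs the
#' within-population (individual) level.
#'
#' @param markers a [four_state_matrix()] or a genotype data frame.
#' @return squared-distance matrix.
#' @export
individual_distance_matrix <- function(markers) {
  if (inherits(markers, "four_state_matrix")) return(epi_distances(markers))
  if (inherits(markers, "freq_table"))
    stop("population-level frequency data (e.g. SNP pools) carry no ",
         "individual genotypes; AMOVA requires individual-level markers")
  if (is.data.frame(markers)) return(microsat_distances(markers))
  stop("unsupported marker object for individual distances")
}

# SS_within for a label assignment: sum over populations of the within-pop
# pairwise squared distances divided by population size.
amova_ss_within <- function(d2, labels) {
  S <- rowsum(d2, labels)                  # P x N
  B <- rowsum(t(S), labels)                # P x P, row/col order identical
  n <- as.vector(table(labels)[rownames(B)])
  sum(diag(B) / (2 * n))
}

#' Two-level distance-based AMOVA
#'
#' Partitions squared molecular distances among and within populations.
#' With N individuals in P populations of sizes n_p:
#' `SS_total = sum_{i<j} d2_ij / N`,
#' `SS_within = sum_p sum_{i<j in p} d2_ij / n_p`,
#' `SS_among = SS_total - SS_within`; `df_among = P - 1`,
#' `df_within = N - P`; `sigma2_within = SS_within / df_within`;
#' `sigma2_among = (MS_among - sigma2_within) / n0` with
#' `n0 = (N - sum(n_p^2) / N) / (P - 1)`. Phi-st is the among-population
#' fraction of total variance. Significance is one-tailed (large Phi-st =
#' more structure) by permuting individual population labels; the observed
#' configuration enters the null through the +1 convention, so the p-value
#' lies in (0, 1].
#'
#' Negative `sigma2_among` estimates are reported as computed (no clamping);
#' `clamp` recomputes the displayed %variation with the among component
#' floored at zero.
#'
#' @param d2 squared-distance matrix from [individual_distance_matrix()].
#' @param populations population label per individual (aligned with the
#'   rows of `d2`).
#' @param n_perm number of label permutations; default 1000.
#' @param seed optional integer seed for the permutation stream.
#' @param clamp floor the among-population component at zero for the
#'   percentage display? Default `FALSE`.
#' @return object of class `amova_result`.
#' @export
amova <- function(d2, populations, n_perm = 1000, seed = NULL, clamp = FALSE) {
  d2 <- as.matrix(d2)
  N <- nrow(d2)
  populations <- as.character(populations)
  if (length(populations) != N)
    stop("one population label per individual required")
  if (n_perm < 1) stop("n_perm must be >= 1")
  n_p <- table(populations)
  P <- length(n_p)
  if (P < 2) stop("need >= 2 populations")
  if (any(n_p < 2))
    stop("population of size 1: ", names(n_p)[which(n_p < 2)[1]])

  ss_total <- sum(lower_tri(d2)) / N
  ss_within <- amova_ss_within(d2, populations)
  ss_among <- ss_total - ss_within
  df_among <- P - 1
  df_within <- N - P
  sigma2_w <- ss_within / df_within
  n0 <- (N - sum(n_p^2) / N) / (P - 1)
  sigma2_a <- (ss_among / df_among - sigma2_w) / n0

  degenerate <- (sigma2_a + sigma2_w) <= 0 || all(lower_tri(d2) == 0)
  phi <- if (degenerate) NA_real_ else sigma2_a / (sigma2_a + sigma2_w)
  sa <- if (clamp) max(sigma2_a, 0) else sigma2_a
  pct <- if (degenerate) NA_real_ else 100 * sa / (sa + sigma2_w)

  if (!is.null(seed)) set.seed(seed)
  p_value <- NA_real_
  if (!degenerate) {
    # Phi is monotone decreasing in SS_within for fixed totals and group
    # sizes, but recompute it in full for clarity.
    phi_perm <- function(labels) {
      ssw <- amova_ss_within(d2, labels)
      sw <- ssw / df_within
      sa <- ((ss_total - ssw) / df_among - sw) / n0
      sa / (sa + sw)
    }
    hits <- 0L
    for (i in seq_len(n_perm))
      if (phi_perm(sample(populations)) >= phi) hits <- hits + 1L
    p_value <- (1 + hits) / (n_perm + 1)
  }

  structure(list(df_among = df_among, df_within = df_within,
                 ss_among = ss_among, ss_within = ss_within,
                 ss_total = ss_total,
                 sigma2_among = sigma2_a, sigma2_within = sigma2_w,
                 pct_variation_among = pct, phi_st = phi,
                 p_value = p_value, n_permutations = n_perm,
                 degenerate = degenerate, n_individuals = N,
                 n_populations = P),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Two-level AMOVA (", x$n_individuals, " individuals, ",
      x$n_populations, " populations)\n", sep = "")
  tab <- data.frame(
    source = c("Among populations", "Within populations", "Total"),
    df = c(x$df_among, x$df_within, x$df_among + x$df_within),
    SS = round(c(x$ss_among, x$ss_within, x$ss_total), 3),
    sigma2 = round(c(x$sigma2_among, x$sigma2_within, NA), 4)
  )
  print(tab, row.names = FALSE)
  if (x$degenerate) {
    cat("Degenerate: no molecular variance; Phi-st undefined\n")
  } else {
    cat(sprintf("Variation among: %.2f%%  Phi-st: %.4f  p = %.4g (%d permutations)\n",
                x$pct_variation_among, x$phi_st, x$p_value, x$n_permutations))
  }
  invisible(x)
}

#' AMOVA result as a one-row report table
#'
#' @param x an [amova()] result.
#' @return data frame mirroring the usual AMOVA report columns.
#' @export
amova_report_row <- function(x) {
  stopifnot(inherits(x, "amova_result"))
  data.frame(df = x$df_among, sum_of_squares = x$ss_among,
             variance_component = x$sigma2_among,
             variation_pct = x$pct_variation_among,
             phi_st = x$phi_st, p_value = x$p_value)
}
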