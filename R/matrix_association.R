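# Permutation inference on distance matrices: the simple Mantel test and
# multiple regression on distance matrices (MRM). Both unfold the lower
# triangle of labeled symmetric matrices; the null is generated by jointly
# permuting rows and columns of one matrix, which preserves the within-site
# dependence structure of pairwise distances.

# Align d2 to d1's labels, validating both.
align_pair <- function(d1, d2, what = "distance matrix") {
  d1 <- validate_distance_matrix(d1, what = what)
  d2 <- validate_distance_matrix(d2, what = what)
  d2 <- align_matrix(d2, rownames(d1), what = what)
  list(d1 = d1, d2 = d2)
}

#' Simple Mantel test
#'
#' Pearson correlation between the lower triangles of two labeled distance
#' matrices, with significance from jointly permuting the rows and columns
#' of the second matrix. For small numbers of sites (factorial up to
#' `exhaustive_limit`, i.e. N <= 7 by default) the complete permutation set
#' is enumerated and the p-value is exact; otherwise `n_perm` random
#' permutations are drawn and the observed configuration is included in the
#' null (+1 convention). The default alternative is one-sided positive
#' association, the usual directional question for isolation-by-distance /
#' isolation-by-environment; `"two.sided"` tests |r|.
#'
#' @param d1,d2 labeled symmetric matrices; matched by site label, not
#'   position.
#' @param n_perm number of sampled permutations; default 1000.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param seed optional integer seed.
#' @param exhaustive_limit enumerate all N! permutations when N! is at most
#'   this; default 5040.
#' @return object of class `mantel_result`: `r`, `p_value`,
#'   `n_permutations`, `exhaustive`, `alternative`.
#' @export
mantel_test <- function(d1, d2, n_perm = 1000, alternative = c("greater", "two.sided"),
                        seed = NULL, exhaustive_limit = 5040) {
  alternative <- match.arg(alternative)
  al <- align_pair(d1, d2)
  d1 <- al$d1; d2 <- al$d2
  N <- nrow(d1)
  if (N < 4) stop("need at least 4 sites for a Mantel test")
  x <- lower_tri(d1)
  if (stats::sd(x) == 0) stop("zero variance in first matrix's distances")
  if (stats::sd(lower_tri(d2)) == 0)
    stop("zero variance in second matrix's distances")
  r_obs <- stats::cor(x, lower_tri(d2))

  stat <- if (alternative == "greater") identity else abs
  r_perm <- function(p) stats::cor(x, lower_tri(d2[p, p]))
  if (factorial(N) <= exhaustive_limit) {
    perms <- all_perms(N)
    rs <- vapply(perms, r_perm, numeric(1))
    p_value <- mean(stat(rs) >= stat(r_obs) - 1e-12)
    exhaustive <- TRUE
    n_used <- length(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_perm))
      if (stat(r_perm(sample.int(N))) >= stat(r_obs) - 1e-12) hits <- hits + 1L
    p_value <- (1 + hits) / (n_perm + 1)
    exhaustive <- FALSE
    n_used <- n_perm
  }
  structure(list(r = r_obs, p_value = p_value, n_permutations = n_used,
                 exhaustive = exhaustive, alternative = alternative,
                 n_sites = N),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%d sites): r = %.4f, p = %.4g (%s, %d %spermutations)\n",
              x$n_sites, x$r, x$p_value, x$alternative, x$n_permutations,
              if (x$exhaustive) "exhaustive " else ""))
  invisible(x)
}

#' Multiple regression on distance matrices (MRM)
#'
#' Ordinary least squares of the unfolded response lower triangle on the
#' unfolded predictor triangles (with intercept). Coefficient significance
#' comes from jointly permuting rows and columns of the response matrix
#' only (predictors fixed) and recomputing the fit: coefficient p-values
#' are two-sided on magnitude, the R-squared p-value one-sided greater. The
#' observed configuration is included in the null (+1 convention).
#'
#' @param response labeled symmetric matrix.
#' @param predictors named list of labeled symmetric matrices.
#' @param n_perm number of permutations; default 1000.
#' @param seed optional integer seed.
#' @return object of class `mrm_result`: `coefficients` (data frame with
#'   estimates and p-values), `r_squared`, `r_squared_p`, `n_permutations`.
#' @export
mrm <- function(response, predictors, n_perm = 1000, seed = NULL) {
  if (!is.list(predictors)) predictors <- list(predictors)
  if (is.null(names(predictors)) || any(names(predictors) == ""))
    names(predictors) <- paste0("X", seq_along(predictors))
  response <- validate_distance_matrix(response, what = "response")
  labels <- rownames(response)
  N <- length(labels)
  preds <- lapply(seq_along(predictors), function(i) {
    p <- validate_distance_matrix(predictors[[i]],
                                  what = names(predictors)[i])
    align_matrix(p, labels, what = names(predictors)[i])
  })
  npair <- N * (N - 1) / 2
  if (npair <= length(preds) + 1)
    stop("too few site pairs for ", length(preds), " predictors")

  X <- cbind(intercept = 1,
             do.call(cbind, lapply(preds, lower_tri)))
  colnames(X) <- c("intercept", names(predictors))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("collinear predictors: design is rank-deficient in ",
         paste(dep, collapse = ", "))
  }
  y <- lower_tri(response)
  fit_stats <- function(yv) {
    b <- qr.coef(qrX, yv)
    res <- yv - X %*% b
    tss <- sum((yv - mean(yv))^2)
    r2 <- if (tss == 0) 0 else 1 - sum(res^2) / tss
    list(b = b, r2 = r2)
  }
  obs <- fit_stats(y)

  if (!is.null(seed)) set.seed(seed)
  hits_b <- integer(ncol(X))
  hits_r2 <- 0L
  for (i in seq_len(n_perm)) {
    p <- sample.int(N)
    st <- fit_stats(lower_tri(response[p, p]))
    hits_b <- hits_b + (abs(st$b) >= abs(obs$b) - 1e-12)
    if (st$r2 >= obs$r2 - 1e-12) hits_r2 <- hits_r2 + 1L
  }
  coef_p <- (1 + hits_b) / (n_perm + 1)
  structure(list(
    coefficients = data.frame(term = colnames(X),
                              estimate = as.numeric(obs$b),
                              p_value = coef_p, row.names = NULL),
    r_squared = obs$r2,
    r_squared_p = (1 + hits_r2) / (n_perm + 1),
    n_permutations = n_perm, n_sites = N),
    class = "mrm_result")
}

#' @export
print.mrm_result <- function(x, ...) {
  cat(sprintf("MRM (%d sites, %d permutations): R2 = %.4f, p = %.4g\n",
              x$n_sites, x$n_permutations, x$r_squared, x$r_squared_p))
  df <- x$coefficients
  df$estimate <- signif(df$estimate, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
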