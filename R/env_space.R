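# Environmental ordination: PCA of site-level variables and per-axis
# distance matrices used as predictors in Mantel / MRM models.

#' The 14 standard riverscape environmental variables
#'
#' Topographical (flow m3/s, width m, slope %, altitude m) and
#' physicochemical (conductivity, BOD, suspended matter, nitrate, nitrite,
#' orthophosphate, oxygen, pH, oxygen saturation, temperature) descriptors
#' of river sites.
#' @export
ENV_VARIABLES <- c("flow", "width", "slope", "altitude", "conductivity",
                   "BOD", "SM", "nitrate", "nitrite", "orthophosphate",
                   "oxygen", "pH", "oxygen_saturation", "temperature")

#' Principal component analysis of a site x environment table
#'
#' Centers (and by default unit-variance scales) the variables and computes
#' principal components ordered by decreasing variance. Because river
#' variables mix units (m3/s, mg/L, %, degrees C), the correlation-matrix
#' PCA (`scale = TRUE`) is the default; an unscaled covariance PCA is
#' available. A deterministic sign convention is applied: each loading
#' column is flipped so that its largest-magnitude entry is positive, making
#' reports reproducible (PCA signs are otherwise arbitrary).
#'
#' @param env numeric sites x variables matrix or data frame, site labels as
#'   row names.
#' @param scale standardize variables to unit variance? Default `TRUE`.
#' @return object of class `env_pca`: list with `loadings` (variables x
#'   components), `scores` (sites x components), `var_fraction`, `sdev`,
#'   `retained` (component indices, initially all).
#' @export
env_pca <- function(env, scale = TRUE) {
  env <- as.matrix(env)
  if (!is.numeric(env)) stop("environmental table must be numeric")
  if (anyNA(env)) stop("environmental table has missing cells")
  if (nrow(env) < 2) stop("need at least 2 sites")
  if (ncol(env) < 2) stop("need at least 2 variables")
  if (is.null(rownames(env))) rownames(env) <- paste0("S", seq_len(nrow(env)))
  if (scale) {
    sds <- apply(env, 2, stats::sd)
    if (any(sds == 0))
      stop("zero-variance variable with scale = TRUE: ",
           colnames(env)[which(sds == 0)[1]])
  }
  p <- stats::prcomp(env, center = TRUE, scale. = scale)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(p$rotation, 2, flip, "*")
  scores <- sweep(p$x, 2, flip, "*")
  vf <- p$sdev^2 / sum(p$sdev^2)
  structure(list(loadings = loadings, scores = scores,
                 var_fraction = vf, sdev = p$sdev,
                 retained = seq_along(vf), scaled = scale),
            class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  cat("Environmental PCA: ", nrow(x$scores), " sites, ",
      nrow(x$loadings), " variables\n", sep = "")
  k <- min(5, length(x$var_fraction))
  cat("Variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$var_fraction[seq_len(k)]),
            collapse = ", "),
      if (length(x$var_fraction) > k) "...", "\n")
  cat("Retained components:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Mark the retained principal components
#'
#' Either a fixed count of leading axes (default 3, the usual choice when
#' three interpretable gradients emerge) or the smallest leading set whose
#' cumulative variance fraction reaches `cum_variance`.
#'
#' @param p an [env_pca()] result.
#' @param fixed_count number of leading components to retain.
#' @param cum_variance alternatively, target cumulative variance fraction in
#'   (0, 1]; overrides `fixed_count` when given.
#' @return the `env_pca` object with `retained` updated.
#' @export
retain_components <- function(p, fixed_count = 3, cum_variance = NULL) {
  stopifnot(inherits(p, "env_pca"))
  if (!is.null(cum_variance)) {
    if (!(cum_variance > 0 && cum_variance <= 1))
      stop("cum_variance must be in (0, 1]")
    k <- which(cumsum(p$var_fraction) >= cum_variance - 1e-12)[1]
    if (is.na(k)) k <- length(p$var_fraction)
  } else {
    k <- fixed_count
    if (k < 1 || k > length(p$var_fraction))
      stop("fixed_count out of range")
  }
  p$retained <- seq_len(k)
  p
}

#' Per-axis environmental distance matrix
#'
#' One-dimensional Euclidean distance on a retained principal component:
#' `D[a, b] = |score(a, axis) - score(b, axis)|`. Each retained axis yields
#' its own predictor matrix so gradients can be tested separately.
#'
#' @param p an [env_pca()] result.
#' @param axis index of a retained component.
#' @return symmetric zero-diagonal site x site matrix.
#' @export
component_distances <- function(p, axis) {
  stopifnot(inherits(p, "env_pca"))
  if (!(axis %in% p$retained))
    stop("axis ", axis, " is not retained; call retain_components() first")
  s <- p$scores[, axis]
  d <- abs(outer(s, s, "-"))
  dimnames(d) <- list(rownames(p$scores), rownames(p$scores))
  d
}

#' Distance matrices for all retained axes
#'
#' @param p an [env_pca()] result.
#' @return named list of matrices, one per retained component.
#' @export
all_component_distances <- function(p) {
  stopifnot(inherits(p, "env_pca"))
  out <- lapply(p$retained, function(a) component_distances(p, a))
  names(out) <- paste0("PC", p$retained)
  out
}
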