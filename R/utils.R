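# Internal helpers shared across modules.

#' Validate a labeled square distance matrix
#'
#' Checks that `m` is square, numeric, non-negative, zero-diagonal and
#' symmetric within `tol`, with unique row/column labels. Asymmetries within
#' tolerance are averaged away; larger ones are an error.
#'
#' @param m numeric matrix.
#' @param tol absolute symmetry tolerance.
#' @param what name used in error messages.
#' @return the validated (symmetrized) matrix.
#' @keywords internal
validate_distance_matrix <- function(m, tol = 1e-9, what = "distance matrix") {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop(what, " is not square", call. = FALSE)
  if (!is.numeric(m)) stop(what, " must be numeric", call. = FALSE)
  if (is.null(rownames(m)) && is.null(colnames(m))) {
    rownames(m) <- colnames(m) <- paste0("S", seq_len(nrow(m)))
  }
  if (is.null(rownames(m))) rownames(m) <- colnames(m)
  if (is.null(colnames(m))) colnames(m) <- rownames(m)
  if (anyDuplicated(rownames(m))) stop(what, ": duplicate labels", call. = FALSE)
  if (!identical(rownames(m), colnames(m)))
    stop(what, ": row and column labels differ", call. = FALSE)
  if (any(m < 0)) stop(what, ": negative entries", call. = FALSE)
  if (any(abs(diag(m)) > tol)) stop(what, ": nonzero diagonal", call. = FALSE)
  asym <- max(abs(m - t(m)))
  if (asym > tol) stop(what, ": asymmetry ", format(asym), " exceeds tolerance",
                       call. = FALSE)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# Lower-triangle (column-major, i > j) unfold of a square matrix.
lower_tri <- function(m) m[lower.tri(m)]

# Align a matrix's rows and columns to `labels`, erroring on mismatch.
align_matrix <- function(m, labels, what = "matrix") {
  if (!setequal(rownames(m), labels)) {
    miss <- setdiff(labels, rownames(m))
    extra <- setdiff(rownames(m), labels)
    stop(what, ": label mismatch (",
         if (length(miss)) paste0("missing: ", miss[1]) else paste0("extra: ", extra[1]),
         ")", call. = FALSE)
  }
  m[labels, labels, drop = FALSE]
}

# Deterministic named sub-seed from a master seed, so that toggling one
# analysis never perturbs another's permutation stream. Kept below 2^31.
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(seed) * 2654435.0 + h * 97.0) %% 2147483647)
}

# All permutations of 1..n as a list (used for exhaustive Mantel nulls).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in 0L:(n - 1L)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos)
    }
  }
  out
}
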