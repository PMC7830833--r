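# MS-AFLP four-state methylation scoring.
#
# Methylation-sensitive AFLP compares the fragment profiles of two double
# digests (EcoRI/MspI and EcoRI/HpaII). Because the isoschizomers HpaII and
# MspI differ in cytosine-methylation sensitivity at CCGG, the joint
# presence/absence pattern of a fragment in the two profiles carries
# methylation information:
#   Condition I   present/present  unmethylated
#   Condition II  MspI only        internal-cytosine (hemi)methylation
#   Condition III HpaII only       external-cytosine hemimethylation
#   Condition IV  absent/absent    uninformative (hypermethylation or
#                                  restriction-site polymorphism)
# All four conditions are treated as informative states downstream; IV is a
# fourth state, never recoded as missing. A distinct NA code is reserved for
# individuals not scored at a locus.

MSAFLP_STATES <- c("I", "II", "III", "IV")

#' Score fragment presence from a peak table
#'
#' Converts a long-format peak table into one binary presence/absence matrix
#' per enzyme profile. A cell is 1 iff the individual has a peak at that
#' fragment size with height at or above `rfu_threshold` (relative
#' fluorescence units) and the size lies inside the inclusive
#' `size_window`. The locus set is the union of surviving fragment sizes
#' across individuals and both profiles, so the two matrices are directly
#' comparable.
#'
#' @param peaks data frame with columns `individual`, `locus_size` (bp,
#'   assumed pre-binned integers), `profile` (`"MSPI"` or `"HPAII"`), `rfu`.
#' @param rfu_threshold peak-height threshold, RFU; default 750.
#' @param size_window inclusive fragment-size window in bp; default
#'   `c(150, 500)`, chosen to limit size homoplasy.
#' @return named list with elements `MSPI` and `HPAII`, each an
#'   individuals x loci 0/1 matrix (locus labels are fragment sizes).
#' @examples
#' pk <- data.frame(individual = "i1", locus_size = 300,
#'                  profile = c("MSPI", "HPAII"), rfu = c(900, 100))
#' call_presence(pk)
#' @export
call_presence <- function(peaks, rfu_threshold = 750, size_window = c(150L, 500L)) {
  stopifnot(is.data.frame(peaks))
  need <- c("individual", "locus_size", "profile", "rfu")
  if (!all(need %in% names(peaks)))
    stop("peak table needs columns: ", paste(need, collapse = ", "))
  if (nrow(peaks) == 0) stop("empty peak table")
  if (rfu_threshold <= 0) stop("rfu_threshold must be positive")
  if (length(size_window) != 2 || size_window[1] >= size_window[2])
    stop("size_window must be an increasing pair")
  peaks$profile <- toupper(as.character(peaks$profile))
  if (!all(peaks$profile %in% c("MSPI", "HPAII")))
    stop("profile must be MSPI or HPAII")
  if (any(peaks$rfu < 0)) stop("negative RFU")
  if (any(peaks$locus_size <= 0)) stop("non-positive fragment size")

  key <- paste(peaks$individual, peaks$locus_size, peaks$profile, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (individual, size, profile) peaks; keeping max RFU")
    peaks <- peaks[order(-peaks$rfu), ]
    peaks <- peaks[!duplicated(paste(peaks$individual, peaks$locus_size,
                                     peaks$profile, sep = "\r")), ]
  }

  individuals <- sort(unique(as.character(peaks$individual)))
  ok <- peaks$rfu >= rfu_threshold &
    peaks$locus_size >= size_window[1] & peaks$locus_size <= size_window[2]
  hits <- peaks[ok, , drop = FALSE]
  sizes <- sort(unique(hits$locus_size))
  if (length(sizes) == 0) stop("no fragment passes the RFU/size filters")

  lab <- as.character(sizes)
  make <- function(prof) {
    m <- matrix(0L, length(individuals), length(sizes),
                dimnames = list(individuals, lab))
    h <- hits[hits$profile == prof, , drop = FALSE]
    if (nrow(h) > 0)
      m[cbind(match(as.character(h$individual), individuals),
              match(h$locus_size, sizes))] <- 1L
    attr(m, "profile") <- prof
    m
  }
  list(MSPI = make("MSPI"), HPAII = make("HPAII"))
}

#' Build a four-state methylation matrix
#'
#' @param states character matrix (individuals x loci) over `"I".."IV"`,
#'   `NA` allowed for unscored cells.
#' @param populations site label per individual (recycled names from
#'   `rownames(states)` if unnamed).
#' @return object of class `four_state_matrix`.
#' @export
four_state_matrix <- function(states, populations) {
  states <- as.matrix(states)
  if (is.null(rownames(states)))
    rownames(states) <- paste0("ind", seq_len(nrow(states)))
  if (is.null(colnames(states)))
    colnames(states) <- paste0("L", seq_len(ncol(states)))
  bad <- !(states %in% MSAFLP_STATES) & !is.na(states)
  if (any(bad)) stop("invalid methylation state: ", states[which(bad)[1]])
  populations <- as.character(populations)
  if (length(populations) != nrow(states))
    stop("one population label per individual required")
  names(populations) <- rownames(states)
  structure(list(states = states, populations = populations),
            class = "four_state_matrix")
}

#' @export
print.four_state_matrix <- function(x, ...) {
  cat("Four-state MS-AFLP matrix: ", nrow(x$states), " individuals x ",
      ncol(x$states), " epiloci, ", length(unique(x$populations)),
      " populations\n", sep = "")
  tab <- table(factor(x$states, levels = MSAFLP_STATES), useNA = "ifany")
  print(round(tab / sum(tab), 3))
  invisible(x)
}

#' Code methylation conditions from two presence matrices
#'
#' Applies the four-condition mapping to the EcoRI/MspI and EcoRI/HpaII
#' presence matrices: (1,1) -> I, (1,0) -> II, (0,1) -> III, (0,0) -> IV.
#'
#' @param mspi,hpaii individuals x loci 0/1 matrices sharing identical
#'   individual and locus labels.
#' @param populations site label per individual.
#' @return a [four_state_matrix()].
#' @export
code_conditions <- function(mspi, hpaii, populations) {
  if (!identical(rownames(mspi), rownames(hpaii))) {
    off <- c(setdiff(rownames(mspi), rownames(hpaii)),
             setdiff(rownames(hpaii), rownames(mspi)),
             rownames(mspi)[rownames(mspi) != rownames(hpaii)])
    stop("individual labels differ between profiles: ", off[1])
  }
  if (!identical(colnames(mspi), colnames(hpaii))) {
    off <- c(setdiff(colnames(mspi), colnames(hpaii)),
             setdiff(colnames(hpaii), colnames(mspi)),
             colnames(mspi)[colnames(mspi) != colnames(hpaii)])
    stop("locus labels differ between profiles: ", off[1])
  }
  if (!all(mspi %in% 0:1) || !all(hpaii %in% 0:1))
    stop("presence matrices must be binary")
  code <- matrix(MSAFLP_STATES[1 + (1 - mspi) * 2 + (1 - hpaii)],
                 nrow(mspi), ncol(mspi), dimnames = dimnames(mspi))
  four_state_matrix(code, populations)
}

#' Decompose a four-state matrix into its two presence matrices
#'
#' Inverse of [code_conditions()]: Conditions I and II imply presence in the
#' MspI profile, I and III in the HpaII profile.
#'
#' @param m a `four_state_matrix`.
#' @return list with `MSPI` and `HPAII` binary matrices.
#' @export
decompose_conditions <- function(m) {
  stopifnot(inherits(m, "four_state_matrix"))
  s <- m$states
  mk <- function(states_present, prof) {
    p <- matrix(as.integer(s %in% states_present), nrow(s), ncol(s),
                dimnames = dimnames(s))
    attr(p, "profile") <- prof
    p
  }
  list(MSPI = mk(c("I", "II"), "MSPI"), HPAII = mk(c("I", "III"), "HPAII"))
}

#' Filter uninformative and monomorphic epiloci
#'
#' Removes loci whose Condition IV (uninformative) fraction is strictly
#' greater than `max_iv_fraction` of scored individuals; the boundary case
#' (exactly the threshold) is retained. Optionally also drops monomorphic
#' loci, i.e. loci at which every scored individual carries the same state.
#'
#' @param m a [four_state_matrix()].
#' @param max_iv_fraction maximum tolerated Condition-IV fraction; default
#'   0.95 (exclusion above 95%).
#' @param drop_monomorphic drop loci with a single observed state?
#' @return filtered `four_state_matrix` with attribute `removed`, a data
#'   frame logging each removed locus and the reason.
#' @export
filter_loci <- function(m, max_iv_fraction = 0.95, drop_monomorphic = FALSE) {
  stopifnot(inherits(m, "four_state_matrix"))
  if (!(max_iv_fraction > 0 && max_iv_fraction <= 1))
    stop("max_iv_fraction must be in (0, 1]")
  s <- m$states
  n_scored <- colSums(!is.na(s))
  iv_frac <- colSums(s == "IV", na.rm = TRUE) / pmax(n_scored, 1)
  drop_iv <- iv_frac > max_iv_fraction
  mono <- vapply(seq_len(ncol(s)), function(j) {
    u <- unique(s[!is.na(s[, j]), j])
    length(u) <= 1
  }, logical(1))
  drop_mono <- drop_monomorphic & mono & !drop_iv
  drop <- drop_iv | drop_mono
  if (all(drop))
    stop("all loci removed; review max_iv_fraction / monomorphism settings")
  removed <- data.frame(
    locus = colnames(s)[drop],
    reason = ifelse(drop_iv[drop], "condition_iv_fraction", "monomorphic"),
    iv_fraction = iv_frac[drop],
    row.names = NULL
  )
  out <- four_state_matrix(s[, !drop, drop = FALSE], m$populations)
  attr(out, "removed") <- removed
  out
}
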