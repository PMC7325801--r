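# Subcortical/cerebellar MD mapping: per-structure task conjunction with
# FDR, voxel-to-core connectivity scores, the permutation null, and
# split-half replication metrics.

#' Subcortical voxel table
#'
#' @param info data.frame with columns `voxel`, `structure` and optionally
#'   `planted` (generator ground truth).
#' @param beta Subjects x voxels x contrasts array of task betas.
#' @return A `voxel_table` (list).
#' @export
voxel_table <- function(info, beta) {
  stopifnot(is.data.frame(info), all(c("voxel", "structure") %in% names(info)))
  unknown <- setdiff(unique(info$structure), md_structures())
  if (length(unknown) > 0)
    stop("unknown structure label(s): ", paste(unknown, collapse = ", "))
  if (!is.array(beta) || length(dim(beta)) != 3L ||
      dim(beta)[2] != nrow(info))
    stop("beta must be a subjects x voxels x contrasts array matching info")
  structure(list(info = info, beta = beta), class = "voxel_table")
}

#' @export
print.voxel_table <- function(x, ...) {
  cat("voxel_table: ", nrow(x$info), " voxels in ",
      length(unique(x$info$structure)), " structures, ",
      dim(x$beta)[1], " subjects, ", dim(x$beta)[3], " contrasts\n", sep = "")
  invisible(x)
}

#' Per-structure task conjunction with FDR correction
#'
#' For each structure and contrast, runs voxelwise one-sample t-tests
#' (two-sided, positive-mean gate) and applies Benjamini-Hochberg FDR
#' within the structure at `q = alpha / n_struct` (the per-structure FDR
#' level Bonferroni-shared across the 19 structures). A voxel is MD when it
#' is significant in all three contrasts.
#'
#' @param v A [voxel_table()].
#' @param alpha Significance level (default 0.05).
#' @param n_struct Bonferroni count over structures (default 19).
#' @return data.frame with `voxel`, `structure`, per-contrast significance
#'   flags and the conjunction flag `significant`.
#' @export
structure_task_conjunction <- function(v, alpha = 0.05, n_struct = 19L) {
  stopifnot(inherits(v, "voxel_table"))
  if (dim(v$beta)[1] < 2) stop("at least 2 subjects required")
  q <- alpha / n_struct
  contrasts <- dimnames(v$beta)[[3]]
  sig <- matrix(NA, nrow(v$info), length(contrasts),
                dimnames = list(v$info$voxel, paste0("sig_", contrasts)))
  for (ci in seq_along(contrasts)) {
    X <- v$beta[, , ci]
    tt <- column_ttests(X)
    for (st in unique(v$info$structure)) {
      idx <- which(v$info$structure == st)
      p_adj <- stats::p.adjust(tt$p[idx], method = "BH")
      sig[idx, ci] <- p_adj <= q & tt$mean[idx] > 0
    }
  }
  data.frame(voxel = v$info$voxel, structure = v$info$structure,
             sig,
             significant = rowSums(sig) == length(contrasts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Voxel-to-core connectivity score
#'
#' Correlates each voxel's time series with each core area's time series
#' and averages the correlations following Fisher r-to-z transformation.
#'
#' @param voxel_ts Timepoints x voxels matrix.
#' @param core_ts Timepoints x core-areas matrix (nonempty, same length).
#' @return Named vector of per-voxel mean-z scores.
#' @export
voxel_core_fc <- function(voxel_ts, core_ts) {
  if (NCOL(core_ts) == 0) stop("core set must be nonempty")
  if (nrow(voxel_ts) != nrow(core_ts))
    stop("time series lengths differ")
  vs <- apply(voxel_ts, 2, stats::sd)
  cs <- apply(core_ts, 2, stats::sd)
  if (any(vs == 0))
    stop("constant time series for voxel(s): ",
         paste(colnames(voxel_ts)[vs == 0], collapse = ", "))
  if (any(cs == 0))
    stop("constant time series for core area(s): ",
         paste(colnames(core_ts)[cs == 0], collapse = ", "))
  z <- fisher_z(stats::cor(voxel_ts, core_ts))
  rowMeans(z)
}

#' Voxel x parcel Fisher-z connectivity matrix
#'
#' Precomputes the z-transformed correlation of every voxel with every
#' cortical parcel, the input to [permutation_null()].
#'
#' @param voxel_ts Timepoints x voxels matrix.
#' @param parcel_ts Timepoints x parcels matrix.
#' @return Voxels x parcels matrix of Fisher-z correlations.
#' @export
voxel_parcel_z <- function(voxel_ts, parcel_ts) {
  if (nrow(voxel_ts) != nrow(parcel_ts))
    stop("time series lengths differ")
  fisher_z(stats::cor(voxel_ts, parcel_ts))
}

#' Permutation null for voxel-to-core connectivity
#'
#' The observed score of each voxel is its mean Fisher-z connectivity to
#' the core parcels. The null distribution is built by drawing
#' `n_perm` random sets of `core_size` parcels (without replacement, across
#' both hemispheres; one shared sequence of draws reused for every voxel)
#' and recomputing the mean-z score for each set. A voxel is significant
#' when its observed score strictly exceeds the nearest-rank percentile of
#' its own null.
#'
#' @param zmat Voxels x parcels Fisher-z matrix (see [voxel_parcel_z()]),
#'   typically from group-average connectivity.
#' @param core_parcels Column names (or indices) of the core set.
#' @param n_perm Number of permutations (default 10000; set 100000 for the
#'   full-scale analysis).
#' @param percentile Null percentile defining significance (default 97.5).
#' @param seed Integer seed for the draws.
#' @param exclude_core Exclude the true core parcels from the random sets
#'   (default `FALSE`: draws may include them).
#' @param exhaustive Enumerate all parcel subsets of size `core_size`
#'   instead of sampling (small problems only; overrides `n_perm`).
#' @return A `voxel_map` data.frame: `voxel`, `score`, `threshold`
#'   (null percentile value), `null_percentile` (percentile of the observed
#'   score within the null) and `significant`.
#' @export
permutation_null <- function(zmat, core_parcels, n_perm = 10000L,
                             percentile = 97.5, seed = 1L,
                             exclude_core = FALSE, exhaustive = FALSE) {
  if (!exhaustive && n_perm < 100) stop("n_perm must be at least 100")
  parcels <- colnames(zmat)
  if (is.character(core_parcels)) {
    missing_p <- setdiff(core_parcels, parcels)
    if (length(missing_p) > 0)
      stop("core parcels not in zmat: ", paste(missing_p, collapse = ", "))
    core_idx <- match(core_parcels, parcels)
  } else core_idx <- as.integer(core_parcels)
  core_size <- length(core_idx)
  pool <- if (exclude_core) setdiff(seq_len(ncol(zmat)), core_idx)
          else seq_len(ncol(zmat))
  if (core_size > length(pool))
    stop("core_size exceeds the number of parcels available for drawing")
  observed <- rowMeans(zmat[, core_idx, drop = FALSE])

  if (exhaustive) {
    sets <- utils::combn(pool, core_size)
    n_perm <- ncol(sets)
  } else {
    set.seed(seed)
    sets <- replicate(n_perm, sample(pool, core_size))
    sets <- matrix(sets, nrow = core_size)
  }
  # voxels x n_perm null scores via one matrix product
  ind <- matrix(0, ncol(zmat), n_perm)
  ind[cbind(as.vector(sets), rep(seq_len(n_perm), each = core_size))] <-
    1 / core_size
  null_scores <- zmat %*% ind

  k <- ceiling(percentile / 100 * n_perm)  # nearest-rank
  thr <- apply(null_scores, 1, function(x) sort(x, partial = k)[k])
  pctl <- rowSums(null_scores < observed) / n_perm * 100
  out <- data.frame(voxel = if (!is.null(rownames(zmat))) rownames(zmat)
                            else seq_len(nrow(zmat)),
                    score = unname(observed),
                    threshold = unname(thr),
                    null_percentile = unname(pctl),
                    significant = unname(observed > thr),
                    stringsAsFactors = FALSE)
  class(out) <- c("voxel_map", "data.frame")
  out
}

#' Split-half replication metrics for voxel maps
#'
#' Pearson correlation of the continuous scores and Dice overlap of the
#' significant-voxel sets, over all voxels of one structure (or all voxels
#' when `structure` is `NULL`).
#'
#' @param mapA,mapB `voxel_map` data.frames over the same voxel universe
#'   (e.g. from two half-cohorts).
#' @param structure Optional structure label to restrict to; requires a
#'   `structure` column or a `structures` vector.
#' @param structures Optional per-voxel structure labels (used when the
#'   maps lack a `structure` column).
#' @return List with `pearson_r` and `dice`.
#' @export
replication_metrics <- function(mapA, mapB, structure = NULL,
                                structures = NULL) {
  if (!identical(mapA$voxel, mapB$voxel))
    stop("voxel universes differ between the two maps")
  keep <- rep(TRUE, nrow(mapA))
  if (!is.null(structure)) {
    lab <- if (!is.null(structures)) structures else mapA$structure
    if (is.null(lab)) stop("no structure labels available")
    keep <- lab == structure
    if (!any(keep)) stop("no voxels in structure ", structure)
  }
  a <- mapA$score[keep]; b <- mapB$score[keep]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant score vector: correlation undefined")
  sa <- mapA$significant[keep]; sb <- mapB$significant[keep]
  denom <- sum(sa) + sum(sb)
  dice <- if (denom == 0) NA_real_ else 2 * sum(sa & sb) / denom
  list(pearson_r = unname(stats::cor(a, b)), dice = dice)
}
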