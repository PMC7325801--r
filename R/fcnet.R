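# Parcellated functional connectivity: per-subject correlation matrices,
# Fisher r-to-z pooling, connection-group statistics, network
# cross-tabulation, and classical MDS of MD connectivity.

#' Parcellated FC matrix from one subject's time series
#'
#' Pearson correlation between every pair of parcel time series.
#'
#' @param ts Timepoints x parcels numeric matrix with parcel column names.
#' @return Symmetric parcels x parcels correlation matrix, unit diagonal.
#' @export
parcel_fc <- function(ts) {
  if (!is.matrix(ts) || nrow(ts) < 3)
    stop("ts must be a matrix with at least 3 timepoints")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0))
    stop("constant time series for parcel(s): ",
         paste(colnames(ts)[sds == 0], collapse = ", "))
  r <- stats::cor(ts)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Fisher r-to-z transformation and its inverse
#'
#' `fisher_z` is `atanh(r)`; values with `|r| >= 1` are clamped to
#' `1 - 1e-7` in magnitude with a warning when `clamp = TRUE`, and rejected
#' otherwise. `fisher_z_inv` is `tanh(z)`.
#'
#' @param r Correlations.
#' @param clamp Clamp `|r| >= 1` instead of erroring.
#' @return Transformed values, same shape as the input.
#' @export
fisher_z <- function(r, clamp = TRUE) {
  out_of_range <- abs(r) >= 1
  if (any(out_of_range, na.rm = TRUE)) {
    if (!clamp) stop("fisher_z requires |r| < 1")
    warning(sum(out_of_range), " correlation(s) with |r| >= 1 clamped")
    r[out_of_range] <- sign(r[out_of_range]) * (1 - 1e-7)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher z values.
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Build a core/penumbra/nonMD partition from the atlas
#'
#' @param atlas Atlas data.frame (see [md_atlas()]); its `md_class` column
#'   is collapsed to the three connection classes.
#' @return Named character vector over parcels with values `"core"`,
#'   `"penumbra"`, `"nonMD"`.
#' @export
fc_partition <- function(atlas = md_atlas()) {
  cls <- c(core_full = "core", core_partial = "core",
           penumbra = "penumbra", background = "nonMD")[atlas$md_class]
  names(cls) <- atlas$parcel
  cls
}

#' @keywords internal
pair_group_labels <- function(class_a, class_b) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-")
  lab <- c("core-core" = "core-core",
           "core-penumbra" = "core-penumbra",
           "penumbra-penumbra" = "penumbra-penumbra",
           "core-nonMD" = "core-nonMD",
           "nonMD-penumbra" = "penumbra-nonMD",
           "nonMD-nonMD" = "nonMD-nonMD")
  unname(lab[key(class_a, class_b)])
}

#' The six connection groups
#' @keywords internal
connection_groups <- function() {
  c("core-core", "core-penumbra", "penumbra-penumbra",
    "core-nonMD", "penumbra-nonMD", "nonMD-nonMD")
}

#' Connection-group FC statistics
#'
#' Classifies every unordered within-hemisphere parcel pair (diagonal
#' excluded) into one of six groups by the classes of its endpoints
#' (core/penumbra/nonMD), averages Fisher-z connectivity over each group
#' per subject, and compares all 15 group pairs per hemisphere with paired
#' t-tests, Bonferroni corrected for 30 comparisons (15 per hemisphere x 2).
#' Groups with no pairs are flagged and their means set to `NA`.
#'
#' @param fc_list List of per-subject FC matrices (parcels x parcels,
#'   common parcel names).
#' @param partition Named vector mapping every parcel to
#'   `"core"`/`"penumbra"`/`"nonMD"` (see [fc_partition()]).
#' @param hemisphere Named vector mapping every parcel to `"L"`/`"R"`;
#'   inferred from `"L_"`/`"R_"` prefixes if `NULL`.
#' @param alpha Significance level (default 0.05).
#' @param m Bonferroni count for the paired comparisons (default 30).
#' @param cross_hemisphere If `TRUE`, pool pairs across hemispheres into a
#'   single analysis instead of per-hemisphere ones.
#' @return List with `group_means` (subjects x 6 groups x hemispheres array
#'   of mean z), `pair_counts`, `empty_groups`, and `tests` (one row per
#'   hemisphere and group pair: paired t, df, p, significance).
#' @export
connection_group_stats <- function(fc_list, partition, hemisphere = NULL,
                                   alpha = 0.05, m = 30L,
                                   cross_hemisphere = FALSE) {
  stopifnot(is.list(fc_list), length(fc_list) >= 1)
  parcels <- colnames(fc_list[[1]])
  if (is.null(parcels)) stop("FC matrices must have parcel names")
  if (!all(parcels %in% names(partition)))
    stop("partition is missing parcels: ",
         paste(setdiff(parcels, names(partition))[1:5], collapse = ", "))
  cls <- partition[parcels]
  if (!all(cls %in% c("core", "penumbra", "nonMD")))
    stop("partition values must be core/penumbra/nonMD")
  if (is.null(hemisphere)) {
    hemisphere <- ifelse(startsWith(parcels, "L_"), "L",
                         ifelse(startsWith(parcels, "R_"), "R", NA))
    names(hemisphere) <- parcels
    if (anyNA(hemisphere))
      stop("cannot infer hemisphere from parcel names; pass `hemisphere`")
  }
  hemi <- hemisphere[parcels]
  hemis <- if (cross_hemisphere) "LR" else sort(unique(hemi))
  groups <- connection_groups()

  # index the pairs of each hemisphere once
  pair_idx <- lapply(hemis, function(h) {
    idx <- if (cross_hemisphere) seq_along(parcels) else which(hemi == h)
    pr <- utils::combn(idx, 2)
    g <- pair_group_labels(cls[pr[1, ]], cls[pr[2, ]])
    lin <- (pr[2, ] - 1L) * length(parcels) + pr[1, ]  # upper-triangle linear
    split(lin, factor(g, levels = groups))
  })
  names(pair_idx) <- hemis

  S <- length(fc_list)
  gm <- array(NA_real_, dim = c(S, length(groups), length(hemis)),
              dimnames = list(NULL, groups, hemis))
  for (s in seq_len(S)) {
    r <- fc_list[[s]][parcels, parcels]
    diag(r) <- 0  # excluded from every group mean
    z <- fisher_z(r)
    for (h in hemis)
      gm[s, , h] <- vapply(pair_idx[[h]],
                           function(lin) if (length(lin)) mean(z[lin]) else
                             NA_real_, numeric(1))
  }
  counts <- sapply(pair_idx, function(px) vapply(px, length, integer(1)))
  empty <- which(counts == 0, arr.ind = TRUE)
  empty_groups <- if (length(empty)) {
    if (is.null(dim(counts))) groups[empty]
    else paste(rownames(counts)[empty[, 1]], colnames(counts)[empty[, 2]])
  } else character(0)

  tests <- do.call(rbind, lapply(hemis, function(h) {
    do.call(rbind, lapply(utils::combn(groups, 2, simplify = FALSE),
      function(gp) {
        a <- gm[, gp[1], h]; b <- gm[, gp[2], h]
        if (anyNA(a) || anyNA(b) || S < 2)
          return(data.frame(hemisphere = h, group1 = gp[1], group2 = gp[2],
                            mean_diff = NA_real_, t = NA_real_,
                            df = NA_integer_, p = NA_real_,
                            significant = NA))
        tt <- column_ttests(matrix(a - b, ncol = 1))
        data.frame(hemisphere = h, group1 = gp[1], group2 = gp[2],
                   mean_diff = tt$mean, t = tt$t, df = tt$df, p = tt$p,
                   significant = tt$p <= alpha / m,
                   stringsAsFactors = FALSE)
      }))
  }))
  rownames(tests) <- NULL
  list(group_means = gm, pair_counts = counts, empty_groups = empty_groups,
       tests = tests)
}

#' Cross-tabulate the MD partition against resting-state networks
#'
#' Counts how many core, penumbra and non-MD parcels fall in each
#' resting-state network.
#'
#' @param partition Named parcel -> class vector (see [fc_partition()]).
#' @param network_labels Named parcel -> network vector.
#' @return Contingency table (networks x classes).
#' @export
network_crosstab <- function(partition, network_labels) {
  missing_lab <- setdiff(names(partition), names(network_labels))
  if (length(missing_lab) > 0)
    stop("parcels without a network label: ",
         paste(missing_lab[seq_len(min(5, length(missing_lab)))],
               collapse = ", "))
  net <- network_labels[names(partition)]
  table(network = net,
        class = factor(partition, levels = c("core", "penumbra", "nonMD")))
}

#' Connection-group statistics restricted to one network
#'
#' Delegates to [connection_group_stats()] using only the parcels of the
#' given resting-state network, for within-network comparisons of
#' core/penumbra/non-MD connectivity.
#'
#' @inheritParams connection_group_stats
#' @param network_labels Named parcel -> network vector.
#' @param network Network to restrict to.
#' @export
network_connection_stats <- function(fc_list, partition, network_labels,
                                     network, ...) {
  parcels <- names(network_labels)[network_labels == network]
  fc_sub <- lapply(fc_list, function(fc) fc[parcels, parcels, drop = FALSE])
  connection_group_stats(fc_sub, partition, ...)
}

#' Group-average FC matrix
#'
#' Elementwise mean of Fisher-z connectivity across subjects, transformed
#' back to r; the diagonal is forced to 1.
#'
#' @param fc_list List of per-subject FC matrices of identical dimension.
#' @return Parcels x parcels group-average correlation matrix.
#' @export
group_average_fc <- function(fc_list) {
  stopifnot(is.list(fc_list), length(fc_list) >= 1)
  d <- dim(fc_list[[1]])
  if (!all(vapply(fc_list, function(m) identical(dim(m), d), TRUE)))
    stop("FC matrices have mismatching dimensions")
  zsum <- 0
  for (fc in fc_list) {
    fc0 <- fc
    diag(fc0) <- 0  # diagonal forced back to 1 afterwards
    zsum <- zsum + fisher_z(fc0)
  }
  r <- fisher_z_inv(zsum / length(fc_list))
  diag(r) <- 1
  dimnames(r) <- dimnames(fc_list[[1]])
  r
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, eigendecomposes, and returns
#' the top-k coordinates scaled by the square root of the eigenvalues
#' (via [stats::cmdscale()]). Negative eigenvalues — possible because
#' `1 - r` need not be Euclidean — are truncated, with a warning reporting
#' their count.
#'
#' @param d Square symmetric nonnegative distance matrix with zero diagonal.
#' @param k Embedding dimension (default 2).
#' @return List with `coordinates` (areas x k), `eigenvalues`, and
#'   `n_negative` (count of truncated negative eigenvalues).
#' @export
classical_mds <- function(d, k = 2L) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("d must be a square matrix")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be nonnegative")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  fit <- stats::cmdscale((d + t(d)) / 2, k = k, eig = TRUE)
  n_neg <- sum(fit$eig < -1e-12 * max(abs(fit$eig)))
  if (n_neg > 0)
    warning(n_neg, " negative eigenvalue(s) truncated (non-Euclidean input)")
  coords <- fit$points
  if (ncol(coords) < k)
    warning("embedding has only ", ncol(coords), " positive dimensions")
  list(coordinates = coords, eigenvalues = fit$eig, n_negative = n_neg)
}

#' 1 - r distance matrix for MDS of MD connectivity
#'
#' @param fc Group-average FC matrix.
#' @param parcels Optional subset of parcels (e.g. the extended MD set).
#' @return Distance matrix `1 - r` with zero diagonal.
#' @export
fc_distance <- function(fc, parcels = NULL) {
  if (!is.null(parcels)) fc <- fc[parcels, parcels, drop = FALSE]
  d <- 1 - fc
  diag(d) <- 0
  d
}
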