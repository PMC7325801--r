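# Parcel-level task statistics: hemisphere averaging, per-area one-sample
# t-tests with Bonferroni correction, the three-contrast conjunction that
# defines the extended MD system, and the above-set-mean core classification.

# Vectorized one-sample t-tests over the columns of a subjects x areas
# matrix. Zero-variance columns are flagged degenerate: p reported as 0,
# significance decided by the sign of the constant mean.
#' @keywords internal
column_ttests <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  s <- sqrt(colSums(sweep(X, 2, m)^2) / (n - 1))
  degenerate <- s == 0
  t <- ifelse(degenerate, ifelse(m > 0, Inf, ifelse(m < 0, -Inf, 0)),
              m / (s / sqrt(n)))
  p <- ifelse(degenerate, ifelse(m == 0, 1, 0),
              2 * stats::pt(-abs(t), df = n - 1))
  data.frame(mean = m, t = t, df = n - 1L, p = p, degenerate = degenerate)
}

#' Average areal activations across hemispheres
#'
#' Averages each area's betas over its left and right parcels, improving
#' signal-to-noise before group testing. Every area must be present in both
#' hemispheres.
#'
#' @param b A [beta_table()] with hemisphere-qualified parcels.
#' @return A [beta_table()] over 180 hemisphere-free areas (hemisphere
#'   attribute `"B"`).
#' @export
hemisphere_average <- function(b) {
  stopifnot(inherits(b, "beta_table"))
  hemi <- area_hemisphere(b)
  parcels <- dimnames(b)[[2]]
  areas <- base_area(parcels)
  left <- parcels[hemi == "L"]
  right <- parcels[hemi == "R"]
  la <- base_area(left)
  ra <- base_area(right)
  unpaired <- c(setdiff(la, ra), setdiff(ra, la),
                areas[!(hemi %in% c("L", "R"))])
  if (length(unpaired) > 0)
    stop("areas not present in both hemispheres: ",
         paste(unique(unpaired), collapse = ", "))
  right <- right[match(la, ra)]
  out <- (unclass(b)[, left, , drop = FALSE] +
            unclass(b)[, right, , drop = FALSE]) / 2
  dimnames(out)[[2]] <- la
  beta_table(out, hemisphere = rep("B", length(la)))
}

#' Per-area one-sample t-tests for one contrast
#'
#' Tests each area's group-mean beta against zero (two-sided one-sample t),
#' flagging areas with a significant positive mean at the Bonferroni
#' threshold `alpha / m`.
#'
#' @param b A [beta_table()].
#' @param contrast Contrast name or index.
#' @param alpha Familywise significance level (default 0.05).
#' @param m Bonferroni correction count (default 180 areas).
#' @return data.frame with columns `area`, `mean_beta`, `t`, `df`, `p`,
#'   `degenerate`, `significant_positive`.
#' @export
area_ttests <- function(b, contrast, alpha = 0.05, m = 180L) {
  stopifnot(inherits(b, "beta_table"))
  if (m < dim(b)[2])
    stop("Bonferroni m (", m, ") must be at least the number of areas tested (",
         dim(b)[2], ")")
  X <- unclass(b)[, , contrast, drop = FALSE]
  X <- matrix(X, dim(b)[1], dim(b)[2], dimnames = dimnames(b)[1:2])
  tt <- column_ttests(X)
  data.frame(area = rownames(tt),
             mean_beta = tt$mean, t = tt$t, df = tt$df, p = tt$p,
             degenerate = tt$degenerate,
             significant_positive = tt$p <= alpha / m & tt$mean > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Three-contrast conjunction defining the extended MD set
#'
#' An area belongs to the extended MD system when it is significantly
#' positively activated in every contrast.
#'
#' @param stats_list List of per-contrast [area_ttests()] data.frames over
#'   the same area universe.
#' @return Character vector of extended-MD area names.
#' @export
conjunction_extended_md <- function(stats_list) {
  stopifnot(is.list(stats_list), length(stats_list) >= 1)
  universes <- lapply(stats_list, function(s) sort(s$area))
  if (!all(vapply(universes[-1], identical, TRUE, universes[[1]])))
    stop("per-contrast statistics cover different area universes")
  sig_sets <- lapply(stats_list, function(s) s$area[s$significant_positive])
  Reduce(intersect, sig_sets)
}

#' Core / penumbra classification within the extended MD set
#'
#' For each extended area and contrast, forms per-subject differences
#' between the area's beta and that subject's mean over the whole extended
#' set, and tests the differences against zero (one-sample t, Bonferroni
#' corrected for the extended-set size). An area significantly above the
#' mean in all three contrasts is full core; in exactly two, partial core;
#' the remainder is penumbra. The paired difference cancels any global
#' per-subject offset. `method = "grand_mean"` instead tests each area's
#' betas against the scalar grand mean over subjects and extended areas
#' (an unpaired variant retained for sensitivity analysis).
#'
#' @param b A [beta_table()] containing at least the extended areas.
#' @param extended_set Character vector of extended-MD area names (>= 2).
#' @param alpha Significance level (default 0.05).
#' @param method `"paired"` (default) or `"grand_mean"`.
#' @return An `md_partition` list: `extended_set`, `core_set`,
#'   `core_full_set`, `core_partial_set`, `penumbra_set`, and the per-area
#'   per-contrast `stats` data.frame.
#' @export
core_classification <- function(b, extended_set, alpha = 0.05,
                                method = c("paired", "grand_mean")) {
  stopifnot(inherits(b, "beta_table"))
  method <- match.arg(method)
  if (length(extended_set) < 2)
    stop("extended_set must contain at least 2 areas ",
         "(the set mean is ill-defined as a comparison target otherwise)")
  missing_areas <- setdiff(extended_set, dimnames(b)[[2]])
  if (length(missing_areas) > 0)
    stop("areas not in the beta table: ", paste(missing_areas, collapse = ", "))
  m <- length(extended_set)
  contrasts <- dimnames(b)[[3]]
  stats <- do.call(rbind, lapply(contrasts, function(cn) {
    X <- unclass(b)[, extended_set, cn]
    D <- if (method == "paired") X - rowMeans(X) else X - mean(X)
    tt <- column_ttests(D)
    data.frame(area = extended_set, contrast = cn,
               mean_diff = tt$mean, t = tt$t, df = tt$df, p = tt$p,
               degenerate = tt$degenerate,
               significant_above = tt$p <= alpha / m & tt$mean > 0,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  n_sig <- tapply(stats$significant_above, stats$area, sum)[extended_set]
  core_full <- extended_set[n_sig == length(contrasts)]
  # "all but one" requires at least one significant contrast
  core_partial <- extended_set[n_sig == length(contrasts) - 1L & n_sig > 0]
  out <- list(extended_set = extended_set,
              core_set = c(core_full, core_partial),
              core_full_set = core_full,
              core_partial_set = core_partial,
              penumbra_set = setdiff(extended_set, c(core_full, core_partial)),
              stats = stats)
  class(out) <- "md_partition"
  out
}

#' @export
print.md_partition <- function(x, ...) {
  cat("MD partition\n")
  cat("  extended:    ", length(x$extended_set), "areas\n")
  cat("  core (full): ", paste(x$core_full_set, collapse = ", "), "\n")
  cat("  core (2/3):  ", paste(x$core_partial_set, collapse = ", "), "\n")
  cat("  penumbra:    ", paste(x$penumbra_set, collapse = ", "), "\n")
  invisible(x)
}

#' Merge areas (or segments) into a single composite area
#'
#' Replaces the listed areas with their weighted per-subject mean, as when
#' combining the significant segments on both sides of an areal border into
#' a composite area.
#'
#' @param b A [beta_table()].
#' @param area_list Areas to merge (>= 1).
#' @param weights Nonnegative weights, recycled/normalized to sum 1;
#'   default equal.
#' @param new_area Name of the merged area.
#' @return A [beta_table()] with the members removed and the composite
#'   appended.
#' @export
merge_areas <- function(b, area_list, weights = NULL, new_area = "merged") {
  stopifnot(inherits(b, "beta_table"))
  if (length(area_list) == 0) stop("area_list must not be empty")
  missing_areas <- setdiff(area_list, dimnames(b)[[2]])
  if (length(missing_areas) > 0)
    stop("unknown areas: ", paste(missing_areas, collapse = ", "))
  if (is.null(weights)) weights <- rep(1, length(area_list))
  if (length(weights) != length(area_list) || any(weights < 0) ||
      sum(weights) == 0)
    stop("weights must be nonnegative, one per area, with positive sum")
  w <- weights / sum(weights)
  hemi <- area_hemisphere(b)
  sub <- unclass(b)[, area_list, , drop = FALSE]
  merged <- apply(sub, c(1, 3), function(v) sum(v * w))
  keep <- setdiff(dimnames(b)[[2]], area_list)
  out <- array(NA_real_, dim = c(dim(b)[1], length(keep) + 1L, dim(b)[3]),
               dimnames = list(dimnames(b)[[1]], c(keep, new_area),
                               dimnames(b)[[3]]))
  out[, keep, ] <- unclass(b)[, keep, , drop = FALSE]
  out[, new_area, ] <- merged
  h_new <- if (length(unique(hemi[area_list])) == 1) unique(hemi[area_list])
           else "B"
  beta_table(out, hemisphere = c(unname(hemi[keep]), h_new))
}

#' Normalized task profiles across the MD system
#'
#' For each subject and contrast, z-scores the betas across the MD areas
#' (mean 0, sample SD 1), then averages the z-scores over subjects. The
#' between-task SD per area is the SD of each subject's three z-scores,
#' averaged over subjects. Preference weights per area are the nonnegative
#' part of the contrast-wise deviation of `zbar` from the area's mean,
#' scaled to sum 1 (areas without a positive deviation get equal weights).
#'
#' @param b A [beta_table()].
#' @param md_set MD area names (>= 3).
#' @return List with `zbar` (areas x contrasts), `sd_between_tasks`
#'   (per area) and `preference_weights` (areas x contrasts).
#' @export
task_profiles <- function(b, md_set) {
  stopifnot(inherits(b, "beta_table"))
  if (length(md_set) < 3) stop("md_set must contain at least 3 areas")
  contrasts <- dimnames(b)[[3]]
  z <- array(NA_real_, dim = c(dim(b)[1], length(md_set), length(contrasts)),
             dimnames = list(dimnames(b)[[1]], md_set, contrasts))
  for (cn in contrasts) {
    X <- unclass(b)[, md_set, cn]
    mu <- rowMeans(X)
    sd_ <- apply(X, 1, stats::sd)
    bad <- which(sd_ == 0)
    if (length(bad) > 0)
      stop("zero across-area variance for subject(s) ",
           paste(dimnames(b)[[1]][bad], collapse = ", "),
           " in contrast ", cn)
    z[, , cn] <- (X - mu) / sd_
  }
  zbar <- apply(z, c(2, 3), mean)
  sd_between <- colMeans(apply(z, c(1, 2), stats::sd))
  dev <- zbar - rowMeans(zbar)
  w <- pmax(dev, 0)
  rs <- rowSums(w)
  w[rs == 0, ] <- 1 / length(contrasts)
  rs[rs == 0] <- 1
  w <- w / rs
  list(zbar = zbar, sd_between_tasks = sd_between, preference_weights = w)
}

#' Split-half replication of task profiles
#'
#' Correlates the group-mean activation profile (across the MD areas) of
#' each contrast in one half-cohort with each contrast in the other half.
#' High diagonal and lower off-diagonal correlations indicate stable,
#' contrast-specific profiles.
#'
#' @param b A [beta_table()].
#' @param md_set MD area names the profiles run across.
#' @param split List with subject index vectors `g1`, `g2` (see
#'   [split_half()]).
#' @return 3 x 3 matrix of Pearson correlations; rows = group-1 contrasts,
#'   columns = group-2 contrasts.
#' @export
split_half_profile_correlation <- function(b, md_set, split) {
  stopifnot(inherits(b, "beta_table"))
  if (length(split$g1) == 0 || length(split$g2) == 0)
    stop("both split groups must be nonempty")
  if (length(intersect(split$g1, split$g2)) > 0)
    stop("split groups must be disjoint")
  contrasts <- dimnames(b)[[3]]
  prof <- function(g) {
    sapply(contrasts, function(cn) colMeans(unclass(b)[g, md_set, cn]))
  }
  p1 <- prof(split$g1)
  p2 <- prof(split$g2)
  if (any(apply(p1, 2, stats::sd) == 0) || any(apply(p2, 2, stats::sd) == 0))
    stop("constant profile: correlation undefined")
  r <- stats::cor(p1, p2)
  dimnames(r) <- list(group1 = contrasts, group2 = contrasts)
  r
}
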