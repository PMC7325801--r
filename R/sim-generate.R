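#' Generate the task-contrast beta table of a synthetic cohort
#'
#' Draws `beta[s, a, c] = effect_table[a, c] + u_s + e_{s,a,c}` with a
#' per-subject global offset `u_s ~ N(0, sigma_subject^2)` shared across all
#' areas and contrasts (a global responder effect; it cancels in the paired
#' core-classification statistic) and independent residuals
#' `e ~ N(0, sigma_noise^2)`. Deterministic given the config's seed.
#'
#' @param config An [md_sim_config()] object.
#' @return A [beta_table()] of dimension subjects x 360 parcels x contrasts.
#' @export
generate_task_betas <- function(config) {
  stopifnot(inherits(config, "md_sim_config"))
  seeds <- derive_seeds(config$seed, 6)
  set.seed(seeds[1])
  S <- config$n_subjects
  A <- nrow(config$effect_table)
  C <- length(config$contrasts)
  u <- rnorm(S, 0, config$sigma_subject)
  e <- array(rnorm(S * A * C, 0, config$sigma_noise), dim = c(S, A, C))
  beta <- array(rep(config$effect_table, each = S), dim = c(S, A, C)) + u + e
  dimnames(beta) <- list(sprintf("sub%03d", seq_len(S)),
                         rownames(config$effect_table),
                         config$contrasts)
  beta_table(beta, hemisphere = config$atlas$hemisphere)
}

#' Generate one subject's resting-state time series
#'
#' Factor model `x_a(t) = sum_k lambda_{a,k} f_k(t) + eps_a(t)` with
#' unit-variance independent Gaussian factors and parcel noise of SD
#' `rest_noise_sd`. Optionally also returns subcortical voxel series that
#' load on the core factor (planted voxels only), sharing the same factor
#' draws so that voxel-to-core connectivity is genuinely present in the
#' data. Each subject has its own deterministic stream derived from the
#' config seed, so subjects can be generated independently in any order.
#'
#' @param config An [md_sim_config()] object.
#' @param subject Subject index (1-based).
#' @param include_subcortex If `TRUE`, also generate voxel time series.
#' @return A timepoints x parcels matrix, or if `include_subcortex` a list
#'   with elements `parcel` and `voxel`.
#' @export
generate_rest_timeseries <- function(config, subject = 1L,
                                     include_subcortex = FALSE) {
  stopifnot(inherits(config, "md_sim_config"))
  if (subject < 1 || subject > config$n_subjects)
    stop("subject index out of range")
  lam <- config$fc_loadings
  K <- ncol(lam)
  seeds <- derive_seeds(config$seed, 6)
  subj_seeds <- derive_seeds(seeds[2], config$n_subjects)
  set.seed(subj_seeds[subject])
  T_ <- config$n_timepoints
  f <- matrix(rnorm(T_ * K), T_, K)
  x <- f %*% t(lam) +
    matrix(rnorm(T_ * nrow(lam), 0, config$rest_noise_sd), T_, nrow(lam))
  colnames(x) <- rownames(lam)
  if (!include_subcortex) return(x)
  info <- config$subcortex$info
  vload <- ifelse(info$planted, config$subcortex$loading, 0)
  v <- f[, 1, drop = FALSE] %*% t(vload) +
    matrix(rnorm(T_ * nrow(info), 0, config$rest_noise_sd), T_, nrow(info))
  colnames(v) <- info$voxel
  list(parcel = x, voxel = v)
}

#' Generate segment-level betas across the SCEF/8BM border
#'
#' Twenty ordered segments (posterior to anterior: SCEF 1-10 then 8BM
#' 11-20) with the planted ramp/plateau profile of
#' [default_segment_profile()] and the same subject-offset + residual noise
#' model as [generate_task_betas()].
#'
#' @param config An [md_sim_config()] object.
#' @return A `segment_beta_table`: subjects x 20 segments x contrasts array
#'   with attributes `segment_area` (10x `"SCEF"`, 10x `"8BM"`) and
#'   `border_after` (= 10).
#' @export
generate_segment_betas <- function(config) {
  stopifnot(inherits(config, "md_sim_config"))
  seeds <- derive_seeds(config$seed, 6)
  set.seed(seeds[3])
  S <- config$n_subjects
  prof <- config$segment_profile
  C <- ncol(prof)
  u <- rnorm(S, 0, config$sigma_subject)
  e <- array(rnorm(S * 20 * C, 0, config$sigma_noise), dim = c(S, 20, C))
  beta <- array(rep(prof, each = S), dim = c(S, 20, C)) + u + e
  dimnames(beta) <- list(sprintf("sub%03d", seq_len(S)),
                         rownames(prof), config$contrasts)
  segment_beta_table(beta)
}

#' Generate subcortical voxel task betas
#'
#' Voxels carry one of the 19 structure labels. Planted MD voxels (caudate
#' head and lateral cerebellum analogues) have a positive effect in all
#' three contrasts; all other voxels are null. Noise model as in
#' [generate_task_betas()].
#'
#' @param config An [md_sim_config()] object.
#' @return A `voxel_table`: list with `info` (voxel, structure, planted)
#'   and `beta` (subjects x voxels x contrasts array).
#' @export
generate_subcortical <- function(config) {
  stopifnot(inherits(config, "md_sim_config"))
  seeds <- derive_seeds(config$seed, 6)
  set.seed(seeds[4])
  info <- config$subcortex$info
  S <- config$n_subjects
  V <- nrow(info)
  C <- length(config$contrasts)
  eff <- matrix(0, V, C)
  eff[info$planted, ] <- config$subcortex$effect
  u <- rnorm(S, 0, config$sigma_subject)
  e <- array(rnorm(S * V * C, 0, config$sigma_noise), dim = c(S, V, C))
  beta <- array(rep(eff, each = S), dim = c(S, V, C)) + u + e
  dimnames(beta) <- list(sprintf("sub%03d", seq_len(S)),
                         info$voxel, config$contrasts)
  voxel_table(info = info, beta = beta)
}

#' Split subjects into two disjoint half-cohorts
#'
#' Plain random half-split used for split-half replication analyses.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed for the split.
#' @return List with integer index vectors `g1` and `g2`.
#' @export
split_half <- function(n_subjects, seed = 1L) {
  s <- derive_seeds(seed, 6)
  set.seed(s[5])
  g1 <- sort(sample.int(n_subjects, floor(n_subjects / 2)))
  list(g1 = g1, g2 = setdiff(seq_len(n_subjects), g1))
}
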