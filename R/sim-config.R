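#' @keywords internal
md_contrasts <- function() c("WM2bk_gt_0bk", "Relational_H_gt_E", "Math_gt_Story")

#' Default planted effect table
#'
#' Population mean beta (in units of the residual noise SD) for every parcel
#' and contrast. Core MD areas get 0.8 in all three contrasts, except the
#' three partial-core areas which get 0.8 in their two preferred contrasts
#' and 0.4 in the third (IFJp prefers relational reasoning and math; 8C and
#' PFm prefer working memory and relational reasoning). Penumbra areas get
#' 0.4 in all three contrasts. A handful of non-MD areas get 0.5 in one or
#' two contrasts only, so they activate strongly yet fail the three-contrast
#' conjunction; all other parcels are 0 throughout.
#'
#' @param atlas Atlas data.frame as returned by [md_atlas()].
#' @param planted If `FALSE`, return an all-zero table (a null cohort).
#' @return Numeric matrix, parcels x contrasts, rownames = `atlas$parcel`.
#' @export
default_effect_table <- function(atlas = md_atlas(), planted = TRUE) {
  contrasts <- md_contrasts()
  eff <- matrix(0, nrow(atlas), length(contrasts),
                dimnames = list(atlas$parcel, contrasts))
  if (!planted) return(eff)
  eff[atlas$md_class == "core_full", ] <- 0.8
  eff[atlas$md_class == "penumbra", ] <- 0.4
  # partial-core preferences
  eff[atlas$area == "IFJp", ] <- rep(c(0.4, 0.8, 0.8), each = 2)
  eff[atlas$area == "8C", ] <- rep(c(0.8, 0.8, 0.4), each = 2)
  eff[atlas$area == "PFm", ] <- rep(c(0.8, 0.8, 0.4), each = 2)
  # task-specific non-MD areas: zero in at least one contrast
  eff[atlas$area == "FEF", 1] <- 0.5
  eff[atlas$area == "9-46d", 1] <- 0.5
  eff[atlas$area == "55b", 1] <- 0.5
  eff[atlas$area == "PEF", 2] <- 0.5
  eff[atlas$area == "IFJa", 2] <- 0.5
  eff[atlas$area == "LIPv", c(1, 2)] <- 0.5
  eff[atlas$area == "7Pm", 3] <- 0.5
  eff[atlas$area == "44", 3] <- 0.5
  eff
}

#' Default factor loadings for the resting-state model
#'
#' Four latent factors generate the tiered connectivity structure: a core
#' factor, a penumbra factor, and two background network factors. Core
#' parcels load 1.0 on the core factor; penumbra parcels load 0.5 on the
#' core factor and 0.3 on the penumbra factor; non-MD parcels load 0.5 on
#' one of the two background factors (split by parcel index). With
#' unit-variance factors and noise the implied population correlations are
#' core-core 0.500 > core-penumbra 0.305 > penumbra-penumbra 0.254 >
#' within-background 0.200 > between-group ~0.
#'
#' @param atlas Atlas data.frame.
#' @return Numeric matrix, parcels x 4 factors.
#' @export
default_fc_loadings <- function(atlas = md_atlas()) {
  lam <- matrix(0, nrow(atlas), 4,
                dimnames = list(atlas$parcel,
                                c("core", "penumbra", "bg1", "bg2")))
  core <- atlas$md_class %in% c("core_full", "core_partial")
  pen <- atlas$md_class == "penumbra"
  bg <- atlas$md_class == "background"
  lam[core, "core"] <- 1.0
  lam[pen, "core"] <- 0.5
  lam[pen, "penumbra"] <- 0.3
  bg_idx <- which(bg)
  half <- bg_idx[seq_along(bg_idx) %% 2L == 1L]
  lam[half, "bg1"] <- 0.5
  lam[setdiff(bg_idx, half), "bg2"] <- 0.5
  lam
}

#' Default planted activation profile across the SCEF/8BM border
#'
#' Twenty segments ordered posterior to anterior: SCEF segments 1-10 then
#' 8BM segments 11-20. The profile is zero over posterior SCEF, ramps up
#' over the two anterior SCEF segments (0.4, 0.8), peaks at the first 8BM
#' segment at the border (1.0) and is sustained at 0.8 through the rest of
#' 8BM; the same profile applies to all three contrasts.
#'
#' @return Numeric matrix, 20 segments x 3 contrasts.
#' @export
default_segment_profile <- function() {
  prof <- c(rep(0, 8), 0.4, 0.8, 1.0, rep(0.8, 9))
  out <- matrix(prof, 20, 3,
                dimnames = list(segment_labels(), md_contrasts()))
  out
}

#' @keywords internal
segment_labels <- function() {
  c(paste0("SCEF_", 1:10), paste0("8BM_", 1:10))
}

#' Default subcortical voxel layout
#'
#' Thirty voxels for each of the 19 structures. MD membership is planted in
#' the head of the caudate (10 voxels per side) and in lateral cerebellum
#' (crus-like territory, 10 voxels per side): these voxels carry a positive
#' task effect (0.5 noise-SD units) in all three contrasts and load 0.6 on
#' the core resting-state factor; all remaining voxels are null.
#'
#' @param n_voxels_per_structure Voxels simulated per structure.
#' @param n_planted Planted MD voxels in each of L/R caudate and cerebellum.
#' @param effect Task effect of planted voxels (all three contrasts).
#' @param loading Core-factor loading of planted voxels' time series.
#' @return A list with a voxel `info` data.frame (`voxel`, `structure`,
#'   `planted`), `effect`, and `loading`.
#' @export
default_subcortex_config <- function(n_voxels_per_structure = 30L,
                                     n_planted = 10L,
                                     effect = 0.5,
                                     loading = 0.6) {
  stopifnot(n_planted <= n_voxels_per_structure)
  structures <- md_structures()
  info <- data.frame(
    voxel = unlist(lapply(structures, function(s)
      sprintf("%s_v%02d", s, seq_len(n_voxels_per_structure)))),
    structure = rep(structures, each = n_voxels_per_structure),
    stringsAsFactors = FALSE)
  planted_str <- c("L_Caudate", "R_Caudate", "L_Cerebellum", "R_Cerebellum")
  info$planted <- info$structure %in% planted_str &
    ave(seq_len(nrow(info)), info$structure, FUN = seq_along) <= n_planted
  list(info = info, effect = effect, loading = loading)
}

#' Configuration of the synthetic MD cohort generator
#'
#' Bundles everything the generators need: cohort size, the planted effect
#' table, noise parameters, the resting-state factor loadings, the
#' areal-border segment profile, the subcortical layout and the seed. The
#' defaults reproduce the statistical structure the downstream analysis
#' assumes: per-subject per-parcel Gaussian task betas with a shared
#' between-subject offset, factor-model rest time series with tiered
#' connectivity, a ramp across the SCEF/8BM border, and subcortical voxels
#' coupled to the cortical core.
#'
#' @param n_subjects Number of subjects (default 449).
#' @param atlas Parcel atlas, see [md_atlas()].
#' @param contrasts Contrast labels (3 by default).
#' @param effect_table Parcels x contrasts matrix of population mean betas.
#' @param sigma_subject SD of the per-subject global additive offset.
#' @param sigma_noise Residual SD per parcel x contrast observation.
#' @param n_timepoints Rest time series length per subject.
#' @param fc_loadings Parcels x K factor-loading matrix.
#' @param rest_noise_sd SD of the parcel-level rest noise (default 1).
#' @param segment_profile 20 x 3 planted segment mean matrix.
#' @param subcortex Subcortical layout from [default_subcortex_config()].
#' @param seed Integer seed; all generators derive their streams from it.
#' @return An object of class `md_sim_config`.
#' @export
#' @examples
#' cfg <- md_sim_config(n_subjects = 20, seed = 7)
#' b <- generate_task_betas(cfg)
#' dim(b)
md_sim_config <- function(n_subjects = 449L,
                          atlas = md_atlas(),
                          contrasts = md_contrasts(),
                          effect_table = default_effect_table(atlas),
                          sigma_subject = 0.25,
                          sigma_noise = 1,
                          n_timepoints = 1200L,
                          fc_loadings = default_fc_loadings(atlas),
                          rest_noise_sd = 1,
                          segment_profile = default_segment_profile(),
                          subcortex = default_subcortex_config(),
                          seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be at least 2")
  if (sigma_subject < 0 || sigma_noise < 0 || rest_noise_sd < 0)
    stop("noise SDs must be nonnegative")
  if (!is.matrix(effect_table) ||
      nrow(effect_table) != nrow(atlas) ||
      ncol(effect_table) != length(contrasts))
    stop("effect_table must be a ", nrow(atlas), " x ", length(contrasts),
         " matrix (one row per parcel per hemisphere, one column per contrast)")
  if (is.null(rownames(effect_table)))
    rownames(effect_table) <- atlas$parcel
  if (!identical(rownames(effect_table), atlas$parcel))
    stop("effect_table rows must match atlas parcels")
  colnames(effect_table) <- contrasts
  if (!is.matrix(fc_loadings) || nrow(fc_loadings) != nrow(atlas))
    stop("fc_loadings must have one row per parcel")
  if (!is.matrix(segment_profile) || nrow(segment_profile) != 20L ||
      ncol(segment_profile) != length(contrasts))
    stop("segment_profile must be a 20 x ", length(contrasts), " matrix")
  if (n_timepoints < 3) stop("n_timepoints must be at least 3")
  if (n_timepoints < 2L * nrow(atlas))
    warning("n_timepoints below twice the parcel count; ",
            "subject FC estimates will be noisy")
  structure(
    list(n_subjects = as.integer(n_subjects),
         atlas = atlas,
         contrasts = contrasts,
         effect_table = effect_table,
         sigma_subject = sigma_subject,
         sigma_noise = sigma_noise,
         n_timepoints = as.integer(n_timepoints),
         fc_loadings = fc_loadings,
         rest_noise_sd = rest_noise_sd,
         segment_profile = segment_profile,
         subcortex = subcortex,
         seed = as.integer(seed)),
    class = "md_sim_config")
}

#' @export
print.md_sim_config <- function(x, ...) {
  cat("Synthetic MD cohort configuration\n")
  cat("  subjects:          ", x$n_subjects, "\n")
  cat("  parcels:           ", nrow(x$atlas), " (",
      nrow(x$atlas) / 2, " per hemisphere)\n", sep = "")
  cat("  contrasts:         ", paste(x$contrasts, collapse = ", "), "\n")
  cat("  sigma_subject:     ", x$sigma_subject, "\n")
  cat("  sigma_noise:       ", x$sigma_noise, "\n")
  cat("  rest timepoints:   ", x$n_timepoints, "\n")
  cat("  latent FC factors: ", ncol(x$fc_loadings), "\n")
  cat("  subcortical voxels:", nrow(x$subcortex$info), "\n")
  cat("  seed:              ", x$seed, "\n")
  invisible(x)
}

#' Planted ground truth of a generator configuration
#'
#' Recovers the membership sets implied by the configuration's effect table,
#' segment profile and subcortical layout: the extended MD set (positive
#' mean in all contrasts), the full/partial core split, the per-segment
#' positive flags, and the planted MD voxels per structure.
#'
#' @param config An [md_sim_config()] object.
#' @return List with `extended_set`, `core_set`, `core_full_set`,
#'   `core_partial_set`, `penumbra_set` (hemisphere-free area names),
#'   `segment_truth` (20 x contrasts logical matrix) and `md_voxel_set`
#'   (list of voxel ids per structure).
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "md_sim_config"))
  atlas <- config$atlas
  left <- atlas$hemisphere == "L"
  eff <- config$effect_table[left, , drop = FALSE]
  areas <- atlas$area[left]
  extended <- areas[apply(eff > 0, 1, all)]
  # core truth: above the extended-set population mean per contrast
  ext_idx <- match(extended, areas)
  mean_ext <- colMeans(eff[ext_idx, , drop = FALSE])
  above <- sweep(eff[ext_idx, , drop = FALSE], 2, mean_ext, ">")
  n_above <- rowSums(above)
  core_full <- extended[n_above == ncol(eff)]
  core_partial <- extended[n_above == ncol(eff) - 1L & n_above > 0]
  seg_truth <- config$segment_profile > 0
  vox <- split(config$subcortex$info$voxel[config$subcortex$info$planted],
               config$subcortex$info$structure[config$subcortex$info$planted])
  list(extended_set = extended,
       core_set = c(core_full, core_partial),
       core_full_set = core_full,
       core_partial_set = core_partial,
       penumbra_set = setdiff(extended, c(core_full, core_partial)),
       segment_truth = seg_truth,
       md_voxel_set = vox)
}

# Derive independent seed streams from one user seed without consuming the
# caller's RNG state.
#' @keywords internal
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
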