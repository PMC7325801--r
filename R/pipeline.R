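#' Run the full MD delineation pipeline on a synthetic cohort
#'
#' Orchestrates the stages in analysis order: task betas -> hemisphere
#' averaging -> per-contrast Bonferroni t-tests -> three-contrast
#' conjunction (extended MD) -> above-set-mean core classification ->
#' SCEF/8BM segment analysis and composite area -> parcellated FC,
#' connection-group statistics, network cross-tabulation and MDS ->
#' subcortical task conjunction, voxel-to-core permutation map and
#' split-half replication metrics.
#'
#' The task-side stages run at the configured cohort size. The FC stages
#' run on the first `n_fc_subjects` subjects: the connection-group and
#' MDS quantities are group-level and stabilize quickly, so a moderate
#' cohort keeps the pipeline fast without changing any definition.
#'
#' @param config An [md_sim_config()] object.
#' @param alpha Significance level used throughout (default 0.05).
#' @param m_areas Bonferroni count for per-area tests (default 180).
#' @param m_comparisons Bonferroni count for connection-group paired tests
#'   (default 30).
#' @param n_struct Bonferroni count over subcortical structures (19).
#' @param n_fc_subjects Subjects used for the FC stages (default 24).
#' @param n_perm Permutations for the subcortical null (default 10000).
#' @param percentile Permutation-null percentile (default 97.5).
#' @param run_fc,run_subcortex Stage switches (both default `TRUE`).
#' @return A `md_report` list with per-stage outputs, provenance and
#'   built-in invariant checks.
#' @export
run_pipeline <- function(config,
                         alpha = 0.05,
                         m_areas = 180L,
                         m_comparisons = 30L,
                         n_struct = 19L,
                         n_fc_subjects = 24L,
                         n_perm = 10000L,
                         percentile = 97.5,
                         run_fc = TRUE,
                         run_subcortex = TRUE) {
  stopifnot(inherits(config, "md_sim_config"))
  stage <- "task betas"
  report <- list(provenance = list(
    package = "mdcore",
    version = as.character(utils::packageVersion("mdcore")),
    seed = config$seed,
    n_subjects = config$n_subjects,
    alpha = alpha,
    bonferroni = list(areas = m_areas, comparisons = m_comparisons,
                      structures = n_struct),
    n_perm = n_perm,
    percentile = percentile))
  tryCatch({
    b <- generate_task_betas(config)
    bh <- hemisphere_average(b)
    contrasts <- dimnames(bh)[[3]]

    stage <- "extended-MD conjunction"
    stats_list <- lapply(contrasts, function(cn)
      area_ttests(bh, cn, alpha = alpha, m = m_areas))
    names(stats_list) <- contrasts
    extended <- conjunction_extended_md(stats_list)

    stage <- "core classification"
    part <- if (length(extended) >= 2)
      core_classification(bh, extended, alpha = alpha)
    else  # nothing (or a singleton) survived the conjunction: no core test
      structure(list(extended_set = extended, core_set = character(0),
                     core_full_set = character(0),
                     core_partial_set = character(0),
                     penumbra_set = extended, stats = NULL),
                class = "md_partition")

    stage <- "segment analysis"
    seg <- generate_segment_betas(config)
    seg_test <- segment_conjunction_test(seg, alpha = alpha, m = m_areas)
    seg_prof <- segment_profile(seg)
    composite <- if (any(seg_test$significant))
      composite_area(seg, seg_test) else NULL

    report$extended_md <- list(n_areas = length(extended), areas = extended)
    report$core_md <- list(
      n_core = length(part$core_set),
      n_full = length(part$core_full_set),
      n_partial = length(part$core_partial_set),
      core_full = part$core_full_set,
      core_partial = part$core_partial_set,
      penumbra = part$penumbra_set)
    report$segments <- list(
      significant = seg_test$segment[seg_test$significant],
      n_significant_scef =
        sum(seg_test$significant & seg_test$area == "SCEF"),
      n_significant_8bm =
        sum(seg_test$significant & seg_test$area == "8BM"),
      profile_argmax = rownames(seg_prof)[which.max(rowMeans(seg_prof))])

    atlas <- config$atlas
    # recovered parcel-level partition (both hemisphere parcels per area)
    cls <- rep("nonMD", nrow(atlas))
    cls[atlas$area %in% part$penumbra_set] <- "penumbra"
    cls[atlas$area %in% part$core_set] <- "core"
    names(cls) <- atlas$parcel

    fc_group <- NULL
    if (run_fc) {
      stage <- "functional connectivity"
      n_fc <- min(n_fc_subjects, config$n_subjects)
      fc_list <- vector("list", n_fc)
      zsum_vox <- NULL
      for (s in seq_len(n_fc)) {
        ts <- generate_rest_timeseries(config, s,
                                       include_subcortex = run_subcortex)
        if (run_subcortex) {
          fc_list[[s]] <- parcel_fc(ts$parcel)
          zv <- voxel_parcel_z(ts$voxel, ts$parcel)
          zsum_vox <- if (is.null(zsum_vox)) zv else zsum_vox + zv
        } else fc_list[[s]] <- parcel_fc(ts)
      }
      fc_group <- group_average_fc(fc_list)
      cg <- connection_group_stats(fc_list, cls, alpha = alpha,
                                   m = m_comparisons)
      networks <- atlas$network
      names(networks) <- atlas$parcel
      xtab <- network_crosstab(cls, networks)

      stage <- "multidimensional scaling"
      ext_parcels <- atlas$parcel[atlas$hemisphere == "L" &
                                    atlas$area %in% extended]
      mds <- if (length(ext_parcels) >= 3)
        classical_mds(fc_distance(fc_group, ext_parcels), k = 2) else NULL

      report$fc <- list(
        n_subjects = n_fc,
        matrix_dim = dim(fc_group),
        n_groups = length(connection_groups()),
        n_comparisons = nrow(cg$tests),
        group_mean_z = apply(cg$group_means, c(2, 3), mean),
        tests = cg$tests)
      report$networks <- list(
        crosstab = as.data.frame.matrix(xtab),
        core_networks =
          names(which(xtab[, "core"] > 0)))
      if (!is.null(mds))
        report$mds <- list(
          eigenvalues = mds$eigenvalues[seq_len(min(5,
            length(mds$eigenvalues)))],
          n_negative = mds$n_negative,
          coordinates = mds$coordinates)
    }

    if (run_subcortex) {
      stage <- "subcortical analysis"
      vox <- generate_subcortical(config)
      conj <- structure_task_conjunction(vox, alpha = alpha,
                                         n_struct = n_struct)
      # split-half replication of the task maps
      halves <- split_half(config$n_subjects, seed = config$seed)
      half_map <- function(g) {
        vh <- voxel_table(vox$info, vox$beta[g, , , drop = FALSE])
        ch <- structure_task_conjunction(vh, alpha = alpha,
                                         n_struct = n_struct)
        data.frame(voxel = ch$voxel,
                   score = apply(vox$beta[g, , , drop = FALSE], 2, mean),
                   significant = ch$significant)
      }
      mA <- half_map(halves$g1)
      mB <- half_map(halves$g2)
      repl <- replication_metrics(mA, mB, structure = "L_Caudate",
                                  structures = vox$info$structure)

      perm <- NULL
      if (run_fc && !is.null(zsum_vox) && length(part$core_set) > 0) {
        stage <- "permutation null"
        zbar <- zsum_vox / min(n_fc_subjects, config$n_subjects)
        core_parcels <- atlas$parcel[atlas$area %in% part$core_set]
        perm <- permutation_null(zbar, core_parcels, n_perm = n_perm,
                                 percentile = percentile,
                                 seed = config$seed)
      }

      report$subcortex <- list(
        n_significant_task = sum(conj$significant),
        significant_structures =
          unique(conj$structure[conj$significant]),
        replication_caudate = repl,
        n_significant_fc = if (!is.null(perm)) sum(perm$significant)
                           else NA_integer_)
      if (!is.null(perm)) report$subcortex$fc_map_significant <-
          perm$voxel[perm$significant]
    }

    stage <- "invariant checks"
    checks <- list(
      core_subset_of_extended =
        all(part$core_set %in% part$extended_set),
      core_split_disjoint =
        length(intersect(part$core_full_set, part$core_partial_set)) == 0,
      penumbra_is_remainder =
        setequal(part$penumbra_set,
                 setdiff(part$extended_set, part$core_set)),
      conjunction_within_each_contrast =
        all(vapply(stats_list, function(s)
          all(extended %in% s$area[s$significant_positive]), TRUE)))
    report$checks <- checks
    report$passed <- all(unlist(checks))
    class(report) <- "md_report"
    report
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' @export
print.md_report <- function(x, ...) {
  cat("MD pipeline report (seed ", x$provenance$seed, ")\n", sep = "")
  cat("  extended MD areas: ", x$extended_md$n_areas, "\n")
  cat("  core MD areas:     ", x$core_md$n_core, " (",
      x$core_md$n_full, " full + ", x$core_md$n_partial, " partial)\n",
      sep = "")
  if (!is.null(x$segments))
    cat("  significant SCEF segments:", x$segments$n_significant_scef, "\n")
  if (!is.null(x$fc))
    cat("  FC matrix: ", paste(x$fc$matrix_dim, collapse = " x "),
        ", ", x$fc$n_comparisons, " paired comparisons\n", sep = "")
  if (!is.null(x$subcortex))
    cat("  subcortical MD voxels (task):", x$subcortex$n_significant_task,
        "\n")
  cat("  invariant checks:", if (isTRUE(x$passed)) "pass" else "FAIL", "\n")
  invisible(x)
}
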