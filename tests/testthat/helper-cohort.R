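# Shared fixtures, built once per test run.

# A small beta_table with explicit values, both hemispheres.
toy_beta_table <- function(n_subjects = 4, areas = c("A", "B"), seed = 42) {
  set.seed(seed)
  parcels <- c(paste0("L_", areas), paste0("R_", areas))
  arr <- array(rnorm(n_subjects * length(parcels) * 3),
               dim = c(n_subjects, length(parcels), 3),
               dimnames = list(sprintf("sub%02d", seq_len(n_subjects)),
                               parcels,
                               c("c1", "c2", "c3")))
  beta_table(arr)
}

# Single-hemisphere table from an explicit subjects x areas matrix,
# replicated over `n_contrasts` contrasts.
mat_beta_table <- function(X, n_contrasts = 1) {
  arr <- array(rep(X, n_contrasts),
               dim = c(nrow(X), ncol(X), n_contrasts),
               dimnames = list(rownames(X) %||% paste0("s", seq_len(nrow(X))),
                               colnames(X) %||% paste0("a", seq_len(ncol(X))),
                               paste0("c", seq_len(n_contrasts))))
  beta_table(arr, hemisphere = rep("B", ncol(X)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reduced resting-state cohort shared by FC tests: tiered loadings, a few
# subjects, shorter series. Cached so the generation cost is paid once.
.fc_cache <- new.env(parent = emptyenv())
fc_cohort <- function() {
  if (!is.null(.fc_cache$cohort)) return(.fc_cache$cohort)
  cfg <- suppressWarnings(
    md_sim_config(n_subjects = 6, n_timepoints = 500, seed = 11))
  fc_list <- list()
  zsum <- NULL
  for (s in 1:6) {
    ts <- generate_rest_timeseries(cfg, s, include_subcortex = TRUE)
    fc_list[[s]] <- parcel_fc(ts$parcel)
    zv <- voxel_parcel_z(ts$voxel, ts$parcel)
    zsum <- if (is.null(zsum)) zv else zsum + zv
  }
  .fc_cache$cohort <- list(config = cfg, fc_list = fc_list,
                           zbar = zsum / 6)
  .fc_cache$cohort
}

# Full-size default task cohort (cheap to generate), cached.
task_cohort <- function(seed = 1) {
  key <- paste0("task", seed)
  if (!is.null(.fc_cache[[key]])) return(.fc_cache[[key]])
  cfg <- md_sim_config(seed = seed)
  .fc_cache[[key]] <- list(config = cfg,
                           betas = generate_task_betas(cfg),
                           truth = ground_truth(cfg))
  .fc_cache[[key]]
}

# Run conjunction + core classification on a beta table.
recover_partition <- function(bh, alpha = 0.05, m = 180) {
  stats_list <- lapply(dimnames(bh)[[3]], function(cn)
    area_ttests(bh, cn, alpha = alpha, m = m))
  ext <- conjunction_extended_md(stats_list)
  if (length(ext) < 2) return(list(extended_set = ext))
  core_classification(bh, ext, alpha = alpha)
}
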