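# Parcel-level statistics: hemisphere averaging, one-sample tests, the
# conjunction, core classification, merging, and task profiles.

test_that("hemisphere averaging is the arithmetic mean of paired parcels", {
  arr <- array(0, dim = c(2, 4, 1),
               dimnames = list(c("s1", "s2"),
                               c("L_A", "L_B", "R_A", "R_B"), "c1"))
  arr[, "L_A", 1] <- 1; arr[, "R_A", 1] <- 2
  arr[, "L_B", 1] <- 5; arr[, "R_B", 1] <- 5
  b <- beta_table(arr)
  h <- hemisphere_average(b)
  expect_equal(unname(unclass(h)[, "A", 1]), c(1.5, 1.5))
  expect_equal(unname(unclass(h)[, "B", 1]), c(5, 5))

  # linearity: subject-mean commutes with hemisphere averaging
  tb <- toy_beta_table(n_subjects = 7)
  h2 <- hemisphere_average(tb)
  m_then_avg <- (apply(unclass(tb)[, 1:2, , drop = FALSE], c(2, 3), mean) +
                   apply(unclass(tb)[, 3:4, , drop = FALSE], c(2, 3), mean)) / 2
  avg_then_m <- apply(unclass(h2), c(2, 3), mean)
  expect_equal(unname(avg_then_m), unname(m_then_avg), tolerance = 1e-12)

  # unpaired area raises a named error
  arr2 <- arr[, c("L_A", "L_B", "R_A"), , drop = FALSE]
  expect_error(hemisphere_average(beta_table(arr2)), "B")
})

test_that("area t-tests match the closed form and gate on positive means", {
  b <- mat_beta_table(matrix(c(0.5, 1.5, 1.0, 1.0), 4, 1,
                             dimnames = list(NULL, "A")))
  st <- area_ttests(b, "c1", m = 1)
  expect_equal(st$t, 4.898979, tolerance = 1e-6)
  expect_equal(st$df, 3)
  expect_equal(st$p, 0.0162766, tolerance = 1e-5)

  # zero betas: t = 0, not significant
  b0 <- mat_beta_table(matrix(0, 4, 1))
  st0 <- area_ttests(b0, "c1", m = 1)
  expect_equal(st0$t, 0)
  expect_false(st0$significant_positive)
  expect_true(st0$degenerate)

  # negative mean: never significant-positive regardless of p
  bn <- mat_beta_table(matrix(c(-1, -2, -1.5, -1.5), 4, 1))
  stn <- area_ttests(bn, "c1", m = 1)
  expect_lt(stn$p, 0.05)
  expect_false(stn$significant_positive)

  # brute-force oracle: t.test on each area of a random table
  tb <- toy_beta_table(n_subjects = 9)
  st2 <- area_ttests(tb, "c2", m = 180)
  for (i in seq_along(st2$area)) {
    ref <- t.test(unclass(tb)[, st2$area[i], "c2"])
    expect_equal(st2$t[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(st2$p[i], ref$p.value, tolerance = 1e-10)
  }
})

test_that("conjunction equals the intersection of significant sets", {
  set.seed(31)
  areas <- paste0("a", 1:30)
  stats_list <- lapply(1:3, function(i) {
    data.frame(area = areas,
               significant_positive = runif(30) < 0.4)
  })
  ext <- conjunction_extended_md(stats_list)
  oracle <- Reduce(intersect, lapply(stats_list, function(s)
    s$area[s$significant_positive]))
  expect_setequal(ext, oracle)
  # subset of every per-contrast set
  for (s in stats_list)
    expect_true(all(ext %in% s$area[s$significant_positive]))
  # mismatched universes rejected
  bad <- stats_list
  bad[[2]]$area[1] <- "other"
  expect_error(conjunction_extended_md(bad), "universe")
})

test_that("Bonferroni conjunction is monotone in alpha", {
  cohort <- task_cohort(seed = 1)
  bh <- hemisphere_average(cohort$betas)
  ext_small <- conjunction_extended_md(lapply(dimnames(bh)[[3]], function(cn)
    area_ttests(bh, cn, alpha = 0.001)))
  ext_large <- conjunction_extended_md(lapply(dimnames(bh)[[3]], function(cn)
    area_ttests(bh, cn, alpha = 0.05)))
  expect_true(all(ext_small %in% ext_large))
})

test_that("core classification matches the hand-worked example", {
  X <- matrix(c(2, 2.1, 1.9,
                1, 1, 1,
                0, -0.1, 0.1), 3, 3,
              dimnames = list(paste0("s", 1:3), c("A", "B", "C")))
  b <- mat_beta_table(X)
  part <- core_classification(b, c("A", "B", "C"))
  stA <- part$stats[part$stats$area == "A", ]
  expect_equal(stA$mean_diff, 1.0, tolerance = 1e-12)
  expect_equal(stA$t, 17.32051, tolerance = 1e-5)
  expect_true(stA$significant_above)
  stB <- part$stats[part$stats$area == "B", ]
  expect_equal(stB$t, 0)
  stC <- part$stats[part$stats$area == "C", ]
  expect_lt(stC$mean_diff, 0)
  expect_equal(part$core_full_set, "A")
  expect_setequal(part$penumbra_set, c("B", "C"))
})

test_that("core classification ignores per-subject global offsets", {
  tb <- toy_beta_table(n_subjects = 8, areas = c("A", "B", "C"))
  h <- hemisphere_average(tb)
  offs <- seq(-2, 5, length.out = 8)
  shifted <- unclass(h) + offs  # recycles over subjects (dim 1)
  h2 <- beta_table(shifted, hemisphere = attr(h, "hemisphere"))
  p1 <- core_classification(h, c("A", "B", "C"))
  p2 <- core_classification(h2, c("A", "B", "C"))
  expect_equal(p1$stats$t, p2$stats$t, tolerance = 1e-9)
  expect_identical(p1$core_full_set, p2$core_full_set)
})

test_that("all-equal areas yield an empty core", {
  X <- matrix(rep(c(1, 2, 3, 2.5), 3), 4, 3,
              dimnames = list(NULL, c("A", "B", "C")))
  part <- core_classification(mat_beta_table(X), c("A", "B", "C"))
  expect_length(part$core_set, 0)
  expect_setequal(part$penumbra_set, c("A", "B", "C"))
  expect_error(core_classification(mat_beta_table(X), "A"), "at least 2")
})

test_that("merge_areas takes weighted means and removes the members", {
  X <- matrix(c(1, 1, 3, 3, 7, 7), 2, 3,
              dimnames = list(NULL, c("A", "B", "C")))
  b <- mat_beta_table(X)
  m1 <- merge_areas(b, c("A", "B"), new_area = "AB")
  expect_equal(unname(unclass(m1)[, "AB", 1]), c(2, 2))
  expect_setequal(dimnames(m1)[[2]], c("C", "AB"))
  # single-area merge is the identity on values
  m2 <- merge_areas(b, "C", new_area = "Cm")
  expect_equal(unname(unclass(m2)[, "Cm", 1]), c(7, 7))
  # explicit weights
  X2 <- matrix(c(4, 4, 0, 0), 2, 2, dimnames = list(NULL, c("A", "B")))
  m3 <- merge_areas(mat_beta_table(X2), c("A", "B"), weights = c(0.75, 0.25))
  expect_equal(unname(unclass(m3)[, "merged", 1]), c(3, 3))
  expect_error(merge_areas(b, character(0)), "empty")
})

test_that("task profiles z-score per subject and conserve mean zero", {
  X <- matrix(c(1, 2, 3,
                1, 2, 3), 2, 3, byrow = TRUE,
              dimnames = list(NULL, c("A", "B", "C")))
  b <- mat_beta_table(X, n_contrasts = 3)
  tp <- task_profiles(b, c("A", "B", "C"))
  expect_equal(unname(tp$zbar[, 1]), c(-1, 0, 1))
  # identical z in all contrasts: between-task SD is zero
  expect_equal(unname(tp$sd_between_tasks), rep(0, 3))
  # zbar columns have mean zero across areas
  cohort <- task_cohort(seed = 1)
  bh <- hemisphere_average(cohort$betas)
  tp2 <- task_profiles(bh, cohort$truth$extended_set)
  expect_lt(max(abs(colMeans(tp2$zbar))), 1e-12)
  expect_true(all(tp2$preference_weights >= 0))
  expect_equal(unname(rowSums(tp2$preference_weights)), rep(1, 27))
  # degenerate subject flagged by name
  Xd <- matrix(c(1, 1, 1, 1, 2, 3), 2, 3, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  expect_error(task_profiles(mat_beta_table(Xd), c("A", "B", "C")), "s1")
})

test_that("split-half profile correlations behave at the limits", {
  X <- matrix(c(1, 2, 4,
                1, 2, 4,
                1, 2, 4,
                1, 2, 4), 4, 3, byrow = TRUE,
              dimnames = list(NULL, c("A", "B", "C")))
  b <- mat_beta_table(X, n_contrasts = 3)
  r <- split_half_profile_correlation(b, c("A", "B", "C"),
                                      list(g1 = 1:2, g2 = 3:4))
  expect_equal(unname(diag(r)), rep(1, 3))
  # negated second group
  Xn <- rbind(X[1:2, ], -X[3:4, ])
  colnames(Xn) <- colnames(X)
  bn <- mat_beta_table(Xn, n_contrasts = 3)
  rn <- split_half_profile_correlation(bn, c("A", "B", "C"),
                                       list(g1 = 1:2, g2 = 3:4))
  expect_equal(unname(diag(rn)), rep(-1, 3))
  expect_error(split_half_profile_correlation(b, c("A", "B", "C"),
                                              list(g1 = 1:2, g2 = 2:4)),
               "disjoint")
})

test_that("profile correlations are diagonally dominant on the cohort", {
  cohort <- task_cohort(seed = 1)
  bh <- hemisphere_average(cohort$betas)
  sp <- split_half(cohort$config$n_subjects, seed = 1)
  r <- split_half_profile_correlation(bh, cohort$truth$extended_set, sp)
  expect_gt(mean(diag(r)), mean(r[row(r) != col(r)]))
  expect_gt(min(diag(r)), 0.9)
})
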