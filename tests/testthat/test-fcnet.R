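# Parcellated FC, Fisher-z pooling, connection groups, MDS.

test_that("parcel_fc matches the covariance/SD oracle", {
  set.seed(7)
  ts <- matrix(rnorm(50 * 5), 50, 5,
               dimnames = list(NULL, paste0("P", 1:5)))
  r <- parcel_fc(ts)
  expect_equal(diag(r), setNames(rep(1, 5), paste0("P", 1:5)))
  for (i in 1:4) for (j in (i + 1):5) {
    num <- mean((ts[, i] - mean(ts[, i])) * (ts[, j] - mean(ts[, j])))
    oracle <- num / (sd(ts[, i]) * sd(ts[, j]) * (49 / 50))
    expect_equal(r[i, j], oracle, tolerance = 1e-12)
  }
  # anti-correlated signal
  ts2 <- cbind(a = ts[, 1], b = -ts[, 1], c = ts[, 2])
  r2 <- parcel_fc(ts2)
  expect_equal(r2["a", "b"], -1)
  # constant parcel named in the error
  ts3 <- cbind(ts, K = rep(1, 50))
  expect_error(parcel_fc(ts3), "K")
})

test_that("fisher transform matches closed form and round-trips", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  grid <- seq(-0.999, 0.999, by = 0.007)
  expect_lt(max(abs(fisher_z_inv(fisher_z(grid)) - grid)), 1e-12)
  expect_warning(z1 <- fisher_z(1), "clamped")
  expect_equal(z1, atanh(1 - 1e-7))
  expect_error(fisher_z(1, clamp = FALSE), "requires")
})

test_that("connection groups enumerate pairs correctly on a toy hemisphere", {
  parcels <- c("L_c1", "L_c2", "L_p1", "L_n1")
  partition <- setNames(c("core", "core", "penumbra", "nonMD"), parcels)
  set.seed(8)
  mk_fc <- function() {
    m <- matrix(runif(16, -0.3, 0.3), 4, 4,
                dimnames = list(parcels, parcels))
    m <- (m + t(m)) / 2; diag(m) <- 1; m
  }
  fc_list <- list(mk_fc(), mk_fc(), mk_fc())
  cg <- connection_group_stats(fc_list, partition)
  counts <- cg$pair_counts[, "L"]
  expect_equal(unname(counts[c("core-core", "core-penumbra",
                               "penumbra-penumbra", "core-nonMD",
                               "penumbra-nonMD", "nonMD-nonMD")]),
               c(1L, 2L, 0L, 2L, 1L, 0L))
  expect_setequal(cg$empty_groups,
                  c("penumbra-penumbra L", "nonMD-nonMD L"))
  # group means equal the z-mean oracle for a defined group
  z1 <- atanh(fc_list[[1]])
  expect_equal(cg$group_means[1, "core-penumbra", "L"],
               mean(z1[c("L_c1", "L_c2"), "L_p1"]), tolerance = 1e-12)
  # 15 group pairs in the single hemisphere
  expect_equal(nrow(cg$tests), 15L)
})

test_that("all-equal FC matrices give equal means and zero paired t", {
  parcels <- c("L_c1", "L_c2", "L_p1", "L_p2", "L_n1", "L_n2")
  partition <- setNames(rep(c("core", "penumbra", "nonMD"), each = 2),
                        parcels)
  m <- matrix(0.3, 6, 6, dimnames = list(parcels, parcels)); diag(m) <- 1
  cg <- connection_group_stats(list(m, m, m), partition)
  gm <- cg$group_means[1, , "L"]
  expect_true(all(abs(gm - atanh(0.3)) < 1e-12))
  expect_true(all(cg$tests$t == 0))
  expect_false(any(cg$tests$significant))
})

test_that("group means are invariant to parcel ordering", {
  co <- fc_cohort()
  atlas <- co$config$atlas
  partition <- fc_partition(atlas)
  cg1 <- connection_group_stats(co$fc_list[1:2], partition)
  set.seed(12)
  perm <- sample(atlas$parcel)
  fc_perm <- lapply(co$fc_list[1:2], function(fc) fc[perm, perm])
  cg2 <- connection_group_stats(fc_perm, partition)
  expect_equal(cg1$group_means, cg2$group_means, tolerance = 1e-12)
})

test_that("cohort connection groups show the planted ordering", {
  co <- fc_cohort()
  partition <- fc_partition(co$config$atlas)
  cg <- connection_group_stats(co$fc_list, partition)
  for (h in c("L", "R")) {
    gm <- colMeans(cg$group_means[, , h])
    expect_true(gm["core-core"] > gm["core-penumbra"])
    expect_true(gm["core-penumbra"] > gm["penumbra-penumbra"])
    expect_true(gm["penumbra-penumbra"] > gm["nonMD-nonMD"])
    expect_true(gm["nonMD-nonMD"] > max(gm["core-nonMD"],
                                        gm["penumbra-nonMD"]))
  }
  tt <- cg$tests
  cc_cp <- tt[tt$group1 == "core-core" & tt$group2 == "core-penumbra", ]
  expect_true(all(cc_cp$significant))
  expect_true(all(cc_cp$t > 0))
})

test_that("network crosstab counts the partition within each network", {
  atlas <- md_atlas()
  partition <- fc_partition(atlas)
  networks <- setNames(atlas$network, atlas$parcel)
  xt <- network_crosstab(partition, networks)
  # every core parcel is in the FPN
  expect_equal(sum(xt[, "core"]), 20L)
  expect_equal(unname(xt["FPN", "core"]), 20L)
  # counts sum to parcel totals per network
  expect_equal(as.integer(rowSums(xt)),
               as.integer(table(atlas$network)[rownames(xt)]))
  expect_error(network_crosstab(partition, networks[-1]), "without a network")
})

test_that("group-average FC pools in z-space", {
  p <- c("L_a", "L_b")
  m1 <- matrix(c(1, 0.6, 0.6, 1), 2, 2, dimnames = list(p, p))
  m2 <- matrix(c(1, -0.6, -0.6, 1), 2, 2, dimnames = list(p, p))
  g <- group_average_fc(list(m1, m2))
  expect_equal(g["L_a", "L_b"], 0)
  expect_equal(diag(g), setNames(c(1, 1), p))
  # single subject: identity
  expect_equal(group_average_fc(list(m1)), m1)
  # oracle on random matrices
  set.seed(9)
  ms <- lapply(1:3, function(i) {
    m <- matrix(runif(9, -0.5, 0.5), 3, 3)
    m <- (m + t(m)) / 2; diag(m) <- 1
    dimnames(m) <- list(paste0("P", 1:3), paste0("P", 1:3)); m
  })
  g2 <- group_average_fc(ms)
  oracle <- tanh((atanh(ms[[1]][1, 2]) + atanh(ms[[2]][1, 2]) +
                    atanh(ms[[3]][1, 2])) / 3)
  expect_equal(g2[1, 2], oracle, tolerance = 1e-12)
  expect_error(group_average_fc(list(m1, matrix(1, 3, 3))), "dimension")
})

test_that("classical MDS reproduces embeddable distances", {
  # two points at distance d: coordinates +- d/2 on one axis
  d2 <- matrix(c(0, 3, 3, 0), 2, 2)
  fit2 <- classical_mds(d2, k = 1)
  expect_equal(sort(fit2$coordinates[, 1]), c(-1.5, 1.5), tolerance = 1e-9)

  # equilateral triangle with unit sides
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  fit3 <- classical_mds(d3, k = 2)
  rec <- as.matrix(dist(fit3$coordinates))
  expect_equal(unname(rec), unname(d3), tolerance = 1e-9)

  # round-trip from points already in the plane
  set.seed(10)
  pts <- matrix(rnorm(14), 7, 2)
  dd <- as.matrix(dist(pts))
  fit <- classical_mds(dd, k = 2)
  expect_lt(max(abs(as.matrix(dist(fit$coordinates)) - dd)), 1e-8)

  # hand-rolled double-centering oracle gives the same embedding distances
  n <- nrow(dd)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (dd^2) %*% J
  eg <- eigen(B, symmetric = TRUE)
  oracle <- eg$vectors[, 1:2] %*% diag(sqrt(eg$values[1:2]))
  expect_lt(max(abs(as.matrix(dist(oracle)) - as.matrix(dist(fit$coordinates)))),
            1e-8)

  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("core areas cluster centrally in the MDS embedding", {
  co <- fc_cohort()
  atlas <- co$config$atlas
  g <- group_average_fc(co$fc_list)
  gt <- ground_truth(co$config)
  ext_parcels <- atlas$parcel[atlas$hemisphere == "L" &
                                atlas$area %in% gt$extended_set]
  fit <- suppressWarnings(classical_mds(fc_distance(g, ext_parcels), k = 2))
  coords <- fit$coordinates
  is_core <- rownames(coords) %in%
    atlas$parcel[atlas$area %in% gt$core_set]
  dmat <- as.matrix(dist(coords))
  core_core <- mean(dmat[is_core, is_core][upper.tri(diag(sum(is_core)))])
  core_pen <- mean(dmat[is_core, !is_core])
  expect_lt(core_core, core_pen)
})
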