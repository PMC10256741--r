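test_that("heritable trait covariance follows h2 times kinship", {
  # independence at h2 = 0
  ped0 <- make_pedigree(mz_pairs = 500)
  tr0 <- simulate_heritable_trait(ped0, h2 = 0, seed = 21)
  m0 <- matrix(tr0$score, ncol = 2, byrow = TRUE)
  expect_lt(abs(cor(m0[, 1], m0[, 2])), 0.1)

  # MZ ~ h2, DZ ~ h2/2 at h2 = 0.6
  ped <- make_pedigree(mz_pairs = 2000, dz_pairs = 2000)
  tr <- simulate_heritable_trait(ped, h2 = 0.6, seed = 22)
  is_mz <- ped$relation == "MZ_twin"
  mz <- matrix(tr$score[is_mz], ncol = 2, byrow = TRUE)
  dz <- matrix(tr$score[!is_mz], ncol = 2, byrow = TRUE)
  expect_lt(abs(cor(mz[, 1], mz[, 2]) - 0.6), 0.05)
  expect_lt(abs(cor(dz[, 1], dz[, 2]) - 0.3), 0.05)
  expect_lt(abs(var(tr$score) - 1), 0.1)

  # determinism and domain check
  tr_again <- simulate_heritable_trait(ped, h2 = 0.6, seed = 22)
  expect_identical(tr, tr_again)
  expect_error(simulate_heritable_trait(ped0, h2 = 1), "\\[0, 1\\)")
})

test_that("noise-free task betas reproduce the configured group asymmetries exactly", {
  cfg <- cohort_config(beta_noise_sd = 0)
  atlas <- make_atlas(cfg$n_regions_per_hemisphere, cfg$n_language_rois,
                      cfg$n_hubs)
  for (grp in c("strong_typical", "atypical")) {
    expected_net <- cfg$beta_effect$network[cfg$beta_effect$group == grp]
    expected_hub <- cfg$beta_effect$hubs[cfg$beta_effect$group == grp]
    b <- simulate_task_betas(atlas, grp, latent_mod = 0, cfg, seed = 1)
    expect_equal(task_asymmetry(b, atlas, "network"), expected_net,
                 tolerance = 1e-12)
    expect_equal(task_asymmetry(b, atlas, "hubs"), expected_hub,
                 tolerance = 1e-12)
  }
  expect_error(simulate_task_betas(atlas, "leftish", 0, cfg), "unknown group")
})

test_that("zero effect size gives zero mean asymmetry", {
  cfg <- cohort_config(
    beta_effect = tibble::tibble(group = c("strong_typical", "mild_typical",
                                           "atypical"),
                                 network = 0, hubs = 0))
  atlas <- make_atlas(cfg$n_regions_per_hemisphere, cfg$n_language_rois,
                      cfg$n_hubs)
  asyms <- vapply(1:300, function(i) {
    b <- simulate_task_betas(atlas, "strong_typical", 0, cfg, seed = 1000 + i)
    task_asymmetry(b, atlas, "network")
  }, numeric(1))
  se <- sd(asyms) / sqrt(length(asyms))
  expect_lt(abs(mean(asyms)), 3 * se + 1e-12)
})

test_that("homotopic coupling dominates other inter-hemispheric correlations", {
  cfg <- cohort_config(n_regions_per_hemisphere = 10, n_language_rois = 3,
                       ts_length = 3000, n_scans = 1,
                       homotopic_coupling = 0.9,
                       cross_hemisphere_scale = 0.05,
                       within_network_coupling = 0)
  atlas <- make_atlas(10, 3, 2)
  scans <- simulate_timeseries(atlas, "strong_typical", 0, cfg, seed = 31)
  r <- cor(t(scans[[1]]))
  li <- which(atlas$hemisphere == "L")
  ri <- match(atlas$homotopic_partner[li], atlas$region_id)
  hom <- r[cbind(li, ri)]
  cross <- r[li, ri]
  nonhom <- cross[row(cross) != col(cross)]
  frac <- mean(outer(hom, nonhom, ">"))
  expect_gt(frac, 0.95)
})

test_that("with all couplings off, off-diagonal correlations center on zero", {
  cfg <- cohort_config(n_regions_per_hemisphere = 8, n_language_rois = 2,
                       ts_length = 2000, n_scans = 1,
                       homotopic_coupling = 0, within_network_coupling = 0,
                       cross_hemisphere_scale = 0,
                       gradient_bandwidth = 1e-4,
                       strength_effect = tibble::tibble(
                         group = c("strong_typical", "mild_typical",
                                   "atypical"),
                         boost_L = 0, boost_R = 0))
  atlas <- make_atlas(8, 2, 1)
  scans <- simulate_timeseries(atlas, "strong_typical", 0, cfg, seed = 32)
  r <- cor(t(scans[[1]]))
  offdiag <- r[row(r) != col(r)]
  expect_lt(abs(mean(offdiag)), 0.01)
  expect_lt(max(abs(offdiag)), 0.12)
})

test_that("sample covariance of a long series matches the analytic covariance", {
  # moderate correlations keep the per-entry sampling SD of the 50k-point
  # covariance estimate well below the 0.02 tolerance
  cfg <- cohort_config(n_regions_per_hemisphere = 10, n_language_rois = 3,
                       ts_length = 50000, n_scans = 1,
                       gradient_bandwidth = 0.1,
                       cross_hemisphere_scale = 0.2,
                       homotopic_coupling = 0.2,
                       within_network_coupling = 0.1)
  atlas <- make_atlas(10, 3, 2)
  sigma <- region_covariance(atlas, "strong_typical", 0, cfg)
  scans <- simulate_timeseries(atlas, "strong_typical", 0, cfg, seed = 33)
  s_hat <- tcrossprod(scans[[1]]) / ncol(scans[[1]])
  expect_lt(max(abs(s_hat - sigma)), 0.02)
})

test_that("cohort composition and determinism behave as configured", {
  cfg <- cohort_config(n_subjects = 1000, n_regions_per_hemisphere = 7,
                       n_language_rois = 2, n_hubs = 1, ts_length = 4,
                       n_scans = 1, seed = 41)
  co <- simulate_cohort(cfg)
  n_atyp <- sum(co$truth$group == "atypical")
  # binomial 99% interval around 8% of 1000
  expect_gte(n_atyp, 60)
  expect_lte(n_atyp, 104)

  co2 <- simulate_cohort(cfg)
  expect_identical(co$truth, co2$truth)
  expect_identical(co$subjects[[17]]$task_betas, co2$subjects[[17]]$task_betas)
  expect_identical(co$subjects[[17]]$scans, co2$subjects[[17]]$scans)

  expect_warning(empty <- simulate_cohort(
    cohort_config(n_subjects = 0, pedigree_spec = list(
      mz_pairs = 0, dz_pairs = 0, sib_pairs = 0, singletons = 0))),
    "empty")
  expect_length(empty$subjects, 0)
})

test_that("MZ co-twins share phenotype more often than unrelated subjects", {
  cfg <- cohort_config(n_subjects = 1200, n_regions_per_hemisphere = 7,
                       n_language_rois = 2, n_hubs = 1, ts_length = 4,
                       n_scans = 1, h2_asym = 0.6, seed = 43,
                       pedigree_spec = list(mz_pairs = 300, dz_pairs = 0,
                                            sib_pairs = 0, singletons = 600))
  co <- simulate_cohort(cfg)
  ped <- co$pedigree
  grp <- co$truth$group
  is_mz <- ped$relation == "MZ_twin"
  mz_pairs <- matrix(grp[is_mz], ncol = 2, byrow = TRUE)
  concord_mz <- mean(mz_pairs[, 1] == mz_pairs[, 2])
  singles <- grp[!is_mz]
  concord_rand <- mean(outer(singles[1:200], singles[201:400], "=="))
  expect_gt(concord_mz, concord_rand + 0.1)
})
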