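make_scan <- function(n_regions, n_time, seed, ids = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(n_regions * n_time), n_regions, n_time)
  rownames(x) <- ids %||% as.character(seq_len(n_regions))
  x
}

test_that("perfectly correlated series are clipped before Fisher z", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  conn <- build_connectivity(list(x))
  expect_equal(conn$values["a", "b"], 1 - 1e-7, tolerance = 1e-9)
  expect_true(all(is.finite(conn$z_values)))
})

test_that("averaging identical scans equals the single-scan result", {
  x <- make_scan(5, 80, seed = 1)
  one <- build_connectivity(list(x))
  four <- build_connectivity(rep(list(x), 4))
  expect_equal(four$values, one$values, tolerance = 1e-12)
  expect_equal(four$n_scans_averaged, 4)
})

test_that("connectivity matches the brute-force Pearson + z-average oracle", {
  scans <- lapply(1:3, function(k) make_scan(5, 200, seed = 10 + k))
  conn <- build_connectivity(scans)
  orc <- oracle_connectivity(scans)
  expect_lt(max(abs(conn$z_values - orc$z)), 1e-12)
  expect_lt(max(abs(conn$values - orc$r)), 1e-12)
  expect_equal(tanh(conn$z_values), conn$values, tolerance = 1e-12)
})

test_that("degenerate scans are rejected with informative errors", {
  x <- make_scan(4, 50, seed = 2)
  const <- x
  const[3, ] <- 5
  expect_error(build_connectivity(list(const)), "region 3")
  expect_error(build_connectivity(list(x, x[-1, ])), "mismatched")
  expect_error(build_connectivity(list(x[, 1:2])), "3 time points")
})

test_that("task asymmetry is the L-minus-R mean over flagged regions", {
  atlas <- toy_atlas()
  betas <- tibble::tibble(region_id = 1:4, beta = c(2, 7, 1, 9))
  expect_equal(task_asymmetry(betas, atlas, "network"), 1)

  sym <- tibble::tibble(region_id = 1:4, beta = c(2, 7, 2, 7))
  expect_equal(task_asymmetry(sym, atlas, "network"), 0)

  swapped <- tibble::tibble(region_id = 1:4, beta = c(1, 9, 2, 7))
  expect_equal(task_asymmetry(swapped, atlas, "network"),
               -task_asymmetry(betas, atlas, "network"))

  no_hubs <- atlas
  expect_error(task_asymmetry(betas, no_hubs, "hubs"), "empty")
})

test_that("strength is the within-hemisphere sum over other language ROIs", {
  atlas <- validate_atlas(tibble::tibble(
    region_id = 1:6,
    hemisphere = rep(c("L", "R"), each = 3),
    homotopic_partner = c(4:6, 1:3),
    network = "default",
    is_language_roi = TRUE,
    is_hub = FALSE
  ))
  r <- matrix(0.5, 6, 6)
  diag(r) <- 0
  conn <- as_conn(r)
  s <- strength_metrics(conn, atlas)
  # each region: 2 same-hemisphere partners at 0.5 -> strength 1.0
  expect_equal(unname(s["strength_sum"]), 2.0)
  expect_equal(unname(s["strength_asym"]), 0.0)

  # hemisphere-swap invariance / antisymmetry
  r2 <- matrix(0, 6, 6)
  r2[1:3, 1:3] <- 0.6
  r2[4:6, 4:6] <- 0.2
  diag(r2) <- 0
  conn2 <- as_conn(r2)
  s2 <- strength_metrics(conn2, atlas)
  perm <- c(4:6, 1:3)
  conn2m <- as_conn(r2[perm, perm], ids = as.character(1:6))
  s2m <- strength_metrics(conn2m, atlas)
  expect_equal(unname(s2m["strength_asym"]), -unname(s2["strength_asym"]),
               tolerance = 1e-12)
  expect_equal(unname(s2m["strength_sum"]), unname(s2["strength_sum"]),
               tolerance = 1e-12)
})

test_that("homotopic connectivity averages z over language pairs", {
  atlas <- validate_atlas(tibble::tibble(
    region_id = 1:6,
    hemisphere = rep(c("L", "R"), each = 3),
    homotopic_partner = c(4:6, 1:3),
    network = "default",
    is_language_roi = TRUE,
    is_hub = FALSE
  ))
  z <- matrix(0, 6, 6)
  z[cbind(1:3, 4:6)] <- c(0.3, 0.5, 0.7)
  z <- z + t(z)
  conn <- as_conn(tanh(z))
  expect_equal(homotopic_connectivity(conn, atlas), 0.5, tolerance = 1e-12)

  null_conn <- as_conn(matrix(0, 6, 6))
  expect_equal(homotopic_connectivity(null_conn, atlas), 0)
})

test_that("hemisphere swap negates asymmetries and preserves symmetric metrics", {
  cfg <- small_cohort_config(seed = 51)
  atlas <- make_atlas(cfg$n_regions_per_hemisphere, cfg$n_language_rois,
                      cfg$n_hubs)
  for (grp in c("strong_typical", "atypical")) {
    subject <- list(
      subject_id = "s1",
      scans = simulate_timeseries(atlas, grp, 0.3, cfg, seed = 61),
      task_betas = simulate_task_betas(atlas, grp, 0.3, cfg, seed = 62)
    )
    f <- compute_language_features(subject, atlas)
    fm <- compute_language_features(mirror_subject(subject, atlas), atlas)
    expect_equal(fm$beta_network_asym, -f$beta_network_asym, tolerance = 1e-12)
    expect_equal(fm$beta_hubs_asym, -f$beta_hubs_asym, tolerance = 1e-12)
    expect_equal(fm$strength_asym, -f$strength_asym, tolerance = 1e-12)
    expect_equal(fm$strength_sum, f$strength_sum, tolerance = 1e-12)
    expect_equal(fm$interhemi_rz, f$interhemi_rz, tolerance = 1e-12)
  }
})

test_that("region relabeling leaves all five metrics unchanged", {
  cfg <- small_cohort_config(seed = 52)
  atlas <- make_atlas(cfg$n_regions_per_hemisphere, cfg$n_language_rois,
                      cfg$n_hubs)
  subject <- list(
    subject_id = "s1",
    scans = simulate_timeseries(atlas, "mild_typical", 0, cfg, seed = 71),
    task_betas = simulate_task_betas(atlas, "mild_typical", 0, cfg, seed = 72)
  )
  f <- compute_language_features(subject, atlas)

  set.seed(73)
  perm <- sample(nrow(atlas))
  atlas_p <- atlas[perm, ]
  subject_p <- list(
    subject_id = "s1",
    scans = lapply(subject$scans, function(x) x[perm, , drop = FALSE]),
    task_betas = subject$task_betas[perm, ]
  )
  fp <- compute_language_features(subject_p, atlas_p)
  expect_equal(as.data.frame(fp), as.data.frame(f), tolerance = 1e-12)
})

test_that("the five-metric vector equals the composition of its parts", {
  cfg <- small_cohort_config(seed = 53)
  atlas <- make_atlas(cfg$n_regions_per_hemisphere, cfg$n_language_rois,
                      cfg$n_hubs)
  subject <- list(
    subject_id = "s1",
    scans = simulate_timeseries(atlas, "strong_typical", 0, cfg, seed = 81),
    task_betas = simulate_task_betas(atlas, "strong_typical", 0, cfg, seed = 82)
  )
  f <- compute_language_features(subject, atlas)
  conn <- build_connectivity(subject$scans)
  s <- strength_metrics(conn, atlas)
  expect_equal(f$beta_network_asym,
               task_asymmetry(subject$task_betas, atlas, "network"))
  expect_equal(f$beta_hubs_asym,
               task_asymmetry(subject$task_betas, atlas, "hubs"))
  expect_equal(f$interhemi_rz, homotopic_connectivity(conn, atlas))
  expect_equal(f$strength_sum, unname(s["strength_sum"]))
  expect_equal(f$strength_asym, unname(s["strength_asym"]))
})
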