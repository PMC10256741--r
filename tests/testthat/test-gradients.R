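random_affinity <- function(n, seed) {
  set.seed(seed)
  x <- matrix(runif(n * n, 0.05, 1), n, n)
  s <- (x + t(x)) / 2
  diag(s) <- 1
  s
}

test_that("row sparsification keeps the right survivors with deterministic ties", {
  set.seed(11)
  m <- matrix(rnorm(121), 11, 11)
  sp <- sparsify_rows(m, retained = 0.1)
  expect_true(all(rowSums(sp != 0) == 1))   # ceiling(0.1 * 10) = 1
  expect_true(all(diag(sp) == 0))

  full <- sparsify_rows(m, retained = 1)
  off <- m
  diag(off) <- 0
  expect_equal(full, off)

  tied <- matrix(0, 4, 4)
  tied[1, 2:4] <- c(0.5, 0.5, 0.2)
  tied[2:4, ] <- 0.1
  sp_t <- sparsify_rows(tied, retained = 1 / 3)  # keep 1 per row
  expect_equal(which(sp_t[1, ] != 0), 2L)        # lowest column index wins

  expect_error(sparsify_rows(m, retained = 0), "\\(0, 1\\]")
  expect_equal(sparsify_rows(m, 0.3), oracle_sparsify(m, 0.3))
})

test_that("normalized angle affinity hits its landmark values", {
  m <- rbind(c(1, 0), c(1, 0), c(0, 2), c(-3, 0))
  s <- normalized_angle_affinity(m)
  expect_equal(s[1, 2], 1)       # identical direction
  expect_equal(s[1, 3], 0.5)     # orthogonal
  expect_equal(s[1, 4], 0)       # anti-parallel
  expect_equal(s, t(s))
  expect_equal(diag(s), rep(1, 4))

  m0 <- rbind(c(1, 1), c(0, 0))
  expect_error(normalized_angle_affinity(m0), "all-zero")

  r <- matrix(rnorm(50), 10, 5)
  expect_equal(normalized_angle_affinity(r), oracle_affinity(r),
               tolerance = 1e-12)
})

test_that("diffusion embedding separates a two-block affinity by sign of G1", {
  n <- 12
  s <- matrix(0.01, n, n)
  s[1:6, 1:6] <- 1
  s[7:12, 7:12] <- 1
  g <- diffusion_embedding(s, gradient_config(n_components = 2))
  g1 <- g$values[, 1]
  expect_true(all(sign(g1[1:6]) == sign(g1[1])))
  expect_true(all(sign(g1[7:12]) == -sign(g1[1])))
})

test_that("diffusion embedding matches the dense nonsymmetric oracle", {
  for (rep in 1:5) {
    s <- random_affinity(10, seed = 500 + rep)
    g <- diffusion_embedding(s, gradient_config(n_components = 3))
    orc <- oracle_diffusion(s, alpha = 0.5, n_comp = 3)
    expect_lt(max(abs(g$eigenvalues - orc$eigenvalues)), 1e-8)
    expect_lt(max_abs_diff_up_to_sign(g$values, orc$values), 1e-8)
  }
})

test_that("diffusion embedding is permutation-equivariant", {
  s <- random_affinity(12, seed = 600)
  g <- diffusion_embedding(s, gradient_config(n_components = 3))
  set.seed(601)
  perm <- sample(12)
  gp <- diffusion_embedding(s[perm, perm], gradient_config(n_components = 3))
  expect_lt(max_abs_diff_up_to_sign(gp$values, g$values[perm, ]), 1e-8)
})

test_that("degenerate affinities are rejected and spectra are ordered", {
  s <- random_affinity(8, seed = 602)
  bad <- s
  bad[1, 2] <- bad[1, 2] + 0.5
  expect_error(diffusion_embedding(bad), "symmetric")

  disc <- matrix(0, 6, 6)
  disc[1:3, 1:3] <- 1
  disc[4:6, 4:6] <- 1
  expect_error(diffusion_embedding(disc), "disconnected")

  g <- diffusion_embedding(s, gradient_config(n_components = 5))
  expect_true(all(diff(g$variance_explained) <= 1e-12))
  expect_true(all(g$variance_explained >= 0 & g$variance_explained <= 1))
})

test_that("Procrustes alignment recovers known orthogonal transforms", {
  set.seed(12)
  x <- matrix(rnorm(60), 20, 3)
  expect_equal(procrustes_align(x, x), x, tolerance = 1e-12)

  theta <- 0.7
  q <- diag(3)
  q[1:2, 1:2] <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)),
                        2, 2)
  expect_lt(max(abs(procrustes_align(x %*% q, x) - x)), 1e-8)

  refl <- diag(c(-1, 1, 1))
  expect_lt(max(abs(procrustes_align(x %*% refl, x) - x)), 1e-8)

  expect_error(procrustes_align(x, x[1:5, ]), "dimensions differ")
})

test_that("min-max scaling maps whole-brain values onto the target range", {
  v <- cbind(G1 = c(2, 4, 6), G2 = c(0, 1, 3))
  s <- minmax_scale(v)
  expect_equal(s[, "G1"], c(0, 50, 100))
  expect_equal(min(s[, "G2"]), 0)
  expect_equal(max(s[, "G2"]), 100)
  expect_equal(minmax_scale(s), s, tolerance = 1e-12)
  expect_error(minmax_scale(cbind(c(1, 1, 1))), "constant")
})

test_that("network gradient asymmetry is the L-minus-R network mean", {
  atlas <- make_atlas(7, 2, 1)
  v <- matrix(40, nrow(atlas), 2,
              dimnames = list(atlas$region_id, c("G1", "G2")))
  v[atlas$hemisphere == "L" & atlas$network == "default", "G1"] <- 60
  asym <- network_gradient_asymmetry(v, atlas)
  expect_equal(asym$asymmetry[asym$network == "default" &
                                asym$gradient == "G1"], 20)
  expect_equal(asym$asymmetry[asym$network == "visual" &
                                asym$gradient == "G1"], 0)

  # hemisphere-swapped values negate every asymmetry
  perm <- match(atlas$homotopic_partner, atlas$region_id)
  vm <- v[perm, , drop = FALSE]
  rownames(vm) <- atlas$region_id
  asym_m <- network_gradient_asymmetry(vm, atlas)
  expect_equal(asym_m$asymmetry, -asym$asymmetry, tolerance = 1e-12)
})

test_that("full stack sparsify -> affinity -> embedding matches a monolithic reference", {
  cfg <- gradient_config(sparsity = 0.7, n_components = 3)
  for (rep in 1:5) {
    set.seed(700 + rep)
    n <- sample(10:12, 1)
    r <- cov2cor(crossprod(matrix(rnorm(3 * n * n), 3 * n, n)))
    diag(r) <- 0
    g <- diffusion_embedding(
      normalized_angle_affinity(sparsify_rows(r, cfg$retained)), cfg)
    orc <- oracle_diffusion(oracle_affinity(oracle_sparsify(r, cfg$retained)),
                            alpha = 0.5, n_comp = 3)
    expect_lt(max_abs_diff_up_to_sign(g$values, orc$values), 1e-8)
  }
})

test_that("subject-level G1 tracks the generator's latent coordinate", {
  cfg <- cohort_config(n_subjects = 20, n_regions_per_hemisphere = 21,
                       n_language_rois = 6, ts_length = 150, seed = 77)
  co <- simulate_cohort(cfg)
  gf <- compute_gradients(co)
  rc <- attr(co$truth, "region_coords")
  cors <- vapply(gf$subject_gradients, function(g) {
    cor(g[as.character(rc$region_id), "G1"], rc$latent_coord)
  }, numeric(1))
  expect_gte(median(abs(cors)), 0.8)
  # sign convention: template G1 increases toward the association end
  expect_gt(median(cors), 0)
})
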