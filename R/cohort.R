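#' Configuration for the synthetic cohort generator
#'
#' Returns the full set of generator parameters with defaults emulating the
#' statistical structure the analysis assumes: three lateralization groups
#' with the published task-asymmetry group means as effect sizes, homotopic
#' inter-hemispheric coupling, a one-dimensional latent gradient coordinate
#' shaping region covariance, group-specific connectivity boosts to the
#' left (typical) or both (atypical) language blocks, and an additive
#' genetic component of the lateralization liability shared within
#' MZ > DZ/sibling pairs.
#'
#' @param n_subjects Cohort size (ignored if `pedigree_spec` is given).
#' @param group_proportions Named proportions for strong_typical,
#'   mild_typical, atypical; must sum to 1.
#' @param n_regions_per_hemisphere Regions per hemisphere.
#' @param n_language_rois Language ROIs per hemisphere (the last, most
#'   associative regions along the latent coordinate).
#' @param n_hubs Hub ROIs per hemisphere (subset of the language ROIs).
#' @param ts_length Time points per scan.
#' @param n_scans Scans per subject.
#' @param homotopic_coupling Additive correlation for homotopic pairs.
#' @param within_network_coupling Additive correlation for same-network pairs.
#' @param gradient_bandwidth Decay scale of the latent-coordinate kernel.
#' @param cross_hemisphere_scale Multiplier on the latent kernel across
#'   hemispheres.
#' @param beta_effect Data frame (group, network, hubs) of mean task-beta
#'   asymmetries in contrast units; defaults are the published group means.
#' @param beta_base Mean task beta of language regions in each hemisphere.
#' @param beta_noise_sd SD of per-region, per-hemisphere beta noise.
#' @param beta_latent_scale Modulation of beta effects by the group-centered
#'   liability.
#' @param strength_effect Data frame (group, boost_L, boost_R) of additive
#'   correlation boosts within the left/right language blocks.
#' @param strength_latent_scale Liability modulation of the strength boost.
#' @param h2_asym Narrow-sense heritability of the lateralization liability.
#' @param latent_offset Optional list(network, hemisphere, delta, group)
#'   shifting the latent coordinate of one network's regions in one
#'   hemisphere, optionally confined to one group.
#' @param pedigree_spec Optional list(mz_pairs, dz_pairs, sib_pairs,
#'   singletons); when `NULL` a composition proportional to a twin-family
#'   cohort (13% MZ, 7% DZ, 48% sibling, rest singleton individuals)
#'   is derived from `n_subjects`.
#' @param seed Master seed; fully determines the cohort.
#' @return A `langlat_cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 120,
                          group_proportions = c(strong_typical = 0.48,
                                                mild_typical = 0.44,
                                                atypical = 0.08),
                          n_regions_per_hemisphere = 40,
                          n_language_rois = 9,
                          n_hubs = 2,
                          ts_length = 200,
                          n_scans = 4,
                          homotopic_coupling = 0.25,
                          within_network_coupling = 0.15,
                          gradient_bandwidth = 0.3,
                          cross_hemisphere_scale = 0.35,
                          beta_effect = NULL,
                          beta_base = 1.0,
                          beta_noise_sd = 0.45,
                          beta_latent_scale = 0.15,
                          strength_effect = NULL,
                          strength_latent_scale = 0.15,
                          h2_asym = 0.3,
                          latent_offset = NULL,
                          pedigree_spec = NULL,
                          seed = 1L) {
  if (is.null(beta_effect)) {
    beta_effect <- tibble::tibble(
      group = PHENOTYPE_LEVELS,
      network = c(1.74, 0.70, -0.96),
      hubs = c(2.64, 1.17, -1.16)
    )
  }
  if (is.null(strength_effect)) {
    strength_effect <- tibble::tibble(
      group = PHENOTYPE_LEVELS,
      boost_L = c(0.10, 0.00, 0.07),
      boost_R = c(0.04, -0.05, 0.07)
    )
  }
  if (abs(sum(group_proportions) - 1) > 1e-8) {
    stop_langlat("group_proportions must sum to 1", "langlat_config_error")
  }
  if (h2_asym < 0 || h2_asym >= 1) {
    stop_langlat("h2_asym must be in [0, 1)", "langlat_config_error")
  }
  if (homotopic_coupling < 0 || homotopic_coupling >= 1) {
    stop_langlat("homotopic_coupling must be in [0, 1)", "langlat_config_error")
  }
  cfg <- list(
    n_subjects = n_subjects,
    group_proportions = group_proportions,
    n_regions_per_hemisphere = n_regions_per_hemisphere,
    n_language_rois = n_language_rois,
    n_hubs = n_hubs,
    ts_length = ts_length,
    n_scans = n_scans,
    homotopic_coupling = homotopic_coupling,
    within_network_coupling = within_network_coupling,
    gradient_bandwidth = gradient_bandwidth,
    cross_hemisphere_scale = cross_hemisphere_scale,
    beta_effect = beta_effect,
    beta_base = beta_base,
    beta_noise_sd = beta_noise_sd,
    beta_latent_scale = beta_latent_scale,
    strength_effect = strength_effect,
    strength_latent_scale = strength_latent_scale,
    h2_asym = h2_asym,
    latent_offset = latent_offset,
    pedigree_spec = pedigree_spec,
    seed = as.integer(seed)
  )
  class(cfg) <- "langlat_cohort_config"
  cfg
}

#' Build a synthetic region atlas
#'
#' Regions within each hemisphere are ordered along a latent
#' unimodal-to-association coordinate, split into the seven canonical
#' networks as contiguous blocks, with the language ROIs placed at the
#' association end and the hubs as the most associative language ROIs.
#' Left regions get ids `1..n`, right regions `n+1..2n`; homotopic partners
#' share the within-hemisphere position.
#'
#' @param n_per_hemisphere Regions per hemisphere (>= 7).
#' @param n_language_rois Language ROIs per hemisphere.
#' @param n_hubs Hub ROIs per hemisphere.
#' @return A validated atlas tibble.
#' @export
make_atlas <- function(n_per_hemisphere = 40, n_language_rois = 9, n_hubs = 2) {
  n <- n_per_hemisphere
  if (n < length(CANONICAL_NETWORKS)) {
    stop_langlat("need at least one region per network and hemisphere",
                 "langlat_atlas_error")
  }
  if (n_language_rois > n || n_hubs > n_language_rois) {
    stop_langlat("language ROI / hub counts exceed available regions",
                 "langlat_atlas_error")
  }
  sizes <- rep(n %/% 7, 7)
  sizes[seq_len(n %% 7)] <- sizes[seq_len(n %% 7)] + 1
  network <- rep(CANONICAL_NETWORKS, times = sizes)
  pos <- seq_len(n)
  is_lang <- pos > n - n_language_rois
  is_hub <- pos > n - n_hubs
  atlas <- tibble::tibble(
    region_id = c(pos, pos + n),
    hemisphere = rep(c("L", "R"), each = n),
    homotopic_partner = c(pos + n, pos),
    network = rep(network, 2),
    is_language_roi = rep(is_lang, 2),
    is_hub = rep(is_hub, 2)
  )
  validate_atlas(atlas)
}

# Latent gradient coordinate: equally spaced in [0, 1] within each
# hemisphere, identical ordering across hemispheres.
latent_coordinates <- function(atlas) {
  g <- numeric(nrow(atlas))
  for (h in c("L", "R")) {
    idx <- which(atlas$hemisphere == h)
    nh <- length(idx)
    g[idx] <- if (nh > 1) seq(0, 1, length.out = nh) else 0.5
  }
  g
}

# Build a synthetic pedigree with the requested composition.
#' Build a synthetic pedigree
#'
#' @param mz_pairs,dz_pairs,sib_pairs,singletons Family counts; sibling
#'   pairs are non-twin full siblings.
#' @return A validated pedigree tibble with subject ids `sub0001`, ...
#' @export
make_pedigree <- function(mz_pairs = 0, dz_pairs = 0, sib_pairs = 0,
                          singletons = 0) {
  rows <- list()
  fam <- 0L
  sub <- 0L
  add <- function(rel, pair) {
    fam <<- fam + 1L
    k <- if (pair) 2L else 1L
    ids <- sprintf("sub%04d", sub + seq_len(k))
    sub <<- sub + k
    pair_id <- if (rel %in% c("MZ_twin", "DZ_twin")) sprintf("pair%04d", fam)
               else NA_character_
    tibble::tibble(
      family_id = sprintf("fam%04d", fam),
      subject_id = ids,
      relation = rel,
      twin_pair_id = pair_id
    )
  }
  for (i in seq_len(mz_pairs)) rows <- c(rows, list(add("MZ_twin", TRUE)))
  for (i in seq_len(dz_pairs)) rows <- c(rows, list(add("DZ_twin", TRUE)))
  for (i in seq_len(sib_pairs)) rows <- c(rows, list(add("full_sibling", TRUE)))
  for (i in seq_len(singletons)) rows <- c(rows, list(add("singleton", FALSE)))
  ped <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble::tibble(family_id = character(), subject_id = character(),
                   relation = character(), twin_pair_id = character())
  suppressWarnings(validate_pedigree(ped))
}

default_pedigree_spec <- function(n) {
  mz <- floor(0.13 * n / 2)
  dz <- floor(0.07 * n / 2)
  sib <- floor(0.48 * n / 2)
  singles <- n - 2L * (mz + dz + sib)
  list(mz_pairs = mz, dz_pairs = dz, sib_pairs = sib, singletons = singles)
}

# Draw genetic (kinship-correlated) and environmental standard-normal
# components for every subject, family block by family block.
sim_genetic_env <- function(pedigree, seed) {
  set.seed(seed)
  n <- nrow(pedigree)
  a <- numeric(n)
  for (f in unique(pedigree$family_id)) {
    idx <- which(pedigree$family_id == f)
    K <- kinship_matrix(pedigree[idx, , drop = FALSE])
    eg <- eigen(K$matrix, symmetric = TRUE)
    L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), length(idx))
    a[idx] <- as.numeric(L %*% rnorm(length(idx)))
  }
  list(a = a, e = rnorm(n))
}

#' Simulate a heritable quantitative trait on a pedigree
#'
#' Draws per-subject scores `y = sqrt(h2) * a + sqrt(1 - h2) * e` where the
#' additive genetic component `a` has covariance equal to the kinship
#' relatedness (2*Phi: 1 within MZ pairs, 0.5 within DZ/sibling pairs, 0
#' across families) and `e` is independent noise, so total variance is 1 in
#' expectation and pair covariance equals `h2 * 2Phi`.
#'
#' @param pedigree A validated pedigree.
#' @param h2 Narrow-sense heritability in `[0, 1)`.
#' @param seed RNG seed; the same seed reproduces identical scores.
#' @return Tibble with `subject_id` and `score`.
#' @export
simulate_heritable_trait <- function(pedigree, h2, seed = 1L) {
  if (!is.numeric(h2) || h2 < 0 || h2 >= 1) {
    stop_langlat("h2 must be in [0, 1)", "langlat_config_error")
  }
  pedigree <- validate_pedigree(pedigree)
  parts <- sim_genetic_env(pedigree, seed)
  tibble::tibble(
    subject_id = pedigree$subject_id,
    score = sqrt(h2) * parts$a + sqrt(1 - h2) * parts$e
  )
}

# Mean of a standard normal truncated to (a, b).
truncnorm_mean <- function(a, b) {
  (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# Assign groups by thresholding the liability at the configured
# proportions (atypical = lowest / most rightward liability), and return
# the group-centered modulation score.
assign_groups <- function(liability, proportions) {
  p_atyp <- proportions[["atypical"]]
  p_mild <- proportions[["mild_typical"]]
  q1 <- qnorm(p_atyp)
  q2 <- qnorm(p_atyp + p_mild)
  group <- ifelse(liability < q1, "atypical",
           ifelse(liability < q2, "mild_typical", "strong_typical"))
  centers <- c(atypical = truncnorm_mean(-Inf, q1),
               mild_typical = truncnorm_mean(q1, q2),
               strong_typical = truncnorm_mean(q2, Inf))
  tibble::tibble(group = group,
                 liability = liability,
                 latent_mod = liability - centers[group])
}

#' Region covariance implied by the generator
#'
#' Builds the region-by-region covariance used to draw BOLD-like time
#' series: an exponential kernel over the latent gradient coordinate
#' (damped across hemispheres), plus within-network and homotopic coupling,
#' plus the group's language-block connectivity boost modulated by the
#' subject's latent asymmetry score. The result is projected to the nearest
#' positive-definite matrix by eigenvalue clipping at 1e-6.
#'
#' @param atlas Validated atlas.
#' @param group Phenotype group label.
#' @param latent_mod Group-centered liability score of the subject.
#' @param config A [cohort_config()].
#' @return Covariance matrix with region ids as dimnames.
#' @export
region_covariance <- function(atlas, group, latent_mod, config) {
  if (!group %in% PHENOTYPE_LEVELS) {
    stop_langlat(paste0("unknown group: ", group), "langlat_config_error")
  }
  g <- latent_coordinates(atlas)
  off <- config$latent_offset
  if (!is.null(off) && (is.null(off$group) || off$group == group)) {
    sel <- atlas$network == off$network & atlas$hemisphere == off$hemisphere
    g[sel] <- g[sel] + off$delta
  }
  n <- nrow(atlas)
  E <- exp(-abs(outer(g, g, "-")) / config$gradient_bandwidth)
  same_hemi <- outer(atlas$hemisphere, atlas$hemisphere, "==")
  M <- ifelse(same_hemi, 1, config$cross_hemisphere_scale)
  sigma <- E * M
  same_net <- outer(atlas$network, atlas$network, "==") & !diag(n)
  sigma <- sigma + config$within_network_coupling * same_net
  partner_idx <- match(atlas$homotopic_partner, atlas$region_id)
  hom <- matrix(FALSE, n, n)
  hom[cbind(seq_len(n), partner_idx)] <- TRUE
  sigma <- sigma + config$homotopic_coupling * hom
  se <- config$strength_effect
  row <- which(se$group == group)
  mod <- 1 + config$strength_latent_scale * latent_mod
  for (h in c("L", "R")) {
    b <- if (h == "L") se$boost_L[row] else se$boost_R[row]
    idx <- which(atlas$is_language_roi & atlas$hemisphere == h)
    sigma[idx, idx] <- sigma[idx, idx] + b * mod * (1 - diag(length(idx)))
  }
  sigma <- (sigma + t(sigma)) / 2
  eg <- eigen(sigma, symmetric = TRUE)
  if (min(eg$values) < 1e-6) {
    vals <- pmax(eg$values, 1e-6)
    sigma <- eg$vectors %*% (vals * t(eg$vectors))
    sigma <- (sigma + t(sigma)) / 2
  }
  dimnames(sigma) <- list(atlas$region_id, atlas$region_id)
  sigma
}

#' Simulate per-scan BOLD-like region time series for one subject
#'
#' Draws zero-mean Gaussian time series with the region covariance from
#' [region_covariance()].
#'
#' @inheritParams region_covariance
#' @param seed RNG seed for this subject.
#' @return List of `n_scans` region-by-time matrices (rownames = region id).
#' @export
simulate_timeseries <- function(atlas, group, latent_mod, config, seed = 1L) {
  sigma <- region_covariance(atlas, group, latent_mod, config)
  eg <- eigen(sigma, symmetric = TRUE)
  if (min(eg$values) <= 0) {
    stop_langlat("region covariance is not positive definite after projection",
                 "langlat_simulation_error")
  }
  L <- eg$vectors %*% diag(sqrt(eg$values), nrow(sigma))
  set.seed(seed)
  lapply(seq_len(config$n_scans), function(s) {
    x <- L %*% matrix(rnorm(nrow(sigma) * config$ts_length),
                      nrow(sigma), config$ts_length)
    rownames(x) <- rownames(sigma)
    x
  })
}

#' Simulate task-contrast betas for one subject
#'
#' Language-ROI betas receive a mean left-minus-right asymmetry equal to
#' the group's configured network-level effect (hubs the hub-level effect),
#' scaled by `1 + beta_latent_scale * latent_mod`; non-language regions
#' have zero mean asymmetry. Non-hub language effects are solved so that
#' the network-level mean (hubs included) equals the network effect
#' exactly. Gaussian noise with SD `beta_noise_sd` is added per region and
#' hemisphere.
#'
#' @inheritParams region_covariance
#' @param seed RNG seed.
#' @return Tibble with `region_id` and `beta`.
#' @export
simulate_task_betas <- function(atlas, group, latent_mod, config, seed = 1L) {
  if (!group %in% PHENOTYPE_LEVELS) {
    stop_langlat(paste0("unknown group: ", group), "langlat_config_error")
  }
  eff <- config$beta_effect
  row <- which(eff$group == group)
  net_eff <- eff$network[row]
  hub_eff <- eff$hubs[row]
  n_lang <- sum(atlas$is_language_roi & atlas$hemisphere == "L")
  n_hub <- sum(atlas$is_hub & atlas$hemisphere == "L")
  nonhub_eff <- if (n_lang > n_hub) {
    (n_lang * net_eff - n_hub * hub_eff) / (n_lang - n_hub)
  } else {
    net_eff
  }
  mod <- 1 + config$beta_latent_scale * latent_mod
  asym <- numeric(nrow(atlas))
  asym[atlas$is_language_roi & !atlas$is_hub] <- nonhub_eff * mod
  asym[atlas$is_hub] <- hub_eff * mod
  base <- ifelse(atlas$is_language_roi, config$beta_base, 0)
  sign_h <- ifelse(atlas$hemisphere == "L", 0.5, -0.5)
  set.seed(seed)
  noise <- rnorm(nrow(atlas), sd = config$beta_noise_sd)
  tibble::tibble(
    region_id = atlas$region_id,
    beta = base + sign_h * asym + noise
  )
}

#' Simulate a full synthetic cohort
#'
#' Composes the pedigree, heritable lateralization liability, group
#' assignment, covariates, task betas and resting time series into one
#' bundle with ground truth. Each subject has its own RNG stream derived
#' from the master seed and subject index, so the cohort is reproducible
#' and stable under subject-count changes.
#'
#' @param config A [cohort_config()].
#' @return A `langlat_cohort` list: `atlas`, `subjects` (list of
#'   `subject_id`, `scans`, `task_betas`), `covariates`, `pedigree`,
#'   `truth` (group labels, liability, latent modulation; plus per-region
#'   latent coordinates in `attr(truth, "region_coords")`), and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  spec <- config$pedigree_spec %||% default_pedigree_spec(config$n_subjects)
  pedigree <- make_pedigree(spec$mz_pairs, spec$dz_pairs, spec$sib_pairs,
                            spec$singletons)
  n <- nrow(pedigree)
  atlas <- make_atlas(config$n_regions_per_hemisphere,
                      config$n_language_rois, config$n_hubs)
  if (n == 0) {
    warn("empty cohort requested")
    out <- list(atlas = atlas, subjects = list(),
                covariates = tibble::tibble(), pedigree = pedigree,
                truth = tibble::tibble(), config = config)
    class(out) <- "langlat_cohort"
    return(out)
  }
  parts <- sim_genetic_env(pedigree, derive_seed(config$seed, 1L))
  liability <- sqrt(config$h2_asym) * parts$a +
    sqrt(1 - config$h2_asym) * parts$e
  truth <- assign_groups(liability, config$group_proportions)
  truth <- dplyr::bind_cols(tibble::tibble(subject_id = pedigree$subject_id),
                            truth)
  attr(truth, "region_coords") <- tibble::tibble(
    region_id = atlas$region_id,
    latent_coord = latent_coordinates(atlas)
  )

  set.seed(derive_seed(config$seed, 2L))
  age <- round(pmin(36, pmax(22, rnorm(n, 28.7, 3.7))))
  sex <- ifelse(runif(n) < 0.48, "F", "M")
  p_left <- plogis(qlogis(0.11) - 0.6 * liability)
  left <- runif(n) < p_left
  handed <- ifelse(left, runif(n, -100, 29), runif(n, 30, 100))
  icv <- rnorm(n, 1.55e6, 1.4e5)
  covariates <- tibble::tibble(
    subject_id = pedigree$subject_id,
    age = age, sex = sex, handedness = handed, icv = icv
  )

  subjects <- purrr::map(seq_len(n), function(i) {
    seed_i <- derive_seed(config$seed, 100L + i)
    betas <- simulate_task_betas(atlas, truth$group[i], truth$latent_mod[i],
                                 config, seed = seed_i)
    scans <- simulate_timeseries(atlas, truth$group[i], truth$latent_mod[i],
                                 config, seed = derive_seed(seed_i, 1L))
    list(subject_id = pedigree$subject_id[i], scans = scans,
         task_betas = betas)
  })
  names(subjects) <- pedigree$subject_id
  out <- list(atlas = atlas, subjects = subjects, covariates = covariates,
              pedigree = pedigree, truth = truth, config = config)
  class(out) <- "langlat_cohort"
  out
}

#' @export
print.langlat_cohort <- function(x, ...) {
  cat("<langlat_cohort> ", length(x$subjects), " subjects, ",
      nrow(x$atlas), " regions (", sum(x$atlas$is_language_roi),
      " language ROIs)\n", sep = "")
  invisible(x)
}

#' Write a cohort to a directory of delimited files
#'
#' Writes `atlas.tsv`, `pedigree.tsv`, `covariates.tsv`, `betas.tsv`
#' (long format), one time-series TSV per subject and scan under
#' `timeseries/`, and `ground_truth.tsv` (used only by tests, never by
#' analysis stages).
#'
#' @param cohort A `langlat_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  readr::write_tsv(cohort$atlas, file.path(dir, "atlas.tsv"), progress = FALSE)
  readr::write_tsv(cohort$pedigree, file.path(dir, "pedigree.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$covariates, file.path(dir, "covariates.tsv"),
                   progress = FALSE)
  betas <- purrr::map_dfr(cohort$subjects, function(s) {
    dplyr::mutate(s$task_betas, subject_id = s$subject_id, .before = 1)
  })
  readr::write_tsv(betas, file.path(dir, "betas.tsv"), progress = FALSE)
  readr::write_tsv(cohort$truth, file.path(dir, "ground_truth.tsv"),
                   progress = FALSE)
  rc <- attr(cohort$truth, "region_coords")
  if (!is.null(rc)) {
    readr::write_tsv(rc, file.path(dir, "region_coords.tsv"), progress = FALSE)
  }
  for (s in cohort$subjects) {
    for (k in seq_along(s$scans)) {
      write_timeseries(s$scans[[k]],
                       file.path(dir, "timeseries",
                                 sprintf("%s_scan%02d.tsv", s$subject_id, k)))
    }
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `langlat_cohort` (without ground truth or config).
#' @export
read_cohort <- function(dir) {
  atlas <- read_atlas(file.path(dir, "atlas.tsv"))
  pedigree <- read_pedigree(file.path(dir, "pedigree.tsv"))
  covariates <- readr::read_tsv(file.path(dir, "covariates.tsv"),
                                show_col_types = FALSE, progress = FALSE)
  betas <- readr::read_tsv(file.path(dir, "betas.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  ts_files <- list.files(file.path(dir, "timeseries"), full.names = TRUE)
  ids <- unique(sub("_scan\\d+\\.tsv$", "", basename(ts_files)))
  subjects <- purrr::map(ids, function(id) {
    files <- sort(ts_files[startsWith(basename(ts_files), paste0(id, "_scan"))])
    list(
      subject_id = id,
      scans = lapply(files, read_timeseries),
      task_betas = dplyr::select(
        dplyr::filter(betas, .data$subject_id == id), -"subject_id")
    )
  })
  names(subjects) <- ids
  out <- list(atlas = atlas, subjects = subjects, covariates = covariates,
              pedigree = pedigree, truth = NULL, config = NULL)
  class(out) <- "langlat_cohort"
  out
}
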