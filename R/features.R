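#' Build an averaged intrinsic connectivity matrix
#'
#' Per scan, Pearson correlations between all region time series are
#' computed, clipped in magnitude to `1 - clip`, Fisher z-transformed,
#' averaged across scans, and back-transformed with the hyperbolic
#' tangent. The diagonal is stored as 0 and excluded from all downstream
#' sums.
#'
#' @param scans List of region-by-time matrices (identical region sets,
#'   rownames = region ids, >= 3 time points).
#' @param clip Distance from 1 at which `|r|` is capped before `atanh`.
#' @return A `langlat_conn` object with `values` (r scale), `z_values`
#'   (Fisher z) and `n_scans_averaged`.
#' @export
build_connectivity <- function(scans, clip = 1e-7) {
  if (!is.list(scans) || length(scans) == 0) {
    stop_langlat("need at least one scan", "langlat_conn_error")
  }
  n_regions <- nrow(scans[[1]])
  ids <- rownames(scans[[1]])
  z_sum <- matrix(0, n_regions, n_regions)
  for (k in seq_along(scans)) {
    x <- scans[[k]]
    if (nrow(x) != n_regions) {
      stop_langlat("scans have mismatched region counts", "langlat_conn_error")
    }
    if (ncol(x) < 3) {
      stop_langlat("scans need at least 3 time points", "langlat_conn_error")
    }
    sds <- apply(x, 1, sd)
    if (any(sds == 0)) {
      offender <- (ids %||% as.character(seq_len(n_regions)))[which(sds == 0)[1]]
      stop_langlat(paste0("region ", offender,
                          " has a constant time series in scan ", k),
                   "langlat_conn_error")
    }
    r <- cor(t(x))
    r <- pmin(pmax(r, -(1 - clip)), 1 - clip)
    z <- atanh(r)
    diag(z) <- 0
    z_sum <- z_sum + z
  }
  z_mean <- z_sum / length(scans)
  values <- tanh(z_mean)
  diag(values) <- 0
  dimnames(values) <- dimnames(z_mean) <- list(ids, ids)
  structure(list(values = values, z_values = z_mean,
                 n_scans_averaged = length(scans)),
            class = "langlat_conn")
}

#' @export
print.langlat_conn <- function(x, ...) {
  cat("<langlat_conn> ", nrow(x$values), " regions, ",
      x$n_scans_averaged, " scan(s) averaged in z\n", sep = "")
  invisible(x)
}

# Positions (row indices) of a region subset of the connectivity matrix.
conn_index <- function(conn, region_ids) {
  ids <- rownames(conn$values)
  idx <- match(as.character(region_ids), ids)
  if (anyNA(idx)) {
    stop_langlat("region(s) absent from connectivity matrix",
                 "langlat_conn_error")
  }
  idx
}

#' Task-activation asymmetry over a ROI set
#'
#' Mean task beta over the flagged left-hemisphere regions minus the mean
#' over the flagged right-hemisphere regions.
#'
#' @param betas Data frame with `region_id` and `beta`.
#' @param atlas Validated atlas.
#' @param roi_set `"network"` (all language ROIs) or `"hubs"`.
#' @return The left-minus-right asymmetry in contrast units.
#' @export
task_asymmetry <- function(betas, atlas, roi_set = c("network", "hubs")) {
  roi_set <- match.arg(roi_set)
  flag <- if (roi_set == "network") atlas$is_language_roi else atlas$is_hub
  b <- betas$beta[match(atlas$region_id, betas$region_id)]
  if (anyNA(b[flag])) {
    stop_langlat("betas missing for flagged regions", "langlat_feature_error")
  }
  left <- flag & atlas$hemisphere == "L"
  right <- flag & atlas$hemisphere == "R"
  if (!any(left) || !any(right)) {
    stop_langlat(paste0("roi set '", roi_set,
                        "' is empty in one hemisphere"),
                 "langlat_feature_error")
  }
  mean(b[left]) - mean(b[right])
}

#' Intra-hemispheric strength sum and asymmetry of the language network
#'
#' Per language ROI, strength is the sum of its r-scale connectivity to
#' the other language ROIs of the same hemisphere (self excluded).
#' Strengths are averaged within each hemisphere; the sum and the
#' left-minus-right difference of the two hemispheric averages are
#' returned.
#'
#' @param conn A [build_connectivity()] result.
#' @param atlas Validated atlas.
#' @return Named numeric: `strength_sum`, `strength_asym` (r units).
#' @export
strength_metrics <- function(conn, atlas) {
  means <- vapply(c("L", "R"), function(h) {
    ids <- atlas$region_id[atlas$is_language_roi & atlas$hemisphere == h]
    if (length(ids) < 2) {
      stop_langlat(paste0("fewer than 2 language ROIs in hemisphere ", h),
                   "langlat_feature_error")
    }
    idx <- conn_index(conn, ids)
    sub <- conn$values[idx, idx, drop = FALSE]
    mean(rowSums(sub))   # diagonal already 0
  }, numeric(1))
  c(strength_sum = unname(means["L"] + means["R"]),
    strength_asym = unname(means["L"] - means["R"]))
}

#' Homotopic inter-hemispheric connectivity of the language network
#'
#' Mean Fisher-z connectivity over the homotopic language region pairs.
#'
#' @param conn A [build_connectivity()] result.
#' @param atlas Validated atlas.
#' @return The mean homotopic z value (Fisher-z units).
#' @export
homotopic_connectivity <- function(conn, atlas) {
  lang_l <- atlas[atlas$is_language_roi & atlas$hemisphere == "L", ]
  if (nrow(lang_l) == 0) {
    stop_langlat("no language ROIs in left hemisphere", "langlat_feature_error")
  }
  idx_l <- conn_index(conn, lang_l$region_id)
  idx_r <- conn_index(conn, lang_l$homotopic_partner)
  mean(conn$z_values[cbind(idx_l, idx_r)])
}

#' Compute the five language lateralization metrics for one subject
#'
#' Composes [task_asymmetry()] (network and hub level),
#' [strength_metrics()] and [homotopic_connectivity()] into the
#' five-feature vector that defines the language-network organization of a
#' subject: `beta_network_asym`, `beta_hubs_asym`, `interhemi_rz`,
#' `strength_sum`, `strength_asym`.
#'
#' @param subject List with `subject_id`, `scans` (list of region-by-time
#'   matrices) and `task_betas` (data frame `region_id`, `beta`).
#' @param atlas Validated atlas.
#' @param conn Optional precomputed [build_connectivity()] result.
#' @return One-row tibble with `subject_id` and the five metrics.
#' @export
compute_language_features <- function(subject, atlas, conn = NULL) {
  conn <- conn %||% build_connectivity(subject$scans)
  strength <- strength_metrics(conn, atlas)
  tibble::tibble(
    subject_id = subject$subject_id %||% NA_character_,
    beta_network_asym = task_asymmetry(subject$task_betas, atlas, "network"),
    beta_hubs_asym = task_asymmetry(subject$task_betas, atlas, "hubs"),
    interhemi_rz = homotopic_connectivity(conn, atlas),
    strength_sum = strength[["strength_sum"]],
    strength_asym = strength[["strength_asym"]]
  )
}

#' Compute language features for every subject of a cohort
#'
#' @param cohort A `langlat_cohort`.
#' @return Tibble with one row per subject and the five metrics.
#' @export
compute_features <- function(cohort) {
  purrr::map_dfr(cohort$subjects, compute_language_features,
                 atlas = cohort$atlas)
}
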