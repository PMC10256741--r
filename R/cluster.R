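#' Standardize feature columns to mean 0, SD 1
#'
#' @param features Data frame; any `subject_id` column is carried through
#'   untouched, every other column must be numeric with positive SD.
#' @return Tibble with standardized columns.
#' @export
standardize_features <- function(features) {
  features <- tibble::as_tibble(features)
  num_cols <- setdiff(names(features), "subject_id")
  if (nrow(features) < 2) {
    stop_langlat("need at least 2 rows to standardize", "langlat_cluster_error")
  }
  for (nm in num_cols) {
    s <- sd(features[[nm]])
    if (!is.finite(s) || s == 0) {
      stop_langlat(paste0("feature '", nm, "' is constant"),
                   "langlat_cluster_error")
    }
    features[[nm]] <- (features[[nm]] - mean(features[[nm]])) / s
  }
  features
}

feature_matrix <- function(features) {
  as.matrix(features[, setdiff(names(features), "subject_id"), drop = FALSE])
}

#' Ward agglomerative clustering of subjects
#'
#' Builds the full agglomeration tree with Euclidean distance and Ward's
#' minimum-variance criterion (Ward.D2 variant: squared distances inside
#' the Lance-Williams update, merge heights in distance units) and cuts it
#' at `k` clusters.
#'
#' @param standardized Standardized feature table (see
#'   [standardize_features()]).
#' @param k Number of clusters, `1 <= k <= n`.
#' @return A `langlat_clust` object with `labels`, `merge_heights`, `k`,
#'   the `hclust` tree, and (after [label_groups()]) `group_names`.
#' @export
ward_cluster <- function(standardized, k = 3) {
  x <- feature_matrix(standardized)
  n <- nrow(x)
  if (k < 1 || k > n) {
    stop_langlat("k must be between 1 and the number of subjects",
                 "langlat_cluster_error")
  }
  hc <- hclust(dist(x), method = "ward.D2")
  labels <- cutree(hc, k = k)
  structure(list(
    labels = unname(labels),
    subject_id = standardized[["subject_id"]],
    merge_heights = hc$height,
    k = as.integer(k),
    tree = hc,
    group_names = NULL
  ), class = "langlat_clust")
}

#' @export
print.langlat_clust <- function(x, ...) {
  cat("<langlat_clust> k = ", x$k, ", n = ", length(x$labels), "\n", sep = "")
  if (!is.null(x$group_names)) {
    tab <- table(x$group_names[x$labels])
    cat(paste0("  ", names(tab), ": ", tab, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Name the three clusters by task-asymmetry ranking
#'
#' Clusters are ranked by their mean `beta_network_asym` in the raw
#' feature table: highest becomes `strong_typical`, middle
#' `mild_typical`, lowest `atypical`. Ties are broken by the mean
#' `beta_hubs_asym`. If the lowest cluster's mean asymmetry is not
#' negative it is still named atypical and a warning is recorded.
#'
#' @param result A `langlat_clust` with `k == 3`.
#' @param features The raw (unstandardized) feature table in the same row
#'   order.
#' @return The `langlat_clust` with `group_names` filled and a
#'   `phenotype` per-subject vector.
#' @export
label_groups <- function(result, features) {
  if (result$k != 3) {
    stop_langlat("group naming is defined only for the 3-cluster solution",
                 "langlat_cluster_error")
  }
  means <- vapply(1:3, function(c) {
    mean(features$beta_network_asym[result$labels == c])
  }, numeric(1))
  tie_break <- vapply(1:3, function(c) {
    mean(features$beta_hubs_asym[result$labels == c])
  }, numeric(1))
  ord <- order(means, tie_break, decreasing = TRUE)
  group_names <- character(3)
  group_names[ord] <- PHENOTYPE_LEVELS
  if (means[ord[3]] >= 0) {
    warn("lowest cluster's mean network asymmetry is not negative; it is still named 'atypical'")
  }
  result$group_names <- group_names
  result$phenotype <- group_names[result$labels]
  result
}

#' Bootstrap stability of the clustering by cluster count
#'
#' For each `k`, subjects are resampled with replacement `n_boot` times,
#' re-clustered, and each full-data cluster is matched to its best
#' bootstrap counterpart by the Jaccard index over the resampled subjects.
#' The score per `k` is the mean best Jaccard across clusters and
#' replicates (an ordinary-bootstrap analogue of multiscale bootstrap
#' cluster support).
#'
#' @param standardized Standardized feature table.
#' @param k_range Integer vector of cluster counts to assess.
#' @param n_boot Bootstrap replicates (>= 100 recommended).
#' @param seed RNG seed; the same seed reproduces identical scores.
#' @return Tibble with `k` and `stability`.
#' @export
cluster_stability <- function(standardized, k_range = 2:4, n_boot = 100,
                              seed = 1L) {
  x <- feature_matrix(standardized)
  n <- nrow(x)
  if (any(k_range < 2) || any(k_range > n - 1)) {
    stop_langlat("k_range must lie in [2, n - 1]", "langlat_cluster_error")
  }
  full <- lapply(k_range, function(k) cutree(hclust(dist(x), "ward.D2"), k))
  names(full) <- as.character(k_range)
  set.seed(seed)
  scores <- matrix(NA_real_, n_boot, length(k_range))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    uniq <- unique(idx)
    hc_b <- hclust(dist(x[uniq, , drop = FALSE]), "ward.D2")
    for (j in seq_along(k_range)) {
      k <- k_range[j]
      if (length(uniq) <= k) next
      lab_b <- cutree(hc_b, k)
      lab_f <- full[[j]][uniq]
      jac <- vapply(unique(lab_f), function(c) {
        a <- lab_f == c
        max(vapply(unique(lab_b), function(d) {
          b2 <- lab_b == d
          sum(a & b2) / sum(a | b2)
        }, numeric(1)))
      }, numeric(1))
      scores[b, j] <- mean(jac)
    }
  }
  tibble::tibble(k = as.integer(k_range),
                 stability = colMeans(scores, na.rm = TRUE))
}

#' Tidy per-subject cluster assignments
#'
#' @param x A `langlat_clust`.
#' @param ... Unused.
#' @return Tibble with `subject_id` (if known), `cluster` and `phenotype`.
#' @method tidy langlat_clust
#' @export
tidy.langlat_clust <- function(x, ...) {
  out <- tibble::tibble(cluster = x$labels)
  if (!is.null(x$subject_id)) {
    out <- dplyr::bind_cols(tibble::tibble(subject_id = x$subject_id), out)
  }
  if (!is.null(x$group_names)) out$phenotype <- x$group_names[x$labels]
  out
}

#' One-row clustering summary
#'
#' @param x A `langlat_clust`.
#' @param ... Unused.
#' @return Tibble with `k`, `n`, and the final merge height.
#' @method glance langlat_clust
#' @export
glance.langlat_clust <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$labels),
                 max_merge_height = max(x$merge_heights))
}
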