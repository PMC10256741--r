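#' Configuration for connectivity gradient estimation
#'
#' @param sparsity Fraction of each row set to zero (default 0.9, i.e. the
#'   top 10% of connections per region retained).
#' @param n_components Number of gradients to retain.
#' @param diffusion_alpha Anisotropic normalization exponent.
#' @param diffusion_time Diffusion time; 0 selects the multiscale
#'   `lambda / (1 - lambda)` scaling.
#' @param align_iterations Procrustes template-refresh iterations.
#' @param scale_range Min-max normalization range.
#' @return A `langlat_gradient_config` list.
#' @export
gradient_config <- function(sparsity = 0.9, n_components = 3,
                            diffusion_alpha = 0.5, diffusion_time = 0,
                            align_iterations = 10,
                            scale_range = c(0, 100)) {
  retained <- 1 - sparsity
  if (retained <= 0 || retained > 1) {
    stop_langlat("sparsity must be in [0, 1)", "langlat_gradient_error")
  }
  if (n_components < 1) {
    stop_langlat("n_components must be >= 1", "langlat_gradient_error")
  }
  structure(list(sparsity = sparsity, retained = retained,
                 n_components = as.integer(n_components),
                 diffusion_alpha = diffusion_alpha,
                 diffusion_time = diffusion_time,
                 align_iterations = as.integer(align_iterations),
                 scale_range = scale_range),
            class = "langlat_gradient_config")
}

#' Row-wise sparsification of a connectivity matrix
#'
#' Keeps, per row, the `ceiling(retained * (n - 1))` largest off-diagonal
#' values by signed value and zeroes everything else (including the
#' diagonal). Ties at the cutoff keep the lowest column index. The output
#' is generally asymmetric.
#'
#' @param matrix Square numeric matrix.
#' @param retained Fraction of off-diagonal entries kept per row, in
#'   `(0, 1]`.
#' @return Sparsified matrix of the same dimensions.
#' @export
sparsify_rows <- function(matrix, retained = 0.1) {
  if (nrow(matrix) != ncol(matrix)) {
    stop_langlat("matrix must be square", "langlat_gradient_error")
  }
  if (retained <= 0 || retained > 1) {
    stop_langlat("retained fraction must be in (0, 1]", "langlat_gradient_error")
  }
  n <- nrow(matrix)
  m <- ceiling(retained * (n - 1))
  out <- array(0, dim(matrix), dimnames = dimnames(matrix))
  for (i in seq_len(n)) {
    vals <- matrix[i, ]
    vals[i] <- -Inf
    keep <- order(-vals, seq_len(n))[seq_len(m)]
    out[i, keep] <- matrix[i, keep]
  }
  out
}

#' Normalized-angle affinity between matrix rows
#'
#' `s_ij = 1 - acos(cosine(row_i, row_j)) / pi`; symmetric with unit
#' diagonal; identical rows map to 1, orthogonal rows to 0.5,
#' anti-parallel rows to 0.
#'
#' @param matrix Numeric matrix; no row may be all zero.
#' @return Symmetric similarity matrix.
#' @export
normalized_angle_affinity <- function(matrix) {
  norms <- sqrt(rowSums(matrix^2))
  if (any(norms == 0)) {
    offender <- (rownames(matrix) %||%
                   as.character(seq_len(nrow(matrix))))[which(norms == 0)[1]]
    stop_langlat(paste0("region ", offender, " has an all-zero row"),
                 "langlat_gradient_error")
  }
  cosine <- tcrossprod(matrix / norms)
  cosine <- pmin(pmax(cosine, -1), 1)
  s <- 1 - acos(cosine) / pi
  s <- (s + t(s)) / 2
  diag(s) <- 1
  if (!is.null(rownames(matrix))) {
    dimnames(s) <- list(rownames(matrix), rownames(matrix))
  }
  s
}

# Connectedness of the positive affinity graph (simple BFS).
affinity_connected <- function(s) {
  n <- nrow(s)
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue) > 0) {
    i <- queue[1]
    queue <- queue[-1]
    nb <- which(s[i, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Diffusion map embedding of an affinity matrix
#'
#' Applies the anisotropic normalization `W = D^-alpha S D^-alpha`, forms
#' the transition operator `P = Dw^-1 W`, extracts its top nontrivial
#' eigenvectors (the trivial constant eigenvector is dropped) through the
#' symmetric conjugate of `P`, and scales each component by
#' `lambda / (1 - lambda)` (diffusion time 0, multiscale) or `lambda^t`.
#' Variance explained is `lambda_i^2 / sum(lambda_j^2)` over the
#' nontrivial spectrum.
#'
#' @param affinity Symmetric nonnegative matrix with a connected positive
#'   graph.
#' @param config A [gradient_config()].
#' @return A `langlat_gradients` object with `values` (region x
#'   component), `eigenvalues` and `variance_explained`.
#' @export
diffusion_embedding <- function(affinity, config = gradient_config()) {
  if (!isTRUE(all.equal(affinity, t(affinity), tolerance = 1e-10))) {
    stop_langlat("affinity matrix must be symmetric", "langlat_gradient_error")
  }
  if (any(affinity < 0)) {
    stop_langlat("affinity matrix must be nonnegative", "langlat_gradient_error")
  }
  if (!affinity_connected(affinity)) {
    stop_langlat("affinity graph is disconnected", "langlat_gradient_error")
  }
  n <- nrow(affinity)
  d <- rowSums(affinity)
  w <- affinity / outer(d^config$diffusion_alpha, d^config$diffusion_alpha)
  dw <- rowSums(w)
  m <- w / outer(sqrt(dw), sqrt(dw))
  m <- (m + t(m)) / 2
  eg <- eigen(m, symmetric = TRUE)
  lambda <- eg$values
  # right eigenvectors of P
  u <- eg$vectors / sqrt(dw)
  # trivial component: lambda = 1, constant eigenvector; drop it
  lambda_nt <- lambda[-1]
  u_nt <- u[, -1, drop = FALSE]
  nc <- min(config$n_components, n - 1)
  lam <- lambda_nt[seq_len(nc)]
  scale_fac <- if (config$diffusion_time == 0) lam / (1 - lam)
               else lam^config$diffusion_time
  values <- sweep(u_nt[, seq_len(nc), drop = FALSE], 2, scale_fac, "*")
  rownames(values) <- rownames(affinity)
  colnames(values) <- paste0("G", seq_len(nc))
  structure(list(
    values = values,
    eigenvalues = lam,
    variance_explained = lam^2 / sum(lambda_nt^2)
  ), class = "langlat_gradients")
}

#' @export
print.langlat_gradients <- function(x, ...) {
  cat("<langlat_gradients> ", nrow(x$values), " regions x ",
      ncol(x$values), " components; variance explained: ",
      paste0(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Orthogonal Procrustes alignment of one embedding to a template
#'
#' Finds the orthogonal matrix (rotation or reflection, no scaling or
#' translation) minimizing the Frobenius distance `||X Q - T||` and
#' applies it.
#'
#' @param individual Region-by-component matrix or `langlat_gradients`.
#' @param template Matrix of the same dimensions.
#' @return The aligned matrix (or `langlat_gradients` with aligned
#'   `values`).
#' @export
procrustes_align <- function(individual, template) {
  x <- if (inherits(individual, "langlat_gradients")) individual$values
       else individual
  tm <- if (inherits(template, "langlat_gradients")) template$values
        else template
  if (!all(dim(x) == dim(tm))) {
    stop_langlat("individual and template dimensions differ",
                 "langlat_gradient_error")
  }
  s <- svd(crossprod(x, tm))
  q <- s$u %*% t(s$v)
  aligned <- x %*% q
  dimnames(aligned) <- dimnames(x)
  if (inherits(individual, "langlat_gradients")) {
    individual$values <- aligned
    individual
  } else {
    aligned
  }
}

#' Min-max normalization of gradient values
#'
#' Linearly maps each component onto `range` using the whole-brain
#' (both-hemisphere) minimum and maximum.
#'
#' @param values Region-by-component matrix.
#' @param range Target range, default `c(0, 100)`.
#' @return Scaled matrix.
#' @export
minmax_scale <- function(values, range = c(0, 100)) {
  apply_names <- dimnames(values)
  out <- apply(values, 2, function(v) {
    lo <- min(v); hi <- max(v)
    if (hi <= lo) {
      stop_langlat("constant gradient component cannot be min-max scaled",
                   "langlat_gradient_error")
    }
    range[1] + (v - lo) / (hi - lo) * (range[2] - range[1])
  })
  dimnames(out) <- apply_names
  out
}

# Embed one connectivity matrix: sparsify -> normalized angle -> diffusion.
embed_connectivity <- function(conn_values, config) {
  sp <- sparsify_rows(conn_values, retained = config$retained)
  aff <- normalized_angle_affinity(sp)
  diffusion_embedding(aff, config)
}

# Fix template component signs against a reference vector (e.g. the
# region order along the association axis): each component is flipped so
# its correlation with the reference is nonnegative; zero-correlation
# components make the largest-magnitude loading positive.
fix_component_signs <- function(gradients, reference = NULL) {
  v <- gradients$values
  for (j in seq_len(ncol(v))) {
    s <- if (!is.null(reference)) sum(v[, j] * (reference - mean(reference)))
         else 0
    if (s == 0) s <- v[which.max(abs(v[, j])), j]
    if (s < 0) v[, j] <- -v[, j]
  }
  gradients$values <- v
  gradients
}

#' Estimate aligned, normalized gradients for every subject of a cohort
#'
#' Per subject, the whole-cortex connectivity matrix (z-averaged across
#' scans) is sparsified, converted to a normalized-angle affinity, and
#' embedded by diffusion maps. The group template is the embedding of the
#' cohort-mean connectivity matrix (z-averaged across subjects, then
#' back-transformed); individual embeddings are aligned to it by
#' orthogonal Procrustes rotation, with the template refreshed as the
#' mean of the aligned embeddings over `align_iterations` rounds.
#' Finally each subject's gradients are min-max scaled over the whole
#' brain.
#'
#' @param cohort A `langlat_cohort` (or list with `subjects`, `atlas`).
#' @param config A [gradient_config()].
#' @param conns Optional precomputed list of [build_connectivity()]
#'   results, one per subject.
#' @return A list: `subject_gradients` (named list of scaled matrices),
#'   `template` (`langlat_gradients`), `variance_explained` (template
#'   spectrum fractions).
#' @export
compute_gradients <- function(cohort, config = gradient_config(),
                              conns = NULL) {
  atlas <- cohort$atlas
  conns <- conns %||% purrr::map(cohort$subjects,
                                 function(s) build_connectivity(s$scans))
  z_mean <- Reduce(`+`, purrr::map(conns, "z_values")) / length(conns)
  group_conn <- tanh(z_mean)
  diag(group_conn) <- 0
  template <- embed_connectivity(group_conn, config)
  reference <- seq_len(nrow(atlas)) * 0
  # association axis reference: within-hemisphere position
  for (h in c("L", "R")) {
    idx <- which(atlas$hemisphere == h)
    reference[idx] <- seq_along(idx)
  }
  template <- fix_component_signs(template, reference)

  raw <- purrr::map(conns, function(cn) {
    embed_connectivity(cn$values, config)$values
  })
  tmpl_vals <- template$values
  aligned <- raw
  for (it in seq_len(config$align_iterations)) {
    aligned <- purrr::map(raw, procrustes_align, template = tmpl_vals)
    tmpl_vals <- Reduce(`+`, aligned) / length(aligned)
  }
  scaled <- purrr::map(aligned, minmax_scale, range = config$scale_range)
  names(scaled) <- names(cohort$subjects)
  list(subject_gradients = scaled, template = template,
       variance_explained = template$variance_explained)
}

#' Per-network hemispheric gradient asymmetry for one subject
#'
#' For every network and gradient component: mean gradient value over the
#' network's left-hemisphere regions minus the mean over its
#' right-hemisphere regions, in normalized gradient units.
#'
#' @param gradients Region-by-component matrix (rownames = region ids) or
#'   `langlat_gradients`.
#' @param atlas Validated atlas; every network must appear in both
#'   hemispheres.
#' @return Tibble with `network`, `gradient`, `asymmetry`.
#' @export
network_gradient_asymmetry <- function(gradients, atlas) {
  v <- if (inherits(gradients, "langlat_gradients")) gradients$values
       else gradients
  idx <- match(as.character(atlas$region_id), rownames(v))
  if (anyNA(idx)) {
    stop_langlat("gradient values missing for atlas regions",
                 "langlat_gradient_error")
  }
  purrr::map_dfr(unique(atlas$network), function(net) {
    li <- idx[atlas$network == net & atlas$hemisphere == "L"]
    ri <- idx[atlas$network == net & atlas$hemisphere == "R"]
    if (length(li) == 0 || length(ri) == 0) {
      stop_langlat(paste0("network '", net,
                          "' is absent from one hemisphere"),
                   "langlat_gradient_error")
    }
    tibble::tibble(
      network = net,
      gradient = colnames(v) %||% paste0("G", seq_len(ncol(v))),
      asymmetry = unname(colMeans(v[li, , drop = FALSE]) -
                           colMeans(v[ri, , drop = FALSE]))
    )
  })
}

#' Network gradient asymmetries for a whole cohort
#'
#' @param gradient_fit Result of [compute_gradients()].
#' @param atlas Validated atlas.
#' @return Tibble with `subject_id`, `network`, `gradient`, `asymmetry`.
#' @export
cohort_gradient_asymmetry <- function(gradient_fit, atlas) {
  purrr::imap_dfr(gradient_fit$subject_gradients, function(g, id) {
    dplyr::mutate(network_gradient_asymmetry(g, atlas),
                  subject_id = id, .before = 1)
  })
}
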