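# Independent oracles and fixture builders. Everything here is coded from
# first principles, separately from the package implementation.

# Hand-coded Pearson correlation via raw sums.
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - sum(a) * sum(b) / n
  den <- sqrt((sum(a^2) - sum(a)^2 / n) * (sum(b^2) - sum(b)^2 / n))
  num / den
}

# Reference for the scan-averaged connectivity matrix: per-scan Pearson by
# explicit sums, clip, atanh, average in z, tanh back.
oracle_connectivity <- function(scans, clip = 1e-7) {
  p <- nrow(scans[[1]])
  z <- matrix(0, p, p)
  for (x in scans) {
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (i != j) {
          r <- oracle_pearson(x[i, ], x[j, ])
          r <- max(min(r, 1 - clip), -(1 - clip))
          z[i, j] <- z[i, j] + atanh(r)
        }
      }
    }
  }
  z <- z / length(scans)
  list(z = z, r = tanh(z) * (1 - diag(p)))
}

# O(n^3) Lance-Williams agglomeration with Ward.D2 coefficients; returns
# the sequence of merge heights (distance units).
oracle_ward_heights <- function(x) {
  n <- nrow(x)
  D <- as.matrix(dist(x))^2
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1, n)
  heights <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    idx <- which(active)
    bestv <- Inf
    bi <- bj <- NA
    for (i in idx) {
      for (j in idx) {
        if (j > i && D[i, j] < bestv) {
          bestv <- D[i, j]
          bi <- i
          bj <- j
        }
      }
    }
    heights[s] <- sqrt(bestv)
    for (k in idx) {
      if (k != bi && k != bj) {
        newd <- ((size[bi] + size[k]) * D[bi, k] +
                   (size[bj] + size[k]) * D[bj, k] -
                   size[k] * D[bi, bj]) /
          (size[bi] + size[bj] + size[k])
        D[bi, k] <- D[k, bi] <- newd
      }
    }
    size[bi] <- size[bi] + size[bj]
    active[bj] <- FALSE
    D[bj, ] <- D[, bj] <- Inf
  }
  heights
}

# Dense reference for the diffusion-map pipeline: explicit anisotropic
# normalization, nonsymmetric eigendecomposition of the transition matrix,
# dw-weighted normalization of the eigenvectors and multiscale scaling.
oracle_diffusion <- function(aff, alpha = 0.5, n_comp = 3) {
  d <- rowSums(aff)
  w <- aff / outer(d^alpha, d^alpha)
  dw <- rowSums(w)
  p <- sweep(w, 1, dw, "/")
  e <- eigen(p)
  ord <- order(Re(e$values), decreasing = TRUE)
  vals <- Re(e$values)[ord]
  vecs <- Re(e$vectors)[, ord, drop = FALSE]
  lam <- vals[seq_len(n_comp) + 1]
  comps <- vecs[, seq_len(n_comp) + 1, drop = FALSE]
  for (j in seq_len(n_comp)) {
    q <- comps[, j]
    q <- q / sqrt(sum(q^2 * dw))      # dw-weighted unit norm
    comps[, j] <- q * lam[j] / (1 - lam[j])
  }
  list(values = comps, eigenvalues = lam)
}

# Row sparsification reimplemented directly with sort().
oracle_sparsify <- function(mat, retained) {
  n <- nrow(mat)
  m <- ceiling(retained * (n - 1))
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    v <- mat[i, -i]
    cutoff <- sort(v, decreasing = TRUE)[m]
    keep <- setdiff(which(mat[i, ] >= cutoff), i)
    if (length(keep) > m) {   # ties at the cutoff: lowest column indices
      at_cut <- keep[mat[i, keep] == cutoff]
      above <- keep[mat[i, keep] > cutoff]
      keep <- c(above, sort(at_cut)[seq_len(m - length(above))])
    }
    out[i, keep] <- mat[i, keep]
  }
  dimnames(out) <- dimnames(mat)
  out
}

# Normalized angle affinity by explicit loops.
oracle_affinity <- function(mat) {
  n <- nrow(mat)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      cs <- sum(mat[i, ] * mat[j, ]) /
        (sqrt(sum(mat[i, ]^2)) * sqrt(sum(mat[j, ]^2)))
      s[i, j] <- 1 - acos(max(min(cs, 1), -1)) / pi
    }
  }
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- dimnames(mat)
  s
}

# Compare two component matrices up to per-column sign.
max_abs_diff_up_to_sign <- function(a, b) {
  max(vapply(seq_len(ncol(a)), function(j) {
    min(max(abs(a[, j] - b[, j])), max(abs(a[, j] + b[, j])))
  }, numeric(1)))
}

# Dense multivariate-normal log-likelihood for the polygenic model.
oracle_dense_loglik <- function(y, X, K, sigma2_g, sigma2_e, beta) {
  n <- length(y)
  V <- sigma2_g * K + sigma2_e * diag(n)
  ch <- chol(V)
  r <- y - as.numeric(X %*% beta)
  z <- backsolve(ch, r, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# Hemisphere-swap a subject: each region takes its homotopic partner's
# time series and task beta.
mirror_subject <- function(subject, atlas) {
  partner <- as.character(atlas$homotopic_partner)
  own <- as.character(atlas$region_id)
  scans <- lapply(subject$scans, function(x) {
    y <- x[partner, , drop = FALSE]
    rownames(y) <- own
    y
  })
  b <- subject$task_betas
  betas <- tibble::tibble(
    region_id = atlas$region_id,
    beta = b$beta[match(atlas$homotopic_partner, b$region_id)]
  )
  list(subject_id = subject$subject_id, scans = scans, task_betas = betas)
}

# Small, fast cohort configuration shared by several tests.
small_cohort_config <- function(...) {
  cohort_config(n_subjects = 40, n_regions_per_hemisphere = 14,
                n_language_rois = 4, ts_length = 120, ...)
}

# A tiny hand-built atlas: 2 homotopic pairs, one language pair.
toy_atlas <- function() {
  validate_atlas(tibble::tibble(
    region_id = c(1L, 2L, 3L, 4L),
    hemisphere = c("L", "L", "R", "R"),
    homotopic_partner = c(3L, 4L, 1L, 2L),
    network = c("default", "visual", "default", "visual"),
    is_language_roi = c(TRUE, FALSE, TRUE, FALSE),
    is_hub = FALSE
  ))
}

# Wrap a plain correlation matrix (diag 0) as a connectivity object.
as_conn <- function(r, ids = NULL) {
  ids <- ids %||% rownames(r) %||% as.character(seq_len(nrow(r)))
  dimnames(r) <- list(ids, ids)
  z <- atanh(r)
  diag(z) <- 0
  structure(list(values = r, z_values = z, n_scans_averaged = 1L),
            class = "langlat_conn")
}
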