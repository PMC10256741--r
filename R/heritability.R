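#' Kinship relatedness matrix (2*Phi) from a pedigree
#'
#' Diagonal 1 (no inbreeding); 1 within MZ pairs; 0.5 between any other
#' members of the same family (DZ twins, full siblings); 0 across
#' families.
#'
#' @param pedigree A validated pedigree.
#' @return A list with `matrix` (n x n) and `subject_id` giving the row
#'   order.
#' @export
kinship_matrix <- function(pedigree) {
  pedigree <- validate_pedigree(pedigree)
  n <- nrow(pedigree)
  K <- matrix(0, n, n)
  same_family <- outer(pedigree$family_id, pedigree$family_id, "==")
  K[same_family] <- 0.5
  is_mz <- pedigree$relation == "MZ_twin"
  if (any(is_mz)) {
    same_pair <- outer(pedigree$twin_pair_id, pedigree$twin_pair_id,
                       function(a, b) !is.na(a) & !is.na(b) & a == b)
    K[same_pair & outer(is_mz, is_mz, "&")] <- 1
  }
  diag(K) <- 1
  dimnames(K) <- list(pedigree$subject_id, pedigree$subject_id)
  list(matrix = K, subject_id = pedigree$subject_id)
}

# Profile log-likelihood of h2 after rotation by the eigenvectors of K.
# ytil, Xtil are rotated; lam the eigenvalues of K.
profile_loglik <- function(h, ytil, Xtil, lam) {
  n <- length(ytil)
  w <- h * lam + (1 - h)
  sw <- sqrt(w)
  yw <- ytil / sw
  Xw <- Xtil / sw
  qr_fit <- qr(Xw)
  rss <- sum(qr.resid(qr_fit, yw)^2)
  sigma2 <- rss / n
  ll <- -0.5 * n * log(2 * pi) - 0.5 * n * log(sigma2) -
    0.5 * sum(log(w)) - 0.5 * n
  list(loglik = ll, sigma2 = sigma2, qr = qr_fit, yw = yw)
}

#' Polygenic variance-components heritability fit
#'
#' Maximum-likelihood fit of `y ~ N(X beta, sigma2_g * K + sigma2_e * I)`
#' where `K` is the kinship relatedness (2*Phi). The model is
#' reparameterized by `h2 = sigma2_g / (sigma2_g + sigma2_e)`; after a
#' one-off eigendecomposition of `K`, each profile-likelihood evaluation
#' is O(n), and `h2` is optimized on `[0, 1)`. The standard error comes
#' from the numeric observed information of the profile log-likelihood;
#' the p-value from the boundary likelihood-ratio test [lrt_h2()].
#'
#' @param y Trait values.
#' @param X Covariate design matrix (intercept included by the caller, or
#'   `NULL` for intercept-only).
#' @param K Kinship object from [kinship_matrix()] or a plain matrix.
#' @param eig Optional precomputed `eigen(K, symmetric = TRUE)`, reusable
#'   across traits on the same pedigree.
#' @return A `langlat_herit` object: `h2`, `se`, `loglik`, `null_loglik`,
#'   `p_value`, `sigma2_g`, `sigma2_e`, `beta`.
#' @export
fit_polygenic <- function(y, X = NULL, K = NULL, eig = NULL) {
  Kmat <- if (is.list(K) && !is.null(K$matrix)) K$matrix else K
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (n <= ncol(X)) {
    stop_langlat("more model columns than observations", "langlat_herit_error")
  }
  if (is.null(eig)) {
    if (is.null(Kmat)) {
      stop_langlat("either K or its eigendecomposition is required",
                   "langlat_herit_error")
    }
    if (max(abs(Kmat[upper.tri(Kmat)])) < 1e-12) {
      stop_langlat("kinship matrix has no related pairs; h2 is not identifiable",
                   "langlat_herit_error")
    }
    eig <- eigen(Kmat, symmetric = TRUE)
  }
  U <- eig$vectors
  lam <- pmax(eig$values, 0)
  ytil <- as.numeric(crossprod(U, y))
  Xtil <- crossprod(U, X)

  obj <- function(h) profile_loglik(h, ytil, Xtil, lam)$loglik
  upper <- 1 - 1e-6
  opt <- optimize(obj, interval = c(0, upper), maximum = TRUE, tol = 1e-8)
  h2 <- opt$maximum
  ll_hat <- opt$objective
  ll_null <- obj(0)
  # boundary handling: accept h2 = 0 when it beats the interior optimum
  if (ll_null >= ll_hat) {
    h2 <- 0
    ll_hat <- ll_null
  }
  prof <- profile_loglik(h2, ytil, Xtil, lam)
  beta <- qr.coef(prof$qr, prof$yw)
  sigma2 <- prof$sigma2

  # observed information of the profile log-likelihood (numeric)
  se <- NA_real_
  step <- 1e-4
  if (h2 > step && h2 < upper - step) {
    d2 <- (obj(h2 + step) - 2 * ll_hat + obj(h2 - step)) / step^2
    if (is.finite(d2) && d2 < 0) se <- sqrt(-1 / d2)
  } else {
    h0 <- max(h2, step)
    d2 <- (obj(min(h0 + step, upper)) - 2 * obj(h0) + obj(h0 - step)) / step^2
    if (is.finite(d2) && d2 < 0) se <- sqrt(-1 / d2)
  }

  fit <- structure(list(
    h2 = h2, se = se, loglik = ll_hat, null_loglik = ll_null,
    sigma2_g = h2 * sigma2, sigma2_e = (1 - h2) * sigma2,
    beta = setNames(as.numeric(beta), colnames(X)), n = n
  ), class = "langlat_herit")
  fit$p_value <- lrt_h2(fit)
  fit
}

#' Boundary likelihood-ratio p-value for h2 > 0
#'
#' The null (`sigma2_g = 0`) lies on the boundary of the parameter space,
#' so the LRT statistic follows a 50:50 mixture of a point mass at zero
#' and a chi-square with 1 df: `p = 0.5 * P(chi2_1 >= T)` for `T > 0` and
#' `p = 1` at `T = 0`.
#'
#' @param fit A `langlat_herit` fit.
#' @param null_loglik Log-likelihood of the null model (defaults to the
#'   value stored in the fit).
#' @return The p-value.
#' @export
lrt_h2 <- function(fit, null_loglik = NULL) {
  ll0 <- null_loglik %||% fit$null_loglik
  T_stat <- 2 * (fit$loglik - ll0)
  if (T_stat < -1e-8) {
    stop_langlat("optimized likelihood below null likelihood; optimization failed",
                 "langlat_herit_error")
  }
  if (T_stat <= 0) return(1)
  0.5 * pchisq(T_stat, df = 1, lower.tail = FALSE)
}

#' @export
print.langlat_herit <- function(x, ...) {
  cat("<langlat_herit> h2 = ", sprintf("%.3f", x$h2),
      " (SE ", ifelse(is.na(x$se), "n/a", sprintf("%.3f", x$se)),
      "), p = ", signif(x$p_value, 3), ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' @method tidy langlat_herit
#' @export
tidy.langlat_herit <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = as.numeric(x$beta))
}

#' @method glance langlat_herit
#' @export
glance.langlat_herit <- function(x, ...) {
  tibble::tibble(h2 = x$h2, se = x$se, p_value = x$p_value,
                 loglik = x$loglik, null_loglik = x$null_loglik, n = x$n)
}

# Design matrix for heritability runs: age, sex, age^2, age x sex,
# age^2 x sex, handedness, intracranial volume.
heritability_design <- function(covariates) {
  cov <- prepare_covariates(covariates)
  cbind(`(Intercept)` = 1,
        age = cov$age, sex = cov$sex01, age2 = cov$age2,
        age_sex = cov$age_sex, age2_sex = cov$age2_sex,
        handedness = as.numeric(cov$handedness_class == "left"),
        icv = cov$icv)
}

#' Heritability grid over networks and gradients, plus the phenotype
#'
#' Estimates h2 of each (gradient, network) asymmetry and of the binary
#' typicality phenotype (typical/atypical as a 0/1 quantitative trait),
#' with the standard covariates and Bonferroni correction over the 7
#' network tests.
#'
#' @param asymmetries Cohort asymmetry table from
#'   [cohort_gradient_asymmetry()].
#' @param phenotype Tibble with `subject_id` and `phenotype`.
#' @param pedigree Validated pedigree covering the subjects.
#' @param covariates Covariate table with `subject_id`.
#' @param n_tests Bonferroni test count per gradient.
#' @return Tibble with `trait`, `gradient`, `network`, `h2`, `se`, `p`,
#'   `p_bonferroni`, `significant`.
#' @export
heritability_grid <- function(asymmetries, phenotype, pedigree, covariates,
                              n_tests = 7) {
  pedigree <- validate_pedigree(pedigree)
  ids <- pedigree$subject_id
  K <- kinship_matrix(pedigree)
  eig <- eigen(K$matrix, symmetric = TRUE)
  cov_ord <- covariates[match(ids, covariates$subject_id), ]
  X <- heritability_design(cov_ord)

  rows <- asymmetries |>
    dplyr::group_by(.data$gradient, .data$network) |>
    dplyr::group_modify(function(d, key) {
      y <- d$asymmetry[match(ids, d$subject_id)]
      fit <- fit_polygenic(y, X, eig = eig)
      tibble::tibble(trait = "gradient_asymmetry", h2 = fit$h2, se = fit$se,
                     p = fit$p_value)
    }) |>
    dplyr::ungroup()
  rows$p_bonferroni <- adjust_bonferroni(rows$p, n_tests)

  y_ph <- as.numeric(phenotype$phenotype[match(ids, phenotype$subject_id)] ==
                       "atypical")
  fit_ph <- fit_polygenic(y_ph, X, eig = eig)
  ph_row <- tibble::tibble(gradient = NA_character_, network = NA_character_,
                           trait = "phenotype", h2 = fit_ph$h2,
                           se = fit_ph$se, p = fit_ph$p_value,
                           p_bonferroni = fit_ph$p_value)
  out <- dplyr::bind_rows(rows, ph_row)
  out$significant <- out$p_bonferroni <= 0.05
  out
}
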