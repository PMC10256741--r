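#' ANCOVA for a phenotype effect with the standard covariate structure
#'
#' Fits an ordinary-least-squares linear model of the outcome on the
#' lateralization phenotype, the covariates (age, sex, handedness class,
#' intracranial volume when supplied), and optionally the
#' handedness-by-phenotype interaction. The phenotype main effect is
#' tested with a Type-II F test (respecting marginality in the presence of
#' the interaction). Post-hoc contrasts use pooled-variance two-sided
#' Student's t tests between phenotype levels.
#'
#' @param y Numeric outcome per subject.
#' @param phenotype Factor-like group labels (>= 2 levels).
#' @param covariates Optional data frame, same row order as `y`; columns
#'   `age`, `sex01`, `handedness_class`, `icv` are used when present (see
#'   [prepare_covariates()]).
#' @param interaction Include handedness x phenotype interaction
#'   (requires `handedness_class` among the covariates).
#' @return A `langlat_ancova` object: `f_statistic`, `p_value`, `df`,
#'   `coefficients` table, `posthoc` table, and the underlying `lm` fit.
#' @export
ancova_fit <- function(y, phenotype, covariates = NULL, interaction = TRUE) {
  phenotype <- factor(phenotype)
  if (nlevels(phenotype) < 2) {
    stop_langlat("phenotype needs at least 2 levels", "langlat_stats_error")
  }
  dat <- tibble::tibble(y = y, phenotype = phenotype)
  cov_terms <- character(0)
  if (!is.null(covariates)) {
    for (nm in intersect(c("age", "sex01", "handedness_class", "icv"),
                         names(covariates))) {
      dat[[nm]] <- covariates[[nm]]
      cov_terms <- c(cov_terms, nm)
    }
  }
  rhs <- c("phenotype", cov_terms)
  if (interaction && "handedness_class" %in% cov_terms) {
    rhs <- c(rhs, "handedness_class:phenotype")
  }
  form <- as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  fit <- lm(form, data = dat)
  if (any(is.na(coef(fit)))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    if (all(grepl(":", aliased, fixed = TRUE))) {
      # empty handedness-by-phenotype cells: drop the interaction
      warn(paste0("interaction inestimable (", paste(aliased, collapse = ", "),
                  "); refitting without it"))
      return(ancova_fit(y, phenotype, covariates, interaction = FALSE))
    }
    stop_langlat(paste0("rank-deficient design; aliased columns: ",
                        paste(aliased, collapse = ", ")),
                 "langlat_stats_error")
  }
  an <- car::Anova(fit, type = 2)
  row <- match("phenotype", rownames(an))
  f_stat <- an[row, "F value"]
  p_val <- an[row, "Pr(>F)"]
  df1 <- an[row, "Df"]
  df2 <- an[nrow(an), "Df"]

  lv <- levels(phenotype)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  posthoc <- purrr::map_dfr(pairs, function(pr) {
    tt <- t.test(y[phenotype == pr[1]], y[phenotype == pr[2]],
                 var.equal = TRUE)
    tibble::tibble(
      contrast = paste(pr[1], "-", pr[2]),
      estimate = unname(diff(rev(tt$estimate))),
      t_statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = tt$p.value
    )
  })
  coefs <- tibble::tibble(
    term = names(coef(fit)),
    estimate = unname(coef(fit)),
    std_error = summary(fit)$coefficients[, "Std. Error"],
    t_statistic = summary(fit)$coefficients[, "t value"],
    p_value = summary(fit)$coefficients[, "Pr(>|t|)"]
  )
  structure(list(
    f_statistic = f_stat, p_value = p_val, df = c(df1 = df1, df2 = df2),
    coefficients = coefs, posthoc = posthoc, anova = an, fit = fit
  ), class = "langlat_ancova")
}

#' @export
print.langlat_ancova <- function(x, ...) {
  cat("<langlat_ancova> phenotype F(", x$df[["df1"]], ", ", x$df[["df2"]],
      ") = ", signif(x$f_statistic, 4), ", p = ", signif(x$p_value, 3),
      "\n", sep = "")
  invisible(x)
}

#' @method tidy langlat_ancova
#' @export
tidy.langlat_ancova <- function(x, ...) x$coefficients

#' @method glance langlat_ancova
#' @export
glance.langlat_ancova <- function(x, ...) {
  tibble::tibble(f_statistic = x$f_statistic, p_value = x$p_value,
                 df1 = x$df[["df1"]], df2 = x$df[["df2"]],
                 r_squared = summary(x$fit)$r.squared)
}

#' Tukey's range test over group pairs
#'
#' Pairwise comparisons with studentized-range adjusted p-values,
#' optionally adjusting for covariates in the underlying ANOVA.
#'
#' @param y Numeric outcome.
#' @param groups Group labels; every group needs >= 2 observations.
#' @param covariates Optional data frame of covariate columns entered
#'   before the group factor.
#' @return Tibble with `contrast`, `estimate`, `conf_low`, `conf_high`,
#'   `p_adjusted`.
#' @export
tukey_hsd <- function(y, groups, covariates = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) {
    stop_langlat("need at least 2 groups", "langlat_stats_error")
  }
  if (any(table(groups) < 2)) {
    stop_langlat("every group needs at least 2 observations",
                 "langlat_stats_error")
  }
  dat <- data.frame(y = y, groups = groups)
  rhs <- "groups"
  if (!is.null(covariates) && ncol(covariates) > 0) {
    dat <- cbind(dat, covariates)
    rhs <- paste(c(names(covariates), "groups"), collapse = " + ")
  }
  fit <- aov(as.formula(paste("y ~", rhs)), data = dat)
  # TukeyHSD warns about the (intentionally non-factor) covariate terms
  tk <- suppressWarnings(TukeyHSD(fit, which = "groups"))$groups
  tibble::tibble(
    contrast = rownames(tk),
    estimate = unname(tk[, "diff"]),
    conf_low = unname(tk[, "lwr"]),
    conf_high = unname(tk[, "upr"]),
    p_adjusted = unname(tk[, "p adj"])
  )
}

#' Bonferroni adjustment for a fixed test count
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param n_tests Number of independent tests corrected for (the
#'   network-level analyses use 7).
#' @return `pmin(1, p * n_tests)`.
#' @export
adjust_bonferroni <- function(p, n_tests = 7) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_langlat("p-values must lie in [0, 1]", "langlat_stats_error")
  }
  pmin(1, p * n_tests)
}

#' Phenotype ANCOVA across the five language features
#'
#' Runs [ancova_fit()] for each feature column with Tukey post-hocs over
#' the three phenotype levels.
#'
#' @param features Feature table (five metric columns + `subject_id`).
#' @param phenotype Per-subject phenotype labels (same order).
#' @param covariates Optional prepared covariate table (same order).
#' @return Tibble with one row per (feature, contrast): F, p, Tukey
#'   adjusted p.
#' @export
feature_ancova <- function(features, phenotype, covariates = NULL) {
  metric_cols <- setdiff(names(features), "subject_id")
  purrr::map_dfr(metric_cols, function(nm) {
    fit <- ancova_fit(features[[nm]], phenotype, covariates)
    cov_df <- if (!is.null(covariates)) {
      as.data.frame(covariates[, intersect(c("age", "sex01",
                                             "handedness_class", "icv"),
                                           names(covariates))])
    } else NULL
    tk <- tukey_hsd(features[[nm]], phenotype, cov_df)
    dplyr::mutate(tk, feature = nm, f_statistic = fit$f_statistic,
                  f_p_value = fit$p_value, .before = 1)
  })
}

#' Typicality ANCOVA grid over networks and gradients
#'
#' For each (gradient, network) cell: ANCOVA of the gradient asymmetry on
#' the binary typicality phenotype (strong and mild typical merged) with
#' the standard covariates, a post-hoc two-sided Student's t statistic for
#' typical vs atypical, and a Bonferroni significance flag for the number
#' of networks (7, i.e. raw p <= 0.007 at the 0.05 family level).
#'
#' @param asymmetries Cohort asymmetry table from
#'   [cohort_gradient_asymmetry()].
#' @param phenotype Tibble with `subject_id` and `phenotype`.
#' @param covariates Optional prepared covariate table with `subject_id`.
#' @param n_tests Bonferroni test count per gradient.
#' @return Tibble with one row per (gradient, network): group means,
#'   t statistic, raw p, Bonferroni-corrected significance flag.
#' @export
asymmetry_ancova <- function(asymmetries, phenotype, covariates = NULL,
                             n_tests = 7) {
  dat <- dplyr::left_join(asymmetries, phenotype, by = "subject_id")
  if (!is.null(covariates)) {
    dat <- dplyr::left_join(dat, covariates, by = "subject_id")
  }
  dat$typicality <- ifelse(dat$phenotype == "atypical", "atypical", "typical")
  out <- dat |>
    dplyr::group_by(.data$gradient, .data$network) |>
    dplyr::group_modify(function(d, key) {
      cov_d <- if (!is.null(covariates)) d else NULL
      fit <- ancova_fit(d$asymmetry, d$typicality, cov_d)
      ph <- fit$posthoc[1, ]
      typ <- d$asymmetry[d$typicality == "typical"]
      atyp <- d$asymmetry[d$typicality == "atypical"]
      tibble::tibble(
        mean_typical = mean(typ),
        ci95_typical = 1.96 * sd(typ) / sqrt(length(typ)),
        mean_atypical = mean(atyp),
        ci95_atypical = 1.96 * sd(atyp) / sqrt(length(atyp)),
        f_statistic = fit$f_statistic,
        t_statistic = ph$t_statistic,
        p_value = ph$p_value
      )
    }) |>
    dplyr::ungroup()
  out$p_bonferroni <- adjust_bonferroni(out$p_value, n_tests)
  out$significant <- out$p_bonferroni <= 0.05
  out
}
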