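#' Pipeline configuration
#'
#' Bundles the module configurations, stage toggles, output directory and
#' master seed for [run_pipeline()].
#'
#' @param out_dir Output directory for all stage tables.
#' @param seed Master seed; forwarded into the cohort config.
#' @param cohort A [cohort_config()].
#' @param gradient A [gradient_config()].
#' @param stages Character vector of stages to run, in dependency order
#'   from `simulate`, `features`, `classify`, `gradients`, `asymmetry`,
#'   `ancova`, `heritability`.
#' @param stability Also compute bootstrap cluster stability (slower).
#' @return A `langlat_pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            cohort = cohort_config(seed = seed),
                            gradient = gradient_config(),
                            stages = c("simulate", "features", "classify",
                                       "gradients", "asymmetry", "ancova",
                                       "heritability"),
                            stability = FALSE) {
  known <- c("simulate", "features", "classify", "gradients", "asymmetry",
             "ancova", "heritability")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    stop_langlat(paste0("unknown stage(s): ", paste(bad, collapse = ", ")),
                 "langlat_pipeline_error")
  }
  cohort$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 cohort = cohort, gradient = gradient,
                 stages = known[known %in% stages], stability = stability),
            class = "langlat_pipeline_config")
}

log_stage <- function(stage, msg) {
  inform(sprintf("[langlat] stage=%s %s", stage, msg))
}

require_file <- function(path, needed_by, produced_by) {
  if (!file.exists(path)) {
    stop_langlat(sprintf(
      "stage '%s' needs %s; run stage '%s' first",
      needed_by, basename(path), produced_by), "langlat_pipeline_error")
  }
  path
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order, each reading and
#' writing only documented TSV interfaces under `config$out_dir`:
#' `simulate` writes the cohort, `features` the five-metric table,
#' `classify` the phenotype labels (and optionally stability scores),
#' `gradients` the per-subject network gradient asymmetries, `asymmetry`
#' the typicality ANCOVA grid, `ancova` the feature ANCOVA table, and
#' `heritability` the h2 grid. A `manifest.json` with row counts and the
#' configuration hash is written at the end. Identical configuration and
#' inputs reproduce identical numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list()
  t0 <- Sys.time()

  if ("simulate" %in% config$stages) {
    log_stage("simulate", paste0("seed=", config$seed))
    cohort <- simulate_cohort(config$cohort)
    write_cohort(cohort, dir)
  }

  read_needed_cohort <- function(stage) {
    require_file(file.path(dir, "atlas.tsv"), stage, "simulate")
    read_cohort(dir)
  }

  if ("features" %in% config$stages) {
    log_stage("features", "computing 5 language metrics")
    cohort <- read_needed_cohort("features")
    features <- compute_features(cohort)
    readr::write_tsv(features, file.path(dir, "features.tsv"), progress = FALSE)
  }

  if ("classify" %in% config$stages) {
    f_path <- require_file(file.path(dir, "features.tsv"), "classify",
                           "features")
    features <- readr::read_tsv(f_path, show_col_types = FALSE,
                                progress = FALSE)
    log_stage("classify", paste0("n=", nrow(features)))
    std <- standardize_features(features)
    clust <- label_groups(ward_cluster(std, k = 3), features)
    labels <- tidy(clust)
    readr::write_tsv(labels, file.path(dir, "labels.tsv"), progress = FALSE)
    if (isTRUE(config$stability)) {
      stab <- cluster_stability(std, k_range = 2:4, n_boot = 100,
                                seed = derive_seed(config$seed, 9L))
      readr::write_tsv(stab, file.path(dir, "stability.tsv"), progress = FALSE)
    }
  }

  if ("gradients" %in% config$stages) {
    cohort <- read_needed_cohort("gradients")
    log_stage("gradients", paste0("embedding ", length(cohort$subjects),
                                  " subjects"))
    gfit <- compute_gradients(cohort, config$gradient)
    asym <- cohort_gradient_asymmetry(gfit, cohort$atlas)
    readr::write_tsv(asym, file.path(dir, "gradient_asymmetry.tsv"),
                     progress = FALSE)
    tmpl <- tibble::as_tibble(gfit$template$values, rownames = "region_id")
    tmpl$region_id <- as.integer(tmpl$region_id)
    readr::write_tsv(tmpl, file.path(dir, "gradient_template.tsv"),
                     progress = FALSE)
    spectrum <- tibble::tibble(
      gradient = paste0("G", seq_along(gfit$variance_explained)),
      variance_explained = gfit$variance_explained
    )
    readr::write_tsv(spectrum, file.path(dir, "gradient_spectrum.tsv"),
                     progress = FALSE)
  }

  get_labels <- function(stage) {
    p <- require_file(file.path(dir, "labels.tsv"), stage, "classify")
    readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
  }
  get_covariates <- function(stage) {
    p <- require_file(file.path(dir, "covariates.tsv"), stage, "simulate")
    prepare_covariates(readr::read_tsv(p, show_col_types = FALSE,
                                       progress = FALSE))
  }

  if ("ancova" %in% config$stages) {
    f_path <- require_file(file.path(dir, "features.tsv"), "ancova",
                           "features")
    features <- readr::read_tsv(f_path, show_col_types = FALSE,
                                progress = FALSE)
    labels <- get_labels("ancova")
    cov <- get_covariates("ancova")
    log_stage("ancova", "feature ANCOVA with Tukey post-hocs")
    ord <- match(features$subject_id, labels$subject_id)
    res <- feature_ancova(features, labels$phenotype[ord],
                          cov[match(features$subject_id, cov$subject_id), ])
    readr::write_tsv(res, file.path(dir, "feature_ancova.tsv"),
                     progress = FALSE)
  }

  if ("asymmetry" %in% config$stages) {
    a_path <- require_file(file.path(dir, "gradient_asymmetry.tsv"),
                           "asymmetry", "gradients")
    asym <- readr::read_tsv(a_path, show_col_types = FALSE, progress = FALSE)
    labels <- get_labels("asymmetry")
    cov <- get_covariates("asymmetry")
    log_stage("asymmetry", "typicality ANCOVA grid")
    grid <- asymmetry_ancova(asym, labels[, c("subject_id", "phenotype")],
                             cov)
    readr::write_tsv(grid, file.path(dir, "asymmetry_grid.tsv"),
                     progress = FALSE)
  }

  if ("heritability" %in% config$stages) {
    a_path <- require_file(file.path(dir, "gradient_asymmetry.tsv"),
                           "heritability", "gradients")
    asym <- readr::read_tsv(a_path, show_col_types = FALSE, progress = FALSE)
    labels <- get_labels("heritability")
    p_path <- require_file(file.path(dir, "pedigree.tsv"), "heritability",
                           "simulate")
    pedigree <- read_pedigree(p_path)
    cov_raw <- readr::read_tsv(require_file(file.path(dir, "covariates.tsv"),
                                            "heritability", "simulate"),
                               show_col_types = FALSE, progress = FALSE)
    log_stage("heritability", "variance-components h2 grid")
    h2 <- heritability_grid(asym, labels[, c("subject_id", "phenotype")],
                            pedigree, cov_raw)
    readr::write_tsv(h2, file.path(dir, "heritability.tsv"), progress = FALSE)
  }

  produced <- intersect(
    c("features.tsv", "labels.tsv", "stability.tsv",
      "gradient_asymmetry.tsv", "gradient_template.tsv",
      "gradient_spectrum.tsv", "feature_ancova.tsv", "asymmetry_grid.tsv",
      "heritability.tsv"),
    list.files(dir))
  manifest <- list(
    files = produced,
    rows = lapply(setNames(produced, produced), function(f) {
      nrow(readr::read_tsv(file.path(dir, f), show_col_types = FALSE,
                           progress = FALSE))
    }),
    seed = config$seed,
    stages = config$stages,
    config_hash = rlang::hash(config[c("seed", "cohort", "gradient",
                                       "stages")]),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("done", sprintf("%.1fs", manifest$elapsed_s))
  invisible(manifest)
}

#' Command-line entry point
#'
#' Thin wrapper used by the `exec/langlat` script: subcommands `simulate`,
#' `features`, `classify`, `gradients`, `asymmetry`, `ancova`,
#' `heritability`, `all`, with `--out`, `--seed`, `--subjects`,
#' `--regions` flags.
#'
#' @param args Character vector of command-line arguments.
#' @return The pipeline manifest, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    stop_langlat("usage: langlat <stage|all> --out DIR [--seed N] [--subjects N] [--regions N]",
                 "langlat_pipeline_error")
  }
  cmd <- args[1]
  opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  out <- opt("--out", NULL)
  if (is.null(out)) {
    stop_langlat("--out is required", "langlat_pipeline_error")
  }
  seed <- as.integer(opt("--seed", "1"))
  n <- as.integer(opt("--subjects", "120"))
  regions <- as.integer(opt("--regions", "40"))
  stages <- if (cmd == "all") {
    c("simulate", "features", "classify", "gradients", "asymmetry",
      "ancova", "heritability")
  } else {
    cmd
  }
  cfg <- pipeline_config(
    out_dir = out, seed = seed,
    cohort = cohort_config(n_subjects = n,
                           n_regions_per_hemisphere = regions,
                           seed = seed),
    stages = stages)
  run_pipeline(cfg)
}
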