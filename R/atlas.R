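#' Validate a region atlas table
#'
#' An atlas table has one row per cortical region with columns `region_id`
#' (integer label), `hemisphere` (`"L"` or `"R"`), `homotopic_partner`
#' (the `region_id` of the mirror region in the other hemisphere),
#' `network` (one of the seven canonical network labels), `is_language_roi`
#' and `is_hub` (logical flags). Hemisphere is always explicit; nothing is
#' inferred from region id values.
#'
#' Invariants enforced: homotopic pairing is a bijection between L and R
#' (partner-of-partner is self, hemispheres differ), every hub is a language
#' ROI, both hemispheres contain the same number of language ROIs, and every
#' region carries exactly one known network label.
#'
#' @param atlas A data frame with the six atlas columns.
#' @return The validated atlas as a tibble, invisibly classed
#'   `langlat_atlas`.
#' @export
validate_atlas <- function(atlas) {
  required <- c("region_id", "hemisphere", "homotopic_partner", "network",
                "is_language_roi", "is_hub")
  missing <- setdiff(required, names(atlas))
  if (length(missing) > 0) {
    stop_langlat(paste0("atlas is missing column(s): ",
                        paste(missing, collapse = ", ")),
                 "langlat_atlas_error")
  }
  atlas <- tibble::as_tibble(atlas)
  atlas$region_id <- as.integer(atlas$region_id)
  atlas$homotopic_partner <- as.integer(atlas$homotopic_partner)
  atlas$is_language_roi <- as.logical(atlas$is_language_roi)
  atlas$is_hub <- as.logical(atlas$is_hub)

  if (anyDuplicated(atlas$region_id)) {
    stop_langlat("duplicate region_id in atlas", "langlat_atlas_error")
  }
  if (!all(atlas$hemisphere %in% c("L", "R"))) {
    stop_langlat("hemisphere must be 'L' or 'R'", "langlat_atlas_error")
  }
  bad_net <- setdiff(unique(atlas$network), CANONICAL_NETWORKS)
  if (length(bad_net) > 0) {
    stop_langlat(paste0("unknown network label(s): ",
                        paste(bad_net, collapse = ", ")),
                 "langlat_atlas_error")
  }

  idx <- match(atlas$homotopic_partner, atlas$region_id)
  if (anyNA(idx)) {
    offender <- atlas$region_id[which(is.na(idx))[1]]
    stop_langlat(paste0("region ", offender,
                        " has a homotopic partner absent from the atlas"),
                 "langlat_atlas_error")
  }
  partner_of_partner <- atlas$homotopic_partner[idx]
  bad <- which(partner_of_partner != atlas$region_id)
  if (length(bad) > 0) {
    stop_langlat(paste0("homotopic pairing is not a bijection: region ",
                        atlas$region_id[bad[1]],
                        "'s partner does not point back to it"),
                 "langlat_atlas_error")
  }
  same_hemi <- which(atlas$hemisphere[idx] == atlas$hemisphere)
  if (length(same_hemi) > 0) {
    stop_langlat(paste0("region ", atlas$region_id[same_hemi[1]],
                        " is homotopically paired within its own hemisphere"),
                 "langlat_atlas_error")
  }
  if (any(atlas$is_hub & !atlas$is_language_roi)) {
    offender <- atlas$region_id[which(atlas$is_hub & !atlas$is_language_roi)[1]]
    stop_langlat(paste0("hub region ", offender,
                        " is not flagged as a language ROI"),
                 "langlat_atlas_error")
  }
  n_lang <- table(factor(atlas$hemisphere[atlas$is_language_roi],
                         levels = c("L", "R")))
  if (n_lang[["L"]] != n_lang[["R"]]) {
    stop_langlat("language ROI count differs between hemispheres",
                 "langlat_atlas_error")
  }
  class(atlas) <- c("langlat_atlas", class(atlas))
  atlas
}

#' Read a region atlas from a tab-separated file
#'
#' @param path Path to a TSV file with the six atlas columns described in
#'   [validate_atlas()].
#' @return A validated atlas tibble.
#' @export
read_atlas <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_atlas(tbl)
}

#' Validate a pedigree table
#'
#' A pedigree table has columns `family_id`, `subject_id`, `relation`
#' (`MZ_twin`, `DZ_twin`, `full_sibling` or `singleton`) and `twin_pair_id`
#' (empty/NA for non-twins). Twin pair ids must occur exactly twice, with
#' both members in the same family; subject ids must be unique.
#'
#' @param pedigree A data frame with the pedigree columns.
#' @return The validated pedigree tibble.
#' @export
validate_pedigree <- function(pedigree) {
  required <- c("family_id", "subject_id", "relation")
  missing <- setdiff(required, names(pedigree))
  if (length(missing) > 0) {
    stop_langlat(paste0("pedigree is missing column(s): ",
                        paste(missing, collapse = ", ")),
                 "langlat_pedigree_error")
  }
  pedigree <- tibble::as_tibble(pedigree)
  if (!"twin_pair_id" %in% names(pedigree)) pedigree$twin_pair_id <- NA_character_
  pedigree$family_id <- as.character(pedigree$family_id)
  pedigree$subject_id <- as.character(pedigree$subject_id)
  pedigree$twin_pair_id <- as.character(pedigree$twin_pair_id)

  if (nrow(pedigree) == 0) {
    warn("pedigree is empty")
    class(pedigree) <- c("langlat_pedigree", class(pedigree))
    return(pedigree)
  }
  valid_rel <- c("MZ_twin", "DZ_twin", "full_sibling", "singleton")
  if (!all(pedigree$relation %in% valid_rel)) {
    stop_langlat(paste0("unknown relation value(s): ",
                        paste(setdiff(unique(pedigree$relation), valid_rel),
                              collapse = ", ")),
                 "langlat_pedigree_error")
  }
  if (anyDuplicated(pedigree$subject_id)) {
    stop_langlat("duplicate subject_id in pedigree", "langlat_pedigree_error")
  }
  twins <- pedigree[pedigree$relation %in% c("MZ_twin", "DZ_twin"), ]
  if (nrow(twins) > 0) {
    if (anyNA(twins$twin_pair_id)) {
      stop_langlat("twin rows must carry a twin_pair_id",
                   "langlat_pedigree_error")
    }
    counts <- table(twins$twin_pair_id)
    bad <- names(counts)[counts != 2]
    if (length(bad) > 0) {
      stop_langlat(paste0("twin pair id(s) not occurring exactly twice: ",
                          paste(bad, collapse = ", ")),
                   "langlat_pedigree_error")
    }
    fam_per_pair <- tapply(twins$family_id, twins$twin_pair_id,
                           function(f) length(unique(f)))
    if (any(fam_per_pair != 1)) {
      stop_langlat("members of a twin pair must share a family_id",
                   "langlat_pedigree_error")
    }
    rel_per_pair <- tapply(twins$relation, twins$twin_pair_id,
                           function(r) length(unique(r)))
    if (any(rel_per_pair != 1)) {
      stop_langlat("members of a twin pair must share zygosity",
                   "langlat_pedigree_error")
    }
  }
  class(pedigree) <- c("langlat_pedigree", class(pedigree))
  pedigree
}

#' Read a pedigree from a tab-separated file
#'
#' @param path Path to a TSV with family/subject/relation columns.
#' @return A validated pedigree tibble; an empty file yields an empty
#'   pedigree with a warning.
#' @export
read_pedigree <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  validate_pedigree(tbl)
}

#' Prepare a covariate table for modeling
#'
#' Adds the derived model columns used throughout: `handedness_class`
#' (left-hander when the Edinburgh-style score is below 30, right-hander
#' otherwise), `sex01` (1 for female), `age2`, `age_sex`, `age2_sex`.
#'
#' @param covariates Data frame with per-subject `subject_id`, `age`
#'   (years), `sex` (`"F"`/`"M"` or 0/1), `handedness` (laterality score)
#'   and `icv` (intracranial volume, mm^3).
#' @param handedness_cut Score below which a subject is classed left-handed.
#' @return A tibble with the base and derived columns.
#' @export
prepare_covariates <- function(covariates, handedness_cut = 30) {
  required <- c("subject_id", "age", "sex", "handedness", "icv")
  missing <- setdiff(required, names(covariates))
  if (length(missing) > 0) {
    stop_langlat(paste0("covariates missing column(s): ",
                        paste(missing, collapse = ", ")),
                 "langlat_covariate_error")
  }
  covariates <- tibble::as_tibble(covariates)
  sex01 <- if (is.numeric(covariates$sex)) as.numeric(covariates$sex != 0)
           else as.numeric(covariates$sex %in% c("F", "female", "Female"))
  dplyr::mutate(covariates,
    sex01 = sex01,
    handedness_class = ifelse(.data$handedness < handedness_cut, "left", "right"),
    age2 = .data$age^2,
    age_sex = .data$age * sex01,
    age2_sex = .data$age^2 * sex01
  )
}
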