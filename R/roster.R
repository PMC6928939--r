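#' Subcortical structure roster
#'
#' The default roster of Freesurfer-segmented subcortical structures used as
#' volumetric phenotypes: 22 entries, of which 13 are bilateral (expanding to
#' a left and a right phenotype) and 9 are unilateral, for 35 phenotypes in
#' total.
#'
#' @return A tibble with columns `id` (structure label), `label`
#'   (human-readable description) and `bilateral` (logical).
#' @export
#' @examples
#' r <- roi_roster()
#' nrow(r)                  # 22 structures
#' length(expand_roster(r)) # 35 phenotypes
roi_roster <- function() {
  tibble::tribble(
    ~id,                       ~label,                                   ~bilateral,
    "Accumbens-area",          "nucleus accumbens",                      TRUE,
    "Amygdala",                "amygdala",                               TRUE,
    "Brain-Stem",              "brainstem",                              FALSE,
    "Caudate",                 "caudate nucleus",                        TRUE,
    "CC_Anterior",             "anterior corpus callosum",               FALSE,
    "CC_Central",              "central corpus callosum",                FALSE,
    "CC_Mid_Anterior",         "middle anterior corpus callosum",        FALSE,
    "CC_Mid_Posterior",        "middle posterior corpus callosum",       FALSE,
    "CC_Posterior",            "posterior corpus callosum",              FALSE,
    "CSF",                     "cerebrospinal fluid",                    FALSE,
    "Cerebellum-Cortex",       "cerebellar cortex",                      TRUE,
    "Cerebellum-White-Matter", "cerebellar white matter",                TRUE,
    "Choroid-plexus",          "choroid plexus",                         TRUE,
    "Hippocampus",             "hippocampus proper",                     TRUE,
    "Inf-Lat-Vent",            "temporal horn of lateral ventricle",     TRUE,
    "Lateral-Ventricle",       "lateral ventricle",                      TRUE,
    "Pallidum",                "globus pallidus",                        TRUE,
    "Putamen",                 "putamen",                                TRUE,
    "Thalamus-Proper",         "thalamus proper",                        TRUE,
    "Ventral-DC",              "ventral diencephalon",                   TRUE,
    "X3rd-Ventricle",          "third ventricle",                        FALSE,
    "X4th-Ventricle",          "fourth ventricle",                       FALSE
  )
}

#' Expand a roster into per-hemisphere phenotype ids
#'
#' Bilateral entries emit a left (`.L`) and a right (`.R`) phenotype;
#' unilateral entries emit themselves. Order is stable: roster order, with L
#' before R.
#'
#' @param roster a tibble as returned by [roi_roster()].
#' @return Character vector of phenotype ids.
#' @export
expand_roster <- function(roster = roi_roster()) {
  stopifnot(all(c("id", "bilateral") %in% names(roster)))
  if (anyDuplicated(roster$id)) stop("duplicate roster ids")
  out <- purrr::map2(roster$id, roster$bilateral, function(id, bi) {
    if (bi) paste0(id, c(".L", ".R")) else id
  })
  ids <- purrr::flatten_chr(out)
  if (anyDuplicated(ids)) stop("roster expansion produced duplicate ids")
  ids
}

#' Reference module assignment of the 35 subcortical phenotypes
#'
#' Anatomical partition of the expanded roster into five modules:
#' I limbic system (hippocampus, amygdala, accumbens; 6 phenotypes),
#' II corpus callosum (5), III thalamus-cerebellum-brainstem-pallidum with
#' ventral diencephalon (11), IV basal ganglia neostriatum (caudate, putamen;
#' 4), and V ventricular system / CSF (9). Used as the generator's default
#' ground truth for module-recovery checks.
#'
#' @return Named integer vector: phenotype id -> module number (1..5).
#' @export
reference_module_assignment <- function() {
  lr <- function(x) paste0(x, c(".L", ".R"))
  mods <- list(
    `1` = c(lr("Hippocampus"), lr("Amygdala"), lr("Accumbens-area")),
    `2` = c("CC_Anterior", "CC_Central", "CC_Mid_Anterior",
            "CC_Mid_Posterior", "CC_Posterior"),
    `3` = c(lr("Ventral-DC"), lr("Thalamus-Proper"), lr("Cerebellum-Cortex"),
            lr("Cerebellum-White-Matter"), lr("Pallidum"), "Brain-Stem"),
    `4` = c(lr("Caudate"), lr("Putamen")),
    `5` = c(lr("Choroid-plexus"), lr("Inf-Lat-Vent"), lr("Lateral-Ventricle"),
            "X3rd-Ventricle", "X4th-Ventricle", "CSF")
  )
  assignment <- integer(0)
  for (m in names(mods)) {
    assignment[mods[[m]]] <- as.integer(m)
  }
  # report in roster order
  assignment[expand_roster()]
}

#' Typical raw volumes for the roster phenotypes
#'
#' Order-of-magnitude mean volumes in cubic millimetres used as generator
#' baselines. Values are anatomically plausible scales, not subject-level
#' measurements.
#'
#' @return Named numeric vector over the expanded roster.
#' @keywords internal
reference_mean_volumes <- function() {
  base <- c(
    "Accumbens-area" = 600, "Amygdala" = 1500, "Brain-Stem" = 21000,
    "Caudate" = 3500, "CC_Anterior" = 900, "CC_Central" = 450,
    "CC_Mid_Anterior" = 450, "CC_Mid_Posterior" = 450, "CC_Posterior" = 950,
    "CSF" = 1100, "Cerebellum-Cortex" = 53000,
    "Cerebellum-White-Matter" = 14000, "Choroid-plexus" = 800,
    "Hippocampus" = 3800, "Inf-Lat-Vent" = 600, "Lateral-Ventricle" = 12000,
    "Pallidum" = 1700, "Putamen" = 4800, "Thalamus-Proper" = 6800,
    "Ventral-DC" = 3900, "X3rd-Ventricle" = 1300, "X4th-Ventricle" = 1800
  )
  ids <- expand_roster()
  stems <- sub("\\.(L|R)$", "", ids)
  setNames(base[stems], ids)
}
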