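#' Per-group demographic summary with Welch tests
#'
#' Summarizes continuous demographic/clinical variables per diagnosis group
#' (mean and standard deviation) and compares groups with a Welch two-sample
#' t-test, mirroring the usual cohort-demographics table.
#'
#' @param pheno phenotype tibble with a `diagnosis` column (`"AD"`/`"NC"`).
#' @param vars continuous variables to summarize; defaults to the
#'   intersection of `c("age", "education", "mmse", "cdrsb")` with
#'   `names(pheno)`.
#' @return Tibble: `variable`, `mean_AD`, `sd_AD`, `mean_NC`, `sd_NC`,
#'   `statistic` (Welch t), `p_value`, plus a leading row of group counts.
#' @export
group_summary <- function(pheno,
                          vars = intersect(c("age", "education", "mmse",
                                             "cdrsb"), names(pheno))) {
  stopifnot("diagnosis" %in% names(pheno))
  g_ad <- dplyr::filter(pheno, .data$diagnosis == "AD")
  g_nc <- dplyr::filter(pheno, .data$diagnosis == "NC")
  if (nrow(g_ad) < 2 || nrow(g_nc) < 2) {
    stop("each diagnosis group needs at least 2 samples")
  }
  rows <- purrr::map(vars, function(v) {
    tt <- t.test(g_ad[[v]], g_nc[[v]])
    tibble::tibble(
      variable = v,
      mean_AD = mean(g_ad[[v]]), sd_AD = sd(g_ad[[v]]),
      mean_NC = mean(g_nc[[v]]), sd_NC = sd(g_nc[[v]]),
      statistic = unname(tt$statistic), p_value = tt$p.value
    )
  })
  counts <- tibble::tibble(
    variable = "n", mean_AD = nrow(g_ad), sd_AD = NA_real_,
    mean_NC = nrow(g_nc), sd_NC = NA_real_,
    statistic = NA_real_, p_value = NA_real_
  )
  dplyr::bind_rows(counts, rows)
}
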