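#' Run the full genotype quality-control stage
#'
#' Applies the sample filters in order — call rate, sex check, relatedness —
#' then the variant filters (call rate, HWE, MAF) on the retained samples,
#' and finally windowed LD pruning. Relatedness is estimated on an
#' internally LD-pruned autosomal subset of the post-call-rate data.
#' Because variant statistics are recomputed on the filtered sample set,
#' re-running QC on its own output changes nothing (idempotence).
#'
#' @param G a [genotype_matrix()].
#' @param sample_call_min minimum per-sample call rate (inclusive).
#' @param variant_call_min minimum per-variant call rate (inclusive).
#' @param maf_min minimum minor allele frequency (inclusive).
#' @param hwe_alpha HWE exact-test exclusion threshold (excluded when
#'   p <= `hwe_alpha`).
#' @param ibd_max PI_HAT threshold; one member of each pair above it is
#'   excluded.
#' @param prune_window,prune_step,prune_r2 LD pruning parameters (window
#'   size and step in variants, maximum r-squared).
#' @param sex_check_enabled run the X-heterozygosity sex check (skipped
#'   automatically, with a note in the report, when no X-flagged variants
#'   are present).
#' @return A list of class `qc_result`: `genotypes` (the filtered
#'   [genotype_matrix()]), `report` (a `qc_report`: tibbles of removed
#'   samples and variants with reason codes, plus the thresholds used).
#' @export
run_qc <- function(G,
                   sample_call_min = 0.90, variant_call_min = 0.90,
                   maf_min = 0.10, hwe_alpha = 5e-7, ibd_max = 0.2,
                   prune_window = 50, prune_step = 5, prune_r2 = 0.8,
                   sex_check_enabled = TRUE) {
  stopifnot(inherits(G, "genotype_matrix"))
  thresholds <- list(
    sample_call_min = sample_call_min, variant_call_min = variant_call_min,
    maf_min = maf_min, hwe_alpha = hwe_alpha, ibd_max = ibd_max,
    prune_window = prune_window, prune_step = prune_step, prune_r2 = prune_r2
  )
  removed_samples <- tibble::tibble(id = character(), reason = character(),
                                    value = numeric())

  # 1. sample call rate
  cr <- call_rates(G)
  bad <- dplyr::filter(cr$samples, .data$call_rate < sample_call_min)
  if (nrow(bad)) {
    removed_samples <- dplyr::bind_rows(
      removed_samples,
      tibble::tibble(id = bad$id, reason = "call_rate", value = bad$call_rate)
    )
    G <- subset_genotypes(G, samples = setdiff(G$sample_meta$id, bad$id))
  }

  # 2. sex check
  has_x <- any(G$variant_meta$x_flag)
  if (sex_check_enabled && has_x) {
    sc <- sex_check(G)
    bad <- dplyr::filter(sc, .data$mismatch)
    if (nrow(bad)) {
      removed_samples <- dplyr::bind_rows(
        removed_samples,
        tibble::tibble(id = bad$id, reason = "sex_mismatch",
                       value = bad$x_het_rate)
      )
      G <- subset_genotypes(G, samples = setdiff(G$sample_meta$id, bad$id))
    }
  }

  # 3. relatedness on an LD-pruned autosomal subset
  auto <- G$variant_meta$id[!G$variant_meta$x_flag]
  if (length(auto) >= 2 && nrow(G$dosages) >= 2) {
    G_auto <- subset_genotypes(G, variants = auto)
    pruned <- ld_prune(G_auto, prune_window, prune_step, prune_r2)
    rel <- suppressWarnings(
      relatedness(subset_genotypes(G_auto, variants = pruned)))
    cr_now <- call_rates(G)$samples
    excl <- ibd_exclusions(rel, cr_now, ibd_max)
    if (nrow(excl)) {
      removed_samples <- dplyr::bind_rows(
        removed_samples,
        tibble::tibble(id = excl$id, reason = "ibd", value = excl$pi_hat)
      )
      G <- subset_genotypes(G, samples = setdiff(G$sample_meta$id, excl$id))
    }
  }

  # 4. variant filters on the retained samples
  vf <- variant_filters(G, maf_min = maf_min, hwe_alpha = hwe_alpha,
                        call_min = variant_call_min)
  removed_variants <- vf$removed
  G <- subset_genotypes(G, variants = vf$retained)

  # 5. LD pruning
  kept <- ld_prune(G, prune_window, prune_step, prune_r2)
  pruned_out <- setdiff(G$variant_meta$id, kept)
  if (length(pruned_out)) {
    removed_variants <- dplyr::bind_rows(
      removed_variants,
      tibble::tibble(id = pruned_out, reason = "ld_prune", value = NA_real_)
    )
    G <- subset_genotypes(G, variants = kept)
  }

  report <- structure(
    list(removed_samples = removed_samples,
         removed_variants = removed_variants,
         thresholds = thresholds,
         sex_check_run = sex_check_enabled && has_x),
    class = "qc_report"
  )
  structure(list(genotypes = G, report = report), class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat("  removed samples:", nrow(x$removed_samples), "\n")
  if (nrow(x$removed_samples)) {
    print(table(x$removed_samples$reason))
  }
  cat("  removed variants:", nrow(x$removed_variants), "\n")
  if (nrow(x$removed_variants)) {
    print(table(x$removed_variants$reason))
  }
  invisible(x)
}

#' @export
print.qc_result <- function(x, ...) {
  print(x$report)
  print(x$genotypes)
  invisible(x)
}

#' @rdname run_qc
#' @param x a `qc_report`.
#' @param ... unused.
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$removed_samples, unit = "sample"),
    dplyr::mutate(x$removed_variants, unit = "variant")
  )
}
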