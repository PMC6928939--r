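#' Genotype matrix container
#'
#' Bundles an additive-dosage matrix (samples in rows, variants in columns,
#' values 0/1/2 counting minor alleles, `NA` for missing calls) with
#' per-variant and per-sample metadata. Variant metadata carries chromosome,
#' 1-based physical position, the allele pair, and an `x_flag` marking
#' X-chromosome variants used by the sex check; sample metadata carries the
#' reported sex.
#'
#' @param dosages numeric matrix, samples x variants, entries in \{0, 1, 2\}
#'   or `NA`; must have row and column names.
#' @param variant_meta tibble with columns `id`, `chrom`, `pos`, `a1`, `a2`,
#'   `x_flag`; one row per column of `dosages`, in the same order.
#' @param sample_meta tibble with columns `id` and `reported_sex`
#'   (`"male"`/`"female"`); one row per row of `dosages`, in the same order.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variant_meta, sample_meta) {
  stopifnot(is.matrix(dosages))
  if (is.null(rownames(dosages)) || is.null(colnames(dosages))) {
    stop("`dosages` must have sample row names and variant column names")
  }
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  variant_meta <- tibble::as_tibble(variant_meta)
  sample_meta <- tibble::as_tibble(sample_meta)
  need_v <- c("id", "chrom", "pos", "a1", "a2", "x_flag")
  if (!all(need_v %in% names(variant_meta))) {
    stop("variant_meta needs columns: ", paste(need_v, collapse = ", "))
  }
  if (!all(c("id", "reported_sex") %in% names(sample_meta))) {
    stop("sample_meta needs columns: id, reported_sex")
  }
  if (anyDuplicated(variant_meta$id)) stop("variant ids must be unique")
  if (anyDuplicated(sample_meta$id)) stop("sample ids must be unique")
  if (!identical(colnames(dosages), variant_meta$id)) {
    stop("column names of dosages must equal variant_meta$id")
  }
  if (!identical(rownames(dosages), sample_meta$id)) {
    stop("row names of dosages must equal sample_meta$id")
  }
  if (any(variant_meta$pos < 0)) stop("positions must be nonnegative")
  structure(
    list(dosages = dosages, variant_meta = variant_meta,
         sample_meta = sample_meta),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$dosages))
  cat(sprintf(
    "<genotype_matrix> %d samples x %d variants (%.2f%% missing)\n",
    nrow(x$dosages), ncol(x$dosages),
    100 * n_miss / length(x$dosages)
  ))
  chroms <- unique(x$variant_meta$chrom)
  cat("  chromosomes:", paste(utils::head(chroms, 12), collapse = ", "),
      if (length(chroms) > 12) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by sample and/or variant ids
#'
#' @param G a [genotype_matrix()].
#' @param samples character vector of sample ids to keep (default all).
#' @param variants character vector of variant ids to keep (default all).
#' @return A new `genotype_matrix` restricted to the requested rows/columns,
#'   in the order given.
#' @export
subset_genotypes <- function(G, samples = NULL, variants = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.null(samples)) samples <- G$sample_meta$id
  if (is.null(variants)) variants <- G$variant_meta$id
  if (!all(samples %in% G$sample_meta$id)) stop("unknown sample id(s)")
  if (!all(variants %in% G$variant_meta$id)) stop("unknown variant id(s)")
  genotype_matrix(
    G$dosages[samples, variants, drop = FALSE],
    G$variant_meta[match(variants, G$variant_meta$id), ],
    G$sample_meta[match(samples, G$sample_meta$id), ]
  )
}

#' Minor allele frequencies from observed dosages
#'
#' Computes, per variant, the frequency of the allele counted by the dosage
#' code from non-missing entries only, folded to the minor side.
#'
#' @param G a [genotype_matrix()].
#' @return A tibble with columns `id`, `maf`.
#' @export
allele_freqs <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  p <- colMeans(G$dosages, na.rm = TRUE) / 2
  tibble::tibble(id = G$variant_meta$id, maf = pmin(p, 1 - p))
}
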