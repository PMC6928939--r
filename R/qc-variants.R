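#' Variant-level quality filters
#'
#' Applies the three marker filters in order: call rate, Hardy-Weinberg
#' exact test, minor allele frequency. A variant is retained iff its call
#' rate is at least `call_min`, its HWE exact p-value exceeds `hwe_alpha`
#' (variants at or below the threshold are excluded), and its MAF from
#' non-missing dosages is at least `maf_min`. Each removed variant gets
#' exactly one primary reason: the first failed filter in that order.
#' X-flagged variants are HWE-tested on reported females only (hemizygous
#' male coding would otherwise fail by construction).
#'
#' @param G a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (inclusive).
#' @param hwe_alpha HWE exclusion threshold: excluded when p <= `hwe_alpha`.
#' @param call_min minimum per-variant call rate (inclusive).
#' @return List with `retained` (character vector of variant ids) and
#'   `removed` (tibble `id`, `reason` in call_rate/hwe/maf, `value`).
#' @export
variant_filters <- function(G, maf_min = 0.10, hwe_alpha = 5e-7,
                            call_min = 0.90) {
  stopifnot(inherits(G, "genotype_matrix"))
  dos <- G$dosages
  cr <- colMeans(!is.na(dos))
  maf <- allele_freqs(G)$maf

  females <- G$sample_meta$reported_sex == "female"
  hwe_p <- vapply(seq_len(ncol(dos)), function(j) {
    g <- dos[, j]
    if (G$variant_meta$x_flag[j]) g <- g[females]
    g <- g[!is.na(g)]
    if (length(g) == 0) return(1)
    .hwe_exact_one(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))

  reason <- rep(NA_character_, ncol(dos))
  value <- rep(NA_real_, ncol(dos))
  fail_cr <- cr < call_min
  fail_hwe <- !fail_cr & hwe_p <= hwe_alpha
  fail_maf <- !fail_cr & !fail_hwe & maf < maf_min
  reason[fail_cr] <- "call_rate"; value[fail_cr] <- cr[fail_cr]
  reason[fail_hwe] <- "hwe"; value[fail_hwe] <- hwe_p[fail_hwe]
  reason[fail_maf] <- "maf"; value[fail_maf] <- maf[fail_maf]

  keep <- is.na(reason)
  list(
    retained = G$variant_meta$id[keep],
    removed = tibble::tibble(
      id = G$variant_meta$id[!keep],
      reason = reason[!keep], value = value[!keep]
    )
  )
}

#' Windowed LD pruning of variants
#'
#' Greedy removal of variants in high linkage disequilibrium, after the
#' PLINK `--indep-pairwise` scheme: per chromosome, a sliding window of
#' `window` variants advances by `step`; within a window, while any pair of
#' retained variants has squared dosage correlation above `r2_max`, the pair
#' with the largest r-squared is resolved first (ties by smallest column
#' index) by removing its lower-MAF member (MAF ties remove the later
#' position). Deterministic.
#'
#' @param G a [genotype_matrix()]; variants are processed in (chromosome,
#'   position) order.
#' @param window window size in variants.
#' @param step window advance in variants.
#' @param r2_max maximum tolerated squared correlation (strict `>` removes).
#' @return Character vector of retained variant ids, in input order.
#' @export
ld_prune <- function(G, window = 50, step = 5, r2_max = 0.8) {
  stopifnot(inherits(G, "genotype_matrix"), window >= 2, step >= 1)
  vm <- G$variant_meta
  maf <- setNames(allele_freqs(G)$maf, vm$id)
  keep <- setNames(rep(TRUE, nrow(vm)), vm$id)

  for (ch in unique(vm$chrom)) {
    ix <- which(vm$chrom == ch)
    ix <- ix[order(vm$pos[ix])]
    nc <- length(ix)
    starts <- if (nc <= window) 1L else
      unique(c(seq(1L, nc - window + 1L, by = step), nc - window + 1L))
    for (s in starts) {
      w_ix <- ix[s:min(s + window - 1L, nc)]
      repeat {
        act <- w_ix[keep[vm$id[w_ix]]]
        if (length(act) < 2) break
        cc <- suppressWarnings(
          cor(G$dosages[, act, drop = FALSE],
              use = "pairwise.complete.obs"))
        cc[is.na(cc)] <- 0
        r2 <- cc^2
        diag(r2) <- 0
        if (max(r2) <= r2_max) break
        # resolve the worst offending pair first (ties: smallest indices)
        off <- which(r2 == max(r2), arr.ind = TRUE)
        off <- off[off[, 1] < off[, 2], , drop = FALSE]
        off <- off[order(off[, 1], off[, 2]), , drop = FALSE][1, ]
        va <- act[off[1]]; vb <- act[off[2]]
        ma <- maf[vm$id[va]]; mb <- maf[vm$id[vb]]
        drop_v <- if (ma < mb) va
                  else if (mb < ma) vb
                  else if (vm$pos[va] > vm$pos[vb]) va else vb
        keep[vm$id[drop_v]] <- FALSE
      }
    }
  }
  vm$id[keep[vm$id]]
}
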