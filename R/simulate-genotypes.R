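#' Simulate additive genotypes under Hardy-Weinberg equilibrium
#'
#' Draws biallelic SNP dosages for unrelated samples. Each variant's minor
#' allele frequency is sampled uniformly from `maf_range` and haplotypes are
#' drawn independently, so genotypes are in HWE by construction. Optional
#' linkage-disequilibrium blocks are generated by Markov copying: within a
#' block each haplotype allele is copied from the neighbouring variant with
#' probability `ld_rho`, else redrawn at the block's MAF, giving an r-squared
#' decay of `ld_rho^(2d)` with marker distance `d`. Copying never crosses a
#' block or chromosome boundary. A final X-flagged chromosome is included for
#' the sex check: males carry a single X haplotype (dosages coded 0/2, zero
#' heterozygosity), females two.
#'
#' @param n_samples number of samples (>= 2).
#' @param n_snps total number of variants (>= 1), including X variants.
#' @param maf_range length-2 numeric in (0, 0.5], sampling interval for MAFs.
#' @param n_ld_blocks number of LD blocks tiling the autosomes (0 = all
#'   variants independent).
#' @param ld_rho per-site copy probability inside a block, in \[0, 1).
#' @param n_chrom number of autosomes to spread variants over (capped at the
#'   autosomal variant count).
#' @param n_x_snps number of X-flagged variants (default ~2% of `n_snps`,
#'   at least 1). Set 0 to omit the X chromosome.
#' @param prop_female expected proportion of female samples.
#' @param seed integer seed; identical arguments and seed reproduce the
#'   matrix exactly.
#'
#' @return A [genotype_matrix()] with no missing entries, plus attributes on
#'   variant metadata (`maf_true` column) recording the generative MAFs.
#' @export
#' @examples
#' G <- simulate_genotypes(50, 100, seed = 1)
#' dim(G)
simulate_genotypes <- function(n_samples, n_snps,
                               maf_range = c(0.1, 0.5),
                               n_ld_blocks = 0, ld_rho = 0.8,
                               n_chrom = 22, n_x_snps = NULL,
                               prop_female = 0.5, seed = 1L) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (n_snps < 1) stop("n_snps must be >= 1")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an interval within (0, 0.5]")
  }
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  set.seed(as.integer(seed))

  if (is.null(n_x_snps)) {
    n_x_snps <- if (n_snps >= 50) max(1L, round(0.02 * n_snps)) else
      as.integer(n_snps >= 10)
  }
  n_x_snps <- as.integer(n_x_snps)
  if (n_x_snps >= n_snps) stop("n_x_snps must leave at least one autosomal variant")
  n_auto <- n_snps - n_x_snps
  n_chrom <- max(1L, min(as.integer(n_chrom), n_auto))

  sex <- ifelse(runif(n_samples) < prop_female, "female", "male")
  sample_ids <- sprintf("S%04d", seq_len(n_samples))

  # contiguous chromosome assignment for autosomes
  chrom_auto <- sort(rep_len(seq_len(n_chrom), n_auto))
  chrom <- c(as.character(chrom_auto), rep("X", n_x_snps))
  pos <- stats::ave(seq_len(n_snps), chrom, FUN = seq_along) * 15000L

  # LD block structure over autosomes only
  block <- if (n_ld_blocks > 0) {
    as.integer(cut(seq_len(n_auto), breaks = n_ld_blocks, labels = FALSE))
  } else {
    seq_len(n_auto)  # every variant its own block = independence
  }
  block <- c(block, max(block) + seq_len(n_x_snps))  # X variants independent

  # one MAF per block so Markov copying preserves the HWE marginal
  n_blocks <- max(block)
  block_maf <- runif(n_blocks, maf_range[1], maf_range[2])
  maf <- block_maf[block]

  new_block <- c(TRUE, diff(block) != 0 | chrom[-1] != chrom[-n_snps])

  draw_haplo <- function(n) {
    h <- matrix(0L, n, n_snps)
    for (j in seq_len(n_snps)) {
      fresh <- runif(n) < 1 - ld_rho
      if (new_block[j]) fresh[] <- TRUE
      h[, j] <- ifelse(fresh, as.integer(runif(n) < maf[j]), h[, max(j - 1, 1)])
    }
    h
  }
  h1 <- draw_haplo(n_samples)
  h2 <- draw_haplo(n_samples)
  dos <- h1 + h2
  if (n_x_snps > 0) {
    xi <- which(chrom == "X")
    male <- sex == "male"
    # hemizygous males: single haplotype, coded homozygous
    dos[male, xi] <- 2L * h1[male, xi, drop = FALSE]
  }
  dos <- matrix(as.numeric(dos), n_samples, n_snps)

  alleles <- matrix(c("A", "C", "G", "T")[
    t(apply(matrix(runif(2 * n_snps), ncol = 2), 1,
            function(u) order(u)[1:2]))], ncol = 2)
  variant_ids <- sprintf("rs%06d", seq_len(n_snps))
  dimnames(dos) <- list(sample_ids, variant_ids)

  genotype_matrix(
    dos,
    tibble::tibble(
      id = variant_ids, chrom = chrom, pos = as.integer(pos),
      a1 = alleles[, 1], a2 = alleles[, 2],
      x_flag = chrom == "X", maf_true = maf
    ),
    tibble::tibble(id = sample_ids, reported_sex = sex)
  )
}
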