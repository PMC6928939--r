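#' Per-sample and per-variant genotyping call rates
#'
#' Fraction of non-missing dosage entries per sample row and per variant
#' column.
#'
#' @param G a [genotype_matrix()].
#' @return A list of two tibbles, `samples` and `variants`, each with
#'   columns `id` and `call_rate` in \[0, 1\].
#' @export
call_rates <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (length(G$dosages) == 0) stop("empty genotype matrix")
  obs <- !is.na(G$dosages)
  list(
    samples = tibble::tibble(id = G$sample_meta$id,
                             call_rate = unname(rowMeans(obs))),
    variants = tibble::tibble(id = G$variant_meta$id,
                              call_rate = unname(colMeans(obs)))
  )
}

#' Sex check from X-chromosome heterozygosity
#'
#' Infers genetic sex from the heterozygosity rate of X-flagged variants:
#' hemizygous males carry no heterozygous X calls, so a rate below `t_male`
#' implies male, above `t_female` implies female, and the band between is
#' left undetermined. Samples whose inferred sex contradicts the reported sex
#' are flagged.
#'
#' @param G a [genotype_matrix()] with at least one X-flagged variant.
#' @param t_male,t_female heterozygosity-rate thresholds.
#' @return Tibble with `id`, `reported_sex`, `x_het_rate`, `inferred_sex`
#'   (`NA` if undetermined) and logical `mismatch`.
#' @export
sex_check <- function(G, t_male = 0.05, t_female = 0.15) {
  stopifnot(inherits(G, "genotype_matrix"))
  xv <- which(G$variant_meta$x_flag)
  if (length(xv) == 0) stop("sex check requires X-flagged variants")
  dx <- G$dosages[, xv, drop = FALSE]
  het <- rowMeans(dx == 1, na.rm = TRUE)
  inferred <- dplyr::case_when(
    het < t_male ~ "male",
    het > t_female ~ "female",
    TRUE ~ NA_character_
  )
  tibble::tibble(
    id = G$sample_meta$id,
    reported_sex = G$sample_meta$reported_sex,
    x_het_rate = het,
    inferred_sex = inferred,
    mismatch = !is.na(inferred) & inferred != G$sample_meta$reported_sex
  )
}

#' Pairwise relatedness (PI_HAT) by IBS method of moments
#'
#' Estimates the proportion of the genome shared identical by descent for
#' every sample pair from identity-by-state counts, using the standard
#' method-of-moments decomposition with allele frequencies estimated from
#' the sample itself. Missing genotypes are excluded pairwise. Best run on
#' LD-pruned autosomal variants.
#'
#' @param G a [genotype_matrix()] with at least two samples.
#' @return Tibble of unordered pairs (`id1` < `id2`) with IBS counts
#'   `ibs0`/`ibs1`/`ibs2`, shared non-missing count `n_loci` and `pi_hat`.
#'   Carries attribute `unreliable = TRUE` (with a warning) when fewer than
#'   50 usable variants are available.
#' @export
relatedness <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  dos <- G$dosages
  if (nrow(dos) < 2) stop("relatedness needs at least two samples")
  p <- colMeans(dos, na.rm = TRUE) / 2
  poly <- is.finite(p) & p > 0 & p < 1
  dos <- dos[, poly, drop = FALSE]
  p <- p[poly]
  m <- ncol(dos)
  unreliable <- m < 50
  if (unreliable) {
    warning("fewer than 50 polymorphic variants; PI_HAT estimates unreliable")
  }
  if (m == 0) stop("no polymorphic variants available")

  M <- (!is.na(dos)) * 1
  A0 <- (dos == 0 & !is.na(dos)) * 1
  A1 <- (dos == 1 & !is.na(dos)) * 1
  A2 <- (dos == 2 & !is.na(dos)) * 1
  ibs0 <- A0 %*% t(A2) + A2 %*% t(A0)
  ibs2 <- A0 %*% t(A0) + A1 %*% t(A1) + A2 %*% t(A2)
  L <- M %*% t(M)
  ibs1 <- L - ibs0 - ibs2

  q <- 1 - p
  # expected IBS probabilities conditional on IBD state, per locus
  w00 <- 2 * p^2 * q^2            # P(IBS0 | Z=0)
  w10 <- 4 * p^3 * q + 4 * p * q^3  # P(IBS1 | Z=0)
  w20 <- p^4 + q^4 + 4 * p^2 * q^2  # P(IBS2 | Z=0)
  w11 <- 2 * p^2 * q + 2 * p * q^2  # P(IBS1 | Z=1)
  w21 <- p^2 + q^2                  # P(IBS2 | Z=1)
  psum <- function(w) (M * rep(w, each = nrow(M))) %*% t(M)
  S00 <- psum(w00); S10 <- psum(w10); S20 <- psum(w20)
  S11 <- psum(w11); S21 <- psum(w21)

  P0 <- ibs0 / S00
  P1 <- (ibs1 - P0 * S10) / S11
  P2 <- (ibs2 - P0 * S20 - P1 * S21) / L
  # only the final estimate is bounded: clamping the intermediate IBD-state
  # probabilities would bias PI_HAT upward for unrelated pairs
  pihat <- pmin(pmax(P1 / 2 + P2, 0), 1)

  ids <- G$sample_meta$id
  ut <- which(upper.tri(pihat), arr.ind = TRUE)
  out <- tibble::tibble(
    id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
    ibs0 = ibs0[ut], ibs1 = ibs1[ut], ibs2 = ibs2[ut],
    n_loci = L[ut], pi_hat = pihat[ut]
  )
  attr(out, "unreliable") <- unreliable
  out
}

#' Resolve related pairs into sample exclusions
#'
#' For every pair whose `pi_hat` exceeds `ibd_max`, one member is excluded:
#' the one with the lower genotyping call rate, ties broken by removing the
#' lexicographically larger id. Pairs are resolved in decreasing `pi_hat`
#' order; a pair already broken by a previous exclusion is skipped.
#'
#' @param rel tibble from [relatedness()].
#' @param sample_call_rates tibble with `id`, `call_rate`
#'   (from [call_rates()]).
#' @param ibd_max exclusion threshold on `pi_hat` (strict `>`).
#' @return Tibble of exclusions: `id`, `pi_hat`, `partner`.
#' @export
ibd_exclusions <- function(rel, sample_call_rates, ibd_max = 0.2) {
  hits <- dplyr::filter(rel, .data$pi_hat > ibd_max)
  hits <- dplyr::arrange(hits, dplyr::desc(.data$pi_hat), .data$id1, .data$id2)
  cr <- setNames(sample_call_rates$call_rate, sample_call_rates$id)
  dropped <- character()
  out <- list()
  for (i in seq_len(nrow(hits))) {
    a <- hits$id1[i]; b <- hits$id2[i]
    if (a %in% dropped || b %in% dropped) next
    drop <- if (cr[a] < cr[b]) a
            else if (cr[b] < cr[a]) b
            else max(a, b)
    dropped <- c(dropped, drop)
    out[[length(out) + 1]] <- tibble::tibble(
      id = drop, pi_hat = hits$pi_hat[i],
      partner = if (drop == a) b else a
    )
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(id = character(), pi_hat = numeric(), partner = character())
}
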