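#' Covariate-adjusted SNP-by-SNP interaction test
#'
#' Tests the product-term coefficient in the full interaction model
#' `trait ~ intercept + g1 + g2 + g1*g2 + covariates`. Computationally the
#' test is the partial correlation between the trait and the raw dosage
#' product after projecting both onto the orthogonal complement of
#' \{intercept, covariates, g1, g2\}, converted to a t statistic on
#' `n - (#covariates + 4)` residual degrees of freedom; this is
#' algebraically identical to the full least-squares fit. Missing dosages
#' are mean-imputed.
#'
#' @param trait numeric response vector (no missing values).
#' @param g1,g2 dosage vectors aligned with `trait`.
#' @param covars data frame of covariates (see [assoc_scan()]).
#' @return One-row tibble: `statistic`, `p`, `df`, `n`, `collinear`. When
#'   the product term is collinear with the conditioning set the test is
#'   flagged and p = 1.
#' @export
interaction_test <- function(trait, g1, g2, covars) {
  n <- length(trait)
  stopifnot(length(g1) == n, length(g2) == n, !anyNA(trait))
  g1 <- .impute_vec(g1); g2 <- .impute_vec(g2)
  # canonical argument order: the test is symmetric in (g1, g2), and fixing
  # the order makes the computed statistic bitwise identical under swaps
  i <- which(g1 != g2)[1]
  if (!is.na(i) && g1[i] > g2[i]) {
    tmp <- g1; g1 <- g2; g2 <- tmp
  }
  C <- .covar_design(covars, n)
  Z <- cbind(C, g1, g2)
  if (qr(Z)$rank < ncol(Z)) stop("conditioning design is rank deficient")
  qz <- qr(Z)
  ry <- qr.resid(qz, trait)
  rp <- qr.resid(qz, g1 * g2)
  df <- n - ncol(Z) - 1
  spp <- sum(rp^2)
  syy <- sum(ry^2)
  if (spp < 1e-10 * max(1, sum((g1 * g2)^2)) || syy < 1e-300) {
    return(tibble::tibble(statistic = 0, p = 1, df = df, n = n,
                          collinear = TRUE))
  }
  r <- sum(ry * rp) / sqrt(syy * spp)
  r <- max(min(r, 1), -1)
  stat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  tibble::tibble(statistic = stat, p = 2 * pt(-abs(stat), df), df = df,
                 n = n, collinear = FALSE)
}

.impute_vec <- function(g) {
  if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
  g
}

#' Genome-wide interaction scan anchored at the main-effect SNPs
#'
#' Tests every (anchor, partner) pair — anchors being a module's main-effect
#' variants, partners every other variant in the matrix — with
#' [interaction_test()], blocked in matrix form over partners for speed but
#' numerically equal to the per-pair test. Pairs with p strictly below
#' `p_thresh` are kept as network edges. Anchor-anchor pairs are not
#' tested.
#'
#' @param trait numeric response, one value per sample of `G`.
#' @param anchors character vector of anchor variant ids (present in `G`).
#' @param G a [genotype_matrix()].
#' @param covars covariate data frame.
#' @param p_thresh edge-retention threshold (default 5e-4, strict `<`).
#' @param keep_all also return the full result for every tested pair.
#' @param module optional label recorded in the result.
#' @return Object of class `epi_scan`: `edges` tibble (`anchor`, `partner`,
#'   `chrom_anchor`, `chrom_partner`, `statistic`, `p`, `n`), the threshold,
#'   counts of tested pairs, and optionally `all_pairs`.
#' @export
scan_anchors <- function(trait, anchors, G, covars, p_thresh = 5e-4,
                         keep_all = FALSE, module = NA_character_) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (length(anchors) == 0) stop("at least one anchor is required")
  missing_a <- setdiff(anchors, G$variant_meta$id)
  if (length(missing_a)) {
    stop("anchor(s) absent from genotypes: ",
         paste(missing_a, collapse = ", "))
  }
  n <- nrow(G$dosages)
  if (!is.null(names(trait))) trait <- trait[G$sample_meta$id]
  stopifnot(length(trait) == n, !anyNA(trait))
  C <- .covar_design(covars, n)
  X <- .impute_means(G$dosages)
  partners <- setdiff(G$variant_meta$id, anchors)
  chrom <- setNames(G$variant_meta$chrom, G$variant_meta$id)

  res <- purrr::map_dfr(anchors, function(a) {
    ga <- X[, a]
    Ca <- cbind(C, ga)
    qa <- qr(Ca)
    ry <- qr.resid(qa, trait)
    RG <- qr.resid(qa, X[, partners, drop = FALSE])
    P <- X[, partners, drop = FALSE] * ga
    RP <- qr.resid(qa, P)
    df <- n - ncol(Ca) - 2          # additionally conditions on the partner

    nrm <- function(M) sqrt(colSums(M^2))
    sy <- sqrt(sum(ry^2))
    ng <- nrm(RG); np <- nrm(RP)
    r_yp <- as.vector(crossprod(RP, ry)) / (np * sy)
    r_yg <- as.vector(crossprod(RG, ry)) / (ng * sy)
    r_pg <- colSums(RP * RG) / (np * ng)
    denom2 <- (1 - r_yg^2) * (1 - r_pg^2)
    bad <- !is.finite(r_yp) | !is.finite(r_pg) | denom2 <= 1e-12 |
      np < 1e-8 * sqrt(n) | ng < 1e-8 * sqrt(n)
    r <- (r_yp - r_yg * r_pg) / sqrt(pmax(denom2, .Machine$double.eps))
    r <- pmax(pmin(r, 1), -1)
    stat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(stat), df)
    stat[bad] <- 0; p[bad] <- 1
    tibble::tibble(
      anchor = a, partner = partners,
      chrom_anchor = unname(chrom[a]), chrom_partner = unname(chrom[partners]),
      statistic = unname(stat), p = unname(pmin(p, 1)), n = n,
      collinear = unname(bad)
    )
  })

  edges <- dplyr::arrange(dplyr::filter(res, .data$p < p_thresh),
                          .data$p, .data$anchor, .data$partner)
  structure(
    list(edges = dplyr::select(edges, -"collinear"),
         p_thresh = p_thresh, n_pairs_tested = nrow(res),
         anchors = anchors, module = module,
         all_pairs = if (keep_all) res else NULL),
    class = "epi_scan"
  )
}

#' @export
print.epi_scan <- function(x, ...) {
  cat(sprintf(
    "<epi_scan> module %s: %d anchors x %d pairs tested, %d edges at p < %g\n",
    x$module, length(x$anchors), x$n_pairs_tested, nrow(x$edges), x$p_thresh
  ))
  invisible(x)
}

#' @rdname scan_anchors
#' @param x an `epi_scan`.
#' @param ... unused.
#' @method tidy epi_scan
#' @export
tidy.epi_scan <- function(x, ...) x$edges
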