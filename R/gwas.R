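#' Covariate-adjusted single-SNP association scan
#'
#' Fits, for every variant, the linear model
#' `trait ~ intercept + dosage + covariates` and tests the dosage
#' coefficient with a two-sided t-test. The scan is matrix-accelerated via
#' the Frisch-Waugh-Lovell projection — trait and dosages are residualized
#' on the covariate design once, then per-SNP slopes follow from simple
#' regression on the residuals — and is numerically identical to fitting
#' each SNP separately. Missing dosages are mean-imputed per SNP before
#' fitting (the default), or handled by per-SNP case deletion.
#'
#' @param trait numeric response, one value per sample row of `G` (a module
#'   volume), or a named vector matched to sample ids.
#' @param G a [genotype_matrix()] (QC output).
#' @param covars data frame of covariates aligned with the samples
#'   (typically age, sex, education). Character/factor columns are expanded
#'   via [stats::model.matrix()]; an intercept is always included.
#' @param missing_action `"mean-impute"` (default) or `"complete-cases"`.
#' @param module optional label recorded in the result.
#' @return Object of class `qt_assoc` with a `results` tibble: `id`,
#'   `chrom`, `pos`, `beta`, `se`, `statistic`, `p`, `n`, `monomorphic`.
#'   Monomorphic variants are flagged and reported with p = 1.
#' @export
assoc_scan <- function(trait, G, covars,
                       missing_action = c("mean-impute", "complete-cases"),
                       module = NA_character_) {
  missing_action <- match.arg(missing_action)
  stopifnot(inherits(G, "genotype_matrix"))
  n <- nrow(G$dosages)
  if (!is.null(names(trait))) trait <- trait[G$sample_meta$id]
  stopifnot(length(trait) == n, !anyNA(trait))
  C <- .covar_design(covars, n)
  if (qr(C)$rank < ncol(C)) stop("covariate design is rank deficient")

  X <- G$dosages
  res <- if (missing_action == "mean-impute") {
    .scan_matrix(trait, .impute_means(X), C)
  } else {
    .scan_casewise(trait, X, C)
  }
  out <- dplyr::bind_cols(
    tibble::tibble(id = G$variant_meta$id, chrom = G$variant_meta$chrom,
                   pos = G$variant_meta$pos),
    res
  )
  structure(
    list(results = out, module = module, covariates = colnames(C)[-1],
         missing_action = missing_action, n_samples = n),
    class = "qt_assoc"
  )
}

.covar_design <- function(covars, n) {
  covars <- as.data.frame(covars)
  stopifnot(nrow(covars) == n, !anyNA(covars))
  C <- stats::model.matrix(~ ., data = covars)
  storage.mode(C) <- "double"
  C
}

.impute_means <- function(X) {
  if (!anyNA(X)) return(X)
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- mu[idx[, 2]]
  X
}

.scan_matrix <- function(y, X, C) {
  n <- length(y)
  qc <- qr(C)
  ry <- qr.resid(qc, y)
  RX <- qr.resid(qc, X)
  sxx <- colSums(RX^2)
  sxy <- as.vector(crossprod(RX, ry))
  syy <- sum(ry^2)
  df <- n - ncol(C) - 1
  mono <- sxx < 1e-10
  beta <- ifelse(mono, 0, sxy / sxx)
  sse <- pmax(syy - beta * sxy, 0)
  se <- ifelse(mono, Inf, sqrt(sse / df / sxx))
  stat <- ifelse(mono, 0, beta / se)
  p <- ifelse(mono, 1, 2 * pt(-abs(stat), df))
  tibble::tibble(beta = unname(beta), se = unname(se),
                 statistic = unname(stat), p = unname(pmin(p, 1)), n = n,
                 monomorphic = unname(mono))
}

.scan_casewise <- function(y, X, C) {
  purrr::map_dfr(seq_len(ncol(X)), function(j) {
    g <- X[, j]
    use <- !is.na(g)
    n_use <- sum(use)
    Z <- cbind(C[use, , drop = FALSE], g = g[use])
    if (n_use <= ncol(Z) || var(g[use]) < 1e-12) {
      return(tibble::tibble(beta = 0, se = Inf, statistic = 0, p = 1,
                            n = n_use, monomorphic = TRUE))
    }
    fit <- lm.fit(Z, y[use])
    df <- n_use - ncol(Z)
    sigma2 <- sum(fit$residuals^2) / df
    XtXinv <- solve(crossprod(Z))
    se <- sqrt(sigma2 * XtXinv[ncol(Z), ncol(Z)])
    beta <- unname(fit$coefficients["g"])
    stat <- beta / se
    tibble::tibble(beta = beta, se = se, statistic = stat,
                   p = 2 * pt(-abs(stat), df), n = n_use,
                   monomorphic = FALSE)
  })
}

#' @export
print.qt_assoc <- function(x, ...) {
  cat(sprintf(
    "<qt_assoc> module %s: %d variants, %d samples, covariates: %s\n",
    x$module, nrow(x$results), x$n_samples,
    paste(x$covariates, collapse = ", ")
  ))
  cat(sprintf("  min p = %.3g\n", min(x$results$p)))
  invisible(x)
}

#' @rdname assoc_scan
#' @param x a `qt_assoc`.
#' @param ... unused.
#' @method tidy qt_assoc
#' @export
tidy.qt_assoc <- function(x, ...) x$results

#' @rdname assoc_scan
#' @method glance qt_assoc
#' @export
glance.qt_assoc <- function(x, ...) {
  chi <- stats::qchisq(1 - x$results$p[!x$results$monomorphic], df = 1)
  tibble::tibble(
    module = x$module, n_samples = x$n_samples,
    n_variants = nrow(x$results),
    n_monomorphic = sum(x$results$monomorphic),
    min_p = min(x$results$p),
    lambda_gc = median(chi) / stats::qchisq(0.5, df = 1)
  )
}

#' Variants passing the significance threshold
#'
#' Strict inequality: a variant is kept only when its p-value is smaller
#' than `p_thresh`; a p-value exactly at the threshold is excluded.
#'
#' @param res a `qt_assoc` from [assoc_scan()].
#' @param p_thresh significance threshold (default 1e-4).
#' @return Tibble of hits sorted by p, then (chromosome, position).
#' @export
significant_hits <- function(res, p_thresh = 1e-4) {
  stopifnot(inherits(res, "qt_assoc"))
  dplyr::arrange(
    dplyr::filter(res$results, .data$p < p_thresh),
    .data$p, .data$chrom, .data$pos
  )
}

#' Top-ranked main-effect variants
#'
#' The `k` variants with the smallest p-values; ties broken by (chromosome,
#' position).
#'
#' @param res a `qt_assoc`.
#' @param k number of variants (default 5).
#' @return Tibble of `k` rows (fewer, with a warning, when fewer variants
#'   were tested).
#' @export
top_main_snps <- function(res, k = 5) {
  stopifnot(inherits(res, "qt_assoc"), k >= 1)
  ordered <- dplyr::arrange(res$results, .data$p, .data$chrom, .data$pos)
  if (nrow(ordered) < k) {
    warning("fewer variants (", nrow(ordered), ") than requested k = ", k)
    return(ordered)
  }
  head(ordered, k)
}

#' Manhattan-plot-ready table
#'
#' One record per tested variant with `-log10(p)` (p floored at 1e-300 so
#' the value stays finite), sorted by (chromosome, position).
#'
#' @param res a `qt_assoc`.
#' @return Tibble: `chrom`, `pos`, `id`, `p`, `neg_log10_p`.
#' @export
manhattan_table <- function(res) {
  stopifnot(inherits(res, "qt_assoc"))
  out <- dplyr::transmute(
    res$results,
    chrom = .data$chrom, pos = .data$pos, id = .data$id, p = .data$p,
    neg_log10_p = -log10(pmax(.data$p, 1e-300))
  )
  dplyr::arrange(out, .chrom_order(.data$chrom), .data$pos)
}

# numeric chromosomes first in numeric order, then X/others
.chrom_order <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  ifelse(is.na(num), 1e6 + as.numeric(factor(chrom)), num)
}
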