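# Independent oracles and tiny fixture builders shared across the suite.
# Every oracle here deliberately uses a different algorithm from the
# package implementation it checks.

# Build a genotype_matrix from a bare dosage matrix with minimal metadata.
make_geno <- function(dos, chrom = NULL, pos = NULL, sex = NULL,
                      x_flag = NULL) {
  n <- nrow(dos); m <- ncol(dos)
  ids_s <- sprintf("S%04d", seq_len(n))
  ids_v <- sprintf("v%04d", seq_len(m))
  dimnames(dos) <- list(ids_s, ids_v)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- stats::ave(seq_len(m), chrom, FUN = seq_along) * 1000L
  if (is.null(sex)) sex <- rep(c("male", "female"), length.out = n)
  if (is.null(x_flag)) x_flag <- chrom == "X"
  genotype_matrix(
    dos,
    tibble::tibble(id = ids_v, chrom = as.character(chrom),
                   pos = as.integer(pos), a1 = "A", a2 = "C",
                   x_flag = x_flag),
    tibble::tibble(id = ids_s, reported_sex = sex)
  )
}

# HWE exact test by mode-anchored log-recurrence (PLINK-style), entirely
# different from the closed-form log-factorial route in the package.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)
  lp <- numeric(length(hets))
  if (length(hets) > 1) {
    for (i in seq_len(length(hets) - 1)) {
      h <- hets[i]
      # P(h+2)/P(h) = [ (nA-h)/2 * (na-h)/2 * 4 ] / [ (h+2)(h+1) ]
      lp[i + 1] <- lp[i] +
        log((nA - h) / 2) + log((na - h) / 2) + log(4) -
        log(h + 2) - log(h + 1)
    }
  }
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  p_obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

# Single-SNP covariate-adjusted OLS oracle via lm().
gwas_oracle <- function(y, g, covars) {
  df <- data.frame(y = y, g = g, covars)
  fit <- summary(lm(y ~ ., data = df))
  co <- coef(fit)["g", ]
  list(beta = co[["Estimate"]], se = co[["Std. Error"]],
       statistic = co[["t value"]], p = co[["Pr(>|t|)"]])
}

# Full interaction-model OLS oracle via lm() with an explicit product column.
epi_oracle <- function(y, g1, g2, covars) {
  df <- data.frame(y = y, g1 = g1, g2 = g2, gg = g1 * g2, covars)
  fit <- summary(lm(y ~ ., data = df))
  co <- coef(fit)["gg", ]
  list(statistic = co[["t value"]], p = co[["Pr(>|t|)"]])
}

# Greedy single-window LD pruning oracle: plain loop over all pairs.
ld_prune_oracle <- function(dos, maf, pos, r2_max = 0.8) {
  keep <- rep(TRUE, ncol(dos))
  repeat {
    act <- which(keep)
    if (length(act) < 2) break
    cc <- suppressWarnings(cor(dos[, act, drop = FALSE],
                               use = "pairwise.complete.obs"))
    cc[is.na(cc)] <- 0
    r2 <- cc^2; diag(r2) <- 0
    if (max(r2) <= r2_max) break
    off <- which(r2 == max(r2), arr.ind = TRUE)
    off <- off[off[, 1] < off[, 2], , drop = FALSE]
    off <- off[order(off[, 1], off[, 2]), , drop = FALSE][1, ]
    a <- act[off[1]]; b <- act[off[2]]
    drop_j <- if (maf[a] < maf[b]) a
              else if (maf[b] < maf[a]) b
              else if (pos[a] > pos[b]) a else b
    keep[drop_j] <- FALSE
  }
  which(keep)
}

# Naive O(n^3) complete-linkage agglomeration oracle.
complete_linkage_oracle <- function(d, k) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    nc <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(nc - 1)) {
      for (j in (i + 1):nc) {
        dij <- max(d[clusters[[i]], clusters[[j]]])
        if (dij < best[1]) best <- c(dij, i, j)
      }
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  lab <- integer(n)
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

# Small covariate table.
make_covars <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(age = rnorm(n, 75, 6),
             sex = rbinom(n, 1, 0.5),
             education = rnorm(n, 15, 3))
}
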