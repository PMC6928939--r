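test_that("genotype simulation has the promised shape and no missingness", {
  G <- simulate_genotypes(388, 2000, maf_range = c(0.1, 0.5), seed = 1)
  expect_identical(dim(G), c(388L, 2000L))
  expect_false(anyNA(G$dosages))
  expect_true(all(G$dosages %in% 0:2))
  expect_identical(nrow(G$variant_meta), 2000L)
  expect_true(any(G$variant_meta$x_flag))
  expect_true(all(diff(G$variant_meta$pos[G$variant_meta$chrom == "1"]) > 0))
})

test_that("dosage means match the Binomial(2, maf) expectation at maf 0.5", {
  n <- 300
  G <- simulate_genotypes(n, 400, maf_range = c(0.5, 0.5), n_x_snps = 0,
                          seed = 2)
  se <- sqrt(2 * 0.5 * 0.5 / n)
  mu <- colMeans(G$dosages)
  expect_gt(mean(abs(mu - 1) <= 3 * se), 0.97)
  expect_lt(abs(mean(mu) - 1), 4 * se / sqrt(400))
})

test_that("identical seeds reproduce identical genotypes bitwise", {
  a <- simulate_genotypes(60, 150, n_ld_blocks = 4, seed = 42)
  b <- simulate_genotypes(60, 150, n_ld_blocks = 4, seed = 42)
  expect_identical(a, b)
  c <- simulate_genotypes(60, 150, n_ld_blocks = 4, seed = 43)
  expect_false(identical(a$dosages, c$dosages))
})

test_that("LD blocks give high neighbour r2 decaying with distance", {
  G <- simulate_genotypes(800, 60, maf_range = c(0.3, 0.5), n_ld_blocks = 3,
                          ld_rho = 0.9, n_chrom = 1, n_x_snps = 0, seed = 5)
  dos <- G$dosages
  r <- cor(dos)
  neigh <- r[cbind(1:19, 2:20)]        # inside the first block
  expect_gt(mean(neigh^2), 0.5)
  cross <- r[1:10, 41:50]              # first vs third block
  expect_lt(mean(cross^2), 0.05)
})

test_that("X-flagged variants separate the sexes by heterozygosity", {
  G <- simulate_genotypes(200, 500, n_x_snps = 40, seed = 3)
  xv <- which(G$variant_meta$x_flag)
  het <- rowMeans(G$dosages[, xv] == 1)
  male <- G$sample_meta$reported_sex == "male"
  expect_true(all(het[male] == 0))
  expect_true(all(het[!male] > 0.05))
})

test_that("invalid generator parameters are rejected", {
  expect_error(simulate_genotypes(1, 10), "n_samples")
  expect_error(simulate_genotypes(10, 10, maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulate_genotypes(10, 10, maf_range = c(0.4, 0.2)),
               "maf_range")
})

test_that("with all effects and noise off, volumes collapse to the ICV line", {
  G <- simulate_genotypes(80, 60, seed = 4)
  spec <- truth_spec(module_factor_sd = 0, noise_sd = 0, seed = 9)
  sim <- simulate_phenotypes(G, spec)
  ph <- sim$phenotypes
  for (roi in c("Hippocampus.L", "CC_Posterior", "CSF")) {
    resid <- ph[[roi]] - spec$icv_slopes[[roi]] * (ph$icv - spec$icv_mean)
    expect_lt(diff(range(resid)), 1e-6)
  }
})

test_that("a single planted main effect is exact on the residualized scale", {
  G <- simulate_genotypes(120, 50, seed = 6)
  spec <- truth_spec(
    module_factor_sd = 0, noise_sd = 0, seed = 11,
    main_effects = tibble::tibble(snp = "rs000010", module = 1L, beta = 500)
  )
  sim <- simulate_phenotypes(G, spec)
  ph <- sim$phenotypes
  members <- names(spec$module_assignment)[spec$module_assignment == 1]
  trait <- rowSums(sapply(members, function(roi) {
    ph[[roi]] - spec$icv_slopes[[roi]] * (ph$icv - spec$icv_mean)
  }))
  expect_equal(abs(cor(trait, G$dosages[, "rs000010"])), 1, tolerance = 1e-10)
  # and the module-trait slope equals the planted beta
  expect_equal(unname(coef(lm(trait ~ G$dosages[, "rs000010"]))[2]), 500,
               tolerance = 1e-6)
})

test_that("module factors induce stronger within- than between-module correlation", {
  G <- simulate_genotypes(300, 30, seed = 7)
  spec <- truth_spec(module_factor_sd = 0.10, noise_sd = 0.02, seed = 12)
  sim <- simulate_phenotypes(G, spec)
  nm <- fit_normalization(sim$phenotypes)
  normd <- normalize_volumes(sim$phenotypes, nm)
  C <- structure_correlation(normd)
  assign <- spec$module_assignment[rownames(C)]
  same <- outer(assign, assign, "==") & upper.tri(C)
  diff_m <- outer(assign, assign, "!=") & upper.tri(C)
  expect_gt(mean(abs(C[same])), mean(abs(C[diff_m])))
  expect_gt(mean(abs(C[same])), 0.5)
})

test_that("phenotype generation echoes the truth record and is deterministic", {
  G <- simulate_genotypes(50, 40, seed = 8)
  spec <- truth_spec(seed = 13)
  a <- simulate_phenotypes(G, spec)
  b <- simulate_phenotypes(G, spec)
  expect_identical(a$truth, spec)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_error(
    simulate_phenotypes(G, truth_spec(
      main_effects = tibble::tibble(snp = "rs999999", module = 1L, beta = 1),
      seed = 1
    )),
    "absent"
  )
})

test_that("defect injection plants what QC must later find", {
  G <- simulate_genotypes(100, 200, maf_range = c(0.2, 0.45), seed = 9)
  d <- defect_spec(
    missing_rate_samples = c(S0001 = 0.15),
    duplicate_pairs = list(c("S0003", "S0004")),
    sex_flip_samples = "S0005",
    hwe_violation_snps = list(rs000050 = c(50, 0, 50)),
    low_maf_snps = c(rs000060 = 0.02)
  )
  G2 <- inject_defects(G, d, seed = 1)
  # original untouched
  expect_false(anyNA(G$dosages))
  # planted missingness drops the call rate below 0.90 (rate 0.15 over 200)
  expect_lt(mean(!is.na(G2$dosages["S0001", ])), 0.90)
  expect_identical(G2$dosages["S0003", ], G2$dosages["S0004", ])
  expect_false(G2$sample_meta$reported_sex[5] == G$sample_meta$reported_sex[5])
  cnt <- table(factor(G2$dosages[, "rs000050"], levels = 0:2))
  expect_identical(as.integer(cnt), c(50L, 0L, 50L))
  expect_lt(mean(G2$dosages[, "rs000060"]) / 2, 0.06)
  # forced het deficit is detectable at the HWE threshold
  expect_lt(hwe_exact_p(50, 0, 50), 5e-7)
})

test_that("conflicting or ill-formed defects are rejected", {
  G <- simulate_genotypes(10, 20, seed = 1)
  expect_error(defect_spec(missing_rate_samples = c(S0001 = 1.5)), "rates")
  expect_error(
    defect_spec(hwe_violation_snps = list(rs000001 = c(5, 0, 5)),
                low_maf_snps = c(rs000001 = 0.01)),
    "conflicting"
  )
  expect_error(
    inject_defects(G, defect_spec(hwe_violation_snps =
                                    list(rs000001 = c(5, 0, 4))), 1),
    "sum"
  )
  expect_error(
    inject_defects(G, defect_spec(sex_flip_samples = "nope"), 1),
    "unknown"
  )
})
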