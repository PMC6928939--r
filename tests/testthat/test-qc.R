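test_that("call rates count observed entries exactly", {
  dos <- matrix(rep(0:2, length.out = 400), 4, 100)
  G <- make_geno(dos)
  cr <- call_rates(G)
  expect_true(all(cr$samples$call_rate == 1))
  expect_true(all(cr$variants$call_rate == 1))
  dos[1, 1:10] <- NA  # 10 of 100 missing: exactly at the 0.90 boundary
  G <- make_geno(dos)
  cr <- call_rates(G)
  expect_equal(cr$samples$call_rate[1], 0.90)
})

test_that("the sample call-rate filter keeps the 0.90 boundary inclusive", {
  set.seed(11)
  dos <- matrix(rbinom(600, 2, 0.4), 6, 100)
  dos[1, 1:10] <- NA   # exactly 0.90: retained under >=
  dos[2, 1:15] <- NA   # 0.85: removed
  G <- make_geno(dos, chrom = rep("1", 100))
  qc <- run_qc(G, maf_min = 0, hwe_alpha = 0, ibd_max = 1, prune_r2 = 1.1,
               sex_check_enabled = FALSE)
  expect_identical(qc$report$removed_samples$id, "S0002")
  expect_identical(qc$report$removed_samples$reason, "call_rate")
})

test_that("sex check flags exactly the discordant samples", {
  G <- simulate_genotypes(150, 300, n_x_snps = 30, seed = 21)
  sc <- sex_check(G)
  expect_false(any(sc$mismatch))
  flips <- c("S0002", "S0010", "S0033")
  G2 <- inject_defects(G, defect_spec(sex_flip_samples = flips), seed = 1)
  sc2 <- sex_check(G2)
  expect_setequal(sc2$id[sc2$mismatch], flips)
  # all-homozygous X with reported female is a contradiction
  dos <- matrix(0, 4, 10)
  Gx <- make_geno(dos, chrom = rep("X", 10),
                  sex = c("male", "female", "male", "female"))
  scx <- sex_check(Gx)
  expect_identical(scx$mismatch, c(FALSE, TRUE, FALSE, TRUE))
  expect_error(sex_check(make_geno(matrix(1, 3, 4))), "X-flagged")
})

test_that("HWE exact p is symmetric under allele relabeling", {
  set.seed(1)
  for (i in 1:50) {
    cnt <- rmultinom(1, sample(10:150, 1), c(0.3, 0.45, 0.25))
    expect_identical(hwe_exact_p(cnt[1], cnt[2], cnt[3]),
                     hwe_exact_p(cnt[3], cnt[2], cnt[1]))
  }
})

test_that("HWE exact p matches the enumeration oracle across all small tables", {
  # exhaustive sweep over every genotype table with n <= 100
  tabs <- do.call(rbind, lapply(c(1:40, seq(45, 100, by = 5)), function(n) {
    g <- expand.grid(nAA = 0:n, nAa = 0:n)
    g <- g[g$nAA + g$nAa <= n, ]
    cbind(g$nAA, g$nAa, n - g$nAA - g$nAa)
  }))
  # randomized tables up to n = 200
  set.seed(7)
  rnd <- t(vapply(1:500, function(i) {
    n <- sample(101:200, 1)
    nAA <- sample(0:n, 1)
    nAa <- sample(0:(n - nAA), 1)
    c(nAA, nAa, n - nAA - nAa)
  }, numeric(3)))
  tabs <- rbind(tabs, rnd)
  got <- hwe_exact_p(tabs[, 1], tabs[, 2], tabs[, 3])
  want <- vapply(seq_len(nrow(tabs)), function(i) {
    hwe_oracle(tabs[i, 1], tabs[i, 2], tabs[i, 3])
  }, numeric(1))
  expect_lt(max(abs(got - want) / pmax(want, 1e-300)), 1e-10)
  expect_true(all(got > 0 & got <= 1))
  # the anchor example: equality to 1e-12 relative
  expect_equal(hwe_exact_p(25, 50, 25), hwe_oracle(25, 50, 25),
               tolerance = 1e-12)
  expect_lt(hwe_exact_p(50, 0, 50), 5e-7)
  expect_error(hwe_exact_p(0, 0, 0), "at least one")
})

test_that("duplicated samples reach PI_HAT near 1 and one of each pair is removed", {
  G <- simulate_genotypes(60, 800, maf_range = c(0.2, 0.45), n_x_snps = 0,
                          seed = 22)
  G2 <- inject_defects(G, defect_spec(duplicate_pairs = list(c("S0001",
                                                               "S0002"))),
                       seed = 1)
  rel <- relatedness(G2)
  dup <- rel[rel$id1 == "S0001" & rel$id2 == "S0002", ]
  expect_lt(abs(dup$pi_hat - 1), 0.05)
  cr <- call_rates(G2)$samples
  excl <- ibd_exclusions(rel, cr, 0.2)
  expect_identical(nrow(excl), 1L)
  # equal call rates: the lexicographically larger id goes
  expect_identical(excl$id, "S0002")
})

test_that("unrelated HWE samples have mean PI_HAT near zero", {
  G <- simulate_genotypes(40, 1000, maf_range = c(0.2, 0.45), n_x_snps = 0,
                          seed = 23)
  rel <- relatedness(G)
  expect_lt(abs(mean(rel$pi_hat)), 0.05)
  expect_true(all(rel$pi_hat < 0.2))
})

test_that("relatedness warns when too few variants are usable", {
  G <- simulate_genotypes(10, 30, seed = 24)
  expect_warning(rel <- relatedness(G), "unreliable")
  expect_true(attr(rel, "unreliable"))
})

test_that("variant filters respect the inclusive MAF boundary", {
  # n = 100; 20 minor alleles as hets -> MAF exactly 0.10; 18 -> 0.09
  dos <- cbind(
    c(rep(1, 20), rep(0, 80)),   # maf 0.10, retained
    c(rep(1, 18), rep(0, 82)),   # maf 0.09, removed
    rep(1, 100)                  # maf 0.50 but all-het: gross HWE violation
  )
  G <- make_geno(dos)
  vf <- variant_filters(G, maf_min = 0.10, hwe_alpha = 5e-7,
                        call_min = 0.90)
  expect_true("v0001" %in% vf$retained)
  expect_identical(vf$removed$reason[vf$removed$id == "v0002"], "maf")
  expect_identical(vf$removed$reason[vf$removed$id == "v0003"], "hwe")
})

test_that("a clean simulated matrix passes every variant filter", {
  G <- simulate_genotypes(300, 400, maf_range = c(0.2, 0.45), seed = 25)
  vf <- variant_filters(G)
  expect_identical(vf$retained, G$variant_meta$id)
})

test_that("the variant removal set equals the planted defect set", {
  G <- simulate_genotypes(200, 150, maf_range = c(0.25, 0.45), seed = 26)
  d <- defect_spec(
    missing_rate_snps = c(rs000010 = 0.2),
    hwe_violation_snps = list(rs000020 = c(100, 0, 100)),
    low_maf_snps = c(rs000030 = 0.02)
  )
  G2 <- inject_defects(G, d, seed = 2)
  vf <- variant_filters(G2)
  expect_setequal(vf$removed$id, c("rs000010", "rs000020", "rs000030"))
  expect_identical(
    setNames(vf$removed$reason, vf$removed$id)[c("rs000010", "rs000020",
                                                 "rs000030")],
    c(rs000010 = "call_rate", rs000020 = "hwe", rs000030 = "maf")
  )
})

test_that("X-flagged variants are HWE-tested on females only", {
  # hemizygous male coding (0/2) would torpedo a naive HWE test
  G <- simulate_genotypes(300, 200, n_x_snps = 40, maf_range = c(0.2, 0.45),
                          seed = 27)
  vf <- variant_filters(G)
  removed_x <- intersect(vf$removed$id,
                         G$variant_meta$id[G$variant_meta$x_flag])
  expect_length(removed_x[vf$removed$reason[match(removed_x,
                                                  vf$removed$id)] == "hwe"],
                0)
})

test_that("LD pruning keeps uncorrelated variants and resolves duplicates", {
  G <- simulate_genotypes(150, 40, maf_range = c(0.2, 0.45), n_x_snps = 0,
                          seed = 28)
  expect_identical(ld_prune(G), G$variant_meta$id)
  # duplicate a column: exactly one of the pair survives
  dos <- cbind(G$dosages, dup = G$dosages[, 5])
  G2 <- make_geno(dos, chrom = rep("1", 41))
  kept <- ld_prune(G2)
  expect_length(setdiff(c("v0005", "v0041"), kept), 1)
  expect_length(kept, 40)
})

test_that("windowed pruning equals the brute-force greedy oracle when the window spans all variants", {
  G <- simulate_genotypes(250, 200, maf_range = c(0.15, 0.45),
                          n_ld_blocks = 10, ld_rho = 0.95, n_chrom = 1,
                          n_x_snps = 0, seed = 29)
  kept <- ld_prune(G, window = 200, step = 5, r2_max = 0.8)
  maf <- allele_freqs(G)$maf
  oracle <- ld_prune_oracle(G$dosages, maf, G$variant_meta$pos, 0.8)
  expect_identical(kept, G$variant_meta$id[oracle])
  # no surviving pair within the window exceeds the cap
  r2 <- cor(G$dosages[, kept])^2
  diag(r2) <- 0
  expect_lte(max(r2), 0.8)
})

test_that("QC runs filters in order and is idempotent", {
  G <- simulate_genotypes(120, 1200, maf_range = c(0.25, 0.45),
                          n_x_snps = 30, seed = 30)
  d <- defect_spec(
    missing_rate_samples = c(S0001 = 0.2),
    duplicate_pairs = list(c("S0010", "S0011")),
    sex_flip_samples = "S0020",
    hwe_violation_snps = list(rs000100 = c(60, 0, 60)),
    low_maf_snps = c(rs000120 = 0.02)
  )
  G2 <- inject_defects(G, d, seed = 3)
  qc <- run_qc(G2)
  rs <- qc$report$removed_samples
  expect_setequal(rs$id[rs$reason == "call_rate"], "S0001")
  expect_setequal(rs$id[rs$reason == "sex_mismatch"], "S0020")
  expect_true(all(rs$id[rs$reason == "ibd"] %in% c("S0010", "S0011")))
  expect_identical(sum(rs$reason == "ibd"), 1L)
  rv <- qc$report$removed_variants
  expect_true(all(c("rs000100", "rs000120") %in% rv$id))
  # every removal has exactly one reason, and removed/retained are disjoint
  expect_identical(anyDuplicated(rs$id), 0L)
  expect_length(intersect(rv$id, qc$genotypes$variant_meta$id), 0)
  # idempotence: QC of the QC output removes nothing
  qc2 <- run_qc(qc$genotypes)
  expect_identical(nrow(qc2$report$removed_samples), 0L)
  expect_identical(nrow(qc2$report$removed_variants), 0L)
  expect_identical(qc2$genotypes$dosages, qc$genotypes$dosages)
})
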