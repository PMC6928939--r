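test_that("the roster expands to 35 phenotypes from 22 structures", {
  r <- roi_roster()
  expect_identical(nrow(r), 22L)
  expect_identical(sum(r$bilateral), 13L)
  ids <- expand_roster(r)
  expect_length(ids, 35)
  expect_identical(anyDuplicated(ids), 0L)
  expect_length(expand_roster(r[0, ]), 0)
  expect_error(expand_roster(rbind(r, r[1, ])), "duplicate")
})

test_that("the reference module partition has the expected sizes", {
  assign <- reference_module_assignment()
  expect_length(assign, 35)
  sizes <- as.integer(table(assign))
  # module I is ambiguous in size; II-V are 5, 11, 4, 9
  expect_identical(sizes[2:5], c(5L, 11L, 4L, 9L))
  expect_identical(sum(sizes), 35L)
})

test_that("normalization slopes recover an exact linear ICV relation", {
  set.seed(31)
  n <- 60
  icv <- rnorm(n, 1.5e6, 1.5e5)
  ph <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:n),
    diagnosis = rep(c("NC", "AD"), length.out = n),
    icv = icv,
    roi = 1000 + 0.02 * icv
  )
  m <- fit_normalization(ph, phenotypes = "roi")
  expect_equal(unname(m$eps["roi"]), 0.02, tolerance = 1e-10)
  # NC-only contract: perturbing AD rows leaves the slope untouched
  ph2 <- ph
  ph2$roi[ph2$diagnosis == "AD"] <- rnorm(sum(ph2$diagnosis == "AD"), 0, 1e4)
  m2 <- fit_normalization(ph2, phenotypes = "roi")
  expect_identical(m2$eps, m$eps)
  # but icv_mean uses ALL samples
  expect_equal(m$icv_mean, mean(icv))
})

test_that("slopes equal the closed-form cov/var oracle on random data", {
  set.seed(32)
  n <- 80
  ph <- tibble::tibble(
    sample_id = as.character(1:n),
    diagnosis = sample(c("AD", "NC"), n, replace = TRUE),
    icv = rnorm(n, 1.5e6, 1e5),
    a = rnorm(n, 5000, 300), b = rnorm(n, 900, 80)
  )
  ph$a <- ph$a + 0.004 * ph$icv
  m <- fit_normalization(ph, phenotypes = c("a", "b"))
  nc <- ph[ph$diagnosis == "NC", ]
  for (v in c("a", "b")) {
    oracle <- cov(nc[[v]], nc$icv) / var(nc$icv)
    expect_equal(unname(m$eps[v]), oracle, tolerance = 1e-10)
  }
  expect_error(fit_normalization(ph[ph$diagnosis == "AD", ],
                                 phenotypes = "a"), "NC")
})

test_that("normalization applies the offset formula exactly", {
  m <- structure(list(icv_mean = 1.5e6, eps = c(roi = 0.003),
                      phenotypes = "roi"), class = "norm_model")
  ph <- tibble::tibble(sample_id = c("x", "y", "z"),
                       icv = c(1.5e6 + 1e5, 1.5e6, 1.4e6),
                       roi = c(5000, 5000, 5000))
  out <- normalize_volumes(ph, m)
  expect_equal(out$roi, c(4700, 5000, 5300))   # 5000 - 0.003 * (+-1e5 / 0)
  # eps = 0 leaves volumes untouched
  m0 <- structure(list(icv_mean = 1.5e6, eps = c(roi = 0),
                       phenotypes = "roi"), class = "norm_model")
  expect_identical(normalize_volumes(ph, m0)$roi, ph$roi)
  expect_error(normalize_volumes(dplyr::select(ph, -"roi"), m), "absent")
})

test_that("normalization is invariant to a constant ICV shift", {
  G <- simulate_genotypes(60, 30, seed = 33)
  sim <- simulate_phenotypes(G, truth_spec(seed = 34))
  ph <- sim$phenotypes
  m1 <- fit_normalization(ph)
  n1 <- normalize_volumes(ph, m1)
  ph2 <- dplyr::mutate(ph, icv = icv + 123456)
  m2 <- fit_normalization(ph2)
  n2 <- normalize_volumes(ph2, m2)
  expect_equal(as.data.frame(n1), as.data.frame(n2), tolerance = 1e-8)
})

test_that("structure correlation is a valid correlation matrix", {
  set.seed(35)
  norm <- tibble::tibble(sample_id = as.character(1:40),
                         a = rnorm(40), b = rnorm(40), c = rnorm(40))
  C <- structure_correlation(norm)
  expect_identical(diag(C), c(a = 1, b = 1, c = 1))
  expect_identical(C, t(C))
  expect_true(all(C >= -1 & C <= 1))
  # textbook Pearson formula oracle
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(C["a", "b"], pearson(norm$a, norm$b), tolerance = 1e-12)
  norm$d <- norm$a
  expect_equal(structure_correlation(norm)["a", "d"], 1)
  norm$e <- 5
  expect_error(structure_correlation(norm), "zero-variance phenotype.*e")
})

test_that("complete-linkage clustering recovers planted blocks", {
  labs <- paste0("p", 1:6)
  C <- diag(6)
  C[1:3, 1:3] <- 0.9; C[4:6, 4:6] <- 0.9; diag(C) <- 1
  dimnames(C) <- list(labs, labs)
  part <- cluster_modules(C, k = 2)
  expect_identical(unname(part$assignment[1:3]), rep(part$assignment[[1]], 3))
  expect_identical(unname(part$assignment[4:6]), rep(part$assignment[[4]], 3))
  expect_false(part$assignment[[1]] == part$assignment[[4]])
  # k = dim gives singletons
  expect_length(unique(cluster_modules(C, k = 6)$assignment), 6)
  expect_error(cluster_modules(C, k = 7), "k must be")
  # anti-correlated structures co-cluster under the |r| distance
  C2 <- diag(4); C2[1, 2] <- C2[2, 1] <- -0.95; C2[3, 4] <- C2[4, 3] <- 0.6
  dimnames(C2) <- list(paste0("q", 1:4), paste0("q", 1:4))
  p2 <- cluster_modules(C2, k = 2)
  expect_identical(p2$assignment[["q1"]], p2$assignment[["q2"]])
})

test_that("clustering agrees with a naive O(n^3) agglomeration oracle", {
  set.seed(36)
  for (trial in 1:100) {
    X <- matrix(rnorm(20 * 10), 20, 10,
                dimnames = list(NULL, paste0("v", 1:10)))
    C <- cor(X)
    d <- 1 - abs(C)
    part <- cluster_modules(C, k = 3)
    oracle <- complete_linkage_oracle(d, 3)
    expect_equal(adjusted_rand_index(unname(part$assignment), oracle), 1)
  }
})

test_that("module traits are member sums and conserve the total", {
  norm <- tibble::tibble(sample_id = c("a", "b"),
                         p1 = c(1, 2), p2 = c(10, 20),
                         p3 = c(100, 200), p4 = c(1000, 2000))
  part <- c(p1 = 1L, p2 = 1L, p3 = 2L, p4 = 3L)
  tr <- module_traits(part, norm)
  expect_equal(tr$M1, c(11, 22))      # hand-summed
  expect_equal(tr$M2, c(100, 200))    # singleton module
  expect_equal(tr$M1 + tr$M2 + tr$M3,
               rowSums(as.matrix(norm[, c("p1", "p2", "p3", "p4")])))
  expect_error(module_traits(c(p9 = 1L), norm), "lacks")
})

test_that("synthetic five-factor volumes recover the planted partition exactly", {
  G <- simulate_genotypes(250, 30, seed = 37)
  spec <- truth_spec(module_factor_sd = 0.10, noise_sd = 0.02, seed = 38)
  sim <- simulate_phenotypes(G, spec)
  nm <- fit_normalization(sim$phenotypes)
  normd <- normalize_volumes(sim$phenotypes, nm)
  C <- structure_correlation(normd)
  part <- cluster_modules(C, k = 5)
  ari <- adjusted_rand_index(part$assignment, spec$module_assignment)
  expect_equal(ari, 1)
  # cross-check our ARI against an independent implementation
  expect_equal(
    ari,
    mclust::adjustedRandIndex(
      part$assignment[names(spec$module_assignment)],
      spec$module_assignment
    )
  )
})

test_that("group summaries match the Welch t closed form", {
  set.seed(39)
  ph <- tibble::tibble(
    diagnosis = rep(c("AD", "NC"), each = 30),
    age = rnorm(60, 75, 5)
  )
  gs <- group_summary(ph, vars = "age")
  x <- ph$age[ph$diagnosis == "AD"]; y <- ph$age[ph$diagnosis == "NC"]
  tt <- (mean(x) - mean(y)) / sqrt(var(x) / 30 + var(y) / 30)
  expect_equal(gs$statistic[gs$variable == "age"], tt, tolerance = 1e-12)
  expect_equal(gs$mean_AD[gs$variable == "n"], 30)
  # identical groups: zero difference, p = 1
  ph2 <- tibble::tibble(diagnosis = rep(c("AD", "NC"), each = 10),
                        age = rep(rnorm(10), 2))
  gs2 <- group_summary(ph2, vars = "age")
  expect_equal(gs2$statistic[2], 0)
  expect_equal(gs2$p_value[2], 1)
  expect_error(group_summary(tibble::tibble(diagnosis = "AD", age = 1)),
               "at least 2")
})

test_that("a planted education gap is detected with high power", {
  # gap ~1.4 y at n = 200/200 with sd ~3: Welch test should nearly always fire
  set.seed(40)
  hits <- vapply(1:100, function(i) {
    ph <- tibble::tibble(
      diagnosis = rep(c("AD", "NC"), each = 200),
      education = c(rnorm(200, 14.65, 3.17), rnorm(200, 16.07, 2.80))
    )
    group_summary(ph, vars = "education")$p_value[2] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})
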