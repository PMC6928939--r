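#' Specification of quality-control defects to plant in genotypes
#'
#' Describes deliberate data pathologies for exercising the QC filters:
#' elevated per-sample or per-variant missingness, duplicated samples (to
#' trip the relatedness check), flipped reported sex, variants with forced
#' genotype counts (Hardy-Weinberg violations) and variants redrawn at a
#' forced low minor allele frequency.
#'
#' @param missing_rate_samples named numeric vector sample id -> missing
#'   rate in \[0, 1\].
#' @param missing_rate_snps named numeric vector variant id -> missing rate.
#' @param duplicate_pairs list of length-2 character vectors
#'   `c(source, target)`: the target sample's dosages are overwritten with
#'   the source's.
#' @param sex_flip_samples character vector of sample ids whose reported sex
#'   is flipped (genotypes untouched).
#' @param hwe_violation_snps named list variant id -> integer genotype counts
#'   `c(n_AA, n_Aa, n_aa)` summing to the sample count; the variant's column
#'   is replaced by a random permutation of those genotypes.
#' @param low_maf_snps named numeric vector variant id -> forced MAF; the
#'   column is redrawn under HWE at that frequency.
#' @return An object of class `defect_spec`.
#' @export
defect_spec <- function(missing_rate_samples = NULL,
                        missing_rate_snps = NULL,
                        duplicate_pairs = NULL,
                        sex_flip_samples = character(),
                        hwe_violation_snps = NULL,
                        low_maf_snps = NULL) {
  chk_rate <- function(x, what) {
    if (!is.null(x) && (any(x < 0) || any(x > 1))) {
      stop(what, " rates must lie in [0, 1]")
    }
  }
  chk_rate(missing_rate_samples, "sample missing")
  chk_rate(missing_rate_snps, "variant missing")
  if (!is.null(low_maf_snps) && (any(low_maf_snps < 0) ||
                                 any(low_maf_snps > 0.5))) {
    stop("forced MAFs must lie in [0, 0.5]")
  }
  both <- intersect(names(hwe_violation_snps), names(low_maf_snps))
  if (length(both)) {
    stop("conflicting defects (HWE violation and forced MAF) on: ",
         paste(both, collapse = ", "))
  }
  structure(
    list(missing_rate_samples = missing_rate_samples,
         missing_rate_snps = missing_rate_snps,
         duplicate_pairs = duplicate_pairs,
         sex_flip_samples = sex_flip_samples,
         hwe_violation_snps = hwe_violation_snps,
         low_maf_snps = low_maf_snps),
    class = "defect_spec"
  )
}

#' Inject QC defects into a genotype matrix
#'
#' Applies a [defect_spec()] to a copy of `G`: duplicates are copied first,
#' then forced-count and forced-MAF variants are rewritten, then missingness
#' is sprinkled, and finally reported sexes are flipped. The input object is
#' not modified.
#'
#' @param G a [genotype_matrix()].
#' @param d a [defect_spec()].
#' @param seed integer seed controlling the random placement of missing
#'   calls, permuted genotypes and redrawn columns.
#' @return A new [genotype_matrix()] with the defects applied.
#' @export
inject_defects <- function(G, d, seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(d, "defect_spec"))
  ids_s <- G$sample_meta$id
  ids_v <- G$variant_meta$id
  ref <- function(x, pool, what) {
    bad <- setdiff(x, pool)
    if (length(bad)) stop("unknown ", what, ": ", paste(bad, collapse = ", "))
  }
  ref(names(d$missing_rate_samples), ids_s, "sample id(s)")
  ref(names(d$missing_rate_snps), ids_v, "variant id(s)")
  ref(unlist(d$duplicate_pairs), ids_s, "sample id(s)")
  ref(d$sex_flip_samples, ids_s, "sample id(s)")
  ref(names(d$hwe_violation_snps), ids_v, "variant id(s)")
  ref(names(d$low_maf_snps), ids_v, "variant id(s)")
  set.seed(as.integer(seed))

  dos <- G$dosages
  n <- nrow(dos)
  for (pair in d$duplicate_pairs) {
    dos[pair[2], ] <- dos[pair[1], ]
  }
  for (v in names(d$hwe_violation_snps)) {
    cnt <- d$hwe_violation_snps[[v]]
    if (length(cnt) != 3 || sum(cnt) != n) {
      stop("forced genotype counts for ", v, " must be length 3 and sum to ",
           n)
    }
    dos[, v] <- sample(rep(c(0, 1, 2), times = cnt))
  }
  for (v in names(d$low_maf_snps)) {
    dos[, v] <- rbinom(n, 2, d$low_maf_snps[[v]])
  }
  for (s in names(d$missing_rate_samples)) {
    hit <- runif(ncol(dos)) < d$missing_rate_samples[[s]]
    dos[s, hit] <- NA
  }
  for (v in names(d$missing_rate_snps)) {
    hit <- runif(n) < d$missing_rate_snps[[v]]
    dos[hit, v] <- NA
  }
  smeta <- G$sample_meta
  flip <- smeta$id %in% d$sex_flip_samples
  smeta$reported_sex[flip] <- ifelse(smeta$reported_sex[flip] == "male",
                                     "female", "male")
  genotype_matrix(dos, G$variant_meta, smeta)
}
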