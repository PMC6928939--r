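#' Ground-truth specification for the phenotype generator
#'
#' Collects every generative parameter of the synthetic phenotype model so
#' that downstream recovery tests can compare pipeline output against a known
#' truth. The volume model for phenotype i of sample s is
#'
#' \deqn{ROI_i = \mu_i + \epsilon_i (ICV_s - \overline{ICV})
#'   + \lambda_i F_{m(i),s} + \frac{1}{|m(i)|}\big(\sum \beta g
#'   + \sum \beta_{12} \tilde g_1 \tilde g_2 + X_s \gamma_{m(i)}\big)
#'   + e_{is}}
#'
#' where \eqn{F_m} is a per-module latent factor inducing within-module
#' correlation, \eqn{\tilde g} are centred dosages (so planted interactions
#' do not leak into marginal effects), and genetic/covariate effects stated
#' per module trait are divided equally over the module's members so the
#' summed module volume carries exactly the stated coefficient.
#'
#' @param roster structure roster tibble ([roi_roster()]).
#' @param module_assignment named integer vector phenotype -> module id.
#' @param icv_slopes named vector of ICV slopes \eqn{\epsilon_i} (mm3 per
#'   mm3 ICV); default scales each structure proportionally,
#'   \eqn{\mu_i / \overline{ICV}}.
#' @param icv_mean generative mean intracranial volume (mm3).
#' @param icv_sd generative ICV standard deviation (mm3).
#' @param mean_volumes named vector of baseline volumes \eqn{\mu_i} (mm3).
#' @param loadings named vector of factor loadings \eqn{\lambda_i}; default
#'   \eqn{\mu_i} so the factor acts as a fractional common scaling.
#' @param module_factor_sd per-module latent factor sd (fraction of volume
#'   when default loadings are used); scalar or named by module.
#' @param noise_sd per-phenotype residual sd (mm3); scalar fraction of
#'   \eqn{\mu_i} if length 1 and < 1, else named vector of absolute sds.
#' @param main_effects tibble with columns `snp`, `module`, `beta`
#'   (mm3 of module volume per minor allele).
#' @param interaction_effects tibble with columns `snp1`, `snp2`, `module`,
#'   `beta` (mm3 per unit product of centred dosages).
#' @param covariate_betas tibble with columns `module`, `age`, `sex`,
#'   `education`: per-module-trait effects (mm3 per year / per male / per
#'   year of education).
#' @param prop_ad expected proportion of AD samples (default 179/393, the
#'   case fraction of the cohort the pipeline emulates).
#' @param demographics list of per-group sampling parameters for age,
#'   education, MMSE and CDR-SB (means/sds for AD and NC).
#' @param seed integer seed for [simulate_phenotypes()].
#'
#' @return An object of class `truth_spec`.
#' @export
truth_spec <- function(roster = roi_roster(),
                       module_assignment = reference_module_assignment(),
                       icv_slopes = NULL,
                       icv_mean = 1.5e6, icv_sd = 1.5e5,
                       mean_volumes = NULL,
                       loadings = NULL,
                       module_factor_sd = 0.05,
                       noise_sd = 0.03,
                       main_effects = NULL,
                       interaction_effects = NULL,
                       covariate_betas = NULL,
                       prop_ad = 179 / 393,
                       demographics = NULL,
                       seed = 1L) {
  phenos <- expand_roster(roster)
  if (!setequal(names(module_assignment), phenos)) {
    stop("module_assignment must cover exactly the expanded roster")
  }
  module_assignment <- module_assignment[phenos]
  modules <- sort(unique(module_assignment))

  if (is.null(mean_volumes)) mean_volumes <- reference_mean_volumes()[phenos]
  stopifnot(setequal(names(mean_volumes), phenos))
  mean_volumes <- mean_volumes[phenos]

  if (is.null(icv_slopes)) icv_slopes <- mean_volumes / icv_mean
  stopifnot(setequal(names(icv_slopes), phenos), all(is.finite(icv_slopes)))
  icv_slopes <- icv_slopes[phenos]

  if (is.null(loadings)) loadings <- mean_volumes
  loadings <- loadings[phenos]

  if (length(module_factor_sd) == 1 && is.null(names(module_factor_sd))) {
    module_factor_sd <- setNames(rep(module_factor_sd, length(modules)),
                                 modules)
  }
  module_factor_sd <- module_factor_sd[as.character(modules)]
  stopifnot(all(module_factor_sd >= 0))

  if (length(noise_sd) == 1 && is.null(names(noise_sd))) {
    # fraction of baseline volume when given as a scalar below 1
    noise_sd <- if (noise_sd < 1) noise_sd * mean_volumes else
      setNames(rep(noise_sd, length(phenos)), phenos)
  }
  noise_sd <- noise_sd[phenos]
  stopifnot(all(noise_sd >= 0))

  empty_main <- tibble::tibble(snp = character(), module = integer(),
                               beta = numeric())
  empty_int <- tibble::tibble(snp1 = character(), snp2 = character(),
                              module = integer(), beta = numeric())
  main_effects <- if (is.null(main_effects)) empty_main else
    tibble::as_tibble(main_effects)
  interaction_effects <- if (is.null(interaction_effects)) empty_int else
    tibble::as_tibble(interaction_effects)
  if (nrow(main_effects) &&
      !all(main_effects$module %in% modules)) {
    stop("main_effects references unknown module id(s)")
  }
  if (nrow(interaction_effects) &&
      !all(interaction_effects$module %in% modules)) {
    stop("interaction_effects references unknown module id(s)")
  }

  if (is.null(covariate_betas)) {
    covariate_betas <- tibble::tibble(
      module = modules, age = 0, sex = 0, education = 0
    )
  }
  covariate_betas <- tibble::as_tibble(covariate_betas)

  if (is.null(demographics)) {
    demographics <- list(
      age = list(AD = c(mean = 75.44, sd = 7.33),
                 NC = c(mean = 75.67, sd = 4.91)),
      education = list(AD = c(mean = 14.65, sd = 3.17),
                       NC = c(mean = 16.07, sd = 2.80)),
      mmse = list(AD = c(mean = 23.34, sd = 2.09),
                  NC = c(mean = 29.11, sd = 0.99)),
      cdrsb = list(AD = c(mean = 4.32, sd = 1.67),
                   NC = c(mean = 0.03, sd = 0.12))
    )
  }

  structure(
    list(
      roster = roster, phenotypes = phenos,
      module_assignment = module_assignment,
      icv_slopes = icv_slopes, icv_mean = icv_mean, icv_sd = icv_sd,
      mean_volumes = mean_volumes, loadings = loadings,
      module_factor_sd = module_factor_sd, noise_sd = noise_sd,
      main_effects = main_effects,
      interaction_effects = interaction_effects,
      covariate_betas = covariate_betas,
      prop_ad = prop_ad, demographics = demographics,
      seed = as.integer(seed)
    ),
    class = "truth_spec"
  )
}

#' @export
print.truth_spec <- function(x, ...) {
  cat(sprintf(
    "<truth_spec> %d phenotypes, %d modules, %d main effects, %d interactions\n",
    length(x$phenotypes), length(unique(x$module_assignment)),
    nrow(x$main_effects), nrow(x$interaction_effects)
  ))
  invisible(x)
}

#' Simulate phenotypes, covariates and diagnoses on top of genotypes
#'
#' Generates a per-sample phenotype table under the volume model described in
#' [truth_spec()]: a baseline volume per structure, a shared ICV-scaling
#' component, a per-module latent factor, planted SNP main and interaction
#' effects, covariate effects, and Gaussian noise. Diagnosis labels (AD/NC)
#' and demographics are drawn per group.
#'
#' @param G a [genotype_matrix()]; planted SNPs must exist among its variants.
#' @param spec a [truth_spec()].
#' @return A list with elements `phenotypes` (tibble: `sample_id`,
#'   `diagnosis`, `age`, `sex`, `education`, `mmse`, `cdrsb`, `icv`, one
#'   column per roster phenotype) and `truth` (the spec, echoed verbatim).
#' @export
simulate_phenotypes <- function(G, spec = truth_spec()) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(spec, "truth_spec"))
  planted <- unique(c(spec$main_effects$snp, spec$interaction_effects$snp1,
                      spec$interaction_effects$snp2))
  missing_snps <- setdiff(planted, G$variant_meta$id)
  if (length(missing_snps)) {
    stop("planted SNP(s) absent from genotypes: ",
         paste(missing_snps, collapse = ", "))
  }
  set.seed(spec$seed)
  n <- nrow(G$dosages)
  ids <- G$sample_meta$id
  sex01 <- as.numeric(G$sample_meta$reported_sex == "male")

  dx <- ifelse(runif(n) < spec$prop_ad, "AD", "NC")
  draw_group <- function(par, clamp = NULL) {
    v <- numeric(n)
    for (g in c("AD", "NC")) {
      idx <- dx == g
      v[idx] <- rnorm(sum(idx), par[[g]]["mean"], par[[g]]["sd"])
    }
    if (!is.null(clamp)) v <- pmin(pmax(v, clamp[1]), clamp[2])
    v
  }
  age <- draw_group(spec$demographics$age, clamp = c(40, 110))
  edu <- draw_group(spec$demographics$education, clamp = c(0, 30))
  mmse <- draw_group(spec$demographics$mmse, clamp = c(0, 30))
  cdrsb <- draw_group(spec$demographics$cdrsb, clamp = c(0, 18))
  icv <- abs(rnorm(n, spec$icv_mean, spec$icv_sd))

  mods <- sort(unique(spec$module_assignment))
  factors <- sapply(as.character(mods), function(m) {
    rnorm(n, 0, spec$module_factor_sd[m])
  })
  colnames(factors) <- mods
  mod_size <- table(spec$module_assignment)

  # per-module genetic + covariate contribution on the module-trait scale
  mod_extra <- matrix(0, n, length(mods), dimnames = list(NULL, mods))
  if (nrow(spec$main_effects)) {
    for (r in seq_len(nrow(spec$main_effects))) {
      e <- spec$main_effects[r, ]
      g <- G$dosages[, e$snp]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      mod_extra[, as.character(e$module)] <-
        mod_extra[, as.character(e$module)] + e$beta * g
    }
  }
  if (nrow(spec$interaction_effects)) {
    for (r in seq_len(nrow(spec$interaction_effects))) {
      e <- spec$interaction_effects[r, ]
      g1 <- G$dosages[, e$snp1]; g2 <- G$dosages[, e$snp2]
      g1[is.na(g1)] <- mean(g1, na.rm = TRUE)
      g2[is.na(g2)] <- mean(g2, na.rm = TRUE)
      prod <- (g1 - mean(g1)) * (g2 - mean(g2))
      mod_extra[, as.character(e$module)] <-
        mod_extra[, as.character(e$module)] + e$beta * prod
    }
  }
  for (r in seq_len(nrow(spec$covariate_betas))) {
    cb <- spec$covariate_betas[r, ]
    m <- as.character(cb$module)
    mod_extra[, m] <- mod_extra[, m] +
      cb$age * (age - 75.5) + cb$sex * sex01 + cb$education * (edu - 15.4)
  }

  vol <- matrix(0, n, length(spec$phenotypes),
                dimnames = list(ids, spec$phenotypes))
  for (i in seq_along(spec$phenotypes)) {
    ph <- spec$phenotypes[i]
    m <- as.character(spec$module_assignment[ph])
    vol[, i] <- spec$mean_volumes[ph] +
      spec$icv_slopes[ph] * (icv - spec$icv_mean) +
      spec$loadings[ph] * factors[, m] +
      mod_extra[, m] / as.numeric(mod_size[m]) +
      rnorm(n, 0, spec$noise_sd[ph])
  }

  phen <- tibble::tibble(
    sample_id = ids, diagnosis = dx, age = age,
    sex = G$sample_meta$reported_sex, education = edu,
    mmse = mmse, cdrsb = cdrsb, icv = icv
  )
  phen <- dplyr::bind_cols(phen, tibble::as_tibble(vol))
  list(phenotypes = phen, truth = spec)
}
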