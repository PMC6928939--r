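#' Assemble a pipeline run configuration
#'
#' Collects every stage threshold and, for synthetic runs, the generator
#' settings, with the analysis defaults: sample/variant call rate 0.90, HWE
#' exclusion at p <= 5e-7, MAF >= 0.10, IBD exclusion above 0.2, pruning
#' window 50 / step 5 / r2 0.8, k = 5 modules, GWAS significance 1e-4,
#' interaction threshold 5e-4, top 5 main-effect and top 3 interactive
#' SNPs. Planted effect sizes are expressed as multiples of each module
#' trait's residual standard deviation so one scale works across modules of
#' very different volume.
#'
#' @param seed integer master seed; every stage derives its randomness from
#'   it.
#' @param sim list of generator settings (see Details); `NULL` entries fall
#'   back to defaults.
#' @param thresholds list of stage thresholds; `NULL` entries fall back to
#'   defaults.
#' @param out_dir optional output directory; when set, every stage writes
#'   its tables there with provenance headers.
#'
#' @details Generator settings: `n_samples` (393), `n_snps` (5000),
#'   `maf_range` (0.1..0.5), `n_ld_blocks` (0), `ld_rho` (0.8),
#'   `n_main_per_module` (2), `main_beta_scales` (0.6, 0.5 module-trait sds
#'   per allele), `n_partners_per_module` (1), `interaction_beta_scale`
#'   (0.8), `anchors_per_partner` (2), `module_factor_sd` (0.05),
#'   `noise_sd` (0.03), `prop_ad` (179/393), `defects` (a [defect_spec()]
#'   or `NULL`).
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, sim = list(), thresholds = list(),
                       out_dir = NULL) {
  sim_def <- list(
    n_samples = 393, n_snps = 5000, maf_range = c(0.1, 0.5),
    n_ld_blocks = 0, ld_rho = 0.8,
    n_main_per_module = 2, main_beta_scales = c(0.6, 0.5),
    n_partners_per_module = 1, interaction_beta_scale = 0.8,
    anchors_per_partner = 2,
    module_factor_sd = 0.05, noise_sd = 0.03, prop_ad = 179 / 393,
    defects = NULL
  )
  thr_def <- list(
    sample_call_min = 0.90, variant_call_min = 0.90,
    maf_min = 0.10, hwe_alpha = 5e-7, ibd_max = 0.2,
    prune_window = 50, prune_step = 5, prune_r2 = 0.8,
    k = 5, gwas_alpha = 1e-4, epi_alpha = 5e-4,
    top_main = 5, top_interactive = 3
  )
  structure(
    list(seed = as.integer(seed),
         sim = modifyList(sim_def, sim),
         thresholds = modifyList(thr_def, thresholds),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys `seed`, `out_dir`, and nested `sim` / `thresholds` maps;
#' anything omitted keeps the [run_config()] default.
#'
#' @param file YAML path.
#' @return A `run_config`.
#' @export
read_run_config <- function(file) {
  y <- yaml::read_yaml(file)
  run_config(
    seed = if (is.null(y$seed)) 1L else y$seed,
    sim = if (is.null(y$sim)) list() else y$sim,
    thresholds = if (is.null(y$thresholds)) list() else y$thresholds,
    out_dir = y$out_dir
  )
}

# residual sd of each module trait implied by the truth parameters
.module_trait_sd <- function(spec) {
  mods <- sort(unique(spec$module_assignment))
  vapply(as.character(mods), function(m) {
    members <- names(spec$module_assignment)[spec$module_assignment == m]
    fac <- sum(spec$loadings[members]) * spec$module_factor_sd[m]
    sqrt(fac^2 + sum(spec$noise_sd[members]^2))
  }, numeric(1))
}

#' Build the planted truth for a synthetic pipeline run
#'
#' Chooses planted main-effect SNPs and interaction partners deterministically
#' from the generated variants (autosomal, generative MAF comfortably above
#' the MAF filter, all distinct), and scales betas by each module trait's
#' residual sd.
#'
#' @param G a [genotype_matrix()] from [simulate_genotypes()].
#' @param cfg a [run_config()].
#' @return A [truth_spec()].
#' @export
plan_truth <- function(G, cfg) {
  sim <- cfg$sim
  base <- truth_spec(
    module_factor_sd = sim$module_factor_sd, noise_sd = sim$noise_sd,
    prop_ad = sim$prop_ad, seed = cfg$seed + 1L
  )
  sd_m <- .module_trait_sd(base)
  mods <- sort(unique(base$module_assignment))

  vm <- G$variant_meta
  eligible <- vm$id[!vm$x_flag &
                      (if ("maf_true" %in% names(vm)) vm$maf_true >= 0.15
                       else TRUE)]
  n_need <- length(mods) * (sim$n_main_per_module +
                              sim$n_partners_per_module)
  if (length(eligible) < n_need) stop("too few eligible variants to plant")
  set.seed(cfg$seed + 2L)
  picks <- sample(eligible, n_need)

  main <- list(); inter <- list()
  idx <- 1
  scales <- rep_len(sim$main_beta_scales, sim$n_main_per_module)
  for (mi in seq_along(mods)) {
    m <- mods[mi]
    mains_m <- picks[idx:(idx + sim$n_main_per_module - 1)]
    idx <- idx + sim$n_main_per_module
    main[[mi]] <- tibble::tibble(
      snp = mains_m, module = m,
      beta = scales * sd_m[as.character(m)]
    )
    if (sim$n_partners_per_module > 0) {
      partners_m <- picks[idx:(idx + sim$n_partners_per_module - 1)]
      idx <- idx + sim$n_partners_per_module
      n_anchor <- min(sim$anchors_per_partner, length(mains_m))
      inter[[length(inter) + 1]] <- tidyr::crossing(
        snp1 = mains_m[seq_len(n_anchor)], snp2 = partners_m
      ) |>
        dplyr::mutate(module = m,
                      beta = sim$interaction_beta_scale *
                        sd_m[as.character(m)])
    }
  }
  truth_spec(
    module_factor_sd = sim$module_factor_sd, noise_sd = sim$noise_sd,
    prop_ad = sim$prop_ad, seed = cfg$seed + 1L,
    main_effects = dplyr::bind_rows(main),
    interaction_effects = if (length(inter)) dplyr::bind_rows(inter) else NULL
  )
}

#' Run the full pipeline on synthetic data
#'
#' Executes the stages in analysis order: genotype simulation, phenotype
#' simulation with planted truth, optional defect injection, genotype QC,
#' ICV normalization, module clustering, module-trait GWAS, anchored
#' interaction scan and interactive-SNP selection, then assembles a
#' machine-readable report including truth-recovery metrics (adjusted Rand
#' index of the module partition, GWAS ranks of planted main-effect SNPs,
#' recovery of planted interaction partners). With `cfg$out_dir` set, every
#' stage writes its tables with seed/threshold headers.
#'
#' @param cfg a [run_config()].
#' @return A list of class `pipeline_result` with every stage output and
#'   `report`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  thr <- cfg$thresholds
  out <- cfg$out_dir
  if (!is.null(out) && !dir.exists(out)) {
    dir.create(out, recursive = TRUE)
  }
  meta <- list(seed = cfg$seed,
               thresholds = paste(names(unlist(thr)), unlist(thr),
                                  sep = "=", collapse = " "))
  emit <- function(df, name) {
    if (!is.null(out)) write_stage_tsv(df, file.path(out, name), meta)
  }

  # --- simulate
  G0 <- simulate_genotypes(
    cfg$sim$n_samples, cfg$sim$n_snps, maf_range = cfg$sim$maf_range,
    n_ld_blocks = cfg$sim$n_ld_blocks, ld_rho = cfg$sim$ld_rho,
    seed = cfg$seed
  )
  truth <- plan_truth(G0, cfg)
  sim_ph <- simulate_phenotypes(G0, truth)
  pheno <- sim_ph$phenotypes
  G_in <- if (!is.null(cfg$sim$defects)) {
    inject_defects(G0, cfg$sim$defects, seed = cfg$seed + 3L)
  } else {
    G0
  }
  if (!is.null(out)) {
    readr::write_tsv(pheno, file.path(out, "phenotypes.tsv"))
    write_truth_json(truth, file.path(out, "truth.json"))
  }

  # --- QC
  qc <- run_qc(
    G_in, sample_call_min = thr$sample_call_min,
    variant_call_min = thr$variant_call_min, maf_min = thr$maf_min,
    hwe_alpha = thr$hwe_alpha, ibd_max = thr$ibd_max,
    prune_window = thr$prune_window, prune_step = thr$prune_step,
    prune_r2 = thr$prune_r2
  )
  G <- qc$genotypes
  emit(tidy(qc$report), "qc_report.tsv")

  pheno <- dplyr::filter(pheno, .data$sample_id %in% G$sample_meta$id)
  pheno <- pheno[match(G$sample_meta$id, pheno$sample_id), ]

  # --- modules
  nm <- fit_normalization(pheno)
  normd <- normalize_volumes(pheno, nm)
  C <- structure_correlation(normd)
  part <- cluster_modules(C, k = thr$k)
  traits <- module_traits(part, normd)
  demog <- group_summary(pheno)
  emit(normd, "normalized_volumes.tsv")
  emit(tibble::as_tibble(C, rownames = "phenotype"), "correlation.tsv")
  emit(tidy(part), "module_partition.tsv")
  emit(traits, "module_traits.tsv")
  emit(demog, "group_summary.tsv")

  ari <- adjusted_rand_index(part$assignment, truth$module_assignment)
  # map estimated module -> majority true module, for recovery bookkeeping
  mod_map <- tidy(part) |>
    dplyr::mutate(true_module =
                    truth$module_assignment[.data$phenotype]) |>
    dplyr::count(.data$module, .data$true_module) |>
    dplyr::group_by(.data$module) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()

  covars <- data.frame(
    age = pheno$age,
    sex = as.numeric(pheno$sex == "male"),
    education = pheno$education
  )

  modules_out <- list()
  for (m in sort(unique(part$assignment))) {
    trait <- setNames(traits[[paste0("M", m)]], traits$sample_id)
    scan <- assoc_scan(trait, G, covars, module = paste0("M", m))
    hits <- significant_hits(scan, thr$gwas_alpha)
    top <- top_main_snps(scan, thr$top_main)
    epi <- scan_anchors(trait, top$id, G, covars,
                        p_thresh = thr$epi_alpha, module = paste0("M", m))
    net <- build_network(epi)
    sel <- suppressWarnings(select_interactive(net, thr$top_interactive))
    true_m <- mod_map$true_module[mod_map$module == m]
    planted_main <- dplyr::filter(truth$main_effects,
                                  .data$module == true_m)
    ranks <- match(planted_main$snp,
                   dplyr::arrange(scan$results, .data$p)$id)
    planted_partners <- unique(dplyr::filter(
      truth$interaction_effects, .data$module == true_m)$snp2)

    emit(dplyr::transmute(
      tidy(scan), CHR = .data$chrom, SNP = .data$id, BP = .data$pos,
      BETA = .data$beta, SE = .data$se, T = .data$statistic, P = .data$p
    ), sprintf("gwas_M%d.tsv", m))
    emit(epi$edges, sprintf("interactions_M%d.tsv", m))

    modules_out[[paste0("M", m)]] <- list(
      module = m, true_module = true_m,
      scan = scan, hits = hits, top_main = top,
      epistasis = epi, network = net, interactive = sel,
      planted_main = planted_main, planted_main_rank = ranks,
      planted_partners = planted_partners,
      planted_partners_selected =
        intersect(planted_partners, sel$partner)
    )
  }

  report <- list(
    seed = cfg$seed, thresholds = thr,
    n_samples_in = nrow(G_in$dosages), n_variants_in = ncol(G_in$dosages),
    n_samples_retained = nrow(G$dosages),
    n_variants_retained = ncol(G$dosages),
    module_sizes = as.list(table(part$assignment)),
    module_ari = ari,
    modules = purrr::map(modules_out, function(mo) {
      list(
        module = mo$module, true_module = mo$true_module,
        n_significant = nrow(mo$hits),
        main_effect_snps = mo$top_main$id,
        planted_main = mo$planted_main$snp,
        planted_main_rank = mo$planted_main_rank,
        interactive_snps = mo$interactive$partner,
        interactive_degrees = mo$interactive$degree,
        planted_partners = mo$planted_partners,
        planted_partners_selected = mo$planted_partners_selected
      )
    })
  )
  if (!is.null(out)) {
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(
    list(config = cfg, genotypes_input = G_in, genotypes = G, qc = qc,
         truth = truth, phenotypes = pheno, norm_model = nm,
         normalized = normd, correlation = C, partition = part,
         traits = traits, group_summary = demog, modules = modules_out,
         report = report),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<pipeline_result> seed %d: %d/%d samples, %d/%d variants retained\n",
    r$seed, r$n_samples_retained, r$n_samples_in,
    r$n_variants_retained, r$n_variants_in
  ))
  cat(sprintf("  module ARI vs truth: %.3f\n", r$module_ari))
  for (m in names(r$modules)) {
    mo <- r$modules[[m]]
    cat(sprintf(
      "  %s: %d significant; main: %s; interactive: %s\n",
      m, mo$n_significant,
      paste(mo$main_effect_snps, collapse = ","),
      paste(mo$interactive_snps, collapse = ",")
    ))
  }
  invisible(x)
}
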