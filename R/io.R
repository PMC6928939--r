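#' Write genotypes as PLINK-style text .ped/.map files
#'
#' The .map file has four columns (chromosome, variant id, genetic distance
#' 0, 1-based bp position); the .ped file has the six standard leading
#' columns (family id, individual id, paternal and maternal id 0, sex coded
#' 1 = male / 2 = female, phenotype -9) followed by two allele columns per
#' variant. Dosage 2 is written as two copies of the counted allele `a1`,
#' 0 as two copies of `a2`, missing as `0 0`.
#'
#' @param G a [genotype_matrix()].
#' @param prefix path prefix; `<prefix>.ped` and `<prefix>.map` are written.
#' @return Invisibly, the two file paths.
#' @export
write_plink <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  vm <- G$variant_meta
  map <- data.frame(chrom = vm$chrom, id = vm$id, cm = 0L, pos = vm$pos)
  write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  dos <- G$dosages
  n <- nrow(dos); m <- ncol(dos)
  al <- matrix("0", n, 2 * m)
  for (j in seq_len(m)) {
    g <- dos[, j]
    a1 <- vm$a1[j]; a2 <- vm$a2[j]
    al[, 2 * j - 1] <- dplyr::case_when(
      is.na(g) ~ "0", g >= 1 ~ a1, TRUE ~ a2)
    al[, 2 * j] <- dplyr::case_when(
      is.na(g) ~ "0", g == 2 ~ a1, TRUE ~ a2)
  }
  lead <- cbind(
    G$sample_meta$id, G$sample_meta$id, "0", "0",
    ifelse(G$sample_meta$reported_sex == "male", "1", "2"), "-9"
  )
  write.table(cbind(lead, al), paste0(prefix, ".ped"), sep = " ",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}

#' Read PLINK-style text .ped/.map files
#'
#' Inverse of [write_plink()]. The counted (dosage) allele per variant is
#' the minor allele among observed calls; at exactly 0.5 the
#' alphabetically smaller allele is counted. Chromosome `"X"` (or `"23"`)
#' sets the `x_flag`.
#'
#' @param prefix path prefix of the `.ped`/`.map` pair.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), sep = "\t",
                    col.names = c("chrom", "id", "cm", "pos"),
                    colClasses = c("character", "character", "integer",
                                   "integer"))
  ped <- read.table(paste0(prefix, ".ped"), sep = " ",
                    colClasses = "character")
  m <- nrow(map)
  stopifnot(ncol(ped) == 6 + 2 * m)
  n <- nrow(ped)
  dos <- matrix(NA_real_, n, m)
  a1 <- a2 <- character(m)
  for (j in seq_len(m)) {
    A <- as.matrix(ped[, 6 + c(2 * j - 1, 2 * j)])
    A[A == "0"] <- NA
    alleles <- sort(unique(stats::na.omit(as.vector(A))))
    if (length(alleles) == 0) alleles <- c("A", "C")
    if (length(alleles) == 1) alleles <- c(alleles, setdiff(c("A", "C"),
                                                            alleles)[1])
    f1 <- mean(A == alleles[1], na.rm = TRUE)
    # `alleles` is sorted, so ties at 0.5 count the alphabetically smaller
    counted <- if (f1 <= 0.5) alleles[1] else alleles[2]
    other <- setdiff(alleles, counted)[1]
    dos[, j] <- rowSums(A == counted)
    a1[j] <- counted; a2[j] <- other
  }
  ids <- ped[, 2]
  dimnames(dos) <- list(ids, map$id)
  genotype_matrix(
    dos,
    tibble::tibble(id = map$id, chrom = map$chrom, pos = map$pos,
                   a1 = a1, a2 = a2,
                   x_flag = map$chrom %in% c("X", "23")),
    tibble::tibble(id = ids,
                   reported_sex = ifelse(ped[, 5] == "1", "male", "female"))
  )
}

#' Write / read a genotype matrix as TSV dosage + variant tables
#'
#' `write_dosage_tsv()` writes two files: `<prefix>.dosage.tsv` (columns
#' `sample_id`, `reported_sex`, then one dosage column per variant, `NA`
#' for missing) and `<prefix>.variants.tsv` (variant metadata).
#' `read_dosage_tsv()` reads them back.
#'
#' @param G a [genotype_matrix()].
#' @param prefix path prefix.
#' @return `write_dosage_tsv()` invisibly returns the paths;
#'   `read_dosage_tsv()` returns a [genotype_matrix()].
#' @export
write_dosage_tsv <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  tab <- dplyr::bind_cols(
    tibble::tibble(sample_id = G$sample_meta$id,
                   reported_sex = G$sample_meta$reported_sex),
    tibble::as_tibble(G$dosages)
  )
  f1 <- paste0(prefix, ".dosage.tsv")
  f2 <- paste0(prefix, ".variants.tsv")
  readr::write_tsv(tab, f1)
  readr::write_tsv(G$variant_meta, f2)
  invisible(c(dosage = f1, variants = f2))
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(prefix) {
  tab <- readr::read_tsv(paste0(prefix, ".dosage.tsv"),
                         show_col_types = FALSE)
  vm <- readr::read_tsv(paste0(prefix, ".variants.tsv"),
                        show_col_types = FALSE,
                        col_types = readr::cols(chrom = "c"))
  dos <- as.matrix(tab[, vm$id, drop = FALSE])
  dimnames(dos) <- list(tab$sample_id, vm$id)
  genotype_matrix(
    dos, vm,
    tibble::tibble(id = tab$sample_id, reported_sex = tab$reported_sex)
  )
}

#' Read a phenotype table from TSV
#'
#' Expects at minimum `sample_id`, `diagnosis`, `age`, `sex`, `education`,
#' `icv`, plus one column per structure volume.
#'
#' @param file TSV path.
#' @return A tibble.
#' @export
read_phenotypes <- function(file) {
  tab <- readr::read_tsv(file, show_col_types = FALSE)
  need <- c("sample_id", "diagnosis", "age", "sex", "education", "icv")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  }
  tab
}

#' Serialize a truth record as JSON
#'
#' @param truth a [truth_spec()].
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_truth_json <- function(truth, file) {
  stopifnot(inherits(truth, "truth_spec"))
  x <- list(
    phenotypes = truth$phenotypes,
    module_assignment = as.list(truth$module_assignment),
    icv_slopes = as.list(truth$icv_slopes),
    icv_mean = truth$icv_mean, icv_sd = truth$icv_sd,
    module_factor_sd = as.list(truth$module_factor_sd),
    noise_sd = as.list(truth$noise_sd),
    main_effects = truth$main_effects,
    interaction_effects = truth$interaction_effects,
    covariate_betas = truth$covariate_betas,
    prop_ad = truth$prop_ad, seed = truth$seed
  )
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

# TSV with '# key: value' header lines recording run provenance
write_stage_tsv <- function(df, path, meta = list()) {
  hdr <- vapply(names(meta), function(k) {
    sprintf("# %s: %s", k, paste(meta[[k]], collapse = " "))
  }, character(1))
  writeLines(hdr, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
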