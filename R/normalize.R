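#' Fit the ICV normalization model
#'
#' For each structure volume the model removes the head-size nuisance via
#' \deqn{ROI_{norm} = ROI_{raw} - \epsilon_i\,(ICV_{raw} - \overline{ICV})}
#' where \eqn{\epsilon_i} is the ordinary least-squares slope of the raw
#' volume on raw ICV fitted in the normal-control (NC) group only — the
#' slope should describe the healthy volume/head-size relationship, which
#' need not hold in the patient group — while \eqn{\overline{ICV}} is the
#' mean ICV across all samples.
#'
#' @param pheno phenotype tibble with columns `diagnosis` (values `"AD"` /
#'   `"NC"`), `icv`, and one column per structure volume.
#' @param phenotypes character vector of volume column names; defaults to
#'   the expanded default roster intersected with `names(pheno)`.
#' @return An object of class `norm_model`: list with `icv_mean`, named
#'   slope vector `eps`, and `phenotypes`.
#' @export
fit_normalization <- function(pheno, phenotypes = NULL) {
  if (is.null(phenotypes)) {
    phenotypes <- intersect(expand_roster(), names(pheno))
  }
  if (length(phenotypes) == 0) stop("no phenotype columns found")
  stopifnot(all(phenotypes %in% names(pheno)),
            all(c("diagnosis", "icv") %in% names(pheno)))
  nc <- dplyr::filter(pheno, .data$diagnosis == "NC")
  if (nrow(nc) < 3) stop("need at least 3 NC samples to fit slopes")
  v_icv <- var(nc$icv)
  if (!is.finite(v_icv) || v_icv <= 0) {
    stop("degenerate fit: ICV has zero variance in the NC group")
  }
  icv_c <- nc$icv - mean(nc$icv)
  eps <- vapply(phenotypes, function(ph) {
    sum(icv_c * (nc[[ph]] - mean(nc[[ph]]))) / sum(icv_c^2)
  }, numeric(1))
  structure(
    list(icv_mean = mean(pheno$icv), eps = eps, phenotypes = phenotypes),
    class = "norm_model"
  )
}

#' @export
print.norm_model <- function(x, ...) {
  cat(sprintf("<norm_model> %d phenotypes, ICV mean %.0f mm^3\n",
              length(x$phenotypes), x$icv_mean))
  invisible(x)
}

#' @rdname fit_normalization
#' @param x a `norm_model`.
#' @param ... unused.
#' @method tidy norm_model
#' @export
tidy.norm_model <- function(x, ...) {
  tibble::tibble(phenotype = x$phenotypes, eps = unname(x$eps),
                 icv_mean = x$icv_mean)
}

#' Apply ICV normalization to raw volumes
#'
#' Subtracts each structure's fitted ICV component,
#' \eqn{ROI_{norm} = ROI_{raw} - \epsilon_i (ICV_{raw} - \overline{ICV})}.
#' A sample at exactly the mean ICV keeps its raw volumes.
#'
#' @param pheno phenotype tibble with `sample_id`, `icv` and the model's
#'   volume columns.
#' @param model a `norm_model` from [fit_normalization()].
#' @return Tibble with `sample_id` and one normalized column per phenotype
#'   (same names as the raw columns).
#' @export
normalize_volumes <- function(pheno, model) {
  stopifnot(inherits(model, "norm_model"))
  missing_ph <- setdiff(model$phenotypes, names(pheno))
  if (length(missing_ph)) {
    stop("phenotype column(s) absent from table: ",
         paste(missing_ph, collapse = ", "))
  }
  off <- pheno$icv - model$icv_mean
  out <- tibble::tibble(sample_id = pheno$sample_id)
  for (ph in model$phenotypes) {
    out[[ph]] <- pheno[[ph]] - model$eps[[ph]] * off
  }
  out
}
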