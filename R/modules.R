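#' Pairwise Pearson correlation of normalized structure volumes
#'
#' @param norm tibble from [normalize_volumes()] (`sample_id` plus volume
#'   columns), or any tibble of numeric phenotype columns.
#' @param phenotypes columns to use; default every column except
#'   `sample_id`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
structure_correlation <- function(norm, phenotypes = NULL) {
  if (is.null(phenotypes)) phenotypes <- setdiff(names(norm), "sample_id")
  x <- as.matrix(norm[, phenotypes, drop = FALSE])
  if (nrow(x) < 3) stop("need at least 3 samples")
  vars <- apply(x, 2, var)
  if (any(vars <= 0 | !is.finite(vars))) {
    stop("zero-variance phenotype(s): ",
         paste(phenotypes[vars <= 0 | !is.finite(vars)], collapse = ", "))
  }
  cor(x)
}

#' Cluster structures into modules by complete-linkage agglomeration
#'
#' Converts the correlation matrix into the dissimilarity `1 - |r|` (the
#' default; ventricular volumes anti-correlate with tissue volumes, and the
#' magnitude of co-variation is what defines a module) or `1 - r`, runs
#' complete-linkage hierarchical agglomeration, and cuts the tree into `k`
#' modules.
#'
#' @param C correlation matrix from [structure_correlation()].
#' @param k number of modules (1..ncol(C)).
#' @param distance `"abs-corr"` for `1 - |r|` (default) or `"corr"` for
#'   `1 - r`.
#' @return Object of class `module_partition`: named assignment vector
#'   (phenotype -> module id 1..k), `k`, the `hclust` tree and its merge
#'   heights.
#' @export
cluster_modules <- function(C, k = 5, distance = c("abs-corr", "corr")) {
  distance <- match.arg(distance)
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (k < 1 || k > nrow(C)) stop("k must be between 1 and ncol(C)")
  d <- if (distance == "abs-corr") 1 - abs(C) else 1 - C
  hc <- hclust(stats::as.dist(d), method = "complete")
  assignment <- cutree(hc, k = k)
  structure(
    list(assignment = assignment, k = as.integer(k), tree = hc,
         heights = hc$height, distance = distance),
    class = "module_partition"
  )
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d phenotypes in %d modules\n",
              length(x$assignment), x$k))
  print(table(module = x$assignment))
  invisible(x)
}

#' @rdname cluster_modules
#' @param x a `module_partition`.
#' @param ... unused.
#' @method tidy module_partition
#' @export
tidy.module_partition <- function(x, ...) {
  tibble::tibble(phenotype = names(x$assignment),
                 module = unname(x$assignment))
}

#' Per-sample module volumes
#'
#' The volume of a module is the sum of its member structures' normalized
#' volumes.
#'
#' @param partition a `module_partition` (or named phenotype -> module
#'   vector) covering every phenotype column used.
#' @param norm tibble from [normalize_volumes()].
#' @return Tibble with `sample_id` and one column `M<id>` per module.
#' @export
module_traits <- function(partition, norm) {
  assignment <- if (inherits(partition, "module_partition")) {
    partition$assignment
  } else {
    partition
  }
  missing_ph <- setdiff(names(assignment), names(norm))
  if (length(missing_ph)) {
    stop("normalized table lacks phenotype(s): ",
         paste(missing_ph, collapse = ", "))
  }
  out <- tibble::tibble(sample_id = norm$sample_id)
  for (m in sort(unique(assignment))) {
    members <- names(assignment)[assignment == m]
    out[[paste0("M", m)]] <-
      rowSums(as.matrix(norm[, members, drop = FALSE]))
  }
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' computed from the contingency table. 1 means identical partitions (up to
#' label permutation), 0 the expectation under random labeling.
#'
#' @param a,b label vectors over the same items (matched by names when both
#'   are named, else by position).
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    stopifnot(setequal(names(a), names(b)))
    b <- b[names(a)]
  }
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
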