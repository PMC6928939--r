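#' Build the anchor-partner interaction network
#'
#' Converts a kept-edge list from [scan_anchors()] (or any tibble with
#' `anchor`, `partner` and optionally `p` columns) into a bipartite network
#' and computes each partner's degree: the number of distinct main-effect
#' anchors it forms a significant interaction with.
#'
#' @param edges edge tibble, or an `epi_scan` object.
#' @return Object of class `interaction_network`: `edges`, and `degrees`
#'   (tibble `partner`, `degree`, `min_p`, `anchors` as a comma-separated
#'   string).
#' @export
build_network <- function(edges) {
  if (inherits(edges, "epi_scan")) edges <- edges$edges
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("anchor", "partner") %in% names(edges)))
  if (!"p" %in% names(edges)) edges$p <- NA_real_
  if (any(edges$anchor == edges$partner)) {
    stop("self-edge (anchor equal to partner) in edge list")
  }
  if (anyDuplicated(edges[, c("anchor", "partner")])) {
    stop("duplicate (anchor, partner) edge(s); deduplicate first")
  }
  degrees <- edges |>
    dplyr::group_by(.data$partner) |>
    dplyr::summarise(
      degree = dplyr::n_distinct(.data$anchor),
      min_p = if (all(is.na(.data$p))) NA_real_ else
        min(.data$p, na.rm = TRUE),
      anchors = paste(sort(unique(.data$anchor)), collapse = ","),
      .groups = "drop"
    )
  structure(list(edges = edges, degrees = degrees),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf(
    "<interaction_network> %d edges, %d partners, %d anchors\n",
    nrow(x$edges), nrow(x$degrees), dplyr::n_distinct(x$edges$anchor)
  ))
  invisible(x)
}

#' @rdname build_network
#' @param x an `interaction_network`.
#' @param ... unused.
#' @method tidy interaction_network
#' @export
tidy.interaction_network <- function(x, ...) x$degrees

#' @rdname build_network
#' @method glance interaction_network
#' @export
glance.interaction_network <- function(x, ...) {
  tibble::tibble(
    n_edges = nrow(x$edges), n_partners = nrow(x$degrees),
    n_anchors = dplyr::n_distinct(x$edges$anchor),
    max_degree = if (nrow(x$degrees)) max(x$degrees$degree) else 0L
  )
}

#' Select interactive-effect SNPs by network degree
#'
#' Ranks partners by degree (number of distinct anchors interacted with,
#' descending), breaking ties by the smallest edge p-value and then by
#' lexicographic variant id, and returns the top `k`. The ranking is
#' invariant to the input edge order.
#'
#' @param net an `interaction_network` from [build_network()].
#' @param k number of SNPs to select (default 3).
#' @return Tibble of the selected partners with `partner`, `degree`,
#'   `min_p`, `anchors`. Empty (with a warning) for an empty network.
#' @export
select_interactive <- function(net, k = 3) {
  stopifnot(inherits(net, "interaction_network"), k >= 1)
  if (nrow(net$degrees) == 0) {
    warning("empty interaction network; nothing to select")
    return(net$degrees)
  }
  ranked <- dplyr::arrange(net$degrees, dplyr::desc(.data$degree),
                           .data$min_p, .data$partner)
  head(ranked, k)
}
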