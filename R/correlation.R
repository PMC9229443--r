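# Pearson correlation of parental genetic distance with heterosis.

#' Pearson correlation with t-based significance
#'
#' Product-moment correlation with a two-sided p-value from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom. Vectors
#' with zero variance are an error, not a silent `NaN`.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return One-row tibble: `r`, `statistic`, `df`, `p_value`, `n`.
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))  # r = 0.8
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_bad("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop_bad("need at least 3 pairs for a correlation (got %d)", n)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_bad("non-finite values in input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_bad("zero variance: correlation undefined")
  }
  r <- cor(x, y)
  if (abs(r) >= 1) {
    statistic <- sign(r) * Inf
    p <- 0
  } else {
    statistic <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(abs(statistic), df = n - 2, lower.tail = FALSE)
  }
  tibble::tibble(r = r, statistic = statistic, df = n - 2, p_value = p, n = n)
}

#' Correlate parental genetic distance with heterosis
#'
#' For each trait, the marker-based genetic distance between a cross's two
#' parents is paired with that cross's mid-parent and better-parent heterosis
#' percentages, and a Pearson correlation with significance is reported for
#' each basis — the test of whether parental marker divergence predicts F1
#' heterosis. Crosses with undefined heterosis are dropped and counted.
#'
#' @param d A `gd_dist` matrix from [pairwise_distances()] covering every
#'   parent that appears in `entries`.
#' @param entries A `heterosis_tbl` from [heterosis_table()].
#' @param similarity If `TRUE`, correlate genetic similarity (1 - distance)
#'   instead of distance; this only flips the sign of r.
#' @param alpha Star levels for the significance code, default
#'   `c(0.05, 0.01)`.
#' @return A tibble of class `gd_cor`: `trait`, `basis` (`"MP"`/`"BP"`),
#'   `r`, `statistic`, `p_value`, `n`, `n_dropped`, `sig`. The per-cross
#'   pairs used are attached as attribute `"pairs"` (used by [autoplot()]).
#' @export
correlate_gd_heterosis <- function(d, entries, similarity = FALSE,
                                   alpha = c(0.05, 0.01)) {
  check_cols(entries, c("cross_id", "parent1", "parent2", "trait",
                        "hmp_pct", "hbp_pct"), "heterosis entries")
  labs <- rownames(d)
  missing <- entries[!(entries$parent1 %in% labs) | !(entries$parent2 %in% labs), ]
  if (nrow(missing) > 0) {
    stop_bad("parent of cross '%s' missing from the distance matrix",
             missing$cross_id[1])
  }
  alpha <- sort(alpha, decreasing = TRUE)
  pairs <- entries |>
    dplyr::mutate(
      gd = unclass(d)[cbind(.data$parent1, .data$parent2)],
      gd = if (similarity) 1 - .data$gd else .data$gd
    ) |>
    dplyr::select("trait", "cross_id", "gd", "hmp_pct", "hbp_pct") |>
    tidyr::pivot_longer(c("hmp_pct", "hbp_pct"),
                        names_to = "basis", values_to = "heterosis_pct") |>
    dplyr::mutate(basis = dplyr::if_else(.data$basis == "hmp_pct", "MP", "BP"))
  out <- pairs |>
    dplyr::group_by(.data$trait, .data$basis) |>
    dplyr::group_modify(function(g, key) {
      ok <- is.finite(g$heterosis_pct)
      res <- pearson_r(g$gd[ok], g$heterosis_pct[ok])
      res$n_dropped <- sum(!ok)
      res
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      sig = dplyr::case_when(
        .data$p_value <= alpha[2] ~ "**",
        .data$p_value <= alpha[1] ~ "*",
        .default = "ns"
      ),
      basis = factor(.data$basis, levels = c("MP", "BP"))
    ) |>
    dplyr::arrange(.data$trait, .data$basis) |>
    dplyr::mutate(basis = as.character(.data$basis))
  structure(tibble::new_tibble(out, class = "gd_cor"), pairs = pairs)
}

#' @rdname correlate_gd_heterosis
#' @param x A `gd_cor` table.
#' @param path File to write (tab separated).
#' @export
write_gd_correlation <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}
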