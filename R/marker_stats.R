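#' Allele frequencies at microsatellite loci
#'
#' Tallies allele frequencies across lines for one locus or for every locus of
#' a genotype table. Missing calls are excluded from the denominator
#' (complete-case per locus); a heterozygous call `"a/b"` contributes half a
#' count to each allele.
#'
#' @param genotypes A genotype table (`line_id` + one column per locus), as
#'   returned by [read_genotypes()] or [simulate_parents()].
#' @param locus Optional locus name; default tallies all loci.
#' @return A tibble with columns `locus`, `allele`, `freq`, `n_lines` (number
#'   of non-missing calls behind the frequencies). Within each locus the
#'   frequencies sum to 1.
#' @examples
#' g <- tibble::tibble(line_id = c("L1", "L2", "L3", "L4"),
#'                     RM1 = c("100", "100", "104", "104"))
#' allele_frequencies(g)
#' @export
allele_frequencies <- function(genotypes, locus = NULL) {
  genotypes <- as_genotype_table(genotypes)
  loci <- setdiff(names(genotypes), "line_id")
  if (!is.null(locus)) {
    if (!locus %in% loci) stop_bad("locus '%s' not present in the table", locus)
    loci <- locus
  }
  out <- purrr::map(loci, function(l) {
    calls <- genotypes[[l]]
    calls <- calls[!is.na(calls)]
    if (length(calls) == 0) {
      stop_bad("all calls missing at locus '%s'", l)
    }
    counts <- Reduce(
      function(acc, w) {
        for (a in names(w)) acc[a] <- (if (a %in% names(acc)) acc[[a]] else 0) + w[[a]]
        acc
      },
      lapply(calls, call_weights),
      init = numeric(0)
    )
    tibble::tibble(
      locus = l,
      allele = names(counts),
      freq = as.double(counts) / sum(counts),
      n_lines = length(calls)
    )
  })
  dplyr::bind_rows(out)
}

check_freqs <- function(p) {
  p <- as.double(p)
  if (length(p) < 1 || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_bad("allele frequencies must lie in [0, 1]")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop_bad("allele frequencies must sum to 1 (got %.6f)", sum(p))
  }
  p
}

#' Nei gene diversity (expected heterozygosity)
#'
#' \eqn{H = 1 - \sum_i p_i^2} over the allele frequencies at one locus.
#' Bounded by \eqn{1 - 1/k} for \eqn{k} alleles, with equality when alleles
#' are equifrequent.
#'
#' @param freqs Numeric vector of allele frequencies (sums to 1), or the
#'   `freq` column of one locus from [allele_frequencies()].
#' @return Gene diversity in \[0, 1\].
#' @examples
#' gene_diversity(c(0.5, 0.5))      # 0.5
#' gene_diversity(rep(0.25, 4))     # 0.75
#' @export
gene_diversity <- function(freqs) {
  p <- check_freqs(freqs)
  1 - sum(p^2)
}

#' Botstein polymorphic information content (PIC)
#'
#' \eqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2}: gene diversity
#' minus a correction for matings between indistinguishable heterozygotes.
#' Always \eqn{\le} [gene_diversity()]; values above 0.5 mark a highly
#' informative marker.
#'
#' @inheritParams gene_diversity
#' @return PIC in \[0, 1\].
#' @examples
#' pic(c(0.5, 0.5))    # 0.375
#' pic(rep(0.25, 4))   # 0.703125
#' @export
pic <- function(freqs) {
  p <- check_freqs(freqs)
  sp2 <- sum(p^2)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - sp2 - (sp2^2 - sum(p^4))
}

#' Per-locus diversity summary of a genotype panel
#'
#' For each locus: number of alleles, allele size range, gene diversity and
#' PIC computed from the observed allele frequencies. Panel-level aggregates
#' (total alleles, mean alleles per locus, mean diversity, polymorphism rate)
#' are available through [glance()] or [aggregate_panel()].
#'
#' @inheritParams allele_frequencies
#' @return An object of class `marker_panel_summary`: the per-locus tibble
#'   (columns `locus`, `n_alleles`, `min_allele`, `max_allele`,
#'   `gene_diversity`, `pic`) with the aggregate row attached; `tidy()`
#'   returns the per-locus table, `glance()` the aggregates.
#' @examples
#' g <- simulate_parents(simulation_config(seed = 1))
#' summarize_panel(g)
#' @export
summarize_panel <- function(genotypes) {
  genotypes <- as_genotype_table(genotypes)
  if (ncol(genotypes) < 2) stop_bad("genotype table has no loci")
  freqs <- allele_frequencies(genotypes)
  loci_order <- setdiff(names(genotypes), "line_id")
  loci <- freqs |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      n_alleles = dplyr::n(),
      min_allele = suppressWarnings(min(as.double(.data$allele))),
      max_allele = suppressWarnings(max(as.double(.data$allele))),
      gene_diversity = gene_diversity(.data$freq),
      pic = pic(.data$freq),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$locus, loci_order))
  new_panel_summary(loci)
}

new_panel_summary <- function(loci) {
  structure(
    list(loci = loci, aggregates = panel_aggregates(loci)),
    class = "marker_panel_summary"
  )
}

panel_aggregates <- function(loci) {
  div_col <- if ("gene_diversity" %in% names(loci)) loci$gene_diversity else NULL
  out <- tibble::tibble(
    n_loci = nrow(loci),
    total_alleles = sum(loci$n_alleles),
    mean_alleles = mean(loci$n_alleles),
    polymorphism_rate = 100 * mean(loci$n_alleles >= 2)
  )
  if (!is.null(div_col)) {
    out$mean_gene_diversity <- mean(div_col)
    out$min_gene_diversity <- min(div_col)
    out$max_gene_diversity <- max(div_col)
  }
  if ("pic" %in% names(loci)) out$mean_pic <- mean(loci$pic)
  out
}

#' Aggregate an existing per-locus summary table
#'
#' Computes the panel-level aggregates (locus count, total and mean allele
#' number, polymorphism rate, and diversity mean/range when a
#' `gene_diversity` column is present) from a per-locus summary supplied as
#' data — for example the bundled reference panel [rice_ssr_panel()], whose
#' published diversity values are inputs rather than quantities recomputed
#' from genotypes.
#'
#' @param loci A data frame with one row per locus, containing `n_alleles`
#'   and optionally `gene_diversity` / `pic` columns.
#' @return A `marker_panel_summary` object.
#' @examples
#' glance(aggregate_panel(rice_ssr_panel()))
#' @export
aggregate_panel <- function(loci) {
  loci <- tibble::as_tibble(loci)
  check_cols(loci, "n_alleles", "locus summary")
  new_panel_summary(loci)
}

#' @export
tidy.marker_panel_summary <- function(x, ...) x$loci

#' @export
glance.marker_panel_summary <- function(x, ...) x$aggregates

#' @export
print.marker_panel_summary <- function(x, ...) {
  cat("Microsatellite panel summary:", nrow(x$loci), "loci\n")
  print(x$loci, n = 15)
  cat("\nAggregates:\n")
  print(x$aggregates)
  invisible(x)
}
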