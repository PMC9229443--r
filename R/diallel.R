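# Half-diallel design, entry means, RCBD ANOVA.

#' Enumerate the crosses of a half diallel
#'
#' All n(n-1)/2 unordered parent pairs (Griffing method 2 mating design:
#' no selfs, no reciprocals), in canonical parent order. Cross ids are
#' written `"P1xP2"` with the first-listed parent first.
#'
#' @param parents Character vector of unique parent ids, in display order.
#' @return A tibble with columns `cross_id`, `parent1`, `parent2`.
#' @examples
#' nrow(enumerate_crosses(paste0("P", 1:8)))  # 28
#' @export
enumerate_crosses <- function(parents) {
  parents <- as.character(parents)
  if (length(parents) < 2) stop_bad("need at least 2 parents")
  if (anyDuplicated(parents)) {
    stop_bad("duplicated parent id(s): %s",
             paste(unique(parents[duplicated(parents)]), collapse = ", "))
  }
  pairs <- utils::combn(parents, 2)
  tibble::tibble(
    cross_id = paste0(pairs[1, ], "x", pairs[2, ]),
    parent1 = pairs[1, ],
    parent2 = pairs[2, ]
  )
}

#' Construct a half-diallel design
#'
#' @inheritParams enumerate_crosses
#' @param r Number of complete blocks (replications), at least 2.
#' @return A `diallel_design`: list with `parents`, `crosses` (tibble from
#'   [enumerate_crosses()]), `r`, and `entries` (parents then crosses).
#' @export
diallel_design <- function(parents, r = 3) {
  if (r < 2) stop_bad("a replicated design needs r >= 2 blocks")
  crosses <- enumerate_crosses(parents)
  structure(
    list(parents = as.character(parents), crosses = crosses, r = as.integer(r),
         entries = c(as.character(parents), crosses$cross_id)),
    class = "diallel_design"
  )
}

#' @export
print.diallel_design <- function(x, ...) {
  cat("Half diallel:", length(x$parents), "parents,",
      nrow(x$crosses), "crosses,", x$r, "blocks\n")
  invisible(x)
}

#' Entry means over blocks
#'
#' Arithmetic mean of each entry's plot values per trait. Missing plots are
#' tolerated with a warning (the mean uses the available blocks); a design
#' can be supplied to assert that every parent and cross is represented for
#' every trait.
#'
#' @param obs Long tibble of observations: `entry`, `block`, `trait`, `value`.
#' @param design Optional [diallel_design()] naming the expected entries.
#' @return A tibble `entry`, `trait`, `mean`, `n_blocks`.
#' @export
entry_means <- function(obs, design = NULL) {
  check_cols(obs, c("entry", "block", "trait", "value"), "observations")
  means <- obs |>
    dplyr::group_by(.data$entry, .data$trait) |>
    dplyr::summarise(mean = mean(.data$value), n_blocks = dplyr::n(),
                     .groups = "drop")
  if (length(unique(means$n_blocks)) > 1) {
    warn(sprintf(
      "unbalanced data: entries observed in %s blocks; means use available blocks",
      paste(sort(unique(means$n_blocks)), collapse = "/")))
  }
  if (!is.null(design)) {
    expected <- tidyr::expand_grid(entry = design$entries,
                                   trait = unique(means$trait))
    absent <- dplyr::anti_join(expected, means, by = c("entry", "trait"))
    if (nrow(absent) > 0) {
      stop_bad("no observations for entry '%s' on trait '%s'",
               absent$entry[1], absent$trait[1])
    }
  }
  means
}

#' Randomized-complete-block ANOVA for one trait
#'
#' Fits the two-way additive RCBD model (genotype + block) with
#' [stats::aov()] on a complete genotype-by-block table and extracts the sum
#' of squares partition and the error mean square used by the heterosis LSD
#' tests. Incomplete tables are an error — the LSD formulas assume balance,
#' and no imputation is attempted.
#'
#' @inheritParams entry_means
#' @param trait Trait name to analyse (may be omitted if `obs` holds one trait).
#' @return An object of class `rcbd_anova`; `tidy()` gives the per-term
#'   table (`term`, `df`, `sumsq`, `meansq`), `glance()` a one-row summary
#'   with `mse`, `df_error`, `n_genotypes`, `n_blocks`.
#' @examples
#' obs <- tidyr::expand_grid(entry = c("A", "B"), block = 1:2) |>
#'   dplyr::mutate(trait = "t", value = c(1, 2, 3, 4))
#' tidy(rcbd_anova(obs))
#' @export
rcbd_anova <- function(obs, trait = NULL) {
  check_cols(obs, c("entry", "block", "trait", "value"), "observations")
  traits <- unique(obs$trait)
  if (is.null(trait)) {
    if (length(traits) != 1) stop_bad("several traits present; name one")
    trait <- traits
  }
  if (!trait %in% traits) stop_bad("trait '%s' not present", trait)
  dat <- obs[obs$trait == trait, , drop = FALSE]
  g <- unique(dat$entry); b <- unique(dat$block)
  if (nrow(dat) != length(g) * length(b) ||
      anyDuplicated(dat[c("entry", "block")]) > 0) {
    stop_bad("incomplete or duplicated genotype x block table for trait '%s' (%d rows, expected %d)",
             trait, nrow(dat), length(g) * length(b))
  }
  if (length(b) < 2 || length(g) < 2) {
    stop_bad("RCBD ANOVA needs at least 2 genotypes and 2 blocks")
  }
  fit <- aov(value ~ entry + block,
             data = dplyr::mutate(dat, entry = factor(.data$entry),
                                  block = factor(.data$block)))
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  table <- tibble::tibble(
    term = c("genotype", "block", "error")[match(terms, c("entry", "block", "Residuals"))],
    df = tab[["Df"]],
    sumsq = tab[["Sum Sq"]],
    meansq = tab[["Mean Sq"]]
  )
  err <- table[table$term == "error", ]
  structure(
    list(trait = trait, table = table, mse = err$meansq, df_error = err$df,
         n_genotypes = length(g), n_blocks = length(b)),
    class = "rcbd_anova"
  )
}

#' @export
tidy.rcbd_anova <- function(x, ...) x$table

#' @export
glance.rcbd_anova <- function(x, ...) {
  tibble::tibble(trait = x$trait, mse = x$mse, df_error = x$df_error,
                 n_genotypes = x$n_genotypes, n_blocks = x$n_blocks)
}

#' @export
print.rcbd_anova <- function(x, ...) {
  cat("RCBD ANOVA —", x$trait, "(", x$n_genotypes, "genotypes x",
      x$n_blocks, "blocks )\n")
  print(x$table)
  invisible(x)
}
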