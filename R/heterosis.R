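# Mid-parent / better-parent heterosis and LSD significance.

#' LSD thresholds for heterosis tests
#'
#' Least-significant-difference thresholds on the trait-unit scale, derived
#' from the RCBD error mean square after Wynne:
#' \deqn{LSD_{MP} = t_{\alpha/2, df} \sqrt{3\,MSE / (2r)}, \qquad
#'       LSD_{BP} = t_{\alpha/2, df} \sqrt{2\,MSE / r}.}
#' The mid-parent contrast \eqn{F_1 - (P_1 + P_2)/2} has variance
#' \eqn{3\sigma^2/(2r)}; the better-parent contrast \eqn{F_1 - BP} has
#' \eqn{2\sigma^2/r}, hence the fixed ratio
#' \eqn{LSD_{BP}/LSD_{MP} = 2/\sqrt{3}}.
#'
#' @param mse Error mean square from [rcbd_anova()] (trait units squared).
#' @param r Number of blocks (replications), at least 2.
#' @param df_error Error degrees of freedom, at least 1.
#' @param alpha Significance level(s); default `c(0.05, 0.01)`.
#' @return A tibble `alpha`, `t_crit`, `lsd_mp`, `lsd_bp`.
#' @examples
#' lsd_thresholds(mse = 6, r = 3, df_error = 70)
#' @export
lsd_thresholds <- function(mse, r, df_error, alpha = c(0.05, 0.01)) {
  if (!is.finite(mse) || mse < 0) stop_bad("mse must be a non-negative number")
  if (r < 2) stop_bad("r must be at least 2")
  if (df_error < 1) stop_bad("df_error must be at least 1")
  if (any(alpha <= 0 | alpha >= 1)) stop_bad("alpha must lie in (0, 1)")
  t_crit <- qt(1 - alpha / 2, df = df_error)
  tibble::tibble(
    alpha = alpha,
    t_crit = t_crit,
    lsd_mp = t_crit * sqrt(3 * mse / (2 * r)),
    lsd_bp = t_crit * sqrt(2 * mse / r)
  )
}

sig_code <- function(diff, lsd05, lsd01) {
  dplyr::case_when(
    is.na(diff) ~ NA_character_,
    abs(diff) > lsd01 ~ "**",
    abs(diff) > lsd05 ~ "*",
    .default = "ns"
  )
}

#' Mid-parent and better-parent heterosis for every cross
#'
#' For each cross and trait: \eqn{HMP = 100 (F_1 - MP)/MP} with
#' \eqn{MP = (P_1 + P_2)/2}, and \eqn{HBP = 100 (F_1 - BP)/BP} with BP the
#' larger-mean parent (so \eqn{HBP \le HMP} whenever parent means are
#' positive). Significance stars compare the trait-unit difference
#' \eqn{F_1 - MP} (resp. \eqn{F_1 - BP}) with the [lsd_thresholds()] at 0.05
#' (`*`) and 0.01 (`**`); trait desirability direction, when supplied, is
#' carried along as metadata and never alters the formulas.
#'
#' @param means Entry-mean tibble from [entry_means()].
#' @param design A [diallel_design()].
#' @param anova A single [rcbd_anova()] (one trait) or a named list of them,
#'   one per trait in `means`.
#' @param alpha Two significance levels, default `c(0.05, 0.01)`.
#' @param trait_directions Optional tibble `trait`, `direction` (see
#'   [rice_traits()]).
#' @param sig_scale `"unit"` (default) compares F1 minus reference against
#'   the LSD in trait units; `"percent"` rescales the LSD by the reference
#'   mean and compares on the percentage scale.
#' @return A tibble of class `heterosis_tbl`: `cross_id`, `parent1`,
#'   `parent2`, `trait`, `f1_mean`, `mp`, `bp`, `hmp_pct`, `hbp_pct`,
#'   `sig_mp`, `sig_bp` (codes `ns`/`*`/`**`). The LSD table is attached as
#'   attribute `"thresholds"` and returned by `glance()`. Crosses whose MP or
#'   BP mean is zero get `NA` heterosis with a warning.
#' @export
heterosis_table <- function(means, design, anova, alpha = c(0.05, 0.01),
                            trait_directions = NULL,
                            sig_scale = c("unit", "percent")) {
  sig_scale <- match.arg(sig_scale)
  check_cols(means, c("entry", "trait", "mean"), "entry means")
  if (length(alpha) != 2) stop_bad("alpha must give the two star levels, e.g. c(0.05, 0.01)")
  alpha <- sort(alpha, decreasing = TRUE)
  traits <- unique(means$trait)
  if (inherits(anova, "rcbd_anova")) {
    anova <- setNames(list(anova), anova$trait)
  }
  missing_anova <- setdiff(traits, names(anova))
  if (length(missing_anova) > 0) {
    stop_bad("no ANOVA supplied for trait(s): %s",
             paste(missing_anova, collapse = ", "))
  }
  thresholds <- purrr::map_dfr(traits, function(tr) {
    a <- anova[[tr]]
    dplyr::mutate(
      lsd_thresholds(a$mse, r = a$n_blocks, df_error = a$df_error, alpha = alpha),
      trait = tr, .before = 1
    )
  })

  lookup <- means |> dplyr::select("entry", "trait", "mean")
  grid <- tidyr::expand_grid(design$crosses, trait = traits) |>
    dplyr::left_join(dplyr::rename(lookup, f1_mean = "mean"),
                     by = c(cross_id = "entry", "trait")) |>
    dplyr::left_join(dplyr::rename(lookup, p1_mean = "mean"),
                     by = c(parent1 = "entry", "trait")) |>
    dplyr::left_join(dplyr::rename(lookup, p2_mean = "mean"),
                     by = c(parent2 = "entry", "trait"))
  absent <- grid[is.na(grid$f1_mean) | is.na(grid$p1_mean) | is.na(grid$p2_mean), ]
  if (nrow(absent) > 0) {
    stop_bad("means unavailable for cross '%s' on trait '%s'",
             absent$cross_id[1], absent$trait[1])
  }
  out <- grid |>
    dplyr::mutate(
      mp = (.data$p1_mean + .data$p2_mean) / 2,
      bp = pmax(.data$p1_mean, .data$p2_mean),
      hmp_pct = dplyr::if_else(.data$mp != 0,
                               100 * (.data$f1_mean - .data$mp) / .data$mp,
                               NA_real_),
      hbp_pct = dplyr::if_else(.data$bp != 0,
                               100 * (.data$f1_mean - .data$bp) / .data$bp,
                               NA_real_)
    )
  if (any(out$mp == 0 | out$bp == 0)) {
    warn("zero mid- or better-parent mean: heterosis undefined for those crosses (NA)")
  }
  thr05 <- thresholds[thresholds$alpha == alpha[1], c("trait", "lsd_mp", "lsd_bp")]
  thr01 <- thresholds[thresholds$alpha == alpha[2], c("trait", "lsd_mp", "lsd_bp")]
  out <- out |>
    dplyr::left_join(dplyr::rename(thr05, lsd_mp05 = "lsd_mp", lsd_bp05 = "lsd_bp"),
                     by = "trait") |>
    dplyr::left_join(dplyr::rename(thr01, lsd_mp01 = "lsd_mp", lsd_bp01 = "lsd_bp"),
                     by = "trait")
  if (sig_scale == "percent") {
    out <- out |>
      dplyr::mutate(
        sig_mp = sig_code(.data$hmp_pct, 100 * .data$lsd_mp05 / abs(.data$mp),
                          100 * .data$lsd_mp01 / abs(.data$mp)),
        sig_bp = sig_code(.data$hbp_pct, 100 * .data$lsd_bp05 / abs(.data$bp),
                          100 * .data$lsd_bp01 / abs(.data$bp))
      )
  } else {
    out <- out |>
      dplyr::mutate(
        sig_mp = sig_code(.data$f1_mean - .data$mp, .data$lsd_mp05, .data$lsd_mp01),
        sig_bp = sig_code(.data$f1_mean - .data$bp, .data$lsd_bp05, .data$lsd_bp01)
      )
  }
  out <- out |>
    dplyr::select("cross_id", "parent1", "parent2", "trait", "f1_mean",
                  "mp", "bp", "hmp_pct", "hbp_pct", "sig_mp", "sig_bp")
  if (!is.null(trait_directions)) {
    check_cols(trait_directions, c("trait", "direction"), "trait directions")
    out <- dplyr::left_join(out,
                            dplyr::select(trait_directions, "trait", "direction"),
                            by = "trait")
  }
  structure(
    tibble::new_tibble(out, class = "heterosis_tbl"),
    thresholds = thresholds, sig_scale = sig_scale
  )
}

#' @export
glance.heterosis_tbl <- function(x, ...) attr(x, "thresholds")

#' Render the heterosis report table
#'
#' One row per cross with `"<trait> MP"` / `"<trait> BP"` columns holding the
#' heterosis percentage and its star code, followed by the two LSD rows (in
#' trait units) — the classic published layout of a diallel heterosis table.
#'
#' @param entries A `heterosis_tbl` from [heterosis_table()].
#' @param digits Decimal places for percentages.
#' @return A character tibble, first column `hybrid`.
#' @export
render_heterosis_report <- function(entries, digits = 2) {
  thresholds <- attr(entries, "thresholds")
  if (is.null(thresholds)) stop_bad("entries must come from heterosis_table()")
  fmt <- function(v, s) {
    ifelse(is.na(v), "NA", paste0(sprintf(paste0("%.", digits, "f"), v),
                                  ifelse(s == "ns", " ns", paste0(" ", s))))
  }
  wide <- entries |>
    dplyr::mutate(
      mp_cell = fmt(.data$hmp_pct, .data$sig_mp),
      bp_cell = fmt(.data$hbp_pct, .data$sig_bp)
    ) |>
    dplyr::select("cross_id", "trait", "mp_cell", "bp_cell") |>
    tidyr::pivot_wider(names_from = "trait",
                       values_from = c("mp_cell", "bp_cell"),
                       names_glue = "{trait} {ifelse(.value == 'mp_cell', 'MP', 'BP')}")
  traits <- unique(entries$trait)
  col_order <- c("cross_id", as.vector(rbind(paste(traits, "MP"), paste(traits, "BP"))))
  wide <- wide[, col_order]
  names(wide)[1] <- "hybrid"
  lsd_row <- function(a) {
    thr <- thresholds[thresholds$alpha == a, ]
    cells <- setNames(
      as.list(rep(NA_character_, length(col_order) - 1)), col_order[-1])
    for (tr in traits) {
      row <- thr[thr$trait == tr, ]
      cells[[paste(tr, "MP")]] <- sprintf(paste0("%.", digits, "f"), row$lsd_mp)
      cells[[paste(tr, "BP")]] <- sprintf(paste0("%.", digits, "f"), row$lsd_bp)
    }
    tibble::as_tibble(c(list(hybrid = sprintf("L.S.D. at %.2f", a)), cells))
  }
  alphas <- sort(unique(thresholds$alpha), decreasing = TRUE)
  dplyr::bind_rows(wide, purrr::map_dfr(alphas, lsd_row))
}

#' @rdname render_heterosis_report
#' @param path File to write (tab separated).
#' @export
write_heterosis_report <- function(entries, path, digits = 2) {
  readr::write_tsv(render_heterosis_report(entries, digits = digits), path)
  invisible(path)
}
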