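# Half-diallel design, entry means, RCBD ANOVA, LSD and heterosis.

test_that("enumerate_crosses gives the n(n-1)/2 unordered pairs", {
  cr8 <- enumerate_crosses(paste0("P", 1:8))
  expect_equal(nrow(cr8), 28)
  expect_equal(nrow(enumerate_crosses(c("a", "b"))), 1)

  cr5 <- enumerate_crosses(paste0("P", 1:5))
  expect_equal(nrow(cr5), 10)
  expect_true(all(cr5$parent1 != cr5$parent2))
  # brute-force: every unordered pair appears exactly once
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_setequal(
    key(cr5$parent1, cr5$parent2),
    key(rep(paste0("P", 1:5), each = 5), rep(paste0("P", 1:5), 5))[
      rep(1:5, each = 5) != rep(1:5, 5)]
  )
  expect_error(enumerate_crosses(c("A", "A", "B")), "duplicated parent")
  expect_error(diallel_design(c("A", "B"), r = 1), "r >= 2")
})

test_that("entry means average over available blocks and flag imbalance", {
  obs <- tibble::tibble(entry = "A", block = 1:3, trait = "t",
                        value = c(10, 12, 14))
  expect_equal(entry_means(obs)$mean, 12)

  one <- tibble::tibble(entry = "A", block = 1, trait = "t", value = 7)
  expect_equal(entry_means(one)$mean, 7)

  unb <- dplyr::bind_rows(obs, tibble::tibble(entry = "B", block = 1:2,
                                              trait = "t", value = c(1, 3)))
  expect_warning(m <- entry_means(unb), "unbalanced")
  expect_equal(m$mean[m$entry == "B"], 2)

  des <- diallel_design(c("A", "B"), r = 2)
  expect_error(suppressWarnings(entry_means(unb, design = des)),
               "AxB.*trait 't'")
})

test_that("RCBD ANOVA decomposes the worked 2x2 example exactly", {
  m <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), NULL))
  fit <- rcbd_anova(obs_from_matrix(m))
  tab <- tidy(fit)
  expect_equal(tab$sumsq[tab$term == "genotype"], 4)
  expect_equal(tab$sumsq[tab$term == "block"], 1)
  expect_equal(tab$sumsq[tab$term == "error"], 0, tolerance = 1e-12)
  expect_equal(tab$df, c(1, 1, 1))
})

test_that("constant data give zero sums of squares", {
  m <- matrix(5, 3, 2, dimnames = list(paste0("g", 1:3), NULL))
  tab <- tidy(rcbd_anova(obs_from_matrix(m)))
  expect_equal(tab$sumsq, rep(0, 3), tolerance = 1e-12)
})

test_that("the SS partition is conserved on random complete tables", {
  set.seed(31)
  for (i in 1:10) {
    g <- sample(10:36, 1); b <- sample(2:4, 1)
    m <- matrix(rnorm(g * b, 50, 8), g, b,
                dimnames = list(paste0("g", seq_len(g)), NULL))
    obs <- obs_from_matrix(m)
    fit <- rcbd_anova(obs)
    tab <- tidy(fit)
    ss_total <- sum((m - mean(m))^2)
    expect_equal(sum(tab$sumsq), ss_total, tolerance = 1e-8 * ss_total)
    expect_equal(fit$df_error, (g - 1) * (b - 1))
  }
})

test_that("incomplete genotype x block tables are rejected, not imputed", {
  m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), NULL))
  obs <- obs_from_matrix(m)[-1, ]
  expect_error(rcbd_anova(obs), "incomplete")
})

test_that("LSD thresholds follow the Wynne formulas", {
  z <- lsd_thresholds(mse = 0, r = 3, df_error = 10)
  expect_equal(z$lsd_mp, c(0, 0))
  expect_equal(z$lsd_bp, c(0, 0))

  w <- lsd_thresholds(mse = 6, r = 3, df_error = 70, alpha = 0.05)
  expect_equal(w$lsd_mp, qt(0.975, 70) * sqrt(3))  # sqrt(3*6/(2*3)) = sqrt(3)
  expect_equal(w$lsd_bp, qt(0.975, 70) * sqrt(2 * 6 / 3))

  set.seed(32)
  for (i in 1:50) {
    mse <- rexp(1, 1 / 5); r <- sample(2:6, 1); df <- sample(1:120, 1)
    t2 <- lsd_thresholds(mse, r, df)
    expect_equal(t2$lsd_bp / t2$lsd_mp, rep(2 / sqrt(3), 2), tolerance = 1e-9)
    # 0.01 threshold exceeds 0.05 threshold
    expect_gt(t2$lsd_mp[t2$alpha == 0.01], t2$lsd_mp[t2$alpha == 0.05])
    # increasing in MSE, decreasing in r
    expect_gt(lsd_thresholds(mse * 2, r, df)$lsd_mp[1], t2$lsd_mp[1])
    expect_lt(lsd_thresholds(mse, r + 1, df)$lsd_mp[1], t2$lsd_mp[1])
  }
  expect_error(lsd_thresholds(1, 3, 0), "df_error")
})

make_het_fixture <- function(p1, p2, f1, mse = 1, r = 3) {
  design <- diallel_design(c("A", "B"), r = r)
  means <- tibble::tibble(entry = c("A", "B", "AxB"), trait = "t",
                          mean = c(p1, p2, f1), n_blocks = r)
  anova <- structure(list(trait = "t", mse = mse, df_error = 2 * (r - 1),
                          n_genotypes = 3, n_blocks = r,
                          table = NULL), class = "rcbd_anova")
  heterosis_table(means, design, anova)
}

test_that("heterosis percentages follow the MP/BP formulas", {
  h <- make_het_fixture(10, 10, 12)
  expect_equal(h$mp, 10)
  expect_equal(h$bp, 10)
  expect_equal(h$hmp_pct, 20)
  expect_equal(h$hbp_pct, 20)

  h2 <- make_het_fixture(10, 8, 12)
  expect_equal(h2$hmp_pct, 100 * (12 - 9) / 9, tolerance = 1e-12)
  expect_equal(round(h2$hmp_pct, 2), 33.33)
  expect_equal(h2$hbp_pct, 20)
  expect_lte(h2$hbp_pct, h2$hmp_pct)

  h3 <- make_het_fixture(10, 14, 12)  # F1 equals MP
  expect_equal(h3$hmp_pct, 0)
  expect_equal(h3$sig_mp, "ns")
})

test_that("zero parent means yield NA heterosis with a warning", {
  expect_warning(h <- make_het_fixture(-5, 5, 3), "undefined")
  expect_true(is.na(h$hmp_pct))
  expect_false(is.na(h$hbp_pct))
})

test_that("better-parent heterosis never exceeds mid-parent heterosis", {
  set.seed(33)
  for (i in 1:200) {
    p1 <- runif(1, 1, 50); p2 <- runif(1, 1, 50); f1 <- runif(1, 1, 80)
    h <- make_het_fixture(p1, p2, f1)
    expect_lte(h$hbp_pct, h$hmp_pct + 1e-12)
  }
})

test_that("with zero error variance every nonzero heterosis is starred", {
  cfg <- simulation_config(seed = 9, residual_sigma = 0, block_effects = 0,
                           dominance_effects = 4)
  sim <- simulate_diallel(cfg)
  means <- entry_means(sim$phenotypes, design = sim$design)
  fit <- rcbd_anova(sim$phenotypes)
  expect_equal(fit$mse, 0, tolerance = 1e-18)
  h <- heterosis_table(means, sim$design, fit)
  nonzero <- abs(h$f1_mean - h$mp) > 1e-8
  expect_true(all(h$sig_mp[nonzero] == "**"))
})

test_that("the rendered report has one row per cross plus two LSD rows", {
  cfg <- simulation_config(seed = 10)
  sim <- simulate_diallel(cfg)
  means <- entry_means(sim$phenotypes, design = sim$design)
  fit <- rcbd_anova(sim$phenotypes)
  h <- heterosis_table(means, sim$design, fit)
  rep_tbl <- render_heterosis_report(h)
  expect_equal(nrow(rep_tbl), 28 + 2)
  expect_equal(names(rep_tbl)[1], "hybrid")
  expect_equal(ncol(rep_tbl), 1 + 2)  # one trait, MP + BP columns
  expect_true(all(grepl("(ns|\\*|\\*\\*)$", rep_tbl[[2]][1:28])))
  expect_equal(rep_tbl$hybrid[29:30], c("L.S.D. at 0.05", "L.S.D. at 0.01"))
  # star codes restricted to the three-level domain
  expect_true(all(h$sig_mp %in% c("ns", "*", "**")))
  expect_true(all(h$sig_bp %in% c("ns", "*", "**")))
})
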