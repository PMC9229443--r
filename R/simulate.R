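# Half-diallel simulator with known additive + dominance architecture.

#' Configuration for a simulated half-diallel study
#'
#' Defaults mirror an eight-parent rice diallel genotyped at 11 multi-allelic
#' microsatellite loci and phenotyped in a three-block RCBD: 8 homozygous
#' parents, 11 marker loci with up to 4 alleles each, 28 F1 crosses, three
#' complete blocks. The genetic model is additive + dominance: a parent's
#' genotypic value is `baseline_mu` plus per-locus additive allele effects;
#' an F1's value is the mid-parent genotypic value plus the dominance effect
#' of every trait locus at which its parents carry different alleles;
#' observed plot values add a block effect and Gaussian residual noise.
#'
#' @param n_parents Number of inbred parents.
#' @param n_marker_loci Number of marker loci.
#' @param alleles_per_locus Alleles in each locus's pool (>= 1; 1 makes all
#'   parents identical).
#' @param n_trait_loci Number of trait loci (ignored when
#'   `markers_are_trait_loci`).
#' @param markers_are_trait_loci If `TRUE` (default) the trait loci are the
#'   marker loci themselves, so marker distance and dominance heterozygosity
#'   coincide — the configuration under which marker distance predicts
#'   heterosis exactly.
#' @param additive_effects Per-locus scale of additive allele effects (trait
#'   units; scalar or length `n_trait_loci`). Allele effects are drawn once
#'   as `N(0, 1)` draws scaled by this value; 0 makes all parents equal.
#' @param dominance_effects Per-locus dominance deviation d expressed in an
#'   F1 heterozygous at that locus (trait units; scalar or vector).
#' @param baseline_mu Baseline trait mean (trait units).
#' @param block_effects Additive block effects (length `r_blocks`; scalar is
#'   recycled).
#' @param residual_sigma Residual standard deviation of a plot value.
#' @param r_blocks Number of complete blocks, >= 2.
#' @param allele_skew Skew of the allele sampling weights (0 = uniform;
#'   weight of allele k is proportional to `k^allele_skew`), for
#'   diversity-statistic stress tests.
#' @param stress_multiplier Multiplier on `baseline_mu`, a label-level knob
#'   for mimicking stress-reduced trait means (drought is agronomic, not
#'   statistical, so this is the only stress control).
#' @param trait Name given to the simulated trait.
#' @param seed Integer seed; every simulation is reproducible given the seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_parents = 8,
                              n_marker_loci = 11,
                              alleles_per_locus = 4,
                              n_trait_loci = n_marker_loci,
                              markers_are_trait_loci = TRUE,
                              additive_effects = 2,
                              dominance_effects = 3,
                              baseline_mu = 100,
                              block_effects = c(-1, 0, 1),
                              residual_sigma = 1,
                              r_blocks = 3,
                              allele_skew = 0,
                              stress_multiplier = 1,
                              trait = "grain_yield",
                              seed = 1) {
  if (n_parents < 2) stop_bad("n_parents must be at least 2")
  if (n_marker_loci < 1 || n_trait_loci < 1) stop_bad("locus counts must be >= 1")
  if (alleles_per_locus < 1) stop_bad("alleles_per_locus must be >= 1")
  if (r_blocks < 2) stop_bad("r_blocks must be >= 2")
  if (residual_sigma < 0) stop_bad("residual_sigma must be >= 0")
  if (markers_are_trait_loci) n_trait_loci <- n_marker_loci
  if (length(block_effects) == 1) block_effects <- rep(block_effects, r_blocks)
  if (length(block_effects) != r_blocks) {
    stop_bad("block_effects must have length r_blocks (%d)", r_blocks)
  }
  additive_effects <- rep_len(additive_effects, n_trait_loci)
  dominance_effects <- rep_len(dominance_effects, n_trait_loci)
  structure(
    list(n_parents = as.integer(n_parents),
         n_marker_loci = as.integer(n_marker_loci),
         alleles_per_locus = as.integer(alleles_per_locus),
         n_trait_loci = as.integer(n_trait_loci),
         markers_are_trait_loci = isTRUE(markers_are_trait_loci),
         additive_effects = as.double(additive_effects),
         dominance_effects = as.double(dominance_effects),
         baseline_mu = as.double(baseline_mu),
         block_effects = as.double(block_effects),
         residual_sigma = as.double(residual_sigma),
         r_blocks = as.integer(r_blocks),
         allele_skew = as.double(allele_skew),
         stress_multiplier = as.double(stress_multiplier),
         trait = as.character(trait),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

allele_pool <- function(locus_index, n_alleles) {
  # bp-like labels: distinct sizes in steps of 2 within a locus
  as.character(80 + 20 * locus_index + 2 * (seq_len(n_alleles) - 1))
}

sample_calls <- function(config, loci_prefix, n_loci) {
  pools <- lapply(seq_len(n_loci), allele_pool, n_alleles = config$alleles_per_locus)
  w <- seq_len(config$alleles_per_locus)^config$allele_skew
  calls <- vapply(pools, function(pool) {
    sample(pool, config$n_parents, replace = TRUE, prob = w / sum(w))
  }, character(config$n_parents))
  calls <- matrix(calls, nrow = config$n_parents)
  colnames(calls) <- paste0(loci_prefix, seq_len(n_loci))
  calls
}

#' Simulate homozygous parental genotypes
#'
#' Each parent is fully homozygous at every marker locus; the allele is drawn
#' from the locus's pool (uniformly by default, skewed via `allele_skew`).
#' Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A genotype tibble (`line_id` = `"P1"`... plus one column per
#'   locus `"M1"`...), in the dialect accepted by every analysis function.
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  calls <- sample_calls(config, "M", config$n_marker_loci)
  tibble::as_tibble(as.data.frame(calls)) |>
    dplyr::mutate(line_id = paste0("P", seq_len(config$n_parents)), .before = 1)
}

#' Simulate replicated phenotypes for a half diallel, with ground truth
#'
#' Applies the additive + dominance genetic model to the parental genotypes
#' and the design's crosses, then adds block effects and `N(0, sigma)` plot
#' noise. With `residual_sigma = 0` and zero block effects, observed plot
#' values equal genotypic values exactly.
#'
#' @param config A [simulation_config()].
#' @param genotypes Parental genotype table from [simulate_parents()].
#' @param design A [diallel_design()] over the same parents whose block
#'   count matches `config$r_blocks`.
#' @return A list: `phenotypes` (long tibble `entry`, `block`, `trait`,
#'   `value`) and `truth` (per cross: `cross_id`, `mp_true`, `d_true`,
#'   `hmp_true`, `het_fraction` — the dominance deviation D, true
#'   mid-parent heterosis `100 D / MP`, and heterozygosity fraction at trait
#'   loci).
#' @export
simulate_phenotypes <- function(config, genotypes, design) {
  stopifnot(inherits(config, "simulation_config"))
  genotypes <- as_genotype_table(genotypes)
  if (!identical(sort(design$parents), sort(genotypes$line_id))) {
    stop_bad("design parents do not match the genotype table")
  }
  if (design$r != config$r_blocks) {
    stop_bad("design has %d blocks but config expects %d", design$r, config$r_blocks)
  }
  set.seed(config$seed + 1L)
  if (config$markers_are_trait_loci) {
    tcalls <- as.matrix(genotypes[, -1, drop = FALSE])
    rownames(tcalls) <- genotypes$line_id
  } else {
    tcalls <- sample_calls(config, "T", config$n_trait_loci)
    rownames(tcalls) <- paste0("P", seq_len(config$n_parents))
    tcalls <- tcalls[genotypes$line_id, , drop = FALSE]
  }
  # additive effect of each allele at each trait locus, drawn once
  effects <- lapply(seq_len(config$n_trait_loci), function(l) {
    pool <- sort(unique(tcalls[, l]))
    setNames(rnorm(length(pool)) * config$additive_effects[l], pool)
  })
  mu <- config$baseline_mu * config$stress_multiplier
  parent_value <- setNames(
    vapply(seq_len(nrow(tcalls)), function(p) {
      mu + sum(vapply(seq_len(config$n_trait_loci),
                      function(l) effects[[l]][[tcalls[p, l]]], 0))
    }, 0),
    rownames(tcalls)
  )
  crosses <- design$crosses
  het <- t(vapply(seq_len(nrow(crosses)), function(k) {
    hz <- tcalls[crosses$parent1[k], ] != tcalls[crosses$parent2[k], ]
    c(d = sum(config$dominance_effects[hz]), frac = mean(hz))
  }, c(d = 0, frac = 0)))
  truth <- tibble::tibble(
    cross_id = crosses$cross_id,
    parent1 = crosses$parent1,
    parent2 = crosses$parent2,
    mp_true = unname(parent_value[crosses$parent1] +
                       parent_value[crosses$parent2]) / 2,
    d_true = unname(het[, "d"]),
    het_fraction = unname(het[, "frac"]),
    hmp_true = ifelse(mp_true != 0, 100 * d_true / mp_true, NA_real_)
  )
  genotypic <- c(parent_value, setNames(truth$mp_true + truth$d_true, truth$cross_id))
  entries <- design$entries
  obs <- tidyr::expand_grid(entry = entries, block = seq_len(config$r_blocks)) |>
    dplyr::mutate(
      trait = config$trait,
      value = unname(genotypic[.data$entry]) +
        config$block_effects[.data$block] +
        rnorm(dplyr::n(), sd = config$residual_sigma)
    )
  list(phenotypes = obs, truth = truth)
}

#' Simulate a complete half-diallel dataset
#'
#' Convenience wrapper: parents, design, phenotypes and ground truth in one
#' call.
#'
#' @param config A [simulation_config()].
#' @return A list of class `diallel_sim` with elements `genotypes`,
#'   `design`, `phenotypes`, `truth`, `config`.
#' @examples
#' sim <- simulate_diallel(simulation_config(seed = 7))
#' head(sim$phenotypes)
#' @export
simulate_diallel <- function(config = simulation_config()) {
  genotypes <- simulate_parents(config)
  design <- diallel_design(genotypes$line_id, r = config$r_blocks)
  ph <- simulate_phenotypes(config, genotypes, design)
  structure(
    list(genotypes = genotypes, design = design,
         phenotypes = ph$phenotypes, truth = ph$truth, config = config),
    class = "diallel_sim"
  )
}

#' @export
print.diallel_sim <- function(x, ...) {
  cat("Simulated half diallel:", x$config$n_parents, "parents,",
      nrow(x$design$crosses), "crosses,", x$config$r_blocks, "blocks, trait",
      shQuote(x$config$trait), "\n")
  invisible(x)
}
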