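# File-level orchestration: write simulated datasets, run the full analysis.

#' Write a simulated half-diallel dataset to disk
#'
#' Runs [simulate_diallel()] and writes the three data files in exactly the
#' dialects the analysis functions consume — `genotypes.csv` (wide genotype
#' table), `phenotypes.csv` (long observations) and `ground_truth.csv` — plus
#' a `manifest.json` recording the seed, the full configuration and an MD5
#' checksum per file. Rerunning with the same configuration reproduces the
#' files byte for byte.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a tibble `artifact`, `path`.
#' @export
write_simulation <- function(config = simulation_config(), dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_bad("cannot create output directory '%s'", dir)
  }
  sim <- simulate_diallel(config)
  paths <- c(
    genotypes = file.path(dir, "genotypes.csv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    ground_truth = file.path(dir, "ground_truth.csv")
  )
  readr::write_csv(sim$genotypes, paths[["genotypes"]])
  readr::write_csv(sim$phenotypes, paths[["phenotypes"]])
  readr::write_csv(sim$truth, paths[["ground_truth"]])
  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    files = lapply(seq_along(paths), function(i) {
      list(artifact = names(paths)[i], file = basename(paths[i]),
           md5 = unname(tools::md5sum(paths[i])))
    })
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(tibble::tibble(
    artifact = c(names(paths), "manifest"),
    path = c(unname(paths), manifest_path)
  ))
}

#' Run the full marker-distance heterosis analysis
#'
#' End-to-end analysis producing the study's report tables as delimited text:
#' per-locus diversity summary, pairwise Nei genetic distance matrix, UPGMA
#' dendrogram (Newick), mid-/better-parent heterosis report with LSD rows,
#' and the genetic distance vs. heterosis correlation table. Without
#' phenotypes only the marker-side artifacts are produced (with a warning);
#' any stage failure raises an error naming the stage.
#'
#' @param genotypes Genotype table or path to a genotype file.
#' @param phenotypes Optional observations (long tibble) or path.
#' @param out_dir Output directory (created if needed).
#' @param distance Distance measure passed to [pairwise_distances()].
#' @param alpha Star levels for LSD tests and correlation codes.
#' @param trait_directions Optional trait desirability table (see
#'   [rice_traits()]).
#' @param sig_scale Scale for the LSD comparison, see [heterosis_table()].
#' @param similarity Correlate similarity (1 - GD) instead of distance.
#' @return Invisibly, a tibble `artifact`, `path` of everything written.
#' @examples
#' sim <- simulate_diallel(simulation_config(seed = 3))
#' out <- run_diallel_analysis(sim$genotypes, sim$phenotypes,
#'                             out_dir = tempfile("run"))
#' @export
run_diallel_analysis <- function(genotypes, phenotypes = NULL, out_dir,
                                 distance = c("nei_da", "nei_standard"),
                                 alpha = c(0.05, 0.01),
                                 trait_directions = NULL,
                                 sig_scale = c("unit", "percent"),
                                 similarity = FALSE) {
  distance <- match.arg(distance)
  sig_scale <- match.arg(sig_scale)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_bad("cannot create output directory '%s'", out_dir)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_bad("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  if (is.character(genotypes)) genotypes <- stage("read_genotypes", read_genotypes(genotypes))
  genotypes <- as_genotype_table(genotypes)

  artifacts <- list()
  panel <- stage("diversity", summarize_panel(genotypes))
  p <- file.path(out_dir, "locus_summary.tsv")
  readr::write_tsv(tidy(panel), p)
  artifacts$locus_summary <- p

  d <- stage("distance", pairwise_distances(genotypes, method = distance))
  p <- file.path(out_dir, "distance_matrix.tsv")
  readr::write_tsv(
    tibble::as_tibble(cbind(line_id = rownames(d), as.data.frame(unclass(d)))), p)
  artifacts$distance_matrix <- p

  tree <- stage("upgma", upgma(d))
  p <- file.path(out_dir, "dendrogram.nwk")
  write_newick(tree, p)
  artifacts$dendrogram <- p

  if (is.null(phenotypes)) {
    warn("no phenotypes supplied: heterosis and correlation stages skipped")
  } else {
    if (is.character(phenotypes)) {
      phenotypes <- stage("read_phenotypes", read_phenotypes(phenotypes))
    }
    het <- stage("heterosis", {
      r <- length(unique(phenotypes$block))
      design <- diallel_design(genotypes$line_id, r = max(2, r))
      means <- entry_means(phenotypes, design = design)
      anovas <- lapply(
        setNames(nm = unique(phenotypes$trait)),
        function(tr) rcbd_anova(phenotypes, trait = tr)
      )
      heterosis_table(means, design, anovas, alpha = alpha,
                      trait_directions = trait_directions,
                      sig_scale = sig_scale)
    })
    p <- file.path(out_dir, "heterosis_report.tsv")
    write_heterosis_report(het, p)
    artifacts$heterosis_report <- p

    cors <- stage("correlation",
                  correlate_gd_heterosis(d, het, similarity = similarity,
                                         alpha = alpha))
    p <- file.path(out_dir, "gd_correlation.tsv")
    write_gd_correlation(cors, p)
    artifacts$gd_correlation <- p
  }
  invisible(tibble::tibble(
    artifact = names(artifacts),
    path = unlist(artifacts, use.names = FALSE)
  ))
}
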