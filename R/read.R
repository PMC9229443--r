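#' Read a parental genotype table
#'
#' Reads a delimited text file of microsatellite calls for inbred lines: the
#' header names the loci, the first column names the lines, and each cell
#' holds one allele label (typically a fragment size in base pairs). The
#' separator (comma or tab) is autodetected from the header line. `"NA"` or an
#' empty cell is a missing call; a cell written `"231/235"` is read as a
#' heterozygote contributing half a count to each allele.
#'
#' @param path Path to the genotype file.
#' @return A tibble with a `line_id` column followed by one character column
#'   per locus.
#' @examples
#' f <- system.file("extdata", "synthetic_genotypes.csv", package = "heterodist")
#' read_genotypes(f)
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop_bad("genotype file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  nf <- count.fields(path, sep = sep, quote = "\"", blank.lines.skip = TRUE)
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop_bad("ragged genotype file: row %d has %d fields, expected %d",
             bad, nf[bad], nf[1])
  }
  raw <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                    check.names = FALSE, quote = "\"",
                    na.strings = c("NA", ""), stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop_bad("genotype file needs a line id column and at least one locus")
  names(raw)[1] <- "line_id"
  as_genotype_table(raw)
}

#' Read replicated phenotype observations
#'
#' Reads the long-format phenotype file of a replicated trial: one row per
#' entry (parent or cross) per block per trait. Cross entries are written
#' `"P1xP2"` with parents in canonical order.
#'
#' @param path Path to a delimited file with columns `entry`, `block`,
#'   `trait`, `value` (comma or tab separated, autodetected).
#' @return A tibble with those four columns; `block` integer, `value` double.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_bad("phenotype file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  obs <- tibble::as_tibble(
    read.table(path, header = TRUE, sep = sep, check.names = FALSE,
               stringsAsFactors = FALSE)
  )
  check_cols(obs, c("entry", "block", "trait", "value"), "phenotype file")
  obs <- obs |>
    dplyr::mutate(
      entry = as.character(.data$entry),
      block = as.integer(.data$block),
      trait = as.character(.data$trait),
      value = as.double(.data$value)
    )
  if (any(!is.finite(obs$value))) {
    stop_bad("phenotype file contains non-finite values")
  }
  dup <- obs |> dplyr::count(.data$entry, .data$block, .data$trait) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_bad("duplicated (entry, block, trait) observation(s), e.g. %s / block %s / %s",
             dup$entry[1], dup$block[1], dup$trait[1])
  }
  obs
}

#' Read marker panel metadata
#'
#' Reads a delimited table describing the microsatellite panel (marker name,
#' chromosome, map position, motif, annealing temperature, repeat category,
#' expected fragment size). Column names are kept as found; `marker` and
#' `chromosome` are required.
#'
#' @param path Path to the metadata file (comma or tab separated).
#' @return A tibble, one row per marker.
#' @export
read_marker_panel <- function(path) {
  if (!file.exists(path)) stop_bad("marker metadata file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  panel <- tibble::as_tibble(
    read.table(path, header = TRUE, sep = sep, check.names = FALSE,
               stringsAsFactors = FALSE)
  )
  check_cols(panel, c("marker", "chromosome"), "marker metadata")
  if (anyDuplicated(panel$marker)) stop_bad("duplicated marker name(s) in metadata")
  if (any(panel$chromosome < 1 | panel$chromosome > 12)) {
    stop_bad("chromosome outside 1-12 in marker metadata")
  }
  panel
}

#' Reference SSR panel bundled with the package
#'
#' Two small reference tables for an eight-parent Egyptian rice diallel
#' genotyped at 11 rice microsatellite (RM) loci: `rice_ssr_panel()` returns
#' the published per-locus summary (allele size range, allele count, gene
#' diversity) and `rice_ssr_markers()` the marker metadata (chromosome, map
#' position, motif, annealing temperature, repeat category, expected size).
#' The diversity column is reproduced as published and is treated as an
#' input; it is not regenerated from genotype calls.
#'
#' @return A tibble.
#' @examples
#' glance(aggregate_panel(rice_ssr_panel()))
#' @export
rice_ssr_panel <- function() {
  readr::read_csv(
    system.file("extdata", "rice_ssr_locus_summary.csv", package = "heterodist"),
    show_col_types = FALSE
  )
}

#' @rdname rice_ssr_panel
#' @export
rice_ssr_markers <- function() {
  read_marker_panel(
    system.file("extdata", "rice_ssr_markers.csv", package = "heterodist")
  )
}

#' Trait desirability directions for the standard rice trait set
#'
#' The eight agronomic and yield traits commonly scored in drought-stress
#' diallel trials, with the direction a breeder considers favourable. Lower
#' values are desirable for plant height (lodging) and sterility percentage;
#' higher for the rest. Desirability is presentation metadata only — it never
#' alters heterosis formulas.
#'
#' @return A tibble with columns `trait`, `direction` (`"higher"`/`"lower"`),
#'   `units`.
#' @export
rice_traits <- function() {
  tibble::tribble(
    ~trait,               ~direction, ~units,
    "plant_height",        "lower",   "cm",
    "panicles_per_plant",  "higher",  "count",
    "panicle_length",      "higher",  "cm",
    "panicle_weight",      "higher",  "g",
    "filled_grains",       "higher",  "count",
    "sterility_pct",       "lower",   "%",
    "grain_weight_100",    "higher",  "g",
    "grain_yield",         "higher",  "g/plant"
  )
}
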