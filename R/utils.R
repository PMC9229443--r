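# Internal validation helpers.

stop_bad <- function(msg, ..., class = "heterodist_error") {
  abort(sprintf(msg, ...), class = class)
}

check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_bad("%s is missing required column(s): %s", what,
             paste(missing, collapse = ", "))
  }
  invisible(df)
}

# Split a call string into per-allele weights within one line at one locus.
# Homozygous "231" -> c("231" = 1); heterozygous "231/235" -> 0.5 each.
call_weights <- function(call) {
  if (is.na(call) || !nzchar(call)) return(NULL)
  alleles <- strsplit(call, "/", fixed = TRUE)[[1]]
  w <- rep(1 / length(alleles), length(alleles))
  tapply(w, alleles, sum)
}

is_genotype_table <- function(x) {
  is.data.frame(x) && ncol(x) >= 2 && names(x)[1] == "line_id"
}

as_genotype_table <- function(x) {
  if (!is.data.frame(x)) {
    stop_bad("genotypes must be a data frame (line_id + one column per locus)")
  }
  x <- tibble::as_tibble(x)
  if (names(x)[1] != "line_id") names(x)[1] <- "line_id"
  x$line_id <- as.character(x$line_id)
  if (anyDuplicated(x$line_id)) {
    stop_bad("duplicated line id(s): %s",
             paste(unique(x$line_id[duplicated(x$line_id)]), collapse = ", "))
  }
  x |>
    dplyr::mutate(dplyr::across(-"line_id", as.character)) |>
    dplyr::mutate(dplyr::across(-"line_id", \(v) dplyr::na_if(v, "NA")))
}
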