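# Independent brute-force oracles and small fixture builders.

# PIC by explicit double loop over allele pairs.
naive_pic <- function(p) {
  k <- length(p)
  s <- 0
  if (k >= 2) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) s <- s + 2 * p[i]^2 * p[j]^2
  }
  1 - sum(p^2) - s
}

# Mismatch proportion between two homozygous call vectors (pairwise-complete).
naive_mismatch <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  mean(x[ok] != y[ok])
}

# Naive O(n^3) UPGMA: inter-cluster distance recomputed each step as the
# mean over all member pairs of the ORIGINAL matrix. Returns the cophenetic
# matrix (pair joined at height h have cophenetic distance h).
naive_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, 0, 0)
    for (a in 1:(m - 1)) for (b in (a + 1):m) {
      dd <- mean(d[clusters[[a]], clusters[[b]]])
      if (dd < best[1]) best <- c(dd, a, b)
    }
    a <- best[2]; b <- best[3]
    for (i in clusters[[a]]) for (j in clusters[[b]]) {
      coph[i, j] <- coph[j, i] <- best[1]
    }
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    clusters[[b]] <- NULL
  }
  dimnames(coph) <- dimnames(d)
  coph
}

# Random homozygous genotype table.
random_genotypes <- function(n_lines, n_loci, n_alleles = 3, p_missing = 0) {
  calls <- matrix(
    sample(as.character(seq_len(n_alleles)), n_lines * n_loci, replace = TRUE),
    n_lines, n_loci
  )
  if (p_missing > 0) calls[runif(length(calls)) < p_missing] <- NA
  out <- tibble::as_tibble(as.data.frame(calls))
  names(out) <- paste0("L", seq_len(n_loci))
  dplyr::mutate(out, line_id = paste0("ln", seq_len(n_lines)), .before = 1)
}

# Random symmetric distance matrix with zero diagonal (continuous entries,
# ties almost surely absent).
random_dist_matrix <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 1)
  d <- d + t(d)
  dimnames(d) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  d
}

# Random frequency vector of k alleles.
random_freqs <- function(k) {
  p <- rexp(k)
  p / sum(p)
}

# Long RCBD observations from a genotype x block matrix of plot values.
obs_from_matrix <- function(m, trait = "t") {
  tidyr::expand_grid(entry = rownames(m), block = seq_len(ncol(m))) |>
    dplyr::mutate(trait = trait,
                  value = m[cbind(match(entry, rownames(m)), block)])
}

# Write a small genotype csv and return its path.
write_geno_file <- function(lines, ...) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
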