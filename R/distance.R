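# Genetic distances among inbred lines and UPGMA clustering.

# Within-line allele-frequency vectors for one locus call: homozygous calls
# give a single frequency of 1, "a/b" heterozygote dialect gives 0.5 each.
line_freqs <- function(call) call_weights(call)

locus_similarity <- function(cx, cy) {
  fx <- line_freqs(cx)
  fy <- line_freqs(cy)
  alleles <- union(names(fx), names(fy))
  px <- ifelse(alleles %in% names(fx), fx[alleles], 0)
  py <- ifelse(alleles %in% names(fy), fy[alleles], 0)
  sum(sqrt(px * py))
}

#' Nei DA genetic distance between two lines
#'
#' \eqn{D_A = 1 - \frac{1}{L}\sum_{loci}\sum_{alleles}\sqrt{x_a y_a}}, where
#' \eqn{x_a, y_a} are the within-line allele frequencies. Loci with a missing
#' call in either line are excluded pairwise (the denominator \eqn{L} counts
#' only shared non-missing loci). For fully homozygous inbreds this reduces
#' to the proportion of compared loci whose alleles differ.
#'
#' @param x,y Character vectors of calls for the two lines at the same loci,
#'   in the same order.
#' @param method `"nei_da"` (default, bounded in \[0, 1\]) or
#'   `"nei_standard"` (Nei's 1972 standard distance,
#'   \eqn{-\log(J_{xy}/\sqrt{J_x J_y})}, unbounded above).
#' @return A single distance.
#' @examples
#' nei_da_distance(c("1", "2", "3"), c("1", "2", "4"))  # 1/3
#' @export
nei_da_distance <- function(x, y, method = c("nei_da", "nei_standard")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_bad("call vectors must cover the same loci")
  x <- as.character(x); y <- as.character(y)
  shared <- !is.na(x) & !is.na(y)
  if (!any(shared)) stop_bad("no locus with non-missing calls in both lines")
  x <- x[shared]; y <- y[shared]
  if (method == "nei_da") {
    sims <- vapply(seq_along(x), function(l) locus_similarity(x[l], y[l]), 0)
    return(1 - mean(sims))
  }
  # Nei (1972) standard distance over shared loci
  acc <- vapply(seq_along(x), function(l) {
    fx <- line_freqs(x[l]); fy <- line_freqs(y[l])
    alleles <- union(names(fx), names(fy))
    px <- ifelse(alleles %in% names(fx), fx[alleles], 0)
    py <- ifelse(alleles %in% names(fy), fy[alleles], 0)
    c(jxy = sum(px * py), jx = sum(px^2), jy = sum(py^2))
  }, c(jxy = 0, jx = 0, jy = 0))
  i <- mean(acc["jxy", ]) / sqrt(mean(acc["jx", ]) * mean(acc["jy", ]))
  if (i <= 0) Inf else -log(i)
}

#' Pairwise genetic distance matrix among parental lines
#'
#' Applies [nei_da_distance()] to every unordered pair of lines in a genotype
#' table. Missing calls are handled pairwise, so the effective locus count can
#' differ between pairs.
#'
#' @inheritParams allele_frequencies
#' @inheritParams nei_da_distance
#' @return A symmetric matrix of class `gd_dist` with zero diagonal, labelled
#'   by line id. `tidy()` returns the upper triangle as a tibble
#'   (`line1`, `line2`, `distance`); `as.dist()` works as usual.
#' @examples
#' g <- simulate_parents(simulation_config(seed = 1))
#' d <- pairwise_distances(g)
#' tidy(d)
#' @export
pairwise_distances <- function(genotypes, method = c("nei_da", "nei_standard")) {
  method <- match.arg(method)
  genotypes <- as_genotype_table(genotypes)
  lines <- genotypes$line_id
  if (length(lines) < 2) stop_bad("need at least 2 lines for a distance matrix")
  calls <- as.matrix(genotypes[, -1, drop = FALSE])
  n <- length(lines)
  d <- matrix(0, n, n, dimnames = list(lines, lines))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- nei_da_distance(calls[i, ], calls[j, ], method = method)
    }
  }
  structure(d, class = c("gd_dist", class(d)))
}

#' @export
tidy.gd_dist <- function(x, ...) {
  labs <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    line1 = labs[idx[, 1]],
    line2 = labs[idx[, 2]],
    distance = x[idx]
  )
}

#' @export
print.gd_dist <- function(x, digits = 3, ...) {
  cat("Genetic distance matrix (", nrow(x), " lines)\n", sep = "")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

validate_distance_input <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- unclass(as.matrix(d))
  if (nrow(d) != ncol(d)) stop_bad("distance matrix must be square")
  if (any(!is.finite(d))) stop_bad("distance matrix has non-finite entries")
  if (any(d < 0)) stop_bad("distance matrix has negative entries")
  if (max(abs(d - t(d))) > 1e-12) stop_bad("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop_bad("distance matrix diagonal must be zero")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("L", seq_len(nrow(d)))
  d
}

#' UPGMA clustering of a genetic distance matrix
#'
#' Agglomerative clustering with arithmetic-mean (size-weighted average)
#' linkage: at each step the closest pair of clusters is merged and the
#' distance from the new cluster to every other is the mean of all
#' member-pair distances. Ties in the closest-pair search are broken by the
#' lowest (row, column) position, so the tree is deterministic. Each internal
#' node sits at half its merge distance, giving an ultrametric tree whose
#' cophenetic tip-to-tip distances equal the merge distances.
#'
#' @param d A `gd_dist` matrix from [pairwise_distances()], a plain symmetric
#'   matrix, or a `dist` object. At least 2 labels.
#' @return An ultrametric tree of class `phylo` (see \pkg{ape}), with the
#'   underlying `hclust` object attached as attribute `"hclust"`.
#' @examples
#' d <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tree <- upgma(d)
#' to_newick(tree)
#' @export
upgma <- function(d) {
  d <- validate_distance_input(d)
  n <- nrow(d)
  if (n < 2) stop_bad("UPGMA needs at least 2 labels")
  labels <- rownames(d)
  active <- seq_len(n)           # positions still in play
  id <- -seq_len(n)              # hclust convention: negatives are leaves
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  work <- d
  diag(work) <- Inf
  for (step in seq_len(n - 1)) {
    sub <- work[active, active, drop = FALSE]
    # lowest (row, col) tie-break: scan column-major over the upper triangle
    best <- c(Inf, 0L, 0L)
    m <- length(active)
    for (jj in 2:m) for (ii in 1:(jj - 1)) {
      if (sub[ii, jj] < best[1]) best <- c(sub[ii, jj], ii, jj)
    }
    i <- active[best[2]]; j <- active[best[3]]
    height[step] <- best[1]
    merge[step, ] <- sort(c(id[i], id[j]))
    # size-weighted average update into slot i
    others <- setdiff(active, c(i, j))
    if (length(others) > 0) {
      upd <- (size[i] * work[i, others] + size[j] * work[j, others]) /
        (size[i] + size[j])
      work[i, others] <- upd
      work[others, i] <- upd
    }
    size[i] <- size[i] + size[j]
    id[i] <- step
    active <- setdiff(active, j)
  }
  hc <- structure(
    list(merge = merge, height = height, order = hclust_order(merge),
         labels = labels, method = "average", call = match.call()),
    class = "hclust"
  )
  phy <- ape::as.phylo(hc)
  attr(phy, "hclust") <- hc
  phy
}

# Leaf order for plotting, recovered from the merge matrix.
hclust_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' Write a dendrogram as a Newick string
#'
#' Branch lengths are parent height minus child height, so cophenetic
#' distances on the written tree equal the UPGMA merge distances.
#'
#' @param tree A `phylo` tree, e.g. from [upgma()].
#' @param digits Significant digits for branch lengths.
#' @return A Newick string terminated by `";"`.
#' @export
to_newick <- function(tree, digits = 10) {
  if (!inherits(tree, "phylo")) stop_bad("'tree' must be a phylo object")
  ape::write.tree(tree, digits = digits)
}

#' @rdname to_newick
#' @param path File to write.
#' @export
write_newick <- function(tree, path, digits = 10) {
  writeLines(to_newick(tree, digits = digits), path)
  invisible(path)
}
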