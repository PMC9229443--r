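# Nei distances, UPGMA clustering, Newick export.

test_that("Nei DA on homozygous lines is the mismatch proportion", {
  x <- as.character(1:11)
  expect_equal(nei_da_distance(x, x), 0)
  expect_equal(nei_da_distance(x, as.character(12:22)), 1)
  y <- x; y[1:4] <- "99"
  expect_equal(nei_da_distance(x, y), 4 / 11)
})

test_that("missing calls are excluded pairwise from the denominator", {
  x <- c("1", NA, "3", "4")
  y <- c("1", "2", NA, "9")
  # shared loci: 1 and 4; one mismatch
  expect_equal(nei_da_distance(x, y), 0.5)
  expect_error(nei_da_distance(c(NA, "1"), c("2", NA)), "no locus")
})

test_that("heterozygous calls give sqrt-frequency overlap", {
  # "a/b" vs "a": sum sqrt(0.5 * 1) = 0.7071; one locus
  expect_equal(nei_da_distance("a/b", "a"), 1 - sqrt(0.5))
})

test_that("Nei standard distance is -log of the normalized identity", {
  x <- as.character(1:10); y <- x; y[1:3] <- "99"
  # homozygous: Jx = Jy = 1, Jxy = 0.7
  expect_equal(nei_da_distance(x, y, method = "nei_standard"), -log(0.7))
  expect_equal(nei_da_distance(x, x, method = "nei_standard"), 0)
})

test_that("pairwise distance matrices satisfy their invariants", {
  g <- tibble::tibble(line_id = c("A", "B"),
                      L1 = c("1", "1"), L2 = c("2", "2"))
  expect_equal(unclass(pairwise_distances(g)),
               matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B"))),
               ignore_attr = TRUE)

  parents <- simulate_parents(simulation_config(seed = 5))
  d <- pairwise_distances(parents)
  expect_equal(dim(d), c(8, 8))
  expect_equal(unclass(d), t(unclass(d)))
  expect_equal(diag(d), setNames(rep(0, 8), parents$line_id))
  expect_length(d[upper.tri(d)], 28)
  expect_true(all(d >= 0 & d <= 1))
})

test_that("pairwise distances match per-pair brute-force mismatch counting", {
  g <- tibble::tibble(
    line_id = c("A", "B", "C"),
    L1 = c("1", "1", "2"), L2 = c("1", "2", "2"), L3 = c("3", "3", "3")
  )
  d <- pairwise_distances(g)
  expect_equal(d["A", "B"], 1 / 3)
  expect_equal(d["A", "C"], 2 / 3)
  expect_equal(d["B", "C"], 1 / 3)
})

test_that("distance is a pseudo-metric on complete tables", {
  # the triangle inequality is a property of the mismatch proportion over a
  # common locus set; pairwise-complete deletion of missing calls can break
  # it, so it is asserted on complete tables only
  set.seed(21)
  for (i in 1:25) {
    g <- random_genotypes(sample(3:6, 1), sample(4:10, 1))
    d <- pairwise_distances(g)
    n <- nrow(d)
    expect_equal(unclass(d), t(unclass(d)))
    for (a in 1:n) for (b in 1:n) for (cc in 1:n) {
      expect_lte(d[a, b], d[a, cc] + d[cc, b] + 1e-12)
    }
  }
})

test_that("distance is invariant to line and locus order", {
  set.seed(25)
  for (i in 1:15) {
    g <- random_genotypes(sample(3:6, 1), sample(4:10, 1), p_missing = 0.05)
    d <- tryCatch(pairwise_distances(g), error = function(e) NULL)
    if (is.null(d)) next  # a pair without shared loci (rare at this missingness)
    perm_lines <- g[sample(nrow(g)), ]
    perm_loci <- g[, c(1, sample(2:ncol(g)))]
    d2 <- pairwise_distances(perm_lines)[rownames(d), colnames(d)]
    d3 <- pairwise_distances(perm_loci)
    expect_equal(unclass(d2), unclass(d), ignore_attr = TRUE)
    expect_equal(unclass(d3), unclass(d))
  }
})

test_that("UPGMA reproduces the hand-agglomerated three-leaf tree", {
  d <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(d)
  hc <- attr(tree, "hclust")
  expect_equal(hc$height, c(0.2, 0.6))
  # Newick with branch lengths = parent height - child height
  ref <- ape::read.tree(text = "((A:0.1,B:0.1):0.2,C:0.3);")
  got <- ape::read.tree(text = to_newick(tree))
  expect_equal(ape::cophenetic.phylo(got)[c("A", "B", "C"), c("A", "B", "C")],
               ape::cophenetic.phylo(ref)[c("A", "B", "C"), c("A", "B", "C")])
  expect_true(ape::all.equal.phylo(got, ref, use.edge.length = TRUE))
})

test_that("two leaves merge at half their distance", {
  d <- matrix(c(0, .4, .4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tree <- upgma(d)
  expect_equal(attr(tree, "hclust")$height, 0.4)
  expect_equal(unname(ape::cophenetic.phylo(tree)["A", "B"]), 0.4)
  expect_match(to_newick(tree), ";$")
})

test_that("UPGMA is exact on ultrametric input", {
  # build an ultrametric matrix from a known tree
  coph <- ape::cophenetic.phylo(
    ape::read.tree(text = "(((A:1,B:1):2,C:3):1,(D:2,E:2):2);"))
  tree <- upgma(coph)
  expect_equal(ape::cophenetic.phylo(tree)[rownames(coph), colnames(coph)],
               coph)
})

test_that("merge heights are monotone and leaves are conserved", {
  set.seed(22)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    d <- random_dist_matrix(n)
    tree <- upgma(d)
    hc <- attr(tree, "hclust")
    expect_true(all(diff(hc$height) >= -1e-12))
    expect_setequal(tree$tip.label, rownames(d))
  }
})

test_that("UPGMA matches the naive O(n^3) oracle and hclust on small matrices", {
  set.seed(23)
  for (n in 2:6) {
    for (i in 1:20) {
      d <- random_dist_matrix(n)
      coph <- ape::cophenetic.phylo(upgma(d))[rownames(d), colnames(d)]
      expect_equal(coph, naive_upgma_cophenetic(d), tolerance = 1e-10)
      if (n >= 3) {
        hc <- stats::hclust(as.dist(d), method = "average")
        expect_equal(sort(attr(upgma(d), "hclust")$height), sort(hc$height),
                     tolerance = 1e-10)
        expect_equal(coph,
                     as.matrix(stats::cophenetic(hc))[rownames(d), colnames(d)],
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("invalid distance input is rejected", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(upgma(bad), "not symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(upgma(neg), "negative")
  expect_error(upgma(matrix(0, 1, 1)), "at least 2")
})

test_that("Newick round-trip preserves topology and heights", {
  set.seed(24)
  for (i in 1:10) {
    d <- random_dist_matrix(sample(3:7, 1))
    tree <- upgma(d)
    back <- ape::read.tree(text = to_newick(tree))
    expect_true(ape::all.equal.phylo(back, tree, use.edge.length = TRUE,
                                     tolerance = 1e-8))
  }
})
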