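test_that("the drug/gene matrix keeps only genes appearing twice across candidate sets", {
  recs <- data.frame(
    drug = c("D1", "D1", "D2"),
    geneA = c("A", "A", "A"),
    geneB = c("B", "C", "B"),
    candidate = c(TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  m <- build_drug_gene_matrix(recs)
  # A appears 3x, B 2x, C once -> C dropped
  expect_setequal(rownames(m), c("A", "B"))
  expect_equal(m["A", "D1"], 1L)
  expect_equal(m["A", "D2"], 1L)
  expect_equal(m["B", "D2"], 1L)
  # appearance is per candidate pair: a gene paired twice for one drug counts twice
  recs2 <- data.frame(
    drug = "D1", geneA = c("A", "A"), geneB = c("B", "C"),
    candidate = TRUE, stringsAsFactors = FALSE
  )
  m2 <- build_drug_gene_matrix(recs2)
  expect_identical(rownames(m2), "A")
  # no candidates -> empty matrix
  empty <- recs[recs$candidate == FALSE, ]
  expect_equal(dim(build_drug_gene_matrix(empty)), c(0L, 0L))
})

test_that("min-max row normalisation scales to [0,1], maps constant rows to 0 and is idempotent", {
  m <- rbind(a = c(0, 5, 10), b = c(3, 3, 3), c = c(2, 4, 6))
  norm <- suppressMessages(minmax_normalize_rows(m))
  expect_equal(unname(norm["a", ]), c(0, 0.5, 1))
  expect_equal(unname(norm["b", ]), c(0, 0, 0))
  expect_equal(unname(norm["c", ]), c(0, 0.5, 1))
  expect_equal(suppressMessages(minmax_normalize_rows(norm)), norm)
})

test_that("the drug/tissue matrix counts MM lines per tissue with drug-wise scaling", {
  meta <- data.frame(
    cell_line = sprintf("L%d", 1:6),
    tissue1 = c("skin", "skin", "lung", "lung", "gut", "gut"),
    tissue2 = c("mel", "mel", "NSCLC", "SCLC", "crc", "crc"),
    stringsAsFactors = FALSE
  )
  mm <- data.frame(
    drug = c("D1", "D1", "D1", "D2"),
    cell_line = c("L1", "L2", "L3", "L5"),
    stringsAsFactors = FALSE
  )
  raw <- build_drug_tissue_matrix(mm, meta, "tissue1", normalize = "none")
  expect_equal(raw["D1", c("gut", "lung", "skin")], c(gut = 0, lung = 1, skin = 2))
  norm <- suppressMessages(build_drug_tissue_matrix(mm, meta, "tissue1"))
  expect_equal(norm["D1", "skin"], 1)
  expect_equal(norm["D1", "gut"], 0)
  # descriptor selectable
  fine <- build_drug_tissue_matrix(mm, meta, "tissue2", normalize = "none")
  expect_true("mel" %in% colnames(fine))
  expect_error(
    build_drug_tissue_matrix(
      data.frame(drug = "D1", cell_line = "LX"), meta
    ),
    "missing from cell-line metadata"
  )
})

test_that("complete-linkage clustering merges identical rows at height 0 and blocks before across", {
  # two tight blocks far apart; hand-computed complete-linkage merge order:
  # {r1,r2} at 0.1, {r3,r4} at 0.2, then across at the max inter-block distance
  m <- rbind(
    r1 = c(0, 0), r2 = c(0, 0.1),
    r3 = c(10, 10), r4 = c(10, 10.2)
  )
  res <- hierarchical_cluster(m, k = 2)
  expect_equal(res$heights[1:2], c(0.1, 0.2), tolerance = 1e-12)
  across <- max(
    sqrt(sum((m["r1", ] - m["r3", ])^2)), sqrt(sum((m["r1", ] - m["r4", ])^2)),
    sqrt(sum((m["r2", ] - m["r3", ])^2)), sqrt(sum((m["r2", ] - m["r4", ])^2))
  )
  expect_equal(res$heights[3], across, tolerance = 1e-12)
  expect_equal(unname(res$clusters[c("r1", "r2")]), c(1, 1))
  expect_equal(unname(res$clusters[c("r3", "r4")]), c(2, 2))
  expect_true(all(diff(res$heights) >= 0)) # complete linkage is monotone
  # identical rows merge at height 0
  dup <- rbind(a = c(1, 1), b = c(1, 1), c = c(5, 5))
  expect_equal(hierarchical_cluster(dup)$heights[1], 0)
  expect_error(hierarchical_cluster(m[1, , drop = FALSE]), "at least 2 rows")
})

test_that("clustering is invariant to row permutation up to relabeling", {
  set.seed(8)
  m <- matrix(rnorm(30), 6, 5, dimnames = list(paste0("r", 1:6), NULL))
  res1 <- hierarchical_cluster(m, k = 3)
  perm <- sample(6)
  res2 <- hierarchical_cluster(m[perm, ], k = 3)
  expect_equal(sort(res1$heights), sort(res2$heights), tolerance = 1e-12)
  # same partition of row names
  part <- function(cl) unname(split(names(cl), cl))
  canon <- function(p) sort(vapply(p, function(g) paste(sort(g), collapse = "+"), ""))
  expect_identical(canon(part(res1$clusters)), canon(part(res2$clusters)))
})

test_that("dendrograms export as Newick text", {
  m <- rbind(r1 = c(0, 0), r2 = c(0, 1), r3 = c(4, 4))
  txt <- export_dendrogram(hierarchical_cluster(m))
  expect_match(txt, "^\\(")
  expect_match(txt, "r1")
  path <- withr::local_tempfile(fileext = ".nwk")
  export_dendrogram(hierarchical_cluster(m), path)
  expect_identical(readLines(path), txt)
})

test_that("tissue enrichment matches the direct chi-squared formula", {
  # identical proportions -> statistic 0, p = 1
  same <- tissue_enrichment(
    c(skin = 10, lung = 30),
    c(skin = 100, lung = 300)
  )
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
  # hand-built 2x2: 10/90 vs 50/50, n = 100 each
  obs <- cbind(c(10, 90), c(50, 50))
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  stat_hand <- sum((obs - expected)^2 / expected)
  res <- tissue_enrichment(c(A = 10, B = 90), c(A = 50, B = 50))
  expect_equal(res$statistic, stat_hand, tolerance = 1e-12)
  expect_equal(res$p_value, stats::pchisq(stat_hand, 1, lower.tail = FALSE))
  # low expected counts produce the standard caveat
  expect_warning(
    tissue_enrichment(c(A = 1, B = 2), c(A = 2, B = 1)),
    "below 5"
  )
  expect_error(
    tissue_enrichment(c(A = 1), c(B = 1)),
    "same tissue categories"
  )
})
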