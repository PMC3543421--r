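fam_table <- function(...) {
  # families given as family_id = c("rep:orf", ...)
  args <- list(...)
  rows <- lapply(names(args), function(f) {
    parts <- strsplit(args[[f]], ":", fixed = TRUE)
    data.frame(family_id = f,
               orf_id = vapply(parts, `[`, "", 2),
               replicon_id = vapply(parts, `[`, "", 1),
               is_representative = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("presence matrix binarizes membership per replicon", {
  fam <- fam_table(F1 = c("r1:a", "r2:b"), F2 = "r1:c", F3 = "r2:d")
  m <- presence_matrix(fam, c("r1", "r2"))
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(unname(rowSums(m)), c(2, 2))
  # paralogs collapse to presence, counts kept on the side
  fam2 <- fam_table(F1 = c("r1:a", "r1:a2", "r2:b"))
  m2 <- presence_matrix(fam2, c("r1", "r2"))
  expect_equal(unname(m2[, "F1"]), c(1, 1))
  expect_equal(unname(attr(m2, "counts")[, "F1"]), c(2, 1))
  expect_error(presence_matrix(fam[0, ], c("r1")), "no gene families")
  expect_error(presence_matrix(fam, c("r1")), "unknown")
})

test_that("gene-content distances follow their closed forms", {
  fam <- fam_table(F1 = c("A:1", "B:5"), F2 = c("A:2", "B:6"),
                   F3 = c("A:3"), F4 = c("A:4"), F5 = c("B:7"))
  m <- presence_matrix(fam, c("A", "B"))
  # A = {F1,F2,F3,F4}, B = {F1,F2,F5}: jaccard 1 - 2/5, shared_min -ln(2/3)
  dj <- gene_content_distance(m, "jaccard")
  expect_equal(dj["A", "B"], 0.6)
  ds <- gene_content_distance(m, "shared_min")
  expect_equal(ds["A", "B"], -log(2 / 3))
  # identical sets -> 0 under both
  fam_id <- fam_table(F1 = c("A:1", "B:2"), F2 = c("A:3", "B:4"))
  mi <- presence_matrix(fam_id, c("A", "B"))
  expect_equal(gene_content_distance(mi, "jaccard")["A", "B"], 0)
  expect_equal(gene_content_distance(mi, "shared_min")["A", "B"], 0)
  # disjoint sets -> jaccard 1, shared_min hits the ceiling
  fam_dis <- fam_table(F1 = "A:1", F2 = "B:2")
  md <- presence_matrix(fam_dis, c("A", "B"))
  expect_equal(gene_content_distance(md, "jaccard")["A", "B"], 1)
  expect_equal(gene_content_distance(md, "shared_min", ceiling = 7)["A", "B"],
               7)
})

test_that("distance axioms hold on random binary matrices", {
  set.seed(211)
  for (i in 1:10) {
    m <- matrix(rbinom(5 * 12, 1, 0.6), nrow = 5,
                dimnames = list(paste0("r", 1:5), paste0("F", 1:12)))
    m[rowSums(m) == 0, 1] <- 1L
    m <- m[, colSums(m) > 0, drop = FALSE]
    for (meth in c("jaccard", "shared_min")) {
      d <- gene_content_distance(m, meth)
      expect_equal(d, t(d))
      expect_true(all(diag(d) == 0))
      expect_true(all(d >= 0))
      expect_true(all(is.finite(d)))
    }
  }
})

test_that("3-taxon NJ matches the closed form", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), (5 + 9 - 10) / 2)
  expect_equal(unname(bl["B"]), (5 + 10 - 9) / 2)
  expect_equal(unname(bl["C"]), (9 + 10 - 5) / 2)
})

test_that("NJ recovers additive 4-taxon trees exactly", {
  set.seed(221)
  for (i in 1:10) {
    ref <- random_additive_matrix(4)
    tr <- nj_tree(ref$d)
    expect_true(same_topology(tr, ref$tree), info = paste("case", i))
    # branch lengths: compare tip-to-tip path distances
    got <- ape::cophenetic.phylo(tr)
    got <- got[rownames(ref$d), colnames(ref$d)]
    expect_equal(got, ref$d, tolerance = 1e-8)
  }
})

test_that("NJ agrees with exhaustive least squares on 5-taxon trees", {
  set.seed(231)
  for (i in 1:6) {
    ref <- random_additive_matrix(5)
    tr <- nj_tree(ref$d)
    ls <- orc_ls_topology(ref$d)
    expect_true(same_topology(tr, ls), info = paste("case", i))
  }
})

test_that("NJ agrees with the reference implementation on noisy matrices", {
  set.seed(241)
  for (i in 1:6) {
    ref <- random_additive_matrix(6)
    d <- ref$d + matrix(runif(36, 0, 0.02), 6, 6)
    d <- (d + t(d)) / 2; diag(d) <- 0
    expect_true(same_topology(nj_tree(d), ape::nj(as.dist(d))),
                info = paste("case", i))
  }
})

test_that("NJ validates its input", {
  d <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(nj_tree(d), "at least 3")
  d3 <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3, 3)
  expect_error(nj_tree(d3), "symmetric")
  d3b <- matrix(c(0, 1, Inf, 1, 0, 3, Inf, 3, 0), 3, 3)
  expect_error(nj_tree(d3b), "finite")
})

test_that("subfamily delineation cuts single-linkage clusters", {
  d <- matrix(10, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 1
  d["c", "d"] <- d["d", "c"] <- 1
  diag(d) <- 0
  labs <- delineate_subfamilies(d, k = 2)
  expect_equal(labs[["a"]], labs[["b"]])
  expect_equal(labs[["c"]], labs[["d"]])
  expect_true(labs[["a"]] != labs[["c"]])
  # k = n: every replicon its own subfamily
  expect_equal(length(unique(delineate_subfamilies(d, k = 4))), 4L)
  expect_error(delineate_subfamilies(d, k = 5), "between")
  # threshold cut
  labs_h <- delineate_subfamilies(d, h = 5)
  expect_equal(length(unique(labs_h)), 2L)
  # all-equal distances: deterministic result in id order
  de <- matrix(1, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  diag(de) <- 0
  l1 <- delineate_subfamilies(de, k = 2)
  l2 <- delineate_subfamilies(de, k = 2)
  expect_equal(l1, l2)
})

test_that("conservation classes follow their definitions and partition", {
  m <- rbind(r1 = c(1, 1, 1, 1, 0),
             r2 = c(1, 1, 0, 1, 0),
             r3 = c(1, 0, 1, 0, 1),
             r4 = c(1, 0, 1, 0, 0))
  colnames(m) <- paste0("F", 1:5)
  labs <- c(r1 = 1L, r2 = 1L, r3 = 2L, r4 = 2L)
  cls <- classify_conservation(m, labs)
  expect_equal(unname(cls["F1"]), "core")           # everywhere
  expect_equal(unname(cls["F2"]), "group_specific") # r1+r2 only
  expect_equal(unname(cls["F3"]), "semi_conserved") # both groups, not all
  expect_equal(unname(cls["F4"]), "group_specific")
  expect_equal(unname(cls["F5"]), "singleton")
  expect_setequal(names(cls), colnames(m))          # a full partition
  expect_error(classify_conservation(m, labs[1:2]), "cover")
  expect_error(classify_conservation(m, c(r1 = 1L, r2 = 1L, r3 = 1L,
                                          r4 = 1L)), "2 subfamilies")
})

test_that("matrix, distances and tree serialize to their formats", {
  fam <- fam_table(F1 = c("A:1", "B:2", "C:3"), F2 = c("A:4", "B:5"),
                   F3 = c("C:6"))
  m <- presence_matrix(fam, c("A", "B", "C"))
  d <- gene_content_distance(m)
  phy <- withr::local_tempfile(fileext = ".phy")
  write_phylip(d, phy)
  lines <- readLines(phy)
  expect_equal(as.integer(trimws(lines[1])), 3L)
  expect_equal(length(lines), 4L)
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  expect_match(attr(tr, "newick"), "^\\(.*\\);$")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
})
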