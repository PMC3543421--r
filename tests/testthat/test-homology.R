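mutate_positions <- function(prot, frac) {
  aa <- strsplit(prot, "")[[1]]
  alphabet <- c("A","R","N","D","C","Q","E","G","H","I",
                "L","K","M","F","P","S","T","W","Y","V")
  k <- ceiling(frac * length(aa))
  idx <- sample(seq_along(aa), k)
  for (i in idx) aa[i] <- sample(setdiff(alphabet, aa[i]), 1)
  paste(aa, collapse = "")
}

test_that("self-alignment gives identity and coverage 1", {
  set.seed(101)
  p <- random_peptide(100)
  hit <- align_pair(p, p, idA = "a", idB = "b")
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$coverage_short, 1.0)
  expect_equal(c(hit$q_start, hit$q_end), c(1L, 100L))
})

test_that("alignment scores are symmetric and match the DP oracle", {
  set.seed(111)
  mat <- mgecompare:::get_submat("BLOSUM62")
  params <- homology_params(min_score = -Inf)
  for (i in 1:30) {
    a <- random_peptide(sample(10:50, 1))
    b <- random_peptide(sample(10:50, 1))
    sab <- align_pair(a, b, params)$score
    sba <- align_pair(b, a, params)$score
    expect_equal(sab, sba)
    expect_equal(sab, orc_sw_score(a, b, mat), info = paste("pair", i))
  }
})

test_that("disjoint-alphabet peptides produce no reportable hit", {
  expect_null(align_pair("KKKKKKKK", "EEEEEEEE"))
  expect_error(align_pair("KKB", "EEE"), "non-amino-acid")
})

test_that("all-vs-all labels full and partial hits by coverage", {
  set.seed(121)
  x <- random_peptide(200)
  prots <- c(p1 = x, p2 = mutate_positions(x, 0.1),
             p3 = mutate_positions(x, 0.1), decoy = random_peptide(200))
  hits <- all_vs_all(prots)
  full <- hits[!hits$partial, ]
  expect_setequal(paste(full$query_id, full$subject_id),
                  c("p1 p2", "p1 p3", "p2 p3"))
  expect_true(all(full$identity > 0.7))
  # unrelated random proteins of matched composition: no hits at all
  set.seed(122)
  decoys <- setNames(replicate(6, random_peptide(150)), paste0("d", 1:6))
  expect_equal(nrow(all_vs_all(decoys)), 0L)
})

test_that("a chimeric protein yields partial hits with disjoint intervals", {
  set.seed(131)
  x <- random_peptide(300); y <- random_peptide(300)
  chim <- paste0(substr(x, 1, 150), substr(y, 151, 300))
  prots <- c(X = x, Y = y, C = chim)
  hits <- all_vs_all(prots)
  cx <- hits[(hits$query_id == "C" & hits$subject_id == "X") |
             (hits$query_id == "X" & hits$subject_id == "C"), ]
  cy <- hits[(hits$query_id == "C" & hits$subject_id == "Y") |
             (hits$query_id == "Y" & hits$subject_id == "C"), ]
  expect_equal(nrow(cx), 1L)
  expect_equal(nrow(cy), 1L)
  expect_true(cx$partial && cy$partial)
  ivl <- function(h) if (h$query_id == "C") c(h$q_start, h$q_end) else
    c(h$s_start, h$s_end)
  expect_lt(ivl(cx)[2], ivl(cy)[1])   # N-half vs C-half
})

test_that("families are single-linkage over full hits only", {
  prots <- c(A = "X", B = "X", C = "X", D = "X", E = "X")
  hits <- rbind(
    data.frame(query_id = "A", subject_id = "B", score = 100, identity = .9,
               q_start = 1, q_end = 1, s_start = 1, s_end = 1,
               coverage_short = 1, partial = FALSE),
    data.frame(query_id = "B", subject_id = "C", score = 100, identity = .9,
               q_start = 1, q_end = 1, s_start = 1, s_end = 1,
               coverage_short = 1, partial = FALSE),
    data.frame(query_id = "D", subject_id = "E", score = 50, identity = .4,
               q_start = 1, q_end = 1, s_start = 1, s_end = 1,
               coverage_short = 0.3, partial = TRUE))
  prots[] <- sapply(seq_along(prots), function(i) random_peptide(50))
  fam <- cluster_families(hits, prots)
  by_fam <- split(fam$orf_id, fam$family_id)
  sizes <- sort(lengths(by_fam), decreasing = TRUE)
  expect_equal(unname(sizes), c(3L, 1L, 1L))
  abc <- by_fam[[which(lengths(by_fam) == 3)]]
  expect_setequal(abc, c("A", "B", "C"))     # transitivity
  expect_false(any(c("D", "E") %in% abc))    # partial never merges
  expect_equal(anyDuplicated(fam$orf_id), 0L)
})

test_that("family ids are invariant to protein input order", {
  set.seed(141)
  x <- random_peptide(120)
  prots <- c(a1 = x, a2 = mutate_positions(x, 0.1),
             b1 = random_peptide(90), b2 = random_peptide(200))
  f1 <- cluster_families(all_vs_all(prots), prots)
  shuffled <- prots[c(3, 1, 4, 2)]
  f2 <- cluster_families(all_vs_all(shuffled), shuffled)
  f1 <- f1[order(f1$orf_id), ]; f2 <- f2[order(f2$orf_id), ]
  expect_equal(f1$family_id, f2$family_id)
  expect_equal(f1$is_representative, f2$is_representative)
})

test_that("planted families are recovered exactly (ARI 1)", {
  for (seed in 1:5) {
    set.seed(200 + seed)
    truth <- character(0); prots <- character(0)
    for (f in 1:4) {
      anc <- random_peptide(sample(80:250, 1))
      for (m in 1:3) {
        id <- sprintf("f%d_m%d", f, m)
        prots[id] <- mutate_positions(anc, 0.15)
        truth[id] <- paste0("f", f)
      }
    }
    fam <- cluster_families(all_vs_all(prots), prots)
    lab <- setNames(fam$family_id, fam$orf_id)[names(prots)]
    expect_equal(ari(lab, truth), 1, info = paste("seed", seed))
  }
})

test_that("the modular map mirrors chimeric architecture", {
  set.seed(151)
  x <- random_peptide(300); y <- random_peptide(300)
  chim <- paste0(substr(x, 1, 150), substr(y, 151, 300))
  prots <- c(X = x, X2 = mutate_positions(x, 0.05),
             Y = y, Y2 = mutate_positions(y, 0.05), C = chim)
  hits <- all_vs_all(prots)
  fam <- cluster_families(hits, prots)
  fmap <- setNames(fam$family_id, fam$orf_id)
  mm <- modular_map("C", hits, fam)
  expect_equal(nrow(mm), 2L)
  expect_setequal(mm$partner_family, unname(fmap[c("X", "Y")]))
  segX <- mm[mm$partner_family == fmap[["X"]], ]
  segY <- mm[mm$partner_family == fmap[["Y"]], ]
  expect_lt(abs(segX$seg_end - 150), 10)     # breakpoint within +-10 aa
  expect_lt(abs(segY$seg_start - 151), 10)
  # a protein with no hits has an empty map
  expect_equal(nrow(modular_map("X", hits[0, ], fam)), 0L)
})

test_that("cross-screen maps shared queries and leaves orphans", {
  set.seed(161)
  x <- random_peptide(150); y <- random_peptide(220)
  prots <- c(x1 = x, x2 = mutate_positions(x, 0.1),
             y1 = y, y2 = mutate_positions(y, 0.1))
  fam <- cluster_families(all_vs_all(prots), prots)
  fmap <- setNames(fam$family_id, fam$orf_id)
  queries <- c(qx = x, qrand = random_peptide(150))
  res <- cross_screen(queries, fam, prots)
  expect_equal(res$family_id[res$query_id == "qx"], unname(fmap[["x1"]]))
  expect_equal(res$identity[res$query_id == "qx"], 1.0)
  expect_true(res$orphan[res$query_id == "qrand"])
})
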