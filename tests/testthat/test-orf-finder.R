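sense_codons <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))

rand_codons <- function(n) paste(sample(sense_codons, n, replace = TRUE),
                                 collapse = "")

test_that("translation follows the standard code with initiator handling", {
  expect_equal(translate_dna("ATGGCT", as_start = TRUE), "MA")
  expect_equal(translate_dna("TTGGCT", as_start = TRUE), "MA")
  expect_equal(translate_dna("GTGGCT", as_start = TRUE), "MA")
  expect_equal(translate_dna("TTGGCT", as_start = FALSE), "LA")
  expect_error(translate_dna("ATGTAAGCT"), "stop")
  expect_error(translate_dna("ATGG"), "multiple of 3")
})

test_that("the 39-codon minimum is counted start through last sense codon", {
  set.seed(5)
  at <- paste0("CCCC", "ATG", rand_codons(38), "TAA", "CCCC")
  s <- circular_seq("t", at, circular = FALSE)
  o <- find_orfs(s)
  expect_true(any(o$n_codons == 39 & o$strand == "+"))
  kept <- o[o$n_codons == 39 & o$strand == "+", ]
  expect_equal(kept$end - kept$start, 3 * (39 + 1))
  below <- paste0("CCCC", "ATG", rand_codons(36), "TAA", "CCCC")
  o2 <- find_orfs(circular_seq("t2", below, circular = FALSE))
  expect_true(all(o2$n_codons >= 39))
})

test_that("a sequence without start codons yields no ORFs", {
  s <- circular_seq("t", strrep("C", 300), circular = FALSE)
  expect_equal(nrow(find_orfs(s)), 0L)
})

test_that("SD scoring finds the longest contiguous consensus match", {
  p <- orf_params()
  # perfect AGGAGG planted with 8 bp between its 3' end and the start
  up <- paste0(strrep("C", 30), "AGGAGG", strrep("C", 8))
  s <- circular_seq("t", paste0(up, "ATGAAA"), circular = FALSE)
  res <- score_sd(s, nchar(up), "+", p)
  expect_equal(res$score, 6L)
  expect_equal(res$offset, 8L)
  # pyrimidine-only window: no match at all
  s0 <- circular_seq("t", paste0(strrep("CT", 22), "ATGAAA"),
                     circular = FALSE)
  res0 <- score_sd(s0, 44, "+", p)
  expect_equal(res0$score, 0L)
  expect_true(is.na(res0$offset))
  # GGAG only -> score 4
  up4 <- paste0(strrep("C", 30), "GGAG", strrep("C", 8))
  s4 <- circular_seq("t", paste0(up4, "ATGAAA"), circular = FALSE)
  expect_equal(score_sd(s4, nchar(up4), "+", p)$score, 4L)
})

test_that("SD scoring agrees with a naive scorer on random contexts", {
  set.seed(99)
  p <- orf_params()
  for (i in 1:40) {
    s <- circular_seq("t", paste0(random_dna(60, gc = 0.6), "ATGAAA"),
                      circular = FALSE)
    got <- score_sd(s, 60, "+", p)
    # naive scorer works on a rotation-free linear string
    want <- orc_sd_score(s$residues, 60, p$sd_window[1], p$sd_window[2],
                         p$sd_consensus)
    expect_equal(got$score, want$score)
    if (got$score > 0) expect_equal(got$offset, want$offset)
  }
})

test_that("start selection prefers SD-supported then longest", {
  p <- orf_params()
  expect_equal(choose_start(100L, 0L, p), 100L)
  expect_equal(choose_start(c(10L, 40L), c(0L, 6L), p), 40L)
  expect_equal(choose_start(c(10L, 40L), c(4L, 4L), p), 10L)
  expect_equal(choose_start(c(10L, 40L), c(0L, 3L), p), 10L)
  expect_error(choose_start(integer(0), integer(0), p), "empty")
})

test_that("an SD-supported internal start is chosen over the upstream one", {
  set.seed(12)
  # upstream start with no SD context, in-frame internal start preceded
  # by a perfect AGGAGG nine bases upstream
  dna <- paste0(strrep("C", 10), "ATG", "CCC", "AGGAGG", strrep("C", 9),
                "ATG", rand_codons(40), "TAA", strrep("C", 10))
  s <- circular_seq("t", dna, circular = FALSE)
  o <- find_orfs(s)
  plus <- o[o$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$sd_score, 6L)
  expect_equal(plus$start_codon, "ATG")
  expect_equal(plus$start, 31L)   # the internal, SD-supported start
  expect_equal(plus$n_codons, 41L)
})

test_that("ORF calls match the rotating brute-force oracle", {
  set.seed(2024)
  for (i in 1:12) {
    s <- circular_seq(paste0("r", i), random_dna(400, gc = 0.45))
    got <- suppressWarnings(find_orfs(s))
    want <- orc_orfs(s)
    expect_equal(nrow(got), nrow(want), info = paste("seq", i))
    expect_equal(got$start, want$start, info = paste("seq", i))
    expect_equal(got$end, want$end)
    expect_equal(got$strand, want$strand)
    expect_equal(got$n_codons, want$n_codons)
    expect_equal(got$sd_score, want$sd_score)
    expect_equal(got$protein, want$protein)
  }
})

test_that("reported proteins reproduce from the reported coordinates", {
  set.seed(77)
  s <- circular_seq("r", random_dna(900, gc = 0.4))
  o <- suppressWarnings(find_orfs(s))
  chars <- strsplit(s$residues, "")[[1]]
  for (i in seq_len(nrow(o))) {
    minus <- o$strand[i] == "-"
    idx <- if (minus) (o$start[i] + 3):(o$end[i] - 1) else
      o$start[i]:(o$end[i] - 4)
    dna <- paste(chars[(idx %% s$length) + 1], collapse = "")
    if (minus) dna <- orc_revcomp(dna)
    expect_equal(translate_dna(dna, as_start = TRUE), o$protein[i])
  }
})

test_that("rotation shifts ORF coordinates and nothing else", {
  set.seed(88)
  s <- circular_seq("r", random_dna(600))
  base <- suppressWarnings(find_orfs(s))
  for (k in c(13, 250, 599)) {
    rot <- suppressWarnings(find_orfs(rotate_seq(s, k)))
    expect_equal(nrow(rot), nrow(base))
    shifted <- sort(paste((base$start - k) %% 600, base$strand))
    expect_equal(sort(paste(rot$start %% 600, rot$strand)), shifted)
    expect_equal(sort(rot$protein), sort(base$protein))
  }
})

test_that("N codons terminate ORFs instead of being read through", {
  set.seed(3)
  body <- rand_codons(60)
  dna <- paste0("CCCC", "ATG", substr(body, 1, 90), "NNN",
                substr(body, 91, 180), "TAA", "CCCC")
  s <- circular_seq("t", dna, circular = FALSE)
  o <- find_orfs(s)
  # no reported ORF may span the N block
  n_at <- 4 + 3 + 90
  spans <- o$start < n_at & o$end > n_at + 3
  expect_false(any(spans & o$strand == "+"))
  expect_false(any(grepl("X", o$protein)))
})

test_that("a stop-free circular frame raises a warning, not an ORF", {
  s <- circular_seq("t", strrep("ATGGCAGCA", 10))  # 90 bp, no stop anywhere
  w <- capture_warnings(o <- find_orfs(s))
  expect_true(any(grepl("stop-free", w)))
  expect_true(all((o$end - o$start) <= s$length))
})

test_that("GFF3 emission is 1-based inclusive with wrap kept explicit", {
  set.seed(6)
  s <- circular_seq("r", random_dna(500))
  o <- suppressWarnings(find_orfs(s))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_orf_gff3(o, s, path)
  lines <- readLines(path)
  expect_equal(lines[1], "##gff-version 3")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(o))
  fields <- strsplit(body, "\t")
  expect_true(all(vapply(fields, `[`, "", 2) == "mge-compare:orf"))
  expect_equal(as.integer(vapply(fields, `[`, "", 4)), o$start + 1L)
  expect_equal(as.integer(vapply(fields, `[`, "", 5)), o$end)
})
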