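test_that("cumulative skew profile: closure, hand-computed walk, rotation", {
  # zero signal
  p0 <- cumulative_skew(circular_seq("a", strrep("A", 50)))
  expect_true(all(p0$values == 0))
  # GGGGCCCC: centred walk climbs 4 then returns; closure at the end
  p <- cumulative_skew(circular_seq("g", "GGGGCCCC"), window = 1L)
  expect_equal(p$values, c(1, 2, 3, 4, 3, 2, 1, 0))
  expect_equal(which.max(p$values), 4L)
  expect_lt(abs(p$values[8]), 1e-9)
  # closure holds for any composition once centred
  set.seed(41)
  for (i in 1:5) {
    s <- circular_seq("r", random_dna(500, gc = runif(1, 0.3, 0.7)))
    v <- cumulative_skew(s)$values
    expect_lt(abs(v[length(v)]), 1e-9)
  }
  # rotation by k shifts the argmin by exactly k (mod length)
  s <- circular_seq("r", random_dna(300, gc = 0.6))
  base <- cumulative_skew(s)$values
  for (k in c(7, 123)) {
    rot <- cumulative_skew(rotate_seq(s, k))$values
    expect_equal((which.min(base) - 1 - k) %% 300, (which.min(rot) - 1) %% 300)
  }
})

test_that("planted direct and inverted repeats are found at their positions", {
  set.seed(51)
  unit <- "ACGTACGTACGT"
  base <- random_dna(200, gc = 0.5)
  chars <- strsplit(base, "")[[1]]
  chars[21:32] <- strsplit(unit, "")[[1]]
  chars[151:162] <- strsplit(unit, "")[[1]]
  s <- circular_seq("r", paste(chars, collapse = ""))
  reps <- find_repeats(s, min_len = 12L)
  hit <- reps[reps$kind == "direct" & reps$pos1 <= 20 & reps$pos2 >= 150, ]
  expect_gte(nrow(hit), 1L)
  expect_gte(max(hit$rep_len), 12L)

  chars2 <- strsplit(random_dna(200), "")[[1]]
  seg <- "GATCCATGGTACGA"
  chars2[31:44] <- strsplit(seg, "")[[1]]
  chars2[121:134] <- strsplit(orc_revcomp(seg), "")[[1]]
  s2 <- circular_seq("r2", paste(chars2, collapse = ""))
  reps2 <- find_repeats(s2, min_len = 12L)
  expect_true(any(reps2$kind == "inverted" & reps2$rep_len >= 14))
})

test_that("repeat detection equals the all-pairs oracle on short circles", {
  set.seed(61)
  for (i in 1:6) {
    # low-complexity-ish alphabet so repeats actually occur at 250 bp
    s <- circular_seq("r", paste(sample(c("A", "C", "G", "T"), 250,
                                        replace = TRUE,
                                        prob = c(.4, .1, .1, .4)),
                                 collapse = ""))
    got <- find_repeats(s, min_len = 8L, max_pairs = 10000L)
    want <- orc_repeats(s, min_len = 8L)
    gk <- sort(paste(got$kind, got$pos1, got$pos2, got$rep_len))
    wk <- sort(paste(want$kind, want$pos1, want$pos2, want$rep_len))
    expect_equal(gk, wk, info = paste("seq", i))
  }
})

test_that("intergenic regions are the wrap-aware complement of ORFs", {
  s <- circular_seq("r", strrep("A", 1000))
  orf1 <- data.frame(seq_id = "r", start = 0L, end = 300L, strand = "+")
  regs <- intergenic_regions(s, orf1, min_len = 150L)
  expect_equal(nrow(regs), 1L)
  expect_equal(c(regs$start, regs$end), c(300L, 1000L))
  # full tiling -> nothing
  tiling <- data.frame(seq_id = "r", start = c(0L, 500L),
                       end = c(500L, 1000L), strand = "+")
  expect_equal(nrow(intergenic_regions(s, tiling, 150L)), 0L)
  # a 149 bp gap misses the 150 bp threshold
  near <- data.frame(seq_id = "r", start = c(0L, 649L), end = c(500L, 1000L),
                     strand = "+")
  expect_equal(nrow(intergenic_regions(s, near, 150L)), 0L)
  expect_equal(nrow(intergenic_regions(s, near, 149L)), 1L)
  # a gap spanning the origin is reported as one region with end > length
  wrap <- data.frame(seq_id = "r", start = 200L, end = 800L, strand = "+")
  regs2 <- intergenic_regions(s, wrap, 150L)
  expect_equal(nrow(regs2), 1L)
  expect_equal(c(regs2$start, regs2$end), c(800L, 1200L))
})

test_that("ori prediction ranks regions by skew-minimum support", {
  # construct a circle that is C-rich then G-rich switching at 500:
  # the centred cumulative skew has its minimum near position 500
  set.seed(71)
  half1 <- paste(sample(c("C", "A", "T"), 500, TRUE, c(.5, .25, .25)),
                 collapse = "")
  half2 <- paste(sample(c("G", "A", "T"), 500, TRUE, c(.5, .25, .25)),
                 collapse = "")
  s <- circular_seq("r", paste0(half1, half2))
  prof <- cumulative_skew(s, window = 51L)
  regions <- data.frame(start = c(450L, 100L), end = c(550L, 200L))
  regions$length <- regions$end - regions$start
  ori <- predict_ori(s, prof, regions)
  expect_equal(nrow(ori), 2L)
  expect_equal(ori$start[ori$rank == 1], 450L)
  expect_equal(ori$dist_to_min[ori$rank == 1], 0L)
  expect_true(all(ori$repeat_support == 0L))  # no repeats supplied
})

test_that("two valleys in two intergenic regions are both reported", {
  # C-rich / G-rich / C-rich / G-rich: two skew minima on the circle
  set.seed(81)
  blk <- function(b, n) paste(sample(c(b, "A", "T"), n, TRUE,
                                     c(.6, .2, .2)), collapse = "")
  s <- circular_seq("r", paste0(blk("C", 250), blk("G", 250),
                                blk("C", 250), blk("G", 250)))
  prof <- cumulative_skew(s, window = 51L)
  regions <- data.frame(start = c(200L, 700L), end = c(300L, 800L))
  regions$length <- 100L
  ori <- predict_ori(s, prof, regions)
  expect_equal(nrow(ori), 2L)
  expect_equal(sort(ori$dist_to_min), c(0L, 0L))
  expect_setequal(ori$rank, 1:2)
})

test_that("degenerate skew inputs are handled explicitly", {
  s <- circular_seq("r", strrep("AT", 300))
  prof <- cumulative_skew(s)
  regions <- data.frame(start = 0L, end = 200L, length = 200L)
  expect_warning(ori <- predict_ori(s, prof, regions), "flat")
  expect_equal(nrow(ori), 0L)
  expect_error(predict_ori(s, prof, regions[0, ]), "no intergenic")
})

test_that("repeat support contributes to ranking and BED output round-trips", {
  set.seed(91)
  chars <- strsplit(random_dna(600), "")[[1]]
  unit <- strsplit("TTGACCGGTCAAGG", "")[[1]]
  chars[101:114] <- unit
  chars[131:144] <- unit
  s <- circular_seq("r", paste(chars, collapse = ""))
  reps <- find_repeats(s, min_len = 12L)
  prof <- cumulative_skew(s, window = 51L)
  regions <- data.frame(start = c(90L, 400L), end = c(160L, 470L),
                        length = 70L)
  ori <- predict_ori(s, prof, regions, reps)
  expect_gte(ori$repeat_support[ori$start == 90], 1L)
  expect_equal(ori$repeat_support[ori$start == 400], 0L)
  path <- withr::local_tempfile(fileext = ".bed")
  write_ori_bed(ori, s, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(nrow(bed), nrow(ori))
  expect_true(all(bed$V5 == ori$rank))
})
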