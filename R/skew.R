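# cumulative GC skew, repeat detection, and replication-origin prediction

#' Cumulative GC skew profile of a circular sequence
#'
#' Per-position increments are +1 for G, -1 for C and 0 otherwise. The
#' mean increment is subtracted before cumulation, so the circular walk
#' closes (ends at 0) and its extrema are rotation-equivariant; the raw
#' (uncentered) cumulative skew of plotting convention is available with
#' `center = FALSE`. An optional circular moving average of width
#' `window` smooths the profile.
#'
#' @param seq a [circular_seq()].
#' @param window moving-average width in bp (1 = no smoothing).
#' @param center subtract the mean increment before cumulation.
#' @return list of class `skew_profile` with fields `seq_id`, `values`
#'   (length = sequence length), `window`, `center`.
#' @export
cumulative_skew <- function(seq, window = 1L, center = TRUE) {
  stopifnot(inherits(seq, "circular_seq"), window >= 1L,
            seq$length > window)
  chars <- chars_of(seq$residues)
  incr <- (chars == "G") - (chars == "C")
  if (center) incr <- incr - mean(incr)
  values <- cumsum(incr)
  if (window > 1L) {
    # circular moving average
    n <- length(values)
    k <- rep(1 / window, window)
    padded <- c(tail(values, window), values, head(values, window))
    sm <- as.numeric(stats::filter(padded, k, sides = 2))
    values <- sm[window + seq_len(n)]
  }
  structure(list(seq_id = seq$id, values = values, window = as.integer(window),
                 center = center),
            class = "skew_profile")
}

#' Find maximal exact repeats on a circular sequence
#'
#' Reports direct repeats (a substring occurring at two places) and
#' inverted repeats (a substring whose reverse complement occurs
#' elsewhere), wrap-aware, as position pairs extended to maximal length.
#' Repeat "significance" is ranked by length: output is sorted by
#' `rep_len` descending and truncated to `max_pairs`.
#'
#' @param seq a [circular_seq()].
#' @param min_len minimum repeat length (>= 8; default 12).
#' @param max_pairs maximum number of pairs returned.
#' @return data frame with columns `kind` (`direct`/`inverted`), `pos1`,
#'   `pos2` (0-based starts of the two copies, `pos1 < pos2`), `rep_len`,
#'   `seq` (the repeat unit, first copy).
#' @export
find_repeats <- function(seq, min_len = 12L, max_pairs = 100L) {
  stopifnot(inherits(seq, "circular_seq"), min_len >= 8L)
  L <- seq$length
  k <- as.integer(min_len)
  if (L < k) return(empty_repeats())
  chars <- chars_of(seq$residues)
  ext <- if (seq$circular) c(chars, chars[seq_len(min(k - 1L, L))]) else chars
  sext <- paste(ext, collapse = "")
  npos <- if (seq$circular) L else L - k + 1L
  if (npos < 2L) return(empty_repeats())
  kmers <- substring(sext, 1:npos, (1:npos) + k - 1L)
  starts0 <- 0:(npos - 1L)

  at <- function(i) chars[(i %% L) + 1L]  # circular base access

  hits <- list()
  add_hit <- function(kind, a, b, len) {
    key <- paste(kind, a, b, len)
    if (!is.null(hits[[key]])) return(invisible())
    unit <- paste(at(a:(a + len - 1L)), collapse = "")
    hits[[key]] <<- data.frame(kind = kind, pos1 = a, pos2 = b,
                               rep_len = len, seq = unit,
                               stringsAsFactors = FALSE)
  }

  # direct repeats: extend each duplicated k-mer pair to maximality
  dup <- split(starts0, kmers)
  dup <- dup[lengths(dup) >= 2L]
  for (grp in dup) {
    prs <- utils::combn(grp, 2L)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      # extend left
      la <- a; lb <- b; len <- k
      while (len < L && at(la - 1L) == at(lb - 1L) &&
             (seq$circular || (la > 0L && lb > 0L))) {
        la <- la - 1L; lb <- lb - 1L; len <- len + 1L
      }
      # extend right
      while (len < L && at(la + len) == at(lb + len) &&
             (seq$circular || (lb + len < L))) {
        len <- len + 1L
      }
      a2 <- ((la %% L)); b2 <- ((lb %% L))
      lo <- min(a2, b2); hi <- max(a2, b2)
      if (lo != hi) add_hit("direct", lo, hi, len)
    }
  }

  # inverted repeats: k-mer whose reverse complement occurs elsewhere
  rc_kmers <- vapply(kmers, revcomp, "", USE.NAMES = FALSE)
  pos_by_kmer <- split(starts0, kmers)
  for (i in seq_len(npos)) {
    partners <- pos_by_kmer[[rc_kmers[i]]]
    if (is.null(partners)) next
    a0 <- starts0[i]
    for (b0 in partners) {
      if (b0 <= a0) next  # canonical orientation once
      a <- a0; b <- b0; len <- k
      # left of copy 1 pairs with right of copy 2
      while (len < L && at(a - 1L) == COMPLEMENT[[at(b + len)]] &&
             (seq$circular || a > 0L)) {
        a <- a - 1L; len <- len + 1L
      }
      while (len < L && at(b - 1L) == COMPLEMENT[[at(a + len)]] &&
             (seq$circular || b > 0L)) {
        b <- b - 1L; len <- len + 1L
      }
      a2 <- a %% L; b2 <- b %% L
      lo <- min(a2, b2); hi <- max(a2, b2)
      if (lo != hi) add_hit("inverted", lo, hi, len)
    }
  }

  if (!length(hits)) return(empty_repeats())
  out <- do.call(rbind, unname(hits))
  out <- out[order(-out$rep_len, out$pos1, out$pos2, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, max_pairs)
}

empty_repeats <- function() {
  data.frame(kind = character(), pos1 = integer(), pos2 = integer(),
             rep_len = integer(), seq = character(), stringsAsFactors = FALSE)
}

#' Intergenic regions of a replicon
#'
#' Complement of the union of ORF intervals on the circle, keeping gaps of
#' at least `min_len` bp.
#'
#' @param seq a [circular_seq()].
#' @param orfs data frame with `start`, `end` columns (e.g. [find_orfs()]).
#' @param min_len minimum region length in bp.
#' @return data frame with 0-based half-open `start`, `end` (wrap-aware)
#'   and `length`.
#' @export
intergenic_regions <- function(seq, orfs, min_len = 150L) {
  stopifnot(inherits(seq, "circular_seq"))
  L <- seq$length
  covered <- logical(L)
  if (nrow(orfs)) {
    if (any(orfs$seq_id != seq$id))
      stop("ORFs do not belong to sequence '", seq$id, "'")
    for (i in seq_len(nrow(orfs)))
      covered[circ_positions(orfs$start[i], orfs$end[i], L)] <- TRUE
  }
  free <- which(!covered) - 1L   # 0-based free positions
  if (!length(free)) {
    return(data.frame(start = integer(), end = integer(),
                      length = integer()))
  }
  if (all(!covered)) {
    regions <- data.frame(start = 0L, end = L)
  } else {
    # runs of free positions, circularly
    brk <- which(diff(free) > 1L)
    starts <- free[c(1L, brk + 1L)]
    ends <- free[c(brk, length(free))] + 1L
    regions <- data.frame(start = starts, end = ends)
    if (seq$circular && nrow(regions) > 1L &&
        regions$start[1] == 0L && regions$end[nrow(regions)] == L) {
      # merge the run spanning the origin
      regions$end[nrow(regions)] <- L + regions$end[1]
      regions <- regions[-1L, , drop = FALSE]
    }
  }
  regions$length <- regions$end - regions$start
  regions <- regions[regions$length >= min_len, , drop = FALSE]
  rownames(regions) <- NULL
  regions
}

# circular local minima of a profile with at least `prominence` depth:
# a minimum's prominence is the smaller of the two barriers that must be
# climbed before reaching a lower value (or completing the circle)
skew_minima <- function(values, prominence) {
  n <- length(values)
  v2 <- c(values, values)
  # candidate local minima (strict against plateau ends)
  cand <- integer(0)
  left <- c(values[n], values[-n])
  right <- c(values[-1], values[1])
  cand <- which(values <= left & values <= right &
                (values < left | values < right)) - 1L
  if (!length(cand)) return(list(pos = integer(0), prom = numeric(0)))
  keep <- logical(length(cand))
  prom <- numeric(length(cand))
  for (i in seq_along(cand)) {
    m <- cand[i] + 1L
    vm <- values[m]
    # climb right
    barrier_r <- 0
    j <- m
    for (step in seq_len(n - 1L)) {
      j <- (m + step - 1L) %% n + 1L
      if (values[j] < vm) break
      barrier_r <- max(barrier_r, values[j] - vm)
    }
    barrier_l <- 0
    for (step in seq_len(n - 1L)) {
      j <- (m - step - 1L) %% n + 1L
      if (values[j] < vm) break
      barrier_l <- max(barrier_l, values[j] - vm)
    }
    prom[i] <- min(barrier_l, barrier_r)
    keep[i] <- prom[i] >= prominence
  }
  # global minimum always qualifies (its prominence is the full range)
  gm <- which.min(values) - 1L
  if (!(gm %in% cand[keep])) {
    keep[cand == gm] <- TRUE
    if (!(gm %in% cand)) {
      cand <- c(cand, gm)
      prom <- c(prom, diff(range(values)))
      keep <- c(keep, TRUE)
    }
  }
  list(pos = cand[keep], prom = prom[keep])
}

#' Predict candidate replication-origin regions
#'
#' Candidate minima of the (smoothed, centred) cumulative GC-skew profile
#' are matched to large intergenic regions; each region is scored by its
#' circular distance to the nearest candidate minimum (0 if the minimum
#' falls inside) with repeat support breaking ties. All qualifying regions
#' are returned, ranked — multi-valley profiles legitimately yield several
#' candidate origins and are never auto-resolved to one.
#'
#' @param seq a [circular_seq()].
#' @param profile a [cumulative_skew()] result.
#' @param regions intergenic regions from [intergenic_regions()].
#' @param repeats repeat table from [find_repeats()] (may be empty).
#' @param prominence_frac minimum depth of a qualifying skew minimum as a
#'   fraction of the profile range.
#' @return data frame ranked by `rank` (1 = best) with columns `start`,
#'   `end`, `skew_min_pos`, `dist_to_min`, `repeat_support`, `rank`.
#' @export
predict_ori <- function(seq, profile, regions, repeats = empty_repeats(),
                        prominence_frac = 0.1) {
  stopifnot(inherits(seq, "circular_seq"), inherits(profile, "skew_profile"))
  if (!nrow(regions))
    stop("no intergenic region >= min_len on '", seq$id, "'")
  L <- seq$length
  vals <- profile$values
  rng <- diff(range(vals))
  if (rng < .Machine$double.eps^0.5) {
    warning("flat skew profile on '", seq$id, "': no minima")
    return(data.frame(start = integer(), end = integer(),
                      skew_min_pos = integer(), dist_to_min = integer(),
                      repeat_support = integer(), rank = integer()))
  }
  mins <- skew_minima(vals, prominence_frac * rng)
  if (!length(mins$pos)) {
    warning("no qualifying skew minimum on '", seq$id, "'")
    return(data.frame(start = integer(), end = integer(),
                      skew_min_pos = integer(), dist_to_min = integer(),
                      repeat_support = integer(), rank = integer()))
  }
  n <- nrow(regions)
  skew_min_pos <- integer(n); dist_to_min <- integer(n)
  repeat_support <- integer(n)
  for (i in seq_len(n)) {
    d <- vapply(mins$pos, function(m)
      circ_point_to_interval(m, regions$start[i], regions$end[i], L), 0L)
    best <- which.min(d)
    skew_min_pos[i] <- mins$pos[best]
    dist_to_min[i] <- d[best]
    if (nrow(repeats)) {
      inside <- vapply(seq_len(nrow(repeats)), function(j) {
        r <- repeats[j, ]
        in1 <- circ_point_to_interval(r$pos1, regions$start[i],
                                      regions$end[i], L) == 0L &&
          circ_point_to_interval((r$pos1 + r$rep_len - 1L) %% L,
                                 regions$start[i], regions$end[i], L) == 0L
        in2 <- circ_point_to_interval(r$pos2, regions$start[i],
                                      regions$end[i], L) == 0L &&
          circ_point_to_interval((r$pos2 + r$rep_len - 1L) %% L,
                                 regions$start[i], regions$end[i], L) == 0L
        in1 && in2
      }, logical(1))
      repeat_support[i] <- sum(inside)
    }
  }
  out <- data.frame(start = regions$start, end = regions$end,
                    skew_min_pos = skew_min_pos, dist_to_min = dist_to_min,
                    repeat_support = repeat_support)
  ord <- order(out$dist_to_min, -out$repeat_support, out$start)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write origin candidates as BED
#'
#' 0-based half-open BED with the rank in the score column; wrap-around
#' regions are split at the origin into two BED lines sharing a name.
#'
#' @param ori result of [predict_ori()].
#' @param seq the [circular_seq()] the predictions belong to.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ori_bed <- function(ori, seq, path) {
  L <- seq$length
  lines <- character(0)
  for (i in seq_len(nrow(ori))) {
    nm <- sprintf("ori_candidate_%d", ori$rank[i])
    s <- ori$start[i]; e <- ori$end[i]
    if (e <= L) {
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t%d\t.", seq$id, s, e, nm,
                                ori$rank[i]))
    } else {
      lines <- c(lines,
                 sprintf("%s\t%d\t%d\t%s\t%d\t.", seq$id, s, L, nm, ori$rank[i]),
                 sprintf("%s\t%d\t%d\t%s\t%d\t.", seq$id, 0L, e - L, nm,
                         ori$rank[i]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Plot a skew profile with predicted origin candidates
#'
#' @param profile a [cumulative_skew()] result.
#' @param ori optional [predict_ori()] result to mark.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plot_skew <- function(profile, ori = NULL, ...) {
  graphics::plot(seq_along(profile$values) - 1L, profile$values, type = "l",
                 xlab = "position (bp)", ylab = "cumulative GC skew",
                 main = profile$seq_id, ...)
  if (!is.null(ori) && nrow(ori)) {
    graphics::abline(v = ori$skew_min_pos, lty = 2, col = "red")
    graphics::rug(ori$start, col = "blue")
  }
  invisible(NULL)
}
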