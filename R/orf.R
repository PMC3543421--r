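# ORF prediction on circular DNA with Shine-Dalgarno start adjustment

#' ORF prediction parameters
#'
#' Defaults follow the standard criteria for small archaeal replicons:
#' minimum length 39 codons, starts ATG/GTG/TTG, stops TAA/TAG/TGA, and a
#' Shine-Dalgarno (SD) consensus AGGAGG scanned 4-20 bp upstream of each
#' candidate start. `min_codons` counts the start codon through the last
#' sense codon; the stop codon is excluded.
#'
#' @param min_codons minimum ORF length in codons (stop excluded).
#' @param start_codons,stop_codons character vectors of codons.
#' @param sd_consensus SD consensus string.
#' @param sd_window integer pair: offsets (bp upstream of the start codon)
#'   searched for an SD match, nearest and farthest.
#' @param sd_min_match minimum contiguous match length for SD evidence to
#'   drive start selection.
#' @return a list of class `orf_params`.
#' @export
orf_params <- function(min_codons = 39L,
                       start_codons = c("ATG", "GTG", "TTG"),
                       stop_codons = c("TAA", "TAG", "TGA"),
                       sd_consensus = "AGGAGG",
                       sd_window = c(4L, 20L),
                       sd_min_match = 4L) {
  stopifnot(min_codons >= 1L, length(sd_window) == 2L,
            sd_window[1] < sd_window[2], sd_min_match >= 1L)
  structure(list(min_codons = as.integer(min_codons),
                 start_codons = toupper(start_codons),
                 stop_codons = toupper(stop_codons),
                 sd_consensus = toupper(sd_consensus),
                 sd_window = as.integer(sd_window),
                 sd_min_match = as.integer(sd_min_match)),
            class = "orf_params")
}

#' Translate a DNA string
#'
#' Standard-code codon translation (the amino-acid assignments of the
#' bacterial/archaeal translation table). When `as_start` is `TRUE` the
#' first codon is rendered as M regardless of ATG/GTG/TTG, matching the
#' initiator-tRNA convention for alternative starts.
#'
#' @param dna DNA string, length a multiple of 3, not containing an
#'   internal stop codon.
#' @param as_start logical; treat the first codon as an initiator.
#' @return amino-acid string.
#' @export
translate_dna <- function(dna, as_start = FALSE) {
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n == 0L || n %% 3L != 0L)
    stop("DNA length ", n, " is not a positive multiple of 3")
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  if (any(aa == "*"))
    stop("internal stop codon at codon ", which(aa == "*")[1])
  if (as_start) aa[1] <- "M"
  paste(aa, collapse = "")
}

# occurrence index of every distinct substring of the SD consensus in a
# string: list E[[k]] = sorted 0-based end positions of any length-k
# consensus substring
sd_occurrence_index <- function(s, consensus) {
  kmax <- nchar(consensus)
  E <- vector("list", kmax)
  for (k in seq_len(kmax)) {
    subs <- unique(substring(consensus, 1:(kmax - k + 1L), k:kmax))
    ends <- integer(0)
    for (u in subs) {
      # lookahead so that overlapping occurrences are all reported
      hits <- gregexpr(paste0("(?=", u, ")"), s, perl = TRUE)[[1]]
      if (hits[1] != -1L)
        ends <- c(ends, as.integer(hits) - 1L + k - 1L)
    }
    E[[k]] <- sort(unique(ends))
  }
  E
}

# SD score for a candidate start at 0-based position c of string s (coding
# strand), using a precomputed occurrence index; lo_off/hi_off are the
# window offsets. Returns c(score, offset) with offset NA when score is 0.
sd_score_at <- function(E, c, lo_off, hi_off) {
  for (k in rev(seq_along(E))) {
    ends <- E[[k]]
    if (!length(ends)) next
    # match must lie fully inside the window: start >= c - hi - 1 + ... a
    # base at offset d sits at position c - d - 1, so the window occupies
    # positions [c - hi - 1, c - lo - 1] and a length-k match needs
    # end in [c - hi - 1 + k - 1, c - lo - 1]
    lo_end <- c - hi_off - 1L + k - 1L
    hi_end <- c - lo_off - 1L
    if (hi_end < 0L) next
    i <- findInterval(hi_end, ends)
    if (i >= 1L && ends[i] >= lo_end)
      return(c(k, c - ends[i] - 1L))  # nearest-to-start match wins ties
  }
  c(0L, NA_integer_)
}

#' Score the Shine-Dalgarno context of a start position
#'
#' Reports the longest contiguous exact match between the SD consensus and
#' the window `sd_window` bp upstream of the start codon on the coding
#' strand, and the offset (bp between the match 3' end and the start
#' codon) of the best match; among equally long matches the one nearest
#' the start wins.
#'
#' @param seq a [circular_seq()].
#' @param start 0-based position of the start codon (forward strand for
#'   `"+"`; for `"-"` the position of the start codon on the coding strand
#'   of the reverse complement).
#' @param strand `"+"` or `"-"`.
#' @param params an [orf_params()].
#' @return list with integer `score` (0..nchar(consensus)) and `offset`
#'   (NA when score is 0).
#' @export
score_sd <- function(seq, start, strand = "+", params = orf_params()) {
  stopifnot(inherits(seq, "circular_seq"), strand %in% c("+", "-"))
  s <- if (strand == "+") seq$residues else revcomp(seq$residues)
  hi <- params$sd_window[2]
  if (seq$circular) {
    # prepend one wrap of upstream context
    pad <- hi + 1L
    reps <- ceiling(pad / seq$length)
    s <- paste0(strrep(s, reps), s)
    start <- start + reps * seq$length
  }
  E <- sd_occurrence_index(s, params$sd_consensus)
  v <- sd_score_at(E, as.integer(start), params$sd_window[1], hi)
  list(score = as.integer(v[1]), offset = if (v[1] == 0L) NA_integer_ else
    as.integer(v[2]))
}

#' Choose the reported start among in-frame candidates sharing a stop
#'
#' Automates manual SD-based start curation: if any candidate has an SD
#' score at or above `sd_min_match`, the candidate maximising (SD score,
#' then ORF length) is chosen; otherwise the most upstream candidate
#' (longest ORF). Ties break to the smaller start coordinate.
#'
#' @param candidates integer vector of candidate start positions (same
#'   frame, same stop; smaller = more upstream = longer ORF).
#' @param sd_scores integer vector of SD scores, parallel to `candidates`.
#' @param params an [orf_params()].
#' @return the chosen start position.
#' @export
choose_start <- function(candidates, sd_scores, params = orf_params()) {
  if (!length(candidates)) stop("empty candidate list")
  stopifnot(length(sd_scores) == length(candidates))
  if (max(sd_scores) >= params$sd_min_match) {
    keep <- order(-sd_scores, candidates)
    candidates[keep[1]]
  } else {
    min(candidates)
  }
}

# scan one coding strand of a sequence; returns a data frame of ORFs in
# coding-strand coordinates (columns cstart, cstop = stop codon position)
scan_strand <- function(s, L, circular, params) {
  if (circular) {
    pad <- params$sd_window[2] + 4L
    k <- max(2L, ceiling(pad / L) + 1L)   # copies before the scan window
    sx <- paste0(strrep(s, k + 1L), substr(s, 1L, pad))
    from <- k * L                          # scan stops in [from, from + L)
  } else {
    sx <- s
    from <- 0L
  }
  n <- nchar(sx)
  npos <- n - 2L
  if (npos < 1L) return(NULL)
  codons <- substring(sx, 1:npos, 3:n)
  is_stop  <- codons %in% params$stop_codons
  is_start <- codons %in% params$start_codons
  has_n    <- grepl("N", codons, fixed = TRUE)
  E <- sd_occurrence_index(sx, params$sd_consensus)

  # per linear frame: sorted boundary (stop or N codon) and start positions
  pos0 <- 0:(npos - 1L)
  res <- list()
  stop_pos <- pos0[is_stop]
  upper <- if (circular) from + L - 1L else npos - 1L
  stops_here <- stop_pos[stop_pos >= from & stop_pos <= upper]
  if (!length(stops_here)) return(NULL)
  bound_by_frame <- split(pos0[is_stop | has_n], pos0[is_stop | has_n] %% 3L)
  start_by_frame <- split(pos0[is_start], pos0[is_start] %% 3L)

  lo_off <- params$sd_window[1]; hi_off <- params$sd_window[2]
  for (p in stops_here) {
    f <- as.character(p %% 3L)
    bnd <- bound_by_frame[[f]]
    i <- if (is.null(bnd)) 0L else findInterval(p - 1L, bnd)
    lo <- if (i >= 1L) bnd[i] + 3L else 0L
    # cap so that the ORF (incl. stop) never exceeds the circle
    if (circular) lo <- max(lo, p + 3L - L)
    hi_c <- p - 3L * params$min_codons
    if (hi_c < lo) next
    sf <- start_by_frame[[f]]
    if (is.null(sf)) next
    j1 <- findInterval(lo - 1L, sf) + 1L
    j2 <- findInterval(hi_c, sf)
    if (j2 < j1) next
    cand <- sf[j1:j2]
    sd <- vapply(cand, function(cc) sd_score_at(E, cc, lo_off, hi_off),
                 numeric(2))
    chosen <- choose_start(cand, sd[1, ], params)
    ci <- match(chosen, cand)
    res[[length(res) + 1L]] <- list(
      cstart = chosen, cstop = p,
      sd_score = as.integer(sd[1, ci]), sd_offset = as.integer(sd[2, ci]),
      cand = cand, cand_sd = as.integer(sd[1, ]))
  }
  if (!length(res)) return(NULL)
  list(orfs = res, sx = sx)
}

#' Predict ORFs on a replicon
#'
#' Scans all six reading frames; on circular sequences the scan covers
#' origin-spanning ORFs, and every distinct (stop codon, strand) yields at
#' most one ORF whose start is SD-adjusted via [choose_start()]. Codons
#' containing N terminate scanning (no ORF is called through an N).
#' Overlapping and nested ORFs are all reported; no ORF exceeds the
#' sequence length. A reading frame of a circular sequence with no stop
#' codon at all is reported as a warning, not an ORF.
#'
#' @param seq a [circular_seq()].
#' @param params an [orf_params()].
#' @param proteins include translated proteins in the result (setting
#'   `FALSE` skips translation, for coordinate-only scans).
#' @return data frame sorted by `start` with columns `orf_id`, `seq_id`,
#'   `start`, `end` (0-based half-open, forward-strand frame of reference,
#'   wrap encoded as `end > length`), `strand`, `start_codon`, `n_codons`,
#'   `sd_score`, `sd_offset`, `protein`. The full candidate-start table is
#'   attached as `attr(, "candidates")` for curation.
#' @export
find_orfs <- function(seq, params = orf_params(), proteins = TRUE) {
  stopifnot(inherits(seq, "circular_seq"))
  L <- seq$length
  if (L < 3L) stop("sequence shorter than one codon")
  parts <- list()
  cands <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq$residues else revcomp(seq$residues)
    sc <- scan_strand(s, L, seq$circular, params)
    if (seq$circular) check_stopfree_frames(s, L, params, seq$id, strand)
    if (is.null(sc)) next
    cstart <- vapply(sc$orfs, `[[`, 0L, "cstart")
    cstop <- vapply(sc$orfs, `[[`, 0L, "cstop")
    len <- cstop + 3L - cstart
    st <- if (strand == "+") cstart %% L else (L - ((cstop + 3L) %% L)) %% L
    prot <- if (proteins)
      vapply(seq_along(cstart), function(i)
        translate_dna(substr(sc$sx, cstart[i] + 1L, cstop[i]),
                      as_start = TRUE), "")
    else rep(NA_character_, length(cstart))
    sd_score <- vapply(sc$orfs, `[[`, 0L, "sd_score")
    sd_offset <- vapply(sc$orfs, `[[`, 0L, "sd_offset")
    parts[[strand]] <- data.frame(
      seq_id = seq$id, start = st, end = st + len, strand = strand,
      start_codon = substring(sc$sx, cstart + 1L, cstart + 3L),
      n_codons = (cstop - cstart) %/% 3L,
      sd_score = sd_score,
      sd_offset = ifelse(sd_score > 0L, sd_offset, NA_integer_),
      protein = prot, stringsAsFactors = FALSE)
    cands[[strand]] <- data.frame(
      seq_id = seq$id, strand = strand,
      stop_coding_pos = rep(cstop %% L, lengths(lapply(sc$orfs, `[[`, "cand"))),
      cand_coding_start = unlist(lapply(sc$orfs, `[[`, "cand")) %% L,
      sd_score = unlist(lapply(sc$orfs, `[[`, "cand_sd")),
      stringsAsFactors = FALSE)
  }
  if (!length(parts)) {
    out <- data.frame(orf_id = character(), seq_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), start_codon = character(),
                      n_codons = integer(), sd_score = integer(),
                      sd_offset = integer(), protein = character(),
                      stringsAsFactors = FALSE)
    attr(out, "candidates") <- NULL
    return(out)
  }
  out <- do.call(rbind, parts)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  # gene numbering clockwise from coordinate 0
  out <- cbind(orf_id = paste0(seq$id, "_gp", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  attr(out, "candidates") <- do.call(rbind, unname(cands))
  out
}

# warn about circular reading frames with no stop codon
check_stopfree_frames <- function(s, L, params, id, strand) {
  s2 <- paste0(s, substr(s, 1L, 2L))
  codons <- substring(s2, 1:L, 3:(L + 2L))
  stops <- which(codons %in% params$stop_codons) - 1L
  if (L %% 3L == 0L) {
    for (r in 0:2)
      if (!any(stops %% 3L == r))
        warning("stop-free frame (offset ", r, ", strand ", strand,
                ") on circular sequence '", id, "'")
  } else if (!length(stops)) {
    warning("stop-free circular reading on sequence '", id,
            "', strand ", strand)
  }
  invisible(NULL)
}

#' Extract predicted proteins as a named vector
#'
#' @param orfs result of [find_orfs()] (one or more replicons' tables
#'   row-bound together).
#' @return named character vector of proteins; names are the `orf_id`s
#'   (`<seq_id>_gp<n>`, numbered clockwise from coordinate 0).
#' @export
orf_proteins <- function(orfs) {
  setNames(orfs$protein, orfs$orf_id)
}

#' Write ORF calls as GFF3
#'
#' Emission converts to 1-based inclusive coordinates; ORFs spanning the
#' origin of a circular sequence keep `end > length`, the GFF3 convention
#' for features crossing the origin of a circular landmark.
#'
#' @param orfs result of [find_orfs()].
#' @param seqs list of [circular_seq()] (for `##sequence-region` lines).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_orf_gff3 <- function(orfs, seqs, path) {
  if (inherits(seqs, "circular_seq")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (s in seqs)
    writeLines(sprintf("##sequence-region %s 1 %d", s$id, s$length), con)
  if (nrow(orfs)) {
    attrs <- sprintf("ID=%s;sd_score=%d%s", orfs$orf_id, orfs$sd_score,
                     ifelse(is.na(orfs$sd_offset), "",
                            sprintf(";sd_offset=%d", orfs$sd_offset)))
    lines <- sprintf("%s\tmge-compare:orf\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                     orfs$seq_id, orfs$start + 1L, orfs$end, orfs$strand,
                     attrs)
    writeLines(lines, con)
  }
  invisible(path)
}
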