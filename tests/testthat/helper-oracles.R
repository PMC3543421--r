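# Independent reference implementations used as oracles. These are
# deliberately naive and share no code with the package internals.

orc_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

orc_char <- function(s, i0) substr(s, (i0 %% nchar(s)) + 1L,
                                   (i0 %% nchar(s)) + 1L)

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

random_peptide <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"),
               n, replace = TRUE), collapse = "")
}

# --- ORF oracle -------------------------------------------------------
# For every circular stop codon (both strands), rotate the sequence so
# that the stop ends at the last linear position, scan that single frame
# backwards for the segment and its candidate starts, and apply the
# documented start-selection rule with a naive SD scorer.

orc_sd_score <- function(lin, cpos0, lo, hi, cons, min_len = 1L) {
  L <- nchar(lin)
  w <- paste(vapply(hi:lo, function(d) orc_char(lin, cpos0 - d - 1L), ""),
             collapse = "")
  best_len <- 0L; best_off <- NA_integer_
  nc <- nchar(cons)
  for (len in nc:1) {
    for (a in 1:(nc - len + 1L)) {
      sub <- substr(cons, a, a + len - 1L)
      for (i in 1:(nchar(w) - len + 1L)) {
        if (substr(w, i, i + len - 1L) == sub) {
          off <- hi - (i + len - 1L) + 1L
          if (len > best_len || (len == best_len && off < best_off)) {
            best_len <- len; best_off <- off
          }
        }
      }
    }
    if (best_len == len) break
  }
  if (best_len == 0L) list(score = 0L, offset = NA_integer_)
  else list(score = best_len, offset = best_off)
}

orc_orfs <- function(seq, params = orf_params()) {
  L <- seq$length
  stopifnot(seq$circular)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq$residues else orc_revcomp(seq$residues)
    for (p0 in 0:(L - 1L)) {
      stop_cod <- paste0(orc_char(s, p0), orc_char(s, p0 + 1L),
                         orc_char(s, p0 + 2L))
      if (!(stop_cod %in% params$stop_codons)) next
      # rotate so the stop codon occupies the last three characters
      o <- (p0 + 3L) %% L
      lin <- paste0(substr(s, o + 1L, L), substr(s, 1L, o))
      # walk the frame backwards from the stop
      cand <- integer(0)
      j <- L - 3L - 3L   # 0-based codon start preceding the stop
      while (j >= 0L) {
        cod <- substr(lin, j + 1L, j + 3L)
        if (cod %in% params$stop_codons || grepl("N", cod)) break
        if (cod %in% params$start_codons) cand <- c(cand, j)
        j <- j - 3L
      }
      cand <- cand[(L - 3L - cand) %/% 3L >= params$min_codons]
      if (!length(cand)) next
      sds <- lapply(cand, function(cc)
        orc_sd_score(lin, cc, params$sd_window[1], params$sd_window[2],
                     params$sd_consensus))
      scores <- vapply(sds, `[[`, 0L, "score")
      if (max(scores) >= params$sd_min_match) {
        pick <- order(-scores, cand)[1]
      } else {
        pick <- which.min(cand)
      }
      cc <- cand[pick]
      len <- (L - cc)                     # ORF length incl stop, in lin
      cstart <- (cc + o) %% L             # coding-strand coordinate
      if (strand == "+") {
        fs <- cstart
      } else {
        fs <- (L - ((p0 + 3L) %% L)) %% L
      }
      prot_dna <- substr(lin, cc + 1L, L - 3L)
      rows[[length(rows) + 1L]] <- data.frame(
        start = fs, end = fs + len, strand = strand,
        n_codons = (L - 3L - cc) %/% 3L,
        sd_score = scores[pick],
        protein = orc_translate(prot_dna), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), n_codons = integer(),
                      sd_score = integer(), protein = character()))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

orc_translate <- function(dna) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(dna)
  aa <- vapply(seq(1L, n, 3L), function(i)
    unname(gc[substr(dna, i, i + 2L)]), "")
  aa[1] <- "M"
  paste(aa, collapse = "")
}

# --- Smith-Waterman oracle -------------------------------------------
# quadratic affine-gap local alignment score; gap of length g costs
# open + g * extend

orc_sw_score <- function(a, b, mat, open = 11, extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (vertical)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a (horizontal)
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      sub <- mat[av[i - 1L], bv[j - 1L]]
      M[i, j] <- max(0, M[i - 1L, j - 1L] + sub, X[i - 1L, j - 1L] + sub,
                     Y[i - 1L, j - 1L] + sub)
      X[i, j] <- max(M[i - 1L, j] - open - extend,
                     Y[i - 1L, j] - open - extend,
                     X[i - 1L, j] - extend)
      Y[i, j] <- max(M[i, j - 1L] - open - extend,
                     X[i, j - 1L] - open - extend,
                     Y[i, j - 1L] - extend)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# --- maximal repeat oracle -------------------------------------------
# all-pairs scan: every maximal (non-extendable) equal/reverse-complement
# substring pair of length >= min_len, wrap-aware

orc_repeats <- function(seq, min_len) {
  s <- seq$residues; L <- seq$length
  hits <- list()
  add <- function(kind, a, b, len) {
    lo <- min(a, b); hi <- max(a, b)
    key <- paste(kind, lo, hi, len)
    hits[[key]] <<- data.frame(kind = kind, pos1 = lo, pos2 = hi,
                               rep_len = len, stringsAsFactors = FALSE)
  }
  for (a in 0:(L - 1L)) for (b in 0:(L - 1L)) {
    if (b <= a) next
    # direct: maximal common extension with alignment offset b - a
    if (orc_char(s, a) == orc_char(s, b)) {
      # leftmost of the run containing (a, b)
      la <- a; lb <- b
      steps <- 0L
      while (steps < L && orc_char(s, la - 1L) == orc_char(s, lb - 1L)) {
        la <- la - 1L; lb <- lb - 1L; steps <- steps + 1L
      }
      len <- 1L
      while (len < L && orc_char(s, la + len) == orc_char(s, lb + len))
        len <- len + 1L
      if (len >= min_len && (la %% L) != (lb %% L))
        add("direct", la %% L, lb %% L, len)
    }
    # inverted: s[a..] vs revcomp starting at b (3' end pairing)
    if (orc_char(s, a) == chartr("ACGT", "TGCA", orc_char(s, b))) {
      la <- a; lb <- b
      steps <- 0L
      # extend left of copy1 / right of copy2
      while (steps < L &&
             orc_char(s, la - 1L) ==
             chartr("ACGT", "TGCA", orc_char(s, lb + 1L))) {
        la <- la - 1L; lb <- lb + 1L; steps <- steps + 1L
      }
      len <- 1L
      while (len < L &&
             orc_char(s, la + len) ==
             chartr("ACGT", "TGCA", orc_char(s, lb - len)))
        len <- len + 1L
      b_start <- lb - len + 1L
      if (len >= min_len && (la %% L) != (b_start %% L))
        add("inverted", la %% L, b_start %% L, len)
    }
  }
  if (!length(hits))
    return(data.frame(kind = character(), pos1 = integer(),
                      pos2 = integer(), rep_len = integer()))
  out <- unique(do.call(rbind, unname(hits)))
  out[order(-out$rep_len, out$pos1, out$pos2, out$kind), , drop = FALSE]
}

# --- least-squares tree oracle ---------------------------------------
# exhaustive search over all unrooted topologies: fit branch lengths by
# ordinary least squares on path-membership design, pick minimal SSE

orc_ls_topology <- function(d) {
  labels <- rownames(d)
  trees <- phangorn::allTrees(length(labels), rooted = FALSE,
                              tip.label = labels)
  npair <- combn(labels, 2L)
  dv <- apply(npair, 2L, function(p) d[p[1], p[2]])
  best <- NULL; best_sse <- Inf
  for (ti in seq_along(trees)) {
    tr <- ape::unroot(trees[[ti]])   # [[ restores shared tip labels
    ne <- nrow(tr$edge)
    X <- matrix(0, ncol(npair), ne)
    for (e in seq_len(ne)) {
      child <- tr$edge[e, 2]
      tips_below <- if (child <= length(labels)) tr$tip.label[child] else
        tr$tip.label[phangorn::Descendants(tr, child, "tips")[[1]]]
      inA <- npair[1, ] %in% tips_below
      inB <- npair[2, ] %in% tips_below
      X[, e] <- as.numeric(xor(inA, inB))
    }
    fit <- stats::lsfit(X, dv, intercept = FALSE)
    sse <- sum(fit$residuals^2)
    if (sse < best_sse - 1e-12) { best_sse <- sse; best <- tr }
  }
  best
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1] == 0
}

# additive distance matrix from a random unrooted tree with positive
# branch lengths
random_additive_matrix <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, rooted = FALSE,
                   br = function(n) stats::runif(n, 0.1, 1))
  d <- ape::cophenetic.phylo(tr)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tr, d = d)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
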