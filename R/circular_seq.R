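# circular sequence container, standard-format I/O, per-replicon statistics

#' Construct a circular (or linear) DNA sequence record
#'
#' The unit that every pipeline stage consumes: an identifier, a DNA string
#' over A/C/G/T/N (case-normalised to upper), and a circular-topology flag.
#'
#' @param id character identifier.
#' @param residues DNA string.
#' @param circular logical; `TRUE` for a circular replicon (the default,
#'   since all replicons in scope are circular).
#' @return an object of class `circular_seq` with fields `id`, `residues`,
#'   `circular` and `length`.
#' @examples
#' s <- circular_seq("p1", "ATGAAATTTAAATAA")
#' s$length
#' @export
circular_seq <- function(id, residues, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(residues)
  if (!nzchar(residues))
    stop("sequence '", id, "' is empty")
  bad <- setdiff(unique(chars_of(residues)), DNA_ALPHABET)
  if (length(bad))
    stop("sequence '", id, "' contains non-DNA characters: ",
         paste(bad, collapse = ", "))
  structure(
    list(id = id, residues = residues, circular = isTRUE(circular),
         length = nchar(residues)),
    class = "circular_seq"
  )
}

#' @export
print.circular_seq <- function(x, ...) {
  cat(sprintf("<circular_seq> %s: %d bp, %s\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Rotate a circular sequence so that position `k` becomes the new origin
#'
#' @param seq a [circular_seq()].
#' @param k 0-based offset of the new origin.
#' @return the rotated `circular_seq`.
#' @export
rotate_seq <- function(seq, k) {
  stopifnot(inherits(seq, "circular_seq"), seq$circular)
  circular_seq(seq$id, rotate_string(seq$residues, k), circular = TRUE)
}

#' Read DNA sequences from a FASTA file
#'
#' Each record becomes a [circular_seq()]. Topology is taken from `circular`
#' unless the record header carries a `circular=true/false` token, which
#' overrides the default per record.
#'
#' @param path FASTA file.
#' @param circular default topology flag.
#' @return list of `circular_seq`, in file order.
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  # read as raw strings: validation (incl. the record name) happens in
  # circular_seq(), and unlike readDNAStringSet nothing is silently dropped
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    header <- headers[i]
    id <- strsplit(header, "[ \t]")[[1]][1]
    circ <- circular
    if (grepl("circular=true", header, ignore.case = TRUE))  circ <- TRUE
    if (grepl("circular=false", header, ignore.case = TRUE)) circ <- FALSE
    out[[i]] <- tryCatch(
      circular_seq(id, as.character(set[[i]]), circular = circ),
      error = function(e) stop("record '", id, "' in '", path, "': ",
                               conditionMessage(e)))
  }
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs a `circular_seq` or list of them.
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "circular_seq")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- vapply(seqs, function(s)
    paste0(s$id, " circular=", tolower(as.character(s$circular))), "")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct an annotated feature on a replicon
#'
#' Coordinates are 0-based half-open throughout the package; on a circular
#' sequence a feature spanning the origin is encoded with `end > length`
#' (and `end - start <= length`).
#'
#' @param seq_id replicon identifier.
#' @param start,end integers, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param kind feature kind, `"CDS"` or `"other"`.
#' @param label free-text label.
#' @param seq_length replicon length, used to validate wrap-around.
#' @return one-row data frame with columns `seq_id`, `start`, `end`,
#'   `strand`, `kind`, `label`.
#' @export
annotated_feature <- function(seq_id, start, end, strand = "+",
                              kind = "CDS", label = "", seq_length = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(start >= 0, start < end, strand %in% c("+", "-"))
  if (!is.null(seq_length)) {
    if (start >= seq_length)
      stop("feature start ", start, " beyond sequence length ", seq_length)
    if (end - start > seq_length)
      stop("feature [", start, ",", end, ") longer than the sequence")
  }
  data.frame(seq_id = seq_id, start = start, end = end, strand = strand,
             kind = kind, label = label, stringsAsFactors = FALSE)
}

#' Read a GenBank flat file
#'
#' Minimal parser for GenBank flat files with an ORIGIN block (no installed
#' package reads local GenBank flat files, so the format is handled here).
#' CDS features are returned with strand and coordinates converted to the
#' package's 0-based half-open convention; `join()` locations spanning the
#' origin of a circular record are mapped to `end > length`.
#'
#' @param path GenBank flat file.
#' @return list with elements `seq` (a [circular_seq()]) and `features`
#'   (data frame of CDS features as from [annotated_feature()]).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus_line)) stop("not a GenBank flat file (no LOCUS): ", path)
  locus_tok <- strsplit(trimws(locus_line[1]), "[ \t]+")[[1]]
  acc <- locus_tok[2]
  circular <- any(grepl("circular", locus_line[1], ignore.case = TRUE))

  ori_at <- grep("^ORIGIN", lines)
  if (!length(ori_at)) stop("GenBank file '", path, "' has no ORIGIN block")
  seq_lines <- lines[(ori_at[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  residues <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  seq <- circular_seq(acc, residues, circular = circular)
  L <- seq$length

  # feature table: lines between FEATURES and ORIGIN; a new feature starts
  # with a key in column 6, continuation lines are indented further
  feat_at <- grep("^FEATURES", lines)
  features <- list()
  if (length(feat_at)) {
    block <- lines[(feat_at[1] + 1L):(ori_at[1] - 1L)]
    is_key <- grepl("^ {5}\\S", block)
    idx <- cumsum(is_key)
    for (g in split(block, idx)[as.character(seq_len(max(idx, 0)))]) {
      key <- strsplit(trimws(g[1]), "[ \t]+")[[1]][1]
      if (!identical(key, "CDS")) next
      loc <- sub("^ {5}\\S+\\s+", "", g[1])
      # location may continue onto lines before the first qualifier
      for (cont in g[-1]) {
        if (grepl("^\\s+/", cont)) break
        loc <- paste0(loc, trimws(cont))
      }
      gene <- sub('.*?/gene="([^"]*)".*', "\\1",
                  paste(g, collapse = " "))
      if (identical(gene, paste(g, collapse = " "))) gene <- ""
      parsed <- tryCatch(parse_genbank_location(loc, L),
                         error = function(e) {
                           warning("skipping CDS with unparseable location '",
                                   loc, "' in ", path, ": ",
                                   conditionMessage(e))
                           NULL
                         })
      if (is.null(parsed)) next
      features[[length(features) + 1L]] <-
        annotated_feature(acc, parsed$start, parsed$end, parsed$strand,
                          kind = "CDS", label = gene, seq_length = L)
    }
  }
  features <- if (length(features)) do.call(rbind, features) else
    annotated_feature("x", 0, 1)[0, ]
  list(seq = seq, features = features)
}

# parse a GenBank location string (1-based inclusive) into 0-based half-open
# coordinates; a join() whose parts wrap past the end of a circular record
# of length L is mapped to end > L
parse_genbank_location <- function(loc, L) {
  loc <- gsub("[<>]", "", gsub("[[:space:]]", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    parts <- strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",", fixed = TRUE)[[1]]
  } else {
    parts <- loc
  }
  rng <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([0-9]+)\\.\\.([0-9]+)$", p))[[1]]
    if (length(m) != 3L) {
      m1 <- regmatches(p, regexec("^([0-9]+)$", p))[[1]]
      if (length(m1) == 2L) return(c(as.integer(m1[2]), as.integer(m1[2])))
      stop("unsupported location part: ", p)
    }
    c(as.integer(m[2]), as.integer(m[3]))
  })
  starts <- vapply(rng, `[`, 0L, 1L) - 1L   # to 0-based
  ends   <- vapply(rng, `[`, 0L, 2L)        # half-open
  if (length(starts) == 1L)
    return(list(start = starts, end = ends, strand = strand))
  # multi-part join: require contiguity on the circle (origin wrap)
  start <- starts[1]; end <- ends[1]
  for (i in seq_along(starts)[-1]) {
    nxt <- starts[i]
    if (nxt == end %% L) {
      end <- end + (ends[i] - starts[i])
    } else {
      stop("non-contiguous join location")
    }
  }
  if (end - start > L) stop("join location longer than the sequence")
  list(start = start, end = end, strand = strand)
}

#' G+C content of a sequence
#'
#' Fraction (G+C) over non-N residues; N positions are excluded from the
#' denominator.
#'
#' @param seq a [circular_seq()].
#' @return fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  stopifnot(inherits(seq, "circular_seq"))
  chars <- chars_of(seq$residues)
  denom <- sum(chars != "N")
  if (denom == 0L) stop("sequence '", seq$id, "' is all N")
  sum(chars %in% c("G", "C")) / denom
}

#' Coding density of a replicon
#'
#' Fraction of sequence positions covered by at least one CDS feature,
#' wrap-aware; overlapping features are counted once. The alternative
#' convention (sum of CDS lengths over sequence length, overlaps counted
#' twice) is available as `method = "sum"`.
#'
#' @param seq a [circular_seq()].
#' @param features data frame of features (see [annotated_feature()]).
#' @param method `"union"` (default) or `"sum"`.
#' @return fraction; under `"union"` always in `[0, 1]`.
#' @export
coding_density <- function(seq, features, method = c("union", "sum")) {
  stopifnot(inherits(seq, "circular_seq"))
  method <- match.arg(method)
  L <- seq$length
  cds <- features[features$kind == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) return(0)
  if (any(cds$end - cds$start > L))
    stop("feature longer than the sequence")
  if (any(cds$end > L) && !seq$circular)
    stop("wrap-around feature on a linear sequence")
  if (method == "sum") return(sum(cds$end - cds$start) / L)
  covered <- logical(L)
  for (i in seq_len(nrow(cds)))
    covered[circ_positions(cds$start[i], cds$end[i], L)] <- TRUE
  mean(covered)
}

#' Per-replicon summary statistics
#'
#' Length, CDS count, coding density and G+C content for each replicon —
#' the standard descriptive table for a small-replicon comparison.
#'
#' @param seqs list of [circular_seq()].
#' @param features_by_seq named list (by replicon id) of feature data frames.
#' @param coding_method passed to [coding_density()].
#' @return data frame with columns `replicon`, `length_bp`, `cds`,
#'   `coding_pct`, `gc_pct`.
#' @export
replicon_stats <- function(seqs, features_by_seq,
                           coding_method = c("union", "sum")) {
  coding_method <- match.arg(coding_method)
  if (inherits(seqs, "circular_seq")) seqs <- list(seqs)
  rows <- lapply(seqs, function(s) {
    feats <- features_by_seq[[s$id]]
    if (is.null(feats)) feats <- annotated_feature("x", 0, 1)[0, ]
    cds <- feats[feats$kind == "CDS", , drop = FALSE]
    data.frame(
      replicon = s$id,
      length_bp = s$length,
      cds = nrow(cds),
      coding_pct = round(100 * coding_density(s, cds, coding_method), 1),
      gc_pct = round(100 * gc_content(s), 1),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
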