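# all-vs-all protein comparison, gene families, domain-level maps,
# cross-screening of an external proteome

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

check_protein <- function(x, id = "protein") {
  bad <- setdiff(unique(chars_of(x)), AA20)
  if (length(bad))
    stop(id, " contains non-amino-acid characters: ",
         paste(bad, collapse = ", "))
  invisible(x)
}

#' Homology search parameters
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gaps
#' (open 11, extend 1 — a gap of length g costs `11 + g`). A pair is a
#' hit when its raw score reaches `min_score`; hits are labelled full
#' when identity and coverage (of the shorter protein) reach
#' `full_identity`/`full_coverage`, and partial (domain-level) when
#' identity passes but coverage only reaches `partial_coverage`.
#'
#' There is no database-size E-value model; the raw-score floor plays
#' that role for the small fixed search spaces this package targets.
#' The default of 45 sits above the score a chance local alignment
#' reaches across a search space of a dozen small replicons (the
#' extreme-value expectation for BLOSUM62 with these gap costs puts
#' chance maxima near the high 30s there), while genuine homologues at
#' the identity/coverage thresholds score several-fold higher.
#'
#' @param matrix substitution matrix name (data set in Biostrings).
#' @param gap_open,gap_extend affine gap penalties.
#' @param min_score minimum raw alignment score.
#' @param full_identity,full_coverage thresholds for full-length hits.
#' @param partial_coverage lower coverage bound for partial hits.
#' @return list of class `homology_params`.
#' @export
homology_params <- function(matrix = "BLOSUM62", gap_open = 11,
                            gap_extend = 1, min_score = 45,
                            full_identity = 0.30, full_coverage = 0.70,
                            partial_coverage = 0.25) {
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, min_score = min_score,
                 full_identity = full_identity,
                 full_coverage = full_coverage,
                 partial_coverage = partial_coverage),
            class = "homology_params")
}

get_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

hit_row <- function(query_id, subject_id, score, identity, qs, qe, ss, se,
                    coverage_short, partial = NA) {
  data.frame(query_id = query_id, subject_id = subject_id, score = score,
             identity = identity, q_start = qs, q_end = qe,
             s_start = ss, s_end = se, coverage_short = coverage_short,
             partial = partial, stringsAsFactors = FALSE)
}

empty_hits <- function() hit_row("a", "b", 0, 0, 0L, 0L, 0L, 0L, 0)[0, ]

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman under the configured substitution matrix and affine gap
#' penalties. Identity is the fraction of identical positions over
#' alignment columns; coverage is the aligned span on the shorter protein
#' over its length. Returns `NULL` when the optimal score is below
#' `params$min_score`.
#'
#' @param protA,protB protein strings (20-letter alphabet).
#' @param params a [homology_params()].
#' @param idA,idB identifiers for the hit record.
#' @return one-row data frame (`query_id`, `subject_id`, `score`,
#'   `identity`, `q_start`, `q_end`, `s_start`, `s_end` — 1-based
#'   inclusive amino-acid coordinates — `coverage_short`, `partial`), or
#'   `NULL`.
#' @export
align_pair <- function(protA, protB, params = homology_params(),
                       idA = "A", idB = "B") {
  check_protein(protA, idA); check_protein(protB, idB)
  mat <- get_submat(params$matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protA), Biostrings::AAString(protB),
    type = "local", substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  sc <- Biostrings::score(pa)
  if (sc < params$min_score) return(NULL)
  hit_from_pa(pa, idA, idB, nchar(protA), nchar(protB))
}

hit_from_pa <- function(pa, idA, idB, lenA, lenB) {
  sc <- Biostrings::score(pa)
  al_len <- Biostrings::nchar(pa)
  ident <- Biostrings::nmatch(pa) / al_len
  qr <- pa@pattern@range
  sr <- pa@subject@range
  qs <- BiocGenerics::start(qr); qe <- BiocGenerics::end(qr)
  ss <- BiocGenerics::start(sr); se <- BiocGenerics::end(sr)
  short_span <- if (lenA <= lenB) qe - qs + 1L else se - ss + 1L
  cov <- short_span / min(lenA, lenB)
  hit_row(idA, idB, sc, ident, qs, qe, ss, se, cov)
}

#' All-vs-all protein comparison
#'
#' Aligns every unordered pair once and keeps pairs passing the score,
#' identity and coverage thresholds, labelled `partial = FALSE` (full) or
#' `partial = TRUE` (domain-level).
#'
#' @param proteins named character vector of proteins (>= 2).
#' @param params a [homology_params()].
#' @return data frame of hits (possibly empty), columns as [align_pair()].
#' @export
all_vs_all <- function(proteins, params = homology_params()) {
  stopifnot(length(proteins) >= 2L, !is.null(names(proteins)))
  ids <- names(proteins)
  for (i in seq_along(proteins)) check_protein(proteins[[i]], ids[i])
  mat <- get_submat(params$matrix)
  lens <- nchar(proteins)
  set <- Biostrings::AAStringSet(proteins)
  out <- list()
  n <- length(proteins)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    pas <- Biostrings::pairwiseAlignment(
      set[js], set[[i]], type = "local", substitutionMatrix = mat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    scs <- Biostrings::score(pas)
    for (kk in which(scs >= params$min_score)) {
      j <- js[kk]
      # pattern = subject j, subject = query i: swap to (query=i, subject=j)
      al_len <- Biostrings::nchar(pas)[kk]
      ident <- Biostrings::nmatch(pas)[kk] / al_len
      qr <- pas@subject@range[kk]   # protein i
      sr <- pas@pattern@range[kk]   # protein j
      qs <- BiocGenerics::start(qr); qe <- BiocGenerics::end(qr)
      ss <- BiocGenerics::start(sr); se <- BiocGenerics::end(sr)
      short_span <- if (lens[i] <= lens[j]) qe - qs + 1L else se - ss + 1L
      cov <- short_span / min(lens[i], lens[j])
      if (ident < params$full_identity || cov < params$partial_coverage)
        next
      out[[length(out) + 1L]] <-
        hit_row(ids[i], ids[j], scs[kk], ident, qs, qe, ss, se, cov,
                partial = cov < params$full_coverage)
    }
  }
  if (!length(out)) return(empty_hits())
  do.call(rbind, out)
}

#' Cluster proteins into gene families
#'
#' Single-linkage transitive closure over full hits only; partial
#' (domain-level) hits never merge families. Proteins without a full hit
#' become singleton families. Family identifiers are deterministic:
#' families are ordered by their sorted member lists, so the same
#' membership always yields the same ids regardless of input order.
#'
#' @param hits hit table from [all_vs_all()].
#' @param proteins named character vector of all proteins (members without
#'   hits become singletons).
#' @return data frame with one row per protein: `family_id`, `orf_id`,
#'   `replicon_id` (text before the last `_gp` in the orf id, `NA` if the
#'   id has no such suffix), `is_representative` (longest protein of the
#'   family, ties to the lexicographically smaller id).
#' @export
cluster_families <- function(hits, proteins) {
  stopifnot(!is.null(names(proteins)))
  ids <- names(proteins)
  full <- hits[!is.na(hits$partial) & !hits$partial, , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(full))
    g <- igraph::add_edges(g, rbind(match(full$query_id, ids),
                                    match(full$subject_id, ids)))
  comp <- igraph::components(g)$membership
  groups <- split(ids, comp)
  # deterministic ordering: by sorted member id lists
  key <- vapply(groups, function(m) paste(sort(m), collapse = "|"), "")
  groups <- groups[order(key)]
  rows <- list()
  for (fi in seq_along(groups)) {
    members <- sort(groups[[fi]])
    lens <- nchar(proteins[members])
    rep_id <- members[order(-lens, members)][1]
    rows[[fi]] <- data.frame(
      family_id = sprintf("F%03d", fi),
      orf_id = members,
      replicon_id = ifelse(grepl("_gp[0-9]+$", members),
                           sub("_gp[0-9]+$", "", members), NA_character_),
      is_representative = members == rep_id,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Domain-level (modular) map of one protein
#'
#' Partitions a protein's coordinate axis into segments supported by hits
#' (full or partial) to distinct gene families, mirroring the bar diagrams
#' used to display modular replicase architectures. Overlapping segments
#' supported by the same family are merged; the reported identity is the
#' best among merged hits.
#'
#' @param protein_id the protein whose axis is mapped.
#' @param hits hit table from [all_vs_all()] (or [cross_screen()] input).
#' @param families membership table from [cluster_families()].
#' @return data frame with `seg_start`, `seg_end` (1-based inclusive),
#'   `partner_family`, `identity`; empty when the protein has no hits to
#'   another family.
#' @export
modular_map <- function(protein_id, hits, families) {
  fam_of <- setNames(families$family_id, families$orf_id)
  segs <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (h$query_id == protein_id) {
      partner <- h$subject_id; s <- h$q_start; e <- h$q_end
    } else if (h$subject_id == protein_id) {
      partner <- h$query_id; s <- h$s_start; e <- h$s_end
    } else next
    pf <- fam_of[[partner]]
    if (is.null(pf) || identical(pf, fam_of[[protein_id]])) next
    segs[[length(segs) + 1L]] <- data.frame(
      seg_start = s, seg_end = e, partner_family = pf,
      identity = h$identity, stringsAsFactors = FALSE)
  }
  if (!length(segs))
    return(data.frame(seg_start = integer(), seg_end = integer(),
                      partner_family = character(), identity = numeric(),
                      stringsAsFactors = FALSE))
  segs <- do.call(rbind, segs)
  out <- list()
  for (pf in unique(segs$partner_family)) {
    ss <- segs[segs$partner_family == pf, , drop = FALSE]
    ss <- ss[order(ss$seg_start), , drop = FALSE]
    cur <- ss[1, ]
    for (i in seq_len(nrow(ss))[-1]) {
      if (ss$seg_start[i] <= cur$seg_end + 1L) {
        cur$seg_end <- max(cur$seg_end, ss$seg_end[i])
        cur$identity <- max(cur$identity, ss$identity[i])
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- ss[i, ]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  out <- do.call(rbind, out)
  out <- out[order(out$seg_start, out$partner_family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen an external proteome against the gene families
#'
#' Each query is aligned to every family representative (or every member
#' with `all_members = TRUE`); the best hit passing the partial-hit
#' thresholds is reported, queries without one are orphans.
#'
#' @param queries named character vector of query proteins.
#' @param families membership table from [cluster_families()].
#' @param proteins named character vector holding the family members.
#' @param params a [homology_params()].
#' @param all_members align to all members rather than representatives.
#' @return data frame with one row per query: `query_id`, `family_id`
#'   (`NA` for orphans), `subject_id`, `score`, `identity`,
#'   `coverage_short`, `orphan`.
#' @export
cross_screen <- function(queries, families, proteins,
                         params = homology_params(), all_members = FALSE) {
  stopifnot(!is.null(names(queries)))
  targets <- if (all_members) families$orf_id else
    families$orf_id[families$is_representative]
  fam_of <- setNames(families$family_id, families$orf_id)
  mat <- get_submat(params$matrix)
  tset <- Biostrings::AAStringSet(proteins[targets])
  tlens <- nchar(proteins[targets])
  rows <- list()
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]; qid <- names(queries)[qi]
    check_protein(q, qid)
    pas <- Biostrings::pairwiseAlignment(
      tset, Biostrings::AAString(q), type = "local",
      substitutionMatrix = mat, gapOpening = params$gap_open,
      gapExtension = params$gap_extend)
    scs <- Biostrings::score(pas)
    best <- NULL
    ord <- order(-scs)
    for (kk in ord) {
      if (scs[kk] < params$min_score) break
      al_len <- Biostrings::nchar(pas)[kk]
      ident <- Biostrings::nmatch(pas)[kk] / al_len
      qlen <- nchar(q); tlen <- tlens[kk]
      qr <- pas@subject@range[kk]; tr <- pas@pattern@range[kk]
      short_span <- if (qlen <= tlen)
        BiocGenerics::end(qr) - BiocGenerics::start(qr) + 1L
      else BiocGenerics::end(tr) - BiocGenerics::start(tr) + 1L
      cov <- short_span / min(qlen, tlen)
      if (ident >= params$full_identity && cov >= params$partial_coverage) {
        best <- data.frame(query_id = qid, family_id = fam_of[[targets[kk]]],
                           subject_id = targets[kk], score = scs[kk],
                           identity = ident, coverage_short = cov,
                           orphan = FALSE, stringsAsFactors = FALSE)
        break
      }
    }
    if (is.null(best))
      best <- data.frame(query_id = qid, family_id = NA_character_,
                         subject_id = NA_character_, score = NA_real_,
                         identity = NA_real_, coverage_short = NA_real_,
                         orphan = TRUE, stringsAsFactors = FALSE)
    rows[[qi]] <- best
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a hit table as TSV
#'
#' Columns follow tabular pairwise-hit conventions: query, subject, score,
#' identity percentage, query/subject intervals, coverage and partial flag.
#'
#' @param hits hit table from [all_vs_all()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- data.frame(query = hits$query_id, subject = hits$subject_id,
                    score = hits$score,
                    identity_pct = round(100 * hits$identity, 1),
                    q_start = hits$q_start, q_end = hits$q_end,
                    s_start = hits$s_start, s_end = hits$s_end,
                    coverage = round(hits$coverage_short, 3),
                    partial = hits$partial)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
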