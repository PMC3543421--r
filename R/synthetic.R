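# synthetic circular replicon sets with planted ground truth

# amino-acid background frequencies (Robinson-Robinson-like, renormalised)
AA_BACKGROUND <- c(A = .079, R = .051, N = .045, D = .054, C = .019,
                   Q = .043, E = .063, G = .074, H = .022, I = .051,
                   L = .091, K = .057, M = .022, F = .039, P = .052,
                   S = .068, T = .059, W = .014, Y = .032, V = .065)

# synonymous codons per amino acid (stops excluded), standard code
syn_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[AA20]
}

all_sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# reverse-complement lookup for all 64 codons, built once at load
RC3 <- local({
  b <- c("A", "C", "G", "T")
  cods <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setNames(vapply(cods, function(x) paste(rev(unname(
    c(A = "T", C = "G", G = "C", T = "A")[strsplit(x, "")[[1]]])),
    collapse = ""), ""), cods)
})

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic replicon generator
#'
#' Defaults emulate a family of small circular archaeal plasmids: two
#' subfamilies of replicons sharing core families (one of them a large
#' replicase/helicase-like gene of more than 650 codons, heading the
#' replication cassette), semi-conserved families present in members of
#' both subfamilies, families specific to each subfamily, and singletons.
#' Each replicon carries an SD motif upstream of every gene start, a
#' strand-compositional (GC-skew) switch at a planted origin inside the
#' large intergenic region preceding the replication cassette, and an
#' optional direct repeat pair near the origin.
#'
#' @param n_replicons number of replicons.
#' @param subfamily_split integer pair, replicons per subfamily (defaults
#'   to an even split).
#' @param n_core families present in every replicon (the first is the
#'   large replication-cassette family).
#' @param n_semi families present in members of both subfamilies but not
#'   all replicons.
#' @param n_group_specific families restricted to one subfamily (this
#'   many per subfamily, each present in at least two of its replicons).
#' @param n_singleton families present in exactly one replicon.
#' @param protein_len_range overall protein length bounds (aa); the
#'   replication-cassette family is drawn from `replicase_len_range`,
#'   all other families from `other_len_range`.
#' @param replicase_len_range,other_len_range per-class length bounds.
#' @param intra_family_divergence per-site substitution probability
#'   between a family member and the family ancestor.
#' @param intergenic_len_range ordinary spacer length bounds (bp).
#' @param large_intergenic_range length bounds of the large region
#'   preceding the replication cassette, which houses the origin.
#' @param ori_bias probability that a skew-informative position carries G
#'   (rather than C) on the leading strand; must be in (0.5, 1].
#' @param repeat_near_ori plant a direct repeat pair inside the origin
#'   region.
#' @param sd_offset bp between the SD motif 3' end and the start codon.
#' @param gc_target genome G+C fraction aimed for.
#' @param length_range admissible replicon lengths (bp).
#' @param seed integer seed; all generator randomness flows from it.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_replicons = 8L, subfamily_split = NULL,
                         n_core = 2L, n_semi = 3L, n_group_specific = 4L,
                         n_singleton = 2L,
                         protein_len_range = c(80L, 900L),
                         replicase_len_range = c(650L, 900L),
                         other_len_range = c(80L, 400L),
                         intra_family_divergence = 0.10,
                         intergenic_len_range = c(30L, 400L),
                         large_intergenic_range = c(300L, 600L),
                         ori_bias = 0.7, repeat_near_ori = TRUE,
                         sd_offset = 8L, gc_target = 0.45,
                         length_range = c(8000L, 14000L), seed = 1L) {
  if (is.null(subfamily_split)) {
    h <- n_replicons %/% 2L
    subfamily_split <- c(n_replicons - h, h)
  }
  stopifnot(sum(subfamily_split) == n_replicons,
            n_core >= 1L, n_semi >= 0L, n_group_specific >= 0L,
            n_singleton >= 0L,
            ori_bias > 0.5, ori_bias <= 1)
  if (n_semi > 0L && any(subfamily_split == 0L))
    stop("semi-conserved families need members in both subfamilies")
  structure(as.list(environment()), class = "synth_config")
}

# draw a random protein of given length (starts with M, never mutated)
random_protein <- function(len) {
  paste0("M", paste(sample(names(AA_BACKGROUND), len - 1L, replace = TRUE,
                           prob = AA_BACKGROUND), collapse = ""))
}

# substitute positions 2..n with probability `rate`
mutate_protein <- function(prot, rate) {
  if (rate <= 0) return(prot)
  aa <- chars_of(prot)
  n <- length(aa)
  if (n < 2L) return(prot)
  hit <- which(runif(n - 1L) < rate) + 1L
  for (i in hit) {
    aa[i] <- sample(setdiff(names(AA_BACKGROUND), aa[i]), 1L)
  }
  paste(aa, collapse = "")
}

# family structure: memberships and conservation classes
plan_families <- function(cfg) {
  reps <- sprintf("R%02d", seq_len(cfg$n_replicons))
  groupA <- reps[seq_len(cfg$subfamily_split[1])]
  groupB <- setdiff(reps, groupA)
  fams <- list(); classes <- character(0); fam_i <- 0L
  add <- function(members, class, len_range) {
    fam_i <<- fam_i + 1L
    id <- sprintf("T%02d", fam_i)
    fams[[id]] <<- list(members = members,
                        len = sample(len_range[1]:len_range[2], 1L))
    classes[id] <<- class
    id
  }
  replicase_fam <- add(reps, "core", cfg$replicase_len_range)
  for (i in seq_len(cfg$n_core - 1L)) add(reps, "core", cfg$other_len_range)
  if (cfg$n_semi > 0L && length(reps) < 3L)
    stop("semi-conserved families need at least 3 replicons")
  for (i in seq_len(cfg$n_semi)) {
    for (try in 1:1000) {
      mem <- reps[runif(length(reps)) < 0.6]
      if (length(intersect(mem, groupA)) >= 1L &&
          length(intersect(mem, groupB)) >= 1L &&
          length(mem) < length(reps)) break
      if (try == 1000) stop("cannot sample a semi-conserved membership")
    }
    add(mem, "semi_conserved", cfg$other_len_range)
  }
  # group-specific families span their whole subfamily: with the core
  # families this guarantees that every within-subfamily gene-content
  # similarity exceeds every across-subfamily one, for all realisable
  # semi/singleton assignments, so the planted split is recoverable by
  # construction
  for (g in list(groupA, groupB)) {
    if (length(g) < 2L) next
    for (i in seq_len(cfg$n_group_specific))
      add(g, "group_specific", cfg$other_len_range)
  }
  host <- sample(reps, min(cfg$n_singleton, length(reps)))
  for (i in seq_len(cfg$n_singleton))
    add(host[((i - 1L) %% length(host)) + 1L], "singleton",
        cfg$other_len_range)
  list(replicons = reps, groupA = groupA, groupB = groupB,
       families = fams, classes = classes,
       subfamily = setNames(ifelse(reps %in% groupA, 1L, 2L), reps))
}

# among equivalent codon candidates, prefer the one whose junction with
# the previous codon seeds the most off-frame stop codons (either strand):
# this thins out chance ORFs without touching protein, G+C or skew
# composition (the candidate subset was already fixed by those)
pick_stop_seeding <- function(cands, prev) {
  if (length(cands) == 1L) return(cands)
  sc <- vapply(cands, function(cod) {
    mer <- paste0(prev, cod)
    n <- 0L
    for (i in 2:3) {
      w <- substr(mer, i, i + 2L)
      if (w %in% c("TAA", "TAG", "TGA")) n <- n + 1L
      if (w %in% c("TTA", "CTA", "TCA")) n <- n + 1L  # minus-strand stops
    }
    n
  }, 0L)
  top <- cands[sc == max(sc)]
  if (length(top) == 1L) top else sample(top, 1L)
}

# pick a codon for `aa`: with prob p3gc prefer a G/C third position (on the
# plus strand), then prefer the skew-favoured base with prob `bias`;
# `want_g` is TRUE on the leading strand. `minus` flags a minus-strand gene
# (plus-strand base is the complement of the codon third base). `prev` is
# the previous codon on the coding strand, used for stop seeding.
pick_codon <- function(syn, aa, want_g, bias, minus, prev = "", p3gc = 0.33) {
  cands <- syn[[aa]]
  if (length(cands) == 1L) return(cands)
  third <- substr(cands, 3L, 3L)
  plus3 <- if (minus) unname(COMPLEMENT[third]) else third
  gc_set <- cands[plus3 %in% c("G", "C")]
  at_set <- cands[!(plus3 %in% c("G", "C"))]
  use_gc <- length(gc_set) > 0L && (length(at_set) == 0L || runif(1) < p3gc)
  if (!use_gc) return(pick_stop_seeding(at_set, prev))
  want <- if (want_g) "G" else "C"
  pref <- gc_set[(if (minus) unname(COMPLEMENT[substr(gc_set, 3, 3)]) else
    substr(gc_set, 3, 3)) == want]
  if (length(pref) && runif(1) < bias) pick_stop_seeding(pref, prev) else
    pick_stop_seeding(gc_set, prev)
}

# leading-strand predicate for forward positions, given ori and terminus
make_leading <- function(ori, L) {
  ter <- (ori + L %/% 2L) %% L
  function(pos) {
    off <- (pos - ori) %% L
    off < ((ter - ori) %% L)
  }
}

#' Generate a synthetic replicon set with planted ground truth
#'
#' Proteins of a family derive from a family ancestor by point
#' substitutions; genes are back-translated with skew-aware synonymous
#' codon choice (planted proteins are preserved exactly), an SD motif and
#' a stop codon immediately upstream of each start are planted, and genes
#' are placed around the circle with intergenic spacers. Downstream of
#' the planted origin the spacer and synonymous third-position
#' composition is G-enriched on the leading strand at `ori_bias`,
#' switching at the antipode (terminus). Each replicon is then refined so
#' that its ORF complement under default [orf_params()] equals the
#' planted gene set exactly: chance ORFs are eliminated by planting stop
#' codons in spacer positions or swapping synonymous codons inside genes.
#'
#' @param cfg a [synth_config()].
#' @return list with `seqs` (list of [circular_seq()]) and `truth`: per
#'   replicon the planted origin position, gene coordinates/strands,
#'   family id per gene and subfamily label, plus the global family ->
#'   conservation-class map and the family ancestor proteins.
#' @export
generate_set <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, generate_set_impl(cfg))
}

generate_set_impl <- function(cfg) {
  syn <- syn_codons()
  # the replicon length band constrains both the family memberships (a
  # replicon must carry enough genes) and the protein lengths; redraw
  # lengths for each membership plan, and the plan itself when no length
  # assignment can fit
  plan_feasible <- function(plan) {
    for (r in plan$replicons) {
      fams_r <- names(plan$families)[vapply(plan$families, function(f)
        r %in% f$members, logical(1))]
      coding <- sum(vapply(fams_r, function(id)
        3L * (plan$families[[id]]$len + 1L), 0L))
      ngenes <- length(fams_r)
      lo <- coding + (ngenes - 1L) * cfg$intergenic_len_range[1] +
        cfg$large_intergenic_range[1]
      hi <- coding + (ngenes - 1L) * cfg$intergenic_len_range[2] +
        cfg$large_intergenic_range[2]
      if (lo > cfg$length_range[2] || hi < cfg$length_range[1])
        return(FALSE)
    }
    TRUE
  }
  plan <- NULL
  for (attempt in 1:300) {
    cand <- plan_families(cfg)
    for (try in 1:60) {
      for (id in names(cand$families)) {
        rng <- if (id == names(cand$families)[1]) cfg$replicase_len_range
        else cfg$other_len_range
        cand$families[[id]]$len <- sample(rng[1]:rng[2], 1L)
      }
      if (plan_feasible(cand)) { plan <- cand; break }
    }
    if (!is.null(plan)) break
  }
  if (is.null(plan))
    stop("infeasible packing: planted genes cannot fit ",
         "the configured replicon length range")
  # family member proteins
  ancestors <- lapply(plan$families, function(f) random_protein(f$len))
  member_prot <- list()
  for (id in names(plan$families))
    for (r in plan$families[[id]]$members)
      member_prot[[paste(r, id)]] <-
        mutate_protein(ancestors[[id]], cfg$intra_family_divergence)

  seqs <- list(); truth_reps <- list()
  for (r in plan$replicons) {
    # chance-ORF elimination can rarely hit an unfixable configuration;
    # rebuilding the replicon with fresh codon/spacer draws resolves it
    built <- NULL
    for (attempt in 1:15) {
      built <- tryCatch(build_replicon(r, plan, member_prot, cfg, syn),
                        error = function(e) e)
      if (!inherits(built, "error")) break
    }
    if (inherits(built, "error"))
      stop("could not build replicon ", r, ": ", conditionMessage(built))
    seqs[[r]] <- built$seq
    truth_reps[[r]] <- built$truth
  }
  list(seqs = seqs,
       truth = list(replicons = truth_reps,
                    classes = plan$classes,
                    subfamily = plan$subfamily,
                    ancestors = ancestors,
                    config = cfg))
}

build_replicon <- function(r, plan, member_prot, cfg, syn) {
  fam_ids <- names(plan$families)[vapply(plan$families, function(f)
    r %in% f$members, logical(1))]
  # replication cassette (first family) stays first; the rest shuffled
  rest <- setdiff(fam_ids, fam_ids[1])
  order_ids <- c(fam_ids[1], sample(rest))
  ngenes <- length(order_ids)
  gene_len <- vapply(order_ids, function(id)
    3L * (plan$families[[id]]$len + 1L), 0L)
  coding <- sum(gene_len)

  # pick a total length, then spacer lengths summing to the remainder
  lo <- coding + (ngenes - 1L) * cfg$intergenic_len_range[1] +
    cfg$large_intergenic_range[1]
  hi <- coding + (ngenes - 1L) * cfg$intergenic_len_range[2] +
    cfg$large_intergenic_range[2]
  L <- sample(max(lo, cfg$length_range[1]):min(hi, cfg$length_range[2]), 1L)
  spacer_total <- L - coding
  spacers <- allocate_spacers(spacer_total, ngenes,
                              cfg$large_intergenic_range,
                              cfg$intergenic_len_range)
  # layout: [large spacer][gene1][spacer2][gene2]...
  gstart <- integer(ngenes); pos <- spacers[1]
  for (i in seq_len(ngenes)) {
    gstart[i] <- pos
    pos <- pos + gene_len[i]
    if (i < ngenes) pos <- pos + spacers[i + 1L]
  }
  stopifnot(pos == L)
  strands <- ifelse(runif(ngenes) < 0.8, "+", "-")
  strands[1] <- "+"   # replication cassette clockwise
  ori <- spacers[1] %/% 2L
  leading <- make_leading(ori, L)

  chars <- rep(NA_character_, L)
  editable <- rep(FALSE, L)
  gene_idx_at <- rep(0L, L)
  codon_idx_at <- rep(0L, L)
  genes <- list()

  for (i in seq_len(ngenes)) {
    id <- order_ids[i]
    prot <- member_prot[[paste(r, id)]]
    s <- gstart[i]; e <- s + gene_len[i]
    minus <- strands[i] == "-"
    aa <- chars_of(prot)
    ncod <- length(aa)
    codons <- character(ncod + 1L)
    codons[1] <- "ATG"
    for (ci in 2:ncod) {
      # forward coordinate of the codon third position
      fpos <- if (!minus) s + 3L * ci - 1L else e - 3L * ci
      codons[ci] <- pick_codon(syn, aa[ci], leading(fpos %% L),
                               cfg$ori_bias, minus, prev = codons[ci - 1L])
    }
    stop_f <- if (!minus) e - 1L else s
    codons[ncod + 1L] <- if (leading(stop_f %% L) == !minus) "TGA" else "TAA"
    dna <- paste(codons, collapse = "")
    fwd <- if (minus) revcomp(dna) else dna
    posi <- circ_positions(s, e, L)
    chars[posi] <- chars_of(fwd)
    gene_idx_at[posi] <- i
    codon_idx_at[posi] <- if (minus) rev(rep(seq_len(ncod + 1L), each = 3L)) else
      rep(seq_len(ncod + 1L), each = 3L)
    genes[[i]] <- list(family = id, start = s, end = e,
                       strand = strands[i], protein = prot,
                       codons = codons, n_codons = ncod)
  }

  # SD cassettes: motif at `sd_offset` bp upstream of the start, with an
  # in-frame stop codon written immediately before the start so that the
  # planted start is always the one reported by find_orfs()
  sd <- cfg$sd_motif_string %||% "AGGAGG"
  off <- as.integer(cfg$sd_offset %||% 8L)
  stopifnot(off >= 3L)
  slen <- nchar(sd)
  cas_len <- slen + off
  protected <- rep(FALSE, L)
  for (i in seq_len(ngenes)) {
    g <- genes[[i]]
    # cassette on the coding strand: [motif][gap of off bp][start codon];
    # the last 3 gap bases are TAA (the pre-start stop)
    gap_fill <- sample(c("A", "T", "C"), off - 3L, replace = TRUE)
    cassette <- c(chars_of(sd), gap_fill, c("T", "A", "A"))
    if (g$strand == "+") {
      m_pos <- circ_positions((g$start - cas_len) %% L,
                              (g$start - cas_len) %% L + cas_len, L)
      chars[m_pos] <- cassette
    } else {
      m_pos <- circ_positions(g$end %% L, g$end %% L + cas_len, L)
      chars[m_pos] <- rev(unname(COMPLEMENT[cassette]))
    }
    protected[m_pos] <- TRUE
  }

  # planted direct repeat near the origin
  planted_repeat <- NULL
  if (isTRUE(cfg$repeat_near_ori) && spacers[1] >= 120L) {
    unit <- paste(sample(c("A", "C", "G", "T"), 14L, replace = TRUE,
                         prob = c(.3, .2, .2, .3)), collapse = "")
    p1 <- (ori - 40L) %% L; p2 <- (ori + 26L) %% L
    for (p in c(p1, p2)) {
      posi <- circ_positions(p, p + 14L, L)
      chars[posi] <- chars_of(unit)
      protected[posi] <- TRUE
    }
    planted_repeat <- list(unit = unit, pos1 = p1, pos2 = p2)
  }

  # free spacer positions: composition closes the loop on the G+C target
  free <- which(is.na(chars))
  gc_fixed <- sum(chars %in% c("G", "C"), na.rm = TRUE)
  p_gc <- (cfg$gc_target * L - gc_fixed) / max(length(free), 1L)
  p_gc <- min(max(p_gc, 0.15), 0.85)
  for (p in free) {
    if (runif(1) < p_gc) {
      want_g <- leading(p - 1L)
      chars[p] <- if (runif(1) < cfg$ori_bias) (if (want_g) "G" else "C")
      else (if (want_g) "C" else "G")
    } else {
      chars[p] <- sample(c("A", "T"), 1L)
    }
    editable[p] <- TRUE
  }

  truth_genes <- do.call(rbind, lapply(genes, function(g)
    data.frame(start = g$start, end = g$end, strand = g$strand,
               family_id = g$family, n_codons = g$n_codons,
               protein = g$protein, stringsAsFactors = FALSE)))

  fixed <- repair_orfs(chars, L, r, truth_genes, editable,
                       genes, gene_idx_at, codon_idx_at, syn)

  # repair may have exchanged the odd amino acid; truth proteins are the
  # translation of the final sequence
  for (i in seq_len(nrow(truth_genes))) {
    minus <- truth_genes$strand[i] == "-"
    posi <- if (minus)
      circ_positions(truth_genes$start[i] + 3L, truth_genes$end[i], L)
    else circ_positions(truth_genes$start[i], truth_genes$end[i] - 3L, L)
    dna <- paste(fixed[posi], collapse = "")
    if (minus) dna <- revcomp(dna)
    truth_genes$protein[i] <- translate_dna(dna, as_start = TRUE)
  }

  seq <- circular_seq(r, paste(fixed, collapse = ""), circular = TRUE)
  list(seq = seq,
       truth = list(id = r, length = L, ori = ori,
                    genes = truth_genes,
                    subfamily = unname(plan$subfamily[r]),
                    planted_repeat = planted_repeat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split `total` bp into one large spacer plus (n-1) ordinary ones
allocate_spacers <- function(total, ngenes, large_range, small_range) {
  n_small <- ngenes - 1L
  large <- sample(large_range[1]:large_range[2], 1L)
  small <- if (n_small > 0L)
    sample(small_range[1]:small_range[2], n_small, replace = TRUE)
  else integer(0)
  diff <- total - large - sum(small)
  # water-fill the difference respecting bounds
  for (iter in 1:10000) {
    if (diff == 0L) break
    step <- sign(diff)
    i <- sample.int(n_small + 1L, 1L)
    if (i == 1L) {
      nv <- large + step
      if (nv >= large_range[1] && nv <= large_range[2]) {
        large <- nv; diff <- diff - step
      }
    } else {
      nv <- small[i - 1L] + step
      if (nv >= small_range[1] && nv <= small_range[2]) {
        small[i - 1L] <- nv; diff <- diff - step
      }
    }
  }
  if (diff != 0L) stop("infeasible packing: spacers cannot absorb ",
                       diff, " bp")
  c(large, small)
}

# refine a replicon until find_orfs() returns exactly the planted genes
repair_orfs <- function(chars, L, id, truth_genes, editable,
                        genes, gene_idx_at, codon_idx_at, syn,
                        max_iter = 40L) {
  params <- orf_params()
  truth_key <- paste(truth_genes$start, truth_genes$end, truth_genes$strand)
  # mutable gene state: non-synonymous fixes update codons and protein so
  # that later fixes can never revert an already-planted stop
  genv <- new.env(parent = emptyenv())
  genv$genes <- genes
  genv$memo <- list()
  seen <- integer(0)   # recurrence count per spurious ORF
  for (iter in seq_len(max_iter)) {
    seq <- circular_seq(id, paste(chars, collapse = ""), circular = TRUE)
    orfs <- suppressWarnings(find_orfs(seq, params, proteins = FALSE))
    pred_key <- paste(orfs$start, orfs$end, orfs$strand)
    spurious <- orfs[!(pred_key %in% truth_key), , drop = FALSE]
    missing <- setdiff(truth_key, pred_key)
    if (!nrow(spurious) && !length(missing)) return(chars)
    if (!nrow(spurious) && length(missing))
      stop("planted gene lost on ", id, ": ", paste(missing, collapse = "; "))
    sp_key <- paste(spurious$start, spurious$end, spurious$strand)
    for (k in seq_len(nrow(spurious))) {
      # earlier fixes in this round may already have destroyed this ORF
      if (!orf_still_present(spurious[k, ], chars, L, params)) next
      prev <- seen[sp_key[k]]
      n_seen <- if (is.na(prev)) 1L else prev + 1L
      seen[sp_key[k]] <- n_seen
      # overlapping chance ORFs can undo each other's synonymous fixes
      # in a cycle; a recurring ORF is fixed with the full codon space
      # and randomised choice, which breaks deterministic cycles
      chars <- squash_orf(spurious[k, ], chars, L, editable, genv,
                          gene_idx_at, codon_idx_at, syn, params,
                          escalate = n_seen >= 3L)
    }
  }
  stop("ORF repair did not converge on replicon ", id)
}

# is the ORF's reading (start codon, stop-free interior) still intact on
# the current sequence?
orf_still_present <- function(orf, chars, L, params) {
  for (j in seq_len(orf$n_codons) - 1L) {
    triplet <- paste(chars[slot_positions(orf, j, L)], collapse = "")
    codon <- if (orf$strand == "+") triplet else revcomp(triplet)
    if (j == 0L && !(codon %in% params$start_codons)) return(FALSE)
    if (codon %in% params$stop_codons) return(FALSE)
  }
  TRUE
}

# forward positions (1-based) of codon slot j (0-based from the ORF start)
slot_positions <- function(orf, j, L) {
  if (orf$strand == "+") {
    p <- orf$start + 3L * j
    circ_positions(p %% L, p %% L + 3L, L)
  } else {
    p <- orf$end - 3L * j - 3L
    circ_positions(((p %% L) + L) %% L, ((p %% L) + L) %% L + 3L, L)
  }
}

# eliminate one chance ORF by planting stops in editable positions, or by
# synonymous codon swaps inside overlapping genes
squash_orf <- function(orf, chars, L, editable, genv, gene_idx_at,
                       codon_idx_at, syn, params, escalate = FALSE) {
  n_slots <- orf$n_codons  # sense-codon slots, excluding the stop
  # walk left to right planting stop codons so that every remaining
  # fragment is shorter than the minimum ORF length; at each step take the
  # farthest admissible slot. Synonymous edits are preferred (editable
  # spacer bases free, gene bases moved between synonymous codons); when a
  # window admits none, a single non-synonymous codon change (one amino
  # acid of one planted protein) guarantees a stop — planted proteins are
  # re-derived from the final sequence afterwards, so truth stays exact.
  frag <- params$min_codons - 1L
  last <- 0L
  while (n_slots - last > frag) {
    placed <- FALSE
    # random slot order within the admissible window: overlapping chance
    # ORFs on opposite strands can otherwise resurrect each other in a
    # cycle of deterministic fixes
    window <- seq(last + 1L, min(last + frag, n_slots))
    window <- if (length(window) > 1L) sample(window) else window
    modes <- if (escalate) "stop_any" else c("stop", "stop_any")
    for (mode in modes) {
      for (j in window) {
        res <- fix_slot(orf, j - 1L, chars, L, editable, genv, gene_idx_at,
                        codon_idx_at, syn, params, mode = mode,
                        shuffle = escalate)
        if (!is.null(res)) {
          chars <- res
          # the window must keep advancing: later stops only
          last <- max(last, j); placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed)
      stop("cannot eliminate chance ORF at ", orf$start, "-", orf$end,
           " (", orf$strand, ")")
  }
  chars
}

# forward positions (1-based) of a planted gene's codon ci
gene_codon_positions <- function(g, ci, L) {
  p <- if (g$strand == "+") g$start + 3L * (ci - 1L) else g$end - 3L * ci
  circ_positions(((p %% L) + L) %% L, ((p %% L) + L) %% L + 3L, L)
}

# Try to rewrite codon slot j (0-based) of a chance ORF so that its coding
# triplet becomes a stop codon (`mode = "stop"`) or stops being a start
# codon (`mode = "kill_start"`). Editable (spacer) positions may take any
# base; positions inside planted genes may only change through synonymous
# codon swaps (the planted proteins are preserved exactly); positions in
# protected elements (SD motifs, planted repeats) are immutable. Returns
# the updated character vector, or NULL when the slot cannot be fixed.
fix_slot <- function(orf, j, chars, L, editable, genv, gene_idx_at,
                     codon_idx_at, syn, params, mode = "stop",
                     shuffle = FALSE) {
  posi <- slot_positions(orf, j, L)
  # fast path: fully editable slot, write a stop directly (random choice
  # among the three stops, again to avoid deterministic fix cycles)
  if (mode != "kill_start" && all(editable[posi])) {
    cod <- sample(params$stop_codons, 1L)
    chars[posi] <- chars_of(if (orf$strand == "+") cod else RC3[[cod]])
    return(chars)
  }
  gidx <- gene_idx_at[posi]
  # groups of jointly-varying positions: each underlying gene codon is one
  # group; each editable position is its own group; anything else is fixed
  group_opts <- list()   # per group: pos (forward), cand (coding codons),
                         # fwd (their forward-strand strings), gene, ci
  pos_group <- character(3)
  pos_off <- integer(3)  # index of posi[t] within its group's positions
  for (t in 1:3) {
    p <- posi[t]
    if (gidx[t] > 0L) {
      key <- paste0("g", gidx[t], "_", codon_idx_at[p])
      pos_group[t] <- key
      if (is.null(group_opts[[key]])) {
        memo_key <- if (mode == "stop_any") paste0(key, "*") else key
        cached <- genv$memo[[memo_key]]
        if (is.null(cached)) {
          g <- genv$genes[[gidx[t]]]
          ci <- codon_idx_at[p]
          cands <- if (ci == 1L) g$codons[1] else
            if (ci == g$n_codons + 1L) c("TAA", "TAG", "TGA") else
              if (mode == "stop_any") all_sense_codons() else
                syn[[substr(g$protein, ci, ci)]]
          cpos <- gene_codon_positions(g, ci, L)
          fwd <- if (g$strand == "+") cands else unname(RC3[cands])
          cached <- list(pos = cpos, cand = cands, fwd = fwd,
                         gene = gidx[t], ci = ci)
          genv$memo[[memo_key]] <- cached
        }
        group_opts[[key]] <- cached
      }
      pos_off[t] <- match(p, group_opts[[key]]$pos)
    } else if (editable[p]) {
      key <- paste0("e", p)
      pos_group[t] <- key
      group_opts[[key]] <- list(pos = p, cand = NULL,
                                fwd = c("A", "C", "G", "T"))
      pos_off[t] <- 1L
    } else {
      pos_group[t] <- "fixed"
    }
  }
  keys <- setdiff(unique(pos_group), "fixed")
  if (!length(keys)) return(NULL)
  minus <- orf$strand == "-"
  # wanted forward triplets
  want_fwd <- if (minus) unname(RC3[params$stop_codons]) else
    params$stop_codons
  # per-position achievable characters at the slot; a componentwise
  # impossibility rules the slot out without enumerating combinations
  ach <- vector("list", 3)
  for (t in 1:3) {
    key <- pos_group[t]
    ach[[t]] <- if (key == "fixed") chars[posi[t]] else
      unique(substr(group_opts[[key]]$fwd, pos_off[t], pos_off[t]))
  }
  if (mode != "kill_start") {
    feasible <- vapply(want_fwd, function(w) {
      substr(w, 1, 1) %in% ach[[1]] && substr(w, 2, 2) %in% ach[[2]] &&
        substr(w, 3, 3) %in% ach[[3]]
    }, logical(1))
    if (!any(feasible)) return(NULL)
  }
  grid <- expand.grid(lapply(group_opts[keys], function(o)
    seq_along(o$fwd)), stringsAsFactors = FALSE)
  current <- paste0(chars[posi[1]], chars[posi[2]], chars[posi[3]])
  slot_chars <- lapply(1:3, function(t) {
    key <- pos_group[t]
    if (key == "fixed") chars[posi[t]] else
      substr(group_opts[[key]]$fwd, pos_off[t], pos_off[t])
  })
  sel_of <- lapply(1:3, function(t) {
    key <- pos_group[t]
    if (key == "fixed") rep(1L, nrow(grid)) else grid[[key]]
  })
  order_gi <- if (shuffle && nrow(grid) > 1L) sample(nrow(grid)) else
    seq_len(nrow(grid))
  for (gi in order_gi) {
    triplet <- paste0(slot_chars[[1]][sel_of[[1]][gi]],
                      slot_chars[[2]][sel_of[[2]][gi]],
                      slot_chars[[3]][sel_of[[3]][gi]])
    if (triplet == current) next
    ok <- if (mode == "kill_start") {
      codon <- if (minus) RC3[[triplet]] else triplet
      !(codon %in% params$start_codons)
    } else triplet %in% want_fwd
    if (ok) {
      for (key in keys) {
        o <- group_opts[[key]]
        sel <- grid[[key]][gi]
        chars[o$pos] <- chars_of(o$fwd[sel])[seq_along(o$pos)]
        if (mode == "stop_any" && !is.null(o$cand) &&
            o$ci <= genv$genes[[o$gene]]$n_codons && o$ci > 1L) {
          # record the (possibly non-synonymous) codon in the gene state
          g <- genv$genes[[o$gene]]
          new_cod <- o$cand[sel]
          g$codons[o$ci] <- new_cod
          substr(g$protein, o$ci, o$ci) <-
            unname(Biostrings::GENETIC_CODE[new_cod])
          genv$genes[[o$gene]] <- g
          genv$memo[[key]] <- NULL   # synonymous cache now stale
        }
      }
      return(chars)
    }
  }
  NULL
}

#' Generate a decoy proteome with a known shared fraction
#'
#' Emulates a viral proteome partially overlapping a plasmid pan-genome:
#' `fraction_shared` of the `n` proteins are diverged copies of randomly
#' chosen family representatives, the rest are composition-matched random
#' strings.
#'
#' @param n number of proteins.
#' @param family_reps named character vector: family id -> representative
#'   protein.
#' @param fraction_shared fraction of proteins derived from families.
#' @param divergence per-site substitution probability applied to the
#'   shared copies.
#' @param seed integer seed.
#' @return list with `proteins` (named `Q01`..) and `truth` (data frame
#'   `query_id`, `source_family` with `NA` for decoys).
#' @export
generate_decoy_proteome <- function(n, family_reps, fraction_shared = 0.5,
                                    divergence = 0.4, seed = 1L) {
  stopifnot(fraction_shared >= 0, fraction_shared <= 1, n >= 1L)
  with_seed(seed, {
    n_shared <- round(fraction_shared * n)
    which_shared <- sort(sample.int(n, n_shared))
    pool_chars <- chars_of(paste(family_reps, collapse = ""))
    lens <- nchar(family_reps)
    proteins <- character(n); src <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      if (i %in% which_shared) {
        fam <- sample(names(family_reps), 1L)
        proteins[i] <- mutate_protein(family_reps[[fam]], divergence)
        src[i] <- fam
      } else {
        len <- sample(lens, 1L)
        proteins[i] <- paste0("M", paste(sample(pool_chars, len - 1L,
                                                replace = TRUE),
                                         collapse = ""))
      }
    }
    names(proteins) <- sprintf("Q%02d", seq_len(n))
    list(proteins = proteins,
         truth = data.frame(query_id = names(proteins), source_family = src,
                            stringsAsFactors = FALSE))
  })
}

#' Write a generated set to disk
#'
#' Emits the replicon FASTA, a truth JSON and a truth GFF3 (planted genes).
#'
#' @param set result of [generate_set()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_set <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(set$seqs, file.path(dir, "replicons.fasta"))
  tr <- set$truth
  json <- list(
    classes = as.list(tr$classes),
    subfamily = as.list(tr$subfamily),
    replicons = lapply(tr$replicons, function(x)
      list(id = x$id, length = x$length, ori = x$ori,
           subfamily = x$subfamily,
           genes = x$genes[, c("start", "end", "strand", "family_id")])))
  jsonlite::write_json(json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  lines <- c("##gff-version 3")
  for (x in tr$replicons) {
    lines <- c(lines, sprintf("##sequence-region %s 1 %d", x$id, x$length))
    g <- x$genes
    lines <- c(lines, sprintf(
      "%s\tmge-compare:synth\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;family=%s",
      x$id, g$start + 1L, g$end, g$strand,
      paste0(x$id, "_true", seq_len(nrow(g))), g$family_id))
  }
  writeLines(lines, file.path(dir, "truth.gff3"))
  invisible(dir)
}
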