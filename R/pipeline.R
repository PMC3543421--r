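# end-to-end orchestration: sequences in, comparative report out

#' Configuration for a full comparative run
#'
#' @param fasta character vector of FASTA paths.
#' @param genbank character vector of GenBank flat-file paths.
#' @param out_dir output directory for artifacts.
#' @param orf an [orf_params()].
#' @param homology a [homology_params()].
#' @param skew_window smoothing width (bp) for the GC-skew profile.
#' @param repeat_min_len minimum repeat length (bp).
#' @param intergenic_min_len minimum intergenic region length (bp).
#' @param distance_method `"jaccard"` or `"shared_min"`.
#' @param k number of subfamilies to delineate.
#' @param screen_fasta optional FASTA of proteins to cross-screen against
#'   the gene families (e.g. a viral proteome).
#' @param trust_annotations use GenBank CDS annotations instead of de novo
#'   ORF prediction for records that carry them.
#' @param coding_method passed to [coding_density()].
#' @param seed integer seed (echoed in the report; the pipeline stages are
#'   deterministic).
#' @return list of class `run_config`.
#' @export
run_config <- function(fasta = character(), genbank = character(),
                       out_dir = ".", orf = orf_params(),
                       homology = homology_params(),
                       skew_window = 100L, repeat_min_len = 12L,
                       intergenic_min_len = 150L,
                       distance_method = "jaccard", k = 2L,
                       screen_fasta = NULL, trust_annotations = FALSE,
                       coding_method = "union", seed = 1L) {
  missing <- c(fasta, genbank, screen_fasta)
  missing <- missing[!file.exists(missing)]
  if (length(missing))
    stop("input files not found: ", paste(missing, collapse = ", "))
  structure(list(fasta = fasta, genbank = genbank, out_dir = out_dir,
                 orf = orf, homology = homology,
                 skew_window = as.integer(skew_window),
                 repeat_min_len = as.integer(repeat_min_len),
                 intergenic_min_len = as.integer(intergenic_min_len),
                 distance_method = distance_method, k = as.integer(k),
                 screen_fasta = screen_fasta,
                 trust_annotations = isTRUE(trust_annotations),
                 coding_method = coding_method, seed = as.integer(seed)),
            class = "run_config")
}

# CDS features of one replicon as an ORF-like table with proteins
features_as_orfs <- function(seq, features) {
  cds <- features[features$kind == "CDS", , drop = FALSE]
  if (!nrow(cds)) return(NULL)
  cds <- cds[order(cds$start, cds$end), , drop = FALSE]
  L <- seq$length
  prot <- character(nrow(cds))
  for (i in seq_len(nrow(cds))) {
    minus <- cds$strand[i] == "-"
    posi <- if (minus) circ_positions(cds$start[i] + 3L, cds$end[i], L) else
      circ_positions(cds$start[i], cds$end[i] - 3L, L)
    dna <- paste(chars_of(seq$residues)[posi], collapse = "")
    if (minus) dna <- revcomp(dna)
    prot[i] <- tryCatch(translate_dna(dna, as_start = TRUE),
                        error = function(e) {
                          warning("cannot translate CDS ", i, " on ",
                                  seq$id, ": ", conditionMessage(e))
                          NA_character_
                        })
  }
  data.frame(orf_id = paste0(seq$id, "_gp", seq_len(nrow(cds))),
             seq_id = seq$id, start = cds$start, end = cds$end,
             strand = cds$strand, start_codon = NA_character_,
             n_codons = (cds$end - cds$start) %/% 3L - 1L,
             sd_score = NA_integer_, sd_offset = NA_integer_,
             protein = prot, stringsAsFactors = FALSE)
}

#' Run the full comparative analysis
#'
#' Stages: sequence ingestion, ORF prediction (or trusted annotations),
#' GC-skew origin prediction, all-vs-all homology and gene families,
#' pan-genome matrix, gene-content distances, NJ tree, subfamilies,
#' conservation classes, and optional cross-screening of an external
#' proteome. All artifacts are written under `cfg$out_dir` together with a
#' JSON report and a MANIFEST listing completed stages.
#'
#' @param cfg a [run_config()].
#' @return the report, invisibly: a list with `stats`, `orfs`, `ori`,
#'   `hits`, `families`, `matrix`, `distances`, `newick`, `subfamilies`,
#'   `conservation`, `screen`, `parameters`.
#' @export
run_compare <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  note <- function(x) manifest <<- c(manifest, x)

  # --- ingest ---------------------------------------------------------
  seqs <- list()
  features <- list()
  for (f in cfg$fasta)
    for (s in read_fasta(f)) seqs[[s$id]] <- s
  for (f in cfg$genbank) {
    gb <- read_genbank(f)
    seqs[[gb$seq$id]] <- gb$seq
    features[[gb$seq$id]] <- gb$features
  }
  if (!length(seqs)) stop("stage ingest: no input replicons")
  note("ingest")

  # --- ORFs -----------------------------------------------------------
  orfs_by <- list()
  for (id in names(seqs)) {
    trusted <- cfg$trust_annotations && !is.null(features[[id]]) &&
      nrow(features[[id]]) > 0L
    orfs_by[[id]] <- if (trusted)
      features_as_orfs(seqs[[id]], features[[id]])
    else find_orfs(seqs[[id]], cfg$orf)
  }
  orfs <- do.call(rbind, unname(orfs_by))
  write_orf_gff3(orfs, seqs, file.path(cfg$out_dir, "orfs.gff3"))
  prots <- orf_proteins(orfs)
  prots <- prots[!is.na(prots)]
  writeLines(paste0(">", names(prots), "\n", unname(prots)),
             file.path(cfg$out_dir, "proteins.faa"))
  note("orfs")

  # --- statistics -----------------------------------------------------
  feats_for_stats <- lapply(names(seqs), function(id) {
    if (!is.null(features[[id]]) && nrow(features[[id]]) > 0L)
      features[[id]]
    else {
      o <- orfs_by[[id]]
      annotated_feature("x", 0, 1)[0, ] |>
        rbind(data.frame(seq_id = o$seq_id, start = o$start, end = o$end,
                         strand = o$strand, kind = "CDS", label = o$orf_id,
                         stringsAsFactors = FALSE))
    }
  })
  names(feats_for_stats) <- names(seqs)
  stats <- replicon_stats(seqs, feats_for_stats, cfg$coding_method)
  utils::write.table(stats, file.path(cfg$out_dir, "stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("stats")

  # --- skew / ori -----------------------------------------------------
  ori_by <- list()
  repeats_all <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    prof <- cumulative_skew(s, window = cfg$skew_window)
    regs <- intergenic_regions(s, orfs_by[[id]], cfg$intergenic_min_len)
    reps <- find_repeats(s, cfg$repeat_min_len)
    if (nrow(reps)) repeats_all[[id]] <- cbind(seq_id = id, reps)
    ori_by[[id]] <- tryCatch({
      o <- predict_ori(s, prof, regs, reps)
      if (nrow(o)) write_ori_bed(o, s, file.path(cfg$out_dir,
                                                 paste0(id, ".ori.bed")))
      o
    }, error = function(e) {
      warning("stage skew_ori on ", id, ": ", conditionMessage(e))
      NULL
    })
  }
  if (length(repeats_all))
    utils::write.table(do.call(rbind, repeats_all),
                       file.path(cfg$out_dir, "repeats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  note("skew_ori")

  # --- homology -------------------------------------------------------
  if (length(prots) >= 2L) {
    hits <- all_vs_all(prots, cfg$homology)
    families <- cluster_families(hits, prots)
    write_hits_tsv(hits, file.path(cfg$out_dir, "hits.tsv"))
    utils::write.table(families, file.path(cfg$out_dir, "families.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("homology")
  } else {
    hits <- NULL; families <- NULL
    warning("fewer than 2 proteins: homology stage skipped")
  }

  # --- pangenome ------------------------------------------------------
  m <- NULL; d <- NULL; newick <- NULL; labs <- NULL; classes <- NULL
  if (!is.null(families) && length(seqs) >= 2L) {
    fam_known <- families[!is.na(families$replicon_id), , drop = FALSE]
    m <- presence_matrix(fam_known, names(seqs))
    utils::write.table(m, file.path(cfg$out_dir, "matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    d <- gene_content_distance(m, cfg$distance_method)
    write_phylip(d, file.path(cfg$out_dir, "distances.phy"))
    if (length(seqs) >= 3L) {
      tree <- nj_tree(d)
      newick <- attr(tree, "newick")
      writeLines(newick, file.path(cfg$out_dir, "tree.nwk"))
    } else warning("fewer than 3 replicons: tree stage skipped")
    if (cfg$k <= nrow(m)) {
      labs <- delineate_subfamilies(d, k = cfg$k)
      if (length(unique(labs)) >= 2L) {
        classes <- classify_conservation(m, labs)
        write_conservation_tsv(classes,
                               file.path(cfg$out_dir, "conservation.tsv"))
      }
    }
    note("pangenome")
  } else if (length(seqs) < 2L) {
    warning("single replicon input: pan-genome stages skipped")
  }

  # --- cross-screen ---------------------------------------------------
  screen <- NULL
  if (!is.null(cfg$screen_fasta) && !is.null(families)) {
    qset <- Biostrings::readAAStringSet(cfg$screen_fasta)
    queries <- setNames(as.character(qset),
                        vapply(strsplit(names(qset), "[ \t]"),
                               `[`, "", 1L))
    screen <- cross_screen(queries, families, prots, cfg$homology)
    utils::write.table(screen, file.path(cfg$out_dir, "screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("cross_screen")
  }

  params_echo <- cfg
  params_echo$homology <- unclass(cfg$homology)
  params_echo$orf <- unclass(cfg$orf)
  report <- list(stats = stats, orfs = orfs, ori = ori_by, hits = hits,
                 families = families, matrix = m, distances = d,
                 newick = newick, subfamilies = labs,
                 conservation = classes, screen = screen,
                 parameters = unclass(params_echo),
                 version = as.character(utils::packageVersion("mgecompare")))
  jsonlite::write_json(
    report_json(report), file.path(cfg$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(manifest, file.path(cfg$out_dir, "MANIFEST"))
  invisible(report)
}

# JSON-friendly view of the report
report_json <- function(report) {
  list(
    stats = report$stats,
    orfs = report$orfs[, setdiff(colnames(report$orfs), "protein")],
    ori = lapply(report$ori, function(x) if (is.null(x)) NULL else x),
    families = report$families,
    matrix = if (is.null(report$matrix)) NULL else {
      mm <- report$matrix; attr(mm, "counts") <- NULL
      list(replicons = rownames(mm), families = colnames(mm),
           cells = unname(apply(mm, 1, as.integer, simplify = FALSE)))
    },
    newick = report$newick,
    subfamilies = as.list(report$subfamilies),
    conservation = as.list(report$conservation),
    screen = report$screen,
    parameters = report$parameters[
      c("skew_window", "repeat_min_len", "intergenic_min_len",
        "distance_method", "k", "trust_annotations", "coding_method",
        "seed")],
    version = report$version
  )
}
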