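# pan-genome presence/absence matrix, gene-content distances,
# neighbor-joining trees, subfamily delineation, conservation classes

#' Build the binary presence/absence matrix over gene families
#'
#' A cell is 1 when the replicon carries at least one member of the
#' family; paralogs collapse to presence (per-family member counts are
#' attached as `attr(, "counts")` for future use).
#'
#' @param families membership table from [cluster_families()].
#' @param replicon_ids ordered replicon identifiers (columns of the study).
#' @return binary integer matrix, replicons x families, with dimnames.
#' @export
presence_matrix <- function(families, replicon_ids) {
  if (!nrow(families)) stop("no gene families")
  unknown <- setdiff(unique(families$replicon_id), replicon_ids)
  if (length(unknown))
    stop("families reference unknown replicons: ",
         paste(unknown, collapse = ", "))
  fam_ids <- sort(unique(families$family_id))
  counts <- matrix(0L, nrow = length(replicon_ids), ncol = length(fam_ids),
                   dimnames = list(replicon_ids, fam_ids))
  tab <- table(families$replicon_id, families$family_id)
  counts[rownames(tab), colnames(tab)] <- as.integer(tab)
  m <- (counts > 0L) + 0L
  keep <- colSums(m) > 0L
  m <- m[, keep, drop = FALSE]
  attr(m, "counts") <- counts[, keep, drop = FALSE]
  m
}

#' Gene-content distances between replicons
#'
#' Two defensible formulas for distances from shared gene-family content:
#' `jaccard` (default), `d = 1 - |A n B| / |A u B|`, and `shared_min`,
#' `d = -ln(|A n B| / min(|A|, |B|))` with empty intersections mapped to
#' `ceiling`.
#'
#' @param m presence/absence matrix from [presence_matrix()].
#' @param method `"jaccard"` or `"shared_min"`.
#' @param ceiling distance assigned when two replicons share no family
#'   (`shared_min` only).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
gene_content_distance <- function(m, method = c("jaccard", "shared_min"),
                                  ceiling = 10) {
  method <- match.arg(method)
  if (nrow(m) < 2L) stop("need at least two replicons")
  if (any(rowSums(m) == 0L))
    stop("replicon with zero families: ",
         paste(rownames(m)[rowSums(m) == 0L], collapse = ", "))
  n <- nrow(m)
  shared <- m %*% t(m)                       # |A n B|
  sizes <- diag(shared)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    inter <- shared[i, j]
    if (method == "jaccard") {
      uni <- sizes[i] + sizes[j] - inter
      d[i, j] <- 1 - inter / uni
    } else {
      d[i, j] <- if (inter == 0L) ceiling else
        min(-log(inter / min(sizes[i], sizes[j])), ceiling)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the standard Q criterion, implemented
#' with a deterministic tie-break (the lowest index pair in current row
#' order). Negative branch lengths are clamped to 0 with the deficit
#' shifted to the sister branch. NJ recovers additive distance matrices
#' exactly (topology and branch lengths).
#'
#' @param d symmetric numeric distance matrix with ids as dimnames.
#' @return an unrooted `phylo` tree (ape) with the newick string attached
#'   as `attr(, "newick")`.
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || !all(is.finite(d)))
    stop("distance matrix must be numeric and finite")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # node strings carry partial newick; lengths carried alongside
  nodes <- labels
  D <- d
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest (i, j) pair among minima, row-major
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    cl <- clamp_pair(bi, bj)
    new_node <- sprintf("(%s:%.10g,%s:%.10g)", nodes[i], cl[1],
                        nodes[j], cl[2])
    duk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], duk[keep]),
                c(duk[keep], 0))
    nodes <- c(nodes[keep], new_node)
    dimnames(D2) <- NULL
    D <- D2
  }
  # closed-form star resolution for the final three nodes
  ba <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  bb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  bc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    nodes[1], max(ba, 0), nodes[2], max(bb, 0),
                    nodes[3], max(bc, 0))
  tree <- ape::read.tree(text = newick)
  attr(tree, "newick") <- newick
  tree
}

# clamp negative branch lengths, moving the deficit to the sister branch
clamp_pair <- function(bi, bj) {
  if (bi < 0) { bj <- bj + bi; bi <- 0 }
  if (bj < 0) { bi <- bi + bj; bj <- 0 }
  c(max(bi, 0), max(bj, 0))
}

#' Delineate subfamilies from gene-content distances
#'
#' Single-linkage agglomerative clustering on the distance matrix, cut to
#' `k` clusters (default 2) or at a distance threshold. Deterministic:
#' equal distances resolve by the merge order of [stats::hclust()], which
#' processes ids in matrix order.
#'
#' @param d distance matrix from [gene_content_distance()].
#' @param k number of subfamilies (ignored when `h` is given).
#' @param h distance threshold to cut at instead of `k`.
#' @return named integer vector of subfamily labels (1-based), one per
#'   replicon.
#' @export
delineate_subfamilies <- function(d, k = 2L, h = NULL) {
  if (is.null(h)) {
    if (k < 1L || k > nrow(d))
      stop("k must be between 1 and the number of replicons")
  }
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  if (is.null(h)) stats::cutree(hc, k = k) else stats::cutree(hc, h = h)
}

#' Conservation class of each gene family
#'
#' Classes follow the colour scheme of comparative plasmid maps: `core`
#' (present in all replicons), `semi_conserved` (present in at least one
#' replicon of each subfamily but not all), `group_specific` (present in
#' two or more replicons of exactly one subfamily), `singleton` (present
#' in exactly one replicon).
#'
#' @param m presence/absence matrix from [presence_matrix()].
#' @param labels subfamily labels from [delineate_subfamilies()].
#' @return named character vector, one class per family; the classes
#'   partition the family set.
#' @export
classify_conservation <- function(m, labels) {
  if (!all(rownames(m) %in% names(labels)))
    stop("labels must cover all replicons")
  labels <- labels[rownames(m)]
  if (length(unique(labels)) < 2L)
    stop("need at least 2 subfamilies")
  vapply(colnames(m), function(f) {
    pres <- m[, f] == 1L
    nrep <- sum(pres)
    if (nrep == nrow(m)) return("core")
    if (nrep == 1L) return("singleton")
    groups <- unique(labels[pres])
    if (length(groups) > 1L) "semi_conserved" else "group_specific"
  }, "")
}

CONSERVATION_COLORS <- c(core = "red", semi_conserved = "green",
                         group_specific = "blue", singleton = "grey")

#' Write conservation classes as TSV
#'
#' Adds a colour column matching the conventional comparative-map scheme
#' (core red, semi-conserved green, group-specific blue).
#'
#' @param classes result of [classify_conservation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(classes, path) {
  out <- data.frame(family_id = names(classes), class = unname(classes),
                    color = unname(CONSERVATION_COLORS[classes]),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d symmetric distance matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(formatC(rownames(d)[i], width = -10),
                     paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  }
  invisible(path)
}
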