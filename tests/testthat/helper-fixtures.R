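# build small plain-text fixtures in code at test time

# minimal GenBank flat-file writer (fixtures only)
write_genbank_fixture <- function(path, id, residues, features,
                                  circular = TRUE) {
  L <- nchar(residues)
  lines <- c(sprintf("LOCUS       %s %d bp    DNA     %s ARC 01-JAN-2020",
                     id, L, if (circular) "circular" else "linear"),
             sprintf("DEFINITION  synthetic fixture %s.", id),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", L))
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    loc <- f$location
    lines <- c(lines,
               sprintf("     CDS             %s", loc),
               sprintf("                     /gene=\"%s\"", f$gene))
  }
  lines <- c(lines, "ORIGIN")
  for (i in seq(1L, L, 60L)) {
    block <- substr(residues, i, min(i + 59L, L))
    chunks <- substring(block, seq(1, nchar(block), 10),
                        pmin(seq(10, nchar(block) + 9, 10), nchar(block)))
    lines <- c(lines, sprintf("%9d %s", i, paste(tolower(chunks),
                                                 collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  path
}

# a small circular sequence carrying one forward gene, one reverse gene
# and one origin-spanning gene, with known coordinates
genbank_fixture <- function(path) {
  set.seed(4711)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  gene <- function(n) paste0("ATG", paste(sample(sense, n, replace = TRUE),
                                          collapse = ""), "TAA")
  g1 <- gene(45)   # 141 bp at 101..241 (1-based)
  g2 <- gene(50)   # 156 bp complement at 301..456
  g3 <- gene(40)   # 126 bp spanning the origin: 575..600 + 1..100
  spacer <- function(n) random_dna(n)
  res <- paste0(spacer(100), g1, spacer(59),
                orc_revcomp(g2), spacer(118))
  # res is 574 bp here; append the wrap gene: last 26 bp at the end,
  # first 100 bp recycled at the start
  stopifnot(nchar(res) == 574)
  res <- paste0(substr(g3, 27, 126), substr(res, 101, 574),
                substr(g3, 1, 26))
  stopifnot(nchar(res) == 600)
  feats <- data.frame(
    location = c("101..241", "complement(301..456)",
                 "join(575..600,1..100)"),
    gene = c("g1", "g2", "g3"), stringsAsFactors = FALSE)
  write_genbank_fixture(path, "SYNFIX1", res, feats)
  list(path = path, length = 600L,
       expected = data.frame(
         start = c(100L, 300L, 574L), end = c(241L, 456L, 700L),
         strand = c("+", "-", "+"), stringsAsFactors = FALSE))
}
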