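# shared internal helpers: circular interval arithmetic and small utilities

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' @param x a DNA character string over A/C/G/T/N.
#' @return the reverse complement as a character string.
#' @export
revcomp <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  paste(rev(unname(COMPLEMENT[chars])), collapse = "")
}

# positions of a wrap-aware interval [start, end) on a circle of length L,
# 1-based for R string/vector indexing
circ_positions <- function(start, end, L) {
  stopifnot(start >= 0, start < L, end > start, end - start <= L)
  ((start:(end - 1L)) %% L) + 1L
}

# circular gap between a point and an interval [start, end) (0 if inside)
circ_point_to_interval <- function(p, start, end, L) {
  pos <- p %% L
  s <- start %% L
  len <- end - start
  # offset of pos from s going clockwise
  off <- (pos - s) %% L
  if (off < len) return(0L)
  # distance past the end vs distance before the start
  min(off - len + 1L, L - off)
}

# smallest circular distance between two points
circ_dist <- function(a, b, L) {
  d <- abs((a %% L) - (b %% L))
  min(d, L - d)
}

chars_of <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

rotate_string <- function(x, k) {
  n <- nchar(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  paste0(substr(x, k + 1L, n), substr(x, 1L, k))
}
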