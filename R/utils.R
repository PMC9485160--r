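# shared low-level helpers

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; `N` maps to `N`.
#'
#' @param x character vector of DNA strings over `{A,C,G,T,N}`.
#' @return character vector of the same length.
#' @export
#' @examples
#' reverse_complement(c("ACGT", "AAN"))
reverse_complement <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# Hamming distance between equal-length strings; vectorised over `a`.
hamming_dist <- function(a, b) {
  stopifnot(all(nchar(a) == nchar(b)))
  am <- strsplit(a, "", fixed = TRUE)
  bm <- strsplit(b, "", fixed = TRUE)
  mapply(function(u, v) sum(u != v), am, bm, USE.NAMES = FALSE)
}

# Hamming distances from one query string to a vector of same-length strings.
# Matrix-free and fast enough for whitelists of a few thousand barcodes.
hamming_to_all <- function(query, pool) {
  if (length(pool) == 0L) return(integer(0))
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  pm <- matrix(unlist(strsplit(pool, "", fixed = TRUE)), nrow = length(q))
  colSums(pm != q)
}

# All k-length windows of a single string, in order; character(0) if too short.
str_windows <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(s, starts, starts + k - 1L)
}

random_dna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

# deterministic distinct DNA strings (index encoded base-4)
indexed_dna <- function(idx, len) {
  bases <- c("A", "C", "G", "T")
  vapply(idx, function(i) {
    d <- integer(len)
    v <- i
    for (p in seq_len(len)) {
      d[p] <- v %% 4L
      v <- v %/% 4L
    }
    paste(bases[d + 1L], collapse = "")
  }, character(1))
}

write_tsv_plain <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
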