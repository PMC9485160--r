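# Shared fixtures built in code: a 30-nt three-exon toy transcript and
# small FASTQ writers. All randomness in tests is locally seeded.

toy_model <- function() {
  transcript_model(
    "ACGTACTGACTTGACCTGAAGGCTATCGAT",
    data.frame(exon_index = 1:3, start = c(1, 11, 21), end = c(10, 20, 30))
  )
}

# transcript in which exon 2 and exon 3 start with the same 5 bases, so
# short-overhang skip probes collide with the unmodified transcript
shared_prefix_model <- function() {
  transcript_model(
    paste0("AAAACCCCGG", "GGGAACCCAA", "GGGTTACGTA"),
    data.frame(exon_index = 1:3, start = c(1, 11, 21), end = c(10, 20, 30))
  )
}

write_fastq_pair <- function(ids, r1, r2,
                             dir = withr::local_tempdir(.local_envir = parent.frame()),
                             gz = TRUE) {
  ext <- if (gz) ".fastq.gz" else ".fastq"
  p1 <- file.path(dir, paste0("R1", ext))
  p2 <- file.path(dir, paste0("R2", ext))
  wr <- function(ids, seqs, path) {
    con <- if (gz) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                      vapply(nchar(seqs), function(n) strrep("I", n),
                             character(1))), con)
  }
  wr(ids, r1, p1)
  wr(ids, r2, p2)
  list(r1 = p1, r2 = p2)
}

# deterministic distinct DNA strings (index encoded base-4)
indexed_dna_test <- function(idx, len) {
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

random_reads <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# naive reference scanner: test every window against the probe table
naive_scan <- function(cdna, kmers) {
  k <- nchar(kmers$kmer[1])
  n <- nchar(cdna)
  out <- list()
  if (n >= k) {
    for (s in seq_len(n - k + 1)) {
      w <- substr(cdna, s, s + k - 1)
      i <- which(kmers$kmer == w)
      if (length(i) == 1) {
        out[[length(out) + 1]] <- tibble::tibble(
          junction = kmers$junction[i], position = s - 1L,
          strand = kmers$strand[i])
      }
    }
  }
  if (length(out) == 0) {
    tibble::tibble(junction = character(), position = integer(),
                   strand = character())
  } else do.call(rbind, out)
}

# enumeration oracle for the exact Mann-Whitney null: all C(n1+n2, n1)
# rank assignments
enumerate_mw_counts <- function(n1, n2) {
  N <- n1 + n2
  counts <- numeric(n1 * n2 + 1)
  for (combo in asplit(utils::combn(N, n1), 2)) {
    ranks_x <- combo
    # U = #pairs x > y = sum over x of (rank - its position among x's)
    u <- sum(ranks_x) - n1 * (n1 + 1) / 2
    counts[u + 1] <- counts[u + 1] + 1
  }
  counts
}
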