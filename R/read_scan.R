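#' Droplet chemistry specification
#'
#' Describes how read 1 of a droplet library is laid out: the first
#' `barcode_len` bases are the cell barcode and the next `umi_len` bases the
#' UMI. `"v3"` is 10x Chromium Single Cell 3' v3 (16 + 12), `"v2"` is 16 + 10.
#'
#' @param name `"v3"`, `"v2"`, or `"custom"`.
#' @param barcode_len,umi_len explicit lengths for `"custom"`.
#' @return list with `barcode_len` and `umi_len`.
#' @export
chemistry <- function(name = c("v3", "v2", "custom"),
                      barcode_len = NULL, umi_len = NULL) {
  name <- match.arg(name)
  out <- switch(name,
    v3 = list(barcode_len = 16L, umi_len = 12L),
    v2 = list(barcode_len = 16L, umi_len = 10L),
    custom = list(barcode_len = as.integer(barcode_len),
                  umi_len = as.integer(umi_len))
  )
  if (is.null(out$barcode_len) || is.null(out$umi_len) ||
      out$barcode_len < 1L || out$umi_len < 1L) {
    abort("chemistry requires barcode_len >= 1 and umi_len >= 1")
  }
  out
}

# Read one chunk of 4-line FASTQ records from an open connection.
# Returns NULL at EOF; errors on a truncated final record.
read_fastq_chunk <- function(con, n_records, what) {
  lines <- readLines(con, n = 4L * n_records)
  if (length(lines) == 0L) return(NULL)
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("truncated FASTQ record at end of %s", what))
  }
  ids <- lines[seq(1L, length(lines), by = 4L)]
  if (!all(startsWith(ids, "@"))) {
    abort(sprintf("malformed FASTQ header in %s", what))
  }
  list(
    id = sub("/[12]$", "", sub("\\s.*$", "", substring(ids, 2L))),
    seq = toupper(lines[seq(2L, length(lines), by = 4L)])
  )
}

fastq_connection <- function(path) {
  con <- gzfile(path, open = "rt")   # transparent for plain text too
  con
}

#' Scan one cDNA sequence for junction k-mers
#'
#' Exact substring matching only: the result is identical to testing every
#' k-length window of `cdna` against the probe table. Windows containing `N`
#' never match (probes never contain `N`).
#'
#' @param cdna a DNA string (read 2 sequence).
#' @param kmers a `kmer_set` from [design_kmers()].
#' @return tibble with one row per probe occurrence: `junction`, `position`
#'   (0-based offset of the probe within `cdna`), `strand`, ordered by
#'   position. Zero rows when nothing matches or the read is shorter than k.
#' @export
scan_read <- function(cdna, kmers) {
  k <- attr(kmers, "k") %||% nchar(kmers$kmer[1])
  win <- str_windows(cdna, k)
  m <- match(win, kmers$kmer)
  hit <- which(!is.na(m))
  tibble(
    junction = kmers$junction[m[hit]],
    position = hit - 1L,
    strand = kmers$strand[m[hit]]
  )
}

# Vectorised scan of many reads; returns (read index, position, kmer index).
scan_cdna_block <- function(cdna, kmer_strings, k) {
  nw <- pmax(nchar(cdna) - k + 1L, 0L)
  if (sum(nw) == 0L) {
    return(list(read = integer(0), position = integer(0), ki = integer(0)))
  }
  idx <- rep(seq_along(cdna), nw)
  starts <- sequence(nw)
  win <- substring(cdna[idx], starts, starts + k - 1L)
  m <- match(win, kmer_strings)
  hit <- which(!is.na(m))
  list(read = idx[hit], position = starts[hit] - 1L, ki = m[hit])
}

#' Scan a paired FASTQ library for junction k-mer hits
#'
#' Streams mate pairs in fixed-size chunks (memory does not grow with file
#' size), splits read 1 into barcode and UMI by the chemistry lengths, and
#' exact-matches every probe against read 2. Mates are paired by file order;
#' a read-id mismatch between the files is a hard error naming the record,
#' since it signals desynchronized files. Read-1 records shorter than
#' `barcode_len + umi_len` are counted malformed and skipped.
#'
#' @param r1_path,r2_path paths to read-1 and read-2 FASTQ files (plain or
#'   gzip).
#' @param kmers a `kmer_set`.
#' @param chem a [chemistry()] specification.
#' @param chunk_size records per streaming chunk.
#' @return list with `hits` (tibble `read_id`, `barcode`, `umi`, `junction`,
#'   `position`, `strand`) and `stats` (list: `reads_processed`,
#'   `reads_with_hit` named per junction, `reads_multi_junction`,
#'   `reads_skipped_malformed`).
#' @export
scan_library <- function(r1_path, r2_path, kmers, chem = chemistry("v3"),
                         chunk_size = 10000L) {
  k <- attr(kmers, "k") %||% nchar(kmers$kmer[1])
  bc_umi <- chem$barcode_len + chem$umi_len
  con1 <- fastq_connection(r1_path)
  con2 <- fastq_connection(r2_path)
  on.exit({ close(con1); close(con2) }, add = TRUE)

  hits <- list()
  n_proc <- 0L
  n_malformed <- 0L
  n_multi <- 0L
  per_junction <- setNames(rep(0L, length(unique(kmers$junction))),
                           sort(unique(kmers$junction)))
  record_base <- 0L

  repeat {
    c1 <- read_fastq_chunk(con1, chunk_size, r1_path)
    c2 <- read_fastq_chunk(con2, chunk_size, r2_path)
    if (is.null(c1) && is.null(c2)) break
    if (is.null(c1) || is.null(c2) || length(c1$id) != length(c2$id)) {
      abort(sprintf("FASTQ files desynchronized near record %d: unequal record counts",
                    record_base + 1L))
    }
    bad_id <- which(c1$id != c2$id)
    if (length(bad_id) > 0L) {
      abort(sprintf("read id mismatch at record %d: '%s' vs '%s'",
                    record_base + bad_id[1], c1$id[bad_id[1]],
                    c2$id[bad_id[1]]))
    }
    n <- length(c1$id)
    malformed <- nchar(c1$seq) < bc_umi
    n_malformed <- n_malformed + sum(malformed)
    n_proc <- n_proc + n
    ok <- which(!malformed)
    if (length(ok) > 0L) {
      res <- scan_cdna_block(c2$seq[ok], kmers$kmer, k)
      if (length(res$read) > 0L) {
        ri <- ok[res$read]
        chunk_hits <- tibble(
          read_id = c1$id[ri],
          barcode = substr(c1$seq[ri], 1L, chem$barcode_len),
          umi = substr(c1$seq[ri], chem$barcode_len + 1L, bc_umi),
          junction = kmers$junction[res$ki],
          position = res$position,
          strand = kmers$strand[res$ki]
        )
        hits[[length(hits) + 1L]] <- chunk_hits
        per_read <- chunk_hits |> distinct(.data$read_id, .data$junction)
        tab <- table(per_read$junction)
        per_junction[names(tab)] <- per_junction[names(tab)] + as.integer(tab)
        n_multi <- n_multi +
          sum(table(per_read$read_id) >= 2L)
      }
    }
    record_base <- record_base + n
    if (n < chunk_size) next
  }

  hits <- if (length(hits) > 0L) bind_rows(hits) else
    tibble(read_id = character(), barcode = character(), umi = character(),
           junction = character(), position = integer(), strand = character())
  list(
    hits = hits,
    stats = list(
      reads_processed = n_proc,
      reads_with_hit = as.list(per_junction),
      reads_multi_junction = n_multi,
      reads_skipped_malformed = n_malformed
    )
  )
}
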