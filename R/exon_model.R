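#' Build a spliced transcript model
#'
#' A transcript model couples a spliced (mRNA) sequence with its ordered exon
#' segments in transcript coordinates. Exons must tile the sequence without
#' gaps or overlaps: exon 1 starts at base 1, each exon starts one base after
#' the previous one ends, and the last exon ends at the sequence length.
#'
#' @param sequence DNA string over `{A,C,G,T,N}` (case-insensitive; `U` is
#'   converted to `T`).
#' @param exons data frame with columns `exon_index`, `start`, `end`
#'   (1-based, inclusive, transcript coordinates).
#' @param transcript_id accession or name for the transcript.
#' @return an object of class `transcript_model`: a list with elements
#'   `transcript_id`, `sequence` and `exons` (a tibble).
#' @export
#' @examples
#' tm <- transcript_model(
#'   paste(rep("ACGTTGCAAC", 3), collapse = ""),
#'   data.frame(exon_index = 1:3, start = c(1, 11, 21), end = c(10, 20, 30))
#' )
#' tm
transcript_model <- function(sequence, exons, transcript_id = "transcript") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq_up <- toupper(sequence)
  seq_up <- gsub("U", "T", seq_up, fixed = TRUE)
  bad <- regexpr("[^ACGTN]", seq_up)
  if (bad > 0L) {
    abort(sprintf("invalid character '%s' at position %d of transcript sequence",
                  substr(seq_up, bad, bad), bad))
  }
  exons <- as_tibble(exons)
  req <- c("exon_index", "start", "end")
  if (!all(req %in% names(exons))) {
    abort("exon table must have columns exon_index, start, end")
  }
  exons <- exons |>
    mutate(across(all_of(req), as.integer)) |>
    arrange(.data$exon_index)
  if (nrow(exons) == 0L) abort("exon table is empty")
  if (any(diff(exons$exon_index) <= 0L)) {
    abort("exon indices must be strictly increasing")
  }
  if (any(exons$end < exons$start)) {
    i <- which(exons$end < exons$start)[1]
    abort(sprintf("exon %d has end < start", exons$exon_index[i]))
  }
  if (exons$start[1] != 1L) {
    abort(sprintf("exon %d must start at base 1", exons$exon_index[1]))
  }
  if (nrow(exons) > 1L) {
    gap <- which(exons$start[-1] != exons$end[-nrow(exons)] + 1L)
    if (length(gap) > 0L) {
      i <- gap[1]
      abort(sprintf("gap between exon %d and exon %d",
                    exons$exon_index[i], exons$exon_index[i + 1L]))
    }
  }
  if (exons$end[nrow(exons)] != nchar(seq_up)) {
    abort(sprintf("exon %d ends at %d but sequence length is %d",
                  exons$exon_index[nrow(exons)], exons$end[nrow(exons)],
                  nchar(seq_up)))
  }
  structure(
    list(transcript_id = transcript_id, sequence = seq_up, exons = exons),
    class = "transcript_model"
  )
}

#' @export
#' @method print transcript_model
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s: %d bp, %d exons\n",
              x$transcript_id, nchar(x$sequence), nrow(x$exons)))
  invisible(x)
}

#' Load a transcript model from FASTA and an exon table
#'
#' @param fasta_path path to a single-record FASTA file (mRNA sequence).
#' @param exon_table_path path to a TSV with header
#'   `exon_index<TAB>start<TAB>end` in 1-based inclusive transcript
#'   coordinates.
#' @return a [transcript_model()].
#' @export
load_transcript <- function(fasta_path, exon_table_path) {
  recs <- Biostrings::readBStringSet(fasta_path)
  if (length(recs) != 1L) {
    abort(sprintf("FASTA must contain exactly one record, found %d",
                  length(recs)))
  }
  exons <- readr::read_tsv(exon_table_path, show_col_types = FALSE,
                           progress = FALSE)
  id <- sub("\\s.*$", "", names(recs)[1])
  transcript_model(as.character(recs[[1]]), exons, transcript_id = id)
}

#' Define exon-junction specifications
#'
#' A junction joins the end of `left_exon` to the start of `right_exon`.
#' Adjacent exons (`right_exon == left_exon + 1`) give a canonical splice
#' junction; a larger gap gives a skipping junction in which all intervening
#' exons are absent (e.g. `e22-e24` marks skipping of exon 23).
#'
#' @param labels character vector like `c("e22-e23", "e22-e24")`, or `NULL`
#'   when `left` and `right` are given.
#' @param left,right integer vectors of exon indices (used when `labels` is
#'   `NULL`).
#' @return tibble with columns `left_exon`, `right_exon`, `label`,
#'   `is_skipping`.
#' @export
#' @examples
#' junction_specs(c("e22-e23", "e23-e24", "e22-e24"))
junction_specs <- function(labels = NULL, left = NULL, right = NULL) {
  if (!is.null(labels)) {
    m <- stringr::str_match(labels, "^e?(\\d+)[-_]e?(\\d+)$")
    if (anyNA(m[, 1])) {
      abort(sprintf("cannot parse junction label '%s'",
                    labels[which(is.na(m[, 1]))[1]]))
    }
    left <- as.integer(m[, 2])
    right <- as.integer(m[, 3])
  } else {
    left <- as.integer(left)
    right <- as.integer(right)
    labels <- sprintf("e%d-e%d", left, right)
  }
  if (any(right <= left)) {
    abort("right_exon must be greater than left_exon for every junction")
  }
  tibble(left_exon = left, right_exon = right, label = labels,
         is_skipping = right > left + 1L)
}

exon_substring <- function(model, idx) {
  row <- model$exons[model$exons$exon_index == idx, ]
  if (nrow(row) == 0L) abort(sprintf("exon %d not in model", idx))
  substr(model$sequence, row$start, row$end)
}

#' Extract the sequence context of a junction
#'
#' Concatenates the last `flank` bases of the left exon with the first
#' `flank` bases of the right exon; for a skipping junction the intervening
#' exon sequence is absent. Flanks are truncated to the exon length when an
#' exon is shorter than `flank`.
#'
#' @param model a [transcript_model()].
#' @param left_exon,right_exon exon indices of the junction.
#' @param flank number of bases requested on each side (>= 1).
#' @return a DNA string; its junction point sits after
#'   `min(flank, left exon length)` bases (attribute `junction_at`).
#' @export
junction_sequence <- function(model, left_exon, right_exon, flank) {
  stopifnot(inherits(model, "transcript_model"), flank >= 1)
  ls <- exon_substring(model, left_exon)
  rs <- exon_substring(model, right_exon)
  lf <- min(flank, nchar(ls))
  rf <- min(flank, nchar(rs))
  out <- paste0(substr(ls, nchar(ls) - lf + 1L, nchar(ls)),
                substr(rs, 1L, rf))
  attr(out, "junction_at") <- lf
  out
}

#' Design junction-spanning k-mer probes
#'
#' Enumerates every k-length window of each junction's context sequence whose
#' junction point lies at least `min_overhang` bases from both window ends,
#' giving `k - 2*min_overhang + 1` candidates per junction per strand when
#' the flanking exons are long enough. With `screen = TRUE`, candidates for a
#' skipping junction that also occur in the full unmodified transcript (either
#' strand), and candidates occurring in another junction's context sequence,
#' are moved to the `dropped` attribute with a reason — such probes could not
#' distinguish splice forms. Candidates containing `N` are never emitted.
#'
#' @param model a [transcript_model()].
#' @param specs junction table from [junction_specs()].
#' @param k probe length in bases.
#' @param min_overhang minimum bases required on each side of the junction
#'   point within a probe.
#' @param strand_mode `"both"` adds the reverse complement of every surviving
#'   sense probe as an antisense entry; `"sense"` emits sense probes only.
#' @param screen logical; apply the cross-reactivity screen described above.
#' @return a `kmer_set`: a tibble with columns `kmer`, `junction`, `offset`
#'   (bases of the left exon inside the probe), `strand`, and attributes `k`,
#'   `min_overhang`, `dropped` (tibble of removed candidates with reasons).
#' @export
#' @examples
#' tm <- transcript_model(
#'   "ACGTACTGACTTGACCTGAAGGCTATCGAT",
#'   data.frame(exon_index = 1:3, start = c(1, 11, 21), end = c(10, 20, 30))
#' )
#' design_kmers(tm, junction_specs(c("e1-e2", "e1-e3")), k = 8)
design_kmers <- function(model, specs, k = 25L, min_overhang = 1L,
                         strand_mode = c("both", "sense"), screen = TRUE) {
  strand_mode <- match.arg(strand_mode)
  k <- as.integer(k)
  min_overhang <- as.integer(min_overhang)
  if (k < 2L * min_overhang) {
    abort(sprintf("k (%d) must be at least 2*min_overhang (%d)",
                  k, 2L * min_overhang))
  }
  specs <- as_tibble(specs)
  if (!"is_skipping" %in% names(specs)) {
    specs$is_skipping <- specs$right_exon > specs$left_exon + 1L
  }

  flank <- k - min_overhang
  jseqs <- pmap(specs, function(left_exon, right_exon, label, is_skipping) {
    junction_sequence(model, left_exon, right_exon, flank)
  })
  names(jseqs) <- specs$label

  cand <- purrr::imap(jseqs, function(js, lab) {
    jat <- attr(js, "junction_at")
    win <- str_windows(js, k)
    if (length(win) == 0L) {
      return(tibble(kmer = character(), junction = character(),
                    offset = integer()))
    }
    starts <- seq_along(win)
    offset <- jat - starts + 1L   # left-exon bases inside the window
    keep <- offset >= min_overhang & offset <= k - min_overhang
    tibble(kmer = win[keep], junction = lab, offset = offset[keep])
  }) |> bind_rows()

  dropped <- tibble(kmer = character(), junction = character(),
                    offset = integer(), reason = character())
  take <- function(df, mask, reason) {
    if (any(mask)) {
      dropped <<- bind_rows(dropped, df[mask, ] |> mutate(reason = reason))
    }
    df[!mask, ]
  }

  cand <- take(cand, grepl("N", cand$kmer, fixed = TRUE), "contains N")

  if (screen && nrow(cand) > 0L) {
    tx <- model$sequence
    tx_rc <- reverse_complement(tx)
    skip_lab <- specs$label[specs$is_skipping]
    in_tx <- cand$junction %in% skip_lab &
      (vapply(cand$kmer, grepl, logical(1), x = tx, fixed = TRUE) |
         vapply(cand$kmer, grepl, logical(1), x = tx_rc, fixed = TRUE))
    cand <- take(cand, in_tx, "matches unmodified transcript")

    if (nrow(cand) > 0L) {
      other_hit <- vapply(seq_len(nrow(cand)), function(i) {
        others <- setdiff(specs$label, cand$junction[i])
        any(vapply(others, function(lab) {
          grepl(cand$kmer[i], jseqs[[lab]], fixed = TRUE)
        }, logical(1)))
      }, logical(1))
      cand <- take(cand, other_hit, "matches another junction sequence")
    }
  }

  # one junction label per probe string, always
  dup <- cand$kmer %in% cand$kmer[duplicated(cand$kmer)]
  cand <- take(cand, dup, "ambiguous across junctions")

  gone <- setdiff(specs$label, unique(cand$junction))
  if (length(gone) > 0L) {
    abort(sprintf("no surviving k-mers for junction %s",
                  paste(gone, collapse = ", ")))
  }

  cand$strand <- "sense"
  if (strand_mode == "both") {
    anti <- cand |> mutate(kmer = reverse_complement(.data$kmer),
                           strand = "antisense")
    cand <- bind_rows(cand, anti) |>
      distinct(.data$kmer, .keep_all = TRUE)   # palindromes collapse to sense
  }
  cand <- cand |> arrange(.data$junction, .data$strand, .data$offset)

  structure(cand,
            class = c("kmer_set", class(tibble())),
            k = k, min_overhang = min_overhang,
            strand_mode = strand_mode, screened = screen,
            dropped = dropped)
}

#' Write and read a k-mer probe set
#'
#' The probe table is written as TSV (`kmer junction offset strand`) with a
#' JSON sidecar (`<path>.json`) recording `k`, `min_overhang`, the strand
#' mode and the screening report.
#'
#' @param x a `kmer_set` from [design_kmers()].
#' @param path output TSV path.
#' @return `path`, invisibly (`write_kmer_set`); a `kmer_set`
#'   (`read_kmer_set`).
#' @export
write_kmer_set <- function(x, path) {
  write_tsv_plain(as_tibble(x), path)
  meta <- list(
    k = attr(x, "k"),
    min_overhang = attr(x, "min_overhang"),
    strand_mode = attr(x, "strand_mode"),
    screened = attr(x, "screened"),
    dropped = attr(x, "dropped")
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_kmer_set
#' @export
read_kmer_set <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tab <- tibble(kmer = raw$kmer, junction = raw$junction,
                offset = as.integer(raw$offset), strand = raw$strand)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  dropped <- tibble(kmer = character(), junction = character(),
                    offset = integer(), reason = character())
  if (length(meta$dropped %||% list()) > 0L) {
    dropped <- bind_rows(lapply(meta$dropped, as_tibble)) |>
      mutate(offset = as.integer(.data$offset))
  }
  structure(tab,
            class = c("kmer_set", class(tibble())),
            k = as.integer(meta$k %||% unique(nchar(tab$kmer))[1]),
            min_overhang = as.integer(meta$min_overhang %||% 1L),
            strand_mode = meta$strand_mode %||% "both",
            screened = meta$screened %||% TRUE,
            dropped = dropped)
}
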