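#' Read a cell-barcode whitelist
#'
#' One barcode per line; all entries must share one length.
#'
#' @param path text file path.
#' @return character vector of barcodes.
#' @export
read_whitelist <- function(path) {
  wl <- readLines(path)
  wl <- wl[nzchar(wl)]
  if (length(wl) == 0L) abort("whitelist is empty")
  if (length(unique(nchar(wl))) != 1L) {
    abort("whitelist barcodes must all have the same length")
  }
  toupper(wl)
}

#' Correct a raw cell barcode against a whitelist
#'
#' An exact whitelist member is returned as-is; otherwise, if exactly one
#' whitelist entry lies within `max_hamming` substitutions, that entry is
#' returned; otherwise `NA` (the read is dropped from quantification).
#'
#' @param raw character vector of observed barcodes.
#' @param whitelist character vector of valid barcodes (uniform length).
#' @param max_hamming maximum substitutions allowed for rescue.
#' @return character vector: corrected barcode or `NA` per input.
#' @export
#' @examples
#' wl <- c("AAAA", "CCCC", "GGGG")
#' correct_barcode(c("AAAA", "AAAT", "ACCC", "ACGT"), wl)
correct_barcode <- function(raw, whitelist, max_hamming = 1L) {
  wl_len <- unique(nchar(whitelist))
  if (length(wl_len) != 1L) abort("whitelist barcodes must have uniform length")
  if (any(nchar(raw) != wl_len)) {
    abort(sprintf("barcode length %d does not match whitelist length %d",
                  nchar(raw)[which(nchar(raw) != wl_len)[1]], wl_len))
  }
  exact <- raw %in% whitelist
  out <- ifelse(exact, raw, NA_character_)
  todo <- which(!exact)
  if (length(todo) > 0L && max_hamming > 0L) {
    fixes <- vapply(unique(raw[todo]), function(b) {
      d <- hamming_to_all(b, whitelist)
      cand <- which(d <= max_hamming)
      if (length(cand) == 1L) whitelist[cand] else NA_character_
    }, character(1))
    out[todo] <- fixes[raw[todo]]
  }
  unname(out)
}

# Directional Hamming-1 collapse of UMIs within one (barcode, junction)
# group. A strictly higher-support UMI absorbs a neighbour when
# support(parent) >= 2*support(child) - 1; the strict inequality keeps
# equal-support UMIs separate, which makes the collapse idempotent.
# Parents are chosen in decreasing support order, ties lexicographic.
collapse_umis_directional <- function(umis, support) {
  n <- length(umis)
  if (n <= 1L) return(seq_len(n))
  ord <- order(-support, umis)
  parent <- rep(NA_integer_, n)
  for (i in ord) {
    if (!is.na(parent[i])) next
    parent[i] <- i
    repeat {
      members <- which(parent == i)
      free <- which(is.na(parent))
      if (length(free) == 0L) break
      absorb <- free[vapply(free, function(j) {
        support[i] > support[j] &&
          support[i] >= 2L * support[j] - 1L &&
          any(hamming_dist(rep(umis[j], length(members)), umis[members]) == 1L)
      }, logical(1))]
      if (length(absorb) == 0L) break
      parent[absorb] <- i
    }
  }
  parent
}

#' Collapse PCR duplicates to unique molecules
#'
#' Reads sharing a (cell barcode, UMI, junction) triple are PCR duplicates of
#' one original molecule and collapse to a single record whose `support` is
#' the number of distinct reads. Optionally corrects barcodes against a
#' whitelist first (reads whose barcode cannot be rescued are discarded and
#' counted) and optionally merges sequencing-error UMIs into a
#' higher-support UMI at Hamming distance 1 (directional rule).
#'
#' @param hits hit table from [scan_library()] (`$hits`), or any data frame
#'   with columns `barcode`, `umi`, `junction` and optionally `read_id`.
#' @param whitelist optional character vector from [read_whitelist()].
#' @param umi_collapse `"exact"` (identical UMIs only) or `"hamming1"`
#'   (directional merge of near-duplicate UMIs).
#' @param max_hamming barcode-correction distance when `whitelist` is given.
#' @return list with `molecules` (tibble `barcode`, `umi`, `junction`,
#'   `support`) and `stats` (`reads_in`, `molecules_out`,
#'   `reads_discarded_barcode`, `barcodes_discarded`).
#' @export
dedup <- function(hits, whitelist = NULL,
                  umi_collapse = c("exact", "hamming1"), max_hamming = 1L) {
  umi_collapse <- match.arg(umi_collapse)
  hits <- as_tibble(hits)
  reads_in <- if ("read_id" %in% names(hits)) {
    nrow(distinct(hits, .data$read_id, .data$junction))
  } else nrow(hits)

  discarded_reads <- 0L
  discarded_barcodes <- 0L
  if (!is.null(whitelist)) {
    corrected <- correct_barcode(hits$barcode, whitelist, max_hamming)
    bad <- is.na(corrected)
    discarded_reads <- sum(bad)
    discarded_barcodes <- length(unique(hits$barcode[bad]))
    hits <- hits[!bad, ]
    hits$barcode <- corrected[!bad]
  }

  mol <- if ("read_id" %in% names(hits)) {
    hits |>
      distinct(.data$read_id, .data$barcode, .data$umi, .data$junction) |>
      count(.data$barcode, .data$umi, .data$junction, name = "support")
  } else {
    hits |> count(.data$barcode, .data$umi, .data$junction, name = "support")
  }

  if (umi_collapse == "hamming1" && nrow(mol) > 0L) {
    mol <- mol |>
      group_by(.data$barcode, .data$junction) |>
      group_modify(function(df, key) {
        p <- collapse_umis_directional(df$umi, df$support)
        df |>
          mutate(umi = df$umi[p]) |>
          group_by(.data$umi) |>
          summarise(support = sum(.data$support), .groups = "drop")
      }) |>
      ungroup() |>
      select("barcode", "umi", "junction", "support")
  }
  mol <- mol |> arrange(.data$barcode, .data$junction, .data$umi)

  list(
    molecules = mol,
    stats = list(
      reads_in = reads_in,
      molecules_out = nrow(mol),
      reads_discarded_barcode = discarded_reads,
      barcodes_discarded = discarded_barcodes
    )
  )
}

#' Classify molecules as skipped or unskipped per cell
#'
#' Molecules at a skipping junction (non-adjacent exon pair) count as
#' skipped; molecules at a canonical junction as unskipped. A single
#' (barcode, UMI) observed at both a skipping and a canonical junction is
#' biologically impossible for mutually exclusive splice forms and is
#' counted as ambiguous, excluded from both classes.
#'
#' @param molecules molecule tibble from [dedup()] (`$molecules`).
#' @param specs junction table from [junction_specs()] covering every label
#'   present in `molecules`.
#' @return tibble with one row per barcode: `barcode`, `unskipped`,
#'   `skipped`, `ambiguous` molecule counts.
#' @export
classify_molecules <- function(molecules, specs) {
  specs <- as_tibble(specs)
  unknown <- setdiff(unique(molecules$junction), specs$label)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown junction label: %s", paste(unknown, collapse = ", ")))
  }
  mol <- molecules |>
    left_join(specs |> select("label", "is_skipping"),
              by = c(junction = "label"))
  amb <- mol |>
    group_by(.data$barcode, .data$umi) |>
    summarise(both = any(.data$is_skipping) && any(!.data$is_skipping),
              .groups = "drop") |>
    filter(.data$both)
  # an ambiguous (barcode, umi) pair counts once, however many junction
  # rows it spans
  mol <- mol |>
    mutate(class = dplyr::case_when(
      paste(.data$barcode, .data$umi) %in% paste(amb$barcode, amb$umi) ~
        "ambiguous",
      .data$is_skipping ~ "skipped",
      TRUE ~ "unskipped"
    )) |>
    distinct(.data$barcode, .data$umi, .data$junction, .data$class) |>
    (\(df) bind_rows(
      df |> filter(.data$class != "ambiguous"),
      df |> filter(.data$class == "ambiguous") |>
        distinct(.data$barcode, .data$umi, .keep_all = TRUE)
    ))()
  mol |>
    count(.data$barcode, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L) |>
    (\(df) {
      for (col in c("unskipped", "skipped", "ambiguous")) {
        if (!col %in% names(df)) df[[col]] <- 0L
      }
      df |> select("barcode", "unskipped", "skipped", "ambiguous")
    })() |>
    arrange(.data$barcode)
}

#' Read a nucleus annotation table
#'
#' TSV with header `barcode<TAB>sample<TAB>condition<TAB>cluster`; one row
#' per nucleus.
#'
#' @param path TSV path.
#' @param myonucleus_clusters optional character vector of cluster labels to
#'   flag as myonuclei (sets `is_myonucleus`).
#' @return tibble `barcode`, `sample`, `condition`, `cluster`,
#'   `is_myonucleus`.
#' @export
read_annotations <- function(path, myonucleus_clusters = NULL) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("barcode", "sample", "condition", "cluster")
  if (!all(req %in% names(ann))) {
    abort("annotation table must have columns barcode, sample, condition, cluster")
  }
  ann$is_myonucleus <- if (is.null(myonucleus_clusters)) NA else
    ann$cluster %in% myonucleus_clusters
  as_tibble(ann)
}

#' Summarise junction-positive nuclei per condition and cell type
#'
#' A nucleus is positive for a junction if it carries at least one unique
#' molecule of that junction. Denominators are all annotated nuclei in each
#' (condition, cluster) stratum, including nuclei with zero molecules.
#' Barcodes with molecules but no annotation are excluded and reported via
#' the `unmatched_barcodes` attribute.
#'
#' @param molecules molecule tibble from [dedup()].
#' @param annotations tibble from [read_annotations()] (or any data frame
#'   with `barcode`, `condition`, `cluster`).
#' @param restrict optional character vector of cluster labels to keep
#'   (e.g. myonucleus clusters only).
#' @param junctions junction labels to tabulate; defaults to those present
#'   in `molecules`.
#' @param digits decimal places for percentages.
#' @return tibble `condition`, `cluster`, `junction`, `n_nuclei`,
#'   `n_positive`, `percent_positive`, `n_molecules`. Empty strata carry
#'   `percent_positive = NA`.
#' @export
per_cluster_summary <- function(molecules, annotations, restrict = NULL,
                                junctions = NULL, digits = 2L) {
  annotations <- as_tibble(annotations)
  if (!is.null(restrict)) {
    annotations <- annotations |> filter(.data$cluster %in% restrict)
  }
  junctions <- junctions %||% sort(unique(molecules$junction))
  unmatched <- setdiff(unique(molecules$barcode), annotations$barcode)
  mol <- molecules |> filter(.data$barcode %in% annotations$barcode)

  # full condition x cluster grid: a stratum absent from one condition is
  # still emitted, with n_nuclei 0 and an undefined percentage
  strata <- annotations |>
    count(.data$condition, .data$cluster, name = "n_nuclei")
  grid <- tidyr::crossing(condition = unique(annotations$condition),
                          cluster = unique(annotations$cluster),
                          junction = junctions) |>
    left_join(strata, by = c("condition", "cluster")) |>
    mutate(n_nuclei = dplyr::coalesce(.data$n_nuclei, 0L))

  pos <- mol |>
    left_join(annotations |> select("barcode", "condition", "cluster"),
              by = "barcode") |>
    group_by(.data$condition, .data$cluster, .data$junction) |>
    summarise(n_positive = dplyr::n_distinct(.data$barcode),
              n_molecules = dplyr::n(), .groups = "drop")

  out <- grid |>
    left_join(pos, by = c("condition", "cluster", "junction")) |>
    mutate(
      n_positive = dplyr::coalesce(.data$n_positive, 0L),
      n_molecules = dplyr::coalesce(.data$n_molecules, 0L),
      percent_positive = ifelse(.data$n_nuclei > 0,
                                round(100 * .data$n_positive / .data$n_nuclei,
                                      digits), NA_real_)
    ) |>
    select("condition", "cluster", "junction", "n_nuclei", "n_positive",
           "percent_positive", "n_molecules") |>
    arrange(.data$condition, .data$cluster, .data$junction)
  attr(out, "unmatched_barcodes") <- unmatched
  class(out) <- c("junction_summary", class(out))
  out
}

#' Ratio of junction-positive percentages between two conditions
#'
#' @param summary a junction summary from [per_cluster_summary()].
#' @param junction junction label to compare.
#' @param cond_a,cond_b condition labels; the ratio is
#'   `percent_positive(cond_a) / percent_positive(cond_b)` pooled over the
#'   selected clusters.
#' @param cluster optional cluster label to restrict to; by default all
#'   clusters in the summary are pooled (weighted by nuclei).
#' @return one-row tibble: `junction`, `cond_a`, `cond_b`, `percent_a`,
#'   `percent_b`, `ratio`, `infinite` (TRUE when `cond_b` has zero positive
#'   nuclei).
#' @export
condition_ratio <- function(summary, junction, cond_a, cond_b,
                            cluster = NULL) {
  df <- as_tibble(summary) |> filter(.data$junction == !!junction)
  if (!is.null(cluster)) df <- df |> filter(.data$cluster %in% !!cluster)
  pool <- function(cond) {
    sub <- df |> filter(.data$condition == cond)
    if (nrow(sub) == 0L || sum(sub$n_nuclei) == 0L) {
      abort(sprintf("condition '%s' has no nuclei for junction %s",
                    cond, junction))
    }
    100 * sum(sub$n_positive) / sum(sub$n_nuclei)
  }
  pa <- pool(cond_a)
  pb <- pool(cond_b)
  tibble(
    junction = junction, cond_a = cond_a, cond_b = cond_b,
    percent_a = pa, percent_b = pb,
    ratio = if (pb == 0) Inf else pa / pb,
    infinite = pb == 0
  )
}
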