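new_count_matrix <- function(mat, features) {
  structure(list(matrix = mat, features = as_tibble(features)),
            class = "count_matrix")
}

#' @export
#' @method print count_matrix
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d barcodes, %d nonzero entries\n",
              nrow(x$matrix), ncol(x$matrix), Matrix::nnzero(x$matrix)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$matrix)

open_maybe_gz <- function(dir, base) {
  for (cand in c(file.path(dir, base), file.path(dir, paste0(base, ".gz")))) {
    if (file.exists(cand)) return(cand)
  }
  abort(sprintf("missing %s(.gz) in %s", base, dir))
}

#' Read a 10x-style MatrixMarket count matrix directory
#'
#' Expects `matrix.mtx`, `features.tsv` and `barcodes.tsv` (each optionally
#' gzipped): a coordinate-format sparse gene x barcode matrix with 1-based
#' indices. Out-of-range indices and non-integer counts are errors naming
#' the offending line; duplicate (gene, barcode) triplets are summed with a
#' warning.
#'
#' @param dir directory path.
#' @return a `count_matrix`: sparse genes x barcodes matrix plus a feature
#'   tibble (`id`, `name`).
#' @export
read_mtx <- function(dir) {
  mtx_path <- open_maybe_gz(dir, "matrix.mtx")
  lines <- readLines(gzfile(mtx_path))
  if (length(lines) == 0L || !grepl("^%%MatrixMarket", lines[1])) {
    abort(sprintf("%s is not a MatrixMarket file", mtx_path))
  }
  body <- which(!startsWith(lines, "%"))
  if (length(body) == 0L) abort("MatrixMarket file has no size line")
  dims_line <- body[1]
  dims <- scan(text = lines[dims_line], quiet = TRUE)
  if (length(dims) != 3L) abort("malformed MatrixMarket size line")
  ng <- as.integer(dims[1]); nb <- as.integer(dims[2]); ne <- as.integer(dims[3])
  trip_lines <- body[-1]
  if (length(trip_lines) != ne) {
    abort(sprintf("header declares %d entries but file has %d",
                  ne, length(trip_lines)))
  }
  trip <- if (ne > 0L) {
    m <- matrix(scan(text = lines[trip_lines], quiet = TRUE),
                ncol = 3L, byrow = TRUE)
    m
  } else matrix(numeric(0), ncol = 3L)
  if (ne > 0L) {
    bad_i <- which(trip[, 1] < 1 | trip[, 1] > ng |
                   trip[, 2] < 1 | trip[, 2] > nb)
    if (length(bad_i) > 0L) {
      abort(sprintf("entry out of range at line %d of %s",
                    trip_lines[bad_i[1]], basename(mtx_path)))
    }
    bad_c <- which(trip[, 3] != round(trip[, 3]) | trip[, 3] < 0)
    if (length(bad_c) > 0L) {
      abort(sprintf("non-integer or negative count at line %d of %s",
                    trip_lines[bad_c[1]], basename(mtx_path)))
    }
    if (anyDuplicated(trip[, 1:2, drop = FALSE]) > 0L) {
      warn("duplicate (gene, barcode) triplets summed")
    }
  }
  mat <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                              dims = c(ng, nb))

  feat_path <- open_maybe_gz(dir, "features.tsv")
  feats <- readr::read_tsv(feat_path, col_names = FALSE,
                           show_col_types = FALSE, progress = FALSE)
  features <- tibble(id = feats[[1]],
                     name = if (ncol(feats) >= 2) feats[[2]] else feats[[1]])
  bc_path <- open_maybe_gz(dir, "barcodes.tsv")
  barcodes <- readLines(gzfile(bc_path))
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(features) != ng || length(barcodes) != nb) {
    abort(sprintf("matrix is %d x %d but features/barcodes have %d/%d rows",
                  ng, nb, nrow(features), length(barcodes)))
  }
  rownames(mat) <- features$id
  colnames(mat) <- barcodes
  new_count_matrix(mat, features)
}

#' Write a count matrix as a MatrixMarket directory
#'
#' @param cm a `count_matrix`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mtx <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(cm$matrix, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  readr::write_tsv(cm$features, file.path(dir, "features.tsv"),
                   col_names = FALSE, progress = FALSE)
  writeLines(colnames(cm$matrix), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Per-nucleus and cohort QC metrics
#'
#' `genes_detected` is the number of genes with nonzero counts in a barcode;
#' `total_umi` the barcode's column sum. Per-sample and cohort means are
#' rounded to integers for reporting (medians are reported alongside, since
#' published summaries use either).
#'
#' @param cm a `count_matrix`.
#' @param barcode_to_sample optional data frame (`barcode`, `sample`)
#'   assigning nuclei to samples; barcodes without an entry fall into sample
#'   `"(unassigned)"`.
#' @return a `qc_report`: list with `per_barcode`, `per_sample` and `cohort`
#'   tibbles.
#' @export
qc_metrics <- function(cm, barcode_to_sample = NULL) {
  mat <- cm$matrix
  per_barcode <- tibble(
    barcode = colnames(mat) %||% as.character(seq_len(ncol(mat))),
    genes_detected = unname(Matrix::colSums(mat > 0)),
    total_umi = unname(Matrix::colSums(mat))
  )
  if (!is.null(barcode_to_sample)) {
    per_barcode <- per_barcode |>
      left_join(as_tibble(barcode_to_sample) |> select("barcode", "sample"),
                by = "barcode") |>
      mutate(sample = dplyr::coalesce(.data$sample, "(unassigned)"))
  } else {
    per_barcode$sample <- "(all)"
  }
  per_sample <- per_barcode |>
    group_by(.data$sample) |>
    summarise(
      n_nuclei = dplyr::n(),
      mean_genes = round(mean(.data$genes_detected)),
      median_genes = median(.data$genes_detected),
      mean_umi = round(mean(.data$total_umi)),
      median_umi = median(.data$total_umi),
      total_umi = sum(.data$total_umi),
      .groups = "drop"
    )
  cohort <- tibble(
    n_samples = nrow(per_sample),
    n_nuclei = nrow(per_barcode),
    mean_nuclei_per_sample = round(mean(per_sample$n_nuclei)),
    mean_genes = round(mean(per_barcode$genes_detected)),
    median_genes = median(per_barcode$genes_detected),
    mean_umi = round(mean(per_barcode$total_umi)),
    median_umi = median(per_barcode$total_umi)
  )
  structure(list(per_barcode = per_barcode, per_sample = per_sample,
                 cohort = cohort),
            class = "qc_report")
}

#' @export
#' @method print qc_report
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d nuclei over %d sample(s); mean %d genes, %d UMI per nucleus\n",
              x$cohort$n_nuclei, x$cohort$n_samples, x$cohort$mean_genes,
              x$cohort$mean_umi))
  invisible(x)
}

#' Cohort totals from per-group nucleus counts
#'
#' Sums published or computed per-sample (or per-group) nucleus counts and
#' reports the rounded mean per group — the arithmetic behind dataset
#' summary sentences such as "34,833 nuclei over 11 samples, averaging 3167
#' per sample".
#'
#' @param counts integer vector of nuclei per sample or per group; may be
#'   omitted when `total` and `n_groups` are given directly (published
#'   reports often state only those).
#' @param total,n_groups cohort total and group count, defaulting to
#'   `sum(counts)` and `length(counts)`.
#' @return one-row tibble: `n_groups`, `total`, `mean_per_group` (rounded).
#' @export
#' @examples
#' cohort_totals(c(4906, 2643))
#' cohort_totals(total = 34833, n_groups = 11)
cohort_totals <- function(counts = NULL, total = sum(counts),
                          n_groups = length(counts)) {
  if (is.null(counts) && (missing(total) || missing(n_groups))) {
    abort("provide counts, or both total and n_groups")
  }
  tibble(n_groups = n_groups, total = total,
         mean_per_group = round(total / n_groups))
}

#' Filter nuclei and mitochondrial genes from a count matrix
#'
#' Applies the standard snRNA-seq cleanup: optionally drop externally called
#' barcodes (e.g. doublets), remove mitochondrial genes by name prefix, then
#' remove nuclei whose metric (genes detected or total UMI) falls strictly
#' below `min_value`. Metrics are computed after mito removal, so the order
#' matters and is recorded step by step in the report.
#'
#' @param cm a `count_matrix`.
#' @param min_value threshold; barcodes with metric `< min_value` are
#'   removed.
#' @param metric `"genes"` (genes detected) or `"umi"` (total UMI).
#' @param drop_mito remove genes whose name starts with `mito_prefix`
#'   (case-insensitive) before thresholding.
#' @param mito_prefix gene-name prefix identifying mitochondrial genes.
#' @param exclude_barcodes optional character vector of barcodes to drop
#'   first (e.g. doublet calls from an external tool).
#' @return list with `matrix` (filtered `count_matrix`) and `report`
#'   (tibble `step`, `removed`, `remaining` in application order).
#' @export
filter_nuclei <- function(cm, min_value = 200L, metric = c("genes", "umi"),
                          drop_mito = TRUE, mito_prefix = "mt-",
                          exclude_barcodes = NULL) {
  metric <- match.arg(metric)
  stopifnot(min_value >= 0)
  mat <- cm$matrix
  features <- cm$features
  report <- list()
  note <- function(step, removed, remaining) {
    report[[length(report) + 1L]] <<- tibble(step = step, removed = removed,
                                             remaining = remaining)
  }

  if (!is.null(exclude_barcodes)) {
    keep <- !(colnames(mat) %in% exclude_barcodes)
    note("exclude_barcodes", sum(!keep), sum(keep))
    mat <- mat[, keep, drop = FALSE]
  }
  if (drop_mito) {
    is_mito <- startsWith(tolower(features$name), tolower(mito_prefix))
    note("drop_mito_genes", sum(is_mito), sum(!is_mito))
    mat <- mat[!is_mito, , drop = FALSE]
    features <- features[!is_mito, , drop = FALSE]
  }
  vals <- if (metric == "genes") Matrix::colSums(mat > 0) else
    Matrix::colSums(mat)
  keep <- vals >= min_value
  note(sprintf("min_%s_%d", metric, as.integer(min_value)),
       sum(!keep), sum(keep))
  if (sum(keep) == 0L) {
    warn("all barcodes removed by filtering; returning an empty matrix")
  }
  mat <- mat[, keep, drop = FALSE]
  list(matrix = new_count_matrix(mat, features), report = bind_rows(report))
}
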