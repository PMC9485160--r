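write_toy_mtx <- function(dir, triplets, ng = 3, nb = 2,
                          gene_names = NULL) {
  dir.create(dir, showWarnings = FALSE)
  ids <- sprintf("G%d", seq_len(ng))
  names_col <- if (is.null(gene_names)) ids else gene_names
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", ng, nb, nrow(triplets)),
               apply(triplets, 1, paste, collapse = " ")),
             file.path(dir, "matrix.mtx"))
  writeLines(paste(ids, names_col, sep = "\t"), file.path(dir, "features.tsv"))
  writeLines(sprintf("BC%d", seq_len(nb)), file.path(dir, "barcodes.tsv"))
  dir
}

test_that("MatrixMarket directories load with validation and round-trip", {
  dir <- withr::local_tempdir()
  write_toy_mtx(file.path(dir, "m1"),
                rbind(c(1, 1, 5), c(2, 1, 2), c(3, 2, 7)))
  cm <- read_mtx(file.path(dir, "m1"))
  expect_equal(dim(cm), c(3L, 2L))
  expect_equal(as.numeric(cm$matrix[1, 1]), 5)
  expect_equal(as.numeric(cm$matrix[3, 2]), 7)
  # independent cross-check with Matrix::readMM on the same file
  ref <- Matrix::readMM(file.path(dir, "m1", "matrix.mtx"))
  expect_equal(unname(as.matrix(cm$matrix)), as.matrix(ref))
  # round trip
  out <- file.path(dir, "rt")
  write_mtx(cm, out)
  cm2 <- read_mtx(out)
  expect_equal(as.matrix(cm2$matrix), as.matrix(cm$matrix))
  expect_equal(cm2$features, cm$features)
})

test_that("malformed matrices are rejected with located errors", {
  dir <- withr::local_tempdir()
  # out-of-range gene index (line 3 = first triplet)
  write_toy_mtx(file.path(dir, "bad1"), rbind(c(4, 1, 5)))
  expect_error(read_mtx(file.path(dir, "bad1")), "line 3")
  # non-integer count
  write_toy_mtx(file.path(dir, "bad2"), rbind(c(1, 1, 2.5)))
  expect_error(read_mtx(file.path(dir, "bad2")), "non-integer")
  # header/triplet count mismatch
  p <- write_toy_mtx(file.path(dir, "bad3"), rbind(c(1, 1, 1)))
  lines <- readLines(file.path(p, "matrix.mtx"))
  lines[2] <- "3 2 5"
  writeLines(lines, file.path(p, "matrix.mtx"))
  expect_error(read_mtx(p), "declares 5")
  # duplicate triplets are summed with a warning
  write_toy_mtx(file.path(dir, "dup"), rbind(c(1, 1, 2), c(1, 1, 3)))
  expect_warning(cm <- read_mtx(file.path(dir, "dup")), "summed")
  expect_equal(as.numeric(cm$matrix[1, 1]), 5)
})

test_that("QC metrics count nonzero genes and column sums per barcode", {
  dir <- withr::local_tempdir()
  write_toy_mtx(dir, rbind(c(2, 1, 5), c(3, 1, 2), c(1, 2, 1)))
  cm <- read_mtx(dir)
  qc <- qc_metrics(cm)
  b1 <- qc$per_barcode[qc$per_barcode$barcode == "BC1", ]
  expect_equal(b1$genes_detected, 2)   # counts (0, 5, 2)
  expect_equal(b1$total_umi, 7)
  # permutation equivariance
  cm_perm <- cm
  cm_perm$matrix <- cm$matrix[, 2:1]
  qc_perm <- qc_metrics(cm_perm)
  expect_equal(qc_perm$per_barcode[order(qc_perm$per_barcode$barcode), ],
               qc$per_barcode[order(qc$per_barcode$barcode), ],
               ignore_attr = TRUE)
})

test_that("cohort totals reproduce published dataset arithmetic", {
  # 34,833 nuclei over 11 samples average 3167 per sample
  expect_equal(cohort_totals(total = 34833, n_groups = 11)$mean_per_group,
               3167)
  # 4906 + 2643 = 7549 human nuclei
  expect_equal(cohort_totals(c(4906, 2643))$total, 7549)
  # 9967 + 8411 + 11,495 = 29,873 mouse nuclei
  expect_equal(cohort_totals(c(9967, 8411, 11495))$total, 29873)
})

test_that("nuclei filtering removes mito genes first, then low barcodes, strictly", {
  sim <- simulate_matrix(n_genes = 150, n_barcodes = 30, n_low = 10,
                         threshold = 50, n_mito_genes = 4, seed = 3)
  filt <- filter_nuclei(sim$cm, min_value = 50, metric = "genes")
  # planted low barcodes are exactly the ones removed
  expect_setequal(setdiff(colnames(sim$cm$matrix),
                          colnames(filt$matrix$matrix)),
                  sim$truth$low_barcodes)
  # mito genes are gone, and the report shows mito removal before threshold
  expect_false(any(sim$truth$mito_genes %in% rownames(filt$matrix$matrix)))
  expect_equal(filt$report$step[1:2],
               c("drop_mito_genes", "min_genes_50"))
  expect_equal(filt$report$removed[1], 4)
})

test_that("UMI metric uses strict less-than at the boundary", {
  # barcode with exactly 199 total UMI is removed at min 200; 200 survives
  mat <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = c(199, 200),
                              dims = c(2, 2))
  rownames(mat) <- c("G1", "G2"); colnames(mat) <- c("B1", "B2")
  cm <- skiptally:::new_count_matrix(mat, tibble::tibble(id = c("G1", "G2"),
                                                         name = c("G1", "G2")))
  filt <- filter_nuclei(cm, min_value = 200, metric = "umi",
                        drop_mito = FALSE)
  expect_equal(colnames(filt$matrix$matrix), "B2")
})

test_that("filtering is monotone in the threshold and can empty the matrix", {
  sim <- simulate_matrix(n_genes = 150, n_barcodes = 30, n_low = 10,
                         threshold = 50, n_mito_genes = 4, seed = 5)
  survivors <- vapply(c(0, 25, 50, 75, 200), function(m) {
    suppressWarnings(ncol(filter_nuclei(sim$cm, min_value = m,
                                        metric = "genes")$matrix))
  }, numeric(1))
  expect_true(all(diff(survivors) <= 0))
  # a matrix whose only counts are mito genes loses every barcode
  mito_mat <- Matrix::sparseMatrix(i = 1, j = 1, x = 10, dims = c(1, 1))
  rownames(mito_mat) <- "Gm"; colnames(mito_mat) <- "B1"
  cm <- skiptally:::new_count_matrix(
    mito_mat, tibble::tibble(id = "Gm", name = "mt-Co1"))
  expect_warning(res <- filter_nuclei(cm, min_value = 1, metric = "genes"),
                 "all barcodes removed")
  expect_equal(ncol(res$matrix), 0L)
})

test_that("external exclusion lists drop the listed barcodes first", {
  sim <- simulate_matrix(n_genes = 100, n_barcodes = 10, n_low = 0,
                         threshold = 30, n_mito_genes = 2, seed = 9)
  excl <- colnames(sim$cm$matrix)[1:3]
  filt <- filter_nuclei(sim$cm, min_value = 0, exclude_barcodes = excl)
  expect_false(any(excl %in% colnames(filt$matrix$matrix)))
  expect_equal(filt$report$step[1], "exclude_barcodes")
  expect_equal(filt$report$removed[1], 3)
})
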