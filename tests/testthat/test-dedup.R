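test_that("barcode correction rescues unambiguous single-mismatch barcodes", {
  wl <- c("AAAA", "CCCC", "GGGG")
  # exact member: identity
  expect_equal(correct_barcode("AAAA", wl), "AAAA")
  # Hamming 1 from exactly one entry (brute-force check over the toy list)
  expect_equal(correct_barcode("AAAT", wl), "AAAA")
  d <- vapply(wl, function(w) sum(strsplit(w, "")[[1]] !=
                                    strsplit("AAAT", "")[[1]]), numeric(1))
  expect_equal(sum(d <= 1), 1)
  # ambiguous: Hamming 1 from two entries
  wl2 <- c("AAAA", "AATT")
  expect_true(is.na(correct_barcode("AATA", wl2)))
  d2 <- vapply(wl2, function(w) sum(strsplit(w, "")[[1]] !=
                                      strsplit("AATA", "")[[1]]), numeric(1))
  expect_equal(sum(d2 <= 1), 2)
  # beyond max_hamming: no rescue
  expect_true(is.na(correct_barcode("ATTA", wl)))
  expect_error(correct_barcode("AAAAA", wl), "length")
})

test_that("pure PCR duplicates collapse to one molecule with full support", {
  hits <- tibble::tibble(
    read_id = paste0("r", 1:5),
    barcode = strrep("A", 16), umi = strrep("C", 12), junction = "e1-e2")
  dd <- dedup(hits)
  expect_equal(nrow(dd$molecules), 1L)
  expect_equal(dd$molecules$support, 5L)
  expect_equal(dd$stats$reads_in, 5L)
  expect_equal(dd$stats$molecules_out, 1L)
})

test_that("directional UMI collapse merges Hamming-1 neighbours by support", {
  u1 <- strrep("A", 12)
  u2 <- paste0(strrep("A", 11), "T")
  hits <- tibble::tibble(
    read_id = paste0("r", 1:4),
    barcode = strrep("G", 16),
    umi = c(u1, u1, u1, u2),
    junction = "e1-e2")
  exact <- dedup(hits, umi_collapse = "exact")
  expect_equal(nrow(exact$molecules), 2L)
  merged <- dedup(hits, umi_collapse = "hamming1")
  expect_equal(nrow(merged$molecules), 1L)
  expect_equal(merged$molecules$umi, u1)     # higher support absorbs
  expect_equal(merged$molecules$support, 4L)
  # distinct UMIs at Hamming > 1 never merge
  u3 <- paste0(strrep("A", 10), "TT")
  hits2 <- dplyr::bind_rows(hits[1:3, ],
                            tibble::tibble(read_id = "r9",
                                           barcode = strrep("G", 16),
                                           umi = u3, junction = "e1-e2"))
  expect_equal(nrow(dedup(hits2, umi_collapse = "hamming1")$molecules), 2L)
})

test_that("whitelist correction discards unrescuable barcodes and counts them", {
  wl <- c(strrep("A", 16), strrep("C", 16))
  hits <- tibble::tibble(
    read_id = paste0("r", 1:3),
    barcode = c(strrep("A", 16),
                paste0(strrep("A", 15), "T"),     # rescued
                paste0("GGGG", strrep("T", 12))), # unrescuable
    umi = strrep("C", 12), junction = "e1-e2")
  dd <- dedup(hits, whitelist = wl)
  expect_equal(dd$stats$reads_discarded_barcode, 1L)
  expect_equal(dd$stats$barcodes_discarded, 1L)
  expect_equal(nrow(dd$molecules), 1L)       # corrected barcode collapses
  expect_equal(dd$molecules$support, 2L)
})

test_that("dedup is idempotent and monotone under UMI-collapse tightening", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 200
    hits <- tibble::tibble(
      read_id = paste0("r", seq_len(n)),
      barcode = sample(indexed_dna_test(0:4, 16), n, replace = TRUE),
      umi = sample(indexed_dna_test(0:9, 12), n, replace = TRUE),
      junction = sample(c("e1-e2", "e1-e3"), n, replace = TRUE))
    for (mode in c("exact", "hamming1")) {
      mol <- dedup(hits, umi_collapse = mode)$molecules
      # molecule count never exceeds hit count
      expect_lte(nrow(mol), n)
      # idempotence: reinterpret molecules as single-support hits
      again <- dedup(mol |> dplyr::select(-"support"),
                     umi_collapse = mode)$molecules
      expect_equal(again |> dplyr::mutate(support = NULL),
                   mol |> dplyr::mutate(support = NULL))
      expect_true(all(again$support == 1L))
    }
    # tightening exact -> hamming1 never increases molecule count
    expect_lte(nrow(dedup(hits, umi_collapse = "hamming1")$molecules),
               nrow(dedup(hits, umi_collapse = "exact")$molecules))
  }
})

test_that("molecule classification separates skip, canonical and ambiguous", {
  specs <- junction_specs(c("e22-e23", "e23-e24", "e22-e24"))
  mol <- tibble::tibble(
    barcode = c("b1", "b1", "b2", "b3", "b3"),
    umi = c("u1", "u2", "u1", "u1", "u1"),
    junction = c("e22-e23", "e23-e24", "e22-e24", "e22-e23", "e22-e24"),
    support = 1L)
  cls <- classify_molecules(mol, specs)
  expect_equal(cls$unskipped[cls$barcode == "b1"], 2L)
  expect_equal(cls$skipped[cls$barcode == "b1"], 0L)
  expect_equal(cls$skipped[cls$barcode == "b2"], 1L)
  # same (barcode, umi) at canonical and skip junction: ambiguous only
  expect_equal(cls$ambiguous[cls$barcode == "b3"], 1L)
  expect_equal(cls$unskipped[cls$barcode == "b3"], 0L)
  expect_equal(cls$skipped[cls$barcode == "b3"], 0L)
  expect_error(classify_molecules(mol |> dplyr::mutate(junction = "e9-e9x"),
                                  specs), "cannot parse|unknown junction")
})

test_that("per-cluster summaries use all annotated nuclei as denominators", {
  ann <- tibble::tibble(
    barcode = c("b1", "b2", "b3", "b4"),
    sample = "s1", condition = "mdx",
    cluster = c("myonuclei", "myonuclei", "myonuclei", "FAP"))
  mol <- tibble::tibble(barcode = "b1", umi = "u1", junction = "e22-e24",
                        support = 1L)
  summ <- per_cluster_summary(mol, ann)
  row <- summ[summ$cluster == "myonuclei" & summ$junction == "e22-e24", ]
  expect_equal(row$n_nuclei, 3L)
  expect_equal(row$n_positive, 1L)
  expect_equal(row$percent_positive, 33.33)
  # zero-count stratum still emitted
  fap <- summ[summ$cluster == "FAP", ]
  expect_equal(fap$n_positive, 0L)
  expect_equal(fap$percent_positive, 0)
  # unannotated barcode: excluded and reported
  mol2 <- dplyr::bind_rows(mol, tibble::tibble(barcode = "zz", umi = "u9",
                                               junction = "e22-e24",
                                               support = 1L))
  summ2 <- per_cluster_summary(mol2, ann)
  expect_equal(attr(summ2, "unmatched_barcodes"), "zz")
  expect_equal(summ2$n_positive[summ2$cluster == "myonuclei"], 1L)
})

test_that("condition ratios reproduce simple arithmetic and flag zero denominators", {
  summ <- tibble::tibble(
    condition = c("mdx_e23AON", "mdx"),
    cluster = "myonuclei", junction = "e22-e24",
    n_nuclei = c(1000L, 2500L), n_positive = c(8L, 2L),
    percent_positive = c(0.8, 0.08), n_molecules = c(8L, 2L))
  r <- condition_ratio(summ, "e22-e24", "mdx_e23AON", "mdx")
  expect_equal(r$ratio, 10)
  expect_false(r$infinite)
  # equal percentages
  summ$n_positive <- c(10L, 25L)
  expect_equal(condition_ratio(summ, "e22-e24", "mdx_e23AON", "mdx")$ratio, 1)
  # zero denominator
  summ$n_positive <- c(5L, 0L)
  r0 <- condition_ratio(summ, "e22-e24", "mdx_e23AON", "mdx")
  expect_true(r0$infinite)
  expect_equal(r0$ratio, Inf)
  expect_error(condition_ratio(summ, "e22-e24", "mdx_e23AON", "WT"),
               "no nuclei")
})
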