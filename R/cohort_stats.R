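#' Per-sample cell-type frequency table
#'
#' Converts per-nucleus annotations into the percentage of each sample's
#' nuclei assigned to each cell type. Rows sum to 100 exactly; cell types
#' absent from a sample get 0.
#'
#' @param annotations data frame with one row per nucleus and columns
#'   `barcode`, `sample`, `condition`, `cluster`.
#' @return a `frequency_table`: a wide tibble with columns `sample`,
#'   `condition`, then one percentage column per cell type.
#' @export
build_frequency_table <- function(annotations) {
  ann <- as_tibble(annotations)
  req <- c("sample", "condition", "cluster")
  if (!all(req %in% names(ann))) {
    abort("annotations must have columns sample, condition, cluster")
  }
  totals <- ann |> count(.data$sample, name = "total")
  if (any(totals$total == 0L)) {
    abort(sprintf("sample %s has 0 nuclei",
                  totals$sample[which(totals$total == 0L)[1]]))
  }
  wide <- ann |>
    count(.data$sample, .data$condition, .data$cluster) |>
    left_join(totals, by = "sample") |>
    mutate(pct = 100 * .data$n / .data$total) |>
    select("sample", "condition", "cluster", "pct") |>
    pivot_wider(names_from = "cluster", values_from = "pct",
                values_fill = 0) |>
    arrange(.data$condition, .data$sample)
  class(wide) <- c("frequency_table", class(wide))
  wide
}

#' @rdname build_frequency_table
#' @param path TSV path with columns `sample`, `condition` and one column per
#'   cell type.
#' @export
read_frequency_table <- function(path) {
  ft <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample", "condition") %in% names(ft))) {
    abort("frequency table must have sample and condition columns")
  }
  class(ft) <- c("frequency_table", class(ft))
  ft
}

freq_cell_types <- function(ft) setdiff(names(ft), c("sample", "condition"))

# Exact null counts of the Mann-Whitney U statistic for group sizes
# (n1, n2): counts[u + 1] arrangements with U = u, u in 0..n1*n2
# (Gaussian-binomial recursion G(m, n) = G(m-1, n) + q^m G(m, n-1)).
mw_null_counts <- function(n1, n2) {
  prev <- rep(list(1), n2 + 1L)            # m = 0
  if (n1 == 0L) return(prev[[n2 + 1L]])
  for (m in seq_len(n1)) {
    cur <- vector("list", n2 + 1L)
    cur[[1L]] <- 1
    if (n2 > 0L) for (n in seq_len(n2)) {
      a <- prev[[n + 1L]]                  # G(m-1, n)
      b <- cur[[n]]                        # G(m, n-1)
      res <- numeric(m * n + 1L)
      res[seq_along(a)] <- a
      res[(m + 1L):(m + length(b))] <- res[(m + 1L):(m + length(b))] + b
      cur[[n + 1L]] <- res
    }
    prev <- cur
  }
  prev[[n2 + 1L]]
}

#' Mann-Whitney U test with exact small-sample p-values
#'
#' Computes `U` as the number of (x, y) pairs with `x > y` (ties contribute
#' one half). Without ties and with `n1 + n2` at most `exact_limit`, the
#' two-sided p-value comes from the exact null distribution of U, doubling
#' the smaller tail (including the observed point) and capping at 1. With
#' ties, or beyond the exact limit, a tie-corrected normal approximation
#' with continuity correction is used and flagged in `method`.
#'
#' @param x,y numeric vectors (e.g. per-sample cell-type percentages for two
#'   conditions).
#' @param exact_limit largest `n1 + n2` for which the exact distribution is
#'   enumerated.
#' @return an object of class `mw_test`: list with `U`, `p_two_sided`,
#'   `method` (`"exact"` or `"normal_tie_corrected"`), `n1`, `n2`.
#' @export
#' @examples
#' mw_exact(c(1, 2, 3), c(4, 5, 6, 7, 8, 9, 10, 11))  # p = 2/165
mw_exact <- function(x, y, exact_limit = 25L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    abort("both groups must be non-empty")
  }
  n1 <- length(x); n2 <- length(y)
  gt <- outer(x, y, ">")
  eq <- outer(x, y, "==")
  U <- sum(gt) + 0.5 * sum(eq)
  has_ties <- anyDuplicated(c(x, y)) > 0L

  if (!has_ties && n1 + n2 <= exact_limit) {
    counts <- mw_null_counts(n1, n2)
    total <- sum(counts)
    u <- as.integer(round(U))
    p_le <- sum(counts[seq_len(u + 1L)]) / total
    p_ge <- sum(counts[(u + 1L):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    N <- n1 + n2
    r <- rank(c(x, y))
    tie_tab <- table(r)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      if (U == mu) z <- 0
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_tie_corrected"
  }
  structure(list(U = U, p_two_sided = p, method = method, n1 = n1, n2 = n2),
            class = "mw_test")
}

#' @export
#' @method print mw_test
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), two-sided p = %.3f [%s]\n",
              x$U, x$n1, x$n2, x$p_two_sided, x$method))
  invisible(x)
}

#' @export
tidy.mw_test <- function(x, ...) {
  tibble(U = x$U, p.value = x$p_two_sided, method = x$method,
         n1 = x$n1, n2 = x$n2)
}

#' @export
glance.mw_test <- function(x, ...) tidy(x)

#' Compare cell-type frequencies between two conditions
#'
#' Runs [mw_exact()] on the per-sample percentages of every cell type,
#' reporting the direction of the mean difference (`group_a` relative to
#' `group_b`). Raw p-values are never altered; Benjamini-Hochberg adjusted
#' values can be added as an extra column.
#'
#' @param ft a [build_frequency_table()] result.
#' @param group_a,group_b condition labels (e.g. `"WT"` vs `"mdx"`).
#' @param adjust `"none"` or `"bh"`.
#' @param exact_limit passed to [mw_exact()].
#' @return tibble `cell_type`, `U`, `p`, `method`, `direction`
#'   (`increase`/`decrease`/`none` for `group_a` vs `group_b`), and `p_bh`
#'   when `adjust = "bh"`.
#' @export
compare_conditions <- function(ft, group_a, group_b,
                               adjust = c("none", "bh"), exact_limit = 25L) {
  adjust <- match.arg(adjust)
  ft <- as_tibble(ft)
  for (g in c(group_a, group_b)) {
    if (!g %in% ft$condition) abort(sprintf("condition '%s' not present", g))
  }
  types <- freq_cell_types(ft)
  res <- purrr::map(types, function(ct) {
    xa <- ft[[ct]][ft$condition == group_a]
    xb <- ft[[ct]][ft$condition == group_b]
    fit <- mw_exact(xa, xb, exact_limit = exact_limit)
    d <- mean(xa) - mean(xb)
    tibble(cell_type = ct, U = fit$U, p = fit$p_two_sided,
           method = fit$method,
           direction = if (d > 0) "increase" else if (d < 0) "decrease"
                       else "none")
  }) |> bind_rows()
  if (adjust == "bh") res$p_bh <- p.adjust(res$p, method = "BH")
  res
}

#' Score treatment recovery toward wild-type composition
#'
#' For each cell type, reports the direction of the disease shift relative
#' to wild type and whether the treated condition moved the condition mean
#' (or median) back toward the wild-type value: recovered when
#' `|center(treated) - center(WT)| < |center(disease) - center(WT)|`.
#' Undefined (`NA`) when disease and wild type do not differ.
#'
#' @param ft a [build_frequency_table()] result.
#' @param wt,disease,treated condition labels.
#' @param center `"mean"` (conditions pooled by mean) or `"median"`.
#' @return tibble `cell_type`, `direction_vs_wt`, `recovered`.
#' @export
recovery_score <- function(ft, wt, disease, treated,
                           center = c("mean", "median")) {
  center <- match.arg(center)
  fun <- if (center == "mean") mean else median
  ft <- as_tibble(ft)
  for (g in c(wt, disease, treated)) {
    if (!g %in% ft$condition) abort(sprintf("condition '%s' not present", g))
  }
  purrr::map(freq_cell_types(ft), function(ct) {
    cw <- fun(ft[[ct]][ft$condition == wt])
    cd <- fun(ft[[ct]][ft$condition == disease])
    cc <- fun(ft[[ct]][ft$condition == treated])
    d <- cd - cw
    tibble(
      cell_type = ct,
      direction_vs_wt = if (d > 0) "increase" else if (d < 0) "decrease"
                        else "none",
      recovered = if (d == 0) NA else abs(cc - cw) < abs(d)
    )
  }) |> bind_rows()
}
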