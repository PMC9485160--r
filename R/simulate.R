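# Synthetic 10x-style library generation with exact ground truth. The
# generator emulates Chromium 3' v3 chemistry (16 bp barcode + 12 bp UMI in
# R1, cDNA fragment in R2) over a compact transcript model with one focal
# skippable exon, so the whole detection pipeline can be validated offline.

#' Generate a synthetic multi-exon transcript model
#'
#' Random uniform base composition; exon boundaries every `exon_len` bases.
#' A compact stand-in for a real mRNA accession when designing and testing
#' junction probes.
#'
#' @param n_exons number of exons.
#' @param exon_len length of each exon in bases.
#' @param seed RNG seed.
#' @return a [transcript_model()].
#' @export
sim_transcript <- function(n_exons = 5L, exon_len = 120L, seed = 1L) {
  set.seed(seed)
  seqs <- random_dna(1L, n_exons * exon_len)
  ends <- seq_len(n_exons) * exon_len
  transcript_model(
    seqs,
    tibble(exon_index = seq_len(n_exons),
           start = ends - exon_len + 1L, end = ends),
    transcript_id = sprintf("SYN%02d", n_exons)
  )
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the read simulator. Defaults emulate
#' a small exon-skipping study: three conditions in which the per-molecule
#' probability that the focal exon is skipped is 0 (wild type), 0.01
#' (disease) and 0.10 (disease + antisense-oligonucleotide treatment, a
#' 10-fold enrichment).
#'
#' @param model a [transcript_model()]; default [sim_transcript()].
#' @param skip_exon focal exon whose exclusion defines the skipping
#'   junction; must have a neighbour on both sides.
#' @param conditions named numeric vector: per-molecule skip probability per
#'   condition.
#' @param n_cells cells per condition (scalar or named like `conditions`).
#' @param n_samples_per_condition samples each condition's cells are split
#'   over (round-robin).
#' @param molecules_per_cell Poisson mean of captured transcript molecules
#'   per cell.
#' @param junction_overlap_frac fraction of molecules whose fragment is
#'   drawn over the junction region (the rest are exon-interior background).
#' @param fragment_len,read_len_r2 cDNA fragment and read-2 lengths (bases).
#' @param chem a [chemistry()] specification.
#' @param pcr_geom_prob geometric success probability for the PCR duplicate
#'   count (reads per molecule = 1 + Geom(p)); `NULL` disables duplication.
#' @param error_rate per-base substitution error probability on read 2.
#' @param junction_placement `"uniform"` places the junction point uniformly
#'   within the fragment; `"centered"` places it mid-fragment so every
#'   junction molecule is detectable by a spanning probe.
#' @param k,min_overhang probe geometry used for the per-molecule
#'   "detectable" flag in the truth table.
#' @param cluster cluster label written to the annotation table.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(model = sim_transcript(),
                       skip_exon = 3L,
                       conditions = c(WT = 0, mdx = 0.01, mdx_e23AON = 0.10),
                       n_cells = 100L,
                       n_samples_per_condition = 1L,
                       molecules_per_cell = 20,
                       junction_overlap_frac = 0.1,
                       fragment_len = 90L,
                       read_len_r2 = 90L,
                       chem = chemistry("v3"),
                       pcr_geom_prob = 0.5,
                       error_rate = 0.001,
                       junction_placement = c("uniform", "centered"),
                       k = 25L, min_overhang = 1L,
                       cluster = "myonuclei") {
  junction_placement <- match.arg(junction_placement)
  stopifnot(inherits(model, "transcript_model"))
  s <- as.integer(skip_exon)
  idx <- model$exons$exon_index
  if (!(s %in% idx) || !((s - 1L) %in% idx) || !((s + 1L) %in% idx)) {
    abort(sprintf("skip_exon %d must have flanking exons in the model", s))
  }
  if (any(conditions < 0 | conditions > 1)) {
    abort("skip probabilities must lie in [0, 1]")
  }
  if (is.null(names(conditions))) abort("conditions must be named")
  if (length(n_cells) == 1L) {
    n_cells <- setNames(rep(as.integer(n_cells), length(conditions)),
                        names(conditions))
  }
  if (junction_overlap_frac < 0 || junction_overlap_frac > 1) {
    abort("junction_overlap_frac must lie in [0, 1]")
  }
  if (fragment_len < k) {
    abort(sprintf("fragment_len (%d) must be >= k (%d)", fragment_len, k))
  }
  if (error_rate < 0 || error_rate > 1) abort("error_rate must lie in [0, 1]")
  stopifnot(fragment_len > 0, read_len_r2 > 0, molecules_per_cell > 0)

  specs <- junction_specs(left = c(s - 1L, s, s - 1L),
                          right = c(s, s + 1L, s + 1L))
  structure(list(
    model = model, skip_exon = s, specs = specs,
    conditions = conditions, n_cells = n_cells,
    n_samples_per_condition = as.integer(n_samples_per_condition),
    molecules_per_cell = molecules_per_cell,
    junction_overlap_frac = junction_overlap_frac,
    fragment_len = as.integer(fragment_len),
    read_len_r2 = as.integer(read_len_r2),
    chem = chem, pcr_geom_prob = pcr_geom_prob,
    error_rate = error_rate, junction_placement = junction_placement,
    k = as.integer(k), min_overhang = as.integer(min_overhang),
    cluster = cluster
  ), class = "sim_config")
}

mutate_bases <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(ch)) < error_rate)
    for (i in hit) {
      ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

write_fastq_gz <- function(ids, seqs, path) {
  con <- gzfile(path, open = "wt")
  on.exit(close(con))
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con, sep = "\n")
  invisible(path)
}

# distinct barcodes of the given length, deterministic under the RNG state
draw_unique_dna <- function(n, len) {
  out <- character(0)
  while (length(out) < n) {
    out <- unique(c(out, random_dna(n - length(out), len)))
  }
  out
}

#' Simulate a paired 10x-style FASTQ library with ground truth
#'
#' Every cell gets a unique whitelist barcode and every molecule a distinct
#' UMI. A configurable fraction of molecules spans the focal junction
#' region; those molecules carry the skipped or unskipped splice form
#' according to the condition's per-molecule skip probability, and their
#' fragment places the junction point uniformly (or centrally) within the
#' fragment. Background molecules are drawn from exon interiors, so no read
#' can contain a junction-spanning probe unless its molecule truly spans
#' the junction. PCR duplicates replicate a molecule's read with fresh
#' per-base substitution errors. Output is fully determined by `seed`.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory for `R1.fastq.gz`, `R2.fastq.gz`,
#'   `annotation.tsv`, `whitelist.txt` and `truth.json`.
#' @param seed RNG seed controlling every random draw.
#' @return list with file `paths`, the `truth` tables (`molecules`,
#'   `per_cell`, `per_condition`, `reads`), the `annotation` tibble and the
#'   `whitelist`.
#' @export
simulate_library <- function(cfg, out_dir, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- cfg$model
  s <- cfg$skip_exon
  exons <- model$exons
  epos <- function(i) exons[exons$exon_index == i, ]

  # spliced source sequences and their junction-point coordinates
  full_seq <- model$sequence
  left_end <- epos(s - 1L)$end              # junction point, unskipped: e(s-1)|e(s)
  skip_row <- epos(s)
  skipped_seq <- paste0(substr(full_seq, 1L, skip_row$start - 1L),
                        substr(full_seq, skip_row$end + 1L, nchar(full_seq)))
  can_left_lab <- cfg$specs$label[1]   # e(s-1)-e(s)
  can_right_lab <- cfg$specs$label[2]  # e(s)-e(s+1)
  skip_lab <- cfg$specs$label[3]       # e(s-1)-e(s+1)
  jpoint <- c(left_end, epos(s)$end, left_end)  # in the molecule's own sequence
  names(jpoint) <- c(can_left_lab, can_right_lab, skip_lab)

  n_total_cells <- sum(cfg$n_cells)
  whitelist <- draw_unique_dna(n_total_cells * 2L, cfg$chem$barcode_len)
  cell_barcodes <- whitelist[seq_len(n_total_cells)]

  cells <- tibble(
    barcode = cell_barcodes,
    condition = rep(names(cfg$conditions), cfg$n_cells)
  ) |>
    group_by(.data$condition) |>
    mutate(sample = sprintf("%s_s%d", .data$condition,
                            (row_number() - 1L) %% cfg$n_samples_per_condition + 1L)) |>
    ungroup() |>
    mutate(cluster = cfg$cluster)

  L <- cfg$fragment_len
  rl <- cfg$read_len_r2
  k <- cfg$k
  mo <- cfg$min_overhang

  mol_rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    n_mol <- rpois(1L, cfg$molecules_per_cell)
    if (n_mol == 0L) next
    umis <- indexed_dna(sample.int(4^cfg$chem$umi_len, n_mol) - 1L,
                        cfg$chem$umi_len)
    overlap <- runif(n_mol) < cfg$junction_overlap_frac
    p_skip <- cfg$conditions[[cells$condition[ci]]]
    skipped <- overlap & (runif(n_mol) < p_skip)
    junction <- rep(NA_character_, n_mol)
    junction[overlap & skipped] <- skip_lab
    can_pick <- runif(n_mol) < 0.5
    junction[overlap & !skipped] <- ifelse(can_pick[overlap & !skipped],
                                           can_left_lab, can_right_lab)
    mol_rows[[ci]] <- tibble(
      barcode = cells$barcode[ci], condition = cells$condition[ci],
      umi = umis, junction = junction, is_skipped = skipped,
      overlaps_junction = overlap
    )
  }
  molecules <- bind_rows(mol_rows)
  if (nrow(molecules) == 0L) abort("simulation produced zero molecules")
  molecules$molecule_id <- sprintf("mol%06d", seq_len(nrow(molecules)))

  # fragment construction
  frag <- character(nrow(molecules))
  covers <- logical(nrow(molecules))
  exon_pick_w <- exons$end - exons$start + 1L
  for (i in seq_len(nrow(molecules))) {
    jlab <- molecules$junction[i]
    if (!is.na(jlab)) {
      src <- if (jlab == skip_lab) skipped_seq else full_seq
      jp <- jpoint[[jlab]]
      a <- if (cfg$junction_placement == "centered") L %/% 2L
           else sample.int(L - 1L, 1L)
      start <- jp - a + 1L
      start <- max(1L, min(start, nchar(src) - L + 1L))
      f <- substr(src, start, start + L - 1L)
      f <- substr(f, 1L, rl)
      a_act <- jp - start + 1L
      b_act <- nchar(f) - a_act
      frag[i] <- f
      # a spanning k-window with >= mo bases each side exists iff:
      covers[i] <- a_act >= mo && b_act >= mo && (a_act + b_act) >= k
    } else {
      # background: fragment confined to one exon interior
      e <- sample.int(nrow(exons), 1L, prob = exon_pick_w)
      es <- exons$start[e]; ee <- exons$end[e]
      len <- min(L, ee - es + 1L)
      start <- es + sample.int(ee - es + 2L - len, 1L) - 1L
      frag[i] <- substr(substr(full_seq, start, start + len - 1L), 1L, rl)
      covers[i] <- FALSE
    }
  }
  molecules$fragment <- frag
  molecules$detectable <- covers

  # PCR duplication + errors
  n_reads_per_mol <- if (is.null(cfg$pcr_geom_prob)) rep(1L, nrow(molecules))
    else 1L + rgeom(nrow(molecules), cfg$pcr_geom_prob)
  mol_idx <- rep(seq_len(nrow(molecules)), n_reads_per_mol)
  r2 <- mutate_bases(molecules$fragment[mol_idx], cfg$error_rate)
  r1 <- paste0(molecules$barcode[mol_idx], molecules$umi[mol_idx])
  read_ids <- sprintf("read%07d", seq_along(mol_idx))
  reads <- tibble(read_id = read_ids,
                  molecule_id = molecules$molecule_id[mol_idx])

  paths <- list(
    r1 = file.path(out_dir, "R1.fastq.gz"),
    r2 = file.path(out_dir, "R2.fastq.gz"),
    annotation = file.path(out_dir, "annotation.tsv"),
    whitelist = file.path(out_dir, "whitelist.txt"),
    truth = file.path(out_dir, "truth.json")
  )
  write_fastq_gz(read_ids, r1, paths$r1)
  write_fastq_gz(read_ids, r2, paths$r2)
  annotation <- cells |> select("barcode", "sample", "condition", "cluster")
  write_tsv_plain(annotation, paths$annotation)
  writeLines(whitelist, paths$whitelist)

  per_cell <- molecules |>
    filter(!is.na(.data$junction)) |>
    count(.data$barcode, .data$junction, name = "n_molecules")
  per_condition <- molecules |>
    filter(.data$overlaps_junction) |>
    group_by(.data$condition) |>
    summarise(
      n_skipped = sum(.data$is_skipped),
      n_unskipped = sum(!.data$is_skipped),
      skip_fraction = n_skipped / (n_skipped + n_unskipped),
      .groups = "drop"
    )
  truth <- list(
    molecules = molecules |>
      select("molecule_id", "barcode", "condition", "umi", "junction",
             "is_skipped", "overlaps_junction", "detectable"),
    per_cell = per_cell,
    per_condition = per_condition,
    reads = reads
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  list(paths = paths, truth = truth, annotation = annotation,
       whitelist = whitelist, specs = cfg$specs)
}

#' Simulate a per-sample cell-type frequency cohort
#'
#' Draws each sample's cell-type composition from a condition-specific
#' Dirichlet distribution (via normalised gamma draws) and converts to
#' percentages. With `nuclei_per_sample` set, compositions are discretised
#' by a multinomial draw of that many nuclei first.
#'
#' @param alpha named list: one positive Dirichlet parameter vector per
#'   condition (equal lengths; names are cell types, or types are
#'   auto-named).
#' @param n_samples named integer vector: samples per condition.
#' @param nuclei_per_sample optional nuclei count per sample for multinomial
#'   discretisation.
#' @param seed RNG seed.
#' @return list with `ft` (a `frequency_table`) and `truth` (the generating
#'   parameters).
#' @export
simulate_frequency_cohort <- function(alpha, n_samples,
                                      nuclei_per_sample = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(names(alpha)) || is.null(names(n_samples))) {
    abort("alpha and n_samples must be named by condition")
  }
  if (any(unlist(alpha) <= 0)) abort("Dirichlet parameters must be positive")
  kt <- unique(vapply(alpha, length, integer(1)))
  if (length(kt) != 1L) abort("alpha vectors must have equal lengths")
  types <- names(alpha[[1]]) %||% sprintf("type%02d", seq_len(kt))

  rows <- purrr::imap(alpha, function(a, cond) {
    ns <- n_samples[[cond]]
    purrr::map(seq_len(ns), function(si) {
      g <- rgamma(kt, shape = a, rate = 1)
      p <- g / sum(g)
      if (!is.null(nuclei_per_sample)) {
        cnt <- as.vector(stats::rmultinom(1L, nuclei_per_sample, p))
        p <- cnt / sum(cnt)
      }
      as_tibble(setNames(as.list(100 * p), types)) |>
        mutate(sample = sprintf("%s_s%d", cond, si), condition = cond,
               .before = 1)
    }) |> bind_rows()
  }) |> bind_rows()
  class(rows) <- c("frequency_table", class(rows))
  list(ft = rows, truth = list(alpha = alpha, n_samples = as.list(n_samples),
                               nuclei_per_sample = nuclei_per_sample))
}

#' Simulate a sparse count matrix with planted QC truth
#'
#' Builds a gene x barcode matrix in which a known subset of barcodes falls
#' strictly below a QC threshold and a known subset of genes is
#' mitochondrial (name prefix `mt-`), so filter behaviour can be checked
#' against planted truth.
#'
#' @param n_genes,n_barcodes matrix dimensions.
#' @param n_low barcodes planted below the threshold.
#' @param threshold the genes-detected threshold the planting refers to.
#' @param n_mito_genes genes given the mitochondrial name prefix.
#' @param seed RNG seed.
#' @return list with `cm` (a `count_matrix`) and `truth` (`low_barcodes`,
#'   `mito_genes`, per-barcode planted metrics).
#' @export
simulate_matrix <- function(n_genes = 300L, n_barcodes = 60L, n_low = 15L,
                            threshold = 200L, n_mito_genes = 5L, seed = 1L) {
  set.seed(seed)
  stopifnot(n_low <= n_barcodes, n_mito_genes < n_genes,
            threshold <= n_genes - n_mito_genes)
  gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
  gene_names <- gene_ids
  mito_idx <- sample.int(n_genes, n_mito_genes)
  gene_names[mito_idx] <- sprintf("mt-Gene%d", seq_len(n_mito_genes))
  barcodes <- draw_unique_dna(n_barcodes, 16L)
  low <- sample.int(n_barcodes, n_low)
  non_mito <- setdiff(seq_len(n_genes), mito_idx)

  trip <- purrr::map(seq_len(n_barcodes), function(b) {
    g_target <- if (b %in% low) sample(seq(5L, threshold - 1L), 1L)
      else sample(seq(threshold, min(n_genes - n_mito_genes,
                                     threshold + 60L)), 1L)
    genes <- sample(non_mito, g_target)
    # sprinkle mito counts on some barcodes; they never count toward genes
    mg <- if (runif(1) < 0.5) sample(mito_idx, 1L) else integer(0)
    tibble(gene = c(genes, mg), barcode = b,
           count = 1L + rpois(length(genes) + length(mg), 1.0))
  }) |> bind_rows()

  mat <- Matrix::sparseMatrix(i = trip$gene, j = trip$barcode, x = trip$count,
                              dims = c(n_genes, n_barcodes))
  rownames(mat) <- gene_ids
  colnames(mat) <- barcodes
  cm <- new_count_matrix(mat, tibble(id = gene_ids, name = gene_names))
  nm_mat <- mat[non_mito, , drop = FALSE]
  truth <- list(
    low_barcodes = barcodes[low],
    mito_genes = gene_ids[mito_idx],
    genes_detected_non_mito = setNames(Matrix::colSums(nm_mat > 0), barcodes),
    threshold = threshold
  )
  list(cm = cm, truth = truth)
}
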