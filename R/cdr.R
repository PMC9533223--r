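#' Z-transform a per-window statistic
#'
#' `z = (x - mean(x)) / sd(x)` with the sample standard deviation
#' (denominator `n - 1`) over non-missing windows; missing in, missing out.
#'
#' @param values Numeric vector of per-window values (at least 2 non-missing).
#' @return Numeric vector of z-scores.
#' @export
z_transform <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) abort("need at least 2 non-missing values")
  s <- sd(values[ok])
  if (s == 0) {
    warn("zero standard deviation; z-scores undefined")
    return(rep(NA_real_, length(values)))
  }
  (values - mean(values[ok])) / s
}

#' Log2 diversity ratio between two groups
#'
#' `log2((pi_a + pseudo) / (pi_b + pseudo))`. The pseudocount (default
#' 1e-6 per bp, one substitution per Mb) keeps windows with zero diversity
#' finite; windows where both diversities are zero are `NA`.
#'
#' @param pi_a,pi_b Aligned per-window diversity vectors.
#' @param pseudo Small positive pseudocount.
#' @return Numeric vector of per-window log2 ratios.
#' @export
log2_pi_ratio <- function(pi_a, pi_b, pseudo = 1e-6) {
  if (length(pi_a) != length(pi_b)) abort("window grids differ in length")
  out <- log2((pi_a + pseudo) / (pi_b + pseudo))
  out[!is.na(pi_a) & !is.na(pi_b) & pi_a == 0 & pi_b == 0] <- NA_real_
  out
}

#' CDR scan configuration
#'
#' @param fst_quantile Upper tail fraction for `z_fst` (default 0.05).
#' @param ratio_quantile Lower tail fraction for `log2_pi_ratio`
#'   (default 0.05).
#' @param merge Fuse overlapping/book-ended flagged windows into maximal
#'   regions (default `TRUE`; on a sliding grid adjacent flagged windows
#'   necessarily overlap).
#' @param fst_abs_cutoff Optional absolute weighted-FST threshold used as a
#'   Manhattan-track flag (default 0.15), not part of CDR calling.
#' @param min_snps Windows with fewer retained SNPs are excluded from
#'   quantile estimation and flagging (default 3).
#' @return A `cdr_config` list.
#' @export
cdr_config <- function(fst_quantile = 0.05, ratio_quantile = 0.05,
                       merge = TRUE, fst_abs_cutoff = 0.15, min_snps = 3) {
  stopifnot(fst_quantile > 0, fst_quantile <= 0.5,
            ratio_quantile > 0, ratio_quantile <= 0.5)
  structure(list(fst_quantile = fst_quantile, ratio_quantile = ratio_quantile,
                 merge = isTRUE(merge), fst_abs_cutoff = fst_abs_cutoff,
                 min_snps = min_snps),
            class = "cdr_config")
}

#' Detect candidate divergent regions (CDRs)
#'
#' A window is flagged when it lies simultaneously in the upper tail of
#' `z_fst` and the lower tail of `log2_pi_ratio`; empirical quantiles use
#' linear interpolation between order statistics (type 7) over non-missing
#' windows genome-wide, and ties at a threshold are included in the tail.
#' Flagged windows that overlap or are book-ended are merged into maximal
#' regions when `cfg$merge`.
#'
#' @param table A window tibble carrying `z_fst` and `log2_pi_ratio`
#'   columns (e.g. from [window_stats()]). Fewer than 20 eligible windows
#'   is an error: tail quantiles would be meaningless.
#' @param cfg A [cdr_config()].
#' @return A `cdr_regions` tibble with one row per region: `contig`,
#'   `start`, `end` (0-based half-open), `n_windows`, `window_id`
#'   (list-column of member window row indices), `mean_z_fst`,
#'   `mean_log2_pi_ratio`. Attributes: `n_flagged` (unmerged flagged-window
#'   count), `thresholds`, `config`.
#' @export
detect_cdr <- function(table, cfg = cdr_config()) {
  if (!all(c("z_fst", "log2_pi_ratio") %in% names(table))) {
    abort("`table` must carry z_fst and log2_pi_ratio columns")
  }
  elig <- !is.na(table$z_fst) & !is.na(table$log2_pi_ratio)
  if (!is.null(table$n_sites)) elig <- elig & table$n_sites >= cfg$min_snps
  if (sum(elig) < 20) {
    abort("fewer than 20 eligible windows; tail quantiles are meaningless")
  }
  z_thr <- quantile(table$z_fst[elig], 1 - cfg$fst_quantile, names = FALSE)
  r_thr <- quantile(table$log2_pi_ratio[elig], cfg$ratio_quantile, names = FALSE)
  flagged <- elig & table$z_fst >= z_thr & table$log2_pi_ratio <= r_thr
  idx <- which(flagged)
  regions <- merge_windows(table[idx, , drop = FALSE], idx,
                           merge = cfg$merge)
  class(regions) <- c("cdr_regions", class(regions))
  attr(regions, "n_flagged") <- length(idx)
  attr(regions, "thresholds") <- c(z_fst = z_thr, log2_pi_ratio = r_thr)
  attr(regions, "config") <- cfg
  regions
}

merge_windows <- function(flagged_tbl, idx, merge = TRUE) {
  if (nrow(flagged_tbl) == 0) {
    return(tibble(contig = character(), start = numeric(), end = numeric(),
                  n_windows = integer(), window_id = list(),
                  mean_z_fst = numeric(), mean_log2_pi_ratio = numeric()))
  }
  o <- order(flagged_tbl$contig, flagged_tbl$start)
  flagged_tbl <- flagged_tbl[o, ]
  idx <- idx[o]
  if (!merge) {
    grp <- seq_len(nrow(flagged_tbl))
  } else {
    # a window opens a new region when its contig changes or its start lies
    # beyond every end seen so far on the same contig (book-ended = merged)
    grp <- integer(nrow(flagged_tbl))
    g <- 0L
    run_max <- -Inf
    last_contig <- ""
    for (k in seq_len(nrow(flagged_tbl))) {
      if (flagged_tbl$contig[k] != last_contig ||
          flagged_tbl$start[k] > run_max) {
        g <- g + 1L
        run_max <- -Inf
      }
      run_max <- max(run_max, flagged_tbl$end[k])
      last_contig <- flagged_tbl$contig[k]
      grp[k] <- g
    }
  }
  flagged_tbl$`..grp` <- grp
  flagged_tbl$`..idx` <- idx
  flagged_tbl |>
    group_by(.data$`..grp`) |>
    summarise(contig = first(.data$contig),
              start = min(.data$start), end = max(.data$end),
              n_windows = dplyr::n(),
              window_id = list(.data$`..idx`),
              mean_z_fst = mean(.data$z_fst),
              mean_log2_pi_ratio = mean(.data$log2_pi_ratio),
              .groups = "drop") |>
    select(-"..grp")
}

#' Genes overlapping candidate regions
#'
#' Reads a GFF3 annotation and reports every feature of the requested type
#' whose 1-based inclusive span overlaps a region by at least 1 bp.
#'
#' @param gff Path to a GFF3 file (v1.26 dialect, as read by rtracklayer).
#' @param regions A `cdr_regions` tibble (0-based half-open intervals), or
#'   any tibble with `contig`, `start`, `end` columns.
#' @param feature Feature type to report (default `"gene"`).
#' @return A tibble with one row per overlapped gene: `gene_id`, `contig`,
#'   `gene_start`, `gene_end` (1-based inclusive), `regions` (list-column of
#'   region row indices hit) and `overlap_bp` (total).
#' @export
genes_in_regions <- function(gff, regions, feature = "gene") {
  gr <- rtracklayer::import(gff)
  gr <- gr[as.character(gr$type) == feature]
  if (!length(gr)) {
    return(tibble(gene_id = character(), contig = character(),
                  gene_start = integer(), gene_end = integer(),
                  regions = list(), overlap_bp = integer()))
  }
  unknown <- setdiff(unique(regions$contig),
                     as.character(GenomicRanges::seqnames(gr)))
  if (length(unknown)) {
    warn(sprintf("region contig(s) absent from annotation: %s",
                 paste(unknown, collapse = ", ")))
  }
  reg_gr <- GenomicRanges::GRanges(
    regions$contig,
    IRanges::IRanges(start = regions$start + 1, end = regions$end))
  hits <- GenomicRanges::findOverlaps(gr, reg_gr, minoverlap = 1L)
  if (!length(hits)) {
    return(tibble(gene_id = character(), contig = character(),
                  gene_start = integer(), gene_end = integer(),
                  regions = list(), overlap_bp = integer()))
  }
  ids <- gr$ID %||% gr$Name %||% as.character(seq_along(gr))
  ov <- IRanges::pintersect(gr[S4Vectors::queryHits(hits)],
                            reg_gr[S4Vectors::subjectHits(hits)])
  tibble(gene_idx = S4Vectors::queryHits(hits),
         region = S4Vectors::subjectHits(hits),
         overlap = GenomicRanges::width(ov)) |>
    group_by(.data$gene_idx) |>
    summarise(regions = list(.data$region),
              overlap_bp = sum(.data$overlap), .groups = "drop") |>
    mutate(gene_id = ids[.data$gene_idx],
           contig = as.character(GenomicRanges::seqnames(gr))[.data$gene_idx],
           gene_start = GenomicRanges::start(gr)[.data$gene_idx],
           gene_end = GenomicRanges::end(gr)[.data$gene_idx]) |>
    select("gene_id", "contig", "gene_start", "gene_end",
           "regions", "overlap_bp")
}

#' Region versus genomic background test
#'
#' Two-sided Mann-Whitney U test comparing a window statistic inside a
#' region against all other windows: exact null when both group sizes are
#' at most 8 and there are no ties, otherwise the normal approximation with
#' tie correction. Windows belong to the region when their midpoint falls
#' inside it.
#'
#' @param table A window tibble with the statistic column.
#' @param region List or one-row tibble with `contig`, `start`, `end`
#'   (0-based half-open bp).
#' @param column Name of the statistic column to compare.
#' @return A one-row tibble: `column`, `U`, `n_in`, `n_out`, `p`, `method`.
#' @export
region_vs_background <- function(table, region, column) {
  if (!column %in% names(table)) abort(sprintf("no column '%s'", column))
  mid <- (table$start + table$end) / 2
  inside <- table$contig == region$contig &
    mid >= region$start & mid < region$end
  x <- table[[column]][inside]
  y <- table[[column]][!inside]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) {
    abort("need at least 3 non-missing windows inside and outside the region")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 8 && length(y) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = FALSE))
  tibble(column = column, U = unname(wt$statistic),
         n_in = length(x), n_out = length(y), p = wt$p.value,
         method = if (exact) "exact" else "normal approximation")
}
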