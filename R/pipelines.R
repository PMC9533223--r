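#' Pipeline run configuration
#'
#' Validated bundle of inputs, population roles and thresholds for the
#' three pipeline drivers. Either `vcf` + `popmap` paths or an in-memory
#' `data` ([hap_data]) must be supplied.
#'
#' @param vcf,popmap,gff3 Input paths (popmap required with `vcf`).
#' @param data Optional in-memory [hap_data] (takes precedence).
#' @param out_dir Optional output directory; when set, result tables are
#'   written as TSV/BED with a header comment carrying the package
#'   version, a config hash and the seed.
#' @param group_a,group_b Groups contrasted by the CDR scan (`group_a` is
#'   the selected/divergent candidate whose diversity loss is scanned).
#' @param pop_obs,pop_ref Observed and reference populations for the
#'   haplotype scans.
#' @param populations,outgroup Ingroup labels and outgroup for the
#'   D-statistic pipeline.
#' @param filters A [site_filter()].
#' @param window_size,window_step Sliding-window grid in bp (10 kb / 5 kb).
#' @param cdr A [cdr_config()].
#' @param ehh An [ehh_config()].
#' @param prop_size,prop_min_snps Proportion-window grid (500 kb) and its
#'   minimum tested-SNP count (100).
#' @param region Optional `list(contig=, start=, end=)` (0-based half-open)
#'   for the region-versus-background reports; defaults to the top-ranked
#'   XP-EHH proportion window.
#' @param block_size Jackknife block size (informative sites) for
#'   D statistics.
#' @param seed Seed recorded in outputs and used for any subsampling.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` list.
#' @export
run_config <- function(vcf = NULL, popmap = NULL, gff3 = NULL, data = NULL,
                       out_dir = NULL,
                       group_a = NULL, group_b = NULL,
                       pop_obs = NULL, pop_ref = NULL,
                       populations = NULL, outgroup = NULL,
                       filters = site_filter(),
                       window_size = 1e4, window_step = 5e3,
                       cdr = cdr_config(), ehh = ehh_config(),
                       prop_size = 5e5, prop_min_snps = 100,
                       region = NULL, block_size = 2000,
                       seed = 1, log_level = "info") {
  if (is.null(data)) {
    if (is.null(vcf) || is.null(popmap)) {
      abort("supply either `data` or both `vcf` and `popmap`")
    }
    for (f in c(vcf, popmap, gff3)) {
      if (!file.exists(f)) abort(sprintf("input file '%s' not found", f))
    }
  } else if (!inherits(data, "hap_data")) {
    abort("`data` must be a hap_data object")
  }
  structure(list(vcf = vcf, popmap = popmap, gff3 = gff3, data = data,
                 out_dir = out_dir, group_a = group_a, group_b = group_b,
                 pop_obs = pop_obs, pop_ref = pop_ref,
                 populations = populations, outgroup = outgroup,
                 filters = filters, window_size = window_size,
                 window_step = window_step, cdr = cdr, ehh = ehh,
                 prop_size = prop_size, prop_min_snps = prop_min_snps,
                 region = region, block_size = block_size,
                 seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

cfg_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg[setdiff(names(cfg), c("data", "out_dir"))]), tmp)
  unname(tools::md5sum(tmp))
}

pipe_log <- function(log, cfg, fmt, ...) {
  line <- sprintf(fmt, ...)
  if (!identical(cfg$log_level, "quiet")) inform(line)
  c(log, line)
}

load_dataset <- function(cfg) {
  if (!is.null(cfg$data)) return(cfg$data)
  read_vcf(cfg$vcf, cfg$popmap)
}

check_pops <- function(ds, labels) {
  missing <- setdiff(labels, unique(ds$pops))
  if (length(missing)) {
    abort(sprintf("population(s) not in dataset: %s",
                  paste(missing, collapse = ", ")))
  }
}

write_table <- function(x, cfg, name, bed = FALSE) {
  if (is.null(cfg$out_dir)) return(invisible(NULL))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  path <- file.path(cfg$out_dir, name)
  header <- sprintf("# hapscan %s; config %s; seed %d",
                    as.character(packageVersion("hapscan")),
                    cfg_hash(cfg), cfg$seed)
  writeLines(header, path)
  x <- as.data.frame(x)
  x <- x[, !vapply(x, is.list, logical(1)), drop = FALSE]
  if (bed) {
    readr::write_tsv(x, path, append = TRUE, col_names = FALSE)
  } else {
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  }
  invisible(path)
}

#' Run the candidate-divergent-region pipeline
#'
#' Filters the input, computes the 10-kb/5-kb window statistics for the
#' two groups, derives Z-transformed FST and the log2 diversity ratio,
#' calls CDRs, and (with an annotation) extracts overlapping genes.
#'
#' @param cfg A [run_config()] with `group_a` and `group_b` set.
#' @return A list: `windows` (win_stats tibble), `cdr` (cdr_regions),
#'   `genes` (tibble or `NULL`), `log` (character). With `out_dir`,
#'   `windows.tsv`, `cdr.bed`, `cdr.tsv`, `manhattan_cdr.tsv` and
#'   `genes.tsv` are written.
#' @export
run_cdr_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$group_a) || is.null(cfg$group_b)) {
    abort("cdr pipeline needs `group_a` and `group_b`")
  }
  log <- character(0)
  ds <- stage(cfg, "read", load_dataset(cfg))
  check_pops(ds, c(cfg$group_a, cfg$group_b))
  log <- pipe_log(log, cfg, "read: %d SNPs, %d samples", n_sites(ds),
                  length(ds$sample_ids))
  dsf <- stage(cfg, "filter", apply_site_filters(ds, cfg$filters))
  tly <- attr(dsf, "tally")
  log <- pipe_log(log, cfg, "filter: %d -> %d SNPs (%s)", n_sites(ds),
                  n_sites(dsf),
                  paste(sprintf("%s removed %d", tly$criterion, tly$removed),
                        collapse = ", "))
  windows <- make_windows(dsf$contig_length, cfg$window_size,
                          cfg$window_step, contig = dsf$contig)
  ws <- stage(cfg, "window_stats",
              window_stats(dsf, cfg$group_a, cfg$group_b, windows))
  log <- pipe_log(log, cfg, "window_stats: %d windows", nrow(ws))
  cdr <- stage(cfg, "detect_cdr", detect_cdr(ws, cfg$cdr))
  log <- pipe_log(log, cfg, "detect_cdr: %d flagged windows, %d merged regions",
                  attr(cdr, "n_flagged"), nrow(cdr))
  genes <- NULL
  if (!is.null(cfg$gff3) && nrow(cdr) > 0) {
    genes <- stage(cfg, "genes", genes_in_regions(cfg$gff3, cdr))
    log <- pipe_log(log, cfg, "genes: %d candidate genes", nrow(genes))
  }
  write_table(ws, cfg, "windows.tsv")
  write_table(cdr[c("contig", "start", "end")], cfg, "cdr.bed", bed = TRUE)
  write_table(cdr, cfg, "cdr.tsv")
  mh <- tibble(contig = ws$contig, pos = (ws$start + ws$end) / 2,
               z_fst = ws$z_fst, log2_pi_ratio = ws$log2_pi_ratio)
  write_table(mh, cfg, "manhattan_cdr.tsv")
  if (!is.null(genes)) write_table(genes, cfg, "genes.tsv")
  list(windows = ws, cdr = cdr, genes = genes, log = log)
}

stage <- function(cfg, name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the haplotype-based sweep-scan pipeline
#'
#' Produces the FST Manhattan table with an absolute cut-off track, the
#' four EHH-family scans (XP-EHH and XP-nSL of `pop_obs` versus `pop_ref`;
#' iHS and nSL within `pop_obs`), their standardization, 500-kb
#' proportion-of-extreme-SNP tables with 95/99 percentile tiers, and
#' region-versus-background Mann-Whitney reports for FST, diversity and
#' Tajima's D.
#'
#' @param cfg A [run_config()] with `pop_obs` and `pop_ref` set; input must
#'   be phased.
#' @return A list: `fst_track`, `scans`, `prop`, `mwu`, `region`, `log`.
#' @export
run_sweep_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$pop_obs) || is.null(cfg$pop_ref)) {
    abort("sweep pipeline needs `pop_obs` and `pop_ref`")
  }
  log <- character(0)
  ds <- stage(cfg, "read", load_dataset(cfg))
  if (!ds$phased) abort("sweep pipeline requires phased input haplotypes")
  check_pops(ds, c(cfg$pop_obs, cfg$pop_ref))
  log <- pipe_log(log, cfg, "read: %d SNPs", n_sites(ds))
  dsf <- stage(cfg, "filter", apply_site_filters(ds, cfg$filters))
  log <- pipe_log(log, cfg, "filter: %d -> %d SNPs", n_sites(ds), n_sites(dsf))

  windows <- make_windows(dsf$contig_length, cfg$window_size,
                          cfg$window_step, contig = dsf$contig)
  ws <- window_stats(dsf, cfg$pop_obs, cfg$pop_ref, windows)
  fst_track <- ws |>
    mutate(pos = (.data$start + .data$end) / 2,
           above_cutoff = !is.na(.data$fst) &
             .data$fst >= cfg$cdr$fst_abs_cutoff) |>
    select("contig", "pos", "start", "end", "fst", "above_cutoff")
  log <- pipe_log(log, cfg, "fst track: %d windows, %d above cutoff %.2f",
                  nrow(fst_track), sum(fst_track$above_cutoff),
                  cfg$cdr$fst_abs_cutoff)

  scans <- list(
    xpehh = xp_scan(dsf, cfg$pop_obs, cfg$pop_ref, "bp", cfg$ehh),
    xpnsl = xp_scan(dsf, cfg$pop_obs, cfg$pop_ref, "sites", cfg$ehh))
  if (!is.null(dsf$ancestral)) {
    scans$ihs <- ihs_scan(dsf, cfg$pop_obs, "bp", cfg$ehh)
    scans$nsl <- ihs_scan(dsf, cfg$pop_obs, "sites", cfg$ehh)
  } else {
    log <- pipe_log(log, cfg,
                    "no ancestral states: iHS/nSL skipped")
  }
  scans <- lapply(scans, function(s) suppressWarnings(standardize_scores(s)))
  prop <- list()
  for (nm in names(scans)) {
    pw <- tryCatch(
      proportion_windows(scans[[nm]], size = cfg$prop_size,
                         min_snps = cfg$prop_min_snps,
                         contig_length = dsf$contig_length),
      error = function(e) NULL)
    if (is.null(pw)) {
      log <- pipe_log(log, cfg, "%s: %d cores, %d scored; proportion table skipped (too few tested SNPs per window)",
                      nm, nrow(scans[[nm]]), sum(!is.na(scans[[nm]]$std)))
    } else {
      prop[[nm]] <- pw
      log <- pipe_log(log, cfg, "%s: %d cores, %d scored, %d proportion windows",
                      nm, nrow(scans[[nm]]), sum(!is.na(scans[[nm]]$std)),
                      nrow(pw))
    }
  }
  if (is.null(prop$xpehh)) {
    abort("no XP-EHH proportion window retained; lower `prop_min_snps` or enlarge windows")
  }

  region <- cfg$region
  if (is.null(region)) {
    top <- prop$xpehh[which.max(prop$xpehh$proportion), ]
    region <- list(contig = top$contig, start = top$start, end = top$end)
  }
  mwu <- bind_rows(lapply(c("fst", "pi_a", "tajima_d"), function(col) {
    region_vs_background(ws, region, col)
  }))
  log <- pipe_log(log, cfg, "region %s:%d-%d vs background: %s",
                  region$contig, region$start, region$end,
                  paste(sprintf("%s p=%.3g", mwu$column, mwu$p),
                        collapse = ", "))

  write_table(fst_track, cfg, "fst_manhattan.tsv")
  for (nm in names(scans)) {
    write_table(scans[[nm]], cfg, sprintf("scan_%s.tsv", nm))
    if (!is.null(prop[[nm]])) write_table(prop[[nm]], cfg, sprintf("prop_%s.tsv", nm))
  }
  write_table(mwu, cfg, "region_tests.tsv")
  list(fst_track = fst_track, scans = scans, prop = prop, mwu = mwu,
       region = region, log = log)
}

#' Run the ABBA-BABA pipeline
#'
#' Thin orchestration over [dstat_trios()] for every ingroup trio against
#' the configured outgroup.
#'
#' @param cfg A [run_config()] with at least 3 `populations` and an
#'   `outgroup`.
#' @return A list: `trios` (tibble), `log`. With `out_dir`, `dstat.tsv` is
#'   written.
#' @export
run_dstat_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (length(cfg$populations) < 3 || is.null(cfg$outgroup)) {
    abort("dstat pipeline needs >= 3 ingroup populations and an outgroup")
  }
  log <- character(0)
  ds <- stage(cfg, "read", load_dataset(cfg))
  check_pops(ds, c(cfg$populations, cfg$outgroup))
  if (length(unique(ds$pops)) < 4) {
    abort("dstat pipeline needs at least 4 populations in the popmap")
  }
  log <- pipe_log(log, cfg, "read: %d SNPs", n_sites(ds))
  trios <- stage(cfg, "dstat",
                 dstat_trios(ds, cfg$populations, cfg$outgroup,
                             block_size = cfg$block_size))
  log <- pipe_log(log, cfg, "dstat: %d trio(s); max |Z| = %.2f",
                  nrow(trios), max(abs(trios$Z), na.rm = TRUE))
  write_table(trios, cfg, "dstat.tsv")
  list(trios = trios, log = log)
}
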