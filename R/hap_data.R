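#' Phased haplotype dataset
#'
#' The in-memory substrate for every statistic in hapscan: a haplotype
#' matrix with one row per haplotype (two consecutive rows per diploid
#' sample, in sample order) and one column per biallelic SNP, plus per-site
#' and per-sample metadata.
#'
#' @param contig Contig (chromosome) identifier, length 1.
#' @param positions Integer vector of strictly increasing 1-based physical
#'   positions (bp).
#' @param H Integer matrix of 0/1 allele codes (`NA` = missing), one row per
#'   haplotype, `2 * length(sample_ids)` rows in total.
#' @param sample_ids Character vector of diploid sample identifiers.
#' @param pops Character vector of population labels, parallel to
#'   `sample_ids`.
#' @param alleles Two-column character matrix (or data frame) of REF/ALT
#'   nucleotides per site; defaults to `"A"`/`"C"` for simulated data.
#' @param ancestral Optional integer vector per site: 0 if the REF allele is
#'   ancestral, 1 if the ALT allele is ancestral, `NA` if unknown.
#' @param phased Logical flag; haplotype-based statistics refuse unphased
#'   data rather than pseudo-phasing it.
#' @param contig_length Optional contig length in bp (used for windowing);
#'   defaults to the last position.
#'
#' @return An object of class `hap_data`.
#' @export
hap_data <- function(contig, positions, H, sample_ids, pops,
                     alleles = NULL, ancestral = NULL, phased = TRUE,
                     contig_length = NULL) {
  positions <- as.integer(positions)
  if (!is.matrix(H)) H <- as.matrix(H)
  storage.mode(H) <- "integer"
  if (is.null(alleles)) {
    alleles <- cbind(ref = rep("A", length(positions)),
                     alt = rep("C", length(positions)))
  }
  alleles <- as.matrix(alleles)
  colnames(alleles) <- c("ref", "alt")
  ds <- structure(list(
    contig = as.character(contig)[1],
    positions = positions,
    alleles = alleles,
    H = H,
    sample_ids = as.character(sample_ids),
    pops = as.character(pops),
    ancestral = if (is.null(ancestral)) NULL else as.integer(ancestral),
    phased = isTRUE(phased),
    contig_length = as.numeric(contig_length %||%
                                 (if (length(positions)) max(positions) else 0))
  ), class = "hap_data")
  validate_hap_data(ds)
  ds
}

validate_hap_data <- function(ds) {
  stopifnot(is.matrix(ds$H))
  n_site <- length(ds$positions)
  if (ncol(ds$H) != n_site) {
    abort("`H` must have one column per position")
  }
  if (nrow(ds$H) != 2L * length(ds$sample_ids)) {
    abort("`H` must have two rows per diploid sample")
  }
  if (length(ds$pops) != length(ds$sample_ids)) {
    abort("`pops` must be parallel to `sample_ids`")
  }
  if (n_site > 1 && any(diff(ds$positions) <= 0)) {
    abort("`positions` must be strictly increasing")
  }
  bad <- ds$H[!is.na(ds$H)]
  if (length(bad) && !all(bad %in% c(0L, 1L))) {
    abort("`H` entries must be 0, 1 or NA")
  }
  if (!is.null(ds$ancestral) && length(ds$ancestral) != n_site) {
    abort("`ancestral` must have one entry per site")
  }
  invisible(ds)
}

#' @exportS3Method base::print
print.hap_data <- function(x, ...) {
  cat(sprintf(
    "<hap_data> %s: %d sites, %d samples (%d haplotypes), %d population(s)%s\n",
    x$contig, n_sites(x), length(x$sample_ids), nrow(x$H),
    length(unique(x$pops)), if (x$phased) "" else " [unphased]"))
  tb <- table(x$pops)
  cat("  ", paste(sprintf("%s: %d", names(tb), as.integer(tb)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Number of SNP sites in a dataset
#' @param ds A [hap_data] object.
#' @return Integer site count.
#' @export
n_sites <- function(ds) length(ds$positions)

#' Haplotype row indices for a population
#' @param ds A [hap_data] object.
#' @param pop Population label.
#' @return Integer vector of row indices into `ds$H`.
#' @export
pop_rows <- function(ds, pop) {
  idx <- which(ds$pops == pop)
  if (!length(idx)) abort(sprintf("population '%s' not present", pop))
  sort(c(2L * idx - 1L, 2L * idx))
}

#' Per-site allele-1 frequency within a population
#' @inheritParams pop_rows
#' @return Numeric vector of allele-1 frequencies over non-missing
#'   haplotypes (NaN where all entries are missing).
#' @export
pop_freq <- function(ds, pop) {
  Hp <- ds$H[pop_rows(ds, pop), , drop = FALSE]
  colSums(Hp == 1L, na.rm = TRUE) / colSums(!is.na(Hp))
}

#' Restrict a dataset to a subset of sites
#' @param ds A [hap_data] object.
#' @param keep Logical or integer index of sites to retain (order preserved).
#' @return A [hap_data] with the selected sites.
#' @export
subset_sites <- function(ds, keep) {
  ds$positions <- ds$positions[keep]
  ds$alleles <- ds$alleles[keep, , drop = FALSE]
  ds$H <- ds$H[, keep, drop = FALSE]
  if (!is.null(ds$ancestral)) ds$ancestral <- ds$ancestral[keep]
  validate_hap_data(ds)
  ds
}

#' Read a sample-to-population map
#'
#' Two-column whitespace- or tab-separated text, `sample<TAB>population`,
#' with `#` comment lines.
#'
#' @param path File path.
#' @return A tibble with columns `sample`, `population`.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) abort(sprintf("popmap '%s' not found", path))
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("sample", "population"),
                          colClasses = "character")
  as_tibble(df)
}

parse_region <- function(region) {
  # samtools dialect: contig[:start-end], 1-based inclusive
  m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
  if (!length(m)) abort(sprintf("cannot parse region '%s'", region))
  list(contig = m[2],
       start = if (nzchar(m[4])) as.numeric(m[4]) else NA_real_,
       end = if (nzchar(m[5])) as.numeric(m[5]) else NA_real_)
}

#' Read phased haplotypes from a VCF
#'
#' Loads biallelic SNP records for one contig (or a region of it) into a
#' [hap_data] object. Non-SNP and multiallelic records are skipped with a
#' message. Unphased heterozygote genotypes are loaded but flag the dataset
#' `phased = FALSE`, which makes the EHH-family scans refuse it.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param popmap A tibble as returned by [read_popmap()], or a path to one.
#'   Samples in the popmap must exist in the VCF; the dataset is restricted
#'   to popmap samples, in popmap order.
#' @param region Optional `contig` or `contig:start-end` string (1-based
#'   inclusive). Defaults to the first contig in the file.
#' @return A [hap_data] object. Ancestral states are taken from the INFO
#'   `AA=` field when present (matched against REF/ALT).
#' @export
read_vcf <- function(path, popmap, region = NULL) {
  if (!file.exists(path)) abort(sprintf("VCF '%s' not found", path))
  if (is.character(popmap)) popmap <- read_popmap(popmap)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) abort("VCF contains no variant records")
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  reg <- if (is.null(region)) list(contig = chrom[1], start = NA, end = NA)
         else parse_region(region)
  keep <- chrom == reg$contig
  if (!is.na(reg$start)) keep <- keep & pos >= reg$start & pos <= reg$end
  is_snp <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(keep & !is_snp)
  if (n_skip > 0) {
    inform(sprintf("skipped %d non-SNP/multiallelic record(s)", n_skip))
  }
  keep <- keep & is_snp
  if (!any(keep)) abort(sprintf("no SNP records for region '%s'", reg$contig))

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  vcf_samples <- colnames(gt)
  missing_samples <- setdiff(popmap$sample, vcf_samples)
  if (length(missing_samples)) {
    abort(sprintf("popmap sample(s) absent from VCF: %s",
                  paste(missing_samples, collapse = ", ")))
  }
  gt <- gt[, popmap$sample, drop = FALSE]

  gtv <- gt[!is.na(gt)]
  # only unphased *heterozygotes* carry phase ambiguity
  unphased <- any(grepl("/", gtv, fixed = TRUE) &
                    substr(gtv, 1, 1) != substr(gtv, 3, 3) &
                    substr(gtv, 1, 1) != "." & substr(gtv, 3, 3) != ".")
  # rows: site x sample -> haplotype matrix 2*n_samp x n_site
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  code <- function(a) {
    out <- suppressWarnings(as.integer(a))
    out[!a %in% c("0", "1")] <- NA_integer_
    out
  }
  n_site <- nrow(gt)
  n_samp <- ncol(gt)
  H <- matrix(NA_integer_, nrow = 2L * n_samp, ncol = n_site)
  H[seq(1L, 2L * n_samp, by = 2L), ] <- t(matrix(code(a1), n_site, n_samp))
  H[seq(2L, 2L * n_samp, by = 2L), ] <- t(matrix(code(a2), n_site, n_samp))

  anc <- rep(NA_integer_, n_site)
  info <- fix[keep, "INFO"]
  aa <- sub(".*(^|;)AA=([^;]+).*", "\\2", info)
  has_aa <- grepl("AA=", info, fixed = TRUE)
  anc[has_aa & aa == ref[keep]] <- 0L
  anc[has_aa & aa == alt[keep]] <- 1L

  contig_len <- NULL
  ctg_meta <- grep("^##contig", v@meta, value = TRUE)
  hit <- grep(sprintf("ID=%s[,>]", reg$contig), ctg_meta, value = TRUE)
  if (length(hit)) {
    len <- sub(".*length=([0-9]+).*", "\\1", hit[1])
    if (grepl("^[0-9]+$", len)) contig_len <- as.numeric(len)
  }

  ord <- order(pos[keep])
  hap_data(contig = reg$contig,
           positions = pos[keep][ord],
           H = H[, ord, drop = FALSE],
           sample_ids = popmap$sample,
           pops = popmap$population,
           alleles = cbind(ref = ref[keep][ord], alt = alt[keep][ord]),
           ancestral = if (any(has_aa)) anc[ord] else NULL,
           phased = !unphased,
           contig_length = contig_len)
}

#' Write a dataset as a phased VCF 4.2 file
#'
#' @param ds A [hap_data] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=hapscan",
    sprintf("##contig=<ID=%s,length=%d>", ds$contig, as.integer(ds$contig_length)),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ds$sample_ids), collapse = "\t")
  ), con)
  n_samp <- length(ds$sample_ids)
  odd <- seq(1L, 2L * n_samp, by = 2L)
  sep <- if (ds$phased) "|" else "/"
  gt_chr <- function(a) ifelse(is.na(a), ".", as.character(a))
  for (j in seq_along(ds$positions)) {
    g <- paste0(gt_chr(ds$H[odd, j]), sep, gt_chr(ds$H[odd + 1L, j]))
    info <- if (is.null(ds$ancestral) || is.na(ds$ancestral[j])) "." else
      sprintf("AA=%s", ds$alleles[j, ds$ancestral[j] + 1L])
    writeLines(paste(c(ds$contig, ds$positions[j], ".", ds$alleles[j, 1],
                       ds$alleles[j, 2], ".", ".", info, "GT", g),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a sample-to-population map
#' @param ds A [hap_data] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(ds, path) {
  writeLines(paste(ds$sample_ids, ds$pops, sep = "\t"), path)
  invisible(path)
}
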