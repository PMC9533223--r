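#' SNP site filter settings
#'
#' Mirrors the usual resequencing-study filter set: biallelic SNPs only,
#' a cap on per-site missingness, a minor-allele-frequency floor, and
#' optional mean-depth bounds that only apply when the source VCF carried
#' per-site depth.
#'
#' @param biallelic_only Keep biallelic SNPs only (always true for data read
#'   through [read_vcf()], which drops other records at parse time).
#' @param max_missing Maximum fraction of missing haplotype entries per site,
#'   in `[0, 1]`. Default 0.2.
#' @param min_maf Minor-allele-frequency floor over non-missing haplotype
#'   entries, in `[0, 0.5]`. Default 0.05.
#' @param min_meanDP,max_meanDP Optional mean-depth bounds; no-ops when the
#'   dataset has no per-site depth.
#' @return A `site_filter` list.
#' @export
site_filter <- function(biallelic_only = TRUE, max_missing = 0.2,
                        min_maf = 0.05, min_meanDP = NULL, max_meanDP = NULL) {
  stopifnot(max_missing >= 0, max_missing <= 1,
            min_maf >= 0, min_maf <= 0.5)
  structure(list(biallelic_only = isTRUE(biallelic_only),
                 max_missing = max_missing, min_maf = min_maf,
                 min_meanDP = min_meanDP, max_meanDP = max_meanDP),
            class = "site_filter")
}

#' Apply site filters to a haplotype dataset
#'
#' Missingness is the fraction of missing haplotype entries at a site; MAF
#' is computed over non-missing haplotype entries (a single consistent
#' denominator, rather than diploid genotypes). Site order is preserved.
#' A per-criterion removal tally is attached as attribute `"tally"`.
#'
#' @param ds A [hap_data] object.
#' @param f A [site_filter()].
#' @return The filtered [hap_data]; `attr(, "tally")` is a tibble with one
#'   row per criterion and the number of sites it removed (a site failing
#'   several criteria counts towards each).
#' @export
apply_site_filters <- function(ds, f = site_filter()) {
  stopifnot(inherits(ds, "hap_data"), inherits(f, "site_filter"))
  n_hap <- nrow(ds$H)
  n_miss <- colSums(is.na(ds$H))
  miss_frac <- n_miss / n_hap
  n_obs <- n_hap - n_miss
  c1 <- colSums(ds$H == 1L, na.rm = TRUE)
  freq <- ifelse(n_obs > 0, c1 / n_obs, NaN)
  maf <- pmin(freq, 1 - freq)

  fail_miss <- miss_frac > f$max_missing
  fail_maf <- is.nan(maf) | maf < f$min_maf
  dp <- ds$site_meanDP
  fail_dp <- rep(FALSE, n_sites(ds))
  if (!is.null(dp)) {
    if (!is.null(f$min_meanDP)) fail_dp <- fail_dp | dp < f$min_meanDP
    if (!is.null(f$max_meanDP)) fail_dp <- fail_dp | dp > f$max_meanDP
  }
  keep <- !(fail_miss | fail_maf | fail_dp)
  out <- subset_sites(ds, keep)
  if (!any(keep)) warn("all sites removed by filters")
  attr(out, "tally") <- tibble(
    criterion = c("max_missing", "min_maf", "meanDP"),
    removed = c(sum(fail_miss), sum(fail_maf), sum(fail_dp)))
  out
}
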