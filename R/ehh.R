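#' EHH scan truncation settings
#'
#' Extension away from a core SNP stops once EHH falls below `cutoff`
#' (0.05); cores are voided when a gap between consecutive SNPs along the
#' extension exceeds `max_gap` (200 kb) or when the curve reaches a
#' chromosome edge while still above the cutoff. Physical-distance scans
#' additionally truncate (without voiding) at `max_extend_bp` (1 Mb) from
#' the core; site-distance (nSL-type) scans truncate at
#' `max_extend_sites` (200) sites. These mirror the documented defaults of
#' the standard haplotype-scan tool so synthetic results are comparable.
#'
#' @param cutoff EHH decay cutoff.
#' @param max_extend_bp Maximum physical extension from the core, bp.
#' @param max_extend_sites Maximum extension in segregating sites
#'   (site-distance scans).
#' @param max_gap Maximum tolerated gap between consecutive SNPs, bp.
#' @param maf_min Core-site minor-allele-frequency floor.
#' @return An `ehh_config` list.
#' @export
ehh_config <- function(cutoff = 0.05, max_extend_bp = 1e6,
                       max_extend_sites = 200, max_gap = 2e5,
                       maf_min = 0.05) {
  structure(list(cutoff = cutoff, max_extend_bp = max_extend_bp,
                 max_extend_sites = max_extend_sites, max_gap = max_gap,
                 maf_min = maf_min), class = "ehh_config")
}

# one-directional scan; returns recorded EHH values, their bp distances,
# site offsets, and a status in {"ok", "edge", "gap"}
ehh_side <- function(H, rows, grp0, core, dir, cfg, mode,
                     positions, forced_steps = NULL) {
  S <- ncol(H)
  sites_to_edge <- if (dir > 0) S - core else core - 1L
  if (mode == "bp") {
    lim <- positions[core] + dir * cfg$max_extend_bp
    within <- if (dir > 0) sum(positions > positions[core] & positions <= lim)
              else sum(positions < positions[core] & positions >= lim)
    max_steps <- within
  } else {
    max_steps <- min(cfg$max_extend_sites, sites_to_edge)
  }
  cutoff <- cfg$cutoff
  if (!is.null(forced_steps)) {
    max_steps <- forced_steps
    cutoff <- -1
  }
  e <- cpp_ehh_steps(H, rows - 1L, grp0, core - 1L, dir, cutoff, max_steps)
  t <- length(e)
  idx <- core + dir * seq_len(t)
  dist <- abs(positions[idx] - positions[core])
  status <- "ok"
  if (is.null(forced_steps)) {
    stopped_below <- t > 0 && e[t] < cfg$cutoff
    if (!stopped_below && t == sites_to_edge) status <- "edge"
    gaps <- diff(c(positions[core], positions[idx]))
    if (any(abs(gaps) > cfg$max_gap)) status <- "gap"
  }
  list(ehh = e, dist = dist, offsets = seq_len(t), status = status)
}

# trapezoid integral of an EHH curve over distance (bp or site units),
# anchored at (0, e0)
ehh_integral <- function(side, e0, mode) {
  x <- c(0, if (mode == "bp") side$dist else side$offsets)
  y <- c(e0, side$ehh)
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Extended haplotype homozygosity curve around a core SNP
#'
#' EHH at offset `k` is the probability that two haplotypes of the chosen
#' class are identical over the inclusive span from the core to offset `k`:
#' `sum_g C(m_g, 2) / C(m, 2)` where the `m` class haplotypes are
#' partitioned into identical extended haplotypes of sizes `m_g`. Allele
#' classes 0/1 use the carriers of that core allele (EHH = 1 at the core);
#' `"pooled"` uses all haplotypes with the partition seeded by the core
#' allele (the cross-population convention, EHH at the core equal to the
#' core-site homozygosity).
#'
#' @param ds A phased [hap_data] object.
#' @param pop Population label.
#' @param core Site index (1-based, into `ds$positions`).
#' @param allele `0`, `1`, or `"pooled"`.
#' @param cfg An [ehh_config()].
#' @return An `ehh_curve` tibble with columns `offset` (signed site
#'   offset), `position`, `distance_bp` and `ehh`; attributes `status_left`
#'   / `status_right` record truncation outcomes.
#' @export
ehh_curve <- function(ds, pop, core, allele = 1, cfg = ehh_config()) {
  if (!ds$phased) abort("EHH requires phased data")
  rows <- pop_rows(ds, pop)
  al <- ds$H[rows, core]
  if (identical(allele, "pooled")) {
    keep <- !is.na(al)
    rows <- rows[keep]
    grp0 <- al[keep]
    m <- length(rows)
    cnt <- table(grp0)
    e0 <- sum(cnt * (cnt - 1)) / (m * (m - 1))
  } else {
    rows <- rows[!is.na(al) & al == allele]
    grp0 <- rep(0L, length(rows))
    e0 <- 1
  }
  if (length(rows) < 2) {
    abort("fewer than 2 carrier haplotypes for this allele class")
  }
  left <- ehh_side(ds$H, rows, grp0, core, -1L, cfg, "bp", ds$positions)
  right <- ehh_side(ds$H, rows, grp0, core, +1L, cfg, "bp", ds$positions)
  out <- tibble(
    offset = c(-rev(left$offsets), 0L, right$offsets),
    position = ds$positions[core + c(-rev(left$offsets), 0L, right$offsets)],
    distance_bp = c(rev(left$dist), 0, right$dist),
    ehh = c(rev(left$ehh), e0, right$ehh))
  class(out) <- c("ehh_curve", class(out))
  attr(out, "status_left") <- left$status
  attr(out, "status_right") <- right$status
  attr(out, "core_position") <- ds$positions[core]
  out
}

#' iHS / nSL scan within one population
#'
#' For each core SNP passing the MAF floor and with known ancestral state,
#' the ancestral- and derived-carrier EHH curves are integrated by the
#' composite trapezoid rule over physical distance (`mode = "bp"`, iHS) or
#' over site index with unit spacing (`mode = "sites"`, nSL). The
#' unstandardized score is `ln(iHH_A / iHH_D)`: large negative values mean
#' unusually long derived haplotypes. Cores voided by the truncation rules
#' (see [ehh_config()]) keep their row with missing scores.
#'
#' @param ds A phased [hap_data] with ancestral states.
#' @param pop Population label.
#' @param mode `"bp"` (iHS) or `"sites"` (nSL).
#' @param cfg An [ehh_config()].
#' @return A `scan_scores` tibble: `contig`, `position`, `freq` (derived
#'   allele), `ihh_a`, `ihh_d`, `unstd`, `std` (`NA` until
#'   [standardize_scores()]), `statistic`.
#' @export
ihs_scan <- function(ds, pop, mode = c("bp", "sites"), cfg = ehh_config()) {
  mode <- match.arg(mode)
  if (!ds$phased) abort("iHS/nSL require phased data")
  if (is.null(ds$ancestral)) {
    abort("iHS/nSL require ancestral allele states (`ds$ancestral`)")
  }
  rows <- pop_rows(ds, pop)
  Hp <- ds$H[rows, , drop = FALSE]
  nobs <- colSums(!is.na(Hp))
  c1 <- colSums(Hp == 1L, na.rm = TRUE)
  freq1 <- c1 / nobs
  maf <- pmin(freq1, 1 - freq1)
  cores <- which(maf >= cfg$maf_min & !is.na(ds$ancestral) & nobs >= 4)
  stat_name <- if (mode == "bp") "iHS" else "nSL"
  res <- lapply(cores, function(core) {
    anc <- ds$ancestral[core]
    der <- 1L - anc
    al <- ds$H[rows, core]
    rows_a <- rows[!is.na(al) & al == anc]
    rows_d <- rows[!is.na(al) & al == der]
    dfreq <- length(rows_d) / (length(rows_a) + length(rows_d))
    if (length(rows_a) < 2 || length(rows_d) < 2) {
      return(list(freq = dfreq, ihh_a = NA_real_, ihh_d = NA_real_,
                  unstd = NA_real_))
    }
    ihh <- vapply(list(rows_a, rows_d), function(rr) {
      grp0 <- rep(0L, length(rr))
      l <- ehh_side(ds$H, rr, grp0, core, -1L, cfg, mode, ds$positions)
      r <- ehh_side(ds$H, rr, grp0, core, +1L, cfg, mode, ds$positions)
      if (l$status != "ok" || r$status != "ok") return(NA_real_)
      ehh_integral(l, 1, mode) + ehh_integral(r, 1, mode)
    }, numeric(1))
    unstd <- if (anyNA(ihh) || any(ihh <= 0)) NA_real_ else log(ihh[1] / ihh[2])
    list(freq = dfreq, ihh_a = ihh[1], ihh_d = ihh[2], unstd = unstd)
  })
  out <- tibble(
    contig = ds$contig,
    position = ds$positions[cores],
    freq = map_dbl(res, "freq"),
    ihh_a = map_dbl(res, "ihh_a"),
    ihh_d = map_dbl(res, "ihh_d"),
    unstd = map_dbl(res, "unstd"),
    std = NA_real_,
    statistic = stat_name)
  class(out) <- c("scan_scores", class(out))
  out
}

#' XP-EHH / XP-nSL scan between two populations
#'
#' Pooled-allele EHH is integrated separately within the observed and
#' reference populations over a common span: extension stops when the EHH
#' of the two populations pooled together falls below the cutoff (the
#' cross-population convention), and voiding rules are evaluated on that
#' combined curve. The unstandardized score is `ln(iHH_obs / iHH_ref)`;
#' positive values mean longer haplotype homozygosity in `pop_obs`.
#'
#' @param ds A phased [hap_data] object.
#' @param pop_obs Observed (candidate-sweep) population.
#' @param pop_ref Reference population.
#' @param mode `"bp"` (XP-EHH) or `"sites"` (XP-nSL).
#' @param cfg An [ehh_config()]; the MAF floor applies to the two
#'   populations pooled.
#' @param min_hap Minimum haplotypes per population (default 4).
#' @return A `scan_scores` tibble as in [ihs_scan()], with `freq` the
#'   pooled allele-1 frequency and columns `ihh_obs`, `ihh_ref`.
#' @export
xp_scan <- function(ds, pop_obs, pop_ref, mode = c("bp", "sites"),
                    cfg = ehh_config(), min_hap = 4) {
  mode <- match.arg(mode)
  if (!ds$phased) abort("XP scans require phased data")
  if (identical(pop_obs, pop_ref)) abort("`pop_obs` and `pop_ref` must differ")
  rows_o <- pop_rows(ds, pop_obs)
  rows_r <- pop_rows(ds, pop_ref)
  if (length(rows_o) < min_hap || length(rows_r) < min_hap) {
    abort(sprintf("both populations need at least %d haplotypes", min_hap))
  }
  rows_all <- c(rows_o, rows_r)
  Hall <- ds$H[rows_all, , drop = FALSE]
  nobs <- colSums(!is.na(Hall))
  c1 <- colSums(Hall == 1L, na.rm = TRUE)
  freq1 <- c1 / nobs
  maf <- pmin(freq1, 1 - freq1)
  cores <- which(maf >= cfg$maf_min & nobs >= 4)
  stat_name <- if (mode == "bp") "XP-EHH" else "XP-nSL"
  core_hom <- function(al) {
    al <- al[!is.na(al)]
    m <- length(al)
    n1 <- sum(al == 1L)
    n0 <- m - n1
    (n0 * (n0 - 1) + n1 * (n1 - 1)) / (m * (m - 1))
  }
  res <- lapply(cores, function(core) {
    al_all <- ds$H[rows_all, core]
    keep_all <- !is.na(al_all)
    comb_rows <- rows_all[keep_all]
    comb_grp <- al_all[keep_all]
    l_c <- ehh_side(ds$H, comb_rows, comb_grp, core, -1L, cfg, mode,
                    ds$positions)
    r_c <- ehh_side(ds$H, comb_rows, comb_grp, core, +1L, cfg, mode,
                    ds$positions)
    if (l_c$status != "ok" || r_c$status != "ok") {
      return(list(ihh_obs = NA_real_, ihh_ref = NA_real_, unstd = NA_real_))
    }
    ihh <- vapply(list(rows_o, rows_r), function(rr) {
      al <- ds$H[rr, core]
      keep <- !is.na(al)
      l <- ehh_side(ds$H, rr[keep], al[keep], core, -1L, cfg, mode,
                    ds$positions, forced_steps = length(l_c$ehh))
      r <- ehh_side(ds$H, rr[keep], al[keep], core, +1L, cfg, mode,
                    ds$positions, forced_steps = length(r_c$ehh))
      e0 <- core_hom(al)
      ehh_integral(l, e0, mode) + ehh_integral(r, e0, mode)
    }, numeric(1))
    unstd <- if (any(ihh <= 0)) NA_real_ else log(ihh[1] / ihh[2])
    list(ihh_obs = ihh[1], ihh_ref = ihh[2], unstd = unstd)
  })
  out <- tibble(
    contig = ds$contig,
    position = ds$positions[cores],
    freq = freq1[cores],
    ihh_obs = map_dbl(res, "ihh_obs"),
    ihh_ref = map_dbl(res, "ihh_ref"),
    unstd = map_dbl(res, "unstd"),
    std = NA_real_,
    statistic = stat_name)
  class(out) <- c("scan_scores", class(out))
  out
}

#' Standardize scan scores
#'
#' Within-population statistics (iHS, nSL) are standardized in equal-width
#' derived-allele-frequency bins on (0, 1) — the usual 100-bin scheme —
#' removing the frequency dependence of the unstandardized score.
#' Cross-population statistics use a single genome-wide mean and standard
#' deviation (`scheme = "global"`). Sample standard deviations throughout;
#' bins with fewer than 2 scores, or zero spread, give missing values.
#'
#' @param table A `scan_scores` tibble.
#' @param scheme `"bins"` or `"global"`; defaults by statistic.
#' @param n_bins Number of frequency bins (default 100).
#' @return The table with its `std` column filled.
#' @export
standardize_scores <- function(table, scheme = NULL, n_bins = 100) {
  stat <- table$statistic[1]
  scheme <- scheme %||% (if (stat %in% c("iHS", "nSL")) "bins" else "global")
  scheme <- match.arg(scheme, c("bins", "global"))
  x <- table$unstd
  if (scheme == "global") {
    ok <- !is.na(x)
    if (sum(ok) < 2) abort("need at least 2 scores to standardize")
    s <- sd(x[ok])
    if (s == 0) {
      warn("zero standard deviation; standardized scores undefined")
      table$std <- NA_real_
      return(table)
    }
    table$std <- (x - mean(x[ok])) / s
    return(table)
  }
  bin <- pmin(pmax(ceiling(table$freq * n_bins), 1L), n_bins)
  std <- rep(NA_real_, length(x))
  zero_sd <- FALSE
  for (b in unique(bin)) {
    sel <- which(bin == b & !is.na(x))
    if (length(sel) < 2) next
    s <- sd(x[sel])
    if (s == 0) { zero_sd <- TRUE; next }
    std[sel] <- (x[sel] - mean(x[sel])) / s
  }
  if (zero_sd) warn("zero standard deviation in one or more frequency bins")
  table$std <- std
  table
}

#' Proportion of extreme SNPs in non-overlapping windows
#'
#' Per non-overlapping window (default 500 kb), the proportion of tested
#' SNPs whose standardized score exceeds the threshold — `score > 2` for
#' the cross-population statistics, `|score| > 2` for iHS/nSL. Windows with
#' fewer than `min_snps` tested SNPs (default 100) are excluded; retained
#' windows are given their genome-wide rank percentile of the proportion
#' and significance tiers at the 95th and 99th percentiles.
#'
#' @param table A standardized `scan_scores` tibble.
#' @param threshold Score threshold (default 2).
#' @param two_sided Use `|score|`; defaults by statistic (TRUE for
#'   iHS/nSL, FALSE for XP-EHH/XP-nSL).
#' @param size Window size in bp (default 500 kb).
#' @param min_snps Minimum tested SNPs per retained window (default 100).
#' @param contig_length Optional contig length for the window grid.
#' @return A `prop_windows` tibble: `contig`, `start`, `end`, `n_tested`,
#'   `n_extreme`, `proportion`, `percentile`, `tier`.
#' @export
proportion_windows <- function(table, threshold = 2, two_sided = NULL,
                               size = 5e5, min_snps = 100,
                               contig_length = NULL) {
  if (all(is.na(table$std))) abort("standardized scores required")
  stat <- table$statistic[1]
  two_sided <- two_sided %||% (stat %in% c("iHS", "nSL"))
  score <- if (two_sided) abs(table$std) else table$std
  len <- contig_length %||% max(table$position)
  w <- make_windows(len, size = size, step = size, contig = table$contig[1])
  tested <- !is.na(score)
  n_tested <- as.integer(window_sums(table$position, as.numeric(tested), w))
  n_extreme <- as.integer(window_sums(
    table$position, as.numeric(tested & score > threshold), w))
  w$n_tested <- n_tested
  w$n_extreme <- n_extreme
  w <- w[w$n_tested >= min_snps, , drop = FALSE]
  if (nrow(w) == 0) abort("no window retains enough tested SNPs")
  w$proportion <- w$n_extreme / w$n_tested
  w$percentile <- 100 * rank(w$proportion, ties.method = "average") / nrow(w)
  w$tier <- ifelse(w$percentile >= 99, ">=99%",
                   ifelse(w$percentile >= 95, ">=95%", "none"))
  w$statistic <- stat
  class(w) <- c("prop_windows", class(w))
  w
}
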