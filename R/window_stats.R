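#' Windowed nucleotide diversity
#'
#' Per-site diversity is the unbiased pairwise-difference probability
#' `2*c0*c1 / (n*(n-1))` with `c0`, `c1` the non-missing allele counts.
#' Window diversity divides the summed per-site values by the window length
#' in bp (monomorphic and unobserved base pairs contribute zero), matching
#' the invariant-site convention of the windowed-diversity tools this
#' estimator follows, so genome values land on the familiar per-bp scale.
#'
#' @param ds A [hap_data] object.
#' @param pop Population label (needs at least 2 haplotypes).
#' @param windows Window tibble from [make_windows()].
#' @return The window tibble with columns `n_sites` and `pi` appended.
#' @export
window_pi <- function(ds, pop, windows) {
  rows <- pop_rows(ds, pop)
  if (length(rows) < 2) abort("`pop` needs at least 2 haplotypes")
  if (any(windows$end <= windows$start)) abort("zero-length window")
  site_pi <- site_pi_values(ds$H[rows, , drop = FALSE])
  windows$n_sites <- count_window_sites(ds, windows)
  windows$pi <- window_sums(ds$positions, site_pi, windows) /
    (windows$end - windows$start)
  windows
}

# per-site pairwise-difference probability; 0 where fewer than 2 non-missing
site_pi_values <- function(Hp) {
  n <- colSums(!is.na(Hp))
  c1 <- colSums(Hp == 1L, na.rm = TRUE)
  c0 <- n - c1
  ifelse(n >= 2, 2 * c0 * c1 / (n * (n - 1)), 0)
}

#' Windowed weighted Weir-Cockerham FST
#'
#' Per-site variance components `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals) follow
#' Weir & Cockerham (1984) for two populations, computed on diploid
#' individuals reconstructed from consecutive haplotype row pairs and using
#' the observed-heterozygosity term. The window estimate is the "weighted"
#' ratio of sums `sum(a) / sum(a + b + c)` over sites with a defined
#' denominator. Small negative values are reported as computed. A haploid
#' variant (`haploid = TRUE`) treats every haplotype as an independent
#' allele copy (no heterozygosity term).
#'
#' @param ds A [hap_data] object.
#' @param pop_a,pop_b Distinct population labels.
#' @param windows Window tibble from [make_windows()].
#' @param haploid Use the haploid estimator instead of the diploid one.
#' @return The window tibble with columns `n_sites` and `fst` appended
#'   (`NA` where no site has a defined denominator).
#' @export
window_fst <- function(ds, pop_a, pop_b, windows, haploid = FALSE) {
  if (identical(pop_a, pop_b)) abort("`pop_a` and `pop_b` must differ")
  comp <- fst_site_components(ds, pop_a, pop_b, haploid = haploid)
  windows$n_sites <- count_window_sites(ds, windows)
  num <- window_sums(ds$positions, comp$a, windows)
  den <- window_sums(ds$positions, comp$abc, windows)
  windows$fst <- ifelse(den > 0 | den < 0, num / den, NA_real_)
  windows
}

fst_site_components <- function(ds, pop_a, pop_b, haploid = FALSE) {
  if (haploid) {
    Ha <- ds$H[pop_rows(ds, pop_a), , drop = FALSE]
    Hb <- ds$H[pop_rows(ds, pop_b), , drop = FALSE]
    n1 <- colSums(!is.na(Ha)); n2 <- colSums(!is.na(Hb))
    p1 <- colSums(Ha == 1L, na.rm = TRUE) / n1
    p2 <- colSums(Hb == 1L, na.rm = TRUE) / n2
    ok <- n1 >= 2 & n2 >= 2
    nt <- n1 + n2
    pbar <- (n1 * p1 + n2 * p2) / nt
    nc <- nt - (n1^2 + n2^2) / nt
    msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2  # r - 1 = 1
    msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nt - 2)
    a <- (msp - msg) / nc
    abc <- a + msg
    a[!ok] <- NA_real_; abc[!ok] <- NA_real_
    return(list(a = a, abc = abc))
  }
  ga <- diploid_geno(ds, pop_a)
  gb <- diploid_geno(ds, pop_b)
  r <- 2
  n1 <- ga$n; n2 <- gb$n
  ok <- n1 >= 1 & n2 >= 1 & (2 * n1) + (2 * n2) >= 4
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * ga$p + n2 * gb$p) / (r * nbar)
  s2 <- (n1 * (ga$p - pbar)^2 + n2 * (gb$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * ga$h + n2 * gb$h) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  ok <- ok & nbar > 1 & nc > 0
  a[!ok] <- NA_real_
  abc <- a + b + cc
  abc[!ok] <- NA_real_
  list(a = a, abc = abc)
}

# per-site diploid summaries for one population: individuals with both
# haplotypes observed; allele-1 frequency and observed-heterozygote fraction
diploid_geno <- function(ds, pop) {
  rows <- pop_rows(ds, pop)
  h1 <- ds$H[rows[seq(1, length(rows), by = 2)], , drop = FALSE]
  h2 <- ds$H[rows[seq(2, length(rows), by = 2)], , drop = FALSE]
  ok <- !is.na(h1) & !is.na(h2)
  n <- colSums(ok)
  alt <- colSums((h1 == 1L) * ok, na.rm = TRUE) +
    colSums((h2 == 1L) * ok, na.rm = TRUE)
  het <- colSums((h1 != h2) * ok, na.rm = TRUE)
  list(n = n, p = ifelse(n > 0, alt / (2 * n), NaN),
       h = ifelse(n > 0, het / n, NaN))
}

#' Windowed Tajima's D
#'
#' Computed per window from the segregating-site count `S` and the mean
#' pairwise difference (in count units) among non-missing entries, with the
#' Tajima (1989) constants evaluated at the population haplotype count.
#' Windows with `S = 0` are `NA`.
#'
#' @param ds A [hap_data] object.
#' @param pop Population label; needs at least 4 haplotypes, otherwise a
#'   column of `NA` is returned with a warning.
#' @param windows Window tibble from [make_windows()].
#' @return The window tibble with columns `n_sites`, `S` and `tajima_d`
#'   appended.
#' @export
window_tajima_d <- function(ds, pop, windows) {
  rows <- pop_rows(ds, pop)
  n <- length(rows)
  windows$n_sites <- count_window_sites(ds, windows)
  if (n < 4) {
    warn("Tajima's D undefined for fewer than 4 haplotypes")
    windows$S <- NA_integer_
    windows$tajima_d <- NA_real_
    return(windows)
  }
  Hp <- ds$H[rows, , drop = FALSE]
  nobs <- colSums(!is.na(Hp))
  c1 <- colSums(Hp == 1L, na.rm = TRUE)
  seg <- nobs >= 2 & c1 > 0 & c1 < nobs
  site_pi <- site_pi_values(Hp)
  windows$S <- as.integer(window_sums(ds$positions, as.numeric(seg), windows))
  pi_hat <- window_sums(ds$positions, site_pi, windows)
  k <- tajima_constants(n)
  S <- windows$S
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  windows$tajima_d <- ifelse(S > 0, (pi_hat - S / k$a1) / denom, NA_real_)
  windows
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Combined window-statistic table for a population pair
#'
#' Convenience wrapper producing the per-window columns used by the CDR
#' scan: diversity for both groups, weighted FST, Tajima's D for the focal
#' group, plus `z_fst` and `log2_pi_ratio`.
#'
#' @param ds A [hap_data] object.
#' @param pop_a Focal group (numerator of the diversity ratio).
#' @param pop_b Contrast group.
#' @param windows Window tibble from [make_windows()].
#' @param pseudo Pseudocount for [log2_pi_ratio()].
#' @return A `win_stats` tibble with one row per window.
#' @export
window_stats <- function(ds, pop_a, pop_b, windows, pseudo = 1e-6) {
  w <- window_pi(ds, pop_a, windows)
  names(w)[names(w) == "pi"] <- "pi_a"
  w$pi_b <- window_pi(ds, pop_b, windows)$pi
  w$fst <- window_fst(ds, pop_a, pop_b, windows)$fst
  w$tajima_d <- window_tajima_d(ds, pop_a, windows)$tajima_d
  w$z_fst <- z_transform(w$fst)
  w$log2_pi_ratio <- log2_pi_ratio(w$pi_a, w$pi_b, pseudo = pseudo)
  class(w) <- c("win_stats", class(w))
  w
}

#' Linkage-disequilibrium decay curve
#'
#' For site pairs within `max_dist` of each other, `r^2` is computed from
#' haplotype frequencies over jointly non-missing haplotypes and aggregated
#' into distance bins. When the number of candidate pairs exceeds
#' `max_pairs` a deterministic seeded subsample is used. Pairs where either
#' site is monomorphic (over the jointly observed haplotypes) are skipped.
#'
#' @param ds A phased [hap_data] object.
#' @param pop Population label with at least 4 haplotypes.
#' @param max_dist Maximum pair distance in bp.
#' @param bin_width Distance-bin width in bp.
#' @param max_pairs Cap on evaluated pairs (default `1e6`); `Inf` for
#'   exhaustive enumeration.
#' @param seed Seed controlling pair subsampling.
#' @return A tibble with `bin_start`, `bin_end`, `mean_r2`, `n_pairs` and a
#'   `population` column, of class `ld_decay`.
#' @export
ld_decay <- function(ds, pop, max_dist = 1e5, bin_width = 1e3,
                     max_pairs = 1e6, seed = 1) {
  if (!ds$phased) abort("LD decay requires phased data")
  rows <- pop_rows(ds, pop)
  if (length(rows) < 4) abort("`pop` needs at least 4 haplotypes")
  Hp <- ds$H[rows, , drop = FALSE]
  pos <- ds$positions
  S <- length(pos)
  hi <- findInterval(pos + max_dist, pos)
  n_per <- pmax(hi - seq_len(S), 0L)
  total <- sum(n_per)
  if (total == 0) abort("no site pairs within `max_dist`")
  if (total > max_pairs) {
    pick <- with_seed(as.integer(seed),
                      sort(sample(total, size = max_pairs)))
  } else {
    pick <- seq_len(total)
  }
  offs <- c(0, cumsum(n_per))
  i <- findInterval(pick - 1, offs, rightmost.closed = FALSE)
  j <- i + (pick - offs[i])
  r2 <- vapply(seq_along(i), function(k) pair_r2(Hp[, i[k]], Hp[, j[k]]),
               numeric(1))
  d <- pos[j] - pos[i]
  keep <- !is.na(r2)
  bin <- floor(d[keep] / bin_width)
  agg <- tibble(bin = bin, r2 = r2[keep]) |>
    group_by(.data$bin) |>
    summarise(mean_r2 = mean(.data$r2), n_pairs = dplyr::n(), .groups = "drop") |>
    arrange(.data$bin)
  out <- tibble(bin_start = agg$bin * bin_width,
                bin_end = (agg$bin + 1) * bin_width,
                mean_r2 = agg$mean_r2, n_pairs = agg$n_pairs,
                population = pop)
  class(out) <- c("ld_decay", class(out))
  out
}

pair_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  pa <- mean(x); pb <- mean(y)
  if (pa == 0 || pa == 1 || pb == 0 || pb == 1) return(NA_real_)
  pab <- mean(x == 1 & y == 1)
  dd <- pab - pa * pb
  dd^2 / (pa * (1 - pa) * pb * (1 - pb))
}
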