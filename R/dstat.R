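#' ABBA-BABA D statistic for one four-taxon arrangement
#'
#' Frequency-based Patterson's D on the rooted topology
#' `(((P1, P2), P3), O)`. Each site is polarized so the outgroup-major
#' allele is ancestral (ties keep the ALT allele as derived); with derived
#' frequencies `p1..p4`,
#' `abba = (1-p1) * p2 * p3 * (1-p4)` and `baba = p1 * (1-p2) * p3 * (1-p4)`,
#' and `D = sum(abba - baba) / sum(abba + baba)` over informative sites
#' (`abba + baba > 0`). Gene flow between P2 and P3 pushes D above zero,
#' between P1 and P3 below zero. The standard error comes from a
#' delete-one block jackknife over consecutive blocks of `block_size`
#' informative sites; `Z = D / SE` with a two-sided normal p-value.
#'
#' @param ds A [hap_data] object.
#' @param p1,p2,p3,outgroup Four disjoint population labels.
#' @param block_size Informative-site count per jackknife block
#'   (default 2000). Fewer than 3 blocks leaves the SE undefined, with a
#'   warning.
#' @return A `dstat` object; see [tidy.dstat()] and [glance.dstat()].
#' @export
dstat <- function(ds, p1, p2, p3, outgroup, block_size = 2000) {
  pops <- c(p1, p2, p3, outgroup)
  if (anyDuplicated(pops)) abort("the four populations must be disjoint")
  fr <- vapply(pops, function(p) pop_freq(ds, p), numeric(n_sites(ds)))
  if (n_sites(ds) == 1) fr <- matrix(fr, nrow = 1)
  ok <- rowSums(is.nan(fr)) == 0  # drop sites with an all-missing population
  fr <- fr[ok, , drop = FALSE]
  flip <- fr[, 4] > 0.5
  fr[flip, ] <- 1 - fr[flip, ]
  q1 <- fr[, 1]; q2 <- fr[, 2]; q3 <- fr[, 3]; q4 <- fr[, 4]
  abba <- (1 - q1) * q2 * q3 * (1 - q4)
  baba <- q1 * (1 - q2) * q3 * (1 - q4)
  inf <- abba + baba > 0
  abba <- abba[inf]; baba <- baba[inf]
  n_inf <- length(abba)
  tot <- sum(abba + baba)
  if (tot == 0) abort("no informative sites: D undefined")
  D <- sum(abba - baba) / tot

  blk <- (seq_len(n_inf) - 1L) %/% block_size + 1L
  B <- max(blk)
  se <- NA_real_
  if (B < 3) {
    warn("fewer than 3 jackknife blocks; SE undefined")
  } else {
    num_b <- vapply(split(abba - baba, blk), sum, numeric(1))
    den_b <- vapply(split(abba + baba, blk), sum, numeric(1))
    d_del <- (sum(num_b) - num_b) / (sum(den_b) - den_b)
    se <- sqrt((B - 1) / B * sum((d_del - mean(d_del))^2))
  }
  Z <- if (!is.na(se) && se > 0) D / se else NA_real_
  structure(list(
    P1 = p1, P2 = p2, P3 = p3, outgroup = outgroup,
    sum_abba = sum(abba), sum_baba = sum(baba),
    D = D, se = se, Z = Z,
    p = if (is.na(Z)) NA_real_ else 2 * pnorm(-abs(Z)),
    n_informative_sites = n_inf, n_blocks = B,
    block_size = block_size), class = "dstat")
}

#' @exportS3Method base::print
print.dstat <- function(x, ...) {
  cat(sprintf("ABBA-BABA D: (((%s, %s), %s), %s)\n", x$P1, x$P2, x$P3,
              x$outgroup))
  cat(sprintf("  D = %.4f  Z = %s  p = %s  (%d informative sites, %d blocks)\n",
              x$D,
              ifelse(is.na(x$Z), "NA", sprintf("%.2f", x$Z)),
              ifelse(is.na(x$p), "NA", format(x$p, digits = 3)),
              x$n_informative_sites, x$n_blocks))
  invisible(x)
}

#' Tidy a D-statistic result
#' @param x A `dstat` object.
#' @param ... Unused.
#' @return A one-row tibble with the arrangement labels, D, SE, Z, p and
#'   site/block counts.
#' @export
tidy.dstat <- function(x, ...) {
  tibble(P1 = x$P1, P2 = x$P2, P3 = x$P3, outgroup = x$outgroup,
         D = x$D, se = x$se, Z = x$Z, p = x$p,
         nABBA = x$sum_abba, nBABA = x$sum_baba,
         n_informative_sites = x$n_informative_sites,
         n_blocks = x$n_blocks)
}

#' One-line summary of a D-statistic result
#' @param x A `dstat` object.
#' @param ... Unused.
#' @return A one-row tibble: `D`, `Z`, `p`, `n_informative_sites`.
#' @export
glance.dstat <- function(x, ...) {
  tibble(D = x$D, Z = x$Z, p = x$p,
         n_informative_sites = x$n_informative_sites)
}

#' D statistics for every ingroup trio
#'
#' For each unordered trio of ingroups the three rotations (each choice of
#' P3) are evaluated, with P1/P2 within each rotation oriented so that
#' `D >= 0` — the orientation that names the discordance-excess pair
#' explicitly. The reported top-level values come from the rotation with
#' the largest D; all rotations are kept in a list-column.
#'
#' @param ds A [hap_data] object.
#' @param populations At least 3 ingroup labels.
#' @param outgroup Outgroup label.
#' @param block_size Passed to [dstat()].
#' @return A tibble with one row per trio: `P1`, `P2`, `P3`, `D`, `Z`,
#'   `p`, `nABBA`, `nBABA`, `n_blocks` and a `rotations` list-column of
#'   three-row tibbles.
#' @export
dstat_trios <- function(ds, populations, outgroup, block_size = 2000) {
  if (length(populations) < 3) abort("need at least 3 ingroup populations")
  trios <- utils::combn(populations, 3, simplify = FALSE)
  rows <- lapply(trios, function(tr) {
    rot <- lapply(seq_len(3), function(k) {
      p3 <- tr[k]
      p12 <- setdiff(tr, p3)
      d <- dstat(ds, p12[1], p12[2], p3, outgroup, block_size = block_size)
      if (!is.na(d$D) && d$D < 0) {
        d <- dstat(ds, p12[2], p12[1], p3, outgroup, block_size = block_size)
      }
      tidy(d)
    })
    rot_tbl <- list_rbind(rot)
    best <- rot_tbl[which.max(rot_tbl$D), ]
    best$rotations <- list(rot_tbl)
    best
  })
  list_rbind(rows)
}
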