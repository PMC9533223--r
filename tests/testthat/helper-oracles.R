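# Independent brute-force oracles. These deliberately avoid the package's
# computational paths: pairwise enumeration instead of counting formulas,
# direct transcription of the published estimating equations, O(m^2)
# haplotype comparison instead of partition refinement.

# seeded random dataset with optional missingness; frequencies drawn per
# site, alleles binomial
rand_hap_data <- function(n_samp = 10, n_site = 50, L = 1e5,
                          pops = NULL, missing_rate = 0, seed = 1,
                          ancestral = FALSE) {
  withr::with_seed(seed, {
    pos <- sort(sample.int(L, n_site))
    f <- runif(n_site, 0.05, 0.95)
    H <- matrix(rbinom(2 * n_samp * n_site, 1, rep(f, each = 2 * n_samp)),
                nrow = 2 * n_samp)
    # keep every site polymorphic so datasets stay valid SNP sets
    mono <- which(colSums(H) %in% c(0, nrow(H)))
    for (j in mono) H[sample.int(nrow(H), 1), j] <- 1L - H[1, j]
    if (missing_rate > 0) {
      H[matrix(runif(length(H)) < missing_rate, nrow(H))] <- NA_integer_
    }
    if (is.null(pops)) pops <- rep("A", n_samp)
    hap_data(contig = "chr1", positions = pos, H = H,
             sample_ids = sprintf("s%03d", seq_len(n_samp)),
             pops = pops,
             ancestral = if (ancestral) rep(0L, n_site) else NULL,
             contig_length = L)
  })
}

# mean number of pairwise differences per site, enumerated over all
# haplotype pairs with pairwise-complete data (enumeration is over pairs;
# only the per-site accumulation is vectorized)
oracle_site_pi <- function(Hp) {
  m <- nrow(Hp)
  diffs <- numeric(ncol(Hp))
  pairs <- numeric(ncol(Hp))
  for (a in seq_len(m - 1)) for (b in seq(a + 1, m)) {
    xa <- Hp[a, ]; xb <- Hp[b, ]
    ok <- !is.na(xa) & !is.na(xb)
    pairs <- pairs + ok
    diffs <- diffs + (ok & xa != xb)
  }
  ifelse(pairs > 0, diffs / pairs, 0)
}

# windowed pi oracle: sum of per-site pairwise-difference probabilities in
# (start, end] over the window length
oracle_window_pi <- function(ds, pop, windows) {
  Hp <- ds$H[pop_rows(ds, pop), , drop = FALSE]
  sp <- oracle_site_pi(Hp)
  vapply(seq_len(nrow(windows)), function(k) {
    sel <- ds$positions - 1 >= windows$start[k] &
      ds$positions - 1 < windows$end[k]
    sum(sp[sel]) / (windows$end[k] - windows$start[k])
  }, numeric(1))
}

# Weir & Cockerham (1984) two-population estimator, transcribed equation by
# equation from genotype counts (diploid) or allele counts (haploid)
oracle_wc_site <- function(geno1, geno2) {
  # genoX: vector of diploid genotypes coded 0/1/2 (NA = missing)
  g1 <- geno1[!is.na(geno1)]; g2 <- geno2[!is.na(geno2)]
  n1 <- length(g1); n2 <- length(g2)
  r <- 2
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

oracle_wc_haploid_site <- function(x1, x2) {
  x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
  n1 <- length(x1); n2 <- length(x2); nt <- n1 + n2
  p1 <- mean(x1); p2 <- mean(x2)
  pbar <- (n1 * p1 + n2 * p2) / nt
  nc <- nt - (n1^2 + n2^2) / nt
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nt - 2)
  c(a = (msp - msg) / nc, abc = (msp - msg) / nc + msg)
}

oracle_window_fst <- function(ds, pop_a, pop_b, windows) {
  ra <- pop_rows(ds, pop_a); rb <- pop_rows(ds, pop_b)
  geno <- function(rows, j) {
    h1 <- ds$H[rows[seq(1, length(rows), 2)], j]
    h2 <- ds$H[rows[seq(2, length(rows), 2)], j]
    ifelse(is.na(h1) | is.na(h2), NA, h1 + h2)
  }
  comps <- vapply(seq_len(n_sites(ds)), function(j) {
    g1 <- geno(ra, j); g2 <- geno(rb, j)
    if (sum(!is.na(g1)) < 1 || sum(!is.na(g2)) < 1 ||
        sum(!is.na(g1)) + sum(!is.na(g2)) < 2) return(c(NA_real_, NA_real_))
    v <- oracle_wc_site(g1, g2)
    c(v["a"], sum(v))
  }, numeric(2))
  vapply(seq_len(nrow(windows)), function(k) {
    sel <- ds$positions - 1 >= windows$start[k] &
      ds$positions - 1 < windows$end[k]
    num <- sum(comps[1, sel], na.rm = TRUE)
    den <- sum(comps[2, sel], na.rm = TRUE)
    if (all(is.na(comps[2, sel])) || den == 0) NA_real_ else num / den
  }, numeric(1))
}

# Tajima (1989): constants written out separately from the package's
oracle_tajima_d <- function(Hp, positions, start, end) {
  n <- nrow(Hp)
  sel <- positions - 1 >= start & positions - 1 < end
  X <- Hp[, sel, drop = FALSE]
  if (ncol(X) == 0) return(NA_real_)
  nm <- colSums(!is.na(X))
  ones <- colSums(X == 1L, na.rm = TRUE)
  seg <- sum(nm >= 2 & ones > 0 & ones < nm)
  pihat <- sum(oracle_site_pi(X))
  if (seg == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pihat - seg / a1) / sqrt(e1 * seg + e2 * seg * (seg - 1))
}

# all-pairs identity spans from a core: for each haplotype pair the number
# of consecutive sites (inclusive of the step site) over which the two stay
# identical scanning outward; EHH at offset k = fraction of pairs whose
# span reaches k. Missing entries break identity.
oracle_ehh_span_curve <- function(Hp, core, dir, max_steps) {
  m <- nrow(Hp)
  S <- ncol(Hp)
  if (dir > 0) idx <- seq(core + 1, length.out = min(max_steps, S - core))
  else idx <- seq(core - 1, by = -1, length.out = min(max_steps, core - 1))
  if (!length(idx)) return(numeric(0))
  spans <- integer(0)
  for (a in seq_len(m - 1)) for (b in seq(a + 1, m)) {
    xa <- Hp[a, idx]; xb <- Hp[b, idx]
    mism <- which(is.na(xa) | is.na(xb) | xa != xb)
    spans <- c(spans, if (length(mism)) mism[1] - 1L else length(idx))
  }
  n_pair <- m * (m - 1) / 2
  vapply(seq_along(idx), function(k) sum(spans >= k) / n_pair, numeric(1))
}

# EHH by O(m^2) pairwise identity of the inclusive span core..k
oracle_ehh_at <- function(Hp, core, k) {
  m <- nrow(Hp)
  span <- seq(min(core, k), max(core, k))
  idn <- 0
  for (a in seq_len(m - 1)) for (b in seq(a + 1, m)) {
    va <- Hp[a, span]; vb <- Hp[b, span]
    same <- !anyNA(va) && !anyNA(vb) && all(va == vb)
    if (same) idn <- idn + 1
  }
  idn / (m * (m - 1) / 2)
}

# full one-sided oracle curve with the package's truncation semantics
# (record until the first value below cutoff, stop at zero, obey caps)
oracle_ehh_side <- function(Hp, core, dir, cutoff, max_steps) {
  S <- ncol(Hp)
  out <- numeric(0)
  k <- core
  for (step in seq_len(max_steps)) {
    k <- k + dir
    if (k < 1 || k > S) break
    e <- oracle_ehh_at(Hp, core, k)
    out <- c(out, e)
    if (cutoff >= 0 && e < cutoff) break
    if (e == 0) break
  }
  out
}

oracle_trapezoid <- function(x, y) {
  if (length(x) < 2) return(0)
  s <- 0
  for (i in seq_len(length(x) - 1)) {
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  s
}

# rank-sum normal approximation with tie correction (no continuity
# correction), written independently of stats::wilcox.test
oracle_ranksum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
  sig <- sqrt(n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term))
  z <- (U - mu) / sig
  list(U = U, z = z, p = 2 * stats::pnorm(-abs(z)))
}

# O(n*m) interval overlap (0-based half-open regions, 1-based closed genes)
oracle_overlaps <- function(genes, regions) {
  hits <- list()
  for (g in seq_len(nrow(genes))) {
    rs <- integer(0)
    for (r in seq_len(nrow(regions))) {
      if (genes$contig[g] == regions$contig[r] &&
          genes$start[g] <= regions$end[r] &&
          genes$end[g] >= regions$start[r] + 1) {
        rs <- c(rs, r)
      }
    }
    if (length(rs)) hits[[genes$gene_id[g]]] <- rs
  }
  hits
}

# frequency-weighted ABBA/BABA sums via literal site loops
oracle_dstat_sums <- function(ds, p1, p2, p3, o) {
  f <- function(p, j) {
    x <- ds$H[pop_rows(ds, p), j]
    x <- x[!is.na(x)]
    if (!length(x)) return(NaN)
    mean(x)
  }
  abba <- 0; baba <- 0
  for (j in seq_len(n_sites(ds))) {
    q <- c(f(p1, j), f(p2, j), f(p3, j), f(o, j))
    if (anyNA(q) || any(is.nan(q))) next
    if (q[4] > 0.5) q <- 1 - q
    abba <- abba + (1 - q[1]) * q[2] * q[3] * (1 - q[4])
    baba <- baba + q[1] * (1 - q[2]) * q[3] * (1 - q[4])
  }
  c(abba = abba, baba = baba)
}
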