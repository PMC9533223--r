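test_that("window pi matches its worked examples", {
  H <- cbind(c(0L, 0L, 1L, 1L))
  ds <- hap_data("c", 5000, H, c("s1", "s2"), rep("A", 2),
                 contig_length = 1e4)
  w <- make_windows(1e4, 1e4, 1e4)
  out <- window_pi(ds, "A", w)
  # 4 of C(4,2)=6 pairs differ -> 2/3 per site, over 10 kb
  expect_equal(out$pi, (2 / 3) / 1e4, tolerance = 1e-12)
  # monomorphic window (no SNPs at all) is zero
  w0 <- make_windows(1e4, 1e4, 1e4)
  dsm <- hap_data("c", 5000, cbind(c(0L, 1L, 0L, 1L)), c("s1", "s2"),
                  rep("A", 2), contig_length = 3e4)
  out0 <- window_pi(dsm, "A", make_windows(3e4, 1e4, 1e4))
  expect_equal(out0$pi[2:3], c(0, 0))
})

test_that("window pi equals the pairwise-difference oracle", {
  ds <- rand_hap_data(n_samp = 10, n_site = 300, L = 5e4,
                      missing_rate = 0.05, seed = 17)
  w <- make_windows(5e4, 1e4, 5e3)
  out <- window_pi(ds, "A", w)
  expect_equal(out$pi, oracle_window_pi(ds, "A", w), tolerance = 1e-12)
})

test_that("weighted FST hits its limiting cases", {
  # complete fixation
  H <- rbind(matrix(0L, 4, 10), matrix(1L, 4, 10))
  ds <- hap_data("c", seq(100, 1000, 100), H, sprintf("s%d", 1:4),
                 c("A", "A", "B", "B"), contig_length = 1e3)
  w <- make_windows(1e3, 1e3, 1e3)
  expect_equal(window_fst(ds, "A", "B", w)$fst, 1)
  expect_equal(window_fst(ds, "A", "B", w, haploid = TRUE)$fst, 1)
  # one panmictic pool: distribution centred near zero
  ds2 <- rand_hap_data(n_samp = 20, n_site = 400, L = 1e5,
                       pops = rep(c("A", "B"), each = 10), seed = 5)
  w2 <- make_windows(1e5, 1e5, 1e5)
  expect_lt(abs(window_fst(ds2, "A", "B", w2)$fst), 0.02)
  expect_error(window_fst(ds2, "A", "A", w2), "must differ")
})

test_that("FST variance components match the WC84 transcription oracle", {
  ds <- rand_hap_data(n_samp = 16, n_site = 250, L = 4e4,
                      pops = rep(c("A", "B"), each = 8),
                      missing_rate = 0.05, seed = 23)
  w <- make_windows(4e4, 1e4, 5e3)
  out <- window_fst(ds, "A", "B", w)
  expect_equal(out$fst, oracle_window_fst(ds, "A", "B", w),
               tolerance = 1e-12)
})

test_that("haploid FST reproduces the frozen single-site oracle value", {
  # p1 = 0.5 (20 haplotypes), p2 = 0.1 (20 haplotypes)
  x1 <- rep(c(0L, 1L), 10)
  x2 <- c(rep(1L, 2), rep(0L, 18))
  H <- cbind(c(x1, x2))
  ds <- hap_data("c", 50, H, sprintf("s%d", 1:20),
                 rep(c("A", "B"), each = 10))
  w <- make_windows(100, 100, 100)
  got <- window_fst(ds, "A", "B", w, haploid = TRUE)$fst
  o <- oracle_wc_haploid_site(x1, x2)
  expect_equal(got, unname(o["a"] / o["abc"]), tolerance = 1e-12)
  expect_equal(got, 0.28421052631578947, tolerance = 1e-9)
})

test_that("ratio-of-sums FST equals per-site FST for one-site windows", {
  ds <- rand_hap_data(n_samp = 10, n_site = 30, L = 3e4,
                      pops = rep(c("A", "B"), each = 5), seed = 31)
  big <- make_windows(3e4, 3e4, 3e4)
  per_site <- vapply(seq_len(30), function(j) {
    one <- subset_sites(ds, j)
    w1 <- make_windows(3e4, 3e4, 3e4)
    window_fst(one, "A", "B", w1)$fst
  }, numeric(1))
  # each one-site window must equal the site's own component ratio, taken
  # from the independent WC84 transcription
  oracle <- vapply(seq_len(30), function(j) {
    geno <- function(rows) {
      h1 <- ds$H[rows[seq(1, length(rows), 2)], j]
      h2 <- ds$H[rows[seq(2, length(rows), 2)], j]
      h1 + h2
    }
    v <- oracle_wc_site(geno(pop_rows(ds, "A")), geno(pop_rows(ds, "B")))
    unname(v["a"] / sum(v))
  }, numeric(1))
  expect_equal(per_site, oracle, tolerance = 1e-12)
})

test_that("Tajima's D matches the constants-level oracle and edge cases", {
  ds <- rand_hap_data(n_samp = 5, n_site = 120, L = 2e4, seed = 41)
  w <- make_windows(2e4, 1e4, 1e4)
  out <- window_tajima_d(ds, "A", w)
  o <- vapply(seq_len(nrow(w)), function(k) {
    oracle_tajima_d(ds$H, ds$positions, w$start[k], w$end[k])
  }, numeric(1))
  expect_equal(out$tajima_d, o, tolerance = 1e-10)
  # S = 0 window is missing
  dsm <- hap_data("c", 5, cbind(c(0L, 1L, 0L, 1L)), c("s1", "s2"),
                  rep("A", 2), contig_length = 3e4)
  w3 <- make_windows(3e4, 1e4, 1e4)
  expect_true(all(is.na(window_tajima_d(dsm, "A", w3)$tajima_d[2:3])))
  # fewer than 4 haplotypes warns and yields missing
  ds1 <- hap_data("c", 5, cbind(c(0L, 1L)), "s1", "A")
  expect_warning(res <- window_tajima_d(ds1, "A", make_windows(10, 10, 10)),
                 "fewer than 4")
  expect_true(all(is.na(res$tajima_d)))
})

test_that("pi, FST and Tajima's D are invariant to row permutation within pops", {
  ds <- rand_hap_data(n_samp = 12, n_site = 100, L = 2e4,
                      pops = rep(c("A", "B"), each = 6), seed = 53)
  w <- make_windows(2e4, 1e4, 5e3)
  base <- list(window_pi(ds, "A", w)$pi,
               window_fst(ds, "A", "B", w)$fst,
               window_tajima_d(ds, "A", w)$tajima_d)
  # permute whole diploid samples within each population
  perm <- c(sample(1:6), sample(7:12))
  ds2 <- ds
  rows <- as.vector(rbind(2 * perm - 1, 2 * perm))
  ds2$H <- ds$H[rows, ]
  got <- list(window_pi(ds2, "A", w)$pi,
              window_fst(ds2, "A", "B", w)$fst,
              window_tajima_d(ds2, "A", w)$tajima_d)
  expect_equal(got, base, tolerance = 1e-12)
})

test_that("non-overlapping grids partition site contributions exactly", {
  ds <- rand_hap_data(n_samp = 8, n_site = 200, L = 5e4, seed = 67)
  w <- make_windows(5e4, 1e4, 1e4)
  out <- window_pi(ds, "A", w)
  whole <- window_pi(ds, "A", make_windows(5e4, 5e4, 5e4))
  expect_equal(sum(out$pi * (out$end - out$start)),
               whole$pi * 5e4, tolerance = 1e-9)
  expect_equal(sum(out$n_sites), 200L)
})

test_that("LD r2 matches its worked examples and the exhaustive oracle", {
  # duplicated site -> r2 = 1
  x <- rep(c(0L, 1L), 6)
  ds <- hap_data("c", c(100, 600), cbind(x, x), sprintf("s%d", 1:6),
                 rep("A", 6), contig_length = 1e3)
  out <- ld_decay(ds, "A", max_dist = 1e3, bin_width = 1e3)
  expect_equal(out$mean_r2, 1)
  # AB/Ab/aB/ab = 2/2/2/2 -> r2 = 0
  h1 <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)
  h2 <- c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L)
  ds0 <- hap_data("c", c(100, 600), cbind(h1, h2), sprintf("s%d", 1:4),
                  rep("A", 4), contig_length = 1e3)
  expect_equal(ld_decay(ds0, "A", 1e3, 1e3)$mean_r2, 0)
  # exhaustive oracle on a random dataset
  ds2 <- rand_hap_data(n_samp = 15, n_site = 60, L = 2e4, seed = 71)
  got <- ld_decay(ds2, "A", max_dist = 5e3, bin_width = 1e3,
                  max_pairs = Inf)
  pos <- ds2$positions
  o_r2 <- function(x, y) {  # independent: joint haplotype counts
    n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
    n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
    n <- n11 + n10 + n01 + n00
    pA <- (n11 + n10) / n; pB <- (n11 + n01) / n
    if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
    (n11 / n - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
  }
  acc <- list()
  for (i in seq_len(59)) for (j in seq(i + 1, 60)) {
    d <- pos[j] - pos[i]
    if (d > 5e3) next
    r2 <- o_r2(ds2$H[, i], ds2$H[, j])
    if (is.na(r2)) next
    b <- floor(d / 1e3)
    acc[[as.character(b)]] <- c(acc[[as.character(b)]], r2)
  }
  for (k in seq_len(nrow(got))) {
    b <- as.character(got$bin_start[k] / 1e3)
    expect_equal(got$mean_r2[k], mean(acc[[b]]), tolerance = 1e-12)
    expect_equal(got$n_pairs[k], length(acc[[b]]))
  }
})

test_that("LD pair subsampling is deterministic under the seed", {
  ds <- rand_hap_data(n_samp = 12, n_site = 120, L = 6e4, seed = 81)
  a <- ld_decay(ds, "A", max_dist = 2e4, bin_width = 2e3, max_pairs = 200,
                seed = 9)
  b <- ld_decay(ds, "A", max_dist = 2e4, bin_width = 2e3, max_pairs = 200,
                seed = 9)
  expect_identical(a, b)
  c2 <- ld_decay(ds, "A", max_dist = 2e4, bin_width = 2e3, max_pairs = 200,
                 seed = 10)
  expect_false(identical(a$mean_r2, c2$mean_r2))
})
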