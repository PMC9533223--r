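# small deterministic dataset builders for EHH checks
ehh_fixture <- function(H, L = NULL, pops = NULL, anc = TRUE) {
  n_hap <- nrow(H)
  stopifnot(n_hap %% 2 == 0)
  n_samp <- n_hap / 2
  pos <- seq(1000, by = 1000, length.out = ncol(H))
  if (is.null(pops)) pops <- rep("A", n_samp)
  hap_data("chr1", pos, H, sprintf("s%02d", seq_len(n_samp)), pops,
           ancestral = if (anc) rep(0L, ncol(H)) else NULL,
           contig_length = max(pos) + 1000)
}

test_that("EHH follows the identity-pair definition and its examples", {
  # 4 carriers of the core allele; over the span to offset 2 they split
  # into identical-haplotype groups {2, 1, 1}
  H <- rbind(
    c(1L, 0L, 0L),
    c(1L, 0L, 0L),
    c(1L, 1L, 0L),
    c(1L, 0L, 1L),
    c(0L, 0L, 0L),
    c(0L, 1L, 1L))
  ds <- ehh_fixture(H)
  cv <- ehh_curve(ds, "A", core = 1, allele = 1)
  expect_equal(cv$ehh[cv$offset == 0], 1)
  # offset 1: groups {3, 1} -> (3*2/2) / C(4,2) = 1/2
  expect_equal(cv$ehh[cv$offset == 1], 1 / 2)
  # offset 2: groups {2, 1, 1} -> exactly one identical pair of C(4,2) = 6
  expect_equal(cv$ehh[cv$offset == 2], 1 / 6)
})

test_that("EHH curves equal the O(m^2) pairwise-identity oracle", {
  for (seed in c(101, 202)) {
    ds <- rand_hap_data(n_samp = 8, n_site = 40, L = 4e4, seed = seed)
    core <- 20
    for (allele in c(0, 1)) {
      rows <- pop_rows(ds, "A")
      rows <- rows[ds$H[rows, core] == allele]
      if (length(rows) < 2) next
      cv <- ehh_curve(ds, "A", core, allele,
                      cfg = ehh_config(cutoff = 0.05))
      Hp <- ds$H[rows, , drop = FALSE]
      right <- cv[cv$offset > 0, ]
      for (k in seq_len(nrow(right))) {
        expect_equal(right$ehh[k],
                     oracle_ehh_at(Hp, core, core + right$offset[k]),
                     tolerance = 1e-12)
      }
      left <- cv[cv$offset < 0, ]
      for (k in seq_len(nrow(left))) {
        expect_equal(left$ehh[k],
                     oracle_ehh_at(Hp, core, core + left$offset[k]),
                     tolerance = 1e-12)
      }
      # monotone non-increasing away from the core, bounded in [0, 1]
      expect_true(all(diff(right$ehh) <= 1e-12))
      expect_true(all(cv$ehh >= 0 & cv$ehh <= 1))
    }
  }
})

test_that("iHS integrals match the trapezoid-over-oracle computation", {
  ds <- rand_hap_data(n_samp = 10, n_site = 60, L = 3e4, seed = 303,
                      ancestral = TRUE)
  cfg <- ehh_config()
  out <- ihs_scan(ds, "A", mode = "bp", cfg = cfg)
  scored <- which(!is.na(out$unstd))
  expect_gt(length(scored), 5)
  for (i in scored[seq_len(min(8, length(scored)))]) {
    core <- match(out$position[i], ds$positions)
    for (allele in c(0L, 1L)) {
      rows <- pop_rows(ds, "A")
      rows <- rows[ds$H[rows, core] == allele]
      Hp <- ds$H[rows, , drop = FALSE]
      co <- match(core, seq_len(n_sites(ds)))
      lim_l <- sum(ds$positions < ds$positions[core] &
                     ds$positions >= ds$positions[core] - cfg$max_extend_bp)
      lim_r <- sum(ds$positions > ds$positions[core] &
                     ds$positions <= ds$positions[core] + cfg$max_extend_bp)
      el <- oracle_ehh_side(Hp, core, -1, cfg$cutoff, lim_l)
      er <- oracle_ehh_side(Hp, core, +1, cfg$cutoff, lim_r)
      xl <- abs(ds$positions[core - seq_along(el)] - ds$positions[core])
      xr <- abs(ds$positions[core + seq_along(er)] - ds$positions[core])
      ihh <- oracle_trapezoid(c(0, xl), c(1, el)) +
        oracle_trapezoid(c(0, xr), c(1, er))
      got <- if (allele == 0L) out$ihh_a[i] else out$ihh_d[i]
      expect_equal(got, ihh, tolerance = 1e-9)
    }
  }
})

test_that("iHS is symmetric, signed correctly, and permutation invariant", {
  # ancestral and derived carriers with mirror-image flank structure:
  # identical partition patterns on both sides of the core give score 0.
  # Flanks are built so each class singletonizes (EHH hits 0) before the
  # chromosome edge, keeping the core un-voided.
  split1 <- c(0L, 0L, 1L, 1L)
  split2 <- c(0L, 1L, 0L, 1L)
  flank_l <- cbind(split2, split1)   # scanning leftwards: {2,2} then {1,1,1,1}
  flank_r <- cbind(split1, split2)
  H <- rbind(cbind(flank_l, 0L, flank_r),
             cbind(flank_l, 1L, flank_r))
  storage.mode(H) <- "integer"
  ds <- ehh_fixture(H)
  core <- 3
  out <- ihs_scan(ds, "A", mode = "sites")
  row <- which(out$position == ds$positions[core])
  expect_equal(unname(out$unstd[row]), 0, tolerance = 1e-12)

  # derived carriers share one long central haplotype (diverse near the
  # chromosome ends, so curves terminate instead of hitting the edge);
  # ancestral background is diverse throughout
  withr::with_seed(5, {
    n <- 20; S <- 41
    Ha <- matrix(rbinom(n * S, 1, 0.5), n, S)
    Hd <- matrix(rep(rbinom(S, 1, 0.5), each = n), n, S)
    edge_cols <- c(1:8, 34:41)
    Hd[, edge_cols] <- matrix(rbinom(n * length(edge_cols), 1, 0.5), n)
  })
  core <- 21
  Ha[, core] <- 0L; Hd[, core] <- 1L
  ds2 <- ehh_fixture(rbind(Ha, Hd))
  out2 <- ihs_scan(ds2, "A", mode = "sites")
  row2 <- which(out2$position == ds2$positions[core])
  expect_lt(out2$unstd[row2], 0)  # iHH_D >> iHH_A

  # permutation of diploid samples leaves scores unchanged
  ds3 <- rand_hap_data(n_samp = 8, n_site = 50, L = 3e4, seed = 404,
                       ancestral = TRUE)
  base <- ihs_scan(ds3, "A", mode = "bp")
  perm <- withr::with_seed(6, sample(8))
  ds4 <- ds3
  ds4$H <- ds3$H[as.vector(rbind(2 * perm - 1, 2 * perm)), ]
  expect_equal(ihs_scan(ds4, "A", mode = "bp")$unstd, base$unstd,
               tolerance = 1e-12)
})

test_that("XP scans are zero on identical populations and antisymmetric", {
  ds <- rand_hap_data(n_samp = 12, n_site = 80, L = 5e4,
                      pops = rep(c("O", "R"), each = 6), seed = 505)
  # identical haplotype content in both populations
  ro <- pop_rows(ds, "O"); rr <- pop_rows(ds, "R")
  ds$H[rr, ] <- ds$H[ro, ]
  out <- xp_scan(ds, "O", "R", "bp")
  expect_true(all(abs(out$unstd[!is.na(out$unstd)]) < 1e-12))
  # antisymmetry on independent data
  ds2 <- rand_hap_data(n_samp = 12, n_site = 80, L = 5e4,
                       pops = rep(c("O", "R"), each = 6), seed = 606)
  a <- xp_scan(ds2, "O", "R", "sites")
  b <- xp_scan(ds2, "R", "O", "sites")
  expect_equal(a$unstd, -b$unstd, tolerance = 1e-12)
  expect_error(xp_scan(ds2, "O", "O", "bp"), "must differ")
})

test_that("standardization identities hold for bins and global schemes", {
  withr::with_seed(77, {
    tab <- tibble::tibble(
      contig = "chr1", position = sort(sample.int(1e6, 3000)),
      freq = runif(3000, 0.02, 0.98),
      unstd = rnorm(3000) + runif(3000, 0.02, 0.98) * 2,
      std = NA_real_, statistic = "iHS")
  })
  out <- standardize_scores(tab, scheme = "bins", n_bins = 100)
  bin <- ceiling(out$freq * 100)
  for (b in unique(bin)) {
    v <- out$std[bin == b]
    v <- v[!is.na(v)]
    if (length(v) >= 2) {
      expect_lt(abs(mean(v)), 1e-10)
      expect_lt(abs(sd(v) - 1), 1e-10)
    }
  }
  # single-bin input {-1, 1}: mean 0, sample sd sqrt(2)
  tab2 <- tibble::tibble(contig = "c", position = c(1L, 2L),
                         freq = c(0.501, 0.502), unstd = c(-1, 1),
                         std = NA_real_, statistic = "iHS")
  expect_equal(standardize_scores(tab2, "bins")$std, c(-1, 1) / sqrt(2))
  # a frequency-proportional confound is removed by bins but not global
  tab3 <- tab
  tab3$unstd <- tab3$freq
  out3 <- standardize_scores(tab3, scheme = "bins")
  bin3 <- ceiling(out3$freq * 100)
  means <- tapply(out3$std, bin3, function(v) mean(v, na.rm = TRUE))
  expect_true(all(abs(means[!is.na(means)]) < 1e-8))
  glob <- standardize_scores(tab3, scheme = "global")
  gm <- tapply(glob$std, bin3, mean)
  expect_gt(max(abs(gm), na.rm = TRUE), 0.5)
  # global scheme normalizes overall
  outg <- standardize_scores(tab, scheme = "global")
  expect_lt(abs(mean(outg$std)), 1e-10)
  expect_lt(abs(sd(outg$std) - 1), 1e-10)
})

test_that("proportion windows count, exclude and rank as specified", {
  withr::with_seed(88, {
    pos1 <- sort(sample(1:499999, 150))
    pos2 <- sort(sample(500001:999999, 99))
    std <- c(ifelse(seq_len(150) <= 30, 3, 0.5), rnorm(99))
  })
  tab <- tibble::tibble(contig = "chr1", position = c(pos1, pos2),
                        freq = 0.5, unstd = std, std = std,
                        statistic = "XP-EHH")
  out <- proportion_windows(tab, threshold = 2, size = 5e5, min_snps = 100,
                            contig_length = 1e6)
  # window 2 has 99 tested SNPs: excluded
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_tested, 150L)
  expect_equal(out$n_extreme, 30L)
  expect_equal(out$proportion, 0.2)
  # two-sidedness defaults: iHS counts |score| > 2
  tab2 <- tab
  tab2$statistic <- "iHS"
  tab2$std <- -tab2$std
  out2 <- proportion_windows(tab2, size = 5e5, min_snps = 50,
                             contig_length = 1e6)
  expect_equal(out2$n_extreme[1], 30L)
  expect_error(proportion_windows(tab, min_snps = 1000,
                                  contig_length = 1e6),
               "no window")
})

test_that("neutral standardized scores put a few percent beyond the threshold", {
  sim <- simulate_cohort(scenario_neutral(3))
  out <- standardize_scores(ihs_scan(sim$data, "A", mode = "sites"))
  frac <- mean(abs(out$std) > 2, na.rm = TRUE)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.10)
})
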