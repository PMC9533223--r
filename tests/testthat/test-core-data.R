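test_that("hap_data enforces its shape contract", {
  H <- matrix(c(0L, 1L, 0L, 1L, 1L, 0L, NA, 1L, 0L, 1L, 1L, 0L), nrow = 4)
  ds <- hap_data("chr1", c(100, 500, 900), H, c("s1", "s2"), c("A", "B"))
  expect_equal(dim(ds$H), c(4L, 3L))
  expect_equal(n_sites(ds), 3L)
  expect_error(hap_data("chr1", c(100, 500), H, c("s1", "s2"), c("A", "B")),
               "one column per position")
  expect_error(hap_data("chr1", c(500, 100, 900), H, c("s1", "s2"),
                        c("A", "B")), "strictly increasing")
  expect_error(hap_data("chr1", c(100, 500, 900), H, c("s1", "s2", "s3"),
                        c("A", "B", "B")), "two rows per diploid sample")
})

test_that("VCF round trip preserves matrix, positions and ancestral states", {
  sim <- simulate_cohort(sim_params(L = 5e4, N = 30, mu = 2e-6, rho = 2e-6,
                                    populations = c("A", "B"),
                                    split_times = 50, sample_sizes = 6,
                                    seed = 11))
  d <- withr::local_tempdir()
  vcf <- file.path(d, "x.vcf")
  pm <- file.path(d, "x.popmap")
  write_vcf(sim$data, vcf)
  write_popmap(sim$data, pm)
  back <- read_vcf(vcf, pm)
  expect_identical(back$H, sim$data$H)
  expect_identical(back$positions, sim$data$positions)
  expect_identical(back$ancestral, sim$data$ancestral)
  expect_identical(back$pops, sim$data$pops)
  expect_identical(back$contig_length, sim$data$contig_length)
  expect_true(back$phased)
})

test_that("missing genotypes load as missing haplotype entries", {
  d <- withr::local_tempdir()
  vcf <- file.path(d, "m.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t10\t.\tA\tC\t.\t.\t.\tGT\t0|1\t./.",
    "chr1\t20\t.\tG\tT\t.\t.\t.\tGT\t1|1\t0|0",
    "chr1\t30\t.\tG\tGT\t.\t.\t.\tGT\t1|1\t0|0"), vcf)
  pm <- file.path(d, "m.popmap")
  writeLines(c("s1\tA", "s2\tB"), pm)
  expect_message(ds <- read_vcf(vcf, pm), "non-SNP")
  expect_equal(n_sites(ds), 2L)  # the indel record is skipped
  expect_equal(ds$H[, 1], c(0L, 1L, NA, NA))
  expect_true(ds$phased)
  # popmap sample absent from the VCF is an error
  writeLines(c("s1\tA", "nope\tB"), pm)
  expect_error(read_vcf(vcf, pm), "absent from VCF")
})

test_that("unphased heterozygotes flag the dataset as unphased", {
  d <- withr::local_tempdir()
  vcf <- file.path(d, "u.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t10\t.\tA\tC\t.\t.\t.\tGT\t0/1\t0|0"), vcf)
  pm <- file.path(d, "u.popmap")
  writeLines(c("s1\tA", "s2\tA"), pm)
  ds <- read_vcf(vcf, pm)
  expect_false(ds$phased)
  expect_error(ehh_curve(ds, "A", 1), "phased")
})

test_that("site filters match a site-by-site oracle and are idempotent", {
  ds <- rand_hap_data(n_samp = 5, n_site = 200, missing_rate = 0.15,
                      seed = 3)
  f <- site_filter(max_missing = 0.2, min_maf = 0.1)
  out <- apply_site_filters(ds, f)
  # oracle: recompute criteria per site from raw entries
  keep <- vapply(seq_len(n_sites(ds)), function(j) {
    x <- ds$H[, j]
    miss <- mean(is.na(x))
    x <- x[!is.na(x)]
    maf <- if (length(x)) min(mean(x), 1 - mean(x)) else NaN
    miss <= 0.2 && !is.nan(maf) && maf >= 0.1
  }, logical(1))
  expect_identical(out$positions, ds$positions[keep])
  expect_identical(out$H, ds$H[, keep])
  # idempotence
  again <- apply_site_filters(out, f)
  expect_identical(again$H, out$H)
  tly <- attr(out, "tally")
  expect_named(tly, c("criterion", "removed"))
})

test_that("filter worked examples behave as specified", {
  # 10 haplotypes, 3 missing entries: missingness 0.3 > 0.2 removes the site
  H <- matrix(rep(c(0L, 1L), 5), ncol = 1)
  H[1:3, 1] <- NA
  H <- cbind(H, rep(c(0L, 1L), 5))
  ds <- hap_data("c", c(10, 20), H, sprintf("s%d", 1:5), rep("A", 5))
  out <- apply_site_filters(ds, site_filter(max_missing = 0.2, min_maf = 0))
  expect_equal(out$positions, 20L)
  # counts 1/9 non-missing: MAF 0.1 >= 0.05 is retained
  H2 <- cbind(c(1L, rep(0L, 9)))
  ds2 <- hap_data("c", 10, H2, sprintf("s%d", 1:5), rep("A", 5))
  out2 <- apply_site_filters(ds2, site_filter(min_maf = 0.05))
  expect_equal(n_sites(out2), 1L)
  # removing everything warns and returns an empty dataset
  expect_warning(out3 <- apply_site_filters(ds2, site_filter(min_maf = 0.2)),
                 "all sites removed")
  expect_equal(n_sites(out3), 0L)
})

test_that("window grids follow the sliding-window arithmetic", {
  w <- make_windows(25000, 10000, 5000)
  expect_equal(w$start, c(0, 5000, 10000, 15000, 20000))
  expect_equal(w$end[5], 25000)
  # non-overlapping 500-kb convention
  w2 <- make_windows(2e6, 5e5, 5e5)
  expect_equal(nrow(w2), 4L)
  expect_equal(w2$end - w2$start, rep(5e5, 4))
  # contig shorter than one window
  w3 <- make_windows(3000, 10000, 5000)
  expect_equal(nrow(w3), 1L)
  expect_equal(w3$end, 3000)
  expect_error(make_windows(1000, 0, 5), "positive")
  expect_error(make_windows(1000, 10, 20), "exceed")
})

test_that("every base pair is covered by ceiling(size/step) windows", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      len <- sample(2e4:1e5, 1)
      size <- sample(c(4e3, 8e3, 1e4), 1)
      step <- size / sample(c(1, 2, 4), 1)
      w <- make_windows(len, size, step)
      bp <- sample.int(len, 50) - 1  # 0-based positions
      cover <- vapply(bp, function(p) sum(w$start <= p & w$end > p),
                      numeric(1))
      # interior positions: exactly size/step windows; fewer near edges
      interior <- bp >= size & bp < len - size
      expect_true(all(cover[interior] == size / step))
      expect_true(all(cover >= 1))
    }
  })
})

test_that("region strings restrict loading in samtools dialect", {
  sim <- simulate_cohort(sim_params(L = 5e4, N = 30, mu = 2e-6, rho = 2e-6,
                                    populations = "A",
                                    split_times = numeric(0),
                                    sample_sizes = 8, seed = 77))
  d <- withr::local_tempdir()
  write_vcf(sim$data, file.path(d, "r.vcf"))
  write_popmap(sim$data, file.path(d, "r.popmap"))
  full <- read_vcf(file.path(d, "r.vcf"), file.path(d, "r.popmap"))
  part <- read_vcf(file.path(d, "r.vcf"), file.path(d, "r.popmap"),
                   region = "chr1:10001-20000")
  expect_true(all(part$positions >= 10001 & part$positions <= 20000))
  expect_equal(part$positions,
               full$positions[full$positions >= 10001 &
                                full$positions <= 20000])
  expect_error(read_vcf(file.path(d, "r.vcf"), file.path(d, "r.popmap"),
                        region = "chrX"), "no SNP records")
})
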