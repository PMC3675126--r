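# Coalescent pool generation and causal-site selection.

test_that("no mutation yields an empty pool and seeds reproduce bit-identically", {
  p0 <- sim_params(n_haplotypes = 100, chrom_lengths = c(1000, 1000),
                   mu = 0, seed = 1)
  pool <- simulate_pool(p0)
  expect_equal(ncol(pool$haplotypes), 0L)
  expect_equal(nrow(pool$sites), 0L)

  p1 <- sim_params(n_haplotypes = 200, chrom_lengths = c(50000, 50000),
                   mu = 1e-7, seed = 7)
  a <- simulate_pool(p1)
  b <- simulate_pool(p1)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$sites, b$sites)
})

test_that("parameter validation rejects bad rates and sizes", {
  expect_error(sim_params(n_haplotypes = 3), "even integer")
  expect_error(sim_params(n_haplotypes = 101), "even integer")
  expect_error(sim_params(mu = -1e-8), "must be >= 0")
  expect_error(sim_params(chrom_lengths = c(0, 1000)), "positive")
})

test_that("segregating sites match Watterson's neutral expectation", {
  n_hap <- 200; ne <- 100; mu <- 1e-7; L <- 100000
  n_reps <- 30
  dir <- simulate_pool_files(
    sim_params(n_haplotypes = n_hap, chrom_lengths = c(L, L), mu = mu,
               effective_size = ne, seed = 314),
    n = n_reps)
  on.exit(unlink(dir, recursive = TRUE))
  params <- sim_params(n_haplotypes = n_hap, chrom_lengths = c(L, L),
                       mu = mu, effective_size = ne)
  counts <- unlist(lapply(seq_len(n_reps), function(i) {
    pool <- read_pool(dir, i, params)
    as.numeric(table(factor(pool$sites$chrom, c("causal", "null"))))
  }))
  expected <- watterson_expected_s(n_hap, ne, mu, L)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("pool invariants hold: folded MAF, ordered positions, rare-skewed SFS", {
  pool <- simulate_pool(sim_params(n_haplotypes = 1000,
                                   chrom_lengths = c(200000, 200000),
                                   mu = 1e-7, seed = 11))
  expect_true(all(pool$sites$maf > 0 & pool$sites$maf <= 0.5))
  expect_equal(pmin(colMeans(pool$haplotypes), 1 - colMeans(pool$haplotypes)),
               pool$sites$maf, tolerance = 1e-9, ignore_attr = TRUE)
  for (ch in c("causal", "null")) {
    pos <- pool$sites$pos[pool$sites$chrom == ch]
    expect_true(all(diff(pos) > 0))
  }
  # neutral SFS is rare-skewed
  expect_gt(mean(pool$sites$maf < 0.05), 0.5)
  # independent assortment: cross-chromosome r^2 averages ~ 1/n
  cc <- which(pool$sites$chrom == "causal")
  nn <- which(pool$sites$chrom == "null")
  set.seed(1)
  pairs <- cbind(sample(cc, 200, TRUE), sample(nn, 200, TRUE))
  r2 <- vapply(seq_len(200), function(k) {
    stats::cor(pool$haplotypes[, pairs[k, 1]],
               pool$haplotypes[, pairs[k, 2]])^2
  }, numeric(1))
  expect_lt(mean(r2, na.rm = TRUE), 3 / 1000)
})

test_that("causal sites are drawn from qualifying central-region sites only", {
  pool <- make_toy_pool(list(
    causal = c(0.004, 0.015, 0.03, 0.2),
    null = c(0.004, 0.2)),
    positions = list(causal = c(210000L, 240000L, 280000L, 250000L),
                     null = c(210000L, 250000L)))
  set.seed(1)
  spec <- select_causal_sites(pool, c(0.002, 0.01), k = 1)
  expect_equal(spec$site_indices, 1L)       # unique qualifier
  expect_error(select_causal_sites(pool, c(0.04, 0.05), k = 1),
               class = "bvlr_retry_error")

  # off-center sites never qualify even with matching MAF
  pool2 <- make_toy_pool(list(causal = c(0.005, 0.005, 0.005, 0.005)),
                         positions = list(causal = c(10000L, 150000L,
                                                     220000L, 400000L)))
  set.seed(2)
  expect_error(select_causal_sites(pool2, c(0.002, 0.01), k = 3),
               class = "bvlr_retry_error")
  spec2 <- select_causal_sites(pool2, c(0.002, 0.01), k = 1)
  expect_equal(spec2$site_indices, 3L)
})

test_that("selected causal sites respect the MAF interval and central region at scale", {
  pool <- simulate_pool(sim_params(seed = 99))
  set.seed(3)
  spec <- select_causal_sites(pool, c(0.002, 0.01), k = 3)
  picked <- pool$sites[spec$site_indices, ]
  expect_equal(nrow(picked), 3L)
  expect_true(all(picked$chrom == "causal"))
  expect_true(all(picked$maf >= 0.002 & picked$maf < 0.01))
  expect_true(all(picked$pos >= 200001 & picked$pos <= 300000))
})

test_that("ms-style pool text round-trips", {
  set.seed(4)
  pool <- make_toy_pool(list(causal = c(0.1, 0.02), null = c(0.25)),
                        n_haplotypes = 40, shuffle = TRUE)
  path <- tempfile(fileext = ".ms")
  write_pool_ms(pool, path)
  back <- read_pool_ms(path)
  expect_identical(unname(back$haplotypes), unname(pool$haplotypes))
  expect_equal(back$sites$pos, pool$sites$pos)
  expect_equal(back$sites$maf, pool$sites$maf, tolerance = 1e-12)
})
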