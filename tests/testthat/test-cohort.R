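# Disease model, case/control sampling, candidate filter, liability
# phenotypes.

test_that("dominant risk assignment: baseline, carrier, saturation", {
  pool <- make_toy_pool(list(causal = c(0.1, 0.1, 0.1)))
  model <- disease_model(make_causal_spec(1:3))
  p <- ncol(pool$haplotypes)
  expect_equal(assign_risk(rep(0L, p), model), 0.01)
  row <- rep(0L, p); row[2] <- 1L
  expect_equal(assign_risk(row, model), 0.03)
  expect_equal(assign_risk(rep(2L, p), model), 0.03)  # not multiplicative
  expect_error(disease_model(make_causal_spec(1), grr = 300,
                             baseline_risk = 0.01), "baseline_risk")
})

test_that("cohorts meet quotas exactly and enrich carriers per Bayes' rule", {
  set.seed(10)
  pool <- make_toy_pool(list(causal = 0.106, null = 0.3), shuffle = TRUE)
  model <- disease_model(make_causal_spec(1))
  coh <- sample_case_control(pool, model, n_cases = 1500, n_controls = 200)
  expect_equal(sum(coh$status == 1), 1500)
  expect_equal(sum(coh$status == 0), 200)
  expect_equal(coh$status, rep(c(1L, 0L), c(1500, 200)))
  # closed-form conditional: P(carrier | case) = 3q / (3q + 1 - q)
  q <- 1 - (1 - 0.106)^2
  expected <- 3 * q / (3 * q + 1 - q)
  carrier <- coh$genotypes[coh$status == 1, 1] > 0
  se <- sqrt(expected * (1 - expected) / 1500)
  expect_lt(abs(mean(carrier) - expected), 3 * se)
})

test_that("null model (grr = 1) leaves carrier fractions exchangeable", {
  set.seed(11)
  pool <- make_toy_pool(list(causal = 0.2), shuffle = TRUE)
  model <- disease_model(make_causal_spec(1), grr = 1)
  coh <- sample_case_control(pool, model, n_cases = 800, n_controls = 800)
  f_case <- mean(coh$genotypes[coh$status == 1, 1] > 0)
  f_ctrl <- mean(coh$genotypes[coh$status == 0, 1] > 0)
  q <- 1 - 0.8^2
  se <- sqrt(2 * q * (1 - q) / 800)
  expect_lt(abs(f_case - f_ctrl), 3 * se)
})

test_that("candidate filter bounds, monomorphic drop, and idempotence", {
  n <- 1000
  X <- cbind(too_common = c(rep(1L, 120), rep(0L, n - 120)),  # MAF 6%
             mono = rep(0L, n),
             too_rare = c(rep(1L, 3), rep(0L, n - 3)),   # MAF 0.15%
             kept = c(rep(1L, 20), rep(0L, n - 20)))     # MAF 1%
  coh <- make_cohort(X, rep(0:1, each = n / 2))
  cand <- candidate_filter(coh, basis = "sample")
  expect_equal(cand$variants$id, coh$variants$id[4])
  cand2 <- candidate_filter(cand, basis = "sample")
  expect_identical(cand2$genotypes, cand$genotypes)

  # population-MAF basis keeps a causal variant whose sample MAF is
  # case-inflated above the bound
  coh2 <- make_cohort(X, rep(0:1, each = n / 2), causal = 1,
                      pop_maf = c(0.045, 0.0, 0.0015, 0.01))
  cand3 <- candidate_filter(coh2, basis = "pop")
  expect_true(coh2$variants$id[1] %in% cand3$variants$id)
  expect_gt(cand3$variants$maf[1], 0.05)  # sample MAF retained as metadata
  expect_error(candidate_filter(make_cohort(X[, 2, drop = FALSE],
                                            rep(0:1, each = n / 2))),
               "no variant passes")
})

test_that("liability phenotypes: variance algebra, median split, noiseless limit", {
  set.seed(12)
  n <- 728
  X <- cbind(rbinom(n, 2, 0.05), rbinom(n, 2, 0.02))
  ph <- simulate_liability_phenotypes(X, 1:2, h2 = 0.1)
  expect_equal(ph$V_e, 9 * ph$V_g)
  expect_equal(sum(ph$status), 364)
  expect_equal(ph$V_g, stats::var(as.numeric(rowSums(X > 0) > 0)))

  # nearly noiseless: every carrier is a case when carriers < n/2
  ph2 <- simulate_liability_phenotypes(X, 1:2, h2 = 0.999)
  carriers <- rowSums(X > 0) > 0
  if (sum(carriers) <= n / 2) expect_true(all(ph2$status[carriers] == 1))

  expect_error(simulate_liability_phenotypes(matrix(0L, 10, 1), 1, 0.1),
               "V_g = 0")
  expect_error(simulate_liability_phenotypes(X, 1:2, h2 = 1.2), "h2")
})

test_that("case MAF at a causal site exceeds control MAF under GRR > 1", {
  set.seed(13)
  pool <- make_toy_pool(list(causal = 0.04), shuffle = TRUE)
  model <- disease_model(make_causal_spec(1))
  coh <- sample_case_control(pool, model, 1000, 1000)
  f_case <- mean(coh$genotypes[coh$status == 1, 1]) / 2
  f_ctrl <- mean(coh$genotypes[coh$status == 0, 1]) / 2
  expect_gt(f_case, f_ctrl)
})
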