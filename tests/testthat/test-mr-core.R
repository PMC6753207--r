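test_that("Wald ratios follow the first-order formula exactly", {
  h <- make_harmonized(3, seed = 1)
  h$beta_exposure <- c(0.1, 0.25, -0.2)
  h$beta_outcome <- c(-0.02, 0, 0.03)
  h$se_outcome <- c(0.01, 0.02, 0.05)
  r <- wald_ratios(h)
  expect_equal(r$theta[1], -0.2)
  expect_equal(r$variance[1], 0.01)       # (0.01/0.1)^2
  expect_equal(r$theta[2], 0)             # zero outcome beta -> zero ratio
  set.seed(2)
  for (i in 1:50) {
    bx <- stats::runif(1, 0.01, 0.5) * sample(c(-1, 1), 1)
    by <- stats::rnorm(1, 0, 0.05)
    sy <- stats::runif(1, 0.005, 0.05)
    hh <- make_harmonized(1)
    hh$beta_exposure <- bx; hh$beta_outcome <- by; hh$se_outcome <- sy
    rr <- wald_ratios(hh)
    expect_equal(rr$variance, (sy / bx)^2, tolerance = 1e-14)
    expect_equal(rr$weight, 1 / rr$variance, tolerance = 1e-14)
  }
})

test_that("a zero exposure beta is an undefined-ratio error naming the SNP", {
  h <- make_harmonized(2, seed = 3)
  h$beta_exposure[2] <- 0
  expect_error(wald_ratios(h), h$rsid[2])
})

test_that("equal-weight pooling of two ratios is their midpoint", {
  h <- make_harmonized(2, seed = 4)
  h$beta_exposure <- c(0.1, 0.1)
  h$se_outcome <- c(0.01, 0.01)
  h$beta_outcome <- c(-0.1, -0.3) * 0.1
  fit <- ivw_pool(wald_ratios(h))
  expect_equal(fit$theta_ivw, -0.2, tolerance = 1e-12)
})

test_that("the IVW estimate equals the weighted no-intercept regression slope", {
  for (seed in 1:10) {
    h <- make_harmonized(20, theta = -0.05, seed = seed)
    fit <- ivw_pool(wald_ratios(h))
    wls <- stats::lm(beta_outcome ~ 0 + beta_exposure, data = h,
                     weights = 1 / se_outcome^2)
    expect_equal(fit$theta_ivw, unname(stats::coef(wls)), tolerance = 1e-12)
  }
})

test_that("IVW matches an independent fixed-effect meta-analysis", {
  skip_if_not_installed("metafor")
  h <- make_harmonized(25, theta = -0.05, seed = 8)
  r <- wald_ratios(h)
  fit <- ivw_pool(r)
  ma <- metafor::rma(yi = r$theta, vi = r$variance, method = "FE")
  expect_equal(fit$theta_ivw, as.numeric(ma$beta), tolerance = 1e-10)
  expect_equal(fit$se_ivw, ma$se, tolerance = 1e-10)
  expect_equal(fit$pvalue, ma$pval, tolerance = 1e-10)
  expect_equal(fit$q_statistic, ma$QE, tolerance = 1e-10)
  expect_equal(fit$q_pvalue, ma$QEp, tolerance = 1e-10)
})

test_that("IVW is permutation-invariant and scale-consistent", {
  h <- make_harmonized(15, theta = -0.1, seed = 5)
  fit <- ivw_pool(wald_ratios(h))
  set.seed(6)
  perm <- h[sample(nrow(h)), , drop = FALSE]
  expect_equal(ivw_pool(wald_ratios(perm))$theta_ivw, fit$theta_ivw,
               tolerance = 1e-14)
  scaled <- h
  scaled$beta_exposure <- h$beta_exposure * 3
  scaled$beta_outcome <- h$beta_outcome * 3
  scaled$se_outcome <- h$se_outcome * 3
  expect_equal(ivw_pool(wald_ratios(scaled))$theta_ivw, fit$theta_ivw,
               tolerance = 1e-12)
})

test_that("a dominant weight pulls the pooled estimate to that SNP's ratio", {
  h <- make_harmonized(10, theta = 0.2, seed = 7)
  h$se_outcome[1] <- h$se_outcome[1] * 1e-6
  r <- wald_ratios(h)
  fit <- ivw_pool(r)
  expect_equal(fit$theta_ivw, r$theta[1], tolerance = 1e-6)
})

test_that("pooled results respect the confidence-interval ordering", {
  for (seed in 1:5) {
    h <- make_harmonized(12, theta = -0.05, seed = seed)
    fit <- ivw_pool(wald_ratios(h))
    expect_lt(fit$ci_low, fit$odds_ratio)
    expect_lt(fit$odds_ratio, fit$ci_high)
    expect_gte(fit$n_snps, 2L)
  }
})

test_that("fewer than two instruments cannot be pooled", {
  h <- make_harmonized(1, seed = 9)
  expect_error(ivw_pool(wald_ratios(h)), "at least 2")
})

test_that("group pooling conserves instrument counts across groupings", {
  h1 <- make_harmonized(8, theta = -0.05, seed = 10)
  h1$cancer_type <- "lung"; h1$smoking_related <- TRUE
  h2 <- make_harmonized(5, theta = -0.05, seed = 11)
  h2$cancer_type <- "breast"; h2$smoking_related <- FALSE
  h <- rbind(h1, h2)
  per <- pool_groups(h, "per-cancer")
  expect_setequal(per$group, c("lung", "breast"))
  expect_equal(per$n_snps[per$group == "lung"], 8L)
  expect_equal(per$n_snps[per$group == "breast"], 5L)
  all_fit <- pool_groups(h, "all")
  expect_equal(all_fit$n_snps, 13L)          # conservation
  expect_equal(pool_groups(h, "smoking")$n_snps, 8L)
  expect_equal(pool_groups(h, "non-smoking")$n_snps, 5L)
  # pooling two cancers sharing one causal effect tightens the estimate
  expect_lt(all_fit$se_ivw, min(per$se_ivw))
})

test_that("an unknown grouping label is a configuration error", {
  h <- make_harmonized(4, seed = 12)
  expect_error(pool_groups(h, "by-tissue"), "unknown grouping")
})

test_that("cross-cancer duplicate rsids are kept unless dedupe is requested", {
  h1 <- make_harmonized(4, seed = 13); h1$cancer_type <- "a"
  h2 <- make_harmonized(4, seed = 13); h2$cancer_type <- "b"
  h <- rbind(h1, h2)                          # same rsids twice
  expect_equal(pool_groups(h, "all")$n_snps, 8L)
  expect_equal(pool_groups(h, "all", dedupe = TRUE)$n_snps, 4L)
})

test_that("single-instrument groups are skipped with a message", {
  h1 <- make_harmonized(4, seed = 14); h1$cancer_type <- "lung"
  h2 <- make_harmonized(1, seed = 15); h2$cancer_type <- "cervical"
  h <- rbind(h1, h2)
  expect_message(per <- pool_groups(h, "per-cancer"), "cervical")
  expect_identical(per$group, "lung")
  # the lone instrument still joins aggregate pooling
  expect_equal(pool_groups(h, "all")$n_snps, 5L)
})

test_that("mr_table stacks per-cancer rows with the three aggregates", {
  h1 <- make_harmonized(6, theta = -0.05, seed = 16)
  h1$cancer_type <- "lung"; h1$smoking_related <- TRUE
  h2 <- make_harmonized(7, theta = -0.05, seed = 17)
  h2$cancer_type <- "leukemia"; h2$smoking_related <- FALSE
  tab <- mr_table(rbind(h1, h2))
  expect_identical(tab$group, c("lung", "leukemia", "smoking_related",
                                "non_smoking_related", "all_cancers"))
  expect_equal(tab$n_snps, c(6L, 7L, 6L, 7L, 13L))
})
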