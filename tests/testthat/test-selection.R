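test_that("significance filtering uses a strict threshold", {
  tab <- make_instruments(c("rs1", "rs2", "rs3"), beta = c(0.1, 0.1, 0.1),
                          se = 0.01, pvalue = c(4.9e-8, 5e-8, 5.1e-8))
  kept <- filter_significant(tab)
  expect_identical(kept$rsid, "rs1")   # 5e-8 itself is dropped
})

test_that("significance filtering keeps exactly the sub-threshold rows in order", {
  p <- c(1e-9, 0.2, 3e-8, 0.5, 4e-7, 0.9, 1e-10, 0.04, 0.6, 0.7)
  tab <- make_instruments(sprintf("rs%02d", 1:10), beta = 0.1, se = 0.01,
                          pvalue = p)
  kept <- filter_significant(tab)
  expect_identical(kept$rsid, sprintf("rs%02d", which(p < 5e-8)))
  expect_equal(nrow(kept), 3L)
})

test_that("LD pruning is a no-op when all pairs are below threshold", {
  fx <- simulate_ld_fixture(3, 2, within_r2 = 0.1, seed = 5)
  tab <- make_instruments(rownames(fx$ld), beta = 0.1, se = 0.01,
                          pvalue = seq(1e-10, 1e-9, length.out = 6))
  res <- ld_prune(tab, fx$ld)
  expect_setequal(res$table$rsid, tab$rsid)
  expect_length(res$report$dropped_ld, 0)
})

test_that("the lead SNP (lowest p-value) survives pruning of a correlated pair", {
  ld <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
               dimnames = list(c("rsA", "rsB"), c("rsA", "rsB")))
  tab <- make_instruments(c("rsA", "rsB"), beta = 0.1, se = 0.01,
                          pvalue = c(1e-9, 1e-10))
  res <- ld_prune(tab, ld)
  expect_identical(res$table$rsid, "rsB")  # 1e-10 beats 1e-9
  expect_identical(unname(res$report$dropped_ld["rsA"]), "rsB")
})

test_that("greedy pruning of an LD chain keeps the p-ordered independent set", {
  # A-B r2=0.3, B-C r2=0.3, A-C r2=0 with p_A < p_B < p_C
  ld <- diag(3)
  dimnames(ld) <- list(c("rsA", "rsB", "rsC"), c("rsA", "rsB", "rsC"))
  ld["rsA", "rsB"] <- ld["rsB", "rsA"] <- 0.3
  ld["rsB", "rsC"] <- ld["rsC", "rsB"] <- 0.3
  tab <- make_instruments(c("rsA", "rsB", "rsC"), beta = 0.1, se = 0.01,
                          pvalue = c(1e-12, 1e-10, 1e-8))
  res <- ld_prune(tab, ld)
  expect_setequal(res$table$rsid, c("rsA", "rsC"))
})

test_that("pruning never retains a violating pair and ignores input order", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    rsids <- sprintf("rs%03d", sample(1:999, n))
    m <- matrix(stats::runif(n * n), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    dimnames(m) <- list(rsids, rsids)
    tab <- make_instruments(rsids, beta = 0.1, se = 0.01,
                            pvalue = stats::runif(n, 1e-12, 1e-8))
    res <- ld_prune(tab, m, r2_max = 0.2)
    kept <- res$table$rsid
    if (length(kept) > 1) {
      pairs <- utils::combn(kept, 2)
      expect_true(all(m[cbind(pairs[1, ], pairs[2, ])] < 0.2))
    }
    # invariant to row order
    perm <- tab[sample(n), , drop = FALSE]
    expect_identical(ld_prune(perm, m, r2_max = 0.2)$table$rsid, kept)
    # partition: kept + dropped covers the input exactly once
    expect_setequal(c(kept, names(res$report$dropped_ld)), rsids)
  }
})

test_that("an rsid absent from the LD matrix is a configuration error", {
  ld <- diag(1); dimnames(ld) <- list("rsA", "rsA")
  tab <- make_instruments(c("rsA", "rsZ"), beta = 0.1, se = 0.01,
                          pvalue = c(1e-9, 1e-9))
  expect_error(ld_prune(tab, ld), "rsZ")
})

test_that("instruments present in the outcome pass through proxying untouched", {
  tab <- make_instruments(c("rs1", "rs2"), beta = c(0.1, -0.2),
                          se = c(0.01, 0.02), pvalue = c(1e-9, 1e-10))
  res <- substitute_proxies(tab, outcome_rsids = c("rs1", "rs2"))
  expect_identical(res$table$rsid, c("rs1", "rs2"))
  expect_equal(res$table$beta, tab$beta)
  expect_equal(res$table$se, tab$se)
  expect_equal(res$table$pvalue, tab$pvalue)
  expect_false(any(res$table$proxy_used))
})

test_that("a proxy at exactly r2 = 0.9 is not used (strict inequality)", {
  tab <- make_instruments("rs1", beta = 0.1, se = 0.01, pvalue = 1e-9)
  proxies <- mrivw:::validate_proxy_table(data.frame(
    target_rsid = "rs1", proxy_rsid = "rs9", r2 = 0.9,
    target_allele = c("A", "G"), proxy_allele = c("C", "T"),
    stringsAsFactors = FALSE))
  res <- substitute_proxies(tab, outcome_rsids = "rs9", proxies = proxies)
  expect_equal(nrow(res$table), 0L)
  expect_identical(res$report$dropped_no_proxy, "rs1")
})

test_that("the highest-r2 qualifying proxy is chosen and alleles remapped", {
  tab <- make_instruments("rs1", beta = 0.1, se = 0.01, pvalue = 1e-9,
                          effect_allele = "A", other_allele = "G")
  proxies <- mrivw:::validate_proxy_table(data.frame(
    target_rsid = "rs1",
    proxy_rsid = c("rs92", "rs92", "rs97", "rs97"),
    r2 = c(0.92, 0.92, 0.97, 0.97),
    target_allele = c("A", "G", "A", "G"),
    proxy_allele = c("A", "G", "T", "C"),
    stringsAsFactors = FALSE))
  res <- substitute_proxies(tab, outcome_rsids = c("rs92", "rs97"),
                            proxies = proxies)
  expect_identical(res$table$rsid, "rs97")
  expect_identical(res$table$effect_allele, "T")  # A -> T per the rs97 map
  expect_identical(res$table$other_allele, "C")
  expect_identical(unname(res$report$proxied["rs1"]), "rs97")
  # exposure-side statistics are inherited from the target unchanged
  expect_equal(res$table$beta, 0.1)
  expect_equal(res$table$se, 0.01)
  expect_equal(res$table$pvalue, 1e-9)
  expect_identical(res$table$proxy_for, "rs1")
})

test_that("a non-bijective allele map is a data error at substitution time", {
  tab <- make_instruments("rs1", beta = 0.1, se = 0.01, pvalue = 1e-9)
  proxies <- data.frame(target_rsid = "rs1", proxy_rsid = "rs9",
                        r2 = 0.95, target_allele = c("A", "G"),
                        proxy_allele = c("C", "C"), stringsAsFactors = FALSE)
  class(proxies) <- c("proxy_table", "data.frame")
  expect_error(substitute_proxies(tab, "rs9", proxies), "bijection")
})

test_that("the selection report partitions the input rsids", {
  fx <- simulate_ld_fixture(3, 3, within_r2 = 0.6, proxy_r2 = 0.95, seed = 7)
  rsids <- rownames(fx$ld)
  tab <- make_instruments(rsids, beta = 0.1, se = 0.01,
                          pvalue = c(1e-12, 1e-11, 1e-10,
                                     1e-12, 1e-11, 0.5,     # one non-significant
                                     1e-12, 1e-11, 1e-10),
                          effect_allele = fx$alleles$a1,
                          other_allele = fx$alleles$a2)
  # outcome misses the designated per-locus SNPs; proxies exist for them
  outcome_rsids <- c(setdiff(rsids, fx$missing),
                     fx$proxies$proxy_rsid)
  res <- select_instruments(tab, outcome_rsids, ld = fx$ld,
                            proxies = fx$proxies)
  rep <- res$report
  accounted <- c(rep$kept, rep$dropped_significance, names(rep$dropped_ld),
                 names(rep$proxied), rep$dropped_no_proxy)
  expect_setequal(accounted, rsids)
  expect_equal(length(accounted), length(rsids))  # exactly once each
  expect_length(intersect(rep$kept, rep$dropped_significance), 0)
  json <- selection_report_json(rep)
  expect_silent(jsonlite::fromJSON(json))
})
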