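# Convergence statistics: exact binomial machinery, power, enrichment, FDR.

test_that("two-sided exact binomial p equals brute-force sequence enumeration", {
  # enumeration over all 2^n success/failure sequences (binom_brute_p)
  for (n in c(5, 9, 12)) {
    for (p0 in c(0.1, 0.3, 0.5, 0.9)) {
      for (x in 0:n) {
        expect_equal(binom_test_two_sided(x, n, p0), binom_brute_p(x, n, p0),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("exact binomial p agrees with the reference implementation", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(1:400, 1)
    x <- sample(0:n, 1)
    p0 <- runif(1)
    expect_equal(binom_test_two_sided(x, n, p0),
                 stats::binom.test(x, n, p0)$p.value, tolerance = 1e-12)
  }
  # degenerate nulls
  expect_equal(binom_test_two_sided(0, 10, 0), 1)
  expect_equal(binom_test_two_sided(3, 10, 0), 0)
  expect_equal(binom_test_two_sided(10, 10, 1), 1)
  expect_equal(binom_test_two_sided(9, 10, 1), 0)
  expect_error(binom_test_two_sided(-1, 10, 0.5), "domain")
  expect_error(binom_test_two_sided(11, 10, 0.5), "domain")
})

test_that("Clopper-Pearson matches tail-inversion and reference intervals", {
  set.seed(2)
  for (i in 1:25) {
    n <- sample(2:200, 1)
    x <- sample(0:n, 1)
    ci <- clopper_pearson(x, n)
    ref <- stats::binom.test(x, n)$conf.int
    expect_equal(unname(ci), as.numeric(ref), tolerance = 1e-9)
  }
  # boundary cases
  expect_equal(clopper_pearson(0, 10)[["low"]], 0)
  expect_equal(clopper_pearson(10, 10)[["high"]], 1)
  # duality: at the bounds, the one-sided tail probability equals alpha/2
  for (x in c(1, 7, 17)) {
    ci <- clopper_pearson(x, 25)
    expect_equal(stats::pbinom(x - 1, 25, ci[["low"]], lower.tail = FALSE),
                 0.025, tolerance = 1e-8)
    expect_equal(stats::pbinom(x, 25, ci[["high"]]), 0.025, tolerance = 1e-8)
  }
  # monotone in x
  lows <- vapply(0:20, function(x) clopper_pearson(x, 20)[["low"]], numeric(1))
  expect_true(all(diff(lows) > 0 | (lows[-1] == 0 & lows[-21] == 0)))
})

test_that("Clopper-Pearson interval covers the truth at nominal rate", {
  set.seed(3)
  n <- 50; p <- 0.2
  x <- rbinom(1e4, n, p)
  lo <- ifelse(x == 0, 0, qbeta(0.025, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(0.975, x + 1, n - x))
  # the qbeta forms above restate the definition; check they match the API
  i <- sample(1e4, 20)
  for (j in i) {
    expect_equal(unname(clopper_pearson(x[j], n)), c(lo[j], hi[j]))
  }
  coverage <- mean(lo <= p & p <= hi)
  expect_gte(coverage, 0.94)
})

test_that("expected convergent probability is the product and bounded by the minimum", {
  expect_equal(expected_convergent_prob(c(0.5, 0.5, 0.5)), 0.125)
  expect_equal(expected_convergent_prob(c(0.3, 0, 0.9)), 0)
  set.seed(4)
  for (i in 1:20) {
    m <- runif(3)
    expect_lte(expected_convergent_prob(m), min(m))
  }
  # Monte-Carlo frequency of simultaneous independent losses
  m <- c(0.25, 0.3, 0.2)
  B <- 1e6
  hits <- (runif(B) < m[1]) & (runif(B) < m[2]) & (runif(B) < m[3])
  p_mc <- mean(hits)
  se <- sqrt(p_mc * (1 - p_mc) / B)
  expect_lt(abs(expected_convergent_prob(m) - p_mc), 3 * se)
})

test_that("exact power enumerates the rejection region; simulation agrees", {
  # size of the test never exceeds alpha by more than discreteness allows
  for (n in c(20, 50)) {
    for (p0 in c(0.1, 0.3)) {
      pw <- binom_power(n, p0, p0, alpha = 0.05)
      expect_lte(pw$power, 0.05 + 1e-12)
    }
  }
  ex <- binom_power(20, 0.1, 0.5, method = "exact")
  si <- binom_power(20, 0.1, 0.5, method = "simulate", B = 1e5, seed = 9)
  se <- sqrt(ex$power * (1 - ex$power) / 1e5)
  expect_lt(abs(ex$power - si$power), 3 * se)
  expect_equal(ex$method, "exact")
  expect_equal(si$method, "simulate")
})

test_that("convergence test assembles marginals, null product, CI, p and power", {
  cfg <- toy_config()
  cl <- list(
    make_cluster("c1", c(P1 = 0, P2 = 0, H1 = 1, H2 = 1, N1 = 1)),
    make_cluster("c2", c(P1 = 0, P2 = 1, H1 = 1, H2 = 1, N1 = 1)),
    make_cluster("c3", c(P1 = 1, P2 = 1, H1 = 1, H2 = 1, N1 = 1)),
    make_cluster("c4", c(P1 = 1, P2 = 1, H1 = 1, H2 = 1, N1 = 0))
  )
  tab <- build_call_table(structure(cl, class = "ortholog_clusters",
                                    focal = cfg$focal), cfg)
  ct <- convergence_test(tab, side = "parasite", event = "loss")
  expect_equal(unname(ct$marginals), c(2 / 4, 1 / 4))
  expect_equal(ct$p0, prod(ct$marginals), tolerance = 1e-12)
  expect_equal(ct$x, 1L)
  expect_equal(ct$p_obs, 1 / 4)
  expect_equal(ct$p_value, binom_test_two_sided(1, 4, ct$p0))
  expect_true(ct$ci[["low"]] <= ct$p_obs && ct$p_obs <= ct$ci[["high"]])
  expect_gte(ct$power, 0)
  expect_lte(ct$power, 1)
  # host side: c4 has host loss (H2 count 0 < P2 count 1) in L2 only
  cth <- convergence_test(tab, side = "host", event = "loss")
  expect_equal(cth$x, 0L)
  expect_equal(cth$p_obs, 0)
})

test_that("subfamily enrichment tests each subfamily against the family-wide null", {
  cfg <- toy_config()
  cl <- lapply(1:12, function(i) {
    counts <- if (i <= 3) c(P1 = 0, P2 = 0, H1 = 1, H2 = 1, N1 = 1)
    else c(P1 = 1, P2 = 1, H1 = 1, H2 = 1, N1 = 1)
    make_cluster(sprintf("c%02d", i), counts)
  })
  tab <- build_call_table(structure(cl, class = "ortholog_clusters",
                                    focal = cfg$focal), cfg)
  subfam <- stats::setNames(rep(c("A", "B"), each = 6),
                            sprintf("c%02d", 1:12))
  enr <- subfamily_enrichment(tab, subfam, p0 = 0.0164)
  expect_equal(nrow(enr), 2L)
  a <- enr[enr$subfamily == "A", ]
  expect_equal(a$x, 3L)
  expect_equal(a$n, 6L)
  expect_equal(a$p_raw, binom_test_two_sided(3, 6, 0.0164))
  expect_equal(enr$p_adj, bh_adjust(enr$p_raw)[order(bh_adjust(enr$p_raw))])
  # subfamily with no convergent loss is not enriched
  b <- enr[enr$subfamily == "B", ]
  expect_gt(b$p_raw, 0.5)
  # single subfamily: adjusted equals raw
  single <- subfamily_enrichment(tab, stats::setNames(rep("A", 12),
                                                      sprintf("c%02d", 1:12)),
                                 p0 = 0.0164)
  expect_equal(single$p_adj, single$p_raw)
})

test_that("equality-of-proportions wraps the chi-square with Yates correction", {
  r <- prop_test(c(5, 5), c(10, 10))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # hand-computed Yates chi-square for (10,0) of (10,10):
  # sum over cells of (|O-E| - 0.5)^2 / E with E = 5 per cell
  hand <- 4 * (abs(10 - 5) - 0.5)^2 / 5
  r2 <- prop_test(c(10, 0), c(10, 10), correction = TRUE)
  expect_equal(r2$statistic, hand)
  expect_equal(r2$statistic, 16.2)
  r3 <- prop_test(c(2, 4, 6), c(10, 20, 30))
  expect_equal(r3$statistic, 0)
  expect_equal(r3$df, 2L)
  expect_error(prop_test(c(1, 1), c(10, 0)), "domain")
})

test_that("BH adjustment equals the step-up definition and preserves order", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(6)
  for (i in 1:10) {
    p <- runif(sample(2:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # monotone on sorted input
    expect_true(all(diff(bh_adjust(sort(p))) >= -1e-15))
  }
})
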