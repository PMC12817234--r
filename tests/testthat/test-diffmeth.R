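test_that("trigamma inversion matches a bisection oracle", {
  bisect <- function(y) {
    lo <- 1e-8; hi <- 1e8
    for (i in 1:200) {
      mid <- sqrt(lo * hi)
      if (trigamma(mid) > y) lo <- mid else hi <- mid
    }
    sqrt(lo * hi)
  }
  for (y in c(0.001, 0.01, 0.1, 0.5, 1, 2, 10, 100)) {
    expect_equal(trigamma_inverse(y), bisect(y), tolerance = 1e-6)
    expect_equal(trigamma(trigamma_inverse(y)), y, tolerance = 1e-8)
  }
})

test_that("moderation prior: equal variances give d0 = Inf, s0^2 = variance", {
  fit <- fit_moderation(rep(0.37, 100), d = 10)
  expect_identical(fit$d0, Inf)
  expect_equal(fit$s0_sq, 0.37)
  expect_error(fit_moderation(rep(0, 100), 10), "zero")
  expect_error(fit_moderation(c(1, 2), 10), ">= 10 probes")
})

test_that("moderation prior recovers known (d0, s0) from simulated variances", {
  withr::local_seed(101)
  d0 <- 4; s0 <- 0.5; d <- 10
  sigma2 <- s0 * d0 / rchisq(5000, df = d0)      # scaled inverse-chi-square
  s2 <- sigma2 * rchisq(5000, df = d) / d
  fit <- fit_moderation(s2, d)
  expect_lt(abs(fit$d0 - d0) / d0, 0.25)
  expect_lt(abs(fit$s0_sq - s0) / s0, 0.25)
})

test_that("moderated t with vanishing prior equals the pooled two-sample t", {
  withr::local_seed(55)
  m <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(sprintf("p%02d", 1:50), NULL))
  colnames(m) <- sprintf("S%02d", 1:12)
  groups <- rep(c("a", "b"), each = 6)
  res <- moderated_t_test(m, groups, params = list(d0 = 0, s0_sq = 1, d = 10))
  oracle <- apply(m, 1L, function(row) {
    tt <- t.test(row[1:6], row[7:12], var.equal = TRUE)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  expect_equal(res$moderated_t, unname(oracle["t", ]), tolerance = 1e-10)
  expect_equal(res$p, unname(oracle["p", ]), tolerance = 1e-10)
})

test_that("moderated t matches limma's empirical-Bayes pipeline", {
  withr::local_seed(77)
  m <- matrix(rnorm(800 * 16, sd = rep(sqrt(0.2 / rchisq(800, 4) * 4), 16)),
              800, 16, dimnames = list(sprintf("p%03d", 1:800), NULL))
  colnames(m) <- sprintf("S%02d", 1:16)
  m[1:40, 1:8] <- m[1:40, 1:8] + 1
  groups <- rep(c("mut", "wt"), each = 8)
  res <- moderated_t_test(m, groups)

  design <- cbind(1, as.numeric(groups == "mut"))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(res, "moderation")$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "moderation")$s0_sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$moderated_t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("moderated t invariances hold", {
  withr::local_seed(9)
  m <- matrix(rnorm(100 * 10), 100, 10,
              dimnames = list(sprintf("p%03d", 1:100), sprintf("S%02d", 1:10)))
  g <- rep(c("x", "y"), each = 5)
  res <- moderated_t_test(m, g)
  swapped <- moderated_t_test(m, factor(g, levels = c("y", "x")))
  expect_equal(swapped$moderated_t, -res$moderated_t, tolerance = 1e-12)
  expect_equal(swapped$p, res$p, tolerance = 1e-12)

  m2 <- m
  m2[7, ] <- m2[7, ] + 100    # constant shift at one probe
  res2 <- moderated_t_test(m2, g, params = attr(res, "moderation"))
  expect_equal(res2$moderated_t[7], res$moderated_t[7], tolerance = 1e-9)

  expect_true(all(res$fdr >= res$p - 1e-15))
  # BH equals the brute-force definition
  p <- res$p
  mlen <- length(p)
  o <- order(p)
  brute <- numeric(mlen)
  for (i in seq_len(mlen)) {
    j <- which(o == i)  # rank of p[i]
    brute[i] <- min(1, min(p[o][j:mlen] * mlen / (j:mlen)))
  }
  expect_equal(res$fdr, brute, tolerance = 1e-12)
})

test_that("degenerate probes give t = 0, p = 1 and group floors are enforced", {
  m <- matrix(c(rep(1, 8), rep(c(0, 1), 4)), 2, 8, byrow = TRUE,
              dimnames = list(c("flat", "var"), sprintf("S%d", 1:8)))
  g <- rep(c("a", "b"), each = 4)
  res <- moderated_t_test(m, g, params = list(d0 = 4, s0_sq = 0.25, d = 6))
  expect_equal(res$moderated_t[res$probe_id == "flat"], 0)
  expect_equal(res$p[res$probe_id == "flat"], 1)
  expect_error(moderated_t_test(m, c("a", rep("b", 7))), ">= 2 samples")
})

test_that("call_dmcs recovers the planted PRC2 differential probes", {
  sim <- generate_cohort(small_config(seed = 62, n_samples = 200L))
  res <- call_dmcs(sim$beta, sim$clinical, "DNMT3A_mut")
  called <- res$probe_id[res$is_dmc]
  planted <- sim$truth$dmc_probes
  recall <- mean(planted %in% called)
  precision <- mean(called %in% planted)
  expect_gt(recall, 0.8)
  expect_gt(precision, 0.8)
  expect_equal(glance(res)$n_dmc, length(called))
})
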