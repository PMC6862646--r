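# DIC, effective sample size, odds ratios, region classes, prediction.

fit_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_survey(small_config(seed = 30))
      frame <- build_design(sim$dataset, kenya_region_graph(),
                            model_spec(linear = c("mother_cut", "urban"),
                                       spatial = TRUE,
                                       unstructured = TRUE))
      s <- run_mcmc(frame, mcmc_config(900, 200, 2, seed = 5))
      cache <<- list(sim = sim, frame = frame, samples = s)
    }
    cache
  }
})

test_that("identical draws give pD = 0 and DIC equal to the deviance", {
  f <- fit_small()
  s1 <- f$samples
  # replicate a single draw across the chain
  for (b in names(s1$draws))
    s1$draws[[b]] <- s1$draws[[b]][rep(1, 40), , drop = FALSE]
  s1$n_store <- 40
  d <- compute_dic(s1, f$frame)
  expect_equal(d$pd, 0, tolerance = 1e-9)
  expect_equal(d$dic, d$dbar, tolerance = 1e-9)
  expect_gt(d$dbar, 0)
})

test_that("DIC is recomputable from persisted draws to 1e-6", {
  f <- fit_small()
  d1 <- compute_dic(f$samples, f$frame)
  dir <- withr::local_tempdir()
  write_samples(f$samples, dir)
  d2 <- compute_dic(read_samples(dir), f$frame)
  expect_equal(d2$dic, d1$dic, tolerance = 1e-6)
  expect_equal(d2$pd, d1$pd, tolerance = 1e-6)
  expect_gte(d1$pd, 0)
})

test_that("ESS is calibrated on iid and AR(1) chains", {
  set.seed(61)
  ess_iid <- mcmc_ess(rnorm(10000))
  expect_gt(ess_iid / 10000, 0.8)
  expect_lt(ess_iid / 10000, 1.2)

  # AR(1) with phi = 0.5 has ESS = N (1 - phi) / (1 + phi) = N / 3
  n <- 20000
  phi <- 0.5
  x <- as.numeric(arima.sim(list(ar = phi), n))
  expect_equal(mcmc_ess(x), n / 3, tolerance = 0.2)

  expect_error(mcmc_ess(rep(1, 100)), "constant")
  expect_error(mcmc_ess(rnorm(10)), "short")
})

test_that("posterior odds ratios match exp-then-quantile computation", {
  f <- fit_small()
  tab <- posterior_odds_ratios(f$samples)
  d <- f$samples$draws$fixed
  for (i in seq_len(nrow(tab))) {
    ed <- exp(d[, tab$term[i]])
    expect_equal(tab$por[i], mean(ed), tolerance = 1e-10)
    expect_equal(tab$lower[i], quantile(ed, 0.025, names = FALSE),
                 tolerance = 1e-10)
    expect_equal(tab$upper[i], quantile(ed, 0.975, names = FALSE),
                 tolerance = 1e-10)
  }

  # degenerate and symmetric cases
  s <- f$samples
  s$draws$fixed <- matrix(log(2), 100, 2,
                          dimnames = list(NULL, c("(Intercept)", "x")))
  tab2 <- posterior_odds_ratios(s)
  expect_equal(tab2$por, 2)
  expect_equal(tab2$lower, 2)
  expect_equal(tab2$upper, 2)
  set.seed(3)
  s$draws$fixed[, "x"] <- c(rnorm(50), -rnorm(50))
  tab3 <- posterior_odds_ratios(s)
  expect_true(tab3$lower < 1 && 1 < tab3$upper)
})

test_that("region classes follow the credible-interval sign rule", {
  f <- fit_small()
  cls <- classify_regions(f$samples, 0.95)
  # agreement with direct quantile computation on the stored draws
  eff <- f$samples$draws$str + f$samples$draws$unstr
  for (i in seq_len(nrow(cls))) {
    q <- quantile(eff[, cls$region[i]], c(0.025, 0.975), names = FALSE)
    expected <- if (q[1] > 0) "HIGH" else if (q[2] < 0) "LOW" else "NONSIG"
    expect_equal(cls$class[i], expected)
    expect_equal(cls$lower[i], q[1], tolerance = 1e-12)
  }

  # forced sign patterns
  s <- f$samples
  S <- ncol(s$draws$str)
  s$draws$str <- matrix(abs(rnorm(100 * S)) + 0.1, 100, S,
                        dimnames = dimnames(s$draws$str))
  s$draws$unstr <- matrix(0, 100, S, dimnames = dimnames(s$draws$str))
  expect_true(all(classify_regions(s)$class == "HIGH"))
  s$draws$str <- -s$draws$str
  expect_true(all(classify_regions(s)$class == "LOW"))
  # zero-centered draws are nonsignificant
  set.seed(8)
  s$draws$str <- matrix(rnorm(2000 * S), 2000, S,
                        dimnames = dimnames(s$draws$str))
  s$draws$unstr <- matrix(0, 2000, S, dimnames = dimnames(s$draws$str))
  expect_true(all(classify_regions(s)$class == "NONSIG"))
  expect_error(classify_regions(s, level = 1.2), "level")
})

test_that("structured-only classification uses only the ICAR field", {
  f <- fit_small()
  c_tot <- classify_regions(f$samples, which = "total")
  c_str <- classify_regions(f$samples, which = "structured")
  expect_equal(c_str$mean, unname(colMeans(f$samples$draws$str)))
  expect_false(isTRUE(all.equal(c_tot$mean, c_str$mean)))
})

test_that("predicted prevalence behaves under the logit link", {
  f <- fit_small()
  # eta identically zero -> prevalence one half
  s <- f$samples
  for (b in names(s$draws)) s$draws[[b]][] <- 0
  pp <- predict_prevalence(s, f$frame, f$frame$region_ids[1])
  expect_equal(pp$mean, 0.5)

  # adding +1 to every eta draw strictly increases the mean
  s$draws$fixed[, "(Intercept)"] <- 1
  pp2 <- predict_prevalence(s, f$frame, f$frame$region_ids[1])
  expect_gt(pp2$mean, pp$mean)

  expect_error(predict_prevalence(f$samples, f$frame, "Atlantis"),
               "unknown region")
})

test_that("fit summaries bundle consistent components", {
  f <- fit_small()
  fs <- fit_summary(f$samples, f$frame)
  expect_equal(fs$dic, fs$dbar + fs$pd, tolerance = 1e-10)
  expect_true(all(fs$por_table$lower <= fs$por_table$por + 1e-12))
  expect_true(all(fs$por_table$por <= fs$por_table$upper + 1e-12))
  expect_equal(nrow(fs$region_class), 8)
  expect_equal(nrow(fs$prevalence), 8)
  expect_true(all(fs$prevalence$prevalence >= 0 &
                    fs$prevalence$prevalence <= 1))
})
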