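# Design assembly, log posterior, and the Polya-Gamma Gibbs sampler.

test_that("design blocks match the specified term structure", {
  ds <- tiny_dataset(12)
  g <- path3_graph()

  # normative-only structure: no spatial or interaction blocks
  specA <- model_spec(linear = "mother_cut",
                      smooth = list(prop_cut = list(n_inner_knots = 2,
                                                    degree = 1)))
  ds$records$mother_cut[ds$records$region_id == "B"] <- 1L
  ds2 <- attach_community_covariates(ds)
  frameA <- build_design(ds2, g, specA)
  expect_setequal(names(frameA$blocks), c("fixed", "sm_prop_cut"))

  # intercept-only model is a single constant column
  frame0 <- build_design(ds, g, model_spec())
  expect_equal(ncol(frame0$blocks$fixed$X), 1)
  expect_true(all(frame0$blocks$fixed$X == 1))

  # block dimensions follow levels and knots
  spec <- model_spec(linear = c("education", "urban"),
                     smooth = list(age_girl = list(n_inner_knots = 4,
                                                   degree = 3)),
                     spatial = TRUE, unstructured = TRUE)
  frame <- build_design(ds, g, spec)
  # intercept + (3-1) education dummies + urban
  expect_equal(ncol(frame$blocks$fixed$X), 1 + 2 + 1)
  expect_equal(ncol(frame$blocks$sm_age_girl$X), 4 + 3 + 1)
  expect_equal(ncol(frame$blocks[["str"]]$X), 3)
  expect_equal(frame$blocks[["str"]]$rank, 2)
  expect_error(build_design(ds, g, model_spec(linear = "no_such")),
               "unknown covariate")
})

test_that("the assembled predictor is the sum of block contributions", {
  ds <- tiny_dataset(10)
  g <- path3_graph()
  spec <- model_spec(linear = "mother_cut",
                     smooth = list(age_girl = list(n_inner_knots = 2,
                                                   degree = 2)),
                     spatial = TRUE, unstructured = TRUE)
  frame <- build_design(ds, g, spec)

  # beta0 = c alone gives constant eta
  params <- lapply(frame$blocks, function(b) numeric(ncol(b$X)))
  params$fixed[1] <- 1.7
  expect_equal(assemble_predictor(frame, params), rep(1.7, frame$n))

  # random state: equals per-block sums computed independently
  set.seed(6)
  params <- lapply(frame$blocks, function(b) rnorm(ncol(b$X)))
  eta <- assemble_predictor(frame, params)
  manual <- Reduce(`+`, lapply(names(frame$blocks), function(b)
    as.numeric(frame$blocks[[b]]$X %*% params[[b]])))
  expect_equal(eta, manual, tolerance = 1e-12)

  params$fixed <- params$fixed[-1]
  expect_error(assemble_predictor(frame, params), "dimension mismatch")
})

test_that("the log posterior matches a term-by-term oracle", {
  set.seed(13)
  ds <- tiny_dataset(7)
  g <- path3_graph()
  spec <- model_spec(linear = "mother_cut", spatial = TRUE,
                     unstructured = TRUE)
  frame <- build_design(ds, g, spec)
  params <- lapply(frame$blocks, function(b) rnorm(ncol(b$X), sd = 0.5))
  tau2 <- c(str = 0.7, unstr = 1.2)

  lp <- log_posterior(frame, params, tau2)

  eta <- assemble_predictor(frame, params)
  p <- plogis(eta)
  oracle <- sum(frame$y * log(p) + (1 - frame$y) * log(1 - p))
  oracle <- oracle - sum(params$fixed^2) / (2 * 1e4)
  Q <- mrf_precision(g)
  oracle <- oracle - 2 / 2 * log(tau2["str"]) -
    as.numeric(params$str %*% Q %*% params$str) / (2 * tau2["str"])
  oracle <- oracle - 3 / 2 * log(tau2["unstr"]) -
    sum(params$unstr^2) / (2 * tau2["unstr"])
  for (b in c("str", "unstr"))
    oracle <- oracle - 2 * log(tau2[[b]]) - 5e-4 / tau2[[b]]
  expect_equal(lp, unname(oracle), tolerance = 1e-8)

  # duplicating every record doubles the likelihood part exactly
  ds2 <- ds
  ds2$records <- rbind(ds$records, transform(ds$records,
                                             girl_id = paste0(girl_id, "b")))
  frame2 <- build_design(ds2, g, spec)
  lp2 <- log_posterior(frame2, params, tau2)
  loglik <- sum(frame$y * eta - log1p(exp(eta)))
  expect_equal(lp2 - lp, unname(loglik), tolerance = 1e-8)

  expect_error(log_posterior(frame, params, c(str = 0, unstr = 1)),
               "positive")
})

test_that("variance updates follow the conjugate inverse-gamma form", {
  K <- rw_penalty(6, 2)$K
  # zero coefficients: IG(a + rank/2, b); check the closed-form mean
  set.seed(31)
  draws <- replicate(4000, update_variance(numeric(6), K, 4, a = 3,
                                           b = 2))
  expect_equal(mean(draws), 2 / (3 + 2 - 1), tolerance = 0.05)
  # scaling coefficients by 2 quadruples the quadratic-form increment
  beta <- rnorm(6)
  q1 <- as.numeric(beta %*% K %*% beta)
  q2 <- as.numeric((2 * beta) %*% K %*% (2 * beta))
  expect_equal(q2, 4 * q1, tolerance = 1e-12)
  # fixed seed reproduces the draw
  set.seed(5); d1 <- update_variance(beta, K, 4)
  set.seed(5); d2 <- update_variance(beta, K, 4)
  expect_identical(d1, d2)
  expect_error(update_variance(beta, K, 4, a = -1), "positive")
})

test_that("the sampler is deterministic under a fixed seed", {
  ds <- tiny_dataset(15)
  g <- path3_graph()
  frame <- build_design(ds, g, model_spec(linear = "mother_cut",
                                          spatial = TRUE))
  cfg <- mcmc_config(300, 100, 2, seed = 42)
  s1 <- suppressWarnings(run_mcmc(frame, cfg))
  s2 <- suppressWarnings(run_mcmc(frame, cfg))
  expect_identical(s1$draws, s2$draws)
  expect_identical(s1$tau2, s2$tau2)
})

test_that("every stored draw satisfies the sum-to-zero constraints", {
  sim <- simulate_survey(small_config(seed = 2))
  spec <- model_spec(linear = "mother_cut",
                     smooth = list(age_girl = list(n_inner_knots = 3,
                                                   degree = 2)),
                     spatial = TRUE, unstructured = TRUE)
  frame <- build_design(sim$dataset, kenya_region_graph(), spec)
  s <- run_mcmc(frame, mcmc_config(400, 200, 1, seed = 8))
  for (b in c("str", "unstr", "sm_age_girl")) {
    expect_lt(max(abs(rowSums(s$draws[[b]]))), 1e-8)
  }
})

test_that("tensor draws satisfy both margin constraints", {
  sim <- simulate_survey(small_config(seed = 4,
                                      years = c(2006L, 2010L, 2014L)))
  spec <- model_spec(linear = "mother_cut", spatial = TRUE,
                     unstructured = TRUE, year_smooth = TRUE,
                     interaction = TRUE)
  frame <- build_design(sim$dataset, kenya_region_graph(), spec)
  s <- run_mcmc(frame, mcmc_config(300, 150, 1, seed = 8))
  dims <- frame$blocks[["st"]]$dims
  for (i in c(1, nrow(s$draws$st))) {
    M <- matrix(s$draws$st[i, ], dims[1], dims[2], byrow = TRUE)
    expect_lt(max(abs(rowSums(M))), 1e-8)   # per-region time profile
    expect_lt(max(abs(colSums(M))), 1e-8)   # per-basis spatial profile
  }
})

test_that("posterior matches quadrature for an intercept-only model", {
  df <- tiny_records(10)
  df$y <- rep(c(1L, 0L), each = 5)
  ds <- as_survey_dataset(df)
  frame <- build_design(ds, path3_graph(), model_spec())
  s <- run_mcmc(frame, mcmc_config(4200, 200, 1, seed = 14))
  chain_b <- s$draws$fixed[, 1]
  chain_p <- plogis(chain_b)
  oracle <- quad_intercept_posterior(ds$records$y)
  mcse <- sd(chain_p) / sqrt(mcmc_ess(chain_p))
  expect_lt(abs(mean(chain_p) - oracle$mean_p), 3 * mcse)
  mcse_b <- sd(chain_b) / sqrt(mcmc_ess(chain_b))
  expect_lt(abs(mean(chain_b) - oracle$mean_b), 3 * mcse_b)
})

test_that("a strong covariate effect is recovered against quadrature", {
  set.seed(77)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  eta <- -0.5 + 2 * x
  df <- tiny_records(n)
  df$mother_cut <- x
  df$y <- rbinom(n, 1, plogis(eta))
  ds <- as_survey_dataset(df)
  frame <- build_design(ds, path3_graph(),
                        model_spec(linear = "mother_cut"))
  s <- run_mcmc(frame, mcmc_config(4200, 200, 1, seed = 15))
  chain <- s$draws$fixed[, "mother_cut"]
  oracle <- quad_logistic2_posterior(x, df$y)
  mcse <- sd(chain) / sqrt(mcmc_ess(chain))
  expect_lt(abs(mean(chain) - oracle$mean_b1), 3 * mcse)
  q <- quantile(chain, c(0.025, 0.975), names = FALSE)
  expect_lt(abs(q[1] - oracle$q_b1[1]), 0.15)
  expect_lt(abs(q[2] - oracle$q_b1[2]), 0.15)
  # the 95% interval covers the generating value
  expect_true(q[1] < 2 && 2 < q[2])
})

test_that("region relabeling leaves the posterior invariant", {
  # swap two automorphic regions of the rook lattice carrying
  # identical data; posterior summaries must agree within MC error
  g <- rook4_graph()
  base <- do.call(rbind, lapply(paste0("r", 1:4), function(r) {
    d <- tiny_records(12, region = r, cluster = paste0(r, "_c1"))
    d$girl_id <- paste0(d$girl_id, r); d
  }))
  base$y <- rep(rep(c(1L, 0L, 0L), each = 4), 4)
  ds <- as_survey_dataset(base)
  swapped <- base
  swapped$region_id[base$region_id == "r2"] <- "r3"
  swapped$region_id[base$region_id == "r3"] <- "r2"
  ds_sw <- as_survey_dataset(swapped)
  spec <- model_spec(spatial = TRUE, unstructured = TRUE)
  cfg <- mcmc_config(3000, 500, 1, seed = 20)
  f1 <- build_design(ds, g, spec)
  f2 <- build_design(ds_sw, g, spec)
  m1 <- colMeans(run_mcmc(f1, cfg)$draws$str)
  m2 <- colMeans(run_mcmc(f2, cfg)$draws$str)
  expect_equal(unname(m1[c("r1", "r2", "r3", "r4")]),
               unname(m2[c("r1", "r3", "r2", "r4")]), tolerance = 0.1)
})

test_that("degenerate responses and bad configs are rejected", {
  df <- tiny_records(6); df$y <- 1L
  ds <- as_survey_dataset(df)
  frame <- build_design(ds, path3_graph(), model_spec())
  expect_error(run_mcmc(frame, mcmc_config(200, 50, 1, seed = 1)),
               "degenerate")
  expect_error(mcmc_config(100, 200, 1), "exceed")
  expect_error(mcmc_config(100, 50, 0), "thin")
  expect_warning(mcmc_config(140, 50, 2), "only")
})

test_that("persisted draws reload identically", {
  sim <- simulate_survey(small_config(seed = 12))
  frame <- build_design(sim$dataset, kenya_region_graph(),
                        model_spec(linear = "mother_cut", spatial = TRUE,
                                   unstructured = TRUE))
  s <- run_mcmc(frame, mcmc_config(250, 100, 1, seed = 2))
  dir <- withr::local_tempdir()
  write_samples(s, dir)
  s2 <- read_samples(dir)
  expect_equal(s2$draws, s$draws, tolerance = 1e-12)
  expect_equal(unname(s2$tau2), unname(s$tau2), tolerance = 1e-12)
})
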