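# Independent oracles and tiny fixtures shared across tests.

# Textbook de Boor recursion, written independently of the package's
# basis construction (which delegates to splines::splineDesign).
deboor_basis <- function(x, knots, degree) {
  n_basis <- length(knots) - degree - 1L
  B <- matrix(0, length(x), n_basis)
  for (i in seq_along(x)) {
    # degree-0 indicators over half-open intervals
    b <- as.numeric(x[i] >= knots[-length(knots)] & x[i] < knots[-1L])
    for (d in seq_len(degree)) {
      nb <- length(b) - 1L
      bn <- numeric(nb)
      for (k in seq_len(nb)) {
        den1 <- knots[k + d] - knots[k]
        den2 <- knots[k + d + 1L] - knots[k + 1L]
        t1 <- if (den1 > 0) (x[i] - knots[k]) / den1 * b[k] else 0
        t2 <- if (den2 > 0) (knots[k + d + 1L] - x[i]) / den2 * b[k + 1L]
              else 0
        bn[k] <- t1 + t2
      }
      b <- bn
    }
    B[i, ] <- b[seq_len(n_basis)]
  }
  B
}

# 1-D quadrature posterior for an intercept-only Bernoulli-logit model
# with a N(0, prior_var) prior: returns moments and quantiles of p.
quad_intercept_posterior <- function(y, prior_var = 1e4) {
  n1 <- sum(y); n0 <- length(y) - n1
  logpost <- function(b) n1 * b - length(y) * log1p(exp(b)) -
    b^2 / (2 * prior_var)
  b <- seq(-8, 8, length.out = 20001)
  lp <- logpost(b); w <- exp(lp - max(lp)); w <- w / sum(w)
  p <- plogis(b)
  cdf <- cumsum(w)
  list(mean_b = sum(w * b), mean_p = sum(w * p),
       q_b = c(b[which.min(abs(cdf - 0.025))],
               b[which.min(abs(cdf - 0.975))]))
}

# 2-D grid-quadrature posterior for intercept + one covariate.
quad_logistic2_posterior <- function(x, y, prior_var = 1e4,
                                     lim = c(-6, 6), ngrid = 401) {
  b0 <- seq(lim[1], lim[2], length.out = ngrid)
  b1 <- seq(lim[1], lim[2], length.out = ngrid)
  ll0 <- outer(b0, rep(1, ngrid))
  ll1 <- outer(rep(1, ngrid), b1)
  lp <- matrix(0, ngrid, ngrid)
  for (i in seq_along(y)) {
    eta <- ll0 + ll1 * x[i]
    lp <- lp + y[i] * eta - log1p(exp(eta))
  }
  lp <- lp - (ll0^2 + ll1^2) / (2 * prior_var)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  mean_b0 <- sum(rowSums(w) * b0)
  mean_b1 <- sum(colSums(w) * b1)
  marg1 <- colSums(w)
  cdf1 <- cumsum(marg1)
  list(mean_b0 = mean_b0, mean_b1 = mean_b1,
       q_b1 = c(b1[which.min(abs(cdf1 - 0.025))],
                b1[which.min(abs(cdf1 - 0.975))]))
}

# small path graph A - B - C
path3_graph <- function() {
  region_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
}

# 2x2 rook lattice: r1 r2 / r3 r4
rook4_graph <- function() {
  region_graph(paste0("r", 1:4),
               rbind(c("r1", "r2"), c("r1", "r3"),
                     c("r2", "r4"), c("r3", "r4")))
}

# minimal valid girl-record data.frame (single cluster/region unless
# overridden); deterministic, no RNG
tiny_records <- function(n = 10, region = "A", cluster = "A_c1",
                         year = 2014L) {
  data.frame(
    girl_id = sprintf("g%03d_%s_%d", seq_len(n), region, year),
    mother_id = sprintf("m%03d_%s_%d", seq_len(n), region, year),
    cluster_id = cluster, region_id = region, survey_year = year,
    y = rep(c(0L, 1L), length.out = n),
    age_girl = rep(0:14, length.out = n),
    age_mother = rep(c(20L, 30L, 40L), length.out = n),
    mother_cut = rep(c(0L, 1L), length.out = n),
    mother_supports_continuation = rep(c(0L, 1L, 0L), length.out = n),
    mother_believes_religious_obligation = rep(c(1L, 0L), length.out = n),
    ethnicity = rep(c("e1", "e2"), length.out = n),
    religion = rep(c("christian", "muslim"), length.out = n),
    education = rep(c("none", "primary", "secondary"), length.out = n),
    wealth_quintile = rep(c("lowest", "middle", "highest"),
                          length.out = n),
    urban = rep(c(0L, 1L), length.out = n),
    weight = seq(0.5, 1.5, length.out = n),
    stringsAsFactors = FALSE)
}

# a two-region dataset spanning the tiny graphs
tiny_dataset <- function(n_per_region = 12, regions = c("A", "B", "C"),
                         year = 2014L) {
  df <- do.call(rbind, lapply(regions, function(r)
    tiny_records(n_per_region, region = r,
                 cluster = paste0(r, "_c1"), year = year)))
  as_survey_dataset(df)
}

# reduced-size generator for fast replicate fits
small_config <- function(seed, years = 2014L, ...) {
  generator_config(n_clusters_per_region = 4L, n_mothers_per_cluster = 10L,
                   years = years, seed = seed, ...)
}
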