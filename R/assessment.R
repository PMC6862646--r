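# Model assessment: DIC/pD, MCMC effective sample size, posterior odds
# ratios, significance classification of regions, predicted prevalence.

# per-stored-draw linear predictor matrix (n_store x n), reassembled
# from the block draws and design matrices
.eta_draws <- function(samples, frame) {
  eta <- matrix(0, samples$n_store, frame$n)
  for (b in names(frame$blocks))
    eta <- eta + samples$draws[[b]] %*% t(frame$blocks[[b]]$X)
  eta
}

.bernoulli_deviance <- function(y, eta) {
  -2 * sum(y * eta - log1p(exp(eta)))
}

#' Deviance information criterion
#'
#' D(theta) = -2 log L; dbar is the posterior mean deviance, and pD =
#' dbar - D(thetabar) uses the plug-in at the posterior mean of the
#' linear predictor eta (well-defined under the sum-to-zero
#' constraints); DIC = dbar + pD.  Smaller is better.  A negative pD is
#' reported with a warning, never clipped.
#'
#' @param samples a `posterior_samples`.
#' @param frame the matching model frame.
#' @return list with `dic`, `pd`, `dbar`.
#' @export
compute_dic <- function(samples, frame) {
  stopifnot(inherits(samples, "posterior_samples"),
            inherits(frame, "model_frame"))
  if (samples$n_store < 2L) stop("need at least 2 stored draws")
  eta <- .eta_draws(samples, frame)
  dev <- apply(eta, 1L, function(e) .bernoulli_deviance(frame$y, e))
  if (any(!is.finite(dev))) stop("non-finite deviance encountered")
  dbar <- mean(dev)
  dhat <- .bernoulli_deviance(frame$y, colMeans(eta))
  pd <- dbar - dhat
  if (pd < 0) warning("negative pD (", format(pd), ")")
  list(dic = dbar + pd, pd = pd, dbar = dbar)
}

#' Effective sample size of an MCMC chain
#'
#' ESS = N / (1 + 2 sum_k rho_k), with the autocorrelations summed
#' under Geyer's initial positive sequence rule: consecutive lag pairs
#' Gamma_m = rho_(2m) + rho_(2m+1) are accumulated while positive.
#'
#' @param chain numeric vector of draws (length >= 50, non-constant).
#' @return effective sample size.
#' @export
mcmc_ess <- function(chain) {
  n <- length(chain)
  if (n < 50L) stop("chain too short (need >= 50)")
  if (var(chain) == 0) stop("constant chain; ESS undefined")
  rho <- as.numeric(acf(chain, lag.max = n - 1L, plot = FALSE,
                        demean = TRUE)$acf)
  m_max <- floor((length(rho) - 1L) / 2L)
  s <- 0
  for (m in 0:m_max) {
    g <- rho[2L * m + 1L] + if (2L * m + 2L <= length(rho))
      rho[2L * m + 2L] else 0
    if (g <= 0) break
    s <- s + g
  }
  n / max(2 * s - 1, 1e-12)
}

#' Per-block effective sample sizes of a fit
#'
#' @param samples a `posterior_samples`.
#' @return named numeric vector: mean ESS over the coefficients of each
#'   block (plus the variance parameters).
#' @export
ess_summary <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  safe_ess <- function(x) tryCatch(mcmc_ess(x), error = function(e) NA_real_)
  out <- vapply(samples$draws, function(d)
    mean(apply(d, 2L, safe_ess), na.rm = TRUE), numeric(1))
  if (!is.null(samples$tau2) && ncol(samples$tau2) > 0)
    out <- c(out, tau2 = mean(apply(samples$tau2, 2L, safe_ess),
                              na.rm = TRUE))
  out
}

#' Posterior odds-ratio table for the linear coefficients
#'
#' Per coefficient of the fixed block (the intercept excluded): POR =
#' posterior mean of exp(beta) with the empirical 2.5% and 97.5%
#' quantiles of exp(beta) as the credible interval.
#'
#' @param samples a `posterior_samples`.
#' @param level credibility level (default 0.95).
#' @return data.frame with `term`, `por`, `lower`, `upper`.
#' @export
posterior_odds_ratios <- function(samples, level = 0.95) {
  stopifnot(inherits(samples, "posterior_samples"))
  d <- samples$draws$fixed
  if (is.null(d)) stop("no fixed-effect block in samples")
  terms <- setdiff(colnames(d), "(Intercept)")
  if (length(terms) == 0L) stop("linear block is empty")
  alpha <- (1 - level) / 2
  rows <- lapply(terms, function(tm) {
    ed <- exp(d[, tm])
    q <- quantile(ed, c(alpha, 1 - alpha), names = FALSE, type = 7)
    data.frame(term = tm, por = mean(ed), lower = q[1], upper = q[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify regional spatial effects by credible interval
#'
#' A region is `HIGH` when the lower quantile of its spatial effect is
#' above zero, `LOW` when the upper quantile is below zero, `NONSIG`
#' otherwise; the default effect is the total (structured +
#' unstructured), with a structured-only variant by flag.
#'
#' @param samples a `posterior_samples` with spatial draws.
#' @param level credibility level in (0, 1), default 0.95.
#' @param which `"total"` or `"structured"`.
#' @return data.frame with `region`, `mean`, `lower`, `upper`, `class`.
#' @export
classify_regions <- function(samples, level = 0.95,
                             which = c("total", "structured")) {
  stopifnot(inherits(samples, "posterior_samples"))
  which <- match.arg(which)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  str <- samples$draws$str
  if (is.null(str)) stop("no structured spatial block in samples")
  eff <- str
  if (which == "total" && !is.null(samples$draws$unstr))
    eff <- eff + samples$draws$unstr
  alpha <- (1 - level) / 2
  q <- apply(eff, 2L, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  cls <- ifelse(q[1L, ] > 0, "HIGH", ifelse(q[2L, ] < 0, "LOW", "NONSIG"))
  data.frame(region = colnames(eff), mean = colMeans(eff),
             lower = q[1L, ], upper = q[2L, ], class = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Build the per-block design row(s) for new data from the stored frame
# bookkeeping; used by prediction.
.predict_design_row <- function(frame, region, year = NULL,
                                profile = NULL) {
  spec <- frame$spec
  if (!(region %in% frame$region_ids)) stop("unknown region: ", region)
  if (is.null(profile)) profile <- frame$profile
  rows <- list()
  x <- 1
  names(x) <- "(Intercept)"
  for (v in names(spec$linear)) {
    info <- frame$linear_info[[v]]
    val <- profile[[v]]
    if (is.null(val)) stop("profile lacks covariate ", v)
    if (info$type == "numeric") {
      x <- c(x, setNames(as.numeric(val), v))
    } else {
      others <- setdiff(info$levels, info$ref)
      x <- c(x, setNames(as.numeric(others == val),
                         paste(v, others, sep = ":")))
    }
  }
  rows$fixed <- x
  for (v in names(spec$smooth)) {
    b <- frame$blocks[[paste0("sm_", v)]]$basis
    val <- profile[[v]]
    if (is.null(val)) stop("profile lacks covariate ", v)
    rows[[paste0("sm_", v)]] <- as.numeric(eval_basis(b, val))
  }
  if (!is.null(frame$blocks[["year"]])) {
    if (is.null(year)) stop("year required for a model with a time term")
    rows$year <- as.numeric(eval_basis(frame$blocks[["year"]]$basis, year))
  }
  z <- as.numeric(frame$region_ids == region)
  if (!is.null(frame$blocks[["str"]])) rows$str <- z
  if (!is.null(frame$blocks[["unstr"]])) rows$unstr <- z
  if (!is.null(frame$blocks[["st"]])) {
    if (is.null(year)) stop("year required for a model with a time term")
    bt <- as.numeric(eval_basis(frame$blocks[["st"]]$basis, year))
    rows$st <- as.numeric(tensor_basis(matrix(z, 1), matrix(bt, 1))$design)
  }
  rows
}

#' Posterior predicted prevalence for a region/year/profile
#'
#' Assembles the linear predictor of the given covariate profile per
#' stored draw, inverts the logit, and summarizes the prevalence draws.
#' Years outside the fitted spline span are clamped with a warning.
#'
#' @param samples a `posterior_samples`.
#' @param frame the matching model frame.
#' @param region region label.
#' @param year survey year (needed when the model has time terms).
#' @param profile optional named list of covariate values; defaults to
#'   the frame's reference profile (sample means / modes).
#' @param level credibility level for the interval.
#' @return list with `mean`, `lower`, `upper`, and the vector `draws`.
#' @export
predict_prevalence <- function(samples, frame, region, year = NULL,
                               profile = NULL, level = 0.95) {
  stopifnot(inherits(samples, "posterior_samples"),
            inherits(frame, "model_frame"))
  rows <- .predict_design_row(frame, region, year, profile)
  eta <- numeric(samples$n_store)
  for (b in names(rows))
    eta <- eta + as.numeric(samples$draws[[b]] %*% rows[[b]])
  p <- plogis(eta)
  alpha <- (1 - level) / 2
  q <- quantile(p, c(alpha, 1 - alpha), names = FALSE)
  list(mean = mean(p), lower = q[1], upper = q[2], draws = p)
}

#' Summarize a fitted model
#'
#' Bundles DIC/pD, per-block ESS, the posterior odds-ratio table,
#' regional significance classes, and a predicted prevalence grid over
#' regions (x years, when the model has time terms).
#'
#' @param samples a `posterior_samples`.
#' @param frame the matching model frame.
#' @param level credibility level (default 0.95).
#' @param which effect used for region classification (see
#'   [classify_regions()]).
#' @return a `fit_summary`.
#' @export
fit_summary <- function(samples, frame, level = 0.95, which = "total") {
  dic <- compute_dic(samples, frame)
  ess <- ess_summary(samples)
  por <- tryCatch(posterior_odds_ratios(samples, level),
                  error = function(e) NULL)
  cls <- tryCatch(classify_regions(samples, level, which),
                  error = function(e) NULL)
  has_time <- !is.null(frame$blocks[["year"]]) || !is.null(frame$blocks[["st"]])
  years <- if (has_time) sort(unique(frame$year)) else NA_integer_
  prev <- NULL
  if (!is.null(frame$blocks[["str"]]) || !is.null(frame$blocks[["unstr"]])) {
    grid <- expand.grid(region = frame$region_ids, year = years,
                        stringsAsFactors = FALSE)
    prev <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      yr <- if (has_time) grid$year[i] else NULL
      pp <- predict_prevalence(samples, frame, grid$region[i], yr,
                               level = level)
      data.frame(region = grid$region[i], year = grid$year[i],
                 prevalence = pp$mean, lower = pp$lower, upper = pp$upper)
    }))
  }
  structure(list(dic = dic$dic, pd = dic$pd, dbar = dic$dbar, ess = ess,
                 por_table = por, region_class = cls, prevalence = prev,
                 level = level, n = frame$n),
            class = "fit_summary")
}

#' @export
print.fit_summary <- function(x, digits = 3, ...) {
  cat(sprintf("fit_summary (n = %d): DIC = %.1f, pD = %.1f\n",
              x$n, x$dic, x$pd))
  if (!is.null(x$por_table)) {
    cat("posterior odds ratios:\n")
    print(format(x$por_table, digits = digits), row.names = FALSE)
  }
  if (!is.null(x$region_class)) {
    cat("region classification (", x$level * 100, "% level):\n", sep = "")
    print(format(x$region_class, digits = digits), row.names = FALSE)
  }
  invisible(x)
}
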