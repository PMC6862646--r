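# Model specification and design-matrix assembly for the structured
# additive predictor.

.default_spline <- function() list(n_inner_knots = 20L, degree = 3L,
                                   order = 2L)
.default_year_spline <- function() list(n_inner_knots = 2L, degree = 1L,
                                        order = 1L)

#' Specify a geo-additive logistic model
#'
#' Defines the term structure of the structured additive predictor
#' eta = beta0 + z'beta + sum_j f_j(x_j) + f_y(year) + f_str(s) +
#' f_unstr(s) + f_st(s, t): which covariates enter linearly (with
#' reference levels for factors), which get P-spline smooths, whether
#' structured/unstructured spatial effects and the space-time tensor
#' interaction are included, and the inverse-gamma hyperparameters of
#' all variance parameters.
#'
#' @param linear character vector of linear covariates, or a named list
#'   mapping a covariate to its reference level (factors only).
#' @param smooth character vector of smooth covariates, or a named list
#'   mapping a covariate to a spline config
#'   `list(n_inner_knots, degree, order)` (defaults: 20 cubic inner
#'   knots, second-order random-walk penalty).
#' @param spatial logical; include the ICAR structured effect.
#' @param unstructured logical; include the iid region effect.
#' @param year_smooth logical; include a P-spline in survey year.
#' @param interaction logical; include the region x time tensor
#'   interaction.
#' @param year_config spline config for the time margin (shared by the
#'   year smooth and the interaction); default degree-1 basis with two
#'   inner knots and a first-order penalty, suited to a handful of
#'   survey waves.
#' @param hyper_a,hyper_b inverse-gamma hyperparameters of every
#'   variance parameter (defaults 1 and 0.0005).
#' @param fixed_prior_var prior variance of intercept and linear
#'   coefficients (diffuse Gaussian; default 1e4).
#' @return an `fgm_model_spec`.
#' @export
model_spec <- function(linear = character(), smooth = character(),
                       spatial = FALSE, unstructured = spatial,
                       year_smooth = FALSE, interaction = FALSE,
                       year_config = .default_year_spline(),
                       hyper_a = 1, hyper_b = 0.0005,
                       fixed_prior_var = 1e4) {
  if (is.character(linear))
    linear <- setNames(vector("list", length(linear)), linear)
  if (is.character(smooth)) {
    smooth <- setNames(rep(list(list()), length(smooth)), smooth)
  }
  smooth <- lapply(smooth, function(cfg) {
    utils::modifyList(.default_spline(), as.list(cfg))
  })
  year_config <- utils::modifyList(.default_year_spline(),
                                   as.list(year_config))
  both <- intersect(names(linear), names(smooth))
  if (length(both)) stop("covariate(s) in both linear and smooth blocks: ",
                         paste(both, collapse = ", "))
  if (hyper_a <= 0 || hyper_b <= 0) stop("hyperparameters must be positive")
  structure(list(linear = linear, smooth = smooth, spatial = spatial,
                 unstructured = unstructured, year_smooth = year_smooth,
                 interaction = interaction, year_config = year_config,
                 hyper_a = hyper_a, hyper_b = hyper_b,
                 fixed_prior_var = fixed_prior_var),
            class = "fgm_model_spec")
}

#' @export
print.fgm_model_spec <- function(x, ...) {
  cat("fgm_model_spec\n")
  cat("  linear:", if (length(x$linear)) paste(names(x$linear),
      collapse = ", ") else "(intercept only)", "\n")
  cat("  smooth:", if (length(x$smooth)) paste(names(x$smooth),
      collapse = ", ") else "none", "\n")
  cat("  spatial:", x$spatial, " unstructured:", x$unstructured,
      " year smooth:", x$year_smooth, " interaction:", x$interaction, "\n")
  invisible(x)
}

# Dummy-code one linear covariate against its reference level.
.linear_columns <- function(x, name, ref = NULL) {
  if (is.numeric(x) && is.null(ref)) {
    m <- matrix(x, ncol = 1, dimnames = list(NULL, name))
    return(list(X = m, info = list(type = "numeric", center = mean(x))))
  }
  x <- as.character(x)
  levels <- sort(unique(x))
  if (name == "education") levels <- intersect(.education_levels, levels)
  if (name == "wealth_quintile") levels <- intersect(.wealth_levels, levels)
  if (is.null(ref)) ref <- levels[1L]
  if (!(ref %in% levels)) stop("reference level '", ref,
                               "' absent from ", name)
  others <- setdiff(levels, ref)
  X <- vapply(others, function(l) as.numeric(x == l),
              numeric(length(x)))
  X <- matrix(X, ncol = length(others),
              dimnames = list(NULL, paste(name, others, sep = ":")))
  list(X = X, info = list(type = "factor", levels = levels, ref = ref))
}

#' Build the design blocks of a geo-additive model
#'
#' Expands a dataset into the response and per-term design blocks:
#' intercept + dummy-coded linear covariates (diffuse Gaussian prior),
#' P-spline design and random-walk penalty per smooth term, a year
#' spline, region incidence blocks with ICAR / iid priors, and the
#' tensor-product interaction block (Kronecker-sum penalty, both
#' margins constrained to sum to zero).  Records with missing values in
#' any used covariate are dropped (complete case) with the count
#' reported.
#'
#' @param ds a `survey_dataset` (community covariates already attached
#'   if the spec smooths them).
#' @param graph a [region_graph()].
#' @param spec an [model_spec()].
#' @return a `model_frame`: list with `y`, `weights`, `blocks` (each
#'   with design `X`, prior precision `K`, its `rank`, constraint
#'   matrix `A`, variance-update flag), `region`, `year`, bookkeeping
#'   maps for prediction, and `n_dropped`.
#' @export
build_design <- function(ds, graph, spec) {
  stopifnot(inherits(ds, "survey_dataset"), inherits(graph, "region_graph"),
            inherits(spec, "fgm_model_spec"))
  df <- ds$records
  used <- c(names(spec$linear), names(spec$smooth))
  missing_cols <- setdiff(used, names(df))
  if (length(missing_cols)) stop("unknown covariate(s): ",
                                 paste(missing_cols, collapse = ", "))
  unknown_regions <- setdiff(unique(as.character(df$region_id)),
                             graph$region_ids)
  if (length(unknown_regions)) stop("region(s) not in graph: ",
                                    paste(unknown_regions, collapse = ", "))
  keep <- rep(TRUE, nrow(df))
  for (v in used) keep <- keep & !is.na(df[[v]])
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message(n_dropped, " record(s) dropped (missing values in used ",
            "covariates)")
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("all records dropped")

  blocks <- list()
  info <- list()

  # fixed block: intercept + linear terms, diffuse Gaussian prior
  X <- matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  for (v in names(spec$linear)) {
    lc <- .linear_columns(df[[v]], v, spec$linear[[v]])
    X <- cbind(X, lc$X)
    info[[v]] <- lc$info
  }
  p <- ncol(X)
  blocks$fixed <- list(X = X, K = diag(p) / spec$fixed_prior_var,
                       rank = p, A = NULL, update_tau = FALSE,
                       type = "fixed")

  for (v in names(spec$smooth)) {
    cfg <- spec$smooth[[v]]
    basis <- bspline_basis(df[[v]], cfg$n_inner_knots, cfg$degree)
    pen <- rw_penalty(basis$n_basis, cfg$order)
    blocks[[paste0("sm_", v)]] <-
      list(X = basis$design, K = pen$K, rank = pen$rank,
           A = matrix(1, 1, basis$n_basis), update_tau = TRUE,
           type = "smooth", var = v, basis = basis)
  }

  year_basis <- NULL
  if (spec$year_smooth || spec$interaction) {
    yrs <- sort(unique(df$survey_year))
    if (length(yrs) < 2L)
      stop("year smooth / interaction needs at least two survey years")
    cfg <- spec$year_config
    year_basis <- bspline_basis(df$survey_year, cfg$n_inner_knots,
                                cfg$degree)
  }
  if (spec$year_smooth) {
    cfg <- spec$year_config
    pen <- rw_penalty(year_basis$n_basis, cfg$order)
    blocks$year <- list(X = year_basis$design, K = pen$K, rank = pen$rank,
                        A = matrix(1, 1, year_basis$n_basis),
                        update_tau = TRUE, type = "year",
                        basis = year_basis)
  }

  S <- length(graph$region_ids)
  Z <- NULL
  if (spec$spatial || spec$unstructured || spec$interaction) {
    Z <- vapply(graph$region_ids,
                function(s) as.numeric(as.character(df$region_id) == s),
                numeric(nrow(df)))
    Z <- matrix(Z, ncol = S, dimnames = list(NULL, graph$region_ids))
  }
  if (spec$spatial) {
    Q <- mrf_precision(graph)
    blocks$str <- list(X = Z, K = Q, rank = S - .n_components(graph),
                       A = matrix(1, 1, S), update_tau = TRUE,
                       type = "str")
  }
  if (spec$unstructured) {
    blocks$unstr <- list(X = Z, K = diag(S), rank = S,
                         A = matrix(1, 1, S), update_tau = TRUE,
                         type = "unstr")
  }
  if (spec$interaction) {
    cfg <- spec$year_config
    Q <- mrf_precision(graph)
    Kt <- rw_penalty(year_basis$n_basis, cfg$order)$K
    tb <- tensor_basis(Z, year_basis$design)
    Kst <- .tensor_penalty(Q, Kt)
    # both margin sums constrained to zero; one redundant row dropped
    A <- rbind(kronecker(matrix(1, 1, S), diag(year_basis$n_basis)),
               kronecker(diag(S), matrix(1, 1, year_basis$n_basis)))
    A <- A[-nrow(A), , drop = FALSE]
    blocks$st <- list(X = tb$design, K = Kst, rank = qr(Kst)$rank,
                      A = A, update_tau = TRUE, type = "st",
                      dims = tb$dims, basis = year_basis)
  }

  # reference covariate profile for prevalence prediction (mean / mode)
  profile <- list()
  for (v in names(spec$linear)) {
    profile[[v]] <- if (info[[v]]$type == "numeric") mean(df[[v]]) else
      names(sort(table(df[[v]]), decreasing = TRUE))[1L]
  }
  for (v in names(spec$smooth)) profile[[v]] <- mean(df[[v]])

  structure(list(y = as.numeric(df$y), weights = df$weight,
                 blocks = blocks, n = nrow(df), n_dropped = n_dropped,
                 region = as.character(df$region_id),
                 year = df$survey_year,
                 region_ids = graph$region_ids,
                 linear_info = info, profile = profile,
                 spec = spec),
            class = "model_frame")
}

#' @export
print.model_frame <- function(x, ...) {
  cat("model_frame:", x$n, "records,", length(x$blocks), "blocks (",
      paste(names(x$blocks), collapse = ", "), ")\n")
  invisible(x)
}

#' Assemble the linear predictor for one parameter state
#'
#' eta_i = sum over blocks of X_b beta_b; p_i = 1 / (1 + exp(-eta_i)).
#'
#' @param frame a [build_design()] model frame.
#' @param params named list of coefficient vectors, one per frame
#'   block.
#' @return numeric vector eta of length `frame$n`.
#' @export
assemble_predictor <- function(frame, params) {
  stopifnot(inherits(frame, "model_frame"))
  eta <- numeric(frame$n)
  for (b in names(frame$blocks)) {
    beta <- params[[b]]
    if (is.null(beta)) stop("missing parameter block: ", b)
    if (length(beta) != ncol(frame$blocks[[b]]$X))
      stop("dimension mismatch in block ", b)
    eta <- eta + as.numeric(frame$blocks[[b]]$X %*% beta)
  }
  eta
}

#' Unnormalized log posterior of a parameter state
#'
#' Bernoulli-logit log likelihood plus the Gaussian log priors of every
#' block (intrinsic priors enter through their quadratic forms with the
#' pseudo-determinant convention: rank/2 * log tau^-2) and the
#' inverse-gamma log priors of the variance parameters.  Additive
#' constants independent of all parameters are omitted consistently.
#'
#' @param frame a [build_design()] model frame.
#' @param params named list of coefficient vectors per block.
#' @param tau2 named vector of variances for the penalized blocks.
#' @return scalar log density.
#' @export
log_posterior <- function(frame, params, tau2) {
  stopifnot(inherits(frame, "model_frame"))
  spec <- frame$spec
  eta <- if (frame$n > 0L) assemble_predictor(frame, params) else numeric(0)
  ll <- if (frame$n > 0L)
    sum(frame$y * eta - log1p(exp(eta))) else 0
  lp <- 0
  for (b in names(frame$blocks)) {
    blk <- frame$blocks[[b]]
    beta <- params[[b]]
    if (blk$update_tau) {
      t2 <- tau2[[b]]
      if (is.null(t2) || t2 <= 0) stop("tau2 must be positive for ", b)
      lp <- lp - blk$rank / 2 * log(t2) -
        as.numeric(beta %*% blk$K %*% beta) / (2 * t2)
      # IG(a, b) prior on tau2
      lp <- lp - (spec$hyper_a + 1) * log(t2) - spec$hyper_b / t2
    } else {
      lp <- lp - as.numeric(beta %*% blk$K %*% beta) / 2
    }
  }
  ll + lp
}
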