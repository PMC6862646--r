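# Gibbs sampler with Polya-Gamma augmentation for the Bernoulli-logit
# geo-additive model.

#' MCMC configuration
#'
#' Defaults follow the single-chain regime of 2e4 total draws, 2e3
#' burn-in, and thinning to every 50th sample.
#'
#' @param n_iter total sweeps.
#' @param burn_in initial sweeps discarded.
#' @param thin keep every `thin`-th sweep after burn-in.
#' @param seed integer seed controlling every random draw of the run.
#' @return an `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 20000L, burn_in = 2000L, thin = 50L,
                        seed = 1L) {
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  if (thin < 1L) stop("thin must be >= 1")
  n_store <- floor((n_iter - burn_in) / thin)
  if (n_store < 2L) stop("configuration stores fewer than 2 draws")
  if (n_store < 50L)
    warning("configuration stores only ", n_store, " draws")
  structure(list(n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 n_store = as.integer(n_store)),
            class = "mcmc_config")
}

# Draw from N(P^-1 b, P^-1), optionally conditioned on A x = 0
# ("conditioning by kriging"); exact constraints per draw.
.draw_gaussian <- function(P, b, A = NULL) {
  R <- tryCatch(chol(P), error = function(e) {
    chol(P + diag(1e-8 * max(diag(P)), nrow(P)))
  })
  mu <- backsolve(R, backsolve(R, b, transpose = TRUE))
  x <- mu + backsolve(R, rnorm(nrow(P)))
  if (!is.null(A)) {
    V <- backsolve(R, backsolve(R, t(A), transpose = TRUE))  # P^-1 A'
    W <- A %*% V
    x <- x - V %*% solve(W, A %*% x)
  }
  as.numeric(x)
}

#' Conjugate update of a block variance parameter
#'
#' Draws tau^2 from its inverse-gamma full conditional
#' IG(a + rank(K)/2, b + beta' K beta / 2).
#'
#' @param block_coefs current coefficient vector of the block.
#' @param K penalty/precision structure of the block prior.
#' @param rank rank of `K` (its pseudo-determinant exponent).
#' @param a,b inverse-gamma hyperparameters.
#' @return one sampled tau^2.
#' @export
update_variance <- function(block_coefs, K, rank, a = 1, b = 0.0005) {
  if (a <= 0 || b <= 0) stop("hyperparameters must be positive")
  q <- as.numeric(block_coefs %*% K %*% block_coefs)
  if (q < -1e-8) stop("penalty quadratic form is negative; K not PSD")
  1 / rgamma(1, shape = a + rank / 2, rate = b + max(q, 0) / 2)
}

#' Fit a geo-additive logistic model by Polya-Gamma Gibbs sampling
#'
#' Augments the Bernoulli-logit likelihood with Polya-Gamma latent
#' variables so that every coefficient block has a conditionally
#' Gaussian update; block variances get conjugate inverse-gamma
#' updates.  Identifiability constraints (sum-to-zero for spatial,
#' smooth, year, and both tensor margins) are imposed exactly on every
#' draw by conditioning the Gaussian full conditionals.  A fixed seed
#' yields bit-identical stored draws.
#'
#' @param frame a [build_design()] model frame.
#' @param config an [mcmc_config()].
#' @param init optional named list of starting values (`coefs` per
#'   block, `tau2`); default: all coefficients 0, tau^2 = 0.1.
#' @param verbose print progress every `verbose` sweeps (0 = silent).
#' @return a `posterior_samples`: per-block draw matrices (`n_store` x
#'   p_b), `tau2` draw matrix, and the configuration.
#' @export
run_mcmc <- function(frame, config = mcmc_config(), init = NULL,
                     verbose = 0L) {
  stopifnot(inherits(frame, "model_frame"), inherits(config, "mcmc_config"))
  y <- frame$y
  if (all(y == 0) || all(y == 1))
    stop("response is degenerate (all 0 or all 1)")
  set.seed(config$seed)

  blocks <- frame$blocks
  bn <- names(blocks)
  spec <- frame$spec
  coefs <- lapply(blocks, function(b) numeric(ncol(b$X)))
  tau2 <- setNames(rep(0.1, length(bn)), bn)
  if (!is.null(init)) {
    if (!is.null(init$coefs)) coefs[names(init$coefs)] <- init$coefs
    if (!is.null(init$tau2)) tau2[names(init$tau2)] <- init$tau2
  }
  kappa <- y - 0.5
  eta <- numeric(frame$n)
  for (b in bn) eta <- eta + as.numeric(blocks[[b]]$X %*% coefs[[b]])

  n_store <- config$n_store
  draws <- lapply(blocks, function(b)
    matrix(NA_real_, n_store, ncol(b$X),
           dimnames = list(NULL, colnames(b$X))))
  tau_blocks <- bn[vapply(blocks, `[[`, logical(1), "update_tau")]
  tau2_draws <- matrix(NA_real_, n_store, length(tau_blocks),
                       dimnames = list(NULL, tau_blocks))
  stored <- 0L

  for (it in seq_len(config$n_iter)) {
    omega <- .rpg_devroye(eta)

    for (b in bn) {
      blk <- blocks[[b]]
      eta_rest <- eta - as.numeric(blk$X %*% coefs[[b]])
      Xw <- blk$X * omega
      P <- crossprod(blk$X, Xw)
      P <- P + if (blk$update_tau) blk$K / tau2[[b]] else blk$K
      bvec <- crossprod(blk$X, kappa - omega * eta_rest)
      beta <- .draw_gaussian(P, bvec, blk$A)
      if (any(!is.finite(beta)))
        stop("non-finite update in block '", b, "' at sweep ", it)
      coefs[[b]] <- beta
      eta <- eta_rest + as.numeric(blk$X %*% beta)
    }

    for (b in tau_blocks) {
      blk <- blocks[[b]]
      tau2[[b]] <- update_variance(coefs[[b]], blk$K, blk$rank,
                                   spec$hyper_a, spec$hyper_b)
    }

    if (it > config$burn_in &&
        (it - config$burn_in) %% config$thin == 0L &&
        stored < n_store) {
      stored <- stored + 1L
      for (b in bn) draws[[b]][stored, ] <- coefs[[b]]
      tau2_draws[stored, ] <- tau2[tau_blocks]
    }
    if (verbose > 0L && it %% verbose == 0L)
      cat("sweep", it, "/", config$n_iter, "\n")
  }

  structure(list(draws = draws, tau2 = tau2_draws,
                 n_store = stored, config = config,
                 block_types = vapply(blocks, `[[`, character(1), "type"),
                 region_ids = frame$region_ids),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("posterior_samples:", x$n_store, "stored draws over",
      length(x$draws), "blocks (", paste(names(x$draws), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Persist posterior draws as plain-text tables
#'
#' Writes one CSV per coefficient block plus the variance draws and a
#' block-index sidecar, so a fit can be reloaded and summaries
#' recomputed offline.
#'
#' @param samples a `posterior_samples`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_samples <- function(samples, dir) {
  stopifnot(inherits(samples, "posterior_samples"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in names(samples$draws))
    write.csv(samples$draws[[b]], file.path(dir, paste0("draws_", b, ".csv")),
              row.names = FALSE)
  write.csv(samples$tau2, file.path(dir, "draws_tau2.csv"),
            row.names = FALSE)
  idx <- data.frame(block = names(samples$draws),
                    type = unname(samples$block_types),
                    p = vapply(samples$draws, ncol, integer(1)))
  write.csv(idx, file.path(dir, "block_index.csv"), row.names = FALSE)
  invisible(dir)
}

#' Reload persisted posterior draws
#'
#' @param dir directory written by [write_samples()].
#' @return a `posterior_samples` (without the original config).
#' @export
read_samples <- function(dir) {
  idx <- read.csv(file.path(dir, "block_index.csv"),
                  stringsAsFactors = FALSE)
  draws <- setNames(lapply(idx$block, function(b)
    as.matrix(read.csv(file.path(dir, paste0("draws_", b, ".csv")),
                       check.names = FALSE))),
    idx$block)
  tau2 <- as.matrix(read.csv(file.path(dir, "draws_tau2.csv"),
                             check.names = FALSE))
  structure(list(draws = draws, tau2 = tau2,
                 n_store = nrow(draws[[1L]]), config = NULL,
                 block_types = setNames(idx$type, idx$block),
                 region_ids = NULL),
            class = "posterior_samples")
}
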