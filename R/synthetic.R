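# Synthetic multi-year clustered survey generator with known ground
# truth, emulating stratified two-stage cluster sampling: regions ->
# clusters -> mothers -> daughters.

#' Generator configuration
#'
#' Defaults define the desk-scale study conditions: the 8-region Kenya
#' adjacency, 10 clusters per region (split across the survey waves),
#' 25 mothers per cluster (about 2000 mothers and 2600 daughters), the
#' 2003/2008/2014 waves with their year-specific outcome-definition
#' rules, attitude items missing in 2003, region-varying ethnic
#' mixtures driving true EFI variation, and a known additive predictor:
#' linear effects, smooth effects of ages / EFI / community norm
#' proportions, an ICAR-distributed structured spatial field, an iid
#' unstructured field, a declining time trend, and a doubly centered
#' space-time interaction.
#'
#' @param graph a [region_graph()]; default [kenya_region_graph()].
#' @param n_clusters_per_region total clusters per region across all
#'   waves (allocated round-robin to the waves).
#' @param n_mothers_per_cluster mothers sampled per cluster.
#' @param years survey waves.
#' @param beta0 true intercept on the logit scale.
#' @param beta named vector of true linear effects; names must be
#'   record columns (`mother_cut`, `urban`, ...).
#' @param smooth_shapes named list of functions of one argument giving
#'   the (uncentered) true smooth effects; defaults cover girl age
#'   (increasing), mother age (decreasing), EFI (rise-then-fall past
#'   0.4), and the three community norm proportions (increasing, with a
#'   sharp rise of the cut proportion above ~55%).
#' @param tau_s_true,tau_u_true scales of the structured (ICAR) and
#'   unstructured spatial fields.
#' @param trend_amplitude total logit drop of the time trend across the
#'   waves.
#' @param interaction_amplitude scale of the space-time interaction.
#' @param mother_cut_rates per-region probabilities that a mother is
#'   cut (region-varying social environment).
#' @param ethnicity_mixture S x G matrix of per-region ethnic mixture
#'   weights (rows sum to 1); default gives each region a dominant
#'   group with alternating dominance so clusters span a wide EFI
#'   range.
#' @param daughters_lambda Poisson mean of daughters per mother.
#' @param seed integer seed.
#' @return a `generator_config`.
#' @export
generator_config <- function(graph = kenya_region_graph(),
                             n_clusters_per_region = 10L,
                             n_mothers_per_cluster = 25L,
                             years = c(2003L, 2008L, 2014L),
                             beta0 = -3,
                             beta = c(mother_cut = 2, urban = -0.3),
                             smooth_shapes = NULL,
                             tau_s_true = 1, tau_u_true = 0.3,
                             trend_amplitude = -0.8,
                             interaction_amplitude = 0.3,
                             mother_cut_rates = NULL,
                             ethnicity_mixture = NULL,
                             daughters_lambda = 1.3,
                             seed = 1L) {
  S <- length(graph$region_ids)
  if (n_clusters_per_region < 1L || n_mothers_per_cluster < 1L)
    stop("counts must be >= 1")
  if (tau_s_true <= 0 || tau_u_true <= 0) stop("scales must be positive")
  defaults <- list(
    age_girl = function(a) 1.2 * plogis((a - 6) / 2),
    age_mother = function(a) -0.03 * (a - 32),
    efi = function(e) 0.8 * sin(pi * pmin(e, 0.8) / 0.8) -
      1.5 * pmax(e - 0.4, 0),
    prop_cut = function(p) 1.5 * plogis((p - 0.55) / 0.08),
    prop_support = function(p) 0.8 * p,
    prop_religious_req = function(p) 0.8 * p
  )
  if (is.null(smooth_shapes)) smooth_shapes <- defaults
  else smooth_shapes <- utils::modifyList(defaults, smooth_shapes)
  if (is.null(mother_cut_rates))
    mother_cut_rates <- setNames(
      seq(0.15, 0.8, length.out = S), graph$region_ids)
  if (is.null(ethnicity_mixture)) {
    G <- S
    M <- matrix(0, S, G, dimnames = list(graph$region_ids,
                                         paste0("eth", seq_len(G))))
    dom <- ifelse(seq_len(S) %% 2L == 0L, 0.85, 0.5)
    for (s in seq_len(S)) {
      M[s, ] <- (1 - dom[s]) / (G - 1)
      M[s, s] <- dom[s]
    }
    ethnicity_mixture <- M
  }
  if (any(abs(rowSums(ethnicity_mixture) - 1) > 1e-8))
    stop("ethnicity mixture rows must sum to 1")
  structure(list(graph = graph,
                 n_clusters_per_region = as.integer(n_clusters_per_region),
                 n_mothers_per_cluster = as.integer(n_mothers_per_cluster),
                 years = as.integer(years), beta0 = beta0, beta = beta,
                 smooth_shapes = smooth_shapes, tau_s_true = tau_s_true,
                 tau_u_true = tau_u_true,
                 trend_amplitude = trend_amplitude,
                 interaction_amplitude = interaction_amplitude,
                 mother_cut_rates = mother_cut_rates,
                 ethnicity_mixture = ethnicity_mixture,
                 daughters_lambda = daughters_lambda,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Simulate structured and unstructured spatial fields
#'
#' The structured field is drawn from the intrinsic MRF on its
#' sum-to-zero subspace (via the spectral pseudo-inverse of the ICAR
#' precision, covariance tau_s^2 Q^+); the unstructured field is iid
#' Gaussian, centered.
#'
#' @param graph a connected [region_graph()].
#' @param tau_s,tau_u positive scales.
#' @param seed optional seed.
#' @return list with named vectors `f_str` and `f_unstr`.
#' @export
simulate_spatial_effects <- function(graph, tau_s, tau_u, seed = NULL) {
  stopifnot(inherits(graph, "region_graph"))
  if (tau_s < 0 || tau_u < 0) stop("scales must be non-negative")
  if (.n_components(graph) > 1L)
    stop("graph is disconnected; intrinsic field undefined under the ",
         "default policy")
  if (!is.null(seed)) set.seed(seed)
  Q <- mrf_precision(graph)
  e <- eigen(Q, symmetric = TRUE)
  pos <- e$values > 1e-10 * max(e$values)
  z <- rnorm(sum(pos))
  f_str <- as.numeric(e$vectors[, pos, drop = FALSE] %*%
                        (z * tau_s / sqrt(e$values[pos])))
  f_unstr <- rnorm(length(graph$region_ids), 0, tau_u)
  f_unstr <- f_unstr - mean(f_unstr)
  list(f_str = setNames(f_str, graph$region_ids),
       f_unstr = setNames(f_unstr, graph$region_ids))
}

#' Simulate a KDHS-like survey with known ground truth
#'
#' Draws the two-stage hierarchy (clusters within regions, mothers
#' within clusters, daughters within mothers), generates mother
#' covariates and region-varying ethnicities, computes the realized
#' community covariates, builds the true additive predictor, draws each
#' daughter's outcome, applies the wave's outcome-definition rule, and
#' attaches log-normal survey weights.  Attitude items are set missing
#' for the 2003-flagged wave.  Smooth effect contributions are centered
#' over the realized daughter records so every truth block sums to
#' zero, matching the fitted model's identifiability convention.
#'
#' @param config a [generator_config()].
#' @return list with `dataset` (a `survey_dataset` with community
#'   covariates attached) and `truth` (a `ground_truth`: spatial
#'   fields, smooth curves on a grid, time trend, interaction matrix,
#'   true coefficients, reference-profile prevalence per region/year).
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  graph <- config$graph
  S <- length(graph$region_ids)
  years <- config$years
  ny <- length(years)

  fields <- simulate_spatial_effects(graph, config$tau_s_true,
                                     config$tau_u_true)

  # time trend: linear decline over the waves, centered
  t01 <- if (ny > 1) (years - min(years)) / diff(range(years)) else 0
  f_y <- config$trend_amplitude * t01
  f_y <- setNames(f_y - mean(f_y), years)

  # doubly centered space-time interaction: outer product of centered
  # region and time scores
  g_s <- rnorm(S); g_s <- g_s - mean(g_s)
  h_t <- seq(-1, 1, length.out = ny); h_t <- h_t - mean(h_t)
  f_st <- config$interaction_amplitude * outer(g_s, h_t)
  dimnames(f_st) <- list(graph$region_ids, years)

  # wave allocation of each region's clusters (round-robin)
  wave_of_cluster <- rep(years, length.out = config$n_clusters_per_region)

  # one predominantly Muslim region (NE-like); modest share elsewhere
  p_muslim <- rep(0.1, S)
  p_muslim[S] <- 0.9

  mothers <- list()
  for (ri in seq_len(S)) {
    region <- graph$region_ids[ri]
    for (ci in seq_len(config$n_clusters_per_region)) {
      cl_id <- sprintf("%s_c%02d", region, ci)
      yr <- wave_of_cluster[ci]
      nm <- config$n_mothers_per_cluster
      urban <- rbinom(1, 1, 0.35)
      eth <- sample(colnames(config$ethnicity_mixture), nm, replace = TRUE,
                    prob = config$ethnicity_mixture[region, ])
      cut <- rbinom(nm, 1, config$mother_cut_rates[[region]])
      support <- rbinom(nm, 1, pmin(0.15 + 0.6 * cut, 1))
      relig <- rbinom(nm, 1, pmin(0.10 + 0.5 * cut, 1))
      if (yr %in% attitude_missing_years()) {
        support <- rep(NA_integer_, nm)
        relig <- rep(NA_integer_, nm)
      }
      mothers[[length(mothers) + 1L]] <- data.frame(
        mother_id = sprintf("%s_m%03d", cl_id, seq_len(nm)),
        cluster_id = cl_id, region_id = region, survey_year = yr,
        age_mother = sample(15:49, nm, replace = TRUE),
        mother_cut = cut,
        mother_supports_continuation = support,
        mother_believes_religious_obligation = relig,
        ethnicity = eth, urban = urban,
        religion = sample(c("christian", "muslim"), nm, replace = TRUE,
                          prob = c(1 - p_muslim[ri], p_muslim[ri])),
        education = sample(.education_levels, nm, replace = TRUE,
                           prob = c(0.25, 0.45, 0.25, 0.05)),
        wealth_quintile = sample(.wealth_levels, nm, replace = TRUE),
        weight = rlnorm(nm, 0, 0.3),
        stringsAsFactors = FALSE)
    }
  }
  mothers <- do.call(rbind, mothers)

  # realized community covariates over each cluster's mothers
  comm <- do.call(rbind, lapply(split(mothers, mothers$cluster_id),
                                function(m) {
    tab <- table(m$ethnicity)
    data.frame(cluster_id = m$cluster_id[1L],
               prop_cut = mean(m$mother_cut),
               prop_support = if (all(is.na(m$mother_supports_continuation)))
                 NA_real_ else mean(m$mother_supports_continuation),
               prop_religious_req =
                 if (all(is.na(m$mother_believes_religious_obligation)))
                   NA_real_ else mean(m$mother_believes_religious_obligation),
               efi = compute_efi(as.numeric(tab) / sum(tab)),
               stringsAsFactors = FALSE)
  }))
  mothers <- merge(mothers, comm, by = "cluster_id", sort = FALSE)

  # daughters
  nd <- rpois(nrow(mothers), config$daughters_lambda)
  idx <- rep(seq_len(nrow(mothers)), nd)
  if (length(idx) == 0L) stop("configuration yields zero daughters")
  daughters <- mothers[idx, , drop = FALSE]
  daughters$age_girl <- sample(0:14, nrow(daughters), replace = TRUE)
  daughters$girl_id <- paste0(daughters$mother_id, "_d",
                              unlist(lapply(nd[nd > 0], seq_len)))

  # true predictor; smooth contributions centered over realized records
  sh <- config$smooth_shapes
  contrib <- list(
    age_girl = sh$age_girl(daughters$age_girl),
    age_mother = sh$age_mother(daughters$age_mother),
    efi = sh$efi(daughters$efi),
    prop_cut = sh$prop_cut(daughters$prop_cut),
    prop_support = ifelse(is.na(daughters$prop_support), 0,
                          sh$prop_support(daughters$prop_support)),
    prop_religious_req = ifelse(is.na(daughters$prop_religious_req), 0,
                                sh$prop_religious_req(
                                  daughters$prop_religious_req)))
  centers <- vapply(contrib, mean, numeric(1))
  contrib <- lapply(names(contrib),
                    function(v) contrib[[v]] - centers[[v]])
  names(contrib) <- names(centers)

  eta <- config$beta0 + Reduce(`+`, contrib)
  for (v in names(config$beta)) {
    x <- daughters[[v]]
    if (is.character(x)) x <- as.numeric(x == "muslim")
    eta <- eta + config$beta[[v]] * x
  }
  eta <- eta + f_y[as.character(daughters$survey_year)] +
    fields$f_str[daughters$region_id] +
    fields$f_unstr[daughters$region_id] +
    f_st[cbind(daughters$region_id, as.character(daughters$survey_year))]
  daughters$true_eta <- eta
  daughters$cut <- rbinom(nrow(daughters), 1, plogis(eta))
  # recency stand-in for the 2008-style rule: age at cutting unknown,
  # younger cut daughters count as more recently cut
  daughters$cut_recency <- -daughters$age_girl

  # year-specific outcome definitions
  rules <- outcome_rules(years)
  girls <- do.call(rbind, lapply(split(daughters, daughters$survey_year),
                                 function(dd) {
    harmonize_outcome(dd, rules[[as.character(dd$survey_year[1L])]])
  }))
  rownames(girls) <- NULL

  ds <- as_survey_dataset(girls[, c(.record_columns,
                                    "prop_cut", "prop_support",
                                    "prop_religious_req", "efi")],
                          graph = graph)

  # ground truth, including reference-profile prevalence per region/year
  grids <- list(age_girl = 0:14, age_mother = 15:49,
                efi = seq(0, 0.9, by = 0.05),
                prop_cut = seq(0, 1, by = 0.05),
                prop_support = seq(0, 1, by = 0.05),
                prop_religious_req = seq(0, 1, by = 0.05))
  curves <- lapply(names(grids), function(v)
    data.frame(x = grids[[v]], f = sh[[v]](grids[[v]]) - centers[[v]]))
  names(curves) <- names(grids)

  profile <- list(mother_cut = 0, urban = 0,
                  age_girl = mean(girls$age_girl),
                  age_mother = mean(girls$age_mother),
                  efi = mean(girls$efi),
                  prop_cut = mean(girls$prop_cut),
                  prop_support = mean(girls$prop_support, na.rm = TRUE),
                  prop_religious_req = mean(girls$prop_religious_req,
                                            na.rm = TRUE))
  eta_ref0 <- config$beta0 +
    sum(vapply(names(grids), function(v) {
      val <- profile[[v]]
      if (v %in% names(config$beta)) 0 else sh[[v]](val) - centers[[v]]
    }, numeric(1))) +
    sum(vapply(names(config$beta), function(v) {
      val <- profile[[v]]
      if (is.null(val)) 0 else config$beta[[v]] * as.numeric(val)
    }, numeric(1)))
  prev <- expand.grid(region = graph$region_ids, year = years,
                      stringsAsFactors = FALSE)
  prev$prevalence <- plogis(eta_ref0 +
    f_y[as.character(prev$year)] +
    fields$f_str[prev$region] + fields$f_unstr[prev$region] +
    f_st[cbind(prev$region, as.character(prev$year))])

  truth <- structure(list(beta0 = config$beta0, beta = config$beta,
                          f_str = fields$f_str, f_unstr = fields$f_unstr,
                          f_y = f_y, f_st = f_st, curves = curves,
                          profile = profile, prevalence_ref = prev,
                          mothers = mothers,
                          eta = data.frame(girl_id = girls$girl_id,
                                           eta = girls$true_eta),
                          config = config),
                     class = "ground_truth")
  list(dataset = ds, truth = truth)
}

#' Model specification matching the generator's data-generating process
#'
#' Returns the [model_spec()] whose term structure mirrors the
#' synthetic truth: the generator's linear effects, P-spline smooths of
#' the ages, EFI, and community norm proportions, both spatial effects,
#' and (for multi-wave data) the time smooth and space-time
#' interaction.  Fitting this specification to generator output is the
#' package's parameter-recovery benchmark.
#'
#' @param config a [generator_config()].
#' @param smooth_config optional spline config applied to every smooth
#'   term (e.g. fewer knots for reduced-size runs).
#' @return an [model_spec()].
#' @export
generator_model_spec <- function(config, smooth_config = NULL) {
  stopifnot(inherits(config, "generator_config"))
  smooths <- c("prop_cut", "prop_support", "prop_religious_req",
               "age_girl", "age_mother", "efi")
  smooth <- if (is.null(smooth_config)) smooths else
    setNames(rep(list(smooth_config), length(smooths)), smooths)
  pooled <- length(config$years) > 1L
  model_spec(linear = names(config$beta), smooth = smooth,
             spatial = TRUE, unstructured = TRUE,
             year_smooth = pooled, interaction = pooled)
}

#' Write the ground-truth sidecar as plain text
#'
#' @param truth a `ground_truth`.
#' @param path output CSV path prefix; writes `<path>_spatial.csv`,
#'   `<path>_prevalence.csv`, `<path>_coefficients.csv`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  write.csv(data.frame(region = names(truth$f_str),
                       f_str = as.numeric(truth$f_str),
                       f_unstr = as.numeric(truth$f_unstr)),
            paste0(path, "_spatial.csv"), row.names = FALSE)
  write.csv(truth$prevalence_ref, paste0(path, "_prevalence.csv"),
            row.names = FALSE)
  write.csv(data.frame(term = c("beta0", names(truth$beta)),
                       value = c(truth$beta0, as.numeric(truth$beta))),
            paste0(path, "_coefficients.csv"), row.names = FALSE)
  invisible(path)
}

#' Compare a fit against the generator's ground truth
#'
#' Reports fixed-effect bias and credible-interval coverage, the
#' Pearson correlation of the posterior mean spatial field with the
#' true field (total = structured + unstructured), RMSE of each
#' posterior mean smooth curve on the truth grid, and RMSE of predicted
#' reference-profile prevalence.
#'
#' @param truth a `ground_truth`.
#' @param samples the `posterior_samples` fitted to the matching
#'   dataset.
#' @param frame the matching model frame.
#' @param level credibility level for coverage.
#' @return a `recovery_report` list.
#' @export
recovery_report <- function(truth, samples, frame, level = 0.95) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(samples, "posterior_samples"),
            inherits(frame, "model_frame"))
  alpha <- (1 - level) / 2
  fixed <- NULL
  d <- samples$draws$fixed
  for (v in names(truth$beta)) {
    col <- if (v %in% colnames(d)) v else {
      hit <- grep(paste0("^", v, ":"), colnames(d), value = TRUE)
      if (length(hit) == 1L) hit else NA_character_
    }
    if (is.na(col)) next
    q <- quantile(d[, col], c(alpha, 1 - alpha), names = FALSE)
    fixed <- rbind(fixed, data.frame(
      term = v, truth = truth$beta[[v]],
      posterior_mean = mean(d[, col]),
      bias = mean(d[, col]) - truth$beta[[v]],
      lower = q[1], upper = q[2],
      covered = q[1] <= truth$beta[[v]] & truth$beta[[v]] <= q[2]))
  }

  spatial_r <- NA_real_
  if (!is.null(samples$draws$str)) {
    est <- colMeans(samples$draws$str)
    if (!is.null(samples$draws$unstr))
      est <- est + colMeans(samples$draws$unstr)
    tru <- truth$f_str[names(est)] + truth$f_unstr[names(est)]
    spatial_r <- suppressWarnings(cor(est, tru))
  }

  smooth_rmse <- c()
  for (v in names(truth$curves)) {
    blk <- frame$blocks[[paste0("sm_", v)]]
    if (is.null(blk)) next
    g <- truth$curves[[v]]
    inside <- g$x >= blk$basis$range[1] & g$x <= blk$basis$range[2]
    B <- eval_basis(blk$basis, g$x[inside])
    est <- as.numeric(B %*% colMeans(samples$draws[[paste0("sm_", v)]]))
    tru <- g$f[inside]
    # both centered over the grid before comparison (level is absorbed
    # by the intercept under the sum-to-zero convention)
    smooth_rmse[v] <- sqrt(mean(((est - mean(est)) -
                                   (tru - mean(tru)))^2))
  }

  prev_rmse <- NA_real_
  if (!is.null(samples$draws$str)) {
    pr <- truth$prevalence_ref
    has_time <- !is.null(frame$blocks[["year"]]) || !is.null(frame$blocks[["st"]])
    if (!has_time) pr <- pr[!duplicated(pr$region), , drop = FALSE]
    est <- vapply(seq_len(nrow(pr)), function(i) {
      predict_prevalence(samples, frame, pr$region[i],
                         if (has_time) pr$year[i] else NULL,
                         profile = truth$profile)$mean
    }, numeric(1))
    prev_rmse <- sqrt(mean((est - pr$prevalence)^2))
  }

  structure(list(fixed = fixed, spatial_r = spatial_r,
                 smooth_rmse = smooth_rmse, prevalence_rmse = prev_rmse,
                 level = level),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery_report\n")
  if (!is.null(x$fixed)) {
    print(format(x$fixed, digits = 3), row.names = FALSE)
    cat(sprintf("coverage: %.0f%% of fixed effects at the %.0f%% level\n",
                100 * mean(x$fixed$covered), 100 * x$level))
  }
  if (!is.na(x$spatial_r))
    cat(sprintf("spatial field Pearson r: %.3f\n", x$spatial_r))
  if (length(x$smooth_rmse))
    cat("smooth RMSE:", paste(sprintf("%s=%.3f", names(x$smooth_rmse),
                                      x$smooth_rmse), collapse = ", "), "\n")
  if (!is.na(x$prevalence_rmse))
    cat(sprintf("prevalence RMSE: %.4f\n", x$prevalence_rmse))
  invisible(x)
}
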