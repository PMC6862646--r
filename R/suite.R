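# Model suites (single-year A/B/C; pooled I/II/III), DIC comparison,
# and map-ready exports.

#' Term sets of the model suites
#'
#' Single-year suite: A = normative-influence variables only (mother's
#' cut status linear; community proportions smooth), B = A + total
#' spatial effects, C = B + individual-level covariates (religion,
#' education, wealth, urban/rural, ethnicity linear; ages and EFI
#' smooth).  Pooled suite: I and II mirror A and B; III adds the time
#' smooth and the space-time tensor interaction on top of the
#' individual-level covariates.
#'
#' @param name one of `"A"`, `"B"`, `"C"`, `"I"`, `"II"`, `"III"`.
#' @return an [model_spec()].
#' @export
suite_definition <- function(name) {
  name <- match.arg(name, c("A", "B", "C", "I", "II", "III"))
  normative_linear <- "mother_cut"
  normative_smooth <- c("prop_cut", "prop_support", "prop_religious_req")
  other_linear <- c("urban", "religion", "education", "wealth_quintile",
                    "ethnicity")
  other_smooth <- c("age_girl", "age_mother", "efi")
  switch(name,
    A = , I = model_spec(linear = normative_linear,
                         smooth = normative_smooth),
    B = , II = model_spec(linear = normative_linear,
                          smooth = normative_smooth,
                          spatial = TRUE, unstructured = TRUE),
    C = model_spec(linear = c(normative_linear, other_linear),
                   smooth = c(normative_smooth, other_smooth),
                   spatial = TRUE, unstructured = TRUE),
    III = model_spec(linear = c(normative_linear, other_linear),
                     smooth = c(normative_smooth, other_smooth),
                     spatial = TRUE, unstructured = TRUE,
                     year_smooth = TRUE, interaction = TRUE))
}

# drop covariates that are absent, constant, or all-missing so a suite
# member degrades gracefully on reduced synthetic data
.prune_spec <- function(spec, df) {
  usable <- function(v) {
    if (!(v %in% names(df))) return(FALSE)
    x <- df[[v]][!is.na(df[[v]])]
    length(x) > 0L && length(unique(x)) > 1L
  }
  dropped <- character()
  for (v in names(spec$linear))
    if (!usable(v)) { spec$linear[[v]] <- NULL; dropped <- c(dropped, v) }
  for (v in names(spec$smooth))
    if (!usable(v)) { spec$smooth[[v]] <- NULL; dropped <- c(dropped, v) }
  attr(spec, "dropped_terms") <- dropped
  spec
}

#' Fit a suite of models and compare them by DIC
#'
#' Fits every named suite member to the same dataset with a common seed
#' policy (per-model seeds derived deterministically from
#' `config$seed`), computing a fit summary for each, and returns a
#' comparison table sorted by DIC.  So that DIC values are comparable,
#' the dataset is reduced once to complete cases on the union of all
#' members' covariates; the dropped count is reported.  Members whose
#' requirements cannot be met are reported and skipped while the others
#' still run.
#'
#' @param ds a `survey_dataset` with community covariates attached.
#' @param graph a [region_graph()].
#' @param suite character vector of suite member names
#'   (see [suite_definition()]).
#' @param config an [mcmc_config()]; member seeds are
#'   `config$seed + position`.
#' @param level credibility level for summaries.
#' @param out_dir optional run directory: persisted draws, summaries,
#'   the comparison table, and the resolved configuration are written
#'   there.
#' @param verbose progress interval for the samplers.
#' @return a `suite_result`: list with `fits` (per member: samples,
#'   frame, summary), `comparison` (model, dic, pd, mean ESS), and
#'   `errors`.
#' @export
run_suite <- function(ds, graph, suite = c("A", "B", "C"),
                      config = mcmc_config(), level = 0.95,
                      out_dir = NULL, verbose = 0L) {
  stopifnot(inherits(ds, "survey_dataset"))
  if (length(suite) == 0L) stop("empty suite")
  specs <- lapply(suite, suite_definition)
  names(specs) <- suite

  # common complete-case dataset over the union of used covariates
  specs <- lapply(specs, .prune_spec, df = ds$records)
  used <- unique(unlist(lapply(specs, function(s)
    c(names(s$linear), names(s$smooth)))))
  keep <- rep(TRUE, nrow(ds$records))
  for (v in used) keep <- keep & !is.na(ds$records[[v]])
  if (sum(!keep) > 0L)
    message(sum(!keep), " record(s) dropped for suite comparability ",
            "(missing values in the union of suite covariates)")
  ds$records <- ds$records[keep, , drop = FALSE]

  fits <- list()
  errors <- list()
  for (i in seq_along(suite)) {
    nm <- suite[i]
    res <- tryCatch({
      frame <- build_design(ds, graph, specs[[nm]])
      cfg <- mcmc_config(config$n_iter, config$burn_in, config$thin,
                         seed = config$seed + i)
      samples <- run_mcmc(frame, cfg, verbose = verbose)
      list(samples = samples, frame = frame,
           summary = fit_summary(samples, frame, level))
    }, error = function(e) e)
    if (inherits(res, "error")) errors[[nm]] <- conditionMessage(res)
    else fits[[nm]] <- res
  }
  if (length(fits) == 0L) stop("every suite member failed: ",
                               paste(unlist(errors), collapse = "; "))

  comparison <- do.call(rbind, lapply(names(fits), function(nm) {
    s <- fits[[nm]]$summary
    data.frame(model = nm, dic = s$dic, pd = s$pd,
               mean_ess = mean(s$ess, na.rm = TRUE))
  }))
  comparison <- comparison[order(comparison$dic), , drop = FALSE]
  rownames(comparison) <- NULL

  out <- structure(list(fits = fits, comparison = comparison,
                        errors = errors, seed = config$seed,
                        level = level),
                   class = "suite_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(comparison, file.path(out_dir, "comparison.csv"),
              row.names = FALSE)
    for (nm in names(fits)) {
      write_samples(fits[[nm]]$samples, file.path(out_dir, nm))
      if (!is.null(fits[[nm]]$summary$region_class))
        export_maps(fits[[nm]]$summary,
                    file.path(out_dir, paste0(nm, "_regions.csv")))
    }
    writeLines(c(paste("seed:", config$seed),
                 paste("n_iter:", config$n_iter),
                 paste("burn_in:", config$burn_in),
                 paste("thin:", config$thin),
                 paste("level:", level),
                 paste("suite:", paste(suite, collapse = ","))),
               file.path(out_dir, "run_config.txt"))
  }
  out
}

#' @export
print.suite_result <- function(x, ...) {
  cat("suite_result (seed", x$seed, ")\n")
  print(format(x$comparison, digits = 4), row.names = FALSE)
  if (length(x$errors))
    for (nm in names(x$errors)) cat("failed:", nm, "-", x$errors[[nm]], "\n")
  invisible(x)
}

#' Export per-region summaries as CSV and optionally GeoJSON
#'
#' Writes the per-region posterior means, credible bounds, significance
#' classes, and (when present) the prevalence-by-year grid.  When a
#' GeoJSON geometry file is supplied, the same quantities are attached
#' to each feature's properties (matched on the `region_id` property).
#'
#' @param summary a [fit_summary()].
#' @param csv_path output CSV path.
#' @param geojson_in optional input GeoJSON with a `region_id` property
#'   per feature.
#' @param geojson_out output GeoJSON path (required with `geojson_in`).
#' @return `csv_path`, invisibly.
#' @export
export_maps <- function(summary, csv_path, geojson_in = NULL,
                        geojson_out = NULL) {
  stopifnot(inherits(summary, "fit_summary"))
  if (is.null(summary$region_class))
    stop("summary has no regional classification to export")
  tab <- summary$region_class
  if (!is.null(summary$prevalence)) {
    prev <- summary$prevalence
    for (yr in unique(prev$year)) {
      sub <- prev[prev$year %in% yr, c("region", "prevalence")]
      nm <- if (is.na(yr)) "prevalence" else paste0("prevalence_", yr)
      names(sub)[2] <- nm
      tab <- merge(tab, sub, by = "region", sort = FALSE)
    }
  }
  write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(geojson_in)) {
    if (is.null(geojson_out)) stop("geojson_out required with geojson_in")
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required for GeoJSON export")
    gj <- jsonlite::read_json(geojson_in)
    feat_ids <- vapply(gj$features, function(f)
      as.character(f$properties$region_id), character(1))
    missing <- setdiff(tab$region, feat_ids)
    extra <- setdiff(feat_ids, tab$region)
    if (length(missing) || length(extra))
      stop("region id mismatch; missing from geometry: ",
           paste(missing, collapse = ", "), "; unknown in geometry: ",
           paste(extra, collapse = ", "))
    for (i in seq_along(gj$features)) {
      row <- tab[tab$region == feat_ids[i], , drop = FALSE]
      for (cn in setdiff(names(row), "region"))
        gj$features[[i]]$properties[[cn]] <- row[[cn]][1L]
    }
    jsonlite::write_json(gj, geojson_out, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
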