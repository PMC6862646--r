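# Community-level normative-influence covariates and the ethnic
# fractionalization index (EFI).

#' Ethnic fractionalization index
#'
#' EFI = 1 - sum(s_k^2), a decreasing transformation of the Herfindahl
#' concentration index of ethnic-group shares s_k.  Zero for a
#' monoethnic community; approaches 1 - 1/n for n equally sized groups.
#'
#' @param group_proportions non-negative shares summing to 1.  A sum
#'   within 1e-3 of 1 is renormalized with a warning; larger deviations
#'   are an error.
#' @return EFI value in `[0, 1 - 1/n]`.
#' @examples
#' compute_efi(c(0.5, 0.3, 0.2))  # 0.62
#' @export
compute_efi <- function(group_proportions) {
  p <- as.numeric(group_proportions)
  if (length(p) < 1L) stop("at least one group required")
  if (any(p < 0)) stop("negative group proportion")
  s <- sum(p)
  if (abs(s - 1) > 1e-8) {
    if (abs(s - 1) <= 1e-3) {
      warning("group proportions renormalized (sum deviates by ",
              format(abs(s - 1)), ")")
      p <- p / s
    } else stop("group proportions must sum to 1 (got ", format(s), ")")
  }
  1 - sum(p^2)
}

#' (Weighted) community proportion of a binary attribute
#'
#' Share of mothers in one cluster with attribute value 1, among those
#' with a non-missing value.  Returns `NA` when every value is missing
#' (e.g. attitude items in the 2003 wave).
#'
#' @param values binary (0/1, possibly NA) attribute values of the
#'   cluster's mothers.
#' @param weights optional positive weights; default unit weights.
#' @export
community_proportions <- function(values, weights = NULL) {
  if (length(values) == 0L) stop("empty cluster")
  v <- as.numeric(values)
  if (!all(is.na(v) | v %in% c(0, 1))) stop("attribute must be binary")
  if (is.null(weights)) weights <- rep(1, length(v))
  if (any(weights <= 0)) stop("weights must be positive")
  ok <- !is.na(v)
  if (!any(ok)) return(NA_real_)
  sum(weights[ok] * v[ok]) / sum(weights[ok])
}

# One row per distinct mother in a cluster (girls repeat their mother's
# covariates; community profiles are defined over mothers).
.mother_level <- function(df) {
  df[!duplicated(df$mother_id), , drop = FALSE]
}

#' Community profiles per cluster
#'
#' Computes, over each cluster's distinct mothers: the number of women,
#' the proportions cut / supporting continuation / believing FGM/C a
#' religious obligation, and the ethnic fractionalization index.
#'
#' @param ds a `survey_dataset`.
#' @param weighted logical; weight mothers by their survey weight
#'   (default unweighted).
#' @return data.frame with one row per cluster.
#' @export
community_profiles <- function(ds, weighted = FALSE) {
  stopifnot(inherits(ds, "survey_dataset"))
  df <- ds$records
  out <- lapply(split(df, df$cluster_id), function(cl) {
    m <- .mother_level(cl)
    w <- if (weighted) m$weight else NULL
    tab <- tapply(if (weighted) m$weight else rep(1, nrow(m)),
                  m$ethnicity, sum)
    data.frame(cluster_id = cl$cluster_id[1L],
               n_women = nrow(m),
               prop_cut = community_proportions(m$mother_cut, w),
               prop_support =
                 community_proportions(m$mother_supports_continuation, w),
               prop_religious_req =
                 community_proportions(m$mother_believes_religious_obligation,
                                       w),
               efi = compute_efi(as.numeric(tab) / sum(tab)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Attach community covariates to every girl record
#'
#' Joins each record's cluster profile (proportion of cut women,
#' proportion supporting continuation, proportion believing a religious
#' obligation, EFI) onto the dataset.  By default the convention is
#' leave-self-in: a mother contributes to her own cluster's
#' proportions; `leave_self_out = TRUE` recomputes each mother's
#' covariates excluding herself (sensitivity variant).  Re-attaching is
#' idempotent.
#'
#' @param ds a `survey_dataset`.
#' @param leave_self_out logical, default `FALSE`.
#' @param weighted logical; survey-weighted proportions (default
#'   unweighted).
#' @return the dataset with columns `prop_cut`, `prop_support`,
#'   `prop_religious_req`, `efi` added/replaced.
#' @export
attach_community_covariates <- function(ds, leave_self_out = FALSE,
                                        weighted = FALSE) {
  stopifnot(inherits(ds, "survey_dataset"))
  df <- ds$records
  vars <- c("prop_cut", "prop_support", "prop_religious_req", "efi")
  df <- df[, setdiff(names(df), vars), drop = FALSE]
  if (!leave_self_out) {
    prof <- community_profiles(ds, weighted = weighted)
    df <- merge(df, prof[, c("cluster_id", vars)], by = "cluster_id",
                sort = FALSE)
  } else {
    for (v in vars) df[[v]] <- NA_real_
    for (cl in split(seq_len(nrow(df)), df$cluster_id)) {
      m <- .mother_level(df[cl, , drop = FALSE])
      if (nrow(m) < 2L) stop("leave-one-out undefined for a cluster ",
                             "with a single mother")
      for (i in cl) {
        others <- m[m$mother_id != df$mother_id[i], , drop = FALSE]
        w <- if (weighted) others$weight else NULL
        df$prop_cut[i] <- community_proportions(others$mother_cut, w)
        df$prop_support[i] <-
          community_proportions(others$mother_supports_continuation, w)
        df$prop_religious_req[i] <-
          community_proportions(others$mother_believes_religious_obligation,
                                w)
        tab <- tapply(if (weighted) others$weight else rep(1, nrow(others)),
                      others$ethnicity, sum)
        df$efi[i] <- compute_efi(as.numeric(tab) / sum(tab))
      }
    }
  }
  ds$records <- df[order(match(df$girl_id, ds$records$girl_id)), ,
                   drop = FALSE]
  rownames(ds$records) <- NULL
  ds
}

#' Survey-weighted outcome prevalence by strata
#'
#' Per stratum of `by`, the weighted share of cut girls
#' sum(w_i y_i) / sum(w_i) together with the unweighted count.  No
#' variance estimation is attempted.  Empty strata are omitted.
#'
#' @param ds a `survey_dataset`.
#' @param by character vector of grouping columns (e.g.
#'   `c("survey_year", "mother_cut")`).
#' @return data.frame with the grouping columns, `prevalence`, and `n`.
#' @export
weighted_prevalence <- function(ds, by) {
  stopifnot(inherits(ds, "survey_dataset"))
  df <- ds$records
  if (any(df$weight <= 0)) stop("weights must be positive")
  missing <- setdiff(by, names(df))
  if (length(missing)) stop("unknown grouping column(s): ",
                            paste(missing, collapse = ", "))
  key <- interaction(df[by], drop = TRUE, sep = "\r")
  num <- tapply(df$weight * df$y, key, sum)
  den <- tapply(df$weight, key, sum)
  n <- tapply(rep(1L, nrow(df)), key, sum)
  parts <- do.call(rbind, strsplit(names(num), "\r", fixed = TRUE))
  out <- as.data.frame(parts, stringsAsFactors = FALSE)
  names(out) <- by
  out$prevalence <- as.numeric(num / den)
  out$n <- as.integer(n)
  rownames(out) <- NULL
  out[do.call(order, out[by]), , drop = FALSE]
}
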