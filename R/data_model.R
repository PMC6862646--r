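# Survey record schema, file IO, outcome harmonization.

# Canonical column order of a girl-level record.  All readers/writers and
# the synthetic generator use this layout.
.record_columns <- c(
  "girl_id", "mother_id", "cluster_id", "region_id", "survey_year", "y",
  "age_girl", "age_mother", "mother_cut", "mother_supports_continuation",
  "mother_believes_religious_obligation", "ethnicity", "religion",
  "education", "wealth_quintile", "urban", "weight"
)

.education_levels <- c("none", "primary", "secondary", "higher")
.wealth_levels <- c("lowest", "lower", "middle", "higher", "highest")

.schema_version <- "1.0"

#' Outcome-definition rules by survey year
#'
#' Survey waves differ in how a daughter's cutting status was recorded:
#' 1998 and 2003 report the eldest daughter, 2008 the most recently cut
#' daughter, and 2014 all daughters aged 0--14.  Unlisted (e.g.
#' synthetic) years default to `ALL_DAUGHTERS`.
#'
#' @param years integer vector of survey years.
#' @param overrides optional named character vector mapping a year to a
#'   rule in `c("ELDEST_DAUGHTER", "MOST_RECENTLY_CUT_DAUGHTER",
#'   "ALL_DAUGHTERS")`.
#' @return named character vector, one rule per year.
#' @export
outcome_rules <- function(years, overrides = NULL) {
  years <- sort(unique(as.integer(years)))
  defaults <- c("1998" = "ELDEST_DAUGHTER", "2003" = "ELDEST_DAUGHTER",
                "2008" = "MOST_RECENTLY_CUT_DAUGHTER",
                "2014" = "ALL_DAUGHTERS")
  rules <- vapply(as.character(years), function(y) {
    if (y %in% names(defaults)) defaults[[y]] else "ALL_DAUGHTERS"
  }, character(1))
  names(rules) <- as.character(years)
  if (!is.null(overrides)) {
    bad <- setdiff(overrides,
                   c("ELDEST_DAUGHTER", "MOST_RECENTLY_CUT_DAUGHTER",
                     "ALL_DAUGHTERS"))
    if (length(bad)) stop("unknown outcome rule(s): ",
                          paste(bad, collapse = ", "))
    rules[names(overrides)] <- overrides
  }
  rules
}

#' Survey years whose questionnaire lacked the attitude items
#'
#' The 2003 wave did not field the continuation-support and
#' religious-obligation items; records from flagged years may carry
#' missing attitude fields without being rejected.
#' @export
attitude_missing_years <- function() 2003L

# Validate one data.frame of girl records; returns list(records, rejected)
# where rejected is a data.frame of (row, rule) diagnostics.
.validate_girl_records <- function(df, graph = NULL) {
  n <- nrow(df)
  diags <- list()
  flag <- function(bad, rule) {
    idx <- which(bad)
    if (length(idx))
      diags[[length(diags) + 1L]] <<- data.frame(row = idx, rule = rule)
  }
  num <- function(x) suppressWarnings(as.numeric(x))

  # non-integer ages are floored with a warning (completed years)
  for (col in c("age_girl", "age_mother")) {
    a <- num(df[[col]])
    frac <- !is.na(a) & a != floor(a)
    if (any(frac)) {
      warning(sum(frac), " non-integer values in '", col, "' floored")
      a[frac] <- floor(a[frac])
    }
    df[[col]] <- a
  }

  flag(is.na(num(df$y)) | !(num(df$y) %in% c(0, 1)), "y must be 0 or 1")
  flag(is.na(df$age_girl) | df$age_girl < 0 | df$age_girl > 14,
       "age_girl must be an integer in 0..14")
  flag(is.na(df$age_mother) | df$age_mother < 15 | df$age_mother > 49,
       "age_mother must be an integer in 15..49")
  flag(is.na(num(df$weight)) | num(df$weight) <= 0, "weight must be > 0")
  flag(!is.na(df$mother_cut) & !(num(df$mother_cut) %in% c(0, 1)),
       "mother_cut must be 0/1")
  flag(is.na(df$mother_cut), "mother_cut missing")

  # attitude fields may be missing only in flagged years
  flagged <- df$survey_year %in% attitude_missing_years()
  for (col in c("mother_supports_continuation",
                "mother_believes_religious_obligation")) {
    flag(is.na(df[[col]]) & !flagged, paste0(col, " missing outside ",
         "attitude-flagged years"))
    flag(!is.na(df[[col]]) & !(num(df[[col]]) %in% c(0, 1)),
         paste0(col, " must be 0/1"))
  }

  if (!is.null(graph)) {
    flag(!(as.character(df$region_id) %in% graph$region_ids),
         "region_id not in region graph")
  }

  rejected <- if (length(diags)) do.call(rbind, diags) else
    data.frame(row = integer(), rule = character())
  rejected <- rejected[order(rejected$row), , drop = FALSE]
  keep <- setdiff(seq_len(n), unique(rejected$row))
  list(records = df[keep, , drop = FALSE], rejected = rejected)
}

.new_survey_dataset <- function(records) {
  rownames(records) <- NULL
  structure(list(records = records,
                 years = sort(unique(records$survey_year)),
                 schema_version = .schema_version),
            class = "survey_dataset")
}

#' Read girl-level survey records from a delimited file
#'
#' Reads a CSV with a header row, maps columns onto the canonical
#' schema, validates every row against the record invariants, and
#' returns the validated dataset.  Rows failing an invariant are
#' dropped with row-indexed diagnostics attached.
#'
#' @param path path to a CSV file (UTF-8, header row).
#' @param schema optional named character vector mapping canonical
#'   column names to the file's column names; canonical names absent
#'   from the mapping are assumed to appear verbatim.
#' @param graph optional [region_graph()]; when given, records whose
#'   `region_id` is not a graph region are rejected.
#' @return a `survey_dataset`: list with `records` (data.frame in
#'   canonical column order), `years`, and `schema_version`.  Rejected
#'   rows are attached as `attr(, "rejected")`.
#' @export
read_records <- function(path, schema = NULL, graph = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  cols <- .record_columns
  rename <- setNames(cols, cols)
  if (!is.null(schema)) {
    unknown <- setdiff(names(schema), cols)
    if (length(unknown)) stop("schema maps unknown canonical column(s): ",
                              paste(unknown, collapse = ", "))
    rename[names(schema)] <- schema
  }
  missing <- rename[!(rename %in% names(raw))]
  if (length(missing)) stop("mapped column(s) absent from file: ",
                            paste(missing, collapse = ", "))
  df <- raw[, unname(rename)]
  names(df) <- cols
  df$survey_year <- as.integer(df$survey_year)
  v <- .validate_girl_records(df, graph)
  if (nrow(v$records) == 0L) stop("no valid records after filtering: ", path)
  ds <- .new_survey_dataset(v$records)
  attr(ds, "rejected") <- v$rejected
  ds
}

#' Write a survey dataset to the canonical CSV layout
#'
#' @param ds a `survey_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(ds, path) {
  stopifnot(inherits(ds, "survey_dataset"))
  extra <- setdiff(names(ds$records), .record_columns)
  write.csv(ds$records[, c(.record_columns, extra)], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a survey dataset from an in-memory data.frame
#'
#' Validates `df` like [read_records()] but without file IO.
#'
#' @inheritParams read_records
#' @param df data.frame with the canonical columns.
#' @export
as_survey_dataset <- function(df, graph = NULL) {
  missing <- setdiff(.record_columns, names(df))
  if (length(missing)) stop("missing column(s): ",
                            paste(missing, collapse = ", "))
  extra <- setdiff(names(df), .record_columns)
  df <- df[, c(.record_columns, extra)]
  df$survey_year <- as.integer(df$survey_year)
  v <- .validate_girl_records(df, graph)
  if (nrow(v$records) == 0L) stop("no valid records after filtering")
  key <- paste(v$records$girl_id, v$records$survey_year)
  if (anyDuplicated(key)) stop("duplicate (girl_id, survey_year) pairs")
  ds <- .new_survey_dataset(v$records)
  attr(ds, "rejected") <- v$rejected
  ds
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("survey_dataset:", nrow(x$records), "girl records,",
      length(unique(x$records$cluster_id)), "clusters,",
      length(unique(x$records$region_id)), "regions; years:",
      paste(x$years, collapse = ", "), "\n")
  invisible(x)
}

#' Harmonize per-daughter rows into girl outcome records
#'
#' Applies the survey wave's outcome-definition rule to mother-level
#' daughter listings, producing one harmonized girl record stream:
#' `ELDEST_DAUGHTER` keeps at most one record per mother (her eldest
#' daughter, with that daughter's cut status); `MOST_RECENTLY_CUT_DAUGHTER`
#' keeps the reported (most recently cut) daughter, or the eldest
#' daughter as uncut when no daughter was cut; `ALL_DAUGHTERS` keeps one
#' record per daughter aged 0--14.  The outcome is coded 1 if the girl
#' was cut, 0 otherwise.
#'
#' @param rows data.frame of per-daughter rows carrying at least
#'   `mother_id`, `survey_year`, `age_girl`, and `cut` (0/1); an
#'   optional `cut_recency` column (larger = more recent) breaks the
#'   2008-style choice among several cut daughters.
#' @param rule one of `"ELDEST_DAUGHTER"`, `"MOST_RECENTLY_CUT_DAUGHTER"`,
#'   `"ALL_DAUGHTERS"`; defaults to the wave's rule via [outcome_rules()].
#' @return data.frame of selected rows with a `y` column; idempotent on
#'   already-harmonized input.
#' @export
harmonize_outcome <- function(rows, rule = NULL) {
  if (nrow(rows) == 0L) {
    rows$y <- integer(0)
    return(rows)
  }
  yr <- unique(rows$survey_year)
  if (length(yr) != 1L)
    stop("harmonize_outcome expects rows from a single survey year")
  if (is.null(rule)) rule <- outcome_rules(yr)[[as.character(yr)]]
  rule <- match.arg(rule, c("ELDEST_DAUGHTER", "MOST_RECENTLY_CUT_DAUGHTER",
                            "ALL_DAUGHTERS"))
  if (any(rows$age_girl < 0 | rows$age_girl > 14))
    stop("daughter age outside 0..14")
  if (!all(rows$cut %in% c(0, 1))) stop("'cut' must be 0/1")

  pick <- switch(rule,
    ELDEST_DAUGHTER = unlist(lapply(split(seq_len(nrow(rows)),
                                          rows$mother_id), function(i) {
      i[which.max(rows$age_girl[i])]
    })),
    MOST_RECENTLY_CUT_DAUGHTER = unlist(lapply(split(seq_len(nrow(rows)),
                                               rows$mother_id), function(i) {
      cut_i <- i[rows$cut[i] == 1]
      if (length(cut_i)) {
        if ("cut_recency" %in% names(rows))
          cut_i[which.max(rows$cut_recency[cut_i])]
        else cut_i[length(cut_i)]
      } else i[which.max(rows$age_girl[i])]
    })),
    ALL_DAUGHTERS = seq_len(nrow(rows))
  )
  out <- rows[sort(unname(pick)), , drop = FALSE]
  out$y <- as.integer(out$cut)
  rownames(out) <- NULL
  out
}

#' Report-only validation of a dataset against a region graph
#'
#' @param ds a `survey_dataset`.
#' @param graph a [region_graph()].
#' @return list with `counts` (records per year x region), `missingness`
#'   (NA share per field), and `unknown_regions` (labels absent from the
#'   graph).  The dataset itself is never modified.
#' @export
validate_dataset <- function(ds, graph) {
  stopifnot(inherits(ds, "survey_dataset"))
  df <- ds$records
  counts <- as.data.frame(table(year = df$survey_year,
                                region = df$region_id),
                          stringsAsFactors = FALSE)
  names(counts)[3] <- "n"
  missingness <- vapply(df[.record_columns], function(x) mean(is.na(x)),
                        numeric(1))
  unknown <- setdiff(unique(as.character(df$region_id)), graph$region_ids)
  structure(list(counts = counts, missingness = missingness,
                 unknown_regions = unknown,
                 n_records = nrow(df)),
            class = "dataset_validation")
}

#' @export
print.dataset_validation <- function(x, ...) {
  cat("dataset validation:", x$n_records, "records\n")
  if (length(x$unknown_regions))
    cat("unknown regions:", paste(x$unknown_regions, collapse = ", "), "\n")
  else cat("all region labels present in graph\n")
  miss <- x$missingness[x$missingness > 0]
  if (length(miss)) {
    cat("missingness:\n")
    for (nm in names(miss)) cat(sprintf("  %s: %.1f%%\n", nm, 100 * miss[nm]))
  }
  invisible(x)
}
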