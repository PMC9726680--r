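#' Compose a scanner identifier from site, machine and protocol
#'
#' A "scanner" is a composite of acquisition site, scanner machine/model and
#' acquisition protocol: two scans count as same-scanner only when all three
#' components agree. The identifier is derived deterministically and is never
#' free-typed.
#'
#' @param site,machine,protocol Character vectors (recycled to common length).
#' @return Character vector `"site|machine|protocol"`.
#' @export
#' @examples
#' make_scanner_id("cambridge", "prisma", "mprage_v1")
make_scanner_id <- function(site, machine, protocol) {
  stopifnot(!anyNA(site), !anyNA(machine), !anyNA(protocol))
  paste(site, machine, protocol, sep = "|")
}

#' Known feature metrics and their admissible value ranges
#' @keywords internal
.metrics <- c("volume", "cortical_thickness", "MD", "FA")

# mandatory per-scan annotation columns in records
.record_cols <- c(
  "subject_id", "scan_id", "site", "machine", "protocol",
  "days_since_first_scan", "age_years", "sex", "icv"
)

#' Construct a validated feature table
#'
#' The canonical container for scan-level imaging features: per-scan
#' annotations (`records`, one row per scan) plus feature values in long
#' format (`values`, one row per scan x feature). One table holds one metric;
#' harmonization is run separately per metric.
#'
#' @param records Data frame with one row per scan and columns `subject_id`,
#'   `scan_id`, `site`, `machine`, `protocol`, `days_since_first_scan`,
#'   `age_years`, `sex` (`"M"`/`"F"`), `icv`, optionally `scanner_id`,
#'   `scan_date`, `group` (`"A"`/`"B"` or `NA`).
#' @param values Data frame with columns `scan_id`, `feature`, `value` in
#'   long format. Every `scan_id` must appear in `records`.
#' @param metric One of `"volume"`, `"cortical_thickness"`, `"MD"`, `"FA"`.
#'   Volumes, thicknesses and MD must be strictly positive; FA must lie in
#'   \[0, 1\].
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(records, values, metric) {
  metric <- match.arg(metric, .metrics)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  values <- as.data.frame(values, stringsAsFactors = FALSE)

  missing_cols <- setdiff(.record_cols, names(records))
  if (length(missing_cols) > 0L) {
    stop("records is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(c("scan_id", "feature", "value") %in% names(values))) {
    stop("values must have columns scan_id, feature, value", call. = FALSE)
  }

  if (is.null(records$scanner_id)) {
    records$scanner_id <-
      make_scanner_id(records$site, records$machine, records$protocol)
  } else {
    derived <- make_scanner_id(records$site, records$machine, records$protocol)
    if (!identical(as.character(records$scanner_id), derived)) {
      stop("scanner_id disagrees with its (site, machine, protocol) components",
           call. = FALSE)
    }
  }
  if (is.null(records$group)) records$group <- NA_character_

  if (anyDuplicated(records$scan_id)) {
    stop("duplicate scan_id in records", call. = FALSE)
  }
  if (anyNA(records$scanner_id)) stop("missing scanner_id", call. = FALSE)
  if (!all(records$sex %in% c("M", "F"))) {
    stop("sex must be coded M/F", call. = FALSE)
  }
  if (any(records$age_years < 0 | records$age_years > 120)) {
    stop("age_years outside [0, 120]", call. = FALSE)
  }
  if (any(records$icv <= 0)) stop("icv must be positive", call. = FALSE)
  if (any(records$days_since_first_scan < 0)) {
    stop("days_since_first_scan must be non-negative", call. = FALSE)
  }
  first <- tapply(records$days_since_first_scan, records$subject_id, min)
  if (any(first != 0)) {
    stop("every subject's earliest scan must have days_since_first_scan == 0; ",
         "violated for subject(s): ",
         paste(names(first)[first != 0], collapse = ", "), call. = FALSE)
  }

  unknown <- setdiff(values$scan_id, records$scan_id)
  if (length(unknown) > 0L) {
    stop("values reference unknown scan_id(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }

  bad <- if (metric == "FA") {
    values$value < 0 | values$value > 1
  } else {
    values$value <= 0
  }
  if (any(bad)) {
    stop("invalid ", metric, " value(s) for scan_id(s): ",
         paste(unique(utils::head(values$scan_id[bad], 5L)), collapse = ", "),
         call. = FALSE)
  }

  # canonical ordering: scans as in records, features alphabetical
  values <- values[order(match(values$scan_id, records$scan_id),
                         values$feature), , drop = FALSE]
  rownames(values) <- NULL
  structure(
    list(records = records, values = values, metric = metric),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> metric=%s: %d scans, %d subjects, %d scanners, %d features\n",
    x$metric, nrow(x$records), length(unique(x$records$subject_id)),
    length(unique(x$records$scanner_id)), length(unique(x$values$feature))
  ))
  invisible(x)
}

#' Feature names of a feature table
#' @param ft A `feature_table`.
#' @return Character vector of feature names, sorted.
#' @export
ft_features <- function(ft) sort(unique(ft$values$feature))

#' Pivot a feature table to the features x scans matrix used by harmonizers
#'
#' Rows are features, columns are scans in the order of `ft$records`.
#'
#' @param ft A `feature_table`.
#' @return Numeric matrix, `dimnames = list(feature, scan_id)`.
#' @export
ft_matrix <- function(ft) {
  feats <- ft_features(ft)
  scans <- ft$records$scan_id
  m <- matrix(NA_real_, nrow = length(feats), ncol = length(scans),
              dimnames = list(feats, scans))
  idx <- cbind(match(ft$values$feature, feats), match(ft$values$scan_id, scans))
  m[idx] <- ft$values$value
  if (anyNA(m)) {
    stop("feature table is not complete: every scan needs every feature",
         call. = FALSE)
  }
  m
}

#' Replace the feature values of a table from a features x scans matrix
#'
#' Inverse of [ft_matrix()]; annotations and row order are preserved.
#'
#' @param ft A `feature_table` providing records and metric.
#' @param m Matrix as returned by [ft_matrix()] (same dimnames).
#' @param validate Re-run range validation on the new values (default TRUE).
#'   Harmonized values can legitimately leave the raw-data range (e.g. an FA
#'   nudged above 1), in which case validation is skipped by the caller.
#' @return A new `feature_table` with identical annotations.
#' @export
ft_with_matrix <- function(ft, m, validate = TRUE) {
  stopifnot(identical(rownames(m), ft_features(ft)),
            identical(colnames(m), ft$records$scan_id))
  long <- data.frame(
    scan_id = rep(colnames(m), each = nrow(m)),
    feature = rep(rownames(m), times = ncol(m)),
    value = as.vector(m),
    stringsAsFactors = FALSE
  )
  if (validate) {
    feature_table(ft$records, long, ft$metric)
  } else {
    out <- ft
    out$values <- long
    out
  }
}

#' Numeric design covariates for a feature table
#'
#' Maps annotation columns to numeric covariates: `sex` becomes a 0/1
#' indicator (F = 0, M = 1), `group` becomes 0/1 (A = 0, B = 1), time is
#' `days_since_first_scan` in days. Other columns pass through.
#'
#' @param ft A `feature_table`.
#' @param covariates Character vector of record column names.
#' @return Numeric matrix with one row per scan (NULL if no covariates).
#' @export
ft_covariate_matrix <- function(ft, covariates) {
  if (is.null(covariates) || length(covariates) == 0L) return(NULL)
  rec <- ft$records
  cols <- lapply(covariates, function(cv) {
    if (!cv %in% names(rec)) {
      stop("unknown covariate column: ", cv, call. = FALSE)
    }
    x <- rec[[cv]]
    if (cv == "sex") as.numeric(x == "M")
    else if (cv == "group") {
      if (anyNA(x)) stop("covariate 'group' contains NA", call. = FALSE)
      as.numeric(x == "B")
    } else as.numeric(x)
  })
  out <- do.call(cbind, cols)
  colnames(out) <- covariates
  rownames(out) <- rec$scan_id
  out
}

#' Read a feature table from a wide CSV/TSV file
#'
#' Expected layout: annotation columns (`subject_id`, `scan_id`, `site`,
#' `machine`, `protocol`, `age_years`, `sex`, `icv`, plus either
#' `scan_date` in ISO-8601 or `days_since_first_scan`), then one column per
#' feature named `metric__roi` (e.g. `volume__brainstem`). `scanner_id` and
#' `days_since_first_scan` are derived when absent.
#'
#' @param path Path to an existing file.
#' @param format `"csv"` or `"tsv"`.
#' @return A validated `feature_table`.
#' @export
read_feature_table <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)

  needed <- setdiff(.record_cols, c("days_since_first_scan"))
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"days_since_first_scan" %in% names(df)) {
    if (!"scan_date" %in% names(df)) {
      stop("missing mandatory column(s): days_since_first_scan (or scan_date)",
           call. = FALSE)
    }
    d <- as.Date(df$scan_date)
    if (anyNA(d)) stop("unparseable scan_date (expect ISO-8601)", call. = FALSE)
    first <- tapply(as.integer(d), df$subject_id, min)
    df$days_since_first_scan <-
      as.integer(d) - as.integer(first[as.character(df$subject_id)])
  }

  feat_cols <- grep("^[A-Za-z_]+__", names(df), value = TRUE)
  if (length(feat_cols) == 0L) {
    stop("no feature columns found (expected names like 'volume__brainstem')",
         call. = FALSE)
  }
  metric <- unique(sub("__.*$", "", feat_cols))
  if (length(metric) != 1L) {
    stop("one metric per table: found ", paste(metric, collapse = ", "),
         call. = FALSE)
  }

  anno_cols <- intersect(
    c(.record_cols, "scanner_id", "scan_date", "group"), names(df))
  records <- df[, anno_cols, drop = FALSE]
  values <- data.frame(
    scan_id = rep(df$scan_id, times = length(feat_cols)),
    feature = rep(feat_cols, each = nrow(df)),
    value = unlist(df[feat_cols], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  feature_table(records, values, metric)
}

#' Write a feature table to a wide CSV/TSV file
#'
#' Inverse of [read_feature_table()]: one row per scan, annotation columns
#' followed by one column per feature.
#'
#' @param ft A `feature_table`.
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  m <- ft_matrix(ft)
  wide <- cbind(ft$records, as.data.frame(t(m), check.names = FALSE))
  sep <- if (format == "csv") "," else "\t"
  utils::write.table(wide, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a tabular report to CSV or JSON
#'
#' Lossless serialization of the data-frame reports produced by the
#' validation stages; [read_report()] round-trips the result.
#'
#' @param report A data frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  report <- as.data.frame(report, stringsAsFactors = FALSE)
  if (format == "csv") {
    utils::write.table(report, path, sep = ",", row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(report, path, digits = NA, dataframe = "rows",
                         na = "null")
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::read.table(path, header = TRUE, sep = ",",
                      stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}

#' Derive the three travelling-subject cohorts from a feature table
#'
#' Applies the inclusion rules of a scan-rescan validation design:
#' * within-scanner pairs: same subject, same scanner, interval strictly
#'   less than `pair_window_days`;
#' * across-scanner pairs: same subject, different scanners, interval
#'   strictly less than `pair_window_days`;
#' * longitudinal triplets: a reference scan plus two follow-ups strictly
#'   more than `followup_min_days` after it, one sharing the reference's
#'   scanner and one not.
#'
#' A subject contributes at most one pair per cohort (the shortest-interval
#' qualifying pair; ties broken by earliest scan date, then lexicographic
#' scan_id) but may appear in several cohorts. The function is pure: identical inputs
#' give identical cohorts.
#'
#' @param ft A `feature_table`.
#' @param pair_window_days Strict upper bound on pair intervals (days).
#' @param followup_min_days Strict lower bound on follow-up delay (days).
#' @return A list of class `travelling_cohorts` with elements
#'   `within_pairs`, `across_pairs` (two-column data frames `scan1`,
#'   `scan2`) and `longitudinal_triplets` (data frame `reference`,
#'   `within_followup`, `across_followup`).
#' @export
derive_cohorts <- function(ft, pair_window_days = 180,
                           followup_min_days = 365) {
  rec <- ft$records
  empty_pair <- data.frame(scan1 = character(0), scan2 = character(0),
                           stringsAsFactors = FALSE)
  within <- across <- empty_pair
  trips <- data.frame(reference = character(0), within_followup = character(0),
                      across_followup = character(0), stringsAsFactors = FALSE)

  for (sub in sort(unique(rec$subject_id))) {
    rs <- rec[rec$subject_id == sub, , drop = FALSE]
    # deterministic scan order: day then scan_id
    rs <- rs[order(rs$days_since_first_scan, rs$scan_id), , drop = FALSE]
    n <- nrow(rs)
    if (n < 2L) next

    pairs <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        gap <- rs$days_since_first_scan[j] - rs$days_since_first_scan[i]
        if (gap < pair_window_days) {
          pairs <- rbind(pairs, data.frame(
            scan1 = rs$scan_id[i], scan2 = rs$scan_id[j],
            day1 = rs$days_since_first_scan[i], gap = gap,
            same = rs$scanner_id[i] == rs$scanner_id[j],
            stringsAsFactors = FALSE))
        }
      }
    }
    if (!is.null(pairs)) {
      pairs <- pairs[order(pairs$gap, pairs$day1, pairs$scan1, pairs$scan2), ,
                     drop = FALSE]
      w <- pairs[pairs$same, , drop = FALSE]
      if (nrow(w) > 0L) within <- rbind(within, w[1L, c("scan1", "scan2")])
      a <- pairs[!pairs$same, , drop = FALSE]
      if (nrow(a) > 0L) across <- rbind(across, a[1L, c("scan1", "scan2")])
    }

    # longitudinal triplet: reference = earliest scan
    ref <- rs[1L, ]
    fu <- rs[rs$days_since_first_scan - ref$days_since_first_scan >
               followup_min_days, , drop = FALSE]
    if (nrow(fu) >= 2L) {
      fw <- fu[fu$scanner_id == ref$scanner_id, , drop = FALSE]
      fa <- fu[fu$scanner_id != ref$scanner_id, , drop = FALSE]
      if (nrow(fw) > 0L && nrow(fa) > 0L) {
        trips <- rbind(trips, data.frame(
          reference = ref$scan_id,
          within_followup = fw$scan_id[1L],
          across_followup = fa$scan_id[1L],
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(within) <- rownames(across) <- rownames(trips) <- NULL
  structure(
    list(within_pairs = within, across_pairs = across,
         longitudinal_triplets = trips),
    class = "travelling_cohorts"
  )
}

#' @export
print.travelling_cohorts <- function(x, ...) {
  cat(sprintf(
    "<travelling_cohorts> %d within-scanner pairs, %d across-scanner pairs, %d longitudinal triplets\n",
    nrow(x$within_pairs), nrow(x$across_pairs), nrow(x$longitudinal_triplets)))
  invisible(x)
}
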