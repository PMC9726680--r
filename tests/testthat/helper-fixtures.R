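# small constructed fixtures shared across tests

# minimal records data frame; days/scanner per scan supplied by caller
make_records <- function(subject, scan, scanner = 1L, day = 0L,
                         age = 50, sex = "F", icv = 1.5e6) {
  n <- length(scan)
  data.frame(
    subject_id = rep_len(subject, n), scan_id = scan,
    site = "site", machine = paste0("scanner", rep_len(scanner, n)),
    protocol = "prot",
    days_since_first_scan = rep_len(day, n),
    age_years = rep_len(age, n), sex = rep_len(sex, n),
    icv = rep_len(icv, n), stringsAsFactors = FALSE)
}

# feature table from a features x scans matrix plus records
ft_from_matrix <- function(records, m, metric = "volume") {
  values <- data.frame(
    scan_id = rep(colnames(m), each = nrow(m)),
    feature = rep(rownames(m), times = ncol(m)),
    value = as.vector(m), stringsAsFactors = FALSE)
  feature_table(records, values, metric)
}

# the classic two-batch toy instance: one feature, batches {1,2,3}, {11,12,13}
toy_two_batch <- function() {
  rec <- make_records(paste0("s", 1:6), paste0("sc", 1:6),
                      scanner = rep(1:2, each = 3))
  m <- matrix(c(1, 2, 3, 11, 12, 13), nrow = 1,
              dimnames = list("volume__roi", rec$scan_id))
  ft_from_matrix(rec, m)
}

# small multi-feature two-batch instance with distinct values, n = 6 scans
toy_three_feature <- function(seed = 42) {
  set.seed(seed)
  rec <- make_records(paste0("s", 1:6), paste0("sc", 1:6),
                      scanner = rep(1:2, each = 3))
  m <- matrix(100 + rnorm(18, sd = 5), nrow = 3,
              dimnames = list(paste0("volume__f", 1:3), rec$scan_id))
  m[, 4:6] <- m[, 4:6] + c(3, -2, 1)   # batch-2 offsets per feature
  ft_from_matrix(rec, m)
}

std_covariates <- c("age_years", "sex", "icv", "days_since_first_scan")

# quiet wrappers: boundary-variance warnings are expected in small fixtures
quiet_longcombat <- function(...) {
  suppressWarnings(harmonize_longcombat(...))
}
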