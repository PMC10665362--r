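# Sample tables are plain data.frames in a fixed CSV dialect:
# columns `sample_id,type,age_months,<abeta columns...>,<feature columns...>`
# (comma separated, header row, '.' decimal, empty cell = missing).
# Abeta columns are those whose name starts with "abeta"; all remaining
# columns are biomarker features.

abeta_columns <- function(tab) grep("^abeta", names(tab), value = TRUE)

feature_columns <- function(tab) {
  setdiff(names(tab), c("sample_id", "type", "age_months",
                        abeta_columns(tab)))
}

#' Read a sample table
#'
#' @param path path to a CSV file in the package's sample-table dialect.
#' @return A validated data.frame (unique ids, known type labels,
#'   positive numeric ages; missing cells are `NA`).
#' @export
read_samples_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  validate_samples_table(tab)
}

validate_samples_table <- function(tab) {
  need <- c("sample_id", "type", "age_months")
  if (!all(need %in% names(tab)))
    stop("sample table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample ids in table", call. = FALSE)
  if (!all(tab$type %in% c("WT", "AD")))
    stop("unknown type labels: ",
         paste(unique(setdiff(tab$type, c("WT", "AD"))), collapse = ", "),
         call. = FALSE)
  if (!is.numeric(tab$age_months) || any(!is.finite(tab$age_months)))
    stop("ages must be numeric and finite", call. = FALSE)
  for (cn in c(abeta_columns(tab), feature_columns(tab)))
    if (!is.numeric(tab[[cn]]) && !all(is.na(tab[[cn]])))
      stop("column '", cn, "' is not numeric", call. = FALSE)
  tab
}

#' Write a sample table
#'
#' Numeric cells are written with 17 significant digits so that a
#' write/read round trip reproduces doubles bit-identically; missing
#' cells are empty.
#'
#' @param tab a sample table data.frame.
#' @param path output CSV path.
#' @export
write_samples_table <- function(tab, path) {
  out <- tab
  for (cn in names(out)) {
    if (is.numeric(out[[cn]])) {
      v <- sprintf("%.17g", out[[cn]])
      v[is.na(out[[cn]])] <- ""
      out[[cn]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Convert a generated study to a sample table
#'
#' @param study output of [generate_synthetic_study()].
#' @param abeta_column name used for the Abeta column.
#' @return A sample table data.frame.
#' @export
study_to_table <- function(study, abeta_column = "abeta40") {
  ds <- study$dataset
  tab <- data.frame(sample_id = ds$id, type = ds$type,
                    age_months = ds$age, check.names = FALSE)
  tab[[abeta_column]] <- ds$y
  if (ds$L > 0) {
    feats <- as.data.frame(ds$X)
    names(feats) <- colnames(ds$X)
    tab <- cbind(tab, feats)
  }
  tab
}

#' Standardize biomarker features
#'
#' Rescales every feature column to mean 0, sd 1 (population sd, i.e.
#' divisor `n`) over the fit subset; the fitted transform is recorded in
#' the report and can be re-applied with [apply_preprocess()].
#'
#' @param tab a sample table.
#' @param fit_on optional character vector of sample ids the transform is
#'   fitted on; default: all rows carrying the feature.
#' @return A list with elements `table` and `report`.
#' @export
standardize_features <- function(tab, fit_on = NULL) {
  feats <- feature_columns(tab)
  stats_df <- data.frame(feature = feats, mean = NA_real_, sd = NA_real_,
                         stringsAsFactors = FALSE)
  for (i in seq_along(feats)) {
    cn <- feats[i]
    sel <- !is.na(tab[[cn]])
    if (!is.null(fit_on)) sel <- sel & tab$sample_id %in% fit_on
    v <- tab[[cn]][sel]
    if (length(v) < 2) stop("need >= 2 observations of feature '", cn, "'",
                            call. = FALSE)
    m <- mean(v); s <- sqrt(mean((v - m)^2))
    if (s <= 0) stop("zero-variance feature: '", cn, "'", call. = FALSE)
    tab[[cn]] <- (tab[[cn]] - m) / s
    stats_df$mean[i] <- m; stats_df$sd[i] <- s
  }
  report <- structure(list(kind = "standardize", feature_stats = stats_df),
                      class = "preprocess_report")
  list(table = tab, report = report)
}

#' Scale Abeta columns to a reference age
#'
#' Divides each Abeta column by its maximum observed value among samples
#' of the reference age, so that maximum maps to exactly 1.0. Values at
#' other ages may exceed 1 after scaling.
#'
#' @param tab a sample table.
#' @param reference_age age (months) whose maximum defines the divisor.
#' @return A list with elements `table` and `report`.
#' @export
scale_abeta <- function(tab, reference_age = 12) {
  cols <- abeta_columns(tab)
  div <- stats::setNames(numeric(length(cols)), cols)
  for (cn in cols) {
    sel <- tab$age_months == reference_age & !is.na(tab[[cn]])
    if (!any(sel))
      stop("no observation of '", cn, "' at reference age ",
           reference_age, call. = FALSE)
    d <- max(tab[[cn]][sel])
    if (d <= 0) stop("non-positive divisor for '", cn, "'", call. = FALSE)
    tab[[cn]] <- tab[[cn]] / d
    div[cn] <- d
  }
  report <- structure(list(kind = "scale_abeta", divisors = div,
                           reference_age = reference_age),
                      class = "preprocess_report")
  list(table = tab, report = report)
}

#' Re-apply a recorded preprocessing transform
#'
#' @param tab a raw sample table.
#' @param report a `preprocess_report` from [standardize_features()] or
#'   [scale_abeta()].
#' @return The transformed table.
#' @export
apply_preprocess <- function(tab, report) {
  stopifnot(inherits(report, "preprocess_report"))
  if (report$kind == "standardize") {
    st <- report$feature_stats
    for (i in seq_len(nrow(st)))
      tab[[st$feature[i]]] <- (tab[[st$feature[i]]] - st$mean[i]) / st$sd[i]
  } else if (report$kind == "scale_abeta") {
    for (cn in names(report$divisors))
      tab[[cn]] <- tab[[cn]] / report$divisors[[cn]]
  } else stop("unknown report kind: ", report$kind)
  tab
}

#' Add virtual wild-type Abeta observations
#'
#' WT animals are assumed to carry no detectable insoluble Abeta over
#' their lifespan, so zero-valued Abeta observations can be added
#' virtually. With `paired = FALSE`, `n_per_age` new Abeta-only WT rows
#' (all Abeta columns 0) are created at each given age. With
#' `paired = TRUE`, zero Abeta values are attached to existing
#' feature-bearing WT rows instead (creating virtual paired samples);
#' `n_paired` rows are selected at random, defaulting to all eligible.
#'
#' @param tab a sample table.
#' @param ages ages (months) of the virtual observations.
#' @param n_per_age new rows per age when `paired = FALSE`.
#' @param paired attach zeros to existing WT feature rows instead?
#' @param n_paired number of WT rows to pair when `paired = TRUE`.
#' @param seed seed for the random selection when `paired = TRUE`.
#' @return The augmented table.
#' @export
augment_virtual_wt <- function(tab, ages = c(8, 12, 18), n_per_age = 3,
                               paired = FALSE, n_paired = NULL,
                               seed = NULL) {
  stopifnot(n_per_age >= 0)
  acols <- abeta_columns(tab)
  if (!paired) {
    if (n_per_age == 0) return(tab)
    new_rows <- do.call(rbind, lapply(ages, function(a) {
      r <- tab[rep(NA_integer_, n_per_age), , drop = FALSE]
      r$sample_id <- sprintf("vWT_a%g_%02d", a, seq_len(n_per_age))
      r$type <- "WT"; r$age_months <- a
      for (cn in acols) r[[cn]] <- 0
      r
    }))
    rownames(new_rows) <- NULL
    out <- rbind(tab, new_rows)
    rownames(out) <- NULL
    return(out)
  }
  feats <- feature_columns(tab)
  has_x <- rowSums(!is.na(tab[, feats, drop = FALSE])) > 0
  eligible <- which(tab$type == "WT" & has_x)
  if (is.null(n_paired)) n_paired <- length(eligible)
  if (n_paired > length(eligible))
    stop("requested ", n_paired, " virtual paired WT samples but only ",
         length(eligible), " eligible rows", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pick <- if (n_paired == length(eligible)) eligible
          else sample(eligible, n_paired)
  for (cn in acols) tab[[cn]][pick] <- 0
  tab
}

#' Assemble a dataset from a sample table
#'
#' Builds an [ab_dataset] using one Abeta column as the target `y`.
#' Samples in `exclusions` are dropped from the paired role only: if such
#' a sample carries biomarker features, its Abeta value is removed and
#' its features are kept as unpaired data.
#'
#' @param tab a (preprocessed) sample table.
#' @param target_column name of the Abeta column used as `y`.
#' @param exclusions sample ids excluded from the paired role.
#' @return An [ab_dataset].
#' @export
assemble_dataset <- function(tab, target_column = "abeta40",
                             exclusions = character(0)) {
  if (!target_column %in% abeta_columns(tab))
    stop("unknown target column: '", target_column, "'", call. = FALSE)
  feats <- feature_columns(tab)
  X <- as.matrix(tab[, feats, drop = FALSE])
  rownames(X) <- NULL
  y <- tab[[target_column]]
  has_x <- if (length(feats)) rowSums(!is.na(X)) > 0 else rep(FALSE, nrow(tab))
  drop_y <- tab$sample_id %in% exclusions & has_x & !is.na(y)
  y[drop_y] <- NA_real_
  keep <- !is.na(y) | has_x
  if (!all(keep))
    stop("row(s) with neither Abeta nor features: ",
         paste(tab$sample_id[!keep], collapse = ", "), call. = FALSE)
  ab_dataset(tab$sample_id, tab$type, tab$age_months, y, X)
}
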