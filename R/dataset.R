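#' Assemble a model-ready dataset
#'
#' Collects per-animal snapshot observations into the partitioned form
#' the learning procedure consumes: the set `S_y` of samples with an
#' Abeta measurement, the set `S_X` of samples with a biomarker vector,
#' and their intersection `S_XY` (paired samples).
#'
#' @param id character vector of unique sample ids.
#' @param type character or factor, `"WT"` or `"AD"`.
#' @param age positive ages in months.
#' @param y numeric Abeta observations (scaled); `NA` where unobserved.
#' @param X numeric matrix of biomarker candidates, one row per sample;
#'   a row of all `NA` marks an unobserved vector. `NULL` if no sample
#'   carries biomarkers.
#' @return An object of class `"ab_dataset"` with elements `id`, `type`,
#'   `age`, `y`, `X`, `L`, the index sets `S_y`, `S_X`, `S_XY`, and the
#'   counts `N_y`, `N_X`.
#' @export
ab_dataset <- function(id, type, age, y = NULL, X = NULL) {
  id <- as.character(id)
  n <- length(id)
  if (anyDuplicated(id)) stop("duplicate sample ids", call. = FALSE)
  type <- as.character(type)
  if (!all(type %in% c("WT", "AD")))
    stop("'type' must be 'WT' or 'AD'", call. = FALSE)
  age <- as.numeric(age)
  if (any(!is.finite(age)) || any(age <= 0))
    stop("ages must be finite and > 0", call. = FALSE)
  stopifnot(length(type) == n, length(age) == n)
  if (is.null(y)) y <- rep(NA_real_, n)
  stopifnot(length(y) == n)
  if (is.null(X)) X <- matrix(NA_real_, n, 0)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  has_x <- if (ncol(X) > 0) apply(X, 1L, function(r) !all(is.na(r)))
           else rep(FALSE, n)
  if (any(has_x) && any(is.na(X[has_x, , drop = FALSE])))
    stop("biomarker vectors must be fully observed or fully missing",
         call. = FALSE)
  has_y <- !is.na(y)
  if (any(!has_y & !has_x))
    stop("every sample needs at least one of y, x", call. = FALSE)
  structure(list(
    id = id, type = type, age = age, y = as.numeric(y), X = X,
    L = ncol(X),
    S_y = which(has_y), S_X = which(has_x),
    S_XY = which(has_y & has_x),
    N_y = sum(has_y), N_X = sum(has_x)
  ), class = "ab_dataset")
}

#' @export
print.ab_dataset <- function(x, ...) {
  cat(sprintf(
    "Abeta/biomarker dataset: %d samples (%d WT, %d AD), L = %d features\n",
    length(x$id), sum(x$type == "WT"), sum(x$type == "AD"), x$L))
  cat(sprintf("  Abeta-observed |S_y| = %d, biomarker-observed |S_X| = %d, paired |S_XY| = %d\n",
              x$N_y, x$N_X, length(x$S_XY)))
  invisible(x)
}

#' Subset a dataset by sample index
#'
#' @param ds an [ab_dataset].
#' @param idx integer indices or logical mask of samples to keep.
#' @return A new [ab_dataset] containing only the selected samples.
#' @export
dataset_subset <- function(ds, idx) {
  ab_dataset(ds$id[idx], ds$type[idx], ds$age[idx], ds$y[idx],
             ds$X[idx, , drop = FALSE])
}

#' Mask Abeta labels of selected samples
#'
#' Removes the `y` observation of the given samples, demoting paired
#' samples to biomarker-only; their biomarker vectors are untouched.
#' Used by the supervised-ratio experiments.
#'
#' @param ds an [ab_dataset].
#' @param ids sample ids whose `y` should be dropped.
#' @return A new [ab_dataset].
#' @export
mask_labels <- function(ds, ids) {
  drop <- ds$id %in% ids
  y <- ds$y
  y[drop] <- NA_real_
  ab_dataset(ds$id, ds$type, ds$age, y, ds$X)
}

# one-hot -> column index (WT = 1, AD = 2)
type_index <- function(type) ifelse(type == "WT", 1L, 2L)
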