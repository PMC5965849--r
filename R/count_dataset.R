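#' Count regression dataset
#'
#' Container for a count-regression problem: a non-negative integer response
#' (event counts per observation unit, e.g. crashes per highway segment), a
#' covariate matrix, and an optional exposure offset that enters the linear
#' predictor with coefficient fixed at 1 (e.g. log of ten times segment
#' length).
#'
#' @param y non-negative integer response vector.
#' @param X numeric covariate matrix, one row per observation; typically
#'   includes a leading intercept column of ones named `"(Intercept)"`.
#' @param offset optional numeric vector added to the linear predictor.
#' @param names optional covariate labels; defaults to `colnames(X)`.
#' @return An object of class `"count_dataset"` with fields `y`, `X`,
#'   `offset`, `names`, `N`.
#' @examples
#' d <- count_dataset(y = c(0L, 2L, 5L),
#'                    X = cbind("(Intercept)" = 1, x = c(0.5, 1.2, 3.0)))
#' @export
count_dataset <- function(y, X, offset = NULL, names = NULL) {
  y <- as.numeric(y)
  if (length(y) < 1L || any(!is.finite(y)) || any(y < 0) ||
      any(y != round(y))) {
    stop("'y' must be non-negative integer counts", call. = FALSE)
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != length(y)) {
    stop("nrow(X) must equal length(y)", call. = FALSE)
  }
  if (any(!is.finite(X))) stop("'X' must be finite", call. = FALSE)
  if (is.null(names)) {
    names <- colnames(X)
    if (is.null(names)) names <- paste0("x", seq_len(ncol(X)))
  }
  if (length(names) != ncol(X)) {
    stop("'names' must have one label per covariate column", call. = FALSE)
  }
  colnames(X) <- names
  if (!is.null(offset)) {
    offset <- as.numeric(offset)
    if (length(offset) != length(y) || any(!is.finite(offset))) {
      stop("'offset' must be finite and the same length as 'y'",
           call. = FALSE)
    }
  }
  structure(
    list(y = y, X = X, offset = offset, names = names, N = length(y)),
    class = "count_dataset"
  )
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("count_dataset: %d observations, %d covariates%s\n",
              x$N, ncol(x$X),
              if (is.null(x$offset)) "" else ", with offset"))
  cat("  covariates:", paste(x$names, collapse = ", "), "\n")
  cat(sprintf("  response: mean %.4g, var %.4g, max %g\n",
              mean(x$y), stats::var(x$y), max(x$y)))
  invisible(x)
}

# index of the intercept column (constant 1), or NA if none
intercept_column <- function(data) {
  cols <- which(apply(data$X, 2L, function(v) all(v == 1)))
  if (length(cols)) cols[1L] else NA_integer_
}

dataset_offset <- function(data) {
  if (is.null(data$offset)) rep(0, data$N) else data$offset
}
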