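# Container for a binary-response regression dataset.

#' Binary regression dataset
#'
#' Bundles a 0/1 response with a design matrix (intercept column prepended),
#' covariate names and optional standardization metadata (the per-covariate
#' mean and sd used to z-score the columns, needed later to predict at raw
#' covariate values).
#'
#' @param y binary response vector (0/1, no missing values).
#' @param x covariate matrix or data.frame (no intercept column), or NULL
#'   for an intercept-only model.
#' @param covariate_names optional character vector of covariate names;
#'   defaults to the column names of `x`.
#' @param standardization optional data.frame with columns `name`, `mean`,
#'   `sd` recording how covariates were z-scored.
#' @return object of class `binary_dataset` with fields `y`, `X` (n x k
#'   design matrix including the intercept), `covariate_names`,
#'   `standardization`, `n`, `k`.
#' @examples
#' d <- binary_dataset(c(0, 1, 1), x = cbind(x1 = c(-1, 0, 1)))
#' d$X
#' @export
binary_dataset <- function(y, x = NULL, covariate_names = NULL,
                           standardization = NULL) {
  y <- as.numeric(y)
  if (anyNA(y)) stop("`y` contains missing values", call. = FALSE)
  if (length(y) && !all(y %in% c(0, 1)))
    stop("`y` must contain only 0 and 1", call. = FALSE)
  n <- length(y)
  if (is.null(x)) {
    X <- matrix(1, nrow = n, ncol = 1)
    covariate_names <- character(0)
  } else {
    x <- as.matrix(x)
    if (anyNA(x)) stop("covariates contain missing values", call. = FALSE)
    if (nrow(x) != n) stop("`y` and `x` have different lengths", call. = FALSE)
    if (is.null(covariate_names)) {
      covariate_names <- colnames(x)
      if (is.null(covariate_names))
        covariate_names <- paste0("x", seq_len(ncol(x)))
    }
    X <- cbind(1, unname(x))
  }
  k <- ncol(X)
  colnames(X) <- c("(Intercept)", covariate_names)
  structure(list(y = y, X = X, covariate_names = covariate_names,
                 standardization = standardization, n = n, k = k),
            class = "binary_dataset")
}

#' @export
print.binary_dataset <- function(x, ...) {
  cat(sprintf("<binary_dataset: n = %d, %d covariate(s)%s, %.1f%% successes>\n",
              x$n, length(x$covariate_names),
              if (!is.null(x$standardization)) ", standardized" else "",
              if (x$n) 100 * mean(x$y) else NA_real_))
  invisible(x)
}
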