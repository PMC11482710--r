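# Application workflow: CSV ingestion, standardization, correlation
# screening, point prediction at raw covariate values, effect curves and
# class-conditional predictive summaries.

#' Load a binary-response CSV dataset
#'
#' Reads a header CSV, validates the response (binary, no missing values),
#' and optionally z-scores every covariate, storing the standardization
#' constants so later predictions can be made at raw covariate values.
#'
#' @param path CSV file path.
#' @param response name of the binary response column.
#' @param standardize z-score the covariates (default TRUE).
#' @return a [binary_dataset()] with `standardization` filled in when
#'   `standardize = TRUE`.
#' @export
load_binary_csv <- function(path, response, standardize = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!response %in% names(df))
    stop("response column '", response, "' not found", call. = FALSE)
  y <- df[[response]]
  x <- df[setdiff(names(df), response)]
  if (anyNA(y) || anyNA(x))
    stop("dataset contains missing values", call. = FALSE)
  if (!all(y %in% c(0, 1)))
    stop("response column '", response, "' is not binary 0/1", call. = FALSE)
  if (!all(vapply(x, is.numeric, TRUE)))
    stop("all covariates must be numeric", call. = FALSE)
  x <- as.matrix(x)
  std <- NULL
  if (standardize && ncol(x) > 0) {
    mu <- colMeans(x)
    sd_ <- apply(x, 2, stats::sd)
    if (any(sd_ == 0))
      stop("covariate(s) with zero standard deviation: ",
           paste(colnames(x)[sd_ == 0], collapse = ", "), call. = FALSE)
    x <- sweep(sweep(x, 2, mu), 2, sd_, "/")
    std <- data.frame(name = colnames(x), mean = unname(mu),
                      sd = unname(sd_))
  }
  binary_dataset(y, x, standardization = std)
}

#' Correlation screening of covariates
#'
#' Finds pairs of covariates whose absolute Pearson correlation reaches
#' `threshold` and drops one member of each pair: the one with the larger
#' mean absolute correlation with the remaining covariates (ties broken by
#' column order).  Repeats until no offending pair remains.
#'
#' @param data a [binary_dataset()] with at least 2 covariates.
#' @param threshold absolute correlation at which a pair is acted on
#'   (default 0.95).
#' @return list of class `preprocess_report`: `data` (screened dataset,
#'   standardization metadata subset accordingly), `dropped` (data.frame
#'   with the dropped covariate, its partner and their correlation) and
#'   `kept` (character vector).
#' @export
correlation_screen <- function(data, threshold = 0.95) {
  stopifnot(inherits(data, "binary_dataset"))
  covs <- data$covariate_names
  if (length(covs) < 2)
    stop("need at least two covariates to screen", call. = FALSE)
  x <- data$X[, -1L, drop = FALSE]
  colnames(x) <- covs
  keep <- covs
  dropped <- data.frame(dropped = character(0), partner = character(0),
                        r = numeric(0))
  repeat {
    cm <- stats::cor(x[, keep, drop = FALSE])
    am <- abs(cm); diag(am) <- 0
    if (all(am < threshold) || length(keep) < 2) break
    ij <- which(am == max(am), arr.ind = TRUE)[1L, ]
    pair <- keep[ij]
    # mean |r| of each member against all other retained covariates
    score <- vapply(pair, function(v)
      mean(am[v, setdiff(keep, v)]), 0)
    drop_v <- pair[which.max(score)]        # which.max keeps first on ties
    partner <- setdiff(pair, drop_v)[1L]
    dropped <- rbind(dropped, data.frame(
      dropped = drop_v, partner = partner,
      r = cm[drop_v, partner]))
    keep <- setdiff(keep, drop_v)
  }
  std <- data$standardization
  if (!is.null(std)) std <- std[std$name %in% keep, , drop = FALSE]
  out_data <- binary_dataset(data$y, x[, keep, drop = FALSE],
                             standardization = std)
  structure(list(data = out_data, dropped = dropped, kept = keep),
            class = "preprocess_report")
}

.standardize_value <- function(value, name, standardization) {
  if (is.null(standardization)) return(value)
  row <- match(name, standardization$name)
  if (is.na(row))
    stop("no standardization constants stored for '", name, "'",
         call. = FALSE)
  (value - standardization$mean[row]) / standardization$sd[row]
}

#' Predict a success probability at raw covariate values
#'
#' Plug-in prediction from point estimates: covariates named in `values`
#' are standardized with the stored constants, all others are held at
#' their mean (standardized 0), the linear predictor is formed and mapped
#' through the link.
#'
#' @param beta coefficient vector (intercept first), on the standardized
#'   scale; typically posterior means.
#' @param lam asymmetry parameter for power links (posterior mean of
#'   exp(delta)); NULL otherwise.
#' @param link a [lomax_link()] or a link name.
#' @param values named list/vector of raw covariate values; unnamed
#'   covariates sit at their mean.
#' @param covariate_names covariate names matching `beta[-1]`.
#' @param standardization data.frame with `name`, `mean`, `sd` (as stored
#'   by [load_binary_csv()]); NULL means `values` are already on the model
#'   scale.
#' @return scalar success probability.
#' @examples
#' # fitted Wilt-type model from printed summaries: P(diseased) at
#' # Mean_R = 90, other covariates at their means
#' std <- data.frame(name = c("GLCM_Pan", "Mean_R", "Mean_NIR", "SD_Pan"),
#'                   mean = c(127.07, 107.74, 453.70, 20.64),
#'                   sd = c(10.67, 71.77, 156.20, 6.76))
#' predict_at(c(26.110, 1.142, 137.094, -19.340, 0.206), lam = 0.256,
#'            link = "rpdlomax", values = c(Mean_R = 90),
#'            covariate_names = std$name, standardization = std)
#' @export
predict_at <- function(beta, lam = NULL, link, values = list(),
                       covariate_names, standardization = NULL) {
  if (is.character(link)) link <- lomax_link(link, lambda = lam)
  else if (!is.null(lam) && link$has_lambda)
    link <- lomax_link(link$name, lambda = lam)
  if (length(beta) != length(covariate_names) + 1L)
    stop("`beta` must have one more element than `covariate_names`",
         call. = FALSE)
  values <- as.list(values)
  bad <- setdiff(names(values), covariate_names)
  if (length(bad))
    stop("unknown covariate(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  z <- numeric(length(covariate_names))     # at-mean => standardized 0
  for (nm in names(values))
    z[match(nm, covariate_names)] <-
      .standardize_value(values[[nm]], nm, standardization)
  eta <- beta[1L] + sum(beta[-1L] * z)
  unname(link_prob(eta, link))
}

#' Effect curve of one covariate on the success probability
#'
#' Varies one covariate over a grid (raw scale) while holding the others
#' at their means, and evaluates the plug-in success probability at each
#' grid point.
#'
#' @inheritParams predict_at
#' @param covariate name of the covariate to vary.
#' @param grid numeric vector of raw values for that covariate.
#' @return data.frame with columns `value` and `prob`.
#' @export
effect_curve <- function(beta, lam = NULL, link, covariate, grid,
                         covariate_names, standardization = NULL) {
  if (!covariate %in% covariate_names)
    stop("unknown covariate '", covariate, "'", call. = FALSE)
  prob <- vapply(grid, function(v)
    predict_at(beta, lam, link, stats::setNames(list(v), covariate),
               covariate_names, standardization), 0)
  data.frame(value = grid, prob = prob)
}

#' Class-conditional summaries of mean predictive probabilities
#'
#' Splits the per-observation posterior-mean predictive probabilities by
#' the observed class and reports min, first quartile, median, mean, third
#' quartile and max for each class.  A well-separating model gives clearly
#' higher probabilities to the observed successes.
#'
#' @param fit a [fit_binreg()] result.
#' @return data.frame with one row per observed class (`success`,
#'   `failure`) and columns `min`, `q1`, `median`, `mean`, `q3`, `max`,
#'   `n`.
#' @export
class_predictive_summary <- function(fit) {
  p_hat <- predict_prob(fit)$mean
  y <- fit$data$y
  if (length(unique(y)) < 2)
    warning("only one class observed; returning its summary only")
  rows <- lapply(c(success = 1, failure = 0), function(cls) {
    p <- p_hat[y == cls]
    if (!length(p)) return(NULL)
    q <- stats::quantile(p, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(class = if (cls == 1) "success" else "failure",
               min = min(p), q1 = q[1], median = q[2], mean = mean(p),
               q3 = q[3], max = max(p), n = length(p))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
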