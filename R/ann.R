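# Run expr with a reproducible RNG state, restoring the caller's state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Min-max normalization
#'
#' Inputs and target of the preference network are mapped to \[0, 1\] by
#' `(a - amin) / (amax - amin)` over each variable's observed (or
#' configured) range; `unscale_minmax()` inverts the map exactly.
#'
#' @param x numeric matrix (or vector, treated as one column).
#' @return `fit_scaler()`: list of class `"minmax_scaler"` with per-column
#'   `min` and `max`.
#' @examples
#' sc <- fit_scaler(cbind(a = 0:10))
#' scale_minmax(cbind(a = 5), sc)
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  mn <- apply(x, 2, min)
  mx <- apply(x, 2, max)
  if (any(mx <= mn))
    stop("cannot scale constant column(s): ",
         paste(colnames(x)[mx <= mn], collapse = ", "))
  structure(list(min = mn, max = mx), class = "minmax_scaler")
}

#' @rdname fit_scaler
#' @param scaler a fitted `"minmax_scaler"`.
#' @export
scale_minmax <- function(x, scaler) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaler$min), 2, scaler$max - scaler$min, `/`)
}

#' @rdname fit_scaler
#' @export
unscale_minmax <- function(x, scaler) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaler$max - scaler$min, `*`), 2, scaler$min, `+`)
}

#' Reproducible train/validation/test partition
#'
#' Sizes follow largest-remainder rounding of `n * fractions` (so a 70/15/15
#' split of 27 rows gives 19/4/4), and the assignment of rows to subsets is
#' a seeded random permutation.
#'
#' @param n number of rows (>= 3).
#' @param fractions nonnegative split fractions summing to 1; default the
#'   conventional 70/15/15.
#' @param seed integer seed.
#' @return list with integer index vectors `train`, `validation`, `test`.
#' @examples
#' lengths(split_data(27, seed = 1))
#' @export
split_data <- function(n, fractions = c(train = 0.70, validation = 0.15,
                                        test = 0.15), seed = 1) {
  if (n < 3) stop("need at least three rows to split")
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be >= 0 and sum to 1")
  target <- n * fractions
  sizes <- floor(target)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(target - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  idx <- .with_seed(seed, sample.int(n))
  out <- split(idx, factor(rep(c("train", "validation", "test"), sizes),
                           levels = c("train", "validation", "test")))
  lapply(out, as.integer)
}

#' Train the hedonic preference network
#'
#' A single-hidden-layer feed-forward network (sigmoidal hidden units,
#' linear output) mapping min-max-normalized flavor-compound inputs to
#' normalized preference. Rows are partitioned 70/15/15 into training,
#' validation and test sets; the network is fitted on the training rows by
#' full-batch quasi-Newton backpropagation ([nnet::nnet()]) from several
#' seeded random initializations, and the restart with the lowest
#' validation MSE is kept, so the validation set guards against a poor
#' local optimum or overfit run. Reported metrics follow the regression-
#' of-outputs-on-targets convention: `r_squared` is the squared Pearson
#' correlation between predicted and observed preference over *all* rows,
#' and `mse` is the mean squared error on the normalized scale.
#'
#' @param X numeric matrix of inputs, one row per observation (the worked
#'   analyses use the six compounds Arg, Ala, Gly, Pro, K, Ca).
#' @param y numeric preference scores (not constant).
#' @param n_hidden hidden-layer size (>= 1).
#' @param seed integer; controls the split and the weight initializations.
#' @param fractions split fractions, see [split_data()].
#' @param restarts number of random initializations (default 5).
#' @param maxit maximum optimizer iterations per restart.
#' @param decay weight decay passed to [nnet::nnet()].
#' @return object of class `"preference_ann"` with elements `fit` (the
#'   selected [nnet::nnet()] fit), `scaler_x`, `scaler_y`, `split`,
#'   `metrics` (list: `r_squared`, `mse`), `n_hidden`, `seed`.
#' @export
ann_train <- function(X, y, n_hidden = 3, seed = 1,
                      fractions = c(train = 0.70, validation = 0.15,
                                    test = 0.15),
                      restarts = 5, maxit = 500, decay = 1e-5) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  if (nrow(X) < 6) stop("need at least six observations")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  if (stats::sd(y) == 0) stop("target is constant; nothing to learn")
  if (n_hidden < 1) stop("n_hidden must be >= 1")
  sx <- fit_scaler(X)
  sy <- fit_scaler(matrix(y, dimnames = list(NULL, "y")))
  Xn <- scale_minmax(X, sx)
  yn <- as.vector(scale_minmax(matrix(y), sy))
  idx <- split_data(nrow(X), fractions, seed)
  val <- if (length(idx$validation)) idx$validation else idx$train
  fits <- lapply(seq_len(restarts), function(r)
    .with_seed(seed * 1000L + r,
               nnet::nnet(Xn[idx$train, , drop = FALSE], yn[idx$train],
                          size = n_hidden, linout = TRUE, trace = FALSE,
                          maxit = maxit, decay = decay)))
  vmse <- vapply(fits, function(f)
    mean((stats::predict(f, Xn[val, , drop = FALSE]) - yn[val])^2), 1)
  fit <- fits[[which.min(vmse)]]
  pred <- as.vector(stats::predict(fit, Xn))
  r <- suppressWarnings(stats::cor(pred, yn))
  model <- structure(list(fit = fit, scaler_x = sx, scaler_y = sy,
                          split = idx,
                          metrics = list(
                            r_squared = if (is.na(r)) 0 else r^2,
                            mse = mean((pred - yn)^2)),
                          n_hidden = n_hidden, seed = seed),
                     class = "preference_ann")
  model
}

#' @export
print.preference_ann <- function(x, ...) {
  cat("Feed-forward preference network:", length(x$scaler_x$min), "->",
      x$n_hidden, "-> 1\n")
  cat(sprintf("R^2 = %.4f, MSE (normalized) = %.4g\n",
              x$metrics$r_squared, x$metrics$mse))
  invisible(x)
}

#' @rdname ann_train
#' @param object a fitted `"preference_ann"`.
#' @param newdata matrix with the same input columns as the training `X`.
#' @param ... unused.
#' @return `predict()`: preference scores on the original scale.
#' @export
predict.preference_ann <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$scaler_x$min))
    stop("newdata must have ", length(object$scaler_x$min), " columns")
  if (!nrow(newdata)) return(numeric(0))
  pn <- stats::predict(object$fit, scale_minmax(newdata, object$scaler_x))
  as.vector(unscale_minmax(matrix(pn), object$scaler_y))
}

#' Hidden-neuron scan
#'
#' Trains one network per candidate hidden-layer size (the trial-and-error
#' sizing the field uses) and tabulates the fit metrics.
#'
#' @inheritParams ann_train
#' @param h_range candidate hidden sizes (default 1 to 10).
#' @return data frame of class `"neuron_scan"` with columns `neurons`,
#'   `r_squared`, `mse`, `seed`; the best (highest R-squared) size is
#'   attached as attribute `"best"`.
#' @export
neuron_scan <- function(X, y, h_range = 1:10, seed = 1, ...) {
  rows <- lapply(h_range, function(h) {
    m <- ann_train(X, y, n_hidden = h, seed = seed, ...)
    data.frame(neurons = h, r_squared = m$metrics$r_squared,
               mse = m$metrics$mse, seed = seed)
  })
  out <- do.call(rbind, rows)
  attr(out, "best") <- out$neurons[which.max(out$r_squared)]
  class(out) <- c("neuron_scan", "data.frame")
  out
}
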