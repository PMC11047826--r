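#' Fit a Gaussian kernel density estimate to one class's feature matrix
#'
#' Product-Gaussian KDE with a per-dimension bandwidth. By default the
#' features are standardized to zero mean / unit variance before fitting
#' and samples are mapped back afterwards, so a single bandwidth rule works
#' across features of very different scales. With `bandwidth_rule =
#' "fixed"` the supplied bandwidth is applied in the original units and no
#' standardization is done.
#'
#' @param points Numeric matrix (rows = observations of one class, columns
#'   = features) or data.frame coercible to one. At least 2 rows, no
#'   missing values.
#' @param bandwidth_rule `"scott"` (default, `n^(-1/(d+4))` on the
#'   standardized scale), `"silverman"` (`(4/(d+2))^(1/(d+4)) *
#'   n^(-1/(d+4))`), or `"fixed"`.
#' @param bandwidth Per-dimension bandwidth(s) for `"fixed"` (scalar or one
#'   per column).
#' @return An object of class `kde_model`.
#' @export
fit_kde <- function(points, bandwidth_rule = c("scott", "silverman", "fixed"),
                    bandwidth = NULL) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  x <- as.matrix(points)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L) stop("fit_kde: need at least 2 training points")
  if (anyNA(x)) stop("fit_kde: missing values in training points")
  d <- ncol(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0) && bandwidth_rule != "fixed") {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("fit_kde: zero-variance feature(s): ",
         paste(bad, collapse = ", "), "; drop or jitter them")
  }
  if (bandwidth_rule == "fixed") {
    if (is.null(bandwidth) || any(bandwidth <= 0))
      stop("fit_kde: bandwidth_rule 'fixed' needs a positive bandwidth")
    h <- rep_len(as.numeric(bandwidth), d)
    center <- rep(0, d); scale <- rep(1, d)
    z <- x
  } else {
    n <- nrow(x)
    factor <- if (bandwidth_rule == "scott") n^(-1 / (d + 4))
              else (4 / (d + 2))^(1 / (d + 4)) * n^(-1 / (d + 4))
    center <- colMeans(x)
    scale <- sds
    z <- sweep(sweep(x, 2, center), 2, scale, "/")
    h <- rep(factor, d)  # unit variance after standardization
  }
  structure(list(z = z, h = h, center = center, scale = scale,
                 bandwidth_rule = bandwidth_rule, d = d, n = nrow(x),
                 colnames = colnames(x)),
            class = "kde_model")
}

#' Evaluate the KDE density
#'
#' @param model A [fit_kde()] model.
#' @param x Numeric matrix (or vector for 1-D) of evaluation points in the
#'   original feature units.
#' @return Numeric vector of density values.
#' @export
dkde <- function(model, x) {
  stopifnot(inherits(model, "kde_model"))
  x <- if (is.null(dim(x))) matrix(x, ncol = model$d) else as.matrix(x)
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  jac <- prod(model$scale)   # density transforms back to original units
  out <- numeric(nrow(z))
  for (i in seq_len(nrow(z))) {
    lk <- rep(1, model$n)
    for (j in seq_len(model$d))
      lk <- lk * stats::dnorm(z[i, j], mean = model$z[, j], sd = model$h[j])
    out[i] <- mean(lk) / jac
  }
  out
}

#' Draw synthetic samples from a fitted KDE
#'
#' Each draw picks a training point uniformly at random and adds Gaussian
#' noise scaled by the per-dimension bandwidth; samples are mapped back to
#' original feature units. Reproducible for a fixed seed.
#'
#' @param model A [fit_kde()] model.
#' @param n Number of draws (`n = 0` yields an empty matrix).
#' @param seed Optional integer RNG seed.
#' @return `n x d` numeric matrix with the training columns' names.
#' @export
sample_kde <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "kde_model"))
  n <- as.integer(n)
  if (n < 0L) stop("sample_kde: n must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(numeric(0), nrow = 0L, ncol = model$d)
  if (n > 0L) {
    idx <- sample.int(model$n, n, replace = TRUE)
    noise <- matrix(stats::rnorm(n * model$d), nrow = n)
    noise <- sweep(noise, 2, model$h, "*")
    z <- model$z[idx, , drop = FALSE] + noise
    out <- sweep(sweep(z, 2, model$scale, "*"), 2, model$center, "+")
  }
  colnames(out) <- model$colnames
  out
}

#' @export
print.kde_model <- function(x, ...) {
  cat(sprintf("<kde_model> %d points, %d dim(s), %s bandwidth (%s)\n",
              x$n, x$d, x$bandwidth_rule,
              paste(signif(x$h, 3), collapse = ", ")))
  invisible(x)
}
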