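# Global sensitivity analysis by partial rank correlation coefficients
# (PRCC): parameters sampled uniformly over a wide multiplicative range,
# model outputs reduced to scalar metrics, rank-transformed, and partially
# correlated with every other parameter regressed out on ranks.

#' Define a sensitivity analysis
#'
#' @param names Parameter names to perturb.
#' @param base Named base (fitted) values; defaults are looked up from
#'   `params` by [run_prcc()].
#' @param lo,hi Multiplicative range limits (defaults 0.01x and 50x the
#'   fitted value).
#' @param n Sample count (must exceed the parameter count plus one).
#' @param seed RNG seed.
#' @return A `sensitivity_spec`.
#' @export
sensitivity_spec <- function(names, base = NULL, lo = 0.01, hi = 50,
                             n = 1000, seed = 1) {
  if (lo >= hi) stop("lo must be < hi")
  if (n < length(names) + 2) stop("sample count too small for PRCC")
  structure(list(names = names, base = base, lo = lo, hi = hi,
                 n = n, seed = seed), class = "sensitivity_spec")
}

#' Sample a uniform parameter design matrix
#'
#' Each column is independently uniform on `[lo * base, hi * base]`.
#'
#' @param spec A [sensitivity_spec()] with `base` values set.
#' @return Matrix (`n` rows, one column per parameter).
#' @export
sample_parameters <- function(spec) {
  if (is.null(spec$base)) stop("spec has no base values")
  set.seed(spec$seed)
  k <- length(spec$names)
  X <- matrix(stats::runif(spec$n * k), nrow = spec$n)
  for (j in seq_len(k)) {
    b <- spec$base[[spec$names[j]]]
    X[, j] <- spec$lo * b + X[, j] * (spec$hi - spec$lo) * b
  }
  colnames(X) <- spec$names
  X
}

#' Partial rank correlation coefficients
#'
#' Ranks inputs and output, then for each parameter correlates the
#' residuals of rank regressions that partial out all other parameters.
#' Significance is a t-test with `n - k - 1` residual degrees of freedom.
#'
#' @param X Design matrix (samples x parameters).
#' @param y Output vector.
#' @return A `prcc_result` tibble: `parameter`, `prcc`, `p_value`, `rank`.
#' @export
prcc <- function(X, y) {
  if (nrow(X) != length(y)) stop("design and output sizes differ")
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant design column")
  if (stats::sd(y) == 0) {
    stop("constant output: PRCC undefined")
  }
  n <- nrow(X); k <- ncol(X)
  R <- apply(X, 2, rank)
  ry <- rank(y)
  out <- numeric(k)
  for (j in seq_len(k)) {
    Z <- cbind(1, R[, -j, drop = FALSE])
    qj <- qr(Z)
    res_x <- stats::resid(stats::lm.fit(Z, R[, j]))
    res_y <- stats::resid(stats::lm.fit(Z, ry))
    out[j] <- stats::cor(res_x, res_y)
    qj
  }
  df <- n - k - 1
  tval <- out * sqrt(pmax(df, 1) / pmax(1 - out^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = pmax(df, 1))
  res <- tibble::tibble(parameter = colnames(X), prcc = out, p_value = p)
  res$rank <- rank(-abs(res$prcc), ties.method = "first")
  class(res) <- c("prcc_result", class(res))
  res
}

#' Run a PRCC analysis on the model
#'
#' Samples the design, simulates the given protocol for each row, reduces
#' each trajectory to the requested metric, and computes PRCC.
#'
#' @param model Model object.
#' @param spec A [sensitivity_spec()]; base values are filled from `params`.
#' @param metric Scalar reduction of a trajectory: name of a trajectory
#'   column (the maximum over time is used) or a function.
#' @param prot Protocol (default 50 ng/ml VEGF for 30 min).
#' @param params Parameter tibble (default: model's).
#' @param downstream Couple downstream modules (default `TRUE`).
#' @param rtol,atol Solver tolerances.
#' @return List: `result` (prcc_result), `design`, `outputs`, `spec`.
#' @export
run_prcc <- function(model, spec, metric = "pR2", prot = NULL, params = NULL,
                     downstream = TRUE, rtol = 1e-6, atol = 1e-8) {
  params <- params %||% model$params
  if (is.null(spec$base)) {
    spec$base <- as.list(stats::setNames(param_get(params, spec$names),
                                         spec$names))
  }
  prot <- prot %||% vegf_protocol(50, duration = 30, dt = 1)
  X <- sample_parameters(spec)
  mfun <- if (is.function(metric)) metric else function(tr) max(tr[[metric]])
  y <- vapply(seq_len(nrow(X)), function(r) {
    p2 <- params
    p2$value[match(spec$names, p2$name)] <- X[r, ]
    tr <- tryCatch(run_protocol(model, prot, params = p2, rtol = rtol,
                                atol = atol, downstream = downstream),
                   error = function(e) NULL)
    if (is.null(tr)) NA_real_ else mfun(tr)
  }, numeric(1))
  ok <- is.finite(y)
  list(result = prcc(X[ok, , drop = FALSE], y[ok]),
       design = X, outputs = y, spec = spec)
}

#' Rank parameters by sensitivity
#'
#' @param result A `prcc_result` (or list from [run_prcc()]).
#' @param top Number of rows to keep (default all).
#' @return Tibble ordered by `|prcc|`, with sign retained.
#' @export
rank_report <- function(result, top = Inf) {
  if (!inherits(result, "prcc_result") && !is.null(result$result)) {
    result <- result$result
  }
  out <- result[order(-abs(result$prcc)), ]
  utils::head(out, top)
}

#' @method autoplot prcc_result
#' @export
autoplot.prcc_result <- function(object, ...) {
  d <- rank_report(object)
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  ggplot2::ggplot(d, ggplot2::aes(.data$prcc, .data$parameter)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "PRCC", y = NULL)
}
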