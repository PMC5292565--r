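# Parameter estimation: weighted least squares over named fit datasets,
# minimized by a derivative-free generalized pattern search (poll step with
# mesh expansion/contraction), by default in log10 parameter space since the
# rate constants span several decades.

#' Construct a fit dataset
#'
#' @param name Dataset identifier.
#' @param observable Trajectory column the dataset constrains (e.g. `"pR2_frac"`,
#'   `"Ca_c"`, `"pERK"`).
#' @param protocol A [protocol()] (time-course data) or a function
#'   `dose -> protocol` plus a dose grid (dose-response data).
#' @param grid Time grid (minutes) or dose grid.
#' @param values Target values, same length as `grid`.
#' @param weight Positive weight.
#' @param normalize `"none"`, `"max"` (normalize simulated curve to its
#'   peak), matching how the corresponding panel is presented.
#' @param type `"timecourse"` or `"dose_response"`.
#' @return A `fit_dataset`.
#' @export
fit_dataset <- function(name, observable, protocol, grid, values,
                        weight = 1, normalize = "none", type = "timecourse") {
  stopifnot(length(grid) == length(values), weight > 0, !is.unsorted(grid),
            all(is.finite(values)))
  structure(list(name = name, observable = observable, protocol = protocol,
                 grid = grid, values = values, weight = weight,
                 normalize = normalize, type = type),
            class = "fit_dataset")
}

# simulate one dataset's predicted curve under params
predict_dataset <- function(model, ds, params, rtol = 1e-6, atol = 1e-8, ...) {
  if (ds$type == "timecourse") {
    tr <- run_protocol(model, ds$protocol, params = params,
                       rtol = rtol, atol = atol, ...)
    pred <- stats::approx(tr$time, tr[[ds$observable]], xout = ds$grid,
                          rule = 2)$y
  } else {
    pred <- vapply(ds$grid, function(d) {
      tr <- run_protocol(model, ds$protocol(d), params = params,
                         rtol = rtol, atol = atol, ...)
      max(tr[[ds$observable]])
    }, numeric(1))
  }
  if (identical(ds$normalize, "max") && max(abs(pred)) > 0) {
    pred <- pred / max(pred)
  }
  pred
}

#' Weighted least-squares objective over fit datasets
#'
#' Sum over datasets of `weight * sum((pred - target)^2)`. A simulation
#' failure contributes a large penalty (flagged via the `"failed"`
#' attribute) so that direct search can continue.
#'
#' @param params Parameter tibble.
#' @param datasets List of [fit_dataset()] objects.
#' @param model Model the datasets refer to.
#' @param penalty Value charged per failed dataset.
#' @param ... Passed to [run_protocol()].
#' @return Scalar objective; attribute `residuals` holds per-dataset sums.
#' @export
fit_objective <- function(params, datasets, model, penalty = 1e6, ...) {
  per <- vapply(datasets, function(ds) {
    pred <- tryCatch(predict_dataset(model, ds, params, ...),
                     error = function(e) NULL)
    if (is.null(pred)) return(NA_real_)
    ds$weight * sum((pred - ds$values)^2)
  }, numeric(1))
  failed <- is.na(per)
  val <- sum(per[!failed]) + penalty * sum(failed)
  attr(val, "residuals") <- stats::setNames(per, vapply(datasets, function(d) d$name, character(1)))
  attr(val, "failed") <- any(failed)
  val
}

#' Generalized pattern search (derivative-free minimization)
#'
#' Coordinate poll with mesh expansion on success (factor `expand`) and
#' contraction on failure (factor `contract`); the incumbent objective is
#' non-increasing by construction. Deterministic for fixed inputs.
#'
#' @param fn Objective `function(x) -> scalar`.
#' @param start Numeric start vector (inside bounds).
#' @param lower,upper Bounds.
#' @param mesh Initial mesh size as a fraction of the bound range per
#'   coordinate (default 0.1).
#' @param contract,expand Mesh update factors.
#' @param mesh_tol Stop when the mesh fraction falls below this.
#' @param max_eval Objective evaluation budget.
#' @param log10_space Search in log10-transformed coordinates (bounds must
#'   be positive).
#' @param seed Recorded in the result (the search itself is deterministic).
#' @return A `fit_result`: `par`, `value`, `trace` (incumbent per
#'   iteration), `evals`, `seed`.
#' @export
direct_search <- function(fn, start, lower, upper, mesh = 0.1,
                          contract = 0.5, expand = 2, mesh_tol = 1e-6,
                          max_eval = 500, log10_space = FALSE, seed = NA) {
  stopifnot(length(start) == length(lower), length(lower) == length(upper))
  if (any(lower > upper)) stop("invalid bounds")
  if (any(start < lower | start > upper)) stop("start outside bounds")
  tf <- if (log10_space) {
    if (any(lower <= 0)) stop("log10 search needs positive bounds")
    list(to = log10, from = function(z) 10^z)
  } else list(to = identity, from = identity)
  lo <- tf$to(lower); hi <- tf$to(upper); x <- tf$to(start)
  rng <- pmax(hi - lo, .Machine$double.eps)
  evals <- 0L
  eval_fn <- function(z) {
    evals <<- evals + 1L
    as.numeric(fn(tf$from(pmin(pmax(z, lo), hi))))
  }
  f <- eval_fn(x)
  m <- mesh
  trace <- f
  n <- length(x)
  while (m > mesh_tol && evals < max_eval) {
    improved <- FALSE
    for (i in seq_len(n)) {
      for (s in c(1, -1)) {
        cand <- x
        cand[i] <- min(max(cand[i] + s * m * rng[i], lo[i]), hi[i])
        if (cand[i] == x[i]) next
        fc <- eval_fn(cand)
        if (fc < f) {
          x <- cand; f <- fc; improved <- TRUE
          break
        }
        if (evals >= max_eval) break
      }
      if (evals >= max_eval) break
    }
    m <- if (improved) min(m * expand, 1) else m * contract
    trace <- c(trace, f)
  }
  structure(list(par = tf$from(x), value = f, trace = trace,
                 evals = evals, mesh_final = m, seed = seed),
            class = "fit_result")
}

#' Fit selected parameters to datasets
#'
#' @param model Model object.
#' @param datasets List of [fit_dataset()].
#' @param fit_names Names of the parameters to adjust.
#' @param params Starting parameter tibble (default: the model's).
#' @param lower,upper Optional bounds (default: the tibble's declared
#'   bounds, or value/100 .. value*100).
#' @param ... Passed to [direct_search()].
#' @return `fit_result` with `params` (fitted tibble) and per-dataset
#'   residuals attached.
#' @export
fit_model <- function(model, datasets, fit_names, params = NULL,
                      lower = NULL, upper = NULL, ...) {
  params <- params %||% model$params
  i <- match(fit_names, params$name)
  if (any(is.na(i))) stop("unknown fit parameter(s)")
  start <- params$value[i]
  lower <- lower %||% ifelse(is.na(params$lower[i]), start / 100, params$lower[i])
  upper <- upper %||% ifelse(is.na(params$upper[i]), start * 100, params$upper[i])
  lower <- pmax(lower, 1e-12)
  fn <- function(x) {
    p2 <- params
    p2$value[i] <- x
    fit_objective(p2, datasets, model)
  }
  res <- direct_search(fn, start, lower, upper, log10_space = TRUE, ...)
  fitted <- params
  fitted$value[i] <- res$par
  res$params <- fitted
  res$fit_names <- fit_names
  final <- fit_objective(fitted, datasets, model)
  res$residuals <- attr(final, "residuals")
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> objective ", format(x$value), " after ", x$evals,
      " evaluations\n", sep = "")
  if (!is.null(x$fit_names)) {
    print(stats::setNames(x$par, x$fit_names))
  }
  invisible(x)
}

#' @method tidy fit_result
#' @export
tidy.fit_result <- function(x, ...) {
  tibble::tibble(term = x$fit_names %||% paste0("par", seq_along(x$par)),
                 estimate = x$par)
}

#' @method glance fit_result
#' @export
glance.fit_result <- function(x, ...) {
  tibble::tibble(objective = x$value, n_eval = x$evals,
                 mesh_final = x$mesh_final)
}
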