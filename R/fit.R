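#' Fit a quantitative infection network to community time series
#'
#' The central estimator of the package.  Takes one or more sampled
#' community time series (or a pre-built regression system), assembles the
#' discrete log-derivative regression of the virus trajectories on the host
#' densities, and solves the non-negatively constrained least-squares
#' problem
#' \deqn{\arg\min_{\tilde M \ge 0,\; m \ge 0}
#'   \left\| W - (\tilde M^\top\; -m) \binom{H}{1} \right\|_F^2}
#' for the quantitative infection network `M_tilde` (effective infection
#' rates `phi * beta` on the interacting pairs, zero elsewhere) and the
#' viral decay rates `m`.
#'
#' Multiple time series are treated as replicate experiments on the same
#' community and concatenated column-wise before solving; this is the
#' multi-experiment design, which improves conditioning at a fixed total
#' measurement budget.
#'
#' @param x a `"community_ts"`, a list of them, or a
#'   `"regression_system"`.
#' @param truth optional true quantitative network; when supplied, the
#'   normalized Frobenius [reconstruction_error()] is computed and stored.
#' @param hosts host-pairing convention passed to [build_regression()].
#' @return An object of class `"infnet_fit"` with components `M_tilde`,
#'   `m`, `objective`, `kappa`, `n_cols`, `hosts`, `sys` (the regression
#'   system), `error` (if `truth` given) and `call`.  Methods: `print`,
#'   `summary`, `coef`, `fitted`, `residuals`, `predict`, `plot`.
#' @examples
#' M <- modular_matrix(4, 4, 2)
#' p <- feasible_parameters(M, seed = 1)
#' ts <- simulate_community(p, M, experiment_design(T = 48), seed = 2)
#' fit <- fit_infection_network(ts, truth = quantitative_network(M, p))
#' fit
#' @export
fit_infection_network <- function(x, truth = NULL,
                                  hosts = c("midpoint", "left")) {
  hosts <- match.arg(hosts)
  sys <- if (inherits(x, "regression_system")) {
    x
  } else if (inherits(x, "community_ts")) {
    build_regression(x, hosts = hosts)
  } else if (is.list(x) && length(x) > 0 &&
             all(vapply(x, inherits, TRUE, "community_ts"))) {
    concat_regressions(lapply(x, build_regression, hosts = hosts))
  } else {
    stop_input("'x' must be a community_ts, a list of them, or a regression_system")
  }
  sol <- solve_network(sys)
  out <- list(M_tilde = sol$M_tilde, m = sol$m, objective = sol$objective,
              row_objectives = sol$row_objectives, kappa = sol$kappa,
              converged = sol$converged, n_cols = ncol(sys$H_aug),
              n_experiments = length(sys$block_cols), hosts = sys$hosts,
              sys = sys, call = match.call())
  if (!is.null(truth)) {
    out$truth <- truth
    out$error <- reconstruction_error(truth, sol$M_tilde)
  }
  structure(out, class = "infnet_fit")
}

#' @export
print.infnet_fit <- function(x, ...) {
  n_h <- nrow(x$M_tilde); n_v <- ncol(x$M_tilde)
  cat(sprintf("Quantitative infection network fit: %d hosts x %d viruses\n",
              n_h, n_v))
  cat(sprintf("  %d regression columns from %d experiment(s), hosts at %s\n",
              x$n_cols, x$n_experiments, x$hosts))
  cat(sprintf("  inferred interactions (>1%% of max): %d\n",
              sum(support_matrix(x$M_tilde))))
  if (!is.null(x$error)) {
    cat(sprintf("  reconstruction error vs truth: %.4g\n", x$error))
  }
  invisible(x)
}

#' @export
summary.infnet_fit <- function(object, ...) {
  structure(list(
    dims = dim(object$M_tilde),
    n_cols = object$n_cols,
    n_experiments = object$n_experiments,
    hosts = object$hosts,
    objective = object$objective,
    kappa = object$kappa,
    converged = object$converged,
    n_interactions = sum(support_matrix(object$M_tilde)),
    rate_range = if (any(object$M_tilde > 0)) {
      range(object$M_tilde[object$M_tilde > 0])
    } else {
      c(0, 0)
    },
    decay_range = range(object$m),
    error = object$error
  ), class = "summary.infnet_fit")
}

#' @export
print.summary.infnet_fit <- function(x, ...) {
  cat(sprintf("Quantitative infection network fit (%d hosts x %d viruses)\n",
              x$dims[1], x$dims[2]))
  cat(sprintf("Regression: %d columns, %d experiment(s), hosts at %s\n",
              x$n_cols, x$n_experiments, x$hosts))
  cat(sprintf("Objective (residual sum of squares): %.6g\n", x$objective))
  cat(sprintf("Design condition number: %.3g%s\n", x$kappa,
              if (x$kappa > 1e12) "  [rank deficient]" else ""))
  cat(sprintf("Interactions above 1%% of max: %d\n", x$n_interactions))
  cat(sprintf("Effective rates: %.3g - %.3g ml/(cell h)\n",
              x$rate_range[1], x$rate_range[2]))
  cat(sprintf("Decay rates: %.3g - %.3g 1/h\n",
              x$decay_range[1], x$decay_range[2]))
  if (!is.null(x$error)) {
    cat(sprintf("Reconstruction error vs truth: %.4g\n", x$error))
  }
  invisible(x)
}

#' @export
coef.infnet_fit <- function(object, what = c("network", "decay"), ...) {
  what <- match.arg(what)
  if (what == "network") object$M_tilde else object$m
}

#' @export
fitted.infnet_fit <- function(object, ...) {
  predict(object, object$sys)
}

#' @export
residuals.infnet_fit <- function(object, ...) {
  object$sys$W - fitted(object)
}

#' Predicted virus log-derivatives
#'
#' Applies the fitted linear map `(M_tilde' | -m)` to host densities,
#' predicting the per-capita growth rates of every virus type.
#'
#' @param object an `"infnet_fit"`.
#' @param newdata a `"community_ts"`, a `"regression_system"`, or a host
#'   density matrix (`n_h` x `N`).  Defaults to the training system.
#' @param ... unused.
#' @return An `n_v` x `N` matrix of predicted log-derivatives, 1/h.
#' @export
predict.infnet_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$sys
  H <- if (inherits(newdata, "regression_system")) {
    newdata$H_aug[-nrow(newdata$H_aug), , drop = FALSE]
  } else if (inherits(newdata, "community_ts")) {
    sys <- build_regression(newdata, hosts = object$hosts)
    sys$H_aug[-nrow(sys$H_aug), , drop = FALSE]
  } else {
    check_matrix(newdata, "newdata")
  }
  if (nrow(H) != nrow(object$M_tilde)) {
    stop_input("'newdata' has the wrong number of host rows")
  }
  crossprod(object$M_tilde, H) - object$m
}

#' Plot a fitted infection network
#'
#' Heatmaps of the reconstructed quantitative network and, when the truth
#' was supplied to the fit, of the true network alongside it.
#'
#' @param x an `"infnet_fit"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.infnet_fit <- function(x, ...) {
  show_net <- function(M, main) {
    graphics::image(t(M)[, rev(seq_len(nrow(M))), drop = FALSE],
                    axes = FALSE, main = main,
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
    graphics::box()
  }
  if (!is.null(x$truth)) {
    op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 3, 1))
    on.exit(graphics::par(op))
    show_net(x$truth, "true network")
    show_net(x$M_tilde, "reconstruction")
  } else {
    show_net(x$M_tilde, "reconstructed network")
  }
  invisible(x)
}
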