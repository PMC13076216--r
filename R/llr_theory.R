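#' Class-conditional Gaussian model of an ensemble of LLR scorers
#'
#' The theoretical model behind the aggregation analysis: conditional on the
#' true class of a variant (pathogenic or benign), the LLR scores emitted by
#' `n_models` scorers are i.i.d. Gaussian. The model is governed by two
#' interpretable quantities — the separation between the class means and the
#' ratio of the class standard deviations. By convention pathogenic LLRs are
#' lower (`mu_p <= mu_b`) and AUC is the probability that a benign variant
#' scores above a pathogenic one, with half credit for ties.
#'
#' @param mu_p,sigma_p Pathogenic class mean and standard deviation.
#' @param mu_b,sigma_b Benign class mean and standard deviation.
#' @param n_models Number of scorers N (>= 1).
#' @return A `gaussian_llr_spec` object.
#' @export
#' @examples
#' gaussian_llr_spec(mu_p = -4, sigma_p = 4, mu_b = 0, sigma_b = 1,
#'                   n_models = 10)
gaussian_llr_spec <- function(mu_p, sigma_p, mu_b, sigma_b, n_models = 1L) {
  stopifnot(sigma_p > 0, sigma_b > 0, n_models >= 1L)
  if (mu_p > mu_b) {
    abort("convention: pathogenic LLRs are lower (mu_p <= mu_b)")
  }
  structure(list(mu_p = mu_p, sigma_p = sigma_p,
                 mu_b = mu_b, sigma_b = sigma_b,
                 n_models = as.integer(n_models)),
            class = "gaussian_llr_spec")
}

#' @export
print.gaussian_llr_spec <- function(x, ...) {
  cat(sprintf(
    "<gaussian_llr_spec> pathogenic N(%.3g, %.3g^2), benign N(%.3g, %.3g^2), N = %d\n",
    x$mu_p, x$sigma_p, x$mu_b, x$sigma_b, x$n_models))
  invisible(x)
}

auc_result <- function(auc, method, tol = NA_real_) {
  tibble::tibble(auc = auc, method = method, tol = tol)
}

#' AUC of a single Gaussian scorer
#'
#' For one scorer the ROC AUC has the classical closed form
#' `Phi((mu_b - mu_p) / sqrt(sigma_p^2 + sigma_b^2))`.
#'
#' @param spec A [gaussian_llr_spec()].
#' @return One-row tibble with `auc`, `method`, `tol`.
#' @export
auc_single <- function(spec) {
  stopifnot(inherits(spec, "gaussian_llr_spec"))
  z <- (spec$mu_b - spec$mu_p) / sqrt(spec$sigma_p^2 + spec$sigma_b^2)
  auc_result(pnorm(z), "closed_form", 0)
}

#' AUC of the averaging aggregator
#'
#' The average of N i.i.d. Gaussians per class is Gaussian with variance
#' `sigma^2 / N`, so averaging simply sharpens both classes:
#' `AUC = Phi((mu_b - mu_p) / sqrt((sigma_p^2 + sigma_b^2) / N))`.
#'
#' @inheritParams auc_single
#' @return One-row tibble with `auc`, `method`, `tol`.
#' @export
auc_average <- function(spec) {
  stopifnot(inherits(spec, "gaussian_llr_spec"))
  z <- (spec$mu_b - spec$mu_p) /
    sqrt((spec$sigma_p^2 + spec$sigma_b^2) / spec$n_models)
  auc_result(pnorm(z), "closed_form", 0)
}

# density of the minimum of N i.i.d. N(mu, sigma^2) draws
min_density <- function(x, mu, sigma, n) {
  z <- (x - mu) / sigma
  n * dnorm(z) / sigma * pnorm(z, lower.tail = FALSE)^(n - 1)
}

# P(min of N i.i.d. N(mu, sigma^2) draws > x)
min_survival <- function(x, mu, sigma, n) {
  pnorm((x - mu) / sigma, lower.tail = FALSE)^n
}

#' AUC of the maximum-confidence (minimum) aggregator
#'
#' With the minimum rule the per-variant score is the smallest of N i.i.d.
#' Gaussian draws, an order statistic with density
#' `f_min(x) = N phi((x - mu)/sigma)/sigma * (1 - Phi((x - mu)/sigma))^(N-1)`.
#' The AUC is `P(min_benign > min_pathogenic)`, computed by adaptive
#' one-dimensional quadrature of the pathogenic minimum density against the
#' benign minimum survival function over a +-10 sd support window.
#'
#' @inheritParams auc_single
#' @param tol Absolute quadrature tolerance (default 1e-8).
#' @return One-row tibble with `auc`, `method`, `tol`.
#' @export
auc_min <- function(spec, tol = 1e-8) {
  stopifnot(inherits(spec, "gaussian_llr_spec"))
  n <- spec$n_models
  if (n == 1L) return(auc_single(spec))
  lo <- min(spec$mu_p - 10 * spec$sigma_p, spec$mu_b - 10 * spec$sigma_b)
  hi <- max(spec$mu_p + 10 * spec$sigma_p, spec$mu_b + 10 * spec$sigma_b)
  integrand <- function(x) {
    min_density(x, spec$mu_p, spec$sigma_p, n) *
      min_survival(x, spec$mu_b, spec$sigma_b, n)
  }
  q <- tryCatch(
    integrate(integrand, lo, hi, abs.tol = tol, rel.tol = tol,
              subdivisions = 500L),
    error = function(e) abort(paste0("quadrature failed: ",
                                     conditionMessage(e))))
  auc_result(min(max(q$value, 0), 1), "quadrature", q$abs.error)
}

#' Simulate labeled LLR ensembles from a Gaussian spec
#'
#' Draws `n_per_class` variants per class, each with `n_models` i.i.d. scorer
#' draws — the Monte-Carlo oracle for the analytic AUC expressions.
#'
#' @inheritParams auc_single
#' @param n_per_class Number of variants per class.
#' @param seed Integer seed.
#' @return Tibble with `variant`, `label` (pathogenic/benign), `model`,
#'   `score`.
#' @export
simulate_llrs <- function(spec, n_per_class, seed = 1L) {
  stopifnot(inherits(spec, "gaussian_llr_spec"), n_per_class >= 1)
  n <- spec$n_models
  withr_seed(seed, {
    path <- matrix(rnorm(n_per_class * n, spec$mu_p, spec$sigma_p),
                   ncol = n)
    ben <- matrix(rnorm(n_per_class * n, spec$mu_b, spec$sigma_b),
                  ncol = n)
  })
  tibble::tibble(
    variant = rep(seq_len(2L * n_per_class), each = n),
    label = rep(c("pathogenic", "benign"), each = n_per_class * n),
    model = rep(seq_len(n), times = 2L * n_per_class),
    score = c(as.vector(t(path)), as.vector(t(ben)))
  )
}

# run code under a local RNG seed without touching the global stream
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Monte-Carlo AUC of an aggregator under a Gaussian spec
#'
#' Aggregates each simulated variant's `n_models` draws by `min` or `mean`
#' and computes the empirical benign-vs-pathogenic AUC; used as the
#' independent arbiter for the analytic expressions.
#'
#' @inheritParams simulate_llrs
#' @param aggregator `"min"` or `"mean"`.
#' @return One-row tibble with `auc`, `method`, `tol` (the Mann-Whitney
#'   standard error estimate is not reported; tol is NA).
#' @export
mc_auc <- function(spec, aggregator = c("min", "mean"),
                   n_per_class = 1e6, seed = 1L) {
  aggregator <- match.arg(aggregator)
  n <- spec$n_models
  f <- if (aggregator == "min") {
    function(m) do.call(pmin, asplit(m, 2L))
  } else {
    function(m) rowMeans(m)
  }
  withr_seed(seed, {
    path <- f(matrix(rnorm(n_per_class * n, spec$mu_p, spec$sigma_p),
                     ncol = n))
    ben <- f(matrix(rnorm(n_per_class * n, spec$mu_b, spec$sigma_b),
                    ncol = n))
  })
  auc_result(auc(c(ben, path), rep(c("benign", "pathogenic"),
                                   each = n_per_class)),
             "monte_carlo")
}

#' @rdname mc_auc
#' @description `mc_auc_pair()` computes both aggregators' Monte-Carlo AUCs
#'   from one shared set of draws (halving simulation cost).
#' @export
mc_auc_pair <- function(spec, n_per_class = 1e6, seed = 1L) {
  n <- spec$n_models
  withr_seed(seed, {
    pm <- matrix(rnorm(n_per_class * n, spec$mu_p, spec$sigma_p), ncol = n)
    bm <- matrix(rnorm(n_per_class * n, spec$mu_b, spec$sigma_b), ncol = n)
  })
  labels <- rep(c("benign", "pathogenic"), each = n_per_class)
  mins <- c(do.call(pmin, asplit(bm, 2L)), do.call(pmin, asplit(pm, 2L)))
  means <- c(rowMeans(bm), rowMeans(pm))
  tibble::tibble(aggregator = c("min", "mean"),
                 auc = c(auc(mins, labels), auc(means, labels)),
                 n_per_class = n_per_class)
}

#' Map the regimes where min or average aggregation wins
#'
#' Evaluates `auc_min` and `auc_average` over a grid of class-mean
#' separations and class-sd ratios (benign sd fixed at 1, pathogenic sd =
#' ratio) and labels each cell by the winner. Min aggregation pulls ahead
#' when pathogenic LLRs are much more dispersed than benign ones; with equal
#' dispersions averaging wins.
#'
#' @param separations Numeric vector of `mu_b - mu_p` values (>= 0).
#' @param sigma_ratios Numeric vector of `sigma_p / sigma_b` values.
#' @param n_models Ensemble size N.
#' @param tie_tol Absolute AUC difference treated as a tie (default 1e-3).
#' @return Tibble with `separation`, `sigma_ratio`, `n_models`, `auc_min`,
#'   `auc_avg`, `winner` (min/avg/tie); class `regime_map`.
#' @export
regime_map <- function(separations, sigma_ratios, n_models = 10L,
                       tie_tol = 1e-3) {
  stopifnot(length(separations) > 0, length(sigma_ratios) > 0)
  grid <- tidyr::expand_grid(separation = separations,
                             sigma_ratio = sigma_ratios)
  out <- purrr::pmap_dfr(grid, function(separation, sigma_ratio) {
    spec <- gaussian_llr_spec(mu_p = -separation, sigma_p = sigma_ratio,
                              mu_b = 0, sigma_b = 1, n_models = n_models)
    amin <- auc_min(spec)$auc
    aavg <- auc_average(spec)$auc
    tibble::tibble(separation, sigma_ratio, n_models = n_models,
                   auc_min = amin, auc_avg = aavg,
                   winner = dplyr::case_when(
                     abs(amin - aavg) <= tie_tol ~ "tie",
                     amin > aavg ~ "min",
                     TRUE ~ "avg"))
  })
  class(out) <- c("regime_map", class(out))
  out
}

#' @export
autoplot.regime_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$separation, .data$sigma_ratio,
                                       fill = .data$auc_min - .data$auc_avg)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "class-mean separation", y = "sd ratio (path/benign)",
                  fill = "AUC(min) - AUC(avg)") +
    ggplot2::theme_minimal()
}
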