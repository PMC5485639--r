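#' True parameters for a simulated frontier population
#'
#' @param alpha0 Intercept of the distance function.
#' @param beta Named coefficients on log inputs (names become input
#'   columns).
#' @param gamma_out Named coefficients on log normalized outputs (empty for
#'   a single-output frontier; names become extra output columns).
#' @param sigma_v_sq,sigma_u_sq Noise and inefficiency variances (>= 0).
#' @returns A list of class `frontier_truth`. Convenience fields
#'   `sigma_sq` and `gamma` follow the frontier parameterization.
#' @export
frontier_truth <- function(alpha0, beta, gamma_out = numeric(),
                           sigma_v_sq, sigma_u_sq) {
  stopifnot(sigma_v_sq >= 0, sigma_u_sq >= 0, length(beta) >= 1)
  if (is.null(names(beta))) names(beta) <- paste0("x", seq_along(beta))
  if (length(gamma_out) && is.null(names(gamma_out)))
    names(gamma_out) <- paste0("out", seq_along(gamma_out) + 1)
  sigma_sq <- sigma_v_sq + sigma_u_sq
  structure(list(alpha0 = alpha0, beta = beta, gamma_out = gamma_out,
                 sigma_v_sq = sigma_v_sq, sigma_u_sq = sigma_u_sq,
                 sigma_sq = sigma_sq,
                 gamma = if (sigma_sq > 0) sigma_u_sq / sigma_sq else 0),
            class = "frontier_truth")
}

#' Generate a right-skewed benchmark survey population
#'
#' Per-farm milk yields are drawn log-normal (strictly positive and
#' right-skewed, which is what makes top-decile means several-fold larger
#' than overall means in real survey data). Deterministic per seed.
#'
#' @param n Number of farms (>= 10).
#' @param zone Zone label attached to every record.
#' @param median_yield Median yield, kg/head/lactation (> 0).
#' @param shape Log-scale standard deviation (> 0 for a spread; values
#'   near 0 collapse the gap to zero).
#' @param seed Integer seed.
#' @returns A `survey_df` with columns `farm_id`, `zone`, `milk_yield`.
#' @export
#' @examples
#' pop <- gen_benchmark_population(100, "LG", 300, 1, seed = 1)
#' compute_yield_gap(pop)
gen_benchmark_population <- function(n, zone = "all", median_yield = 300,
                                     shape = 1, seed = 1) {
  stopifnot(n >= 10, median_yield > 0, shape >= 0)
  set.seed(seed)
  y <- rlnorm(n, meanlog = log(median_yield), sdlog = shape)
  survey_table(tibble::tibble(
    farm_id = paste0(zone, "_", seq_len(n)), zone = zone, milk_yield = y
  ))
}

#' Generate a farm population from a known Cobb-Douglas frontier
#'
#' Inputs are drawn log-normal; for each farm `v ~ N(0, sigma_v^2)` and
#' `u = |N(0, sigma_u^2)|`, and the normalizing output satisfies
#' `-ln(y_M) = alpha0 + sum beta ln(x) + sum gamma_out ln(y_m / y_M) + v + u`.
#' The output-mix ratios `y_m / y_M` are drawn exogenously (log-normal) and
#' secondary output levels derived as `ratio * y_M`, so the regressors are
#' independent of the composed error and the frontier is recoverable by
#' maximum likelihood. True efficiencies are `te = exp(-u)`. The generator
#' shares no code with the estimator.
#'
#' @param n Number of farms (>= 50).
#' @param truth A [frontier_truth()].
#' @param input_meanlog,input_sdlog Log-normal parameters for the inputs.
#' @param ratio_sdlog Log-scale sd of the exogenous output-mix ratios.
#' @param seed Integer seed.
#' @returns List: `table` (a `survey_df` with output column `milk`,
#'   secondary outputs and the input columns), `te_true`, `truth`.
#' @export
gen_frontier_population <- function(n, truth, input_meanlog = 1,
                                    input_sdlog = 0.7, ratio_sdlog = 0.5,
                                    seed = 1) {
  stopifnot(inherits(truth, "frontier_truth"), n >= 50)
  set.seed(seed)
  K <- length(truth$beta)
  M1 <- length(truth$gamma_out)
  X <- matrix(rnorm(n * K, input_meanlog, input_sdlog), n, K)
  lnratio <- if (M1) matrix(rnorm(n * M1, 0, ratio_sdlog), n, M1) else
    matrix(0, n, 0)
  v <- rnorm(n, 0, sqrt(truth$sigma_v_sq))
  u <- abs(rnorm(n, 0, sqrt(truth$sigma_u_sq)))
  r <- truth$alpha0 + drop(X %*% truth$beta) +
    (if (M1) drop(lnratio %*% truth$gamma_out) else 0) + v + u
  yM <- exp(-r)
  df <- tibble::tibble(farm_id = paste0("farm_", seq_len(n)), zone = "all",
                       milk_yield = yM, milk = yM)
  out_names <- "milk"
  if (M1) {
    for (j in seq_len(M1)) {
      nm <- names(truth$gamma_out)[j]
      df[[nm]] <- exp(lnratio[, j]) * yM
      out_names <- c(out_names, nm)
    }
  }
  for (k in seq_len(K)) df[[names(truth$beta)[k]]] <- exp(X[, k])
  tab <- survey_table(df, outputs = out_names, inputs = names(truth$beta))
  list(table = tab, te_true = exp(-u), truth = truth)
}
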