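#' Build the regression design for a multi-output distance frontier
#'
#' For a Cobb-Douglas output distance function, linear homogeneity in
#' outputs is imposed by normalizing on one output: the regressand is
#' `r = -ln(y_M)` (the normalizing output) and the regressors are an
#' intercept, `ln(x_k)` for each input and `ln(y_m / y_M)` for each other
#' output. Farms with any zero (or missing) output or input are outside
#' the log domain and are dropped with a count.
#'
#' @param table A `survey_df` holding the output and input columns.
#' @param outputs Character vector of output column names (M >= 1).
#' @param inputs Character vector of input column names (K >= 1).
#' @param normalize Name of the normalizing output (default: first).
#' @returns A list of class `frontier_design`: `r` (numeric), `X` (matrix
#'   with intercept), `farm_id`, `dropped`, plus the naming metadata.
#' @export
frontier_design <- function(table, outputs, inputs,
                            normalize = outputs[[1]]) {
  stopifnot(length(outputs) >= 1, length(inputs) >= 1)
  if (!normalize %in% outputs) {
    abort("`normalize` must be one of `outputs`",
          class = "dairygap_schema_error")
  }
  cols <- c(outputs, inputs)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    abort(paste0("columns not found: ", paste(missing_cols, collapse = ", ")),
          class = "dairygap_schema_error")
  }
  vals <- as.matrix(tibble::as_tibble(table)[, cols])
  ok <- apply(vals, 1L, function(v) all(is.finite(v) & v > 0))
  dropped <- sum(!ok)
  tab <- table[ok, ]
  other_out <- setdiff(outputs, normalize)
  yM <- tab[[normalize]]
  r <- -log(yM)
  X <- cbind(`(Intercept)` = rep(1, nrow(tab)))
  for (k in inputs) X <- cbind(X, log(tab[[k]]))
  for (m in other_out) X <- cbind(X, log(tab[[m]] / yM))
  colnames(X) <- c("(Intercept)", paste0("ln_", inputs),
                   if (length(other_out)) paste0("ln_", other_out, "_ratio"))
  if (nrow(X) < ncol(X) + 2L) {
    abort("under-identified design: fewer farms than parameters + 2",
          class = "dairygap_underidentified_error")
  }
  structure(list(r = r, X = X, farm_id = tab$farm_id, dropped = dropped,
                 outputs = outputs, inputs = inputs, normalize = normalize),
            class = "frontier_design")
}

#' Negative log-likelihood of the normal/half-normal frontier
#'
#' The composed error is `eps = r - X theta = v + u` with
#' `v ~ N(0, sigma_v^2)` and `u >= 0` half-normal; its density is
#' `f(eps) = (2/sigma) phi(eps/sigma) Phi(lambda eps / sigma)` where
#' `sigma^2 = sigma_v^2 + sigma_u^2`, `gamma = sigma_u^2 / sigma^2` and
#' `lambda = sqrt(gamma / (1 - gamma))`. At `gamma = 0` this reduces to
#' the Gaussian negative log-likelihood with variance `sigma^2`.
#'
#' @param theta Coefficient vector (intercept first), conformable with
#'   `design$X`.
#' @param sigma_sq Total variance, > 0.
#' @param gamma Inefficiency share of variance, in `[0, 1)`.
#' @param design A `frontier_design`.
#' @returns A finite scalar (negative log-likelihood).
#' @export
sfa_nll <- function(theta, sigma_sq, gamma, design) {
  stopifnot(sigma_sq > 0, gamma >= 0, gamma < 1)
  eps <- drop(design$r - design$X %*% theta)
  sigma <- sqrt(sigma_sq)
  lambda <- sqrt(gamma / (1 - gamma))
  ll <- log(2) - log(sigma) + dnorm(eps / sigma, log = TRUE) +
    pnorm(lambda * eps / sigma, log.p = TRUE)
  if (!all(is.finite(ll))) {
    bad <- which(!is.finite(ll))[1]
    abort(paste0("non-finite likelihood contribution at row ", bad),
          class = "dairygap_numeric_error")
  }
  -sum(ll)
}

# corrected-OLS starting values: OLS slopes, then sigma_u from the third
# central moment of the residuals (half-normal skewness), intercept shifted
# by E[u] = sigma_u * sqrt(2/pi)
cols_start <- function(design) {
  fit <- lm.fit(design$X, design$r)
  res <- fit$residuals
  m2 <- mean(res^2)
  m3 <- mean(res^3)
  # third central moment of |N(0, s^2)| is s^3 * sqrt(2/pi) * (4/pi - 1)
  c3 <- sqrt(2 / pi) * (4 / pi - 1)
  sigma_u <- if (m3 > 0) (m3 / c3)^(1 / 3) else 0
  sigma_u_sq <- sigma_u^2
  sigma_v_sq <- max(m2 - sigma_u_sq * (1 - 2 / pi), 0.05 * m2)
  sigma_sq <- sigma_u_sq + sigma_v_sq
  gamma <- max(sigma_u_sq / sigma_sq, 0.05)
  theta <- fit$coefficients
  theta[1] <- theta[1] - sigma_u * sqrt(2 / pi)
  list(theta = theta, sigma_sq = sigma_sq, gamma = gamma, m2 = m2)
}

#' Fit a stochastic Cobb-Douglas output distance frontier
#'
#' Maximum-likelihood estimation of the normal/half-normal frontier in the
#' (sigma^2, gamma) parameterization of the FRONTIER tradition. gamma is
#' optimized on a logit scale and sigma^2 on a log scale for box
#' constraints. Optimization starts from the corrected OLS solution (gamma
#' floored at 0.05) plus additional starts at gamma = 0.3 and 0.7; the best
#' log-likelihood is kept. Standard errors come from the inverse observed
#' information at the optimum, evaluated in the (theta, sigma^2, gamma)
#' parameterization.
#'
#' @inheritParams frontier_design
#' @param extra_starts Additional gamma starting values.
#' @returns An object of class `frontier_fit`: coefficients, `sigma_sq`,
#'   `gamma`, `loglik`, `std_errors`, `converged`, `n`, `dropped` and the
#'   design. Methods: [tidy()], [glance()], `print`.
#' @export
#' @examples
#' pop <- gen_frontier_population(200, frontier_truth(
#'   alpha0 = 0.5, beta = c(land = 0.4, herd = 0.3),
#'   sigma_v_sq = 0.05, sigma_u_sq = 0.2), seed = 1)
#' fit <- fit_frontier(pop$table, outputs = "milk",
#'                     inputs = c("land", "herd"))
#' glance(fit)
fit_frontier <- function(table, outputs, inputs, normalize = outputs[[1]],
                         extra_starts = c(0.3, 0.7)) {
  design <- frontier_design(table, outputs, inputs, normalize)
  p <- ncol(design$X)
  st <- cols_start(design)

  obj <- function(par) {
    theta <- par[seq_len(p)]
    sigma_sq <- exp(par[p + 1])
    gamma <- stats::plogis(par[p + 2])
    tryCatch(sfa_nll(theta, sigma_sq, gamma, design),
             error = function(e) 1e10)
  }
  make_start <- function(gamma0) {
    sigma_u <- sqrt(gamma0 * st$sigma_sq)
    theta <- st$theta
    # re-centre the intercept for this gamma's implied mean inefficiency
    theta[1] <- theta[1] + sqrt(st$gamma * st$sigma_sq) * sqrt(2 / pi) -
      sigma_u * sqrt(2 / pi)
    c(theta, log(st$sigma_sq), stats::qlogis(gamma0))
  }
  starts <- lapply(unique(c(st$gamma, extra_starts)), make_start)
  fits <- lapply(starts, function(s) {
    tryCatch(optim(s, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) {
    abort("optimizer failed on all starts",
          class = "dairygap_nonconvergence_error")
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  theta <- unname(best$par[seq_len(p)])
  sigma_sq <- unname(exp(best$par[p + 1]))
  gamma <- unname(stats::plogis(best$par[p + 2]))
  converged <- best$convergence == 0

  # observed information in the natural parameterization
  nat <- c(theta, sigma_sq, gamma)
  nat_obj <- function(q) {
    tryCatch(sfa_nll(q[seq_len(p)], max(q[p + 1], 1e-10),
                     min(max(q[p + 2], 0), 1 - 1e-10), design),
             error = function(e) NA_real_)
  }
  se <- rep(NA_real_, p + 2)
  H <- tryCatch(optimHess(nat, nat_obj), error = function(e) NULL)
  if (!is.null(H) && all(is.finite(H))) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)
      se[dv > 0] <- sqrt(dv[dv > 0])
    }
  }
  nm <- c(colnames(design$X), "sigma_sq", "gamma")
  names(se) <- nm
  coefs <- stats::setNames(theta, colnames(design$X))

  structure(list(
    coefficients = coefs,
    alpha0 = unname(theta[1]),
    beta = coefs[paste0("ln_", inputs)],
    gamma_out = if (length(outputs) > 1)
      coefs[grep("_ratio$", names(coefs))] else numeric(),
    sigma_sq = sigma_sq, gamma = gamma,
    loglik = -best$value, std_errors = se,
    converged = converged, n = nrow(design$X), dropped = design$dropped,
    design = design
  ), class = "frontier_fit")
}

#' @export
print.frontier_fit <- function(x, ...) {
  cat("Stochastic output distance frontier (normal/half-normal)\n")
  cat(sprintf("  farms: %d (dropped %d)   logLik: %.3f   converged: %s\n",
              x$n, x$dropped, x$loglik, x$converged))
  cat(sprintf("  sigma^2 = %.4f   gamma = %.4f\n", x$sigma_sq, x$gamma))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @rdname fit_frontier
#' @param x A `frontier_fit`.
#' @param ... Unused.
#' @method tidy frontier_fit
#' @export
tidy.frontier_fit <- function(x, ...) {
  est <- c(x$coefficients, sigma_sq = x$sigma_sq, gamma = x$gamma)
  se <- x$std_errors
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se[names(est)]),
    statistic = unname(est / se[names(est)])
  )
}

#' @rdname fit_frontier
#' @method glance frontier_fit
#' @export
glance.frontier_fit <- function(x, ...) {
  tibble::tibble(
    sigma_sq = x$sigma_sq, gamma = x$gamma, logLik = x$loglik,
    n = x$n, dropped = x$dropped, converged = x$converged
  )
}

#' Per-farm technical efficiency scores
#'
#' Point efficiencies from the conditional distribution of the half-normal
#' inefficiency `u` given the composed residual `eps`: with
#' `mu*_i = gamma * eps_i` and `sigma*^2 = gamma (1 - gamma) sigma^2`, the
#' default (Battese-Coelli) estimator is the conditional expectation
#' `TE_i = E[exp(-u_i) | eps_i] =
#'   exp(-mu*_i + sigma*^2/2) Phi(mu*_i/sigma* - sigma*) / Phi(mu*_i/sigma*)`,
#' and the alternative (`"jlms"`) is `exp(-E[u_i | eps_i])`. Scores lie in
#' (0, 1]; Phi ratios are floored away from zero at `prob_floor`.
#'
#' @param fit A converged `frontier_fit`.
#' @param estimator `"bc"` (conditional expectation of `exp(-u)`, default)
#'   or `"jlms"` (`exp(-E[u|eps])`).
#' @param prob_floor Floor applied to the denominator Phi.
#' @returns A tibble `farm_id`, `te`, with the mean score in attribute
#'   `mean_te`.
#' @export
technical_efficiency <- function(fit, estimator = c("bc", "jlms"),
                                 prob_floor = 1e-300) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(fit, "frontier_fit"))
  if (!fit$converged) warn("frontier fit did not converge; scores indicative")
  design <- fit$design
  eps <- drop(design$r - design$X %*% fit$coefficients)
  te <- te_from_eps(eps, fit$sigma_sq, fit$gamma, estimator, prob_floor)
  out <- tibble::tibble(farm_id = design$farm_id, te = te)
  attr(out, "mean_te") <- mean(te)
  out
}

# efficiency scores from residuals; shared by technical_efficiency and the
# oracle-facing tests
te_from_eps <- function(eps, sigma_sq, gamma, estimator = "bc",
                        prob_floor = 1e-300) {
  if (gamma <= 0) return(rep(1, length(eps)))
  mu_star <- gamma * eps
  s_star <- sqrt(gamma * (1 - gamma) * sigma_sq)
  if (s_star == 0) return(pmin(exp(-pmax(mu_star, 0)), 1))
  z <- mu_star / s_star
  te <- if (estimator == "bc") {
    exp(-mu_star + s_star^2 / 2) * pnorm(z - s_star) /
      pmax(pnorm(z), prob_floor)
  } else {
    exp(-(mu_star + s_star * dnorm(z) / pmax(pnorm(z), prob_floor)))
  }
  pmin(pmax(te, .Machine$double.xmin), 1)
}

#' z-test for the presence of inefficiency
#'
#' Tests the null of no inefficiency via the parameter representing
#' inefficiency effects divided by its standard error: `z = gamma / SE(gamma)`
#' with a one-sided normal reference, `p = 1 - Phi(z)`. The significance
#' band is the smallest of 0.001, 0.01, 0.05, 0.1 that `p` falls under, or
#' `"none"`.
#'
#' @param fit A `frontier_fit` with a standard error for `gamma`.
#' @returns One-row tibble: `z_value`, `p_value`, `significant_at`.
#' @export
inefficiency_z_test <- function(fit) {
  se <- fit$std_errors[["gamma"]]
  if (is.na(se) || se == 0) {
    abort("degenerate information: no usable standard error for gamma",
          class = "dairygap_degenerate_information_error")
  }
  z <- fit$gamma / se
  z_band(z)
}

# band mapping for a given z statistic (exposed through inefficiency_z_test;
# kept separate so printed z values can be mapped directly)
z_band <- function(z) {
  p <- pnorm(z, lower.tail = FALSE)
  bands <- c(0.001, 0.01, 0.05, 0.1)
  hit <- bands[p < bands]
  tibble::tibble(
    z_value = z, p_value = p,
    significant_at = if (length(hit)) paste0("<", format(hit[1])) else "none"
  )
}

#' Convert mean technical efficiency to a yield-gap percentage
#'
#' The percentage increase in output needed to reach the frontier at the
#' observed input basket: `gap = (1/TE - 1) * 100`. Zero iff fully
#' efficient. Because the reciprocal is convex, applying this farm-wise and
#' averaging gives a larger gap than applying it to the mean score; both
#' conventions are therefore useful (`gap_from_efficiency(mean(te))` vs
#' `mean(gap_from_efficiency(te))`).
#'
#' @param te Technical efficiency score(s) in (0, 1].
#' @returns Percentage increase(s), >= 0.
#' @export
#' @examples
#' gap_from_efficiency(0.69)  # ~ 45
gap_from_efficiency <- function(te) {
  stopifnot(all(te > 0), all(te <= 1))
  (1 / te - 1) * 100
}

#' Histogram of technical efficiency scores
#'
#' @param x A `frontier_fit`.
#' @param ... Unused.
#' @returns A ggplot object.
#' @method autoplot frontier_fit
#' @export
autoplot.frontier_fit <- function(x, ...) {
  scores <- technical_efficiency(x)
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$te)) +
    ggplot2::geom_histogram(bins = 30, boundary = 1) +
    ggplot2::geom_vline(xintercept = mean(scores$te), linetype = 2) +
    ggplot2::labs(x = "technical efficiency", y = "farms") +
    ggplot2::theme_minimal()
}
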