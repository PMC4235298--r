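#' Control parameters for the Laplace GLMM fitter
#'
#' @param inner_tol Relative tolerance on the penalized deviance for the
#'   inner mode-finding iterations.
#' @param inner_maxit Maximum inner (penalized IRLS) iterations per
#'   objective evaluation.
#' @param outer_reltol Relative convergence tolerance of the outer
#'   optimization over log-SD parameters.
#' @param outer_maxit Maximum outer iterations.
#' @param log_sigma_floor Lower clamp on log-SD parameters (SDs cannot fall
#'   below `exp(log_sigma_floor)`), avoiding boundary pathologies.
#' @param boundary_tol SDs below this value are flagged as boundary fits and
#'   reported as 0.
#' @param theta_init Initial value of every log-SD parameter.
#' @return A named list of control values.
#' @export
glmm_control <- function(inner_tol = 1e-8, inner_maxit = 80,
                         outer_reltol = 1e-8, outer_maxit = 500,
                         log_sigma_floor = -10, boundary_tol = 1e-3,
                         theta_init = log(0.5)) {
  list(
    inner_tol = inner_tol, inner_maxit = inner_maxit,
    outer_reltol = outer_reltol, outer_maxit = outer_maxit,
    log_sigma_floor = log_sigma_floor, boundary_tol = boundary_tol,
    theta_init = theta_init
  )
}

# weighted binomial log-likelihood kernel for proportion data
# (non-integer successes allowed), with the generalized binomial constant
binom_loglik <- function(y, w, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  kern <- sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
  const <- sum(lgamma(w + 1) - lgamma(w * y + 1) - lgamma(w * (1 - y) + 1))
  kern + const
}

# Penalized IRLS to the joint mode of (beta, v_small) with the
# observation-level effect eliminated analytically: because its design is
# the identity, the OLRE enters the working-response normal equations only
# through the effective weights W / (1 + sigma_obs^2 W), and its mode is
# recovered in closed form afterwards.
pirls_mode <- function(y, w, X, Zs, sigma_s, sigma_o, pen_mask, eta0, control) {
  n <- length(y)
  Xs <- X
  if (length(sigma_s) > 0) {
    Zsc <- Zs
    off <- 0
    for (k in seq_along(sigma_s)) {
      Zsc[, off + seq_len(attr(Zs, "levels")[k])] <-
        Zs[, off + seq_len(attr(Zs, "levels")[k])] * sigma_s[k]
      off <- off + attr(Zs, "levels")[k]
    }
    Xs <- cbind(X, Zsc)
  }
  m <- ncol(Xs)
  D <- diag(pen_mask, m, m)
  eta <- eta0
  a <- rep(0, m)
  b <- rep(0, n)
  pdev_of <- function(eta, a, b) {
    mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
    -2 * sum(w * (y * log(mu) + (1 - y) * log(1 - mu))) +
      sum(a^2 * pen_mask) + sum(b^2)
  }
  pdev <- pdev_of(eta, a, b)
  conv <- FALSE
  for (it in seq_len(control$inner_maxit)) {
    mu <- pmin(pmax(plogis(eta), 1e-6), 1 - 1e-6)
    W <- w * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    Wt <- W / (1 + sigma_o^2 * W)
    XsW <- Xs * Wt
    H <- crossprod(XsW, Xs) + D
    a_new <- tryCatch(
      drop(solve(H, crossprod(XsW, z))),
      error = function(e) {
        hd_abort(paste0("fixed-effect design is computationally singular; ",
                        "there are likely more plot-level predictors than ",
                        "plots can support (", conditionMessage(e), ")"),
                 "singular")
      }
    )
    r <- z - drop(Xs %*% a_new)
    b_new <- sigma_o * W * r / (1 + sigma_o^2 * W)
    # step-halving on the penalized deviance
    step <- 1
    repeat {
      a_try <- a + step * (a_new - a)
      b_try <- b + step * (b_new - b)
      eta_try <- drop(Xs %*% a_try) + sigma_o * b_try
      pdev_try <- pdev_of(eta_try, a_try, b_try)
      if (pdev_try <= pdev + 1e-10 || step < 1e-4) break
      step <- step / 2
    }
    delta <- abs(pdev - pdev_try) / (abs(pdev_try) + 0.1)
    a <- a_try
    b <- b_try
    eta <- eta_try
    pdev <- pdev_try
    if (delta < control$inner_tol) {
      conv <- TRUE
      break
    }
  }
  mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
  W <- w * mu * (1 - mu)
  Wt <- W / (1 + sigma_o^2 * W)
  list(a = a, b = b, eta = eta, mu = mu, W = W, Wt = Wt,
       Xs = Xs, pdev = pdev, converged = conv, iter = it)
}

# Laplace-approximate log marginal likelihood at the conditional mode
laplace_loglik <- function(fit, y, w, p, sigma_o) {
  ll_data <- binom_loglik(y, w, fit$mu)
  pen <- 0.5 * (sum(fit$a[-seq_len(p)]^2) + sum(fit$b^2))
  logdet_obs <- sum(log1p(sigma_o^2 * fit$W))
  m <- ncol(fit$Xs)
  if (m > p) {
    Zv <- fit$Xs[, (p + 1):m, drop = FALSE]
    Gv <- crossprod(Zv * sqrt(fit$Wt)) + diag(m - p)
    logdet_small <- 2 * sum(log(diag(chol(Gv))))
  } else {
    logdet_small <- 0
  }
  ll_data - pen - 0.5 * (logdet_obs + logdet_small)
}

#' Fit a binomial mixed model by Laplace approximation
#'
#' Fits a logit-link binomial regression of per-sapling damage proportions
#' (`y`, weighted by leaf counts `w`) on standardized predictors, with
#' independent mean-zero random intercepts for each grouping factor in
#' `random` (typically crossed `species` and `plot` effects) plus an
#' optional observation-level random effect (OLRE) absorbing overdispersion.
#' The likelihood uses the proportional-binomial form, so non-integer
#' success counts are allowed.
#'
#' The marginal likelihood is approximated by a second-order (Laplace)
#' expansion of the joint log-likelihood around the conditional mode of the
#' random effects. The mode of fixed effects and random intercepts is found
#' jointly by penalized iteratively reweighted least squares, with the
#' observation-level block eliminated analytically (its design matrix is the
#' identity, so it only rescales the working weights); the outer
#' optimization runs over the log-SD parameters (Nelder-Mead, deterministic
#' initialization). Wald standard errors come from the fixed-effects block
#' of the inverse joint observed information.
#'
#' @param data A predictor table (see [build_predictor_table()] and
#'   [standardize_predictors()]).
#' @param predictors Character vector of fixed-effect columns (an intercept
#'   is always included); may be empty for an intercept-only model.
#' @param response,weights Column names of the damage proportion and the
#'   leaf-count trial weight.
#' @param random Grouping-factor columns for random intercepts (default
#'   `c("species", "plot")`).
#' @param olre Include an observation-level random intercept? Default `TRUE`.
#' @param fixed_sigma Optional named numeric vector pinning SDs of specific
#'   components instead of estimating them, e.g. `c(species = 0, plot = 0,
#'   obs = 0)` for the fixed-effects-only limit. Use the factor column name,
#'   or `"obs"` for the observation-level term.
#' @param control A list from [glmm_control()].
#' @param theta_init Optional named starting values for the free log-SDs
#'   (used to warm-start refits during model selection).
#' @return An object of class `herb_glmm` with coefficient table, variance
#'   components, Laplace log-likelihood, AICc and diagnostics; see
#'   [tidy.herb_glmm()] and [glance.herb_glmm()].
#' @export
fit_binomial_glmm <- function(data, predictors = character(),
                              response = "y", weights = "w",
                              random = c("species", "plot"), olre = TRUE,
                              fixed_sigma = NULL, control = glmm_control(),
                              theta_init = NULL) {
  y <- data[[response]]
  w <- data[[weights]]
  n <- length(y)
  if (any(y < 0 | y > 1)) hd_abort("response must lie in [0, 1]", "validation")
  if (any(w < 1)) hd_abort("trial weights must be >= 1", "validation")
  X <- cbind(`(Intercept)` = rep(1, n))
  if (length(predictors) > 0) {
    miss <- setdiff(predictors, names(data))
    if (length(miss) > 0) {
      hd_abort(paste0("unknown predictor(s): ", paste(miss, collapse = ", ")),
               "argument")
    }
    X <- cbind(X, as.matrix(data[, predictors, drop = FALSE]))
  }
  p <- ncol(X)
  if (n <= p + 2) hd_abort("too few observations for the requested model", "validation")

  # dense indicator blocks for the small crossed factors
  fac_levels <- integer(0)
  Zs <- NULL
  if (length(random) > 0) {
    blocks <- lapply(random, function(f) {
      fx <- factor(data[[f]])
      stats::model.matrix(~ fx - 1)
    })
    fac_levels <- vapply(blocks, ncol, integer(1))
    Zs <- do.call(cbind, blocks)
    attr(Zs, "levels") <- fac_levels
  }
  comp_names <- c(random, if (olre) "obs")
  fixed_sigma <- fixed_sigma %||% numeric(0)
  bad_fix <- setdiff(names(fixed_sigma), comp_names)
  if (length(bad_fix) > 0) {
    hd_abort(paste0("fixed_sigma names not in model: ",
                    paste(bad_fix, collapse = ", ")), "argument")
  }
  free <- setdiff(comp_names, names(fixed_sigma))

  sigma_of <- function(theta) {
    s <- setNames(rep(0, length(comp_names)), comp_names)
    s[names(fixed_sigma)] <- fixed_sigma
    if (length(free) > 0) {
      s[free] <- exp(pmax(theta, control$log_sigma_floor))
    }
    s
  }
  pen_mask <- c(rep(0, p), rep(1, sum(fac_levels)))

  # warm start of the linear predictor carried across objective evaluations
  env <- new.env()
  env$eta <- qlogis(pmin(pmax((w * y + 0.5) / (w + 1), 0.02), 0.98))

  objective <- function(theta) {
    s <- sigma_of(theta)
    sig_s <- if (length(random) > 0) unname(s[random]) else numeric(0)
    sig_o <- if (olre) unname(s["obs"]) else 0
    mode <- pirls_mode(y, w, X, Zs, sig_s, sig_o, pen_mask, env$eta, control)
    env$eta <- mode$eta
    -laplace_loglik(mode, y, w, p, sig_o)
  }

  if (length(free) > 0) {
    th0 <- setNames(rep(control$theta_init, length(free)), free)
    if (!is.null(theta_init)) {
      common <- intersect(names(theta_init), free)
      th0[common] <- theta_init[common]
    }
    opt <- if (length(free) == 1) {
      o <- stats::optimize(function(t) objective(t), interval = c(-8, 4), tol = 1e-7)
      list(par = setNames(o$minimum, free), value = o$objective,
           convergence = 0L, counts = NA_integer_)
    } else {
      o <- optim(th0, objective, method = "Nelder-Mead",
                 control = list(reltol = control$outer_reltol,
                                maxit = control$outer_maxit))
      list(par = o$par, value = o$value, convergence = o$convergence,
           counts = o$counts[1])
    }
    theta_hat <- opt$par
    if (opt$convergence != 0) {
      rlang::warn(paste0("outer optimization did not converge (code ",
                         opt$convergence, ")"))
    }
  } else {
    theta_hat <- numeric(0)
    opt <- list(convergence = 0L, counts = 0L)
  }

  s_hat <- sigma_of(theta_hat)
  sig_s <- if (length(random) > 0) unname(s_hat[random]) else numeric(0)
  sig_o <- if (olre) unname(s_hat["obs"]) else 0
  mode <- pirls_mode(y, w, X, Zs, sig_s, sig_o, pen_mask, env$eta, control)
  if (!mode$converged) {
    hd_abort(paste0("inner mode-finding did not converge in ",
                    control$inner_maxit, " iterations"), "convergence")
  }
  ll <- laplace_loglik(mode, y, w, p, sig_o)

  H <- crossprod(mode$Xs * mode$Wt, mode$Xs) +
    diag(pen_mask, ncol(mode$Xs), ncol(mode$Xs))
  V <- solve(H)
  beta <- unname(mode$a[seq_len(p)])
  se <- unname(sqrt(pmax(diag(V)[seq_len(p)], 0)))
  zval <- beta / se
  coefs <- tibble::tibble(
    term = colnames(X), estimate = unname(beta), std.error = unname(se),
    statistic = unname(zval), p.value = 2 * pnorm(-abs(zval))
  )
  boundary <- s_hat < control$boundary_tol
  s_report <- ifelse(boundary, 0, s_hat)
  k <- p + length(free)

  ranef <- NULL
  if (length(random) > 0) {
    v <- mode$a[-seq_len(p)]
    off <- 0
    ranef <- list()
    for (i in seq_along(random)) {
      idx <- off + seq_len(fac_levels[i])
      lv <- levels(factor(data[[random[i]]]))
      ranef[[random[i]]] <- setNames(sig_s[i] * v[idx], lv)
      off <- off + fac_levels[i]
    }
  }

  structure(list(
    coefficients = coefs,
    sigma = setNames(s_report, comp_names),
    sigma_raw = setNames(s_hat, comp_names),
    boundary = setNames(boundary, comp_names),
    logLik = ll, k = k, n = n, aicc = aicc(ll, k, n),
    predictors = predictors, random = random, olre = olre,
    fixed_sigma = fixed_sigma,
    theta = theta_hat,
    fitted = mode$mu, eta = mode$eta,
    ranef = ranef,
    X = X, y = y, w = w,
    convergence = list(outer_code = opt$convergence, outer_evals = opt$counts,
                       inner_iter = mode$iter)
  ), class = "herb_glmm")
}

#' @export
print.herb_glmm <- function(x, ...) {
  cat("Binomial mixed model (Laplace approximation)\n")
  cat("  n =", x$n, " logLik =", format(x$logLik, digits = 6),
      " AICc =", format(x$aicc, digits = 6), "\n")
  if (length(x$sigma) > 0) {
    cat("  random-intercept SDs (logit scale):\n")
    for (nm in names(x$sigma)) {
      cat("    ", nm, "=", format(x$sigma[[nm]], digits = 4),
          if (x$boundary[[nm]]) "(boundary)" else "", "\n")
    }
  }
  print(x$coefficients)
  invisible(x)
}

#' Tidy and summarize fitted mixed models
#'
#' `tidy()` returns the fixed-effect table (standardized estimate, SE, Wald
#' z and two-sided normal P); `glance()` returns one-row model-level
#' summaries.
#'
#' @param x A `herb_glmm` fit.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.herb_glmm <- function(x, ...) x$coefficients

#' @rdname tidy.herb_glmm
#' @export
glance.herb_glmm <- function(x, ...) {
  out <- tibble::tibble(nobs = x$n, k = x$k, logLik = x$logLik, AICc = x$aicc)
  for (nm in names(x$sigma)) out[[paste0("sigma_", nm)]] <- x$sigma[[nm]]
  out
}

#' @rdname tidy.herb_glmm
#' @param object A `herb_glmm` fit.
#' @export
autoplot.herb_glmm <- function(object, ...) {
  d <- object$coefficients |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::mutate(term = stats::reorder(.data$term, abs(.data$estimate)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error
    )) +
    ggplot2::labs(x = "standardized estimate (logit scale)", y = NULL)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param logLik Maximized log-likelihood.
#' @param k Number of estimated parameters (fixed effects including the
#'   intercept, plus estimated variance components).
#' @param n Number of observations.
#' @return The AICc value.
#' @export
#' @examples
#' aicc(-5, 2, 10) # 14 + 12/7
aicc <- function(logLik, k, n) {
  if (n <= k + 1) hd_abort("AICc requires n > k + 1", "domain")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}
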