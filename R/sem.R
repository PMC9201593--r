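#' Path model specification (observed variables)
#'
#' A recursive (acyclic) path model over observed variables: directed
#' paths among named columns of a feature table. Fixed (non-free) paths
#' are constrained to zero.
#'
#' @param paths data.frame with columns `from`, `to` (and optionally
#'   `free`, default `TRUE`).
#' @return object of class `"path_model_spec"`: the paths plus the
#'   variable set in a topological order.
#' @seealso [build_mediation_spec()], [parse_path_dsl()]
#' @export
path_model_spec <- function(paths) {
  stopifnot(is.data.frame(paths), all(c("from", "to") %in% names(paths)))
  if (is.null(paths$free)) paths$free <- TRUE
  stop_if(any(paths$from == paths$to), "self-loops are not allowed")
  stop_if(anyDuplicated(paths[c("from", "to")]) > 0, "duplicate paths")
  g <- igraph::graph_from_data_frame(paths[c("from", "to")])
  stop_if(!igraph::is_dag(g), "path graph must be acyclic")
  vars <- igraph::topo_sort(g, mode = "out")$name
  structure(list(paths = paths, variables = vars),
            class = "path_model_spec")
}

#' @export
print.path_model_spec <- function(x, ...) {
  cat(sprintf("<path_model_spec> %d variables, %d paths\n",
              length(x$variables), nrow(x$paths)))
  for (i in seq_len(nrow(x$paths))) {
    cat(sprintf("  %s -> %s%s\n", x$paths$from[i], x$paths$to[i],
                if (x$paths$free[i]) "" else " (fixed 0)"))
  }
  invisible(x)
}

#' Build a 1- or 2-mediator path model
#'
#' Paths `input -> each mediator`, `each mediator -> output`, and the
#' direct `input -> output`: 3 paths with one mediator, 5 with two.
#'
#' @param input,output variable names.
#' @param mediators character vector of 1 or 2 mediator names.
#' @return a [path_model_spec()].
#' @examples
#' build_mediation_spec("tpdc", c("coherence", "power"), "su_rate")
#' @export
build_mediation_spec <- function(input, mediators, output) {
  stopifnot(length(mediators) %in% 1:2)
  vars <- c(input, mediators, output)
  stop_if(anyDuplicated(vars) > 0, "variable names must be distinct")
  paths <- rbind(
    data.frame(from = input, to = mediators),
    data.frame(from = mediators, to = output),
    data.frame(from = input, to = output))
  path_model_spec(paths)
}

#' Parse a small path-model text DSL
#'
#' Statements `from -> to`, separated by `;` or newlines, e.g.
#' `"tpdc -> coh; tpdc -> pow; coh -> su; pow -> su; tpdc -> su"`.
#'
#' @param text the model string.
#' @return a [path_model_spec()].
#' @export
parse_path_dsl <- function(text) {
  stmts <- trimws(unlist(strsplit(text, "[;\n]")))
  stmts <- stmts[nzchar(stmts)]
  m <- regmatches(stmts, regexec("^([A-Za-z0-9_.]+)\\s*->\\s*([A-Za-z0-9_.]+)$", stmts))
  bad <- vapply(m, length, integer(1)) != 3L
  stop_if(any(bad), "cannot parse path statement '%s'", stmts[bad][1])
  path_model_spec(data.frame(from = vapply(m, `[`, "", 2L),
                             to = vapply(m, `[`, "", 3L)))
}

# implied covariance of a recursive path model:
# Sigma = (I - B)^{-1} Psi (I - B)^{-T}
implied_sigma <- function(B, Psi) {
  IB <- solve(diag(nrow(B)) - B)
  IB %*% Psi %*% t(IB)
}

#' Fit a path model by maximum likelihood
#'
#' Minimizes the ML discrepancy
#' `F = log|Sigma(theta)| + tr(S Sigma(theta)^-1) - log|S| - k`
#' over the free path coefficients and disturbance (co)variances of a
#' recursive observed-variable path model; `chi^2 = (n - 1) F` at the
#' optimum. Disturbances are uncorrelated by default;
#' `free_mediator_cov` frees one covariance between the two mediators of
#' a [build_mediation_spec()] model.
#'
#' @param spec a [path_model_spec()].
#' @param data data.frame containing every model variable (complete
#'   cases only).
#' @param free_mediator_cov free the disturbance covariance between the
#'   2nd and 3rd variables in topological order (the two mediators of a
#'   mediation spec). Default FALSE.
#' @return An object of class `"sem_fit"`: standardized and raw path
#'   coefficients with SEs and p-values, `chi2`, `df`, `rmsea`, `aic`
#'   (chi-square + 2 q convention), `aic_loglik` (-2 logL + 2 q),
#'   `n`, `converged`, `sigma_hat`.
#' @export
fit_ml <- function(spec, data, free_mediator_cov = FALSE) {
  stopifnot(inherits(spec, "path_model_spec"), is.data.frame(data))
  vars <- spec$variables
  stop_if(!all(vars %in% names(data)), "data lacks column(s): %s",
          paste(setdiff(vars, names(data)), collapse = ", "))
  X <- as.matrix(data[vars])
  stop_if(anyNA(X), "data must be complete for all model variables")
  n <- nrow(X); k <- length(vars)
  S <- stats::cov(X)
  stop_if(!all(is.finite(S)) || det(S) <= 0, "sample covariance is singular")
  free <- spec$paths[spec$paths$free, , drop = FALSE]
  q_paths <- nrow(free)
  cov_pair <- NULL
  if (free_mediator_cov) {
    stop_if(k < 4L, "free_mediator_cov needs a two-mediator model")
    cov_pair <- c(2L, 3L)
  }
  n_free <- q_paths + k + length(cov_pair) / 2
  stop_if(n <= n_free, "n (%d) must exceed the number of free parameters (%d)",
          n, n_free)
  bi <- match(free$to, vars); bj <- match(free$from, vars)
  build <- function(theta) {
    B <- matrix(0, k, k)
    B[cbind(bi, bj)] <- theta[seq_len(q_paths)]
    psi <- exp(theta[q_paths + seq_len(k)])
    Psi <- diag(psi, k)
    if (!is.null(cov_pair)) {
      rho <- tanh(theta[q_paths + k + 1L])
      Psi[cov_pair[1], cov_pair[2]] <- Psi[cov_pair[2], cov_pair[1]] <-
        rho * sqrt(psi[cov_pair[1]] * psi[cov_pair[2]])
    }
    list(B = B, Psi = Psi)
  }
  logdetS <- determinant(S, logarithm = TRUE)$modulus
  discrepancy <- function(theta) {
    m <- build(theta)
    Sig <- implied_sigma(m$B, m$Psi)
    ld <- determinant(Sig, logarithm = TRUE)
    if (ld$sign <= 0) return(1e10)
    v <- as.numeric(ld$modulus + sum(diag(S %*% solve(Sig))) - logdetS - k)
    if (!is.finite(v)) 1e10 else v
  }
  # start values: equation-wise OLS (ML for a recursive model with
  # diagonal Psi), exogenous variances from the sample
  theta0 <- numeric(n_free)
  psi0 <- diag(S)
  for (v in vars) {
    par <- free$from[free$to == v]
    if (length(par)) {
      fit0 <- stats::lm.fit(cbind(1, X[, par, drop = FALSE]), X[, v])
      cf <- fit0$coefficients[-1]
      theta0[which(free$to == v)] <- cf[free$from[free$to == v]]
      psi0[v] <- sum(fit0$residuals^2) / (n - 1)
    }
  }
  theta0[q_paths + seq_len(k)] <- log(pmax(psi0[vars], 1e-8))
  opt <- stats::optim(theta0, discrepancy, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  grad <- numDeriv_grad(discrepancy, opt$par)
  if (opt$convergence != 0 && sqrt(sum(grad^2)) > 1e-4) {
    stop(sprintf("ML fit did not converge (gradient norm %.3g)",
                 sqrt(sum(grad^2))), call. = FALSE)
  }
  theta <- opt$par
  m <- build(theta)
  Sig <- implied_sigma(m$B, m$Psi)
  Fmin <- opt$value
  chi2 <- max(0, (n - 1) * Fmin)
  df <- k * (k + 1) / 2 - n_free
  H <- stats::optimHess(theta, discrepancy)
  acov <- tryCatch(solve(H * (n - 1) / 2), error = function(e) NULL)
  se <- if (is.null(acov)) rep(NA_real_, n_free) else {
    d <- diag(acov); d[d < 0] <- NA; sqrt(d)
  }
  sds <- sqrt(diag(Sig))
  est <- data.frame(from = free$from, to = free$to,
                    estimate = theta[seq_len(q_paths)],
                    se = se[seq_len(q_paths)],
                    stringsAsFactors = FALSE)
  est$z <- est$estimate / est$se
  est$p_value <- 2 * stats::pnorm(-abs(est$z))
  est$standardized <- est$estimate * sds[match(est$from, vars)] /
    sds[match(est$to, vars)]
  S_ml <- S * (n - 1) / n
  loglik <- -(n / 2) * (k * log(2 * pi) +
    as.numeric(determinant(Sig, logarithm = TRUE)$modulus) +
    sum(diag(S_ml %*% solve(Sig))))
  structure(list(paths = est, chi2 = chi2, df = df, n = n,
                 n_free = n_free,
                 rmsea = rmsea(chi2, df, n),
                 aic = chi2 + 2 * n_free,
                 aic_loglik = -2 * loglik + 2 * n_free,
                 loglik = loglik,
                 sigma_hat = Sig, psi = m$Psi, B = m$B,
                 variables = vars, spec = spec,
                 converged = opt$convergence == 0,
                 gradient_norm = sqrt(sum(grad^2))),
            class = "sem_fit")
}

# central-difference gradient (small helper; models here have < 15
# parameters so numerical differentiation is cheap)
numDeriv_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("<sem_fit> n=%d, chi2=%.4g on df=%g, RMSEA=%.4g, AIC=%.4g\n",
              x$n, x$chi2, x$df, x$rmsea, x$aic))
  p <- x$paths
  cat("  standardized paths:\n")
  for (i in seq_len(nrow(p))) {
    cat(sprintf("    %s -> %s: s=%.3f (p=%.3g)\n", p$from[i], p$to[i],
                p$standardized[i], p$p_value[i]))
  }
  invisible(x)
}

#' @export
summary.sem_fit <- function(object, ...) {
  cat(sprintf("Path model fit by maximum likelihood (n = %d)\n", object$n))
  cat(sprintf("chi-square %.4f on %g df; RMSEA %.4f; AIC %.4f (-2logL+2q: %.2f)\n",
              object$chi2, object$df, object$rmsea, object$aic,
              object$aic_loglik))
  print(object$paths, digits = 3)
  invisible(object)
}

#' @export
coef.sem_fit <- function(object, standardized = TRUE, ...) {
  p <- object$paths
  stats::setNames(if (standardized) p$standardized else p$estimate,
                  paste(p$from, p$to, sep = "->"))
}

#' Root-mean-square error of approximation
#'
#' `sqrt(max(0, (chi2 - df) / (df (n - 1))))`; 0 by definition for a
#' saturated model (df = 0). Values below 0.05 conventionally indicate
#' close fit.
#'
#' @param chi2 model chi-square.
#' @param df model degrees of freedom (>= 0).
#' @param n sample size (>= 2).
#' @return RMSEA (non-negative scalar).
#' @examples
#' rmsea(20, 10, 101)   # 0.1
#' @export
rmsea <- function(chi2, df, n) {
  stop_if(df < 0, "df must be >= 0")
  stop_if(n < 2, "n must be >= 2")
  if (df == 0) return(0)
  sqrt(max(0, (chi2 - df) / (df * (n - 1))))
}

#' Akaike information criterion of a path-model fit
#'
#' SEM convention: `chi2 + 2 q` with `q` free parameters (the
#' `-2 logL + 2 q` variant is available as `fit$aic_loglik`). Smaller is
#' better; only differences between models on the same data are
#' meaningful.
#'
#' @param fit a [fit_ml()] result.
#' @return numeric AIC.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  fit$aic
}

#' Invariance of standardized coefficients under constant scaling
#'
#' Refits the model after multiplying each column by an independent
#' random positive constant and reports the largest absolute change in
#' any standardized coefficient. For a correctly implemented
#' covariance-based fit this is ~0 (standardization removes scale); it
#' serves as an internal consistency criterion.
#'
#' @param spec a [path_model_spec()].
#' @param data feature table.
#' @param n_draws random rescalings (default 5).
#' @param scale_range log-uniform range of the scaling constants.
#' @param seed integer RNG seed.
#' @return largest absolute change in standardized coefficients.
#' @export
ics_criterion <- function(spec, data, n_draws = 5L,
                          scale_range = c(0.1, 10), seed = NULL) {
  base <- fit_ml(spec, data)$paths$standardized
  with_seed(seed, {
    worst <- 0
    for (i in seq_len(n_draws)) {
      sc <- exp(stats::runif(length(spec$variables),
                             log(scale_range[1]), log(scale_range[2])))
      d2 <- data
      for (j in seq_along(spec$variables)) {
        v <- spec$variables[j]
        d2[[v]] <- d2[[v]] * sc[j]
      }
      s2 <- fit_ml(spec, d2)$paths$standardized
      worst <- max(worst, max(abs(s2 - base)))
    }
    worst
  })
}
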