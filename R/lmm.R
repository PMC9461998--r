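#' Prepare a trial table for mixed modelling
#'
#' Applies the standard encodings: two-level factors are sum-coded
#' (canonical level +1, so the intercept is the grand mean), continuous
#' predictors are z-transformed over the analysis set, and orthogonal
#' polynomial columns are added for predictors modelled with higher-order
#' trends (conventionally prestimulus amplitude to 2nd order and
#' speaker-based surprisal to 3rd order). Rows with missing values in any
#' referenced column are dropped with a message. All transform constants
#' are stored in the `"transforms"` attribute and can be re-applied to new
#' data for out-of-sample prediction.
#'
#' @param data Trial data.frame.
#' @param sum_code Character vector of factor columns to sum-code. Each
#'   becomes a numeric +1/-1 column (first sorted level, or `"C"` if
#'   present, maps to +1).
#' @param zscore Character vector of continuous columns to z-transform
#'   in place.
#' @param poly Named list: column -> polynomial degree. Adds columns
#'   `<col>_p1 ... <col>_p<degree>` (orthogonal on the design points).
#' @param transforms Stored transforms from a previous call, to re-apply
#'   the same centring/scaling/polynomial basis to new rows.
#' @return The transformed data.frame with attribute `"transforms"`.
#' @export
build_model_frame <- function(data, sum_code = character(0L),
                              zscore = character(0L), poly = list(),
                              transforms = NULL) {
  cols <- unique(c(sum_code, zscore, names(poly)))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L) {
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))
  }
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  if (!all(keep)) {
    message(sum(!keep), " row(s) with missing values dropped")
    data <- data[keep, , drop = FALSE]
  }
  tr <- transforms %||% list(sum_code = list(), zscore = list(), poly = list())
  for (f in sum_code) {
    lv <- tr$sum_code[[f]] %||% {
      u <- sort(unique(as.character(data[[f]])))
      if ("C" %in% u) u <- c("C", setdiff(u, "C"))
      u
    }
    if (length(lv) != 2L) stop("sum coding requires exactly 2 levels in ", f)
    tr$sum_code[[f]] <- lv
    data[[f]] <- ifelse(as.character(data[[f]]) == lv[[1L]], 1, -1)
  }
  for (v in zscore) {
    ms <- tr$zscore[[v]] %||% c(mean = mean(data[[v]]), sd = stats::sd(data[[v]]))
    if (ms[["sd"]] == 0) stop("constant continuous predictor: ", v)
    tr$zscore[[v]] <- ms
    data[[v]] <- (data[[v]] - ms[["mean"]]) / ms[["sd"]]
  }
  for (v in names(poly)) {
    deg <- poly[[v]]
    basis <- if (!is.null(tr$poly[[v]])) {
      stats::predict(tr$poly[[v]], data[[v]])
    } else {
      p <- stats::poly(data[[v]], degree = deg)
      tr$poly[[v]] <- p
      p
    }
    for (j in seq_len(deg)) data[[paste0(v, "_p", j)]] <- basis[, j]
  }
  attr(data, "transforms") <- tr
  data
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- formula parsing -------------------------------------------------------

# split a mixed formula into fixed part and (expr | group) random terms
split_vc_formula <- function(formula) {
  rhs <- formula[[3L]]
  flatten <- function(e) {
    if (is.call(e) && identical(e[[1L]], as.name("+"))) {
      c(flatten(e[[2L]]), flatten(e[[3L]]))
    } else list(e)
  }
  is_bar <- function(e) {
    (is.call(e) && identical(e[[1L]], as.name("|"))) ||
      (is.call(e) && identical(e[[1L]], as.name("(")) && is.call(e[[2L]]) &&
         identical(e[[2L]][[1L]], as.name("|")))
  }
  unwrap <- function(e) if (identical(e[[1L]], as.name("("))) e[[2L]] else e
  parts <- flatten(rhs)
  bars <- lapply(Filter(is_bar, parts), unwrap)
  fixed <- Filter(Negate(is_bar), parts)
  fixed_str <- if (length(fixed) == 0L) "1" else
    paste(vapply(fixed, function(e) deparse(e, width.cutoff = 500L),
                 character(1L)), collapse = " + ")
  fixed_formula <- stats::as.formula(
    paste(deparse(formula[[2L]]), "~", fixed_str), env = environment(formula))
  list(fixed = fixed_formula, bars = bars)
}

#' Fit a crossed variance-components linear mixed model
#'
#' Random-effect terms are written lme4-style, `(expr | group)`, but every
#' column of the term's model matrix becomes an independent variance
#' component: covariances between random effects are structurally zero
#' (the diagonal "parsimonious" structure in which correlation parameters
#' are constrained to zero). Estimation profiles the deviance over the
#' ratios `theta = sd_component / sd_residual`: for each `theta` the fixed
#' effects, the conditional modes and the residual variance have closed
#' forms via a blocked Cholesky factorisation, and the resulting profiled
#' REML (default) or ML criterion is minimised by bounded quasi-Newton
#' search on the log-ratio scale (relative tolerance 1e-8). Deterministic
#' given data and options.
#'
#' @param formula Model formula, e.g.
#'   `amplitude ~ surprisal * epoch_z + canonicity + (1 | subject) + (1 | item)`.
#' @param data Trial data.frame (typically from [build_model_frame()]).
#' @param REML Use the REML criterion (default `TRUE`); `FALSE` gives ML,
#'   required for likelihood-ratio model comparison.
#' @return A `vc_lmm` object with elements `beta` (coefficient table:
#'   estimate, se, z), `theta` (sd ratios per component), `sigma`
#'   (residual sd), `sd_components` (component sds in response units),
#'   `deviance` (the optimised -2 log-criterion), `df` (number of model
#'   parameters: fixed + components + residual), `aic`, `aicc`, `bic`,
#'   `n`, `REML`, `convergence`, plus the internals needed for fitted
#'   values and partial effects.
#' @export
fit_vc_lmm <- function(formula, data, REML = TRUE) {
  sp <- split_vc_formula(formula)
  if (length(sp$bars) == 0L) {
    stop("at least one random-effect term (expr | group) is required")
  }
  mf_terms <- stats::terms(sp$fixed)
  needed <- unique(c(all.vars(sp$fixed),
                     unlist(lapply(sp$bars, all.vars))))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))
  }
  keep <- stats::complete.cases(data[, needed, drop = FALSE])
  if (!all(keep)) {
    message(sum(!keep), " row(s) with missing values dropped")
    data <- data[keep, , drop = FALSE]
  }
  X <- stats::model.matrix(sp$fixed, data)
  y <- stats::model.response(stats::model.frame(sp$fixed, data))
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) stop("singular fixed-effects design")

  # one Z block and one theta per variance component (column x group)
  comp_name <- character(0L); comp_group <- character(0L)
  Zs <- list(); comp_q <- integer(0L); group_levels <- list()
  for (bar in sp$bars) {
    expr <- bar[[2L]]; grp <- deparse(bar[[3L]])
    f <- factor(data[[grp]])
    q <- nlevels(f)
    Xj <- stats::model.matrix(
      stats::reformulate(deparse(expr, width.cutoff = 500L)), data)
    for (cname in colnames(Xj)) {
      Zs[[length(Zs) + 1L]] <- Matrix::sparseMatrix(
        i = seq_len(n), j = as.integer(f), x = Xj[, cname], dims = c(n, q))
      comp_name <- c(comp_name, paste0(grp, ":", cname))
      comp_group <- c(comp_group, grp)
      comp_q <- c(comp_q, q)
      group_levels[[length(Zs)]] <- levels(f)
    }
  }
  B <- length(Zs)
  Z <- do.call(cbind, Zs)
  block <- rep.int(seq_len(B), comp_q)

  ZtZ <- as.matrix(Matrix::crossprod(Z))
  ZtX <- as.matrix(Matrix::crossprod(Z, X))
  Zty <- as.numeric(Matrix::crossprod(Z, y))
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y^2)
  qtot <- ncol(Z)

  profile <- function(log_theta, what = "dev") {
    lam <- exp(log_theta)[block]
    A <- ZtZ * tcrossprod(lam)
    diag(A) <- diag(A) + 1
    L <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(L)) return(if (what == "dev") 1e10 else NULL)
    cZX <- lam * ZtX
    cZy <- lam * Zty
    RZX <- backsolve(L, cZX, transpose = TRUE)
    cy <- backsolve(L, cZy, transpose = TRUE)
    S <- XtX - crossprod(RZX)
    Rx <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(Rx)) return(if (what == "dev") 1e10 else NULL)
    cb <- backsolve(Rx, Xty - crossprod(RZX, cy), transpose = TRUE)
    pwrss <- max(yty - sum(cy^2) - sum(cb^2), 1e-12)
    ldA <- 2 * sum(log(diag(L)))
    dev <- if (REML) {
      ldA + 2 * sum(log(diag(Rx))) +
        (n - p) * (1 + log(2 * pi * pwrss / (n - p)))
    } else {
      ldA + n * (1 + log(2 * pi * pwrss / n))
    }
    if (what == "dev") return(as.numeric(dev))
    beta <- backsolve(Rx, cb)
    u <- backsolve(L, cy - RZX %*% beta)
    sigma2 <- pwrss / (if (REML) n - p else n)
    vcov_beta <- sigma2 * chol2inv(Rx)
    list(dev = as.numeric(dev), beta = as.numeric(beta), u = as.numeric(u),
         sigma = sqrt(sigma2), vcov_beta = vcov_beta, pwrss = pwrss)
  }

  # derivative-free search on the log-ratio scale (the profiled deviance is
  # smooth but its gradient is awkward near component boundaries)
  if (B == 1L) {
    opt1 <- stats::optimize(profile, interval = c(-13, 8), tol = 1e-9)
    opt <- list(par = opt1$minimum, value = opt1$objective, convergence = 0L)
  } else {
    opt <- stats::optim(rep(0, B), profile, method = "Nelder-Mead",
                        control = list(maxit = 2000L, reltol = 1e-12))
    # polish from the NM optimum; keeps the boundary components stable
    opt2 <- stats::optim(opt$par, profile, method = "Nelder-Mead",
                         control = list(maxit = 2000L, reltol = 1e-12))
    if (opt2$value <= opt$value) opt <- opt2
  }
  opt$par <- pmin(pmax(opt$par, -13), 8)
  if (opt$convergence != 0L) {
    warning("variance-component optimisation did not fully converge (code ",
            opt$convergence, ")")
  }
  theta <- exp(opt$par)
  theta[theta < 2e-6] <- 0
  fin <- profile(log(pmax(theta, 2e-6)), what = "full")
  se <- sqrt(diag(fin$vcov_beta))
  beta_tab <- data.frame(term = colnames(X), estimate = fin$beta, se = se,
                         z = fin$beta / se, stringsAsFactors = FALSE)
  df <- p + B + 1L
  dev <- fin$dev
  aic <- dev + 2 * df
  structure(list(
    formula = formula, REML = REML, n = n, p = p,
    beta = beta_tab, theta = stats::setNames(theta, comp_name),
    sigma = fin$sigma,
    sd_components = stats::setNames(theta * fin$sigma, comp_name),
    u = fin$u, block = block, comp_name = comp_name,
    comp_group = comp_group, group_levels = group_levels,
    deviance = dev, df = df, aic = aic,
    aicc = aic + 2 * df * (df + 1) / max(n - df - 1, 1),
    bic = dev + df * log(n),
    vcov_beta = fin$vcov_beta,
    X = X, Z = Z, y = y,
    assign = attr(X, "assign"), terms = mf_terms,
    convergence = opt$convergence
  ), class = "vc_lmm")
}

#' @export
print.vc_lmm <- function(x, ...) {
  cat("Variance-components LMM (", if (x$REML) "REML" else "ML",
      "), n = ", x$n, "\n", sep = "")
  cat("Deviance:", format(x$deviance, digits = 8),
      " AIC:", format(x$aic, digits = 8),
      " BIC:", format(x$bic, digits = 8), "\n\n")
  cat("Random-effect standard deviations (residual sd ",
      format(x$sigma, digits = 4), "):\n", sep = "")
  print(round(x$sd_components, 4))
  cat("\nFixed effects:\n")
  print(x$beta, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Fitted values of a variance-components LMM
#'
#' @param object A `vc_lmm`.
#' @param ... Unused.
#' @return Numeric vector `X beta + Z b`.
#' @export
fitted.vc_lmm <- function(object, ...) {
  lam <- object$theta[object$block]
  as.numeric(object$X %*% object$beta$estimate +
               object$Z %*% (lam * object$u))
}

#' Compare fitted models by information criteria and likelihood-ratio tests
#'
#' Produces the conventional goodness-of-fit table (columns Model, dof,
#' Deviance, AIC, AICc, BIC) and, for successive nested pairs of ML fits,
#' the likelihood-ratio statistic (deviance difference) on the difference
#' in parameter count.
#'
#' @param fits Named list of `vc_lmm` fits on the same response rows.
#' @param lrt Run LRTs between successive fits? Requires ML fits in
#'   non-decreasing parameter order. Default `TRUE`.
#' @return A `vc_lmm_comparison`: data.frame with the criterion columns and
#'   (when requested) `lrt_stat`, `lrt_df`, `lrt_p` against the previous
#'   row.
#' @export
compare_models <- function(fits, lrt = TRUE) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, logical(1L),
                                           "vc_lmm")))
  if (is.null(names(fits))) names(fits) <- paste0("m", seq_along(fits))
  ns <- vapply(fits, `[[`, numeric(1L), "n")
  if (length(unique(ns)) != 1L) stop("fits use different response rows")
  tab <- data.frame(
    Model = names(fits),
    dof = vapply(fits, `[[`, integer(1L), "df"),
    Deviance = vapply(fits, `[[`, numeric(1L), "deviance"),
    AIC = vapply(fits, `[[`, numeric(1L), "aic"),
    AICc = vapply(fits, `[[`, numeric(1L), "aicc"),
    BIC = vapply(fits, `[[`, numeric(1L), "bic"),
    stringsAsFactors = FALSE
  )
  if (lrt && length(fits) >= 2L) {
    if (any(vapply(fits, `[[`, logical(1L), "REML"))) {
      stop("likelihood-ratio tests require ML fits (REML = FALSE)")
    }
    stat <- c(NA, -diff(tab$Deviance))
    dfd <- c(NA, diff(tab$dof))
    if (any(dfd[-1L] < 0)) stop("fits must be ordered by non-decreasing dof")
    tab$lrt_stat <- stat
    tab$lrt_df <- dfd
    tab$lrt_p <- ifelse(dfd > 0, stats::pchisq(stat, dfd, lower.tail = FALSE),
                        ifelse(is.na(dfd), NA, 1))
  }
  rownames(tab) <- NULL
  class(tab) <- c("vc_lmm_comparison", "data.frame")
  tab
}

#' Extract partial effects by removing fitted nuisance contributions
#'
#' Returns the observed response adjusted by subtracting the fitted
#' contributions of the fixed-effect terms and random-effect components
#' that are *not* kept (remef-style). Keeping everything returns the
#' observed response exactly; keeping nothing removes all modelled
#' structure, leaving intercept + residuals.
#'
#' @param fit A `vc_lmm`.
#' @param keep_fixed Character vector of fixed-effect term labels to keep
#'   (as in `attr(terms, "term.labels")`; the intercept is always kept),
#'   or `NULL` to keep all.
#' @param keep_re Character vector of random components to keep, matched
#'   against either the component name (`"subject:(Intercept)"`) or the
#'   grouping factor name (`"subject"`); `NULL` keeps all.
#' @return Numeric vector of adjusted response values.
#' @export
partial_effects <- function(fit, keep_fixed = NULL, keep_re = NULL) {
  stopifnot(inherits(fit, "vc_lmm"))
  labels <- attr(fit$terms, "term.labels")
  if (is.null(keep_fixed)) keep_fixed <- labels
  unknown <- setdiff(keep_fixed, labels)
  if (length(unknown) > 0L) {
    stop("unknown fixed term(s): ", paste(unknown, collapse = ", "))
  }
  drop_terms <- which(!(labels %in% keep_fixed))
  adj <- fit$y
  if (length(drop_terms) > 0L) {
    cols <- which(fit$assign %in% drop_terms)
    adj <- adj - as.numeric(fit$X[, cols, drop = FALSE] %*%
                              fit$beta$estimate[cols])
  }
  re_names <- unique(c(fit$comp_name, fit$comp_group))
  if (is.null(keep_re)) keep_re <- re_names
  unknown <- setdiff(keep_re, re_names)
  if (length(unknown) > 0L) {
    stop("unknown random component(s): ", paste(unknown, collapse = ", "))
  }
  keep_comp <- fit$comp_name %in% keep_re | fit$comp_group %in% keep_re
  if (!all(keep_comp)) {
    lam <- fit$theta[fit$block]
    u_drop <- lam * fit$u
    u_drop[keep_comp[fit$block]] <- 0
    adj <- adj - as.numeric(fit$Z %*% u_drop)
  }
  adj
}

#' Principal components of the fitted random-effect covariance
#'
#' With diagonal variance components the per-group random-effect covariance
#' is diagonal, so its principal directions are the components themselves;
#' the report gives, per grouping factor, the component standard deviations
#' relative to the residual sd and the cumulative proportion of
#' random-effect variance they explain — the overparameterisation
#' diagnostic used during random-effect structure selection.
#'
#' @param fit A `vc_lmm`.
#' @return Named list (one entry per grouping factor) of data.frames with
#'   `component`, `sd_ratio`, `prop_var`, `cum_prop`.
#' @export
re_pca <- function(fit) {
  stopifnot(inherits(fit, "vc_lmm"))
  out <- list()
  for (g in unique(fit$comp_group)) {
    idx <- which(fit$comp_group == g)
    v <- fit$theta[idx]^2
    ord <- order(v, decreasing = TRUE)
    prop <- if (sum(v) > 0) v[ord] / sum(v) else v[ord]
    out[[g]] <- data.frame(component = fit$comp_name[idx][ord],
                           sd_ratio = fit$theta[idx][ord],
                           prop_var = prop,
                           cum_prop = cumsum(prop),
                           row.names = NULL)
  }
  out
}

#' Simulation-based parameter recovery for the trial-amplitude model
#'
#' Repeats simulate-then-fit: each replicate draws a fresh trial table from
#' the generative model (via [simulate_trial_amplitudes()] with a
#' replicate-specific seed), fits the supplied model by REML (the criterion
#' used for variance and standard-error reporting; ML is reserved for
#' model comparison), and records the coefficients of interest. Reports bias, RMSE, Wald confidence-interval
#' coverage and rejection rate (share of |z| exceeding the two-sided
#' critical value — type-I error when the true value is zero, power
#' otherwise) for every coefficient named in `truth`.
#'
#' @param nps Surprisal-annotated NP table (see [add_surprisal()]).
#' @param participants Participant covariate table.
#' @param cfg A `sim_config`; its `beta_true` defines the generative truth.
#' @param formula Model formula for [fit_vc_lmm()].
#' @param truth Named numeric: model coefficient name -> true value.
#' @param n_reps Number of replicates (>= 2).
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @param conf_level Confidence level for coverage (default 0.95).
#' @param REML Criterion for the replicate fits (default `TRUE`).
#' @return A `recovery_report`: data.frame per coefficient with `bias`,
#'   `rmse`, `coverage`, `reject_rate`, `mean_se`; attributes `n_reps`,
#'   `n_failed`, `seed`, and `estimates` (the replicate-level draws).
#' @export
recovery_study <- function(nps, participants, cfg, formula, truth,
                           n_reps = 200L, seed = 1L, conf_level = 0.95,
                           REML = TRUE) {
  stopifnot(inherits(cfg, "sim_config"), n_reps >= 2L)
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- se <- matrix(NA_real_, n_reps, length(truth),
                      dimnames = list(NULL, names(truth)))
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg
    cfg_r$seed <- as.integer(seed + r)
    trials <- simulate_trial_amplitudes(nps, participants, cfg_r)
    fit <- tryCatch(fit_vc_lmm(formula, trials, REML = REML),
                    error = function(e) NULL)
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    m <- match(names(truth), fit$beta$term)
    est[r, ] <- fit$beta$estimate[m]
    se[r, ] <- fit$beta$se[m]
  }
  ok <- stats::complete.cases(est)
  report <- data.frame(
    term = names(truth),
    truth = as.numeric(truth),
    bias = colMeans(est[ok, , drop = FALSE]) - as.numeric(truth),
    rmse = sqrt(colMeans((est[ok, , drop = FALSE] -
                            matrix(truth, sum(ok), length(truth),
                                   byrow = TRUE))^2)),
    coverage = colMeans(abs(est[ok, , drop = FALSE] -
                              matrix(truth, sum(ok), length(truth),
                                     byrow = TRUE)) <=
                          zc * se[ok, , drop = FALSE]),
    reject_rate = colMeans(abs(est[ok, , drop = FALSE] /
                                 se[ok, , drop = FALSE]) > zc),
    mean_se = colMeans(se[ok, , drop = FALSE]),
    row.names = NULL
  )
  attr(report, "n_reps") <- n_reps
  attr(report, "n_failed") <- n_failed
  attr(report, "seed") <- seed
  attr(report, "estimates") <- est
  class(report) <- c("recovery_report", "data.frame")
  report
}
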