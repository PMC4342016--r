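#' AICc model dredging and multimodel averaging
#'
#' Diversity responses are regressed on disturbance, loss and spatial trend
#' predictors; for multi-life-stage plant data a linear mixed model with a
#' plot random intercept is used, for single-group data ordinary least
#' squares. All models are fitted by maximum likelihood (not REML) so AICc
#' values are comparable across fixed-effect structures. Every admissible
#' subset of the fixed terms (interactions only alongside both parents) is
#' fitted, models within `delta` AICc of the best are averaged with Akaike
#' weights, and per-term importances are the summed weights of retained
#' models containing the term.
#'
#' @name models_module
NULL

#' Z-transform a numeric vector
#'
#' @param x numeric vector with positive standard deviation.
#' @return `(x - mean) / sd`, using the sample standard deviation.
#' @export
z_transform <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort("Cannot Z-transform a constant column.")
  (x - mean(x)) / s
}

#' Small-sample Akaike information criterion
#'
#' @param log_likelihood model log-likelihood (ML).
#' @param k number of estimated parameters (fixed effects + variance
#'   components + residual variance).
#' @param n number of observations; must exceed `k + 1`.
#' @return `2k - 2 logLik + 2k(k+1)/(n - k - 1)`.
#' @export
aicc <- function(log_likelihood, k, n) {
  if (n <= k + 1) abort("AICc undefined: n must exceed k + 1.")
  2 * k - 2 * log_likelihood + 2 * k * (k + 1) / (n - k - 1)
}

term_formula <- function(response, terms, random_intercept = NULL) {
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  if (!is.null(random_intercept)) {
    rhs <- paste0(rhs, " + (1 | ", random_intercept, ")")
  }
  as.formula(paste(response, "~", rhs))
}

#' Fit one diversity regression by maximum likelihood
#'
#' @param data rectangular data (complete cases are required for the
#'   modelled columns).
#' @param response response column name.
#' @param terms character vector of fixed-effect terms (main effects and
#'   `a:b` interactions); empty for the intercept-only model.
#' @param random_intercept grouping column for a random intercept, or
#'   `NULL` for ordinary least squares.
#' @return object of class `ml_fit`: list with `coefficients` (tibble term,
#'   estimate, se), `log_likelihood`, `k`, `n`, `aicc`, `terms`, `converged`
#'   and the underlying fit.
#' @export
fit_model <- function(data, response, terms = character(),
                      random_intercept = NULL) {
  data <- as.data.frame(data)
  f <- term_formula(response, terms, random_intercept)
  converged <- TRUE
  if (is.null(random_intercept)) {
    fit <- stats::lm(f, data = data)
    if (anyNA(coef(fit))) {
      abort(paste0("Singular fixed-effect design; aliased: ",
                   paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
    }
    est <- coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    ll <- as.numeric(logLik(fit))
    k <- length(est) + 1L                      # + residual variance
    n <- stats::nobs(fit)
  } else {
    fit <- withCallingHandlers(
      lme4::lmer(f, data = data, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
          converged <<- FALSE
        }
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage")
    )
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    ll <- as.numeric(logLik(fit))
    k <- length(est) + 2L                      # + random-intercept + residual
    n <- stats::nobs(fit)
  }
  structure(
    list(
      coefficients = tibble::tibble(term = names(est),
                                    estimate = unname(est), se = unname(se)),
      log_likelihood = ll, k = k, n = n, aicc = aicc(ll, k, n),
      terms = terms, random_intercept = random_intercept,
      response = response, converged = converged, fit = fit
    ),
    class = "ml_fit"
  )
}

#' @export
print.ml_fit <- function(x, ...) {
  cat("ML fit:", x$response, "~",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
      if (!is.null(x$random_intercept)) paste0(" + (1|", x$random_intercept, ")"),
      "\n  logLik ", round(x$log_likelihood, 2), ", k ", x$k,
      ", n ", x$n, ", AICc ", round(x$aicc, 2), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.ml_fit <- function(x, ...) x$coefficients

#' @export
glance.ml_fit <- function(x, ...) {
  tibble::tibble(log_likelihood = x$log_likelihood, k = x$k, n = x$n,
                 aicc = x$aicc, converged = x$converged)
}

# all subsets of `terms` respecting marginality (a:b needs a and b)
admissible_subsets <- function(terms) {
  n <- length(terms)
  if (n == 0) return(list(character()))
  keep <- list()
  for (mask in 0:(2^n - 1)) {
    sel <- terms[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    ok <- TRUE
    for (tm in sel) {
      if (grepl(":", tm, fixed = TRUE)) {
        parents <- strsplit(tm, ":", fixed = TRUE)[[1]]
        if (!all(parents %in% sel)) { ok <- FALSE; break }
      }
    }
    if (ok) keep[[length(keep) + 1]] <- sel
  }
  keep
}

#' Dredge all admissible fixed-effect subsets
#'
#' Enumerates every subset of the global model's fixed terms that respects
#' marginality (an interaction only with both parents present), always
#' including the intercept-only model, and fits each by ML on the same data.
#' Non-converging members are dropped with a warning.
#'
#' @inheritParams fit_model
#' @param terms fixed terms of the global model.
#' @return object of class `dredge_set`: list of `ml_fit`s sorted by AICc,
#'   with a `table` attribute (tibble of model formulas, k, logLik, AICc,
#'   delta, weight over the full set).
#' @export
dredge <- function(data, response, terms, random_intercept = NULL) {
  subsets <- admissible_subsets(terms)
  fits <- list()
  for (s in subsets) {
    f <- tryCatch(fit_model(data, response, s, random_intercept),
                  error = function(e) NULL)
    if (is.null(f)) {
      warn(paste0("Model {", paste(s, collapse = " + "),
                  "} failed to fit and was dropped."))
    } else if (!f$converged) {
      warn(paste0("Model {", paste(s, collapse = " + "),
                  "} did not converge and was dropped."))
    } else {
      fits[[length(fits) + 1]] <- f
    }
  }
  if (length(fits) == 0) abort("No model could be fitted.")
  ord <- order(vapply(fits, `[[`, numeric(1), "aicc"))
  fits <- fits[ord]
  aic <- vapply(fits, `[[`, numeric(1), "aicc")
  delta <- aic - min(aic)
  w <- exp(-delta / 2); w <- w / sum(w)
  tab <- tibble::tibble(
    model = vapply(fits, function(f) {
      if (length(f$terms)) paste(f$terms, collapse = " + ") else "(intercept)"
    }, character(1)),
    k = vapply(fits, `[[`, numeric(1), "k"),
    log_likelihood = vapply(fits, `[[`, numeric(1), "log_likelihood"),
    aicc = aic, delta = delta, weight = w
  )
  structure(fits, class = "dredge_set", table = tab)
}

#' @export
print.dredge_set <- function(x, ...) {
  cat("Dredge set:", length(x), "models\n")
  print(utils::head(attr(x, "table"), 10))
  invisible(x)
}

#' @export
tidy.dredge_set <- function(x, ...) attr(x, "table")

#' Average the equivalently likely models
#'
#' Retains models with AICc within `delta` of the best, renormalizes their
#' Akaike weights, and averages each term conditionally over the retained
#' models containing it (`method = "full"` substitutes zero where a term is
#' absent). The unconditional SE follows Burnham & Anderson,
#' `sqrt(sum w (se^2 + (est - avg)^2))`; the adjusted SE is the revised form
#' `sum w sqrt((se * t-factor)^2 + (est - avg)^2)` with a per-model
#' small-sample t/normal quantile factor (df = n - k). z = |estimate| /
#' adjusted SE with a two-sided normal p-value; importance is the summed
#' weight of retained models containing the term.
#'
#' @param models a `dredge_set` (or list of `ml_fit`).
#' @param delta AICc window (default 2.0).
#' @param method conditional (default) or full-model averaging.
#' @return object of class `averaged_model`: tibble term, estimate, se,
#'   adjusted_se, z, p, importance; attributes `model_table` (retained set)
#'   and `method`.
#' @export
average_models <- function(models, delta = 2.0,
                           method = c("conditional", "full")) {
  method <- match.arg(method)
  fits <- unclass(models)
  if (length(fits) == 0) abort("No models to average.")
  aic <- vapply(fits, `[[`, numeric(1), "aicc")
  keep <- which(aic - min(aic) < delta)
  fits <- fits[keep]
  d <- aic[keep] - min(aic)
  w <- exp(-d / 2); w <- w / sum(w)
  all_terms <- unique(unlist(lapply(fits, function(f) f$coefficients$term)))
  rows <- lapply(all_terms, function(tm) {
    est <- se <- wt <- tfac <- numeric(length(fits))
    has <- logical(length(fits))
    for (i in seq_along(fits)) {
      cf <- fits[[i]]$coefficients
      j <- match(tm, cf$term)
      has[i] <- !is.na(j)
      if (has[i]) {
        est[i] <- cf$estimate[j]
        se[i] <- cf$se[j]
        df <- max(fits[[i]]$n - fits[[i]]$k, 1)
        tfac[i] <- qt(0.975, df) / qnorm(0.975)
      }
      wt[i] <- w[i]
    }
    importance <- sum(wt[has])
    if (method == "conditional") {
      ww <- wt[has] / sum(wt[has])
      e <- est[has]; s <- se[has]; tf <- tfac[has]
    } else {
      ww <- wt
      e <- ifelse(has, est, 0); s <- ifelse(has, se, 0)
      tf <- ifelse(has, tfac, 1)
    }
    avg <- sum(ww * e)
    se_u <- sqrt(sum(ww * (s^2 + (e - avg)^2)))
    se_adj <- sum(ww * sqrt((s * tf)^2 + (e - avg)^2))
    z <- if (se_adj > 0) abs(avg) / se_adj else NA_real_
    tibble::tibble(term = tm, estimate = avg, se = se_u,
                   adjusted_se = se_adj, z = z,
                   p = if (is.na(z)) NA_real_ else 2 * (1 - pnorm(z)),
                   importance = importance)
  })
  out <- dplyr::bind_rows(rows)
  mt <- tibble::tibble(
    model = vapply(fits, function(f) {
      if (length(f$terms)) paste(f$terms, collapse = " + ") else "(intercept)"
    }, character(1)),
    aicc = aic[keep], delta = d, weight = w
  )
  structure(out, class = c("averaged_model", class(out)),
            model_table = mt, method = method, delta = delta)
}

#' @export
tidy.averaged_model <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.averaged_model <- function(x, ...) {
  mt <- attr(x, "model_table")
  tibble::tibble(n_models = nrow(mt), delta = attr(x, "delta"),
                 method = attr(x, "method"),
                 best_aicc = min(mt$aicc))
}
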