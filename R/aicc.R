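#' Akaike's information criterion corrected for small samples
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1)/(n - k - 1)`, which converges to AIC
#' as `n` grows.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations; must exceed `k + 1`.
#' @return AICc value.
#' @examples
#' aicc(-10, 2, 20)  # 24 + 12/17
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

.fixed_coefs <- function(model) {
  if (inherits(model, "merMod")) {
    est <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(vcov(model))))
  } else {
    est <- coef(model)
    se <- sqrt(diag(vcov(model)))
  }
  list(est = est, se = se[names(est)])
}

#' Compare candidate models by AICc with model averaging
#'
#' Ranks a candidate set by AICc, identifies the competitive set (models
#' within `delta_max` of the best), excludes competitive models that only
#' add potentially uninformative parameters (a superset of the best model's
#' fixed-effect terms with a higher AICc), and, when more than one model
#' remains, model-averages fixed-effect coefficients with AICc weights
#' renormalized over the competitive set. Unconditional standard errors use
#' the usual weight-combined formula
#' `SE = sum w_m * sqrt(se_m^2 + (b_m - b_bar)^2)`.
#'
#' @param models named list of fitted models (`lm`, `glm`, or `merMod`
#'   objects fitted by maximum likelihood).
#' @param terms list (same length) of character vectors naming each model's
#'   fixed-effect terms (excluding the intercept).
#' @param n number of observations used for every model.
#' @param delta_max AICc difference defining the competitive set; default 2.
#' @return An object of class `model_comparison` with elements `table`
#'   (per-model logLik, k, AICc, delta, weight, competitive flag),
#'   `averaged` (term, estimate, unconditional se, n_models), `best`
#'   (name of the lowest-AICc model), and `models`.
#' @export
model_comparison <- function(models, terms, n, delta_max = 2) {
  stopifnot(length(models) == length(terms))
  if (is.null(names(models))) {
    names(models) <- vapply(terms, function(tt)
      if (length(tt) == 0) "(intercept)" else paste(tt, collapse = "+"), "")
  }
  ll <- vapply(models, function(m) as.numeric(logLik(m)), 0)
  k <- vapply(models, function(m) attr(logLik(m), "df"), 0)
  ic <- mapply(aicc, ll, k, MoreArgs = list(n = n))
  delta <- ic - min(ic)
  w <- exp(-delta / 2); w <- w / sum(w)
  best <- which.min(ic)

  competitive <- delta < delta_max
  ## Arnold rule: drop competitive models that contain every term of the best
  ## model plus extras (uninformative-parameter exclusion)
  for (i in seq_along(models)) {
    if (i == best || !competitive[i]) next
    if (all(terms[[best]] %in% terms[[i]]) && length(terms[[i]]) > length(terms[[best]])) {
      competitive[i] <- FALSE
    }
  }

  tab <- data.frame(
    model = names(models), terms = vapply(terms, paste, "", collapse = "+"),
    logLik = ll, k = k, AICc = ic, delta = delta, weight = w,
    competitive = competitive, row.names = NULL
  )
  tab <- tab[order(tab$AICc), ]

  keep <- which(competitive)
  wk <- w[keep] / sum(w[keep])
  cf <- lapply(models[keep], .fixed_coefs)
  all_terms <- unique(unlist(lapply(cf, function(x) names(x$est))))
  averaged <- do.call(rbind, lapply(all_terms, function(tm) {
    has <- vapply(cf, function(x) tm %in% names(x$est), TRUE)
    if (!any(has)) return(NULL)
    wi <- wk[has] / sum(wk[has])
    bs <- vapply(cf[has], function(x) unname(x$est[tm]), 0)
    ses <- vapply(cf[has], function(x) unname(x$se[tm]), 0)
    bbar <- sum(wi * bs)
    data.frame(term = tm, estimate = bbar,
               se = sum(wi * sqrt(ses^2 + (bs - bbar)^2)),
               n_models = sum(has))
  }))

  structure(list(table = tab, averaged = averaged,
                 best = names(models)[best], models = models, n = n),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("AICc model comparison (n =", x$n, ")\n")
  print(x$table[, c("model", "logLik", "k", "AICc", "delta", "weight", "competitive")],
        digits = 4, row.names = FALSE)
  cat("\nModel-averaged coefficients over the competitive set:\n")
  print(x$averaged, digits = 4, row.names = FALSE)
  invisible(x)
}
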