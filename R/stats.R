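# Mixed-effects model stage: behaviour LMMs and the Poisson productivity
# GLMM, with the AIC selection ledger. Numerical optimisation is delegated
# to lme4; the contract here is model structure, convergence reporting and
# reproducibility.

#' Specify a (generalised) linear mixed model
#'
#' @param response response column name.
#' @param fixed character vector of fixed-effect terms (formula fragments,
#'   e.g. `c("t_air_c * imidacloprid * log_size")`).
#' @param random character vector of lme4 random terms, e.g.
#'   `c("(1 | colony_id/bee_id)", "(1 | block_id)")`; NULL fits a fixed-
#'   effects-only model.
#' @param family `"gaussian"` or `"poisson"` (log link).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(response, fixed, random = NULL,
                       family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  structure(list(response = response, fixed = fixed, random = random,
                 family = family), class = "model_spec")
}

spec_formula <- function(spec) {
  rhs <- paste(c(spec$fixed, spec$random), collapse = " + ")
  if (rhs == "") rhs <- "1"
  stats::as.formula(paste(spec$response, "~", rhs))
}

spec_columns <- function(spec) {
  unique(c(spec$response,
           all.vars(stats::as.formula(
             paste("~", paste(c(spec$fixed, spec$random, "1"),
                              collapse = "+"))))))
}

#' Fit a model specification
#'
#' Gaussian mixed models use lme4::lmer (ML by default so AIC values are
#' comparable across fixed-effect structures; set `reml = TRUE` for final
#' reporting); Poisson models use lme4::glmer with log link. Specs with no
#' random terms fall back to lm/glm. P-values for mixed models use the
#' normal approximation (flagged `df_method = "normal"`); Satterthwaite
#' degrees of freedom are reported only when a backend providing them is
#' available, which this deployment does not ship.
#'
#' @param table data.frame containing every column the spec references.
#' @param spec a [model_spec()].
#' @param reml logical, Gaussian mixed models only.
#' @return object of class `fit_result`: coefficient table, AIC, logLik,
#'   convergence and singularity flags, df method, the fitted object.
#' @export
fit_model <- function(table, spec, reml = FALSE) {
  missing_cols <- setdiff(spec_columns(spec), names(table))
  if (length(missing_cols))
    stop("table lacks column(s): ", paste(missing_cols, collapse = ", "))
  f <- spec_formula(spec)
  mixed <- !is.null(spec$random)
  converged <- TRUE
  singular <- FALSE
  fit <- withCallingHandlers(
    {
      if (mixed && spec$family == "gaussian")
        lme4::lmer(f, data = table, REML = reml)
      else if (mixed)
        lme4::glmer(f, data = table, family = stats::poisson())
      else if (spec$family == "gaussian")
        stats::lm(f, data = table)
      else
        stats::glm(f, data = table, family = stats::poisson())
    },
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (mixed) {
    singular <- lme4::isSingular(fit)
    cf <- as.data.frame(summary(fit)$coefficients)
    names(cf)[1:2] <- c("estimate", "se")
    stat <- cf[[3]]
    cf <- data.frame(term = rownames(cf), estimate = cf$estimate,
                     se = cf$se, statistic = stat,
                     p_value = if (converged)
                       2 * stats::pnorm(-abs(stat)) else NA_real_)
  } else {
    cf <- as.data.frame(summary(fit)$coefficients)
    cf <- data.frame(term = rownames(cf), estimate = cf[[1]], se = cf[[2]],
                     statistic = cf[[3]], p_value = cf[[4]])
  }
  rownames(cf) <- NULL
  structure(list(spec = spec, formula = deparse1(f),
                 coefficients = cf,
                 aic = stats::AIC(fit),
                 loglik = as.numeric(stats::logLik(fit)),
                 n_fixed = nrow(cf),
                 converged = converged, singular = singular,
                 df_method = "normal",
                 reml = if (spec$family == "gaussian" && mixed) reml else NA,
                 fit = fit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s | AIC %.1f%s%s>\n", x$formula, x$aic,
              if (!x$converged) " NOT CONVERGED" else "",
              if (x$singular) " singular" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Select among candidate models by AIC
#'
#' Fits every candidate (ML), then chooses the simplest model (fewest fixed
#' effect parameters) within `delta` AIC of the minimum; ties break by
#' candidate order. A more complex model is preferred only when it improves
#' AIC by more than `delta` (default 4).
#'
#' @param specs list of [model_spec()] candidates (>= 2).
#' @param table data.frame.
#' @param delta AIC window for "no significant improvement".
#' @return list `best_index`, `best_spec`, `best_fit`, and `ledger`
#'   (data.frame of candidate, formula, n_fixed, AIC, dAIC, chosen).
#' @export
select_by_aic <- function(specs, table, delta = 4) {
  if (length(specs) < 2L) stop("need >= 2 candidate specs")
  fits <- lapply(specs, function(s)
    tryCatch(fit_model(table, s, reml = FALSE), error = function(e) e))
  failed <- vapply(fits, inherits, logical(1), "error")
  if (all(failed))
    stop("all candidates failed: ",
         paste(vapply(fits, conditionMessage, character(1)),
               collapse = " | "))
  aics <- vapply(fits, function(f) if (inherits(f, "error")) Inf else f$aic,
                 numeric(1))
  nfix <- vapply(fits, function(f) if (inherits(f, "error")) NA_integer_
                 else f$n_fixed, integer(1))
  daic <- aics - min(aics)
  eligible <- which(daic <= delta)
  best <- eligible[order(nfix[eligible], eligible)][1L]
  ledger <- data.frame(candidate = seq_along(specs),
                       formula = vapply(specs, function(s)
                         deparse1(spec_formula(s)), character(1)),
                       n_fixed = nfix, aic = aics, daic = daic,
                       chosen = seq_along(specs) == best)
  list(best_index = best, best_spec = specs[[best]],
       best_fit = fits[[best]], ledger = ledger)
}

#' Colony-productivity analysis
#'
#' Joins census to treatment metadata, applies the size filter (colonies of
#' a single bee and colonies larger than `max_size` at treatment are
#' excluded), fits the Poisson GLMM with the cold x imidacloprid x
#' log10(size) interaction and block random intercept (plus species random
#' slopes for size when several species are present), and predicts
#' productivity per arm at reference sizes from the fixed effects.
#'
#' @param census census data.frame (see [read_census()]).
#' @param meta colony metadata (see [colony_meta()]).
#' @param ref_sizes sizes at which to report predictions.
#' @param max_size exclusion threshold.
#' @return list `fit` (a `fit_result`), `predictions` (arm x size with 95%
#'   CIs on the response scale), `n_used`.
#' @export
productivity_analysis <- function(census, meta, ref_sizes = c(4, 40),
                                  max_size = 40) {
  d <- merge(census, meta, by = "colony_id")
  d <- d[d$colony_size_at_treatment > 1 &
           d$colony_size_at_treatment <= max_size, ]
  d$log_size <- log10(d$colony_size_at_treatment)
  d$cold <- as.numeric(d$cold)
  d$imidacloprid <- as.numeric(d$imidacloprid)
  cells <- with(d, table(cold, imidacloprid))
  if (any(cells == 0)) warning("empty treatment cell(s); fit proceeds")
  random <- "(1 | block_id)"
  if (length(unique(d$species)) > 1L)
    random <- c(random, "(1 + log_size | species)")
  spec <- model_spec(
    "total_productivity",
    fixed = c("log_size", "cold * imidacloprid",
              "cold:imidacloprid:log_size"),
    random = random, family = "poisson")
  res <- fit_model(d, spec)
  grid <- expand.grid(cold = c(0, 1), imidacloprid = c(0, 1),
                      size = ref_sizes)
  grid$log_size <- log10(grid$size)
  X <- cbind(1, grid$log_size, grid$cold, grid$imidacloprid,
             grid$cold * grid$imidacloprid,
             grid$cold * grid$imidacloprid * grid$log_size)
  beta <- lme4::fixef(res$fit)
  V <- as.matrix(stats::vcov(res$fit))
  eta <- as.vector(X %*% beta)
  se <- sqrt(rowSums((X %*% V) * X))
  grid$predicted <- exp(eta)
  grid$lo <- exp(eta - 1.96 * se)
  grid$hi <- exp(eta + 1.96 * se)
  grid$arm <- c("control", "cold", "imidacloprid",
                "combined")[1 + grid$cold + 2 * grid$imidacloprid]
  list(fit = res, predictions = grid[, c("arm", "size", "predicted",
                                         "lo", "hi")],
       n_used = nrow(d))
}

#' Residuals from an intercept-only random-effects model
#'
#' Removes bee- and colony-level baseline differences from a score before
#' plotting or summarising against temperature: fits
#' `value ~ 1 + (1 | colony_id/bee_id)` and returns the residuals.
#'
#' @param table data.frame with `colony_id`, `bee_id` and the value column.
#' @param value column name to residualise.
#' @return numeric vector of residuals aligned with `table` rows.
#' @export
re_residuals <- function(table, value) {
  f <- stats::as.formula(paste(value, "~ 1 + (1 | colony_id / bee_id)"))
  fit <- lme4::lmer(f, data = table, REML = TRUE)
  unname(stats::resid(fit))
}
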