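# Spatial centrality: PCA over the behavioural metrics, PC1 orientation,
# Yeo-Johnson normalisation and scoring.

#' Variable sets for the centrality PCA
#'
#' `queenright_11` is the full headline metric list; `microcolony_5` is the
#' reduced set used for queenless microcolonies (mean distance to other
#' bees, minimum distance to brood, brood interaction rate, distance to the
#' social nest centre, and number of unique physical contacts).
#'
#' @param variable_set `"queenright_11"` or `"microcolony_5"`.
#' @return character vector of behaviour-table columns.
#' @export
centrality_variables <- function(variable_set = c("queenright_11",
                                                  "microcolony_5")) {
  switch(match.arg(variable_set),
         queenright_11 = behaviour_metric_names(),
         microcolony_5 = c("mean_dist_nestmates", "min_dist_closest_brood",
                           "brood_interaction_rate", "distance_to_centre",
                           "degree_centrality"))
}

#' Fit the centrality PCA
#'
#' Centres and scales each variable to unit variance and eigendecomposes the
#' correlation structure. Rows with any missing variable are dropped (and
#' counted); variables constant across records are removed with a warning
#' and recorded in the model.
#'
#' @param records behaviour table (data.frame).
#' @param variable_set see [centrality_variables()].
#' @return object of class `pca_model`: variables, centre, scale, rotation
#'   (orthonormal loadings), variance-explained fractions, `pc1_sign`.
#' @export
fit_pca <- function(records, variable_set = "queenright_11") {
  vars <- centrality_variables(variable_set)
  missing_cols <- setdiff(vars, names(records))
  if (length(missing_cols))
    stop("records lack variable(s): ", paste(missing_cols, collapse = ", "))
  X <- records[, vars, drop = FALSE]
  complete <- stats::complete.cases(X)
  X <- as.matrix(X[complete, , drop = FALSE])
  if (nrow(X) < 2L) stop("need >= 2 complete records")
  sds <- apply(X, 2, stats::sd)
  dropped_vars <- colnames(X)[sds < 1e-12]
  if (length(dropped_vars)) {
    warning("constant variable(s) removed from PCA: ",
            paste(dropped_vars, collapse = ", "))
    X <- X[, sds >= 1e-12, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  structure(list(variable_set = variable_set,
                 variables = colnames(X),
                 dropped_vars = dropped_vars,
                 n_dropped_rows = sum(!complete),
                 center = pc$center, scale = pc$scale,
                 rotation = pc$rotation,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2),
                 pc1_sign = 1,
                 yj_lambda = NULL),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model (%s): %d vars, PC1 %.1f%% variance, sign %+d>\n",
              x$variable_set, length(x$variables),
              100 * x$var_explained[1], x$pc1_sign))
  invisible(x)
}

#' Orient PC1 so higher scores mean greater spatial centrality
#'
#' The sign of a principal component is arbitrary; this flips PC1 (if
#' needed) so the loading of `distance_to_centre` is negative, i.e. higher
#' scores are nearer the nest centre. Idempotent.
#'
#' @param model a `pca_model` containing `distance_to_centre`.
#' @return the model, possibly with `pc1_sign` flipped.
#' @export
orient_pc1 <- function(model) {
  if (!"distance_to_centre" %in% model$variables)
    stop("model lacks distance_to_centre; cannot orient PC1")
  loading <- model$pc1_sign *
    model$rotation["distance_to_centre", 1]
  if (loading > 0) model$pc1_sign <- -model$pc1_sign
  model
}

yj_apply <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- x >= 0
  if (abs(lambda) > 1e-12) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log(x[pos] + 1)
  }
  if (abs(lambda - 2) > 1e-12) {
    out[!pos] <- -((1 - x[!pos])^(2 - lambda) - 1) / (2 - lambda)
  } else {
    out[!pos] <- -log(1 - x[!pos])
  }
  out
}

#' Yeo-Johnson transformation with maximum-likelihood lambda
#'
#' The standard piecewise power transform; lambda is chosen by maximising
#' the Gaussian profile log-likelihood (including the Jacobian term) with a
#' golden-section search on [-3, 5].
#'
#' @param values numeric vector (>= 10 finite values) unless `lambda` given.
#' @param lambda optional fixed lambda (skips optimisation).
#' @return list `transformed`, `lambda`.
#' @export
yeo_johnson <- function(values, lambda = NULL) {
  bad <- which(!is.finite(values))
  if (length(bad))
    stop("non-finite inputs at indices: ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (is.null(lambda)) {
    if (length(values) < 10L) stop("need >= 10 values to estimate lambda")
    loglik <- function(l) {
      y <- yj_apply(values, l)
      v <- stats::var(y)
      if (!is.finite(v) || v <= 0) return(-Inf)
      -0.5 * length(values) * log(v) +
        (l - 1) * sum(sign(values) * log(abs(values) + 1))
    }
    lambda <- stats::optimize(loglik, c(-3, 5), maximum = TRUE)$maximum
  }
  list(transformed = yj_apply(values, lambda), lambda = lambda)
}

#' Fit the full centrality model (PCA + orientation + Yeo-Johnson)
#'
#' Convenience wrapper: [fit_pca()], [orient_pc1()], then Yeo-Johnson lambda
#' estimated on the pooled training PC1 scores and stored in the model.
#'
#' @inheritParams fit_pca
#' @return an oriented `pca_model` with `yj_lambda` set.
#' @export
centrality_model <- function(records, variable_set = "queenright_11") {
  model <- orient_pc1(fit_pca(records, variable_set))
  raw <- project_pc1(records, model)
  ok <- is.finite(raw$pc1_raw)
  model$yj_lambda <- yeo_johnson(raw$pc1_raw[ok])$lambda
  model
}

project_pc1 <- function(records, model, impute = TRUE) {
  X <- as.matrix(records[, model$variables, drop = FALSE])
  imputed <- rep(FALSE, nrow(X))
  if (impute) {
    for (j in seq_len(ncol(X))) {
      na <- is.na(X[, j])
      if (any(na)) {
        X[na, j] <- model$center[j]
        imputed <- imputed | na
      }
    }
  }
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  data.frame(pc1_raw = model$pc1_sign * as.vector(Z %*% model$rotation[, 1]),
             imputed = imputed)
}

#' Score records with a fitted centrality model
#'
#' Projects onto the oriented PC1 with the stored centring/scaling and
#' applies the Yeo-Johnson transform with the stored lambda. Records with
#' missing variables are mean-imputed and flagged.
#'
#' @param records behaviour table containing the model's variables.
#' @param model a `pca_model` from [centrality_model()].
#' @return data.frame `bee_id`, `video_id`, `pc1_raw`, `pc1_transformed`,
#'   `lambda`, `imputed`.
#' @export
score_centrality <- function(records, model) {
  missing_cols <- setdiff(model$variables, names(records))
  if (length(missing_cols))
    stop("records lack model variable(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(model$yj_lambda))
    stop("model has no Yeo-Johnson lambda; fit with centrality_model()")
  pr <- project_pc1(records, model)
  data.frame(bee_id = records$bee_id, video_id = records$video_id,
             pc1_raw = pr$pc1_raw,
             pc1_transformed = yj_apply(pr$pc1_raw, model$yj_lambda),
             lambda = model$yj_lambda, imputed = pr$imputed,
             stringsAsFactors = FALSE)
}
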