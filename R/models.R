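#' @name rsf_models
#' @title Weighted use-availability mixed logistic models
#'
#' @description Fits the two candidate families -- the landscape use
#' model (habitat class, optionally crossed with day/night) and the
#' landscape distance model (standardised distances to the seven
#' features, optionally crossed with time and sex) -- as weighted
#' binomial-logit models with an optional per-animal random intercept
#' (Laplace approximation via lme4). Candidate sets are ranked by AICc
#' and Akaike weights, with Nakagawa-Schielzeth marginal/conditional
#' R-squared.
NULL

habitat_factor <- function(class_codes, levels_present = NULL) {
  nm <- names(landscape_classes)[pmax(class_codes, 1L)]
  nm[class_codes < 1L | class_codes > 6L] <- NA
  if (is.null(levels_present)) {
    levels_present <- names(landscape_classes)[sort(unique(class_codes[class_codes >= 1L & class_codes <= 6L]))]
    # reference class first: woodland_scrub, the dominant natural class
    levels_present <- c(intersect("woodland_scrub", levels_present),
                        setdiff(levels_present, "woodland_scrub"))
  }
  factor(nm, levels = levels_present)
}

# shared fitting core: fixed RHS string + optional random intercept
fit_core <- function(data, rhs_fixed, random, weights, family_label,
                     structure, recipe = NULL) {
  data$.w <- weights
  n <- nrow(data)
  if (random == "intercept_by_id") {
    form <- stats::as.formula(paste("case ~", rhs_fixed, "+ (1 | animal_id)"))
    fit <- suppressWarnings(suppressMessages(
      lme4::glmer(form, data = data, family = stats::binomial(),
                  weights = .w,
                  control = lme4::glmerControl(check.nobs.vs.nlev = "ignore",
                                               calc.derivs = FALSE))
    ))
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    sigma2_u <- as.numeric(lme4::VarCorr(fit)$animal_id[1])
    conv <- length(fit@optinfo$conv$lme4$messages) == 0
    X <- lme4::getME(fit, "X")
  } else {
    form <- stats::as.formula(paste("case ~", rhs_fixed))
    fit <- suppressWarnings(
      stats::glm(form, data = data, family = stats::binomial(), weights = .w)
    )
    if (any(is.na(stats::coef(fit)))) {
      aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop("rank-deficient design; aliased terms: ",
           paste(aliased, collapse = ", "))
    }
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
    sigma2_u <- 0
    conv <- fit$converged
    X <- stats::model.matrix(fit)
  }
  eta_fixed <- as.numeric(X %*% beta)
  k <- length(beta) + (random == "intercept_by_id")
  xlev <- list()
  for (v in c("habitat", "time", "sex")) {
    if (v %in% names(data) && is.factor(data[[v]]))
      xlev[[v]] <- levels(data[[v]])
  }
  structure(
    list(
      fit = fit, family = family_label, structure = structure,
      random = random, rhs_fixed = rhs_fixed,
      beta = beta, vcov = V, se = sqrt(diag(V)),
      sigma2_u = sigma2_u,
      sigma2_f = stats::var(eta_fixed),
      logLik = as.numeric(stats::logLik(fit)),
      k = k, n = n, xlev = xlev, recipe = recipe,
      converged = conv
    ),
    class = "fitted_rsf"
  )
}

#' @export
print.fitted_rsf <- function(x, ...) {
  cat(sprintf(
    "fitted_rsf [%s family, %s, random = %s]\n  n = %d, k = %d, logLik = %.2f, sigma2_u = %.4f\n",
    x$family, x$structure, x$random, x$n, x$k, x$logLik, x$sigma2_u
  ))
  print(round(cbind(estimate = x$beta, se = x$se), 4))
  invisible(x)
}

# prepare use-model data: factor habitat (classes 1-6, reference
# woodland_scrub) and diel time (reference day)
prepare_use_data <- function(records) {
  keep <- records$habitat_class >= 1L & records$habitat_class <= 6L
  if (!all(keep)) {
    warning(sum(!keep), " record(s) on waterbody/nodata cells dropped ",
            "from the use model")
    records <- records[keep, , drop = FALSE]
  }
  records$habitat <- habitat_factor(records$habitat_class)
  records$time <- factor(records$diel, levels = c("day", "night"))
  records
}

#' Fit the landscape use model
#'
#' Weighted binomial-logit model of case status (1 = observed fix,
#' 0 = simulated availability point) on habitat class, optionally
#' crossed with the day/night factor, with an optional per-animal
#' random intercept. Waterbody is never a predictor class (unsuitable
#' habitat) and sex is never included in this family. Reference levels:
#' habitat = woodland_scrub, time = day.
#'
#' @param records Annotated case-control records (columns `case`,
#'   `habitat_class`, `diel`, `animal_id`, `weight`).
#' @param structure `"null"`, `"additive"` or `"time_interaction"`.
#' @param random `"intercept_by_id"` or `"none"`.
#' @return A `fitted_rsf` object.
#' @export
fit_use_model <- function(records,
                          structure = c("time_interaction", "additive", "null"),
                          random = c("intercept_by_id", "none")) {
  structure <- match.arg(structure)
  random <- match.arg(random)
  data <- prepare_use_data(records)
  rhs <- switch(structure,
    null = "1",
    additive = "habitat + time",
    time_interaction = "habitat * time"
  )
  fit_core(data, rhs, random, data$weight, "use", structure)
}

# polynomial term block for the distance model, on the standardised
# scale: z_f and I(z_f^2) per the recipe's degrees
distance_terms <- function(recipe) {
  terms <- character()
  for (k in 1:7) {
    deg <- recipe$degrees[[paste0("dist_", k)]]
    terms <- c(terms, paste0("z_", k))
    if (deg >= 2L) terms <- c(terms, sprintf("I(z_%d^2)", k))
  }
  terms
}

#' Fit the landscape distance model
#'
#' Weighted binomial-logit model of case status on the standardised
#' distances to all seven landscape features (polynomial degree per the
#' recipe), in additive or fully crossed combination with time and sex,
#' plus an optional per-animal random intercept. Reference levels:
#' time = day, sex = F.
#'
#' @param records Annotated case-control records with `z_1` .. `z_7`
#'   columns (or raw distances plus `recipe` to standardise here).
#' @param structure `"null"`, `"additive"`, `"time_interaction"` or
#'   `"time_sex_interaction"` (three-way crossing).
#' @param recipe A [covariate_recipe()].
#' @param random `"intercept_by_id"` or `"none"`.
#' @return A `fitted_rsf` object.
#' @export
fit_distance_model <- function(records,
                               structure = c("time_sex_interaction",
                                             "time_interaction",
                                             "additive", "null"),
                               recipe,
                               random = c("intercept_by_id", "none")) {
  structure <- match.arg(structure)
  random <- match.arg(random)
  if (!"z_1" %in% names(records)) records <- apply_recipe(records, recipe)
  records$time <- factor(records$diel, levels = c("day", "night"))
  records$sex <- factor(records$sex, levels = c("F", "M"))
  block <- paste(distance_terms(recipe), collapse = " + ")
  rhs <- switch(structure,
    null = "1",
    additive = block,
    time_interaction = sprintf("(%s) * time", block),
    time_sex_interaction = sprintf("(%s) * time * sex", block)
  )
  fit_core(records, rhs, random, records$weight, "distance", structure,
           recipe = recipe)
}

#' AICc: small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 * logLik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param logLik Maximised log-likelihood.
#' @param k Parameter count (fixed coefficients plus variance
#'   parameters).
#' @param n Number of records.
#' @return AICc value.
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aicc
#' @param model A `fitted_rsf`.
#' @export
aicc_model <- function(model) aicc(model$logLik, model$k, model$n)

#' Rank a candidate model set by AICc
#'
#' All models must be fitted to the same records and weights (equal n).
#' Akaike weights are `exp(-dAICc/2)` normalised over the set,
#' computed stably. Ties in AICc rank the model with fewer parameters
#' first, then input order.
#'
#' @param models Named list of `fitted_rsf` objects.
#' @return Data frame (one row per model, best first): `model`, `df`,
#'   `AICc`, `dAICc`, `weight`, `logLik`, `R2m`, `R2c`.
#' @export
rank_models <- function(models) {
  if (is.null(names(models)))
    names(models) <- paste0("model_", seq_along(models))
  n_set <- vapply(models, function(m) m$n, numeric(1))
  if (length(unique(n_set)) != 1L)
    stop("models fitted to different record sets (n differs); refusing to rank")
  a <- vapply(models, aicc_model, numeric(1))
  k <- vapply(models, function(m) m$k, numeric(1))
  d <- a - min(a)
  w <- exp(-d / 2)
  w <- w / sum(w)
  r2 <- t(vapply(models, function(m) unlist(r2_nakagawa(m)), numeric(2)))
  out <- data.frame(
    model = names(models), df = k, AICc = a, dAICc = d, weight = w,
    logLik = vapply(models, function(m) m$logLik, numeric(1)),
    R2m = r2[, 1], R2c = r2[, 2],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$dAICc, out$df, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nakagawa-Schielzeth R-squared for a binomial-logit mixed model
#'
#' Marginal R2 is the variance of the fixed-effect linear predictor
#' over the fitted records divided by the total latent variance (fixed
#' + random-intercept + logit distributional variance pi^2/3);
#' conditional R2 adds the random-intercept variance to the numerator.
#'
#' @param model A `fitted_rsf`.
#' @return List with `R2m`, `R2c`.
#' @export
r2_nakagawa <- function(model) {
  tot <- model$sigma2_f + model$sigma2_u + pi^2 / 3
  list(R2m = model$sigma2_f / tot,
       R2c = (model$sigma2_f + model$sigma2_u) / tot)
}

#' Choose the random-effect structure by AICc parsimony
#'
#' Fits the same fixed structure with and without the per-animal random
#' intercept and keeps the intercept only when it improves AICc by more
#' than 2 units; a tie (dAICc < 2) keeps the simpler structure. The
#' winner is used for the whole candidate set. If one fit fails, the
#' other wins with a warning.
#'
#' @param records Annotated case-control records.
#' @param family `"use"` or `"distance"`.
#' @param structure Fixed structure passed to the family's fit
#'   function.
#' @param recipe Required for the distance family.
#' @return `"intercept_by_id"` or `"none"`.
#' @export
select_random_structure <- function(records, family = c("use", "distance"),
                                    structure = "time_interaction",
                                    recipe = NULL) {
  family <- match.arg(family)
  fit1 <- function(random) {
    if (family == "use") fit_use_model(records, structure, random)
    else fit_distance_model(records, structure, recipe, random)
  }
  m_re <- tryCatch(fit1("intercept_by_id"), error = function(e) e)
  m_none <- tryCatch(fit1("none"), error = function(e) e)
  if (inherits(m_re, "error") && inherits(m_none, "error"))
    stop("both random-structure candidates failed to fit")
  if (inherits(m_re, "error")) {
    warning("random-intercept fit failed; using 'none'")
    return("none")
  }
  if (inherits(m_none, "error")) {
    warning("fixed-only fit failed; using 'intercept_by_id'")
    return("intercept_by_id")
  }
  if (aicc_model(m_re) < aicc_model(m_none) - 2) "intercept_by_id" else "none"
}

#' Population-level prediction from a fitted RSF
#'
#' Prediction with the random intercept at its mean (zero): the fixed
#' design matrix is built from `newdata` with the training factor
#' levels, and the linear predictor (optionally with delta-method
#' standard errors) is mapped through the inverse logit.
#'
#' @param model A `fitted_rsf`.
#' @param newdata Data frame providing the model's covariates.
#' @param se Logical: return delta-method CI columns?
#' @param level Confidence level (default 0.95).
#' @return Data frame with `prob` and, if `se`, `eta`, `se_eta`, `lwr`,
#'   `upr` (CI endpoints on the probability scale).
#' @export
predict_rsf <- function(model, newdata, se = FALSE, level = 0.95) {
  # convenience: derive the model factors from raw record columns
  if (!"habitat" %in% names(newdata) && "habitat_class" %in% names(newdata))
    newdata$habitat <- names(landscape_classes)[newdata$habitat_class]
  if (!"time" %in% names(newdata) && "diel" %in% names(newdata))
    newdata$time <- newdata$diel
  for (v in names(model$xlev)) {
    if (v %in% names(newdata))
      newdata[[v]] <- factor(newdata[[v]], levels = model$xlev[[v]])
  }
  ff <- stats::as.formula(paste("~", model$rhs_fixed))
  X <- stats::model.matrix(ff, data = newdata)
  if (!identical(colnames(X), names(model$beta)))
    X <- X[, names(model$beta), drop = FALSE]
  eta <- as.numeric(X %*% model$beta)
  out <- data.frame(prob = stats::plogis(eta))
  if (se) {
    se_eta <- sqrt(rowSums((X %*% model$vcov) * X))
    zq <- stats::qnorm(1 - (1 - level) / 2)
    out$eta <- eta
    out$se_eta <- se_eta
    out$lwr <- stats::plogis(eta - zq * se_eta)
    out$upr <- stats::plogis(eta + zq * se_eta)
  }
  out
}
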