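#' Working-outcome-model strategy specification
#'
#' @param kind one of `"none"`, `"allelic"`, `"forward_backward"`,
#'   `"penalized"`.
#' @param p_enter,p_remove Wald p-value thresholds of the forward and
#'   backward steps of stepwise haplotype selection (defaults 0.1).
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param cv_folds number of cross-validation folds for the penalized
#'   strategy; folds are formed at the individual level so that all
#'   weighted rows of one individual share a fold.
#' @param lambda_rule `"min"` (minimum CV deviance, default) or `"1se"`.
#' @param seed integer seed for the fold assignment.
#' @return list of class `strategy_spec`.
#' @export
strategy_spec <- function(kind = c("none", "allelic", "forward_backward",
                                   "penalized"),
                          p_enter = 0.1, p_remove = 0.1, alpha = 0.5,
                          cv_folds = 10, lambda_rule = c("min", "1se"),
                          seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(p_enter > 0, p_enter < 1, p_remove > 0, p_remove < 1,
            alpha >= 0, alpha <= 1, cv_folds >= 2)
  structure(list(kind = kind, p_enter = p_enter, p_remove = p_remove,
                 alpha = alpha, cv_folds = cv_folds,
                 lambda_rule = match.arg(lambda_rule), seed = seed),
            class = "strategy_spec")
}

#' Fitted outcome-model parameters
#'
#' @param beta named coefficients, `(Intercept)` first.
#' @param phi dispersion (gaussian residual variance; fixed at 1 for
#'   binomial).
#' @param family `"gaussian"` or `"binomial"`.
#' @param details optional fitting diagnostics.
#' @return list of class `outcome_params`.
#' @export
outcome_params <- function(beta, phi = 1, family = "gaussian",
                           details = list()) {
  stopifnot(all(is.finite(beta)), !anyDuplicated(names(beta)))
  structure(list(beta = beta, phi = phi, family = family, details = details),
            class = "outcome_params")
}

#' @export
print.outcome_params <- function(x, ...) {
  cat("Outcome model (", x$family, "), ", length(x$beta), " terms",
      if (x$family == "gaussian") paste0(", phi = ", signif(x$phi, 4)),
      "\n", sep = "")
  print(round(x$beta, 4))
  invisible(x)
}

glm_family <- function(family) {
  switch(family,
         gaussian = stats::gaussian(),
         binomial = stats::binomial(),
         stop("unsupported outcome family: ", family))
}

## drop aliased columns deterministically (first-listed kept), via pivoted QR
## of the weight-scaled design
drop_aliased <- function(X, w) {
  sw <- sqrt(w)
  qr_ <- qr(X * sw)
  if (qr_$rank == ncol(X)) return(seq_len(ncol(X)))
  keep <- sort(qr_$pivot[seq_len(qr_$rank)])
  keep
}

## weighted GLM treating weights as frequency weights; rows of one
## individual carry posterior weights summing to 1, so the effective sample
## size is sum(w)
fit_wglm <- function(X, y, w, family) {
  keep <- drop_aliased(X, w)
  Xk <- X[, keep, drop = FALSE]
  fam <- glm_family(family)
  fit <- suppressWarnings(
    stats::glm.fit(x = Xk, y = y, weights = w, family = fam))
  if (!fit$converged) stop("weighted GLM did not converge")
  beta <- stats::setNames(fit$coefficients, colnames(Xk))
  n_eff <- sum(w)
  p <- length(beta)
  mu <- fit$fitted.values
  if (family == "gaussian") {
    ## ML estimate (divisor n, not n - p): the exact conditional maximizer
    ## inside the EM, keeping the joint likelihood monotone
    phi <- sum(w * (y - mu)^2) / n_eff
  } else phi <- 1
  ## Wald covariance on the frequency-weight scale
  ww <- fit$weights  # IRLS weights already include w
  XtWX <- crossprod(Xk * sqrt(ww))
  vc <- tryCatch(phi * chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(vc)) {
    se <- rep(NA_real_, p)
  } else se <- sqrt(pmax(diag(vc), 0))
  z <- beta / se
  pval <- if (family == "gaussian") {
    2 * stats::pt(abs(z), df = max(n_eff - p, 1), lower.tail = FALSE)
  } else 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  list(beta = beta, se = stats::setNames(se, names(beta)),
       p = stats::setNames(pval, names(beta)), phi = phi,
       deviance = fit$deviance, dropped = setdiff(colnames(X), colnames(Xk)))
}

## dispersion for a beta vector evaluated on (X, y, w)
dispersion_of <- function(beta, X, y, w, family) {
  if (family != "gaussian") return(1)
  eta <- as.numeric(X[, names(beta), drop = FALSE] %*% beta)
  sum(w * (y - eta)^2) / sum(w)
}

#' Strategy 1: allelic working model
#'
#' Weighted GLM on the intercept and single-allele dosage columns only;
#' haplotype columns are discarded and CNVs contribute additively to their
#' constituent alleles (already decomposed in the design).
#'
#' @param design result of [build_design()] (list with `X` and `order`).
#' @param y outcome vector aligned with the design rows.
#' @param weights nonnegative row weights, summing to 1 per individual.
#' @param family `"gaussian"` or `"binomial"`.
#' @param extra_cols names of fully observed covariate columns in the
#'   design that are always kept.
#' @return an `outcome_params` object.
#' @export
fit_allelic <- function(design, y, weights, family = "gaussian",
                        extra_cols = character()) {
  cols <- c("(Intercept)", names(design$order)[design$order == 1], extra_cols)
  X <- design$X[, cols, drop = FALSE]
  f <- fit_wglm(X, y, weights, family)
  outcome_params(f$beta, f$phi, family,
                 details = list(p = f$p, se = f$se, dropped = f$dropped))
}

#' Strategy 2: forward-backward haplotype selection
#'
#' Starts from the allelic fit.  Order-2 haplotype columns whose
#' constituent alleles are all significant (Wald p < `p_enter`) are added
#' en bloc; haplotype columns are then removed backward one at a time
#' (largest p > `p_remove`).  While haplotype terms of the current order
#' survive, the forward-backward step is repeated at the next order.
#' Alleles are never removed, so the returned model respects the
#' allele-haplotype hierarchy.  Selection is deterministic given the data.
#'
#' @inheritParams fit_allelic
#' @param spec a [strategy_spec()] providing `p_enter` / `p_remove`.
#' @return an `outcome_params` object.
#' @export
fit_forward_backward <- function(design, y, weights, family = "gaussian",
                                 spec = strategy_spec("forward_backward"),
                                 extra_cols = character()) {
  ord <- design$order
  allele_cols <- names(ord)[ord == 1]
  base_cols <- c("(Intercept)", allele_cols, extra_cols)
  fit <- fit_wglm(design$X[, base_cols, drop = FALSE], y, weights, family)
  selected <- character(0)
  max_ord <- if (length(ord)) max(ord) else 1
  for (k in seq_len(max_ord)[-1]) {
    sig_alleles <- allele_cols[allele_cols %in% names(fit$p) &
                                 fit$p[allele_cols] < spec$p_enter]
    ## constituent-allele check: every member allele significant
    cand <- names(ord)[ord == k]
    cand <- cand[vapply(cand, function(nm) {
      mem <- strsplit(nm, "-", fixed = TRUE)[[1]]
      all(mem %in% sig_alleles)
    }, logical(1))]
    if (!length(cand)) break
    current <- c(base_cols, selected, cand)
    fit_k <- fit_wglm(design$X[, current, drop = FALSE], y, weights, family)
    ## backward: drop worst haplotype term while any exceeds p_remove
    hap_terms <- c(selected, cand)
    repeat {
      present <- intersect(hap_terms, names(fit_k$p))
      if (!length(present)) break
      worst <- present[which.max(fit_k$p[present])]
      if (fit_k$p[worst] <= spec$p_remove) break
      hap_terms <- setdiff(hap_terms, worst)
      current <- c(base_cols, hap_terms)
      fit_k <- fit_wglm(design$X[, current, drop = FALSE], y, weights, family)
    }
    new_k <- intersect(hap_terms, names(ord)[ord == k])
    selected <- hap_terms
    fit <- fit_k
    if (!length(new_k)) break
  }
  outcome_params(fit$beta, fit$phi, family,
                 details = list(p = fit$p, se = fit$se,
                                selected = selected, dropped = fit$dropped))
}

#' Strategy 3: elastic-net penalized working model
#'
#' Elastic-net GLM (`glmnet`) on the full NEG-filtered design; the tuning
#' parameter is chosen by cross-validated deviance with individual-level
#' folds, the intercept is unpenalized, and an all-zero coefficient
#' solution (intercept-only) is a valid outcome.
#'
#' @inheritParams fit_forward_backward
#' @param row_ind integer individual index per design row, used to keep all
#'   rows of one individual in the same fold.
#' @param lambda optional fixed penalty; skips cross-validation.
#' @return an `outcome_params` object (zero coefficients are kept so the
#'   coefficient vector stays aligned with the design).
#' @export
fit_penalized <- function(design, y, weights, family = "gaussian",
                          spec = strategy_spec("penalized"), row_ind = NULL,
                          lambda = NULL, extra_cols = character()) {
  X <- design$X[, setdiff(colnames(design$X), "(Intercept)"), drop = FALSE]
  if (ncol(X) < 2)
    stop("penalized strategy needs at least two predictor columns")
  if (is.null(row_ind)) row_ind <- seq_len(nrow(X))
  if (is.null(lambda)) {
    n_id <- max(row_ind)
    if (!is.null(spec$seed)) set.seed(spec$seed)
    fold_of <- sample(rep_len(seq_len(spec$cv_folds), n_id))
    cv <- glmnet::cv.glmnet(X, y, weights = weights, family = family,
                            alpha = spec$alpha, foldid = fold_of[row_ind],
                            standardize = TRUE)
    lambda <- if (spec$lambda_rule == "1se") cv$lambda.1se else cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    ## fixed penalty: fit at the requested lambda with a tight threshold
    fit <- suppressWarnings(
      glmnet::glmnet(X, y, weights = weights, family = family,
                     alpha = spec$alpha, standardize = TRUE,
                     lambda = lambda, thresh = 1e-14))
  }
  cf <- as.numeric(glmnet::coef.glmnet(fit, s = lambda, exact = FALSE))
  beta <- stats::setNames(cf, c("(Intercept)", colnames(X)))
  phi <- dispersion_of(beta, design$X, y, weights, family)
  outcome_params(beta, phi, family,
                 details = list(lambda = lambda,
                                nonzero = sum(beta[-1] != 0)))
}

#' Substantive models fitted after reconstruction
#'
#' Variant `"allelic"` fits an unpenalized GLM on the expected allele
#' dosages implied by the posterior haplotype counts of a completed EM
#' fit.  Variant `"candidate_list"` fits an elastic-net GLM on the
#' expected dosages of the candidate-list haplotypes (haplotypes with
#' expected frequency above 0.01), the penalization being required because
#' this design is typically high-dimensional.
#'
#' @param posterior_counts expected haplotype count matrix from a completed
#'   EM fit (rows sum to 2).
#' @param y outcome vector, one entry per individual.
#' @param variant `"allelic"` or `"candidate_list"`.
#' @param candidate_list haplotype labels used as predictors by the
#'   candidate-list variant.
#' @param family `"gaussian"` or `"binomial"`.
#' @param spec [strategy_spec()] controlling the elastic-net fit.
#' @param lambda optional fixed penalty for the candidate-list variant.
#' @return an `outcome_params` object.
#' @export
fit_substantive <- function(posterior_counts, y,
                            variant = c("allelic", "candidate_list"),
                            candidate_list = NULL, family = "gaussian",
                            spec = strategy_spec("penalized"),
                            lambda = NULL) {
  variant <- match.arg(variant)
  w <- rep(1, nrow(posterior_counts))
  if (variant == "allelic") {
    design <- build_design(posterior_counts, max_order = 1)
    return(fit_allelic(design, y, w, family))
  }
  stopifnot(!is.null(candidate_list))
  D <- hap_dose_matrix(posterior_counts, candidate_list)
  design <- list(X = cbind(`(Intercept)` = 1, D),
                 order = stats::setNames(
                   vapply(colnames(D), function(x)
                     length(hap_alleles(x)), numeric(1)), colnames(D)))
  fit_penalized(design, y, w, family, spec = spec, lambda = lambda)
}
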