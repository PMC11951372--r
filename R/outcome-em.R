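## log outcome density under the working model
log_outcome_density <- function(y, eta, family, phi = 1) {
  switch(family,
         gaussian = stats::dnorm(y, mean = eta, sd = sqrt(phi), log = TRUE),
         binomial = {
           p <- stats::plogis(eta)
           y * log(p) + (1 - y) * log1p(-p)
         },
         stop("unsupported outcome family: ", family))
}

## linear predictor for a fitted working model on a full design matrix;
## the model's columns are a (named) subset of the design columns
linear_predictor <- function(tau, X) {
  bn <- names(tau$beta)
  missing_cols <- setdiff(bn, colnames(X))
  if (length(missing_cols))
    stop("design lacks model columns: ", paste(missing_cols, collapse = ", "))
  as.numeric(X[, bn, drop = FALSE] %*% tau$beta)
}

#' Rescale outcome density terms within collapsed / non-collapsed strata
#'
#' Outcome density values can underflow when effects are large; within each
#' individual they are rescaled so that the maximum equals `c_thresh`,
#' separately for diplotypes containing the collapsed haplotype and those
#' containing none, preserving ratios within each stratum.  Keeping the
#' strata separate prevents all posterior mass from drifting onto the
#' collapsed category.
#'
#' @param terms nonnegative density values for the compatible diplotypes of
#'   one individual.
#' @param collapsed_flags logical, `TRUE` where the diplotype contains the
#'   collapsed haplotype.
#' @param c_thresh rescaling constant (default 1).
#' @return rescaled terms.
#' @export
rescale_outcome_terms <- function(terms, collapsed_flags, c_thresh = 1) {
  stopifnot(length(terms) == length(collapsed_flags), all(terms >= 0))
  out <- terms
  for (stratum in unique(collapsed_flags)) {
    sel <- collapsed_flags == stratum
    mx <- max(terms[sel])
    if (mx == 0) {
      if (any(sel)) stop("all outcome density terms are zero in a stratum")
      next
    }
    out[sel] <- terms[sel] / mx * c_thresh
  }
  out
}

## vectorized log-scale version over a whole compatibility table:
## subtract the per-(individual, stratum) maximum, add log(c_thresh)
rescale_log_terms <- function(log_terms, ind, clps_flag, c_thresh) {
  grp <- paste0(ind, "_", as.integer(clps_flag))
  mx <- vapply(split(log_terms, grp), max, numeric(1))
  log_terms - mx[grp] + log(c_thresh)
}

#' Diplotype posterior for one individual, given the outcome
#'
#' Evaluates `P(d | g, y) \propto P(y | d; tau) pi_h1 pi_h2 c_h` over the
#' diplotypes compatible with an ambiguous genotype, with the outcome
#' density rescaled per stratum.  With `tau = NULL`, or when the density is
#' constant across compatible diplotypes, the result reduces to the
#' genetic-only posterior.
#'
#' @param pi a `hap_freq` vector.
#' @param tau an `outcome_params` working model, or `NULL` for no outcome.
#' @param calls_i per-locus call list of the individual (see
#'   [enumerate_compatible_diplotypes()]).
#' @param y the individual's outcome value.
#' @param covariates optional named numeric vector of fully observed
#'   covariate values entering the working model.
#' @param c_thresh rescaling constant.
#' @return data.frame `h1`, `h2`, `prob` (probabilities summing to 1).
#' @export
diplotype_posterior_with_outcome <- function(pi, tau, calls_i, y,
                                             covariates = NULL,
                                             c_thresh = 1) {
  d <- enumerate_compatible_diplotypes(calls_i)
  state <- new_em_state(names(pi), as.numeric(pi),
                        attr(pi, "clps_members") %||% numeric(0),
                        attr(pi, "clps_prefixes") %||% numeric(0))
  idx <- index_compat(cbind(ind = 1L, d), state)
  w <- NULL
  if (!is.null(tau)) {
    feats <- hap_design_features(state$labels)
    X <- feats$F[idx$i1, , drop = FALSE] + feats$F[idx$i2, , drop = FALSE]
    X <- cbind(`(Intercept)` = 1, X)
    if (!is.null(covariates))
      X <- cbind(X, matrix(covariates, nrow(X), length(covariates),
                           byrow = TRUE,
                           dimnames = list(NULL, names(covariates))))
    ld <- log_outcome_density(y, linear_predictor(tau, X), tau$family,
                              tau$phi)
    clps_i <- match(CLPS_LABEL, state$labels)
    flag <- !is.na(clps_i) & (idx$i1 == clps_i | idx$i2 == clps_i)
    ld <- rescale_log_terms(ld, idx$ind, flag, c_thresh)
    w <- exp(ld)
  }
  prob <- posterior_probs(idx, state$freq, 1L, "1", extra_weight = w)
  data.frame(h1 = state$labels[idx$i1], h2 = state$labels[idx$i2],
             prob = prob, stringsAsFactors = FALSE)
}

#' Expand posteriors into a weighted outcome-regression dataset
#'
#' Each individual enters once per compatible diplotype, weighted by the
#' posterior probability of that diplotype; per-individual weights sum
#' to 1.  The working outcome model is fitted to these rows by weighted
#' regression.
#'
#' @param posterior data.frame `id`, `h1`, `h2`, `prob` as produced by the
#'   EM fits.
#' @param outcomes named or id-aligned outcome vector (one per individual).
#' @param covariates optional data.frame / matrix of fully observed
#'   covariates, one row per individual.
#' @param max_order highest haplotype order in the design.
#' @return list with `X` (design incl. intercept), `y`, `weights`, `ind`
#'   (individual index per row) and `order` (column orders).
#' @export
build_weighted_outcome_dataset <- function(posterior, outcomes,
                                           covariates = NULL,
                                           max_order = NULL) {
  ids <- unique(posterior$id)
  ind <- match(posterior$id, ids)
  labels <- sort(unique(c(posterior$h1, posterior$h2)), method = "radix")
  feats <- hap_design_features(labels, max_order = max_order)
  i1 <- match(posterior$h1, labels)
  i2 <- match(posterior$h2, labels)
  X <- feats$F[i1, , drop = FALSE] + feats$F[i2, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1, X)
  rownames(X) <- NULL
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    X <- cbind(X, cv[ind, , drop = FALSE])
  }
  y <- if (!is.null(names(outcomes))) outcomes[posterior$id] else
    outcomes[ind]
  list(X = X, y = as.numeric(y), weights = posterior$prob, ind = ind,
       order = feats$order)
}

## fit the configured working model; returns outcome_params or condition
fit_working_model <- function(design, y, w, family, spec, row_ind,
                              extra_cols = character()) {
  switch(spec$kind,
         allelic = fit_allelic(design, y, w, family, extra_cols = extra_cols),
         forward_backward = fit_forward_backward(design, y, w, family,
                                                 spec = spec,
                                                 extra_cols = extra_cols),
         penalized = fit_penalized(design, y, w, family, spec = spec,
                                   row_ind = row_ind,
                                   extra_cols = extra_cols),
         stop("unknown working-model strategy: ", spec$kind))
}

#' Profile EM with a working outcome model
#'
#' The outcome-augmented reconstruction: a no-outcome profile EM provides
#' starting values, after which the algorithm alternates between (i)
#' fitting the working outcome model by weighted regression on the
#' posterior-expanded dataset, (ii) recomputing diplotype posteriors with
#' the outcome density (rescaled per collapsed/non-collapsed stratum) and
#' (iii) updating haplotype frequencies with the collapsed category
#' profiled, until the largest frequency change falls below the
#' tolerance.
#'
#' @param genotypes a `hap_genotypes` object.
#' @param outcomes outcome vector, one value per individual (continuous or
#'   0/1).
#' @param covariates optional fully observed covariate matrix/data.frame,
#'   one row per individual.
#' @param family `"gaussian"` or `"binomial"`.
#' @param strategy a [strategy_spec()] or one of its `kind` strings;
#'   `"none"` reproduces the baseline [run_profile_em()] exactly.
#' @param config an [em_config()].
#' @param init_fit optional previously computed baseline `hap_em_fit` used
#'   for starting values (avoids refitting step 1).
#' @return a `hap_em_fit` with additional elements `tau` (the final
#'   working-model parameters), `strategy` and `family`; the trace gains
#'   the joint log-likelihood and a fit-failure flag per iteration.
#' @export
run_outcome_em <- function(genotypes, outcomes, covariates = NULL,
                           family = c("gaussian", "binomial"),
                           strategy = strategy_spec("allelic"),
                           config = em_config(), init_fit = NULL) {
  family <- match.arg(family)
  if (is.character(strategy)) strategy <- strategy_spec(strategy)
  if (is.null(strategy$seed)) strategy$seed <- config$seed
  if (strategy$kind == "none") {
    return(if (is.null(init_fit)) run_profile_em(genotypes, config) else
      init_fit)
  }
  stopifnot(length(outcomes) == n_individuals(genotypes),
            all(is.finite(outcomes)))
  if (family == "binomial") stopifnot(all(outcomes %in% 0:1))
  base <- if (is.null(init_fit)) run_profile_em(genotypes, config) else
    init_fit
  ids <- genotypes$ids
  N <- length(ids)
  compat_raw <- base$compat_raw
  state <- base$state
  cv <- if (!is.null(covariates)) as.matrix(covariates) else NULL

  idx <- index_compat(compat_raw, state)
  make_X <- function(state, idx) {
    feats <- hap_design_features(state$labels)
    X <- feats$F[idx$i1, , drop = FALSE] + feats$F[idx$i2, , drop = FALSE]
    X <- cbind(`(Intercept)` = 1, X)
    rownames(X) <- NULL
    if (!is.null(cv)) X <- cbind(X, cv[idx$ind, , drop = FALSE])
    list(X = X, order = feats$order)
  }
  dsg <- make_X(state, idx)
  extra_cols <- if (!is.null(cv)) colnames(cv) else character()
  y_row <- outcomes[idx$ind]

  tau <- NULL
  fails <- 0L
  trace <- list()
  pi_hist <- list()
  converged <- FALSE
  outcome_weight <- function(tau, dsg, idx, state) {
    if (is.null(tau)) return(NULL)
    ld <- log_outcome_density(y_row, linear_predictor(tau, dsg$X),
                              tau$family, tau$phi)
    clps_i <- match(CLPS_LABEL, state$labels)
    flag <- !is.na(clps_i) & (idx$i1 == clps_i | idx$i2 == clps_i)
    exp(rescale_log_terms(ld, idx$ind, flag, config$c_thresh))
  }

  for (it in seq_len(config$max_iter)) {
    ## E-weights under current parameters, then M-step for tau
    w_cur <- outcome_weight(tau, dsg, idx, state)
    post <- posterior_probs(idx, state$freq, N, ids, extra_weight = w_cur)
    fit_failed <- FALSE
    tau_new <- tryCatch(
      fit_working_model(dsg, y_row, post, family, strategy, idx$ind,
                        extra_cols = extra_cols),
      error = function(e) e)
    if (inherits(tau_new, "error")) {
      fit_failed <- TRUE
      fails <- fails + 1L
      if (fails >= 3L)
        stop("working outcome model failed in 3 consecutive iterations: ",
             conditionMessage(tau_new))
      tau_new <- tau
    } else fails <- 0L
    tau <- tau_new

    ## E-step with the updated outcome model, then M-step for pi
    w_new <- outcome_weight(tau, dsg, idx, state)
    post <- posterior_probs(idx, state$freq, N, ids, extra_weight = w_new)
    tot <- hap_totals(idx, post, length(state$labels))
    raw <- tot / (2 * N)
    new_freq <- state$freq
    profiled <- intersect(CLPS_LABEL, state$labels)
    if (length(profiled)) {
      prof_mass <- sum(state$freq[profiled])
      if (prof_mass >= 1)
        stop("profiled haplotypes carry the entire probability mass")
      free <- setdiff(seq_along(state$labels),
                      match(profiled, state$labels))
      new_freq[free] <- raw[free] / sum(raw[free]) * (1 - prof_mass)
    } else new_freq <- raw / sum(raw)
    delta <- max(abs(new_freq - state$freq))
    state$freq <- as.numeric(new_freq)
    names(state$freq) <- state$labels

    cl <- state_collapse(state, config)
    if (cl$collapsed) {
      state <- cl$state
      idx <- index_compat(compat_raw, state)
      dsg <- make_X(state, idx)
      y_row <- outcomes[idx$ind]
      delta <- Inf
    }

    ## joint observed-data log-likelihood (unscaled densities)
    ll_terms <- log(state$freq[idx$i1]) + log(state$freq[idx$i2]) +
      log(idx$c_het)
    if (!is.null(tau))
      ll_terms <- ll_terms +
        log_outcome_density(y_row, linear_predictor(tau, dsg$X),
                            tau$family, tau$phi)
    mx <- vapply(split(ll_terms, idx$ind), max, numeric(1))
    ll <- sum(mx + log(rowsum(exp(ll_terms - mx[as.character(idx$ind)]),
                              idx$ind, reorder = TRUE)[, 1]))
    lik_g <- state$freq[idx$i1] * state$freq[idx$i2] * idx$c_het
    ll_g <- sum(log(rowsum(lik_g, idx$ind, reorder = TRUE)[, 1]))
    trace[[it]] <- c(iter = it, loglik = ll, loglik_genetic = ll_g,
                     max_delta_pi = if (is.finite(delta)) delta else NA_real_,
                     fit_failed = as.numeric(fit_failed))
    pi_hist[[it]] <- state$freq
    if (is.finite(delta) && delta < config$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("outcome EM did not converge within ", config$max_iter,
            " iterations")
  w_fin <- outcome_weight(tau, dsg, idx, state)
  post <- posterior_probs(idx, state$freq, N, ids, extra_weight = w_fin)
  engine <- list(state = state, idx = idx, post = post,
                 trace = as.data.frame(do.call(rbind, trace)),
                 pi_history = pi_hist, converged = converged)
  fit <- finish_fit(engine, compat_raw, ids, genotypes$loci, config)
  fit$tau <- tau
  fit$strategy <- strategy
  fit$family <- family
  fit
}
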