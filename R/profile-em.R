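#' Haplotype frequency vector
#'
#' A simplex-constrained named vector of haplotype frequencies over a
#' haplotype universe, optionally containing the synthetic collapsed
#' category `CLPS` (always last).  The frequencies of haplotypes pooled
#' into `CLPS` at collapse time are retained as an attribute so that the
#' collapsed mass can later be redistributed for evaluation.
#'
#' @param freq named nonnegative numeric vector summing to 1.
#' @param clps_members named numeric vector: pooled haplotype labels with
#'   their last pre-collapse frequency estimates.
#' @param clps_prefixes named numeric vector of shorter-arity labels pooled
#'   during earlier locus-addition stages (bookkeeping only).
#' @return object of class `hap_freq`.
#' @export
hap_freq <- function(freq, clps_members = numeric(0), clps_prefixes = numeric(0)) {
  stopifnot(is.numeric(freq), !is.null(names(freq)), all(freq >= 0))
  if (abs(sum(freq) - 1) > 1e-8)
    stop("frequencies must sum to 1 (got ", format(sum(freq)), ")")
  if (anyDuplicated(names(freq))) stop("duplicate haplotype labels")
  has_clps <- CLPS_LABEL %in% names(freq)
  if (has_clps) { # keep CLPS last
    ord <- c(setdiff(names(freq), CLPS_LABEL), CLPS_LABEL)
    freq <- freq[ord]
  }
  structure(freq, clps_members = clps_members, clps_prefixes = clps_prefixes,
            class = "hap_freq")
}

#' @export
print.hap_freq <- function(x, ...) {
  cat("Haplotype frequencies over", length(x), "haplotypes\n")
  print(round(unclass(x), 6), ...)
  cm <- attr(x, "clps_members")
  if (length(cm))
    cat("collapsed members:", paste(names(cm), collapse = ", "), "\n")
  invisible(x)
}

#' EM configuration
#'
#' @param collapse_threshold haplotypes with estimated frequency below this
#'   value are pooled into the synthetic collapsed category (default 1e-7).
#'   Use 0 to disable collapsing.
#' @param max_iter maximum EM iterations per locus stage (default 200).
#' @param convergence_tol convergence is declared when the largest absolute
#'   change in haplotype frequencies between iterations falls below this
#'   value (default 1e-5).
#' @param protected_haplotypes labels (typically the candidate list of
#'   haplotypes with expected frequency > 0.01) that are never collapsed,
#'   even when estimated below the threshold.
#' @param locus_order order in which loci are added during reconstruction;
#'   default is the input column order.
#' @param c_thresh constant to which outcome density terms are rescaled
#'   within each individual, separately for collapsed and non-collapsed
#'   strata (default 1).
#' @param seed integer seed for stochastic substeps (cross-validation folds).
#' @return list of class `em_config`.
#' @export
em_config <- function(collapse_threshold = 1e-7, max_iter = 200,
                      convergence_tol = 1e-5,
                      protected_haplotypes = character(),
                      locus_order = NULL, c_thresh = 1, seed = NULL) {
  stopifnot(collapse_threshold >= 0, max_iter >= 1,
            convergence_tol > 0, c_thresh > 0)
  structure(list(collapse_threshold = collapse_threshold,
                 max_iter = max_iter,
                 convergence_tol = convergence_tol,
                 protected_haplotypes = as.character(protected_haplotypes),
                 locus_order = locus_order, c_thresh = c_thresh, seed = seed),
            class = "em_config")
}

## ---- internal EM state ----------------------------------------------------
## labels: current universe (CLPS last when present)
## freq: named numeric over labels
## clps_members / clps_prefixes: see hap_freq()
new_em_state <- function(labels, freq, clps_members = numeric(0),
                         clps_prefixes = numeric(0)) {
  names(freq) <- labels
  list(labels = labels, freq = freq, clps_members = clps_members,
       clps_prefixes = clps_prefixes)
}

state_freq <- function(state) {
  hap_freq(state$freq, clps_members = state$clps_members,
           clps_prefixes = state$clps_prefixes)
}

## map an original haplotype label to the current universe (CLPS-aware)
map_labels <- function(labels_in, state) {
  out <- labels_in
  known <- labels_in %in% state$labels
  if (all(known)) return(out)
  rest <- unique(labels_in[!known])
  for (lb in rest) {
    if (lb %in% names(state$clps_members)) {
      out[labels_in == lb] <- CLPS_LABEL
    } else if (length(state$clps_prefixes) &&
               any(vapply(names(state$clps_prefixes),
                          function(p) startsWith(lb, paste0(p, "-")),
                          logical(1)))) {
      out[labels_in == lb] <- CLPS_LABEL
    } else {
      stop("haplotype label not in universe: ", lb)
    }
  }
  out
}

## flatten a raw compatibility table into integer indices under the current
## mapping; diplotypes that coincide after collapsing are merged (union)
index_compat <- function(compat_raw, state) {
  h1 <- map_labels(compat_raw$h1, state)
  h2 <- map_labels(compat_raw$h2, state)
  i1 <- match(h1, state$labels)
  i2 <- match(h2, state$labels)
  ## canonical order within the pair (by universe label rank)
  rk <- match(state$labels, sort(state$labels, method = "radix"))
  swap <- rk[i2] < rk[i1]
  tmp <- i1[swap]; i1[swap] <- i2[swap]; i2[swap] <- tmp
  key <- paste(compat_raw$ind, i1, i2, sep = "\r")
  keep <- !duplicated(key)
  ind <- compat_raw$ind[keep]; i1 <- i1[keep]; i2 <- i2[keep]
  list(ind = ind, i1 = i1, i2 = i2, c_het = ifelse(i1 == i2, 1, 2))
}

## E-step diplotype probabilities; extra_weight multiplies the genetic term
## (used for the rescaled outcome densities); returns per-row posterior
posterior_probs <- function(idx, freq, N, ids, extra_weight = NULL) {
  lik <- freq[idx$i1] * freq[idx$i2] * idx$c_het
  if (!is.null(extra_weight)) lik <- lik * extra_weight
  den <- rowsum(lik, idx$ind, reorder = TRUE)[, 1]
  if (any(den <= 0) || any(!is.finite(den))) {
    bad <- which(den <= 0 | !is.finite(den))[1]
    stop("individual ", ids[bad],
         " has zero or non-finite posterior support")
  }
  as.numeric(lik / den[idx$ind])
}

## expected haplotype counts per haplotype (length M), and full N x M matrix
hap_totals <- function(idx, post, M) {
  acc <- rowsum(c(post, post), c(idx$i1, idx$i2), reorder = TRUE)
  tot <- numeric(M)
  tot[as.integer(rownames(acc))] <- acc[, 1]
  tot
}

counts_matrix <- function(idx, post, N, M, ids, labels) {
  lin1 <- (idx$i1 - 1L) * N + idx$ind
  lin2 <- (idx$i2 - 1L) * N + idx$ind
  acc <- rowsum(c(post, post), c(lin1, lin2), reorder = TRUE)
  A <- numeric(N * M)
  A[as.integer(rownames(acc))] <- acc[, 1]
  dim(A) <- c(N, M)
  dimnames(A) <- list(ids, labels)
  A
}

#' Observed-data genetic log-likelihood
#'
#' Computes `sum_i log sum_{d ~ g_i} pi_h1 pi_h2 c_h` over the compatibility
#' set of each individual, the likelihood whose maximizer the profile EM
#' algorithm targets.
#'
#' @param pi a `hap_freq` vector (may contain `CLPS`).
#' @param genotypes a `hap_genotypes` object, or a precomputed raw
#'   compatibility table as returned in `$table` by [compat_table()].
#' @return log-likelihood value.
#' @export
observed_loglik <- function(pi, genotypes) {
  compat_raw <- if (inherits(genotypes, "hap_genotypes"))
    compat_table(genotypes)$table else genotypes
  state <- new_em_state(names(pi), as.numeric(pi),
                        clps_members = attr(pi, "clps_members") %||% numeric(0),
                        clps_prefixes = attr(pi, "clps_prefixes") %||% numeric(0))
  idx <- index_compat(compat_raw, state)
  lik <- state$freq[idx$i1] * state$freq[idx$i2] * idx$c_het
  den <- rowsum(lik, idx$ind, reorder = TRUE)[, 1]
  if (any(den <= 0)) {
    bad <- which(den <= 0)[1]
    stop("individual ", names(den)[bad] %||% bad,
         " has zero support under the supplied frequencies")
  }
  sum(log(den))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' E-step: expected haplotype counts
#'
#' Posterior diplotype probabilities are computed from the genetic
#' likelihood alone and marginalized to expected per-haplotype counts;
#' every row sums to 2 (one diploid genome).
#'
#' @inheritParams observed_loglik
#' @return matrix of expected counts, individuals by haplotypes.
#' @export
e_step_counts <- function(pi, genotypes) {
  g <- genotypes
  compat_raw <- if (inherits(g, "hap_genotypes")) compat_table(g)$table else g
  ids <- if (inherits(g, "hap_genotypes")) g$ids else
    as.character(seq_len(max(compat_raw$ind)))
  N <- length(ids)
  state <- new_em_state(names(pi), as.numeric(pi),
                        clps_members = attr(pi, "clps_members") %||% numeric(0),
                        clps_prefixes = attr(pi, "clps_prefixes") %||% numeric(0))
  idx <- index_compat(compat_raw, state)
  post <- posterior_probs(idx, state$freq, N, ids)
  counts_matrix(idx, post, N, length(state$labels), ids, state$labels)
}

#' M-step: haplotype frequency update with profiling
#'
#' Non-profiled frequencies are set proportional to the expected population
#' counts `(1/2N) sum_i A_ij` and rescaled so that profiled entries (the
#' collapsed category) keep their previous values and the vector stays on
#' the simplex.
#'
#' @param counts expected haplotype count matrix (individuals x haplotypes).
#' @param profiled labels whose frequencies are held fixed.
#' @param pi_prev previous frequency vector (required when `profiled` is
#'   nonempty).
#' @return named frequency vector.
#' @export
m_step_htf <- function(counts, profiled = character(), pi_prev = NULL) {
  labels <- colnames(counts)
  raw <- colSums(counts) / (2 * nrow(counts))
  names(raw) <- labels
  if (!length(profiled)) return(raw / sum(raw))
  stopifnot(!is.null(pi_prev), all(profiled %in% labels))
  prof_mass <- sum(pi_prev[profiled])
  if (prof_mass >= 1)
    stop("profiled haplotypes carry the entire probability mass")
  free <- setdiff(labels, profiled)
  out <- raw
  out[profiled] <- pi_prev[profiled]
  out[free] <- raw[free] / sum(raw[free]) * (1 - prof_mass)
  out
}

#' Collapse rare haplotypes into the synthetic category
#'
#' Haplotypes with frequency below the collapsing threshold that are not
#' protected are pooled, mass-conserving, into `CLPS`; their last estimates
#' are recorded in the membership attribute.
#'
#' @param pi a `hap_freq` vector.
#' @param config an [em_config()] object.
#' @return a `hap_freq` vector over the (possibly reduced) universe.
#' @export
collapse_rare <- function(pi, config) {
  freq <- unclass(pi)
  attributes(freq) <- list(names = names(freq))
  cm <- attr(pi, "clps_members") %||% numeric(0)
  cp <- attr(pi, "clps_prefixes") %||% numeric(0)
  rare <- names(freq)[freq < config$collapse_threshold &
                        !(names(freq) %in% config$protected_haplotypes) &
                        names(freq) != CLPS_LABEL]
  if (!length(rare)) return(hap_freq(freq, cm, cp))
  pooled <- sum(freq[rare])
  cm <- c(cm, freq[rare])
  clps <- if (CLPS_LABEL %in% names(freq)) freq[[CLPS_LABEL]] else 0
  freq <- freq[setdiff(names(freq), c(rare, CLPS_LABEL))]
  freq[[CLPS_LABEL]] <- clps + pooled
  hap_freq(freq, cm, cp)
}

## collapse applied to the internal state; returns updated state + flag
state_collapse <- function(state, config) {
  rare <- state$labels[state$freq < config$collapse_threshold &
                         !(state$labels %in% config$protected_haplotypes) &
                         state$labels != CLPS_LABEL]
  if (!length(rare)) return(list(state = state, collapsed = FALSE))
  pooled <- sum(state$freq[rare])
  cm <- c(state$clps_members, state$freq[rare])
  clps <- if (CLPS_LABEL %in% state$labels) state$freq[[CLPS_LABEL]] else 0
  keep <- setdiff(state$labels, c(rare, CLPS_LABEL))
  freq <- c(state$freq[keep], clps + pooled)
  labels <- c(keep, CLPS_LABEL)
  list(state = new_em_state(labels, as.numeric(freq), cm, state$clps_prefixes),
       collapsed = TRUE)
}

## ---- the genetic profile EM loop ------------------------------------------
profile_em_engine <- function(compat_raw, ids, state, config) {
  N <- length(ids)
  idx <- index_compat(compat_raw, state)
  trace <- list()
  pi_hist <- list()
  converged <- FALSE
  profiled <- intersect(CLPS_LABEL, state$labels)
  for (it in seq_len(config$max_iter)) {
    post <- posterior_probs(idx, state$freq, N, ids)
    M <- length(state$labels)
    tot <- hap_totals(idx, post, M)
    raw <- tot / (2 * N)
    new_freq <- state$freq
    if (length(profiled)) {
      prof_mass <- sum(state$freq[profiled])
      if (prof_mass >= 1)
        stop("profiled haplotypes carry the entire probability mass")
      free <- setdiff(seq_len(M), match(profiled, state$labels))
      new_freq[free] <- raw[free] / sum(raw[free]) * (1 - prof_mass)
    } else {
      new_freq <- raw / sum(raw)
    }
    delta <- max(abs(new_freq - state$freq))
    state$freq <- as.numeric(new_freq)
    names(state$freq) <- state$labels
    cl <- state_collapse(state, config)
    if (cl$collapsed) {
      state <- cl$state
      idx <- index_compat(compat_raw, state)
      profiled <- CLPS_LABEL
      delta <- Inf  # universe changed; keep iterating
    }
    lik <- state$freq[idx$i1] * state$freq[idx$i2] * idx$c_het
    ll <- sum(log(rowsum(lik, idx$ind, reorder = TRUE)[, 1]))
    trace[[it]] <- c(iter = it, loglik = ll,
                     max_delta_pi = if (is.finite(delta)) delta else NA_real_)
    pi_hist[[it]] <- state$freq
    if (is.finite(delta) && delta < config$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  post <- posterior_probs(idx, state$freq, N, ids)
  list(state = state, idx = idx, post = post,
       trace = as.data.frame(do.call(rbind, trace)), pi_history = pi_hist,
       converged = converged)
}

finish_fit <- function(engine, compat_raw, ids, loci, config) {
  state <- engine$state
  N <- length(ids)
  M <- length(state$labels)
  A <- counts_matrix(engine$idx, engine$post, N, M, ids, state$labels)
  posterior <- data.frame(id = ids[engine$idx$ind],
                          h1 = state$labels[engine$idx$i1],
                          h2 = state$labels[engine$idx$i2],
                          prob = engine$post, stringsAsFactors = FALSE)
  structure(list(freq = state_freq(state), counts = A, posterior = posterior,
                 trace = engine$trace, pi_history = engine$pi_history,
                 converged = engine$converged,
                 loci = loci, ids = ids, compat_raw = compat_raw,
                 state = state, config = config),
            class = "hap_em_fit")
}

#' @export
print.hap_em_fit <- function(x, ...) {
  cat("Profile EM fit:", length(x$ids), "individuals,",
      length(x$loci), "loci,", length(x$freq), "haplotypes;",
      if (x$converged) "converged" else "NOT converged",
      "after", nrow(x$trace), "iterations\n")
  invisible(x)
}

#' Baseline profile EM without outcome information
#'
#' Iterates the genetic E-step, once-per-iteration collapsing of rare
#' haplotypes and the profiled M-step until the largest change in
#' haplotype frequencies falls below the tolerance or the iteration cap is
#' reached (non-convergence is flagged in the result, not an error).
#'
#' @param genotypes a `hap_genotypes` object.
#' @param config an [em_config()].
#' @param init optional initial `hap_freq`; default is uniform over the
#'   universe of haplotypes compatible with the data.
#' @return object of class `hap_em_fit` with elements `freq`, `counts`
#'   (expected haplotype counts, rows summing to 2), `posterior`
#'   (per-individual diplotype probabilities), `trace` and `converged`.
#' @export
run_profile_em <- function(genotypes, config = em_config(), init = NULL) {
  ct <- compat_table(genotypes)
  if (is.null(init)) {
    labels <- ct$labels
    state <- new_em_state(labels, rep(1 / length(labels), length(labels)))
  } else {
    state <- new_em_state(names(init), as.numeric(init),
                          attr(init, "clps_members") %||% numeric(0),
                          attr(init, "clps_prefixes") %||% numeric(0))
  }
  engine <- profile_em_engine(ct$table, genotypes$ids, state, config)
  if (!engine$converged)
    warning("profile EM did not converge within ", config$max_iter,
            " iterations")
  finish_fit(engine, ct$table, genotypes$ids, genotypes$loci, config)
}
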