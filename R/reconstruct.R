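## truncate full-length haplotype labels to their first k loci
prefix_labels <- function(labels, k) {
  vapply(labels, function(lb) paste(hap_alleles(lb)[seq_len(k)],
                                    collapse = "-"), character(1),
         USE.NAMES = FALSE)
}

stage_config <- function(config, k) {
  cfg <- config
  if (length(config$protected_haplotypes))
    cfg$protected_haplotypes <-
      unique(prefix_labels(config$protected_haplotypes, k))
  cfg
}

#' Extend a reconstruction by one locus
#'
#' The universe becomes the cross of the retained (non-collapsed)
#' haplotypes with the alleles of the new locus; initial frequencies are
#' the product of the previous estimates and the new locus' marginal
#' allele frequencies (estimated by a single-locus EM), after which the
#' profile EM is run on the extended data.  A collapsed category carries
#' over with its profiled frequency.
#'
#' @param fit_prev `hap_em_fit` covering a prefix of the locus order.
#' @param genotypes `hap_genotypes` containing at least one further locus.
#' @param config an [em_config()]; `locus_order` defaults to the input
#'   locus order.
#' @return `hap_em_fit` over the extended locus set.
#' @export
add_locus <- function(fit_prev, genotypes, config = em_config()) {
  lo <- config$locus_order %||% genotypes$loci
  s <- length(fit_prev$loci)
  if (s >= length(lo)) stop("no further locus to add")
  new_locus <- lo[s + 1]
  g_new <- subset_loci(genotypes, match(lo[seq_len(s + 1)], genotypes$loci))

  ## marginal allele frequencies of the new locus (single-locus EM)
  g_loc <- subset_loci(genotypes, match(new_locus, genotypes$loci))
  cfg_loc <- config
  cfg_loc$collapse_threshold <- 0
  cfg_loc$protected_haplotypes <- character()
  q <- run_profile_em(g_loc, cfg_loc)$freq

  prev <- fit_prev$freq
  retained <- setdiff(names(prev), CLPS_LABEL)
  alleles <- setdiff(names(q), CLPS_LABEL)
  qn <- as.numeric(q)[match(alleles, names(q))]
  qn <- qn / sum(qn)
  labels <- as.vector(outer(retained, alleles, paste, sep = "-"))
  freq <- as.vector(outer(as.numeric(prev[retained]), qn))
  clps_prefixes <- attr(prev, "clps_prefixes") %||% numeric(0)
  clps_members <- numeric(0)
  if (CLPS_LABEL %in% names(prev)) {
    clps_prefixes <- c(clps_prefixes, attr(prev, "clps_members"))
    labels <- c(labels, CLPS_LABEL)
    freq <- c(freq, as.numeric(prev[CLPS_LABEL]))
  }
  names(freq) <- labels
  init <- hap_freq(freq / sum(freq), clps_members, clps_prefixes)
  run_profile_em(g_new, stage_config(config, s + 1), init = init)
}

#' Full reconstruction with iterative locus addition
#'
#' Runs the profile EM locus by locus in the configured order; when an
#' outcome and a working-model strategy are supplied, each stage's
#' genotype-only fit provides the starting values for the
#' outcome-augmented EM at that stage, whose frequencies seed the next
#' stage.
#'
#' @inheritParams run_outcome_em
#' @param outcomes optional outcome vector; `NULL` reproduces the baseline
#'   reconstruction.
#' @return the final `hap_em_fit` over all loci.
#' @export
reconstruct_haplotypes <- function(genotypes, config = em_config(),
                                   outcomes = NULL, covariates = NULL,
                                   family = c("gaussian", "binomial"),
                                   strategy = strategy_spec("none")) {
  family <- match.arg(family)
  if (is.character(strategy)) strategy <- strategy_spec(strategy)
  lo <- config$locus_order %||% genotypes$loci
  if (!setequal(lo, genotypes$loci) || length(lo) != length(genotypes$loci))
    stop("locus_order must be a permutation of the input loci")
  config$locus_order <- lo
  use_outcome <- !is.null(outcomes) && strategy$kind != "none"

  run_stage <- function(fit) {
    if (!use_outcome) return(fit)
    g_stage <- subset_loci(genotypes,
                           match(fit$loci, genotypes$loci))
    run_outcome_em(g_stage, outcomes, covariates, family = family,
                   strategy = strategy, config = stage_config(
                     config, length(fit$loci)), init_fit = fit)
  }

  g1 <- subset_loci(genotypes, match(lo[1], genotypes$loci))
  fit <- run_stage(run_profile_em(g1, stage_config(config, 1)))
  while (length(fit$loci) < length(lo)) {
    fit <- run_stage(add_locus(fit, genotypes, config))
  }
  fit
}

#' Candidate-list haplotypes
#'
#' Haplotypes whose frequency exceeds a threshold (default 0.01); in the
#' simulation studies the list is built from the true haplotype
#' distribution and these haplotypes are protected from collapsing and
#' eligible as substantive-model predictors.
#'
#' @param freq a `hap_freq` (or named numeric) vector.
#' @param threshold frequency cutoff (default 0.01).
#' @return character vector of labels (never the collapsed category).
#' @export
candidate_haplotypes <- function(freq, threshold = 0.01) {
  labels <- names(freq)[as.numeric(freq) > threshold]
  setdiff(labels, CLPS_LABEL)
}
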