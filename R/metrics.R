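#' Root mean square error over replications
#'
#' `sqrt(mean((Z - Zhat)^2))`, combining bias and variance of an
#' estimator across simulation replications.
#'
#' @param estimates numeric vector of estimates (one per replication).
#' @param truth true value (scalar, or vector recycled against
#'   `estimates`).
#' @return nonnegative scalar.
#' @export
rmse <- function(estimates, truth) {
  stopifnot(length(estimates) >= 1)
  sqrt(mean((truth - estimates)^2))
}

## per-locus allele dose rows (CNV decomposed, NEG kept as a category) for
## a set of haplotype labels; CLPS rows are member-frequency-weighted
## averages of their members' rows
locus_dose_rows <- function(labels, clps_members = numeric(0)) {
  plain <- setdiff(labels, CLPS_LABEL)
  all_labels <- unique(c(plain, names(clps_members)))
  if (!length(all_labels)) stop("no haplotype labels to decompose")
  alleles <- strsplit(all_labels, "-", fixed = TRUE)
  L <- unique(lengths(alleles))
  if (length(L) != 1L)
    stop("haplotype labels span different numbers of loci")
  out <- vector("list", L)
  for (l in seq_len(L)) {
    contribs <- lapply(alleles, function(a) {
      al <- a[l]
      if (allele_is_neg(al)) stats::setNames(1, al) else decompose_cnv(al)
    })
    cats <- sort(unique(unlist(lapply(contribs, names))), method = "radix")
    D <- matrix(0, length(labels), length(cats),
                dimnames = list(labels, cats))
    rows <- match(all_labels, labels)
    for (m in seq_along(all_labels)) {
      if (is.na(rows[m])) next
      D[rows[m], names(contribs[[m]])] <- as.numeric(contribs[[m]])
    }
    if (CLPS_LABEL %in% labels) {
      if (length(clps_members) && sum(clps_members) > 0) {
        w <- clps_members / sum(clps_members)
        acc <- numeric(length(cats))
        for (m in seq_along(w)) {
          cm <- contribs[[match(names(w)[m], all_labels)]]
          acc[match(names(cm), cats)] <-
            acc[match(names(cm), cats)] + w[m] * as.numeric(cm)
        }
        D[CLPS_LABEL, ] <- acc
      }
    }
    out[[l]] <- D
  }
  out
}

#' Phase-insensitive haplotype reconstruction (HTR) measure
#'
#' Posterior haplotype counts and true diplotypes are converted into
#' per-locus expected allele-dose vectors (CNVs decomposed, NEG kept as a
#' category; each vector sums to 2) and compared by squared Euclidean
#' distance, averaged over individuals and loci.  Differences that are due
#' only to haplotype phasing do not contribute.
#'
#' @param posteriors expected haplotype count matrix (individuals x
#'   haplotypes, rows summing to 2), e.g. the `counts` element of an EM
#'   fit.
#' @param true_diplotypes data.frame `id`, `h1`, `h2` of true diplotypes
#'   (ids aligned with the count matrix rows).
#' @param clps_members named numeric of member frequencies used to spread
#'   the collapsed category's dose (see `hap_freq`).
#' @return nonnegative scalar; 0 for dose-exact reconstruction.
#' @export
htr <- function(posteriors, true_diplotypes, clps_members = numeric(0)) {
  stopifnot(nrow(posteriors) == nrow(true_diplotypes))
  est_labels <- colnames(posteriors)
  tru_labels <- sort(unique(c(true_diplotypes$h1, true_diplotypes$h2)),
                     method = "radix")
  A_true <- true_counts(true_diplotypes, tru_labels)
  ## shared per-locus categories
  D_est <- locus_dose_rows(est_labels, clps_members)
  D_tru <- locus_dose_rows(tru_labels)
  L <- length(D_est)
  stopifnot(length(D_tru) == L)
  total <- 0
  for (l in seq_len(L)) {
    cats <- sort(unique(c(colnames(D_est[[l]]), colnames(D_tru[[l]]))),
                 method = "radix")
    De <- matrix(0, length(est_labels), length(cats),
                 dimnames = list(est_labels, cats))
    De[, colnames(D_est[[l]])] <- D_est[[l]]
    Dt <- matrix(0, length(tru_labels), length(cats),
                 dimnames = list(tru_labels, cats))
    Dt[, colnames(D_tru[[l]])] <- D_tru[[l]]
    diff <- posteriors %*% De - A_true %*% Dt
    total <- total + mean(rowSums(diff^2))
  }
  total / L
}

#' Redistribute collapsed mass over its member haplotypes
#'
#' The collapsed category's frequency is spread over its recorded members
#' proportionally to their last pre-collapse estimates, enabling
#' truth-aligned comparisons.
#'
#' @param freq a `hap_freq` vector.
#' @return named numeric without the collapsed category (unless it has no
#'   recorded members).
#' @export
expand_clps <- function(freq) {
  x <- stats::setNames(as.numeric(freq), names(freq))
  if (!(CLPS_LABEL %in% names(x))) return(x)
  cm <- attr(freq, "clps_members") %||% numeric(0)
  if (!length(cm) || sum(cm) <= 0) return(x)
  w <- cm / sum(cm)
  mass <- x[[CLPS_LABEL]]
  x <- x[names(x) != CLPS_LABEL]
  for (m in names(w)) {
    cur <- if (m %in% names(x)) x[[m]] else 0
    x[m] <- cur + mass * w[[m]]
  }
  x
}

#' Kullback-Leibler divergence between haplotype distributions
#'
#' `KLD(truth || estimate)` with supports aligned to the truth's positive
#' entries; estimated mass is floored at `floor` and renormalized, so a
#' zero estimate on a truth atom is heavily (but finitely) penalized.
#' Collapsed mass in the estimate is first redistributed over its members
#' via [expand_clps()].
#'
#' @param p the reference (true) distribution, a named vector.
#' @param q the estimated distribution (`hap_freq` or named vector).
#' @param floor lower bound applied to the aligned estimate (default
#'   1e-12).
#' @return nonnegative scalar; 0 when the distributions coincide.
#' @export
kld <- function(p, q, floor = 1e-12) {
  pv <- stats::setNames(as.numeric(p), names(p))
  pv <- pv[pv > 0]
  qv <- if (inherits(q, "hap_freq")) expand_clps(q) else
    stats::setNames(as.numeric(q), names(q))
  qa <- qv[names(pv)]
  qa[is.na(qa)] <- 0
  qa <- pmax(qa, floor)
  qa <- qa / sum(qa)
  pv <- pv / sum(pv)
  sum(pv * log(pv / qa))
}

#' @rdname kld
#' @param no_outcome_kld,outcome_kld divergences of the baseline and the
#'   outcome-augmented estimates from the truth.
#' @details The KLD ratio `no_outcome_kld / outcome_kld` exceeds 1 when
#'   the outcome model's frequencies are closer to the truth than the
#'   baseline's.
#' @export
kld_ratio <- function(no_outcome_kld, outcome_kld) {
  no_outcome_kld / outcome_kld
}
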