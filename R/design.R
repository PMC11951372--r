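#' Fractional decomposition of a CNV compound allele
#'
#' For model-fitting design matrices, a compound copy-number allele is
#' decomposed into its constituent simple alleles, each contributing a
#' fractional count of one over the number of single-allele assignments
#' the compound can stand for (1/2 per member for a two-member compound).
#' A simple allele maps to itself with count 1; a NEG allele is the
#' reference and contributes no column.
#'
#' @param label a single allele label.
#' @return named numeric vector of fractional counts.
#' @export
decompose_cnv <- function(label) {
  if (allele_is_neg(label)) return(stats::setNames(numeric(0), character(0)))
  mem <- cnv_members(label)
  if (length(mem) == 1L) return(stats::setNames(1, label))
  stats::setNames(rep(1 / length(mem), length(mem)), mem)
}

## per-haplotype feature rows: expected additive dosage contributed by one
## copy of each universe haplotype to every design column
hap_design_features <- function(labels, max_order = NULL,
                                decompose = TRUE) {
  stopifnot(length(labels) >= 1)
  alleles <- lapply(labels, function(lb)
    if (lb == CLPS_LABEL) character(0) else hap_alleles(lb))
  L <- max(vapply(alleles, length, integer(1)))
  if (is.null(max_order)) max_order <- L
  max_order <- min(max_order, L)

  contrib_of <- function(a) {
    if (allele_is_neg(a)) return(stats::setNames(numeric(0), character(0)))
    if (decompose) decompose_cnv(a) else stats::setNames(1, a)
  }

  col_order <- list()   # name -> c(order, subset key)
  rows <- vector("list", length(labels))
  subsets <- unlist(lapply(seq_len(max_order), function(k)
    utils::combn(L, k, simplify = FALSE)), recursive = FALSE)
  for (m in seq_along(labels)) {
    if (labels[m] == CLPS_LABEL) { rows[[m]] <- numeric(0); next }
    contribs <- lapply(alleles[[m]], contrib_of)
    vals <- numeric(0)
    for (S in subsets) {
      parts <- contribs[S]
      if (any(vapply(parts, length, integer(1)) == 0L)) next  # NEG involved
      grid <- Reduce(function(acc, p) {
        list(name = paste(rep(acc$name, times = length(p)),
                          rep(names(p), each = length(acc$name)),
                          sep = if (length(acc$name) && nzchar(acc$name[1])) "-" else ""),
             val = rep(acc$val, times = length(p)) *
               rep(as.numeric(p), each = length(acc$name)))
      }, parts, init = list(name = "", val = 1))
      key <- paste(sprintf("%02d", S), collapse = "")
      for (j in seq_along(grid$name)) {
        nm <- grid$name[j]
        if (is.null(col_order[[nm]]))
          col_order[[nm]] <- list(order = length(S), key = key)
        vals[nm] <- (if (is.na(vals[nm])) 0 else vals[nm]) + grid$val[j]
      }
    }
    rows[[m]] <- vals
  }
  if (!length(col_order)) stop("design has no non-reference columns")
  meta <- data.frame(name = names(col_order),
                     order = vapply(col_order, function(z) z$order, numeric(1)),
                     key = vapply(col_order, function(z) z$key, character(1)),
                     stringsAsFactors = FALSE)
  meta <- meta[order(meta$order, meta$key, meta$name, method = "radix"), ]
  P <- nrow(meta)
  F <- matrix(0, length(labels), P, dimnames = list(labels, meta$name))
  for (m in seq_along(labels)) {
    v <- rows[[m]]
    if (length(v)) F[m, names(v)] <- as.numeric(v)
  }
  list(F = F, order = stats::setNames(meta$order, meta$name))
}

#' Build an outcome design matrix from (expected) diplotype counts
#'
#' Starting from a matrix of known or expected haplotype counts (rows
#' summing to 2), columns are formed by marginalization: expected additive
#' dosages of single alleles, of pairwise (cis) haplotypes, and so on up to
#' `max_order` loci.  Columns involving a NEG allele are excluded (NEG is
#' the reference), CNV compound alleles are fractionally decomposed when
#' `decompose = TRUE`, and the collapsed category contributes zero to every
#' column.  An intercept column is prepended.
#'
#' @param counts numeric matrix, individuals x universe haplotypes, with
#'   haplotype labels as column names; rows must sum to 2.
#' @param max_order highest number of loci joined into a haplotype column
#'   (default: all loci, i.e. a saturated design).
#' @param decompose decompose CNV compound alleles into fractional simple
#'   allele counts (TRUE for model fitting; FALSE for the simulation
#'   design, where a compound is its own allele).
#' @param include optional character vector restricting the non-intercept
#'   columns.
#' @return list with `X` (design matrix, intercept first) and `order`
#'   (named integer: number of loci behind each non-intercept column).
#' @export
build_design <- function(counts, max_order = NULL, decompose = TRUE,
                         include = NULL) {
  stopifnot(is.matrix(counts), !is.null(colnames(counts)))
  feats <- hap_design_features(colnames(counts), max_order = max_order,
                               decompose = decompose)
  X <- counts %*% feats$F
  ord <- feats$order
  if (!is.null(include)) {
    keep <- intersect(colnames(X), include)
    X <- X[, keep, drop = FALSE]
    ord <- ord[keep]
  }
  X <- cbind(`(Intercept)` = 1, X)
  list(X = X, order = ord)
}

#' Expected dosages of full-length target haplotypes
#'
#' Maps expected haplotype counts onto a set of target haplotype labels
#' (e.g. the candidate list), decomposing CNV compound alleles
#' fractionally: a universe haplotype contributes to a target the product
#' over loci of its per-copy decomposition weight for the target's allele
#' (identity counts 1; the collapsed category contributes nothing).
#'
#' @param counts expected haplotype count matrix (individuals x universe).
#' @param targets character vector of full-length haplotype labels.
#' @return matrix of expected dosages, individuals x targets.
#' @export
hap_dose_matrix <- function(counts, targets) {
  labels <- colnames(counts)
  W <- matrix(0, length(labels), length(targets),
              dimnames = list(labels, targets))
  tg_alleles <- lapply(targets, hap_alleles)
  for (m in seq_along(labels)) {
    if (labels[m] == CLPS_LABEL) next
    al <- hap_alleles(labels[m])
    for (t in seq_along(targets)) {
      ta <- tg_alleles[[t]]
      if (length(ta) != length(al)) next
      wgt <- 1
      for (l in seq_along(al)) {
        if (al[l] == ta[l]) next
        d <- decompose_cnv(al[l])
        wl <- if (ta[l] %in% names(d)) d[[ta[l]]] else 0
        wgt <- wgt * wl
        if (wgt == 0) break
      }
      W[m, t] <- wgt
    }
  }
  counts %*% W
}
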