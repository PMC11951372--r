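#' @keywords internal
"_PACKAGE"

## Label conventions used throughout:
##  - allele tokens may contain "^" joining the members of a compound
##    copy-number (CNV) allele, e.g. "E^F" = two gene copies E and F on one
##    chromosome;
##  - tokens starting with "NEG" denote absence of the gene at that locus;
##  - haplotype labels join allele tokens with "-" in the fixed locus order;
##  - "CLPS" is reserved for the synthetic collapsed haplotype.

CLPS_LABEL <- "CLPS"

ALLELE_TOKEN_RE <- "^[A-Za-z0-9_.^]+$"

#' Is an allele label a NEG (gene-absence) allele?
#'
#' @param label character vector of allele labels.
#' @return logical vector.
#' @export
allele_is_neg <- function(label) {
  startsWith(label, "NEG")
}

#' Members of a compound CNV allele
#'
#' A compound allele such as `"E^F"` represents several gene copies carried
#' on one chromosome and is treated as a single (separate) allele of its
#' locus.  Its members are the simple allele labels joined by `"^"`.
#'
#' @param label a single allele label.
#' @return character vector of member labels; length 1 for a simple allele.
#' @export
cnv_members <- function(label) {
  strsplit(label, "^", fixed = TRUE)[[1]]
}

#' Is an allele label a compound CNV allele?
#' @param label character vector of allele labels.
#' @return logical vector.
#' @export
allele_is_cnv <- function(label) {
  grepl("^", label, fixed = TRUE)
}

#' Build a haplotype label from per-locus allele labels
#' @param alleles character vector, one allele label per locus in locus order.
#' @return single haplotype label, alleles joined by `"-"`.
#' @export
hap_label <- function(alleles) {
  paste(alleles, collapse = "-")
}

#' Split a haplotype label into per-locus allele labels
#' @param label character vector of haplotype labels.
#' @return for a single label, a character vector of alleles; for several, a
#'   list of such vectors.
#' @export
hap_alleles <- function(label) {
  out <- strsplit(label, "-", fixed = TRUE)
  if (length(label) == 1L) out[[1]] else out
}

## locale-independent lexicographic order for label canonicalization
label_lt <- function(a, b) {
  if (a == b) return(FALSE)
  order(c(a, b), method = "radix")[1] == 1L
}

#' Canonicalize an unordered haplotype pair into a diplotype
#'
#' Diplotype identity is phase-free: the two haplotypes are sorted
#' lexicographically so that `canonicalize_diplotype(x, y)` and
#' `canonicalize_diplotype(y, x)` give identical results.  The
#' heterozygosity constant is 2 for a heterozygote and 1 for a homozygote.
#'
#' @param h1,h2 haplotype labels drawn from the same locus set.
#' @return list with elements `h1`, `h2` (sorted labels), `het` (logical) and
#'   `c_het` (1 or 2).
#' @export
canonicalize_diplotype <- function(h1, h2) {
  stopifnot(is.character(h1), is.character(h2),
            length(h1) == 1L, length(h2) == 1L)
  n1 <- length(hap_alleles(h1))
  n2 <- length(hap_alleles(h2))
  if (n1 != n2)
    stop("haplotypes span different numbers of loci: ", h1, " vs ", h2)
  if (label_lt(h2, h1)) { tmp <- h1; h1 <- h2; h2 <- tmp }
  het <- h1 != h2
  list(h1 = h1, h2 = h2, het = het, c_het = if (het) 2 else 1)
}

#' Multi-locus ambiguous genotype container
#'
#' Stores, for each individual and locus, exactly two chromosome "copies".
#' Each copy is a set of allele labels (a singleton for an unambiguous
#' call).  A locus observed with a single call is padded with the locus NEG
#' allele, reflecting presence/absence genotyping; CNV multiplicity is
#' carried inside compound alleles, never as extra copies.
#'
#' @param ids character vector of individual identifiers.
#' @param loci character vector of locus names.
#' @param calls list of length `length(ids)`; element `i` is a list of
#'   length `length(loci)` whose element `l` is a list of two character
#'   vectors (the per-copy allele sets).
#' @param neg character vector of the NEG allele label of each locus;
#'   defaults to `NEG1`, `NEG2`, ... by locus position.
#' @return an object of class `hap_genotypes`.
#' @export
hap_genotypes <- function(ids, loci, calls, neg = paste0("NEG", seq_along(loci))) {
  ids <- as.character(ids)
  loci <- as.character(loci)
  stopifnot(length(calls) == length(ids), length(neg) == length(loci))
  for (i in seq_along(calls)) {
    if (length(calls[[i]]) != length(loci))
      stop("individual ", ids[i], ": expected calls at ", length(loci), " loci")
    for (l in seq_along(loci)) {
      cp <- calls[[i]][[l]]
      if (!is.list(cp) || length(cp) != 2L)
        stop("individual ", ids[i], ", locus ", loci[l],
             ": each locus must carry exactly 2 copies after NEG padding")
      for (k in 1:2) {
        if (!length(cp[[k]]) || !all(grepl(ALLELE_TOKEN_RE, cp[[k]])))
          stop("individual ", ids[i], ", locus ", loci[l],
               ": invalid allele token in copy ", k)
      }
    }
  }
  structure(list(ids = ids, loci = loci, calls = calls, neg = neg),
            class = "hap_genotypes")
}

#' @export
print.hap_genotypes <- function(x, ...) {
  cat("Ambiguous genotypes:", length(x$ids), "individuals,",
      length(x$loci), "loci (", paste(x$loci, collapse = ", "), ")\n")
  invisible(x)
}

#' Number of individuals in a genotype container
#' @param g a `hap_genotypes` object.
#' @return integer count.
#' @export
n_individuals <- function(g) length(g$ids)

## restrict a genotype object to a subset of loci (by index)
subset_loci <- function(g, which_loci) {
  calls <- lapply(g$calls, function(ci) ci[which_loci])
  hap_genotypes(g$ids, g$loci[which_loci], calls, neg = g$neg[which_loci])
}

#' Enumerate the diplotypes compatible with one ambiguous genotype
#'
#' Returns exactly the unordered haplotype pairs whose per-locus allele
#' multisets match some resolution of each copy's allele set, under every
#' phase assignment, deduplicated.  The result is never empty and is
#' returned in a deterministic label-sorted order.
#'
#' @param calls_i per-individual call list: one element per locus, each a
#'   list of two character vectors (copy allele sets).
#' @param universe optional character vector of known haplotype labels; when
#'   supplied, enumerated haplotypes absent from it raise an error (unknown
#'   allele/haplotype) unless they belong to the collapsed category.
#' @return data.frame with columns `h1`, `h2` (canonical labels) and `het`.
#' @export
enumerate_compatible_diplotypes <- function(calls_i, universe = NULL) {
  L <- length(calls_i)
  if (L == 0L) stop("no loci")
  ## per locus: the set of ordered allele pairs consistent with the two copies
  pair_sets <- vector("list", L)
  for (l in seq_len(L)) {
    cp1 <- unique(calls_i[[l]][[1]])
    cp2 <- unique(calls_i[[l]][[2]])
    a <- c(rep(cp1, times = length(cp2)), rep(cp2, times = length(cp1)))
    b <- c(rep(cp2, each = length(cp1)), rep(cp1, each = length(cp2)))
    key <- paste(a, b, sep = "\r")
    keep <- !duplicated(key)
    pair_sets[[l]] <- cbind(a[keep], b[keep])
  }
  ## cross loci, tracking both chromosomes
  h1 <- ""
  h2 <- ""
  for (l in seq_len(L)) {
    ps <- pair_sets[[l]]
    n_old <- length(h1)
    n_new <- nrow(ps)
    sep <- if (l == 1L) "" else "-"
    h1 <- paste(rep(h1, times = n_new), rep(ps[, 1], each = n_old), sep = sep)
    h2 <- paste(rep(h2, times = n_new), rep(ps[, 2], each = n_old), sep = sep)
  }
  ## canonical unordered pairs, deduplicated (radix order, locale-independent)
  levs <- sort(unique(c(h1, h2)), method = "radix")
  flip <- match(h2, levs) < match(h1, levs)
  tmp <- h1[flip]; h1[flip] <- h2[flip]; h2[flip] <- tmp
  key <- paste(h1, h2, sep = "\r")
  keep <- !duplicated(key)
  h1 <- h1[keep]; h2 <- h2[keep]
  ord <- order(h1, h2, method = "radix")
  h1 <- h1[ord]; h2 <- h2[ord]
  if (!is.null(universe)) {
    unknown <- setdiff(unique(c(h1, h2)), universe)
    if (length(unknown))
      stop("enumerated haplotypes not present in the universe: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
  }
  data.frame(h1 = h1, h2 = h2, het = h1 != h2, stringsAsFactors = FALSE)
}

#' Compatibility table for a set of genotypes
#'
#' Stacks [enumerate_compatible_diplotypes()] over all individuals into one
#' flat table used by the EM routines.
#'
#' @param g a `hap_genotypes` object.
#' @return list with `table` (data.frame `ind`, `h1`, `h2`, `het`) and
#'   `labels` (sorted universe of haplotype labels appearing in any
#'   compatibility set).
#' @export
compat_table <- function(g) {
  N <- n_individuals(g)
  pieces <- vector("list", N)
  for (i in seq_len(N)) {
    d <- enumerate_compatible_diplotypes(g$calls[[i]])
    pieces[[i]] <- cbind(ind = i, d)
  }
  tab <- do.call(rbind, pieces)
  labels <- sort(unique(c(tab$h1, tab$h2)), method = "radix")
  list(table = tab, labels = labels)
}
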