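## small builders and independent oracles shared across the test files

## one locus: two copies, each a character vector (ambiguity set)
lc <- function(c1, c2) list(c1, c2)

## genotype container from explicit per-individual call lists
gt <- function(..., loci = NULL) {
  calls <- list(...)
  L <- length(calls[[1]])
  if (is.null(loci)) loci <- paste0("g", seq_len(L))
  hap_genotypes(as.character(seq_along(calls)), loci, calls)
}

## unambiguous genotypes from a pair of haplotype label vectors
geno_from_dips <- function(h1, h2) {
  a1 <- strsplit(h1, "-", fixed = TRUE)
  a2 <- strsplit(h2, "-", fixed = TRUE)
  L <- length(a1[[1]])
  calls <- lapply(seq_along(h1), function(i)
    lapply(seq_len(L), function(l) list(a1[[i]][l], a2[[i]][l])))
  hap_genotypes(as.character(seq_along(h1)), paste0("g", seq_len(L)), calls)
}

## restrict a genotype container to a subset of loci
subset_loci_for_test <- function(g, which) {
  calls <- lapply(g$calls, function(ci) ci[which])
  hap_genotypes(g$ids, g$loci[which], calls, neg = g$neg[which])
}

## exact haplotype count matrix from true diplotypes
true_counts_for_test <- function(dips, universe) {
  N <- nrow(dips)
  A <- matrix(0, N, length(universe), dimnames = list(dips$id, universe))
  for (i in seq_len(N)) {
    A[i, dips$h1[i]] <- A[i, dips$h1[i]] + 1
    A[i, dips$h2[i]] <- A[i, dips$h2[i]] + 1
  }
  A
}

## brute-force enumeration over every per-copy resolution and phase
## assignment, deduplicated -- the independent oracle for enumeration
brute_force_diplotypes <- function(calls_i) {
  combos <- list(list(h1 = character(0), h2 = character(0)))
  for (l in seq_along(calls_i)) {
    cp <- calls_i[[l]]
    new <- list()
    for (cmb in combos) for (a in cp[[1]]) for (b in cp[[2]])
      for (ph in 1:2) {
        x <- if (ph == 1) c(a, b) else c(b, a)
        new[[length(new) + 1L]] <- list(h1 = c(cmb$h1, x[1]),
                                        h2 = c(cmb$h2, x[2]))
      }
    combos <- new
  }
  labs <- t(vapply(combos, function(z)
    sort(c(paste(z$h1, collapse = "-"), paste(z$h2, collapse = "-")),
         method = "radix"), character(2)))
  df <- unique(data.frame(h1 = labs[, 1], h2 = labs[, 2],
                          stringsAsFactors = FALSE))
  df <- df[order(df$h1, df$h2, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## direct summation of the observed-data likelihood over explicitly listed
## compatibility sets (oracle for observed_loglik)
brute_force_loglik <- function(pi, genotypes) {
  total <- 0
  for (i in seq_along(genotypes$ids)) {
    d <- brute_force_diplotypes(genotypes$calls[[i]])
    li <- sum(vapply(seq_len(nrow(d)), function(r) {
      ch <- if (d$h1[r] == d$h2[r]) 1 else 2
      pi[[d$h1[r]]] * pi[[d$h2[r]]] * ch
    }, numeric(1)))
    total <- total + log(li)
  }
  total
}

## exhaustive simplex grid search of the observed-data log-likelihood for
## universes of 2 or 3 haplotypes (coarse grid, then local refinement)
grid_search_loglik <- function(genotypes, step = 1e-3, refine = 1e-5) {
  ct <- compat_table(genotypes)
  labels <- ct$labels
  M <- length(labels)
  stopifnot(M %in% 2:3)
  tab <- ct$table
  tab$i1 <- match(tab$h1, labels)
  tab$i2 <- match(tab$h2, labels)
  tab$ch <- ifelse(tab$i1 == tab$i2, 1, 2)
  eval_ll <- function(P) {  # P: npts x M matrix of candidate frequencies
    ll <- numeric(nrow(P))
    for (i in unique(tab$ind)) {
      rows <- tab[tab$ind == i, , drop = FALSE]
      li <- rep(0, nrow(P))
      for (r in seq_len(nrow(rows)))
        li <- li + P[, rows$i1[r]] * P[, rows$i2[r]] * rows$ch[r]
      ll <- ll + log(li)
    }
    ll
  }
  make_grid <- function(lo, hi, by) {
    s1 <- seq(max(lo[1], 0), min(hi[1], 1), by = by)
    if (M == 2) {
      P <- cbind(s1, 1 - s1)
    } else {
      s2 <- seq(max(lo[2], 0), min(hi[2], 1), by = by)
      P <- as.matrix(expand.grid(s1, s2))
      P <- cbind(P, 1 - rowSums(P))
      P <- P[P[, 3] >= 0, , drop = FALSE]
    }
    P
  }
  P <- make_grid(rep(0, M - 1), rep(1, M - 1), step)
  ll <- eval_ll(P)
  best <- P[which.max(ll), seq_len(M - 1)]
  P2 <- make_grid(best - step, best + step, refine)
  ll2 <- eval_ll(P2)
  max(max(ll), max(ll2))
}
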