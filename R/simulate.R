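#' Scenario specification for the simulator
#'
#' Bundles the data-generating parameters of one simulation scenario: the
#' per-locus allele frequencies (compound CNV alleles are alleles of their
#' locus here), the allele effect sizes, linkage-disequilibrium pairs on a
#' standardized 0-1 scale, pairwise allelic ambiguity groups, haplotype
#' effects and the outcome family.
#'
#' @param af named list (one element per locus) of named allele frequency
#'   vectors; each must sum to 1.
#' @param effects named numeric of per-allele outcome effects (NEG alleles
#'   0); haplotype effects are derived as sums of allele effects.
#' @param ld_pairs list of length-2 character vectors `(earlier allele,
#'   later allele)` receiving the standardized LD level.
#' @param ld_level standardized LD level in `[0, 1]` (0 none, 0.4 medium,
#'   0.8 high) applied to every pair.
#' @param ambiguity_groups list of pairwise allele groups (e.g.
#'   `c("A", "C")`) whose member calls become ambiguous.
#' @param ambiguity_level per-copy probability that an eligible call is
#'   replaced by its group's allele set (0, 0.4 or 0.8 in the study).
#' @param hap_effects haplotype labels (allele pairs such as `"A-F"`) that
#'   carry an additional effect equal to the sum of their allele effects.
#' @param use_hap_effects whether the haplotype effects enter the outcome.
#' @param family `"gaussian"` (intercept 0, unit error variance) or
#'   `"binomial"` (intercept -1.75, about a 15% baseline event rate).
#' @param effect_multiplier scales all non-intercept effects.
#' @param N number of individuals (2000 in the study).
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(af, effects, ld_pairs = list(), ld_level = 0,
                          ambiguity_groups = list(), ambiguity_level = 0,
                          hap_effects = character(),
                          use_hap_effects = FALSE,
                          family = c("gaussian", "binomial"),
                          effect_multiplier = 1, N = 2000) {
  family <- match.arg(family)
  stopifnot(is.list(af), length(af) >= 1, !is.null(names(af)))
  for (l in names(af)) {
    if (abs(sum(af[[l]]) - 1) > 1e-12)
      stop("allele frequencies at locus ", l, " do not sum to 1")
    if (is.null(names(af[[l]])) || anyDuplicated(names(af[[l]])))
      stop("allele frequencies at locus ", l, " must be uniquely named")
  }
  stopifnot(ld_level >= 0, ld_level <= 1,
            ambiguity_level >= 0, ambiguity_level <= 1,
            effect_multiplier > 0, N >= 1)
  structure(list(af = af, loci = names(af), effects = effects,
                 ld_pairs = ld_pairs, ld_level = ld_level,
                 ambiguity_groups = ambiguity_groups,
                 ambiguity_level = ambiguity_level,
                 hap_effects = hap_effects,
                 use_hap_effects = use_hap_effects, family = family,
                 effect_multiplier = effect_multiplier, N = N),
            class = "scenario_spec")
}

## locus index of an allele label within the af lists (must be unique)
allele_locus <- function(spec, allele) {
  hits <- which(vapply(spec$af, function(a) allele %in% names(a),
                       logical(1)))
  if (length(hits) != 1L)
    stop("allele ", allele, " is not a unique allele of one locus")
  hits
}

#' True haplotype distribution of a scenario
#'
#' Loci are added iteratively; at each step the joint distribution over
#' (existing haplotype, new allele) starts from independence and, for each
#' LD pair at the standardized level `l`, the joint cell mass of
#' (haplotypes carrying the earlier allele, the later allele) is raised to
#' `P(h)P(a) + l * Dmax` with `Dmax = min(P(h)(1 - P(a)), (1 - P(h))P(a))`
#' (the Lewontin D' normalization); remaining cells are adjusted
#' proportionally so that every per-locus marginal is preserved exactly.
#' Overlapping constraints are reconciled by cyclic proportional fitting.
#'
#' @param spec a [scenario_spec()].
#' @return a `hap_freq` vector over the full haplotype universe.
#' @export
build_true_htfs <- function(spec) {
  loci <- spec$loci
  labels <- names(spec$af[[1]])
  probs <- as.numeric(spec$af[[1]])
  if (length(loci) == 1L)
    return(hap_freq(stats::setNames(probs, labels)))
  for (j in 2:length(loci)) {
    q <- spec$af[[j]]
    qn <- as.numeric(q)
    J <- outer(probs, qn)
    if (spec$ld_level > 0 && length(spec$ld_pairs)) {
      constraints <- list()
      for (pr in spec$ld_pairs) {
        if (!(pr[2] %in% names(q))) next
        l_prev <- allele_locus(spec, pr[1])
        if (l_prev >= j) next
        prefix_allele <- vapply(strsplit(labels, "-", fixed = TRUE),
                                `[`, character(1), l_prev)
        rowsA <- which(prefix_allele == pr[1])
        col <- match(pr[2], names(q))
        pA <- sum(probs[rowsA])
        pa <- qn[col]
        dmax <- min(pA * (1 - pa), (1 - pA) * pa)
        target <- pA * pa + spec$ld_level * dmax
        constraints[[length(constraints) + 1L]] <-
          list(rowsA = rowsA, col = col, pA = pA, pa = pa, target = target,
               pair = pr)
      }
      if (length(constraints)) {
        for (iter in seq_len(2000L)) {
          for (cs in constraints) {
            m11 <- sum(J[cs$rowsA, cs$col])
            m12 <- sum(J[cs$rowsA, -cs$col])
            m21 <- sum(J[-cs$rowsA, cs$col])
            m22 <- sum(J[-cs$rowsA, -cs$col])
            tg <- c(cs$target, cs$pA - cs$target, cs$pa - cs$target,
                    1 - cs$pA - cs$pa + cs$target)
            if (any(tg < -1e-12))
              stop("infeasible LD level for pair ",
                   paste(cs$pair, collapse = "-"))
            cur <- c(m11, m12, m21, m22)
            if (any(cur == 0 & tg > 1e-12))
              stop("infeasible LD level for pair ",
                   paste(cs$pair, collapse = "-"),
                   " (no supporting cells)")
            sc <- ifelse(cur > 0, tg / cur, 0)
            J[cs$rowsA, cs$col] <- J[cs$rowsA, cs$col] * sc[1]
            J[cs$rowsA, -cs$col] <- J[cs$rowsA, -cs$col] * sc[2]
            J[-cs$rowsA, cs$col] <- J[-cs$rowsA, cs$col] * sc[3]
            J[-cs$rowsA, -cs$col] <- J[-cs$rowsA, -cs$col] * sc[4]
          }
          ## restore exact margins (rows then columns)
          rs <- rowSums(J)
          J <- J * ifelse(probs > 0, probs / pmax(rs, .Machine$double.xmin),
                          0)
          csum <- colSums(J)
          J <- sweep(J, 2, ifelse(qn > 0,
                                  qn / pmax(csum, .Machine$double.xmin), 0),
                     `*`)
          err_m <- max(abs(rowSums(J) - probs), abs(colSums(J) - qn))
          err_t <- max(vapply(constraints, function(cs)
            abs(sum(J[cs$rowsA, cs$col]) - cs$target), numeric(1)))
          if (err_m < 1e-13 && err_t < 1e-12) break
        }
        if (err_m >= 1e-10 || err_t >= 1e-9)
          stop("LD construction did not converge; the requested levels ",
               "appear jointly infeasible")
      }
    }
    labels <- as.vector(outer(labels, names(q), paste, sep = "-"))
    probs <- as.vector(J)
    keep <- probs > 0
    labels <- labels[keep]
    probs <- probs[keep]
  }
  hap_freq(stats::setNames(probs / sum(probs), labels))
}

#' Draw diplotypes under Hardy-Weinberg equilibrium
#'
#' `2N` haplotypes are drawn independently from the haplotype distribution
#' and paired into `N` diplotypes.
#'
#' @param htfs a `hap_freq` vector.
#' @param N number of individuals.
#' @param seed integer seed (draws are reproducible bit for bit).
#' @return data.frame `id`, `h1`, `h2` with canonically ordered pairs.
#' @export
draw_diplotypes <- function(htfs, N, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- names(htfs)
  draws <- sample(labels, 2 * N, replace = TRUE, prob = as.numeric(htfs))
  h1 <- draws[seq_len(N) * 2 - 1]
  h2 <- draws[seq_len(N) * 2]
  levs <- sort(unique(c(h1, h2)), method = "radix")
  swap <- match(h2, levs) < match(h1, levs)
  tmp <- h1[swap]; h1[swap] <- h2[swap]; h2[swap] <- tmp
  data.frame(id = as.character(seq_len(N)), h1 = h1, h2 = h2,
             stringsAsFactors = FALSE)
}

#' Coarsen diplotypes into ambiguous genotype calls
#'
#' Phase is always lost.  Every allele copy belonging to a pairwise
#' ambiguity group is replaced by the group's allele set with probability
#' equal to the ambiguity level; the replacement probability depends only
#' on the resulting ambiguous call (the MAR mechanism).  Compound CNV
#' alleles remain compound, so some ambiguity (phasing, CNV) persists even
#' at level 0.
#'
#' @param diplotypes data.frame `id`, `h1`, `h2` of true diplotypes.
#' @param spec a [scenario_spec()] supplying the groups and the level.
#' @param seed integer seed.
#' @return a `hap_genotypes` object.
#' @export
inject_ambiguity <- function(diplotypes, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loci <- spec$loci
  level <- spec$ambiguity_level
  group_of <- list()
  for (gr in spec$ambiguity_groups) {
    gr <- sort(gr, method = "radix")
    for (a in gr) group_of[[a]] <- gr
  }
  N <- nrow(diplotypes)
  a1 <- do.call(rbind, strsplit(diplotypes$h1, "-", fixed = TRUE))
  a2 <- do.call(rbind, strsplit(diplotypes$h2, "-", fixed = TRUE))
  calls <- vector("list", N)
  for (i in seq_len(N)) {
    ci <- vector("list", length(loci))
    for (l in seq_along(loci)) {
      cp <- list(a1[i, l], a2[i, l])
      for (k in 1:2) {
        g <- group_of[[cp[[k]]]]
        if (!is.null(g) && level > 0 && stats::runif(1) < level)
          cp[[k]] <- g
      }
      ci[[l]] <- cp
    }
    calls[[i]] <- ci
  }
  hap_genotypes(diplotypes$id, loci, calls,
                neg = paste0("NEG", seq_along(loci)))
}

## exact haplotype count matrix of true diplotypes over a universe
true_counts <- function(diplotypes, universe) {
  N <- nrow(diplotypes)
  A <- matrix(0, N, length(universe),
              dimnames = list(diplotypes$id, universe))
  A[cbind(seq_len(N), match(diplotypes$h1, universe))] <-
    A[cbind(seq_len(N), match(diplotypes$h1, universe))] + 1
  A[cbind(seq_len(N), match(diplotypes$h2, universe))] <-
    A[cbind(seq_len(N), match(diplotypes$h2, universe))] + 1
  A
}

## design matrix and coefficient vector of the generating outcome model;
## the simulation design keeps CNV compounds as their own alleles
simulation_design <- function(diplotypes, spec, universe) {
  A <- true_counts(diplotypes, universe)
  mo <- if (spec$use_hap_effects) 2L else 1L
  d <- build_design(A, max_order = mo, decompose = FALSE)
  cols <- names(d$order)[d$order == 1]
  if (spec$use_hap_effects)
    cols <- c(cols, intersect(spec$hap_effects, names(d$order)))
  X <- d$X[, c("(Intercept)", cols), drop = FALSE]
  beta0 <- if (spec$family == "binomial") -1.75 else 0
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  beta["(Intercept)"] <- beta0
  for (cn in cols) {
    al <- hap_alleles(cn)
    eff <- sum(vapply(al, function(a)
      spec$effects[[a]] %||% 0, numeric(1)))
    beta[cn] <- eff * spec$effect_multiplier
  }
  list(X = X, beta = beta)
}

#' Simulate outcomes from true diplotypes
#'
#' Continuous outcomes follow `Y = X' beta + e`, `e ~ N(0, 1)` with zero
#' intercept; binary outcomes are Bernoulli with logit link and intercept
#' -1.75 (about a 15% baseline event rate).  Haplotype effects, when
#' present, equal the sum of their allele effects and are added on top of
#' the allele effects.
#'
#' @param diplotypes data.frame of true diplotypes.
#' @param spec a [scenario_spec()].
#' @param universe haplotype labels of the true distribution.
#' @param seed integer seed.
#' @return list `y`, `X` (generating design), `beta` (named true
#'   coefficients).
#' @export
simulate_outcome <- function(diplotypes, spec, universe, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sd_ <- simulation_design(diplotypes, spec, universe)
  eta <- as.numeric(sd_$X %*% sd_$beta)
  y <- if (spec$family == "binomial") {
    stats::rbinom(length(eta), 1, stats::plogis(eta))
  } else {
    eta + stats::rnorm(length(eta))
  }
  list(y = y, X = sd_$X, beta = sd_$beta)
}

#' Simulate one complete dataset
#'
#' Runs the full data-generating mechanism: true haplotype distribution,
#' Hardy-Weinberg diplotype draws, ambiguity injection and outcome
#' simulation, returning the observed data together with a truth sidecar
#' for metric computation.  Substream seeds for the three stochastic steps
#' are derived deterministically from the root seed.
#'
#' @param spec a [scenario_spec()].
#' @param seed root integer seed of the replication.
#' @return list `genotypes`, `outcomes`, `truth` (with `diplotypes`,
#'   `htf`, `beta`, `X`) and `spec`.
#' @export
simulate_dataset <- function(spec, seed = 1) {
  seed <- as.integer(seed)
  htf <- build_true_htfs(spec)
  dips <- draw_diplotypes(htf, spec$N, seed = seed)
  geno <- inject_ambiguity(dips, spec, seed = seed + 1000003L)
  out <- simulate_outcome(dips, spec, names(htf), seed = seed + 2000003L)
  list(genotypes = geno, outcomes = out$y,
       truth = list(diplotypes = dips, htf = htf, beta = out$beta,
                    X = out$X),
       spec = spec)
}

#' Expand a scenario grid
#'
#' Full cross of base scenarios with the study factors (LD level,
#' ambiguity level, within-EM outcome model, effect-size multiplier) in a
#' deterministic order with unique scenario ids.
#'
#' @param base_scenarios data.frame of base scenarios with a unique
#'   `base_id` column (or a character vector of ids).
#' @param factors named list of factor levels; defaults to the study's
#'   factors: LD and ambiguity levels 0/0.4/0.8, the four within-EM
#'   models, and multipliers 1/5, 1, 5.
#' @return data.frame with one row per scenario and a unique
#'   `scenario_id`.
#' @export
build_scenario_grid <- function(base_scenarios,
                                factors = list(
                                  ld_level = c(0, 0.4, 0.8),
                                  ambiguity_level = c(0, 0.4, 0.8),
                                  strategy = c("none", "allelic",
                                               "forward_backward",
                                               "penalized"),
                                  effect_multiplier = c(0.2, 1, 5))) {
  if (is.character(base_scenarios))
    base_scenarios <- data.frame(base_id = base_scenarios,
                                 stringsAsFactors = FALSE)
  stopifnot(is.data.frame(base_scenarios), "base_id" %in%
              names(base_scenarios))
  if (anyDuplicated(base_scenarios$base_id))
    stop("duplicate base-scenario ids")
  stopifnot(length(factors) >= 1, all(lengths(factors) >= 1))
  grid <- expand.grid(c(list(base_id = base_scenarios$base_id), factors),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- merge(grid, base_scenarios, by = "base_id", sort = FALSE)
  ord <- do.call(order, c(unname(grid[c("base_id", names(factors))]),
                          list(method = "radix")))
  grid <- grid[ord, , drop = FALSE]
  grid$scenario_id <- sprintf("S%04d", seq_len(nrow(grid)))
  rownames(grid) <- NULL
  grid
}
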