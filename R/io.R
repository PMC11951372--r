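## cell grammar: copy ( "+" copy )? ; copy := allele ( "/" allele )* ;
## "/" separates the members of an ambiguity set; "^" joins CNV members;
## a missing second copy is padded with the locus NEG allele

parse_genotype_cell <- function(cell, neg, line = NA, column = NA) {
  where <- paste0(" (line ", line, ", column ", column, ")")
  cell <- trimws(cell)
  if (cell == "" || is.na(cell)) return(list(neg, neg))
  copies <- strsplit(cell, "+", fixed = TRUE)[[1]]
  if (length(copies) < 1L || length(copies) > 2L || any(copies == ""))
    stop("malformed genotype cell '", cell, "'", where)
  out <- lapply(copies, function(cp) {
    al <- strsplit(cp, "/", fixed = TRUE)[[1]]
    if (!length(al) || any(!grepl(ALLELE_TOKEN_RE, al)))
      stop("invalid allele token in cell '", cell, "'", where)
    unique(al)
  })
  if (length(out) == 1L) out <- c(out, list(neg))
  out
}

#' Read ambiguous genotypes from TSV
#'
#' Expects a column `id` followed by one column per locus.  Cell grammar:
#' `copy("+"copy)?` where `copy := allele("/"allele)*`; `"/"` lists an
#' ambiguity set and `"^"` inside a token joins the members of a compound
#' CNV allele (example cell: `A/C+B`).  A missing second copy is padded
#' with the locus NEG allele (`NEG1`, `NEG2`, ... by column position).
#'
#' @param path TSV file path.
#' @return a `hap_genotypes` object.
#' @export
read_genotypes <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (!"id" %in% names(tab) || ncol(tab) < 2L)
    stop("genotype file needs an 'id' column plus one column per locus")
  loci <- setdiff(names(tab), "id")
  neg <- paste0("NEG", seq_along(loci))
  calls <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    calls[[i]] <- lapply(seq_along(loci), function(l)
      parse_genotype_cell(tab[i, loci[l]], neg[l],
                          line = i + 1L, column = l + 1L))
  }
  hap_genotypes(tab$id, loci, calls, neg = neg)
}

format_copy <- function(cp) paste(cp, collapse = "/")

#' Write ambiguous genotypes to TSV
#'
#' Inverse of [read_genotypes()]; `read_genotypes(write_genotypes(g))`
#' reproduces the structure exactly.
#'
#' @param g a `hap_genotypes` object.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_genotypes <- function(g, path) {
  rows <- vapply(seq_along(g$ids), function(i) {
    cells <- vapply(seq_along(g$loci), function(l) {
      cp <- g$calls[[i]][[l]]
      paste(format_copy(cp[[1]]), format_copy(cp[[2]]), sep = "+")
    }, character(1))
    paste(c(g$ids[i], cells), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("id", g$loci), collapse = "\t"), rows), path)
  invisible(path)
}

#' Write haplotype frequencies to TSV
#' @param freq a `hap_freq` vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_htf <- function(freq, path) {
  utils::write.table(
    data.frame(haplotype = names(freq),
               frequency = signif(as.numeric(freq), 10)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read haplotype frequencies written by [write_htf()]
#' @param path TSV path.
#' @return a `hap_freq` vector.
#' @export
read_htf <- function(path) {
  tab <- utils::read.delim(path, colClasses = c("character", "numeric"))
  x <- stats::setNames(tab$frequency, tab$haplotype)
  hap_freq(x / sum(x))
}

#' Write per-individual diplotype posteriors to TSV
#' @param fit a `hap_em_fit`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_posteriors <- function(fit, path) {
  post <- fit$posterior
  out <- data.frame(id = post$id,
                    diplotype = paste(post$h1, post$h2, sep = "|"),
                    probability = signif(post$prob, 10))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write working / substantive model coefficients to TSV
#' @param tau an `outcome_params` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_coefficients <- function(tau, path) {
  utils::write.table(
    data.frame(term = names(tau$beta),
               estimate = signif(tau$beta, 10)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Evaluate a fit against simulation truth
#'
#' Computes the population-level and individual-level performance
#' measures for one replication: per-haplotype frequency errors, the HTR
#' measure and the divergence from the true distribution.
#'
#' @param fit a `hap_em_fit`.
#' @param truth the `truth` element of [simulate_dataset()].
#' @return list with `htf_error` (named estimated-minus-true vector over
#'   the truth support), `max_abs_htf_error`, `htr` and `kld`.
#' @export
evaluate_fit <- function(fit, truth) {
  est <- expand_clps(fit$freq)
  tru <- stats::setNames(as.numeric(truth$htf), names(truth$htf))
  err <- stats::setNames(numeric(length(tru)), names(tru))
  for (h in names(tru))
    err[h] <- (if (h %in% names(est)) est[[h]] else 0) - tru[[h]]
  list(htf_error = err,
       max_abs_htf_error = max(abs(err)),
       htr = htr(fit$counts, truth$diplotypes,
                 clps_members = attr(fit$freq, "clps_members") %||%
                   numeric(0)),
       kld = kld(tru, fit$freq))
}

#' Read a scenario specification from YAML
#'
#' The YAML mirrors the arguments of [scenario_spec()]: `af` (map of
#' locus to allele-frequency map), `effects`, `ld_pairs`,
#' `ambiguity_groups`, levels, `family`, `effect_multiplier`, `N`,
#' `hap_effects`, `use_hap_effects`.
#'
#' @param path YAML path.
#' @return a [scenario_spec()].
#' @export
read_scenario_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- c("af", "effects")
  if (!all(need %in% names(raw)))
    stop("scenario YAML must define: ", paste(need, collapse = ", "))
  af <- lapply(raw$af, function(a) unlist(a))
  scenario_spec(af = af, effects = unlist(raw$effects),
                ld_pairs = lapply(raw$ld_pairs %||% list(), unlist),
                ld_level = raw$ld_level %||% 0,
                ambiguity_groups = lapply(raw$ambiguity_groups %||% list(),
                                          unlist),
                ambiguity_level = raw$ambiguity_level %||% 0,
                hap_effects = unlist(raw$hap_effects %||% character()),
                use_hap_effects = isTRUE(raw$use_hap_effects),
                family = raw$family %||% "gaussian",
                effect_multiplier = raw$effect_multiplier %||% 1,
                N = raw$N %||% 2000)
}

#' Write per-replication metrics as JSON
#' @param metrics named list of numeric metrics.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
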