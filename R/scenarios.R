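#' Shipped simulation parameter sets
#'
#' `scenario_main()` returns the three-locus scenario used in the main
#' simulation study: two sets of KIR-like allele frequencies (set 1
#' skewed/non-uniform, set 2 approximately uniform) with compound CNV
#' alleles, two corresponding effect-size sets, LD on the pairs B-F, D-G
#' and E-H and allelic ambiguity between A/C, B/D, E/F and G/H.
#' `scenario_poc()` returns the simpler proof-of-concept scenario with
#' strong effects and no CNV alleles: variant `"A"` has allele effects
#' only, variant `"B"` adds haplotype effects on A-E and F-H.
#'
#' @param af_set,effect_set which frequency / effect-size column to use
#'   (1 or 2).
#' @param ... further arguments passed to [scenario_spec()] (LD and
#'   ambiguity levels, family, multiplier, N, `use_hap_effects`).
#' @return a [scenario_spec()].
#' @export
scenario_main <- function(af_set = 1, effect_set = 1, ...) {
  af <- if (af_set == 1) {
    list(g1 = c(NEG1 = 0.15, A = 0.40, B = 0.30, C = 0.10, D = 0.04,
                `A^B` = 0.008, `C^D` = 0.002),
         g2 = c(NEG2 = 0.31, E = 0.43, F = 0.25, `E^F` = 0.01),
         g3 = c(NEG3 = 0.70, G = 0.19, H = 0.10, `G^H` = 0.01))
  } else {
    list(g1 = c(NEG1 = 0.15, A = 0.20, B = 0.20, C = 0.20, D = 0.20,
                `A^B` = 0.04, `C^D` = 0.01),
         g2 = c(NEG2 = 0.31, E = 0.32, F = 0.32, `E^F` = 0.05),
         g3 = c(NEG3 = 0.70, G = 0.125, H = 0.125, `G^H` = 0.05))
  }
  effects <- if (effect_set == 1) {
    c(NEG1 = 0, A = 0.75, B = 0.25, C = -0.75, D = -0.25,
      `A^B` = 1.00, `C^D` = -1.00,
      NEG2 = 0, E = -0.50, F = 0.50, `E^F` = 0.00,
      NEG3 = 0, G = 0.25, H = -0.50, `G^H` = -0.25)
  } else {
    c(NEG1 = 0, A = 0.75, B = 0.25, C = -0.75, D = -0.25,
      `A^B` = 2.00, `C^D` = -2.00,
      NEG2 = 0, E = -0.50, F = 0.50, `E^F` = -0.50,
      NEG3 = 0, G = 0.25, H = -0.50, `G^H` = -0.50)
  }
  scenario_spec(af = af, effects = effects,
                ld_pairs = list(c("B", "F"), c("D", "G"), c("E", "H")),
                ambiguity_groups = list(c("A", "C"), c("B", "D"),
                                        c("E", "F"), c("G", "H")),
                hap_effects = c("A-F", "C-H"), ...)
}

#' @rdname scenario_main
#' @param variant `"A"` (allele effects only) or `"B"` (with haplotype
#'   effects).
#' @export
scenario_poc <- function(variant = c("A", "B"), ...) {
  variant <- match.arg(variant)
  scenario_spec(
    af = list(g1 = c(NEG1 = 0.25, A = 0.45, B = 0.30),
              g2 = c(NEG2 = 0.35, E = 0.35, F = 0.30),
              g3 = c(NEG3 = 0.70, G = 0.15, H = 0.15)),
    effects = c(NEG1 = 0, A = 5.0, B = -5.0,
                NEG2 = 0, E = 3.5, F = -3.5,
                NEG3 = 0, G = 2.5, H = -2.5),
    ld_pairs = list(c("A", "F"), c("B", "G"), c("E", "H")),
    ambiguity_groups = list(c("A", "B"), c("E", "F"), c("G", "H")),
    hap_effects = c("A-E", "F-H"),
    use_hap_effects = variant == "B", ...)
}

#' Default base scenarios of the partial factorial design
#'
#' Eight base scenarios formed from the four binary design factors —
#' allele-frequency set (non-uniform vs approximately uniform), effect
#' set (small vs strong CNV effects), haplotype effects (absent vs
#' present) and outcome type (continuous vs binary).  Scenario 001 is the
#' all-default combination and 002 adds haplotype effects; the remaining
#' rows vary one or two factors at a time, avoiding combinations that pair
#' weak effects with ill-conditioned outcome models.  Crossed with the LD,
#' ambiguity, within-EM model and multiplier factors this yields the
#' study's 864 scenarios.
#'
#' @return data.frame with columns `base_id`, `af_set`, `effect_set`,
#'   `use_hap_effects`, `family`.
#' @export
default_base_scenarios <- function() {
  data.frame(
    base_id = sprintf("%03d", 1:8),
    af_set = c(1, 1, 1, 2, 1, 1, 2, 1),
    effect_set = c(1, 1, 1, 1, 2, 1, 2, 2),
    use_hap_effects = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE,
                        TRUE),
    family = c("gaussian", "gaussian", "binomial", "gaussian", "gaussian",
               "binomial", "gaussian", "gaussian"),
    stringsAsFactors = FALSE)
}
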