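#' Weight vector for the HemeLock index
#'
#' Four dimensionless weights on the interaction frequency/distance ratios
#' (backbone carbon hydrogen bonds, sidechain hydrogen bonds, sidechain
#' carbon hydrogen bonds, sidechain salt bridges) plus the volume-scaled
#' size weight w5 (Å³). Defaults are the published fitted values, in which
#' the sidechain carbon-hydrogen-bond and salt-bridge weights are zero.
#'
#' @param w1,w2,w3,w4 interaction-term weights (dimensionless, >= 0).
#' @param w5 size-score weight (Å³-scaled, >= 0).
#' @return Object of class `hemelock_weights`.
#' @export
hemelock_weights <- function(w1 = 2.974, w2 = 0.9201, w3 = 0, w4 = 0,
                             w5 = 282.3) {
  w <- c(w1 = w1, w2 = w2, w3 = w3, w4 = w4, w5 = w5)
  if (!all(is.finite(w)) || any(w < 0)) {
    stop("weights must be finite and non-negative")
  }
  structure(as.list(w), class = "hemelock_weights")
}

#' @export
print.hemelock_weights <- function(x, ...) {
  cat(sprintf("<hemelock_weights> w1=%.4g w2=%.4g w3=%.4g w4=%.4g w5=%.4g\n",
              x$w1, x$w2, x$w3, x$w4, x$w5))
  invisible(x)
}

#' The published index-to-Tm linear model
#'
#' The fitted linear law `Tm = a * index + b` with a = 4.995 °C per index
#' unit and b = 42.86 °C, together with the published weight vector.
#'
#' @return Object of class `hemelock_model`: list with `a`, `b`, `weights`.
#' @export
published_model <- function() {
  structure(list(a = 4.995, b = 42.86, weights = hemelock_weights(),
                 provenance = "published fit"),
            class = "hemelock_model")
}

#' @export
print.hemelock_model <- function(x, ...) {
  cat(sprintf("<hemelock_model> Tm = %.4g * index + %.4g  (%s)\n",
              x$a, x$b, x$provenance %||% "unlabelled"))
  print(x$weights)
  invisible(x)
}

# Frequency/distance ratio with the zero-frequency convention: a category
# that never fires contributes exactly 0, not 0/0.
safe_ratio <- function(i, d) {
  if (i == 0) return(0)
  if (!is.finite(d) || d <= 0) stop("positive frequency with non-positive distance")
  i / d
}

#' Interaction score of a residue summary
#'
#' The weighted sum of the four frequency/distance ratios:
#' `w1*BBCHI/BBCHD + w2*SCHI/SCHD + w3*SCCHI/SCCHD + w4*SCSBI/SCSBD`.
#' All units cancel by convention; a zero-frequency category contributes
#' exactly 0 regardless of its weight.
#'
#' @param summary an [interaction_summary()] (or a list with the eight
#'   fields).
#' @param weights a [hemelock_weights()].
#' @return Dimensionless score (scalar).
#' @export
interaction_score <- function(summary, weights = hemelock_weights()) {
  terms <- interaction_terms(summary, weights)
  sum(terms)
}

interaction_terms <- function(summary, weights) {
  c(BB_CH = weights$w1 * safe_ratio(summary$BBCHI, summary$BBCHD),
    SC_H  = weights$w2 * safe_ratio(summary$SCHI, summary$SCHD),
    SC_CH = weights$w3 * safe_ratio(summary$SCCHI, summary$SCCHD),
    SC_SB = weights$w4 * safe_ratio(summary$SCSBI, summary$SCSBD))
}

#' Amino-acid size score
#'
#' `w5 / volume`, strictly decreasing in residue volume: a smaller residue
#' at the heme-contacting position scores higher. With the published
#' w5 = 282.3 the score spans 1.239 (Trp) to 3.186 (Ala) over the tested
#' substitutions.
#'
#' @param amino_acid 1- or 3-letter residue code.
#' @param w5 size weight (Å³-scaled).
#' @param volumes named volume table, see [aa_volumes()].
#' @return Dimensionless score.
#' @export
size_score <- function(amino_acid, w5 = hemelock_weights()$w5,
                       volumes = aa_volumes()) {
  aa <- canonical_aa(amino_acid)
  unname(w5 / volumes[aa])
}

#' HemeLock index of a variant
#'
#' The sum of the interaction score and the size score, with the per-term
#' breakdown. With the published weights the sidechain carbon-hydrogen-bond
#' and salt-bridge terms are zero.
#'
#' @inheritParams interaction_score
#' @inheritParams size_score
#' @return Object of class `score_breakdown`: list with `terms` (the four
#'   weighted interaction terms), `interaction_score`, `size_score` and
#'   `hemelock_index` (their exact sum).
#' @export
hemelock_index <- function(summary, amino_acid,
                           weights = hemelock_weights(),
                           volumes = aa_volumes()) {
  terms <- interaction_terms(summary, weights)
  iscore <- sum(terms)
  sscore <- size_score(amino_acid, weights$w5, volumes)
  structure(list(terms = terms, interaction_score = iscore,
                 size_score = sscore,
                 hemelock_index = iscore + sscore,
                 amino_acid = canonical_aa(amino_acid)),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("<score_breakdown> %s: index = %.4f\n", x$amino_acid,
              x$hemelock_index))
  cat(sprintf("  interaction score %.4f (BB_CH %.4f, SC_H %.4f, SC_CH %.4f, SC_SB %.4f)\n",
              x$interaction_score, x$terms[["BB_CH"]], x$terms[["SC_H"]],
              x$terms[["SC_CH"]], x$terms[["SC_SB"]]))
  cat(sprintf("  size score        %.4f\n", x$size_score))
  invisible(x)
}

#' Predict melting temperature from a HemeLock index
#'
#' The linear law `Tm = a * index + b`.
#'
#' @param index HemeLock index value(s) or `score_breakdown` object(s).
#' @param model a `hemelock_model` (default: the published fit).
#' @return Predicted Tm in °C.
#' @export
predict_tm <- function(index, model = published_model()) {
  if (inherits(index, "score_breakdown")) index <- index$hemelock_index
  stopifnot(is.finite(model$a), is.finite(model$b))
  model$a * index + model$b
}

#' Ligand-receptor binding energy by subtraction
#'
#' `E_binding = E_complex - E_ligand - E_receptor`; all three inputs must
#' share one unit, which the result preserves. (Evaluating the three
#' component energies with a force field is outside this package.)
#'
#' @param e_complex,e_ligand,e_receptor energies in a common unit.
#' @return Binding energy, same unit.
#' @export
binding_energy <- function(e_complex, e_ligand, e_receptor) {
  stopifnot(is.finite(e_complex), is.finite(e_ligand), is.finite(e_receptor))
  e_complex - e_ligand - e_receptor
}
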