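#' Score a predicted species set against ground truth
#'
#' Species identity is by normalized name (case-folded, whitespace
#' collapsed). Precision is `TP / (TP + FP)`, recall is `TP / (TP + FN)`
#' (each 0 when its denominator is 0) and F1 is their harmonic mean (0 when
#' both are 0).
#'
#' @param predicted Character vector (or set) of predicted species names.
#' @param truth Character vector of species truly present.
#' @return A `species_evaluation` list: `true_positives`,
#'   `false_positives`, `false_negatives`, `precision`, `recall`, `f1`.
#' @examples
#' score_species_sets(paste0("sp", 1:8), paste0("sp", 1:10))
#' @export
score_species_sets <- function(predicted, truth) {
  p <- unique(normalize_species(predicted))
  t <- unique(normalize_species(truth))
  p <- p[nzchar(p)]
  t <- t[nzchar(t)]
  tp <- length(intersect(p, t))
  fp <- length(setdiff(p, t))
  fn <- length(setdiff(t, p))
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(true_positives = tp, false_positives = fp,
                 false_negatives = fn, precision = precision,
                 recall = recall, f1 = f1),
            class = "species_evaluation")
}

#' @export
print.species_evaluation <- function(x, ...) {
  cat(sprintf("<species_evaluation> TP=%d FP=%d FN=%d\n", x$true_positives,
              x$false_positives, x$false_negatives))
  cat(sprintf("  precision %.3f  recall %.3f  F1 %.3f\n", x$precision,
              x$recall, x$f1))
  invisible(x)
}
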