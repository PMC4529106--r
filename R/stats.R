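## Comparison layer: per-subject effect sizes, cross-subject rank-sum
## tests with FDR correction, cross-subject AROC, and between-measure
## change correlations.

#' Cohen's d with pooled standard deviation
#'
#' `(mean(a) - mean(b)) / sp` with
#' `sp = sqrt(((na-1) sa^2 + (nb-1) sb^2) / (na+nb-2))`. Values with
#' `|d| > 0.8` are conventionally read as a large effect.
#'
#' @param a,b numeric samples of size >= 2 each
#' @return Cohen's d (antisymmetric in its arguments)
#' @export
#' @examples
#' cohensD(c(2, 4), c(0, 2))  # sqrt(2)
cohensD <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each sample needs at least 2 values")
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) stop("pooled standard deviation is zero")
  (mean(a) - mean(b)) / sp
}

#' Area under the ROC curve from two score sets
#'
#' Empirical AROC for discriminating state A from state B using one score
#' per subject: the Mann-Whitney probability `P(a > b) + 0.5 P(a = b)`
#' over all cross pairs, identical to the trapezoid area under the
#' threshold-sweep ROC curve. 1 means a threshold separates the states
#' perfectly with A on top, 0 perfect separation the other way, 0.5 no
#' discriminability.
#'
#' @param a,b per-subject mean scores for the two states
#' @return a number in \\[0, 1\\]; `aroc(a, b) + aroc(b, a) == 1`
#' @export
#' @examples
#' aroc(c(3, 5, 7), c(2, 4, 6))  # 0.7222
aroc <- function(a, b) {
  cmp <- outer(a, b, ">") + 0.5 * outer(a, b, "==")
  mean(cmp)
}

#' Per-subject state comparison with rank-sum tests and FDR correction
#'
#' The full comparison table for a set of measures and state pairs. For
#' each (measure, state pair): per-subject Cohen's d across segments and
#' the triple count of subjects with the left state substantially higher
#' (`d > 0.8`), no substantial difference (`|d| <= 0.8`), or the right
#' state substantially higher; a two-sided Wilcoxon rank-sum test on the
#' per-subject mean scores (exact for small untied samples, normal
#' approximation with tie correction otherwise); and the cross-subject
#' AROC. P-values are Benjamini-Hochberg adjusted across the whole family
#' of (measure x state pair) tests in the call. Stars mark adjusted
#' p < 0.05 (`*`) and < 0.01 (`**`).
#'
#' @param scores data.frame with columns `subject`, `state`, `measure`,
#'   `score`, one row per segment
#' @param statePairs list of length-2 character vectors, or a single
#'   length-2 vector, e.g. `list(c("WR", "LOC"))`
#' @param dThreshold effect-size threshold (default 0.8)
#' @return data.frame with one row per measure and state pair: counts
#'   `nHigherLeft`, `nNoSubstantial`, `nHigherRight`, `p`, `pAdj`, `stars`,
#'   `aroc`
#' @export
compareStates <- function(scores, statePairs, dThreshold = 0.8) {
  stopifnot(all(c("subject", "state", "measure", "score") %in%
                  names(scores)))
  if (!is.list(statePairs)) statePairs <- list(statePairs)
  rows <- list()
  for (m in unique(scores$measure)) {
    sm <- scores[scores$measure == m, ]
    for (pair in statePairs) {
      a <- sm[sm$state == pair[1], ]
      b <- sm[sm$state == pair[2], ]
      subj <- intersect(unique(a$subject), unique(b$subject))
      if (length(subj) < 2L)
        stop("need at least 2 subjects with both states for measure ", m)
      d <- vapply(subj, function(s)
        cohensD(a$score[a$subject == s], b$score[b$subject == s]),
        numeric(1))
      meanA <- vapply(subj, function(s) mean(a$score[a$subject == s]),
                      numeric(1))
      meanB <- vapply(subj, function(s) mean(b$score[b$subject == s]),
                      numeric(1))
      p <- if (all(meanA == meanB)) 1
      else suppressWarnings(stats::wilcox.test(meanA, meanB,
                                               exact = NULL)$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = m, stateLeft = pair[1], stateRight = pair[2],
        nHigherLeft = sum(d > dThreshold),
        nNoSubstantial = sum(abs(d) <= dThreshold),
        nHigherRight = sum(d < -dThreshold),
        p = p, aroc = aroc(meanA, meanB))
    }
  }
  out <- do.call(rbind, rows)
  out$pAdj <- stats::p.adjust(out$p, method = "BH")
  out$stars <- ifelse(out$pAdj < 0.01, "**",
                      ifelse(out$pAdj < 0.05, "*", ""))
  out[, c("measure", "stateLeft", "stateRight", "nHigherLeft",
          "nNoSubstantial", "nHigherRight", "p", "pAdj", "stars", "aroc")]
}

#' Correlations between per-subject state-change ratios of measure pairs
#'
#' For each subject the ratio `measure(stateA) / measure(stateB)` of mean
#' scores is formed (subjects with a zero denominator are excluded with a
#' warning); for each measure pair the Pearson correlation of the two
#' ratio vectors across subjects is computed with a two-tailed p-value.
#' Pairs with p above `alpha` are marked non-significant (and dropped when
#' `filter = TRUE`, the conventional presentation).
#'
#' @param scores data.frame with columns `subject`, `state`, `measure`,
#'   `score` (per segment; per-subject means are taken internally)
#' @param states length-2 character vector `c(stateA, stateB)`: the ratio
#'   is stateA over stateB
#' @param measurePairs list of length-2 character vectors; default all
#'   unordered pairs of measures present
#' @param alpha significance level for the two-tailed test (default 0.05)
#' @param filter drop non-significant pairs? (default FALSE)
#' @return data.frame with columns measureA, measureB, r, p, significant
#' @export
changeCorrelations <- function(scores, states, measurePairs = NULL,
                               alpha = 0.05, filter = FALSE) {
  stopifnot(length(states) == 2L)
  ms <- unique(scores$measure)
  if (is.null(measurePairs)) {
    cmb <- utils::combn(ms, 2L)
    measurePairs <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  }
  subj <- unique(scores$subject)
  ratio <- function(m) {
    vapply(subj, function(s) {
      num <- mean(scores$score[scores$subject == s &
                                 scores$state == states[1] &
                                 scores$measure == m])
      den <- mean(scores$score[scores$subject == s &
                                 scores$state == states[2] &
                                 scores$measure == m])
      if (is.na(num) || is.na(den)) stop(
        "subject ", s, " lacks state data for measure ", m)
      if (den == 0) return(NA_real_)
      num / den
    }, numeric(1))
  }
  ratios <- vapply(ms, ratio, numeric(length(subj)))
  rows <- lapply(measurePairs, function(pair) {
    x <- ratios[, pair[1]]; y <- ratios[, pair[2]]
    keep <- is.finite(x) & is.finite(y)
    if (sum(!keep))
      warning(sum(!keep), " subject(s) excluded (zero denominator) for ",
              pair[1], " vs ", pair[2])
    ct <- stats::cor.test(x[keep], y[keep], method = "pearson",
                          alternative = "two.sided")
    data.frame(measureA = pair[1], measureB = pair[2],
               r = unname(ct$estimate), p = ct$p.value,
               significant = ct$p.value <= alpha)
  })
  out <- do.call(rbind, rows)
  if (filter) out <- out[out$significant, ]
  out
}
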