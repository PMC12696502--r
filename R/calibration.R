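# Clinical calibration: balanced precision-recall benchmarking of a map
# against pathogenic/benign reference sets, kernel-density log likelihood
# ratios of pathogenicity, and ACMG/AMP-style evidence strengths.

#' Join a variant-effect map with a clinical reference set
#'
#' Inner join on the variant name; only reference variants with map scores
#' participate in evaluation, and dropped variants are reported.
#'
#' @param map A `variant_effect_map`.
#' @param refs A `reference_set` (columns `variant`, `label` with values
#'   `positive`/`negative`) or a data frame read by [read_reference_csv()].
#' @param well_measured_only Restrict to well-measured map entries.
#' @return Data frame `variant`, `score`, `label`; attribute `dropped`
#'   lists labelled variants without scores.
#' @export
assemble_labeled_scores <- function(map, refs, well_measured_only = TRUE) {
  if (anyDuplicated(refs$variant))
    stop("reference set assigns multiple labels to one variant")
  m <- map
  if (well_measured_only) m <- m[m$well_measured, ]
  out <- merge(refs[, c("variant", "label")], m[, c("variant", "score")],
               by = "variant")
  dropped <- setdiff(refs$variant, out$variant)
  counts <- table(out$label)
  if (length(counts) < 2 || any(counts < 2))
    stop("need at least 2 scored variants per label; have ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  attr(out, "dropped") <- dropped
  out
}

#' Balanced precision-recall curve
#'
#' With a lower score indicating pathogenicity, every unique score acts as
#' a threshold (variant called positive when `score <= t`). At each
#' threshold the recall (sensitivity), false-positive rate and balanced
#' precision are reported. Balanced precision reweights the positive and
#' negative sets 50/50 by Bayes' rule,
#' `bp = recall * pi / (recall * pi + fpr * (1 - pi))` with prior
#' `pi = 0.5`, i.e. `recall / (recall + fpr)`, making the curve invariant
#' to reference-set imbalance.
#'
#' @param labeled Data frame from [assemble_labeled_scores()].
#' @return A `balanced_pr_curve` data frame: `threshold`, `recall`, `fpr`,
#'   `balanced_precision`, ordered from tightest (lowest) threshold to
#'   loosest, with endpoints at recall 0 (carrying the tightest threshold's
#'   balanced precision) and recall 1.
#' @export
balanced_precision_recall <- function(labeled) {
  stopifnot(all(labeled$label %in% c("positive", "negative")))
  P <- sum(labeled$label == "positive")
  N <- sum(labeled$label == "negative")
  if (P == 0 || N == 0) stop("both labels must be represented")
  ord <- order(labeled$score)
  s <- labeled$score[ord]
  is_pos <- labeled$label[ord] == "positive"
  last_of_run <- !duplicated(s, fromLast = TRUE)  # one point per unique score
  thr <- s[last_of_run]
  if (length(thr) == 1)
    warning("single unique score; curve is degenerate")
  recall <- cumsum(is_pos)[last_of_run] / P
  fpr <- cumsum(!is_pos)[last_of_run] / N
  bp <- ifelse(recall + fpr == 0, NA_real_, recall / (recall + fpr))
  curve <- data.frame(threshold = thr, recall = recall, fpr = fpr,
                      balanced_precision = bp)
  # endpoint handling: extend to recall 0 with the tightest informative
  # threshold's balanced precision, and to recall 1 with the loosest
  first_bp <- bp[which(!is.na(bp))[1]]
  curve$balanced_precision[is.na(curve$balanced_precision)] <- first_bp
  if (curve$recall[1] > 0)
    curve <- rbind(data.frame(threshold = -Inf, recall = 0, fpr = 0,
                              balanced_precision = first_bp), curve)
  if (curve$recall[nrow(curve)] < 1)
    curve <- rbind(curve,
                   data.frame(threshold = Inf, recall = 1, fpr = 1,
                              balanced_precision = 0.5))
  class(curve) <- c("balanced_pr_curve", "data.frame")
  curve
}

#' Area under the balanced precision-recall curve
#'
#' Trapezoidal integral of balanced precision over recall in `[0, 1]`.
#'
#' @param curve A `balanced_pr_curve`.
#' @return Numeric in `[0, 1]`.
#' @export
aubprc <- function(curve) {
  stopifnot(nrow(curve) >= 2)
  r <- curve$recall
  bp <- curve$balanced_precision
  sum(diff(r) * (utils::head(bp, -1) + utils::tail(bp, -1)) / 2)
}

#' Recall at 80% balanced precision
#'
#' The maximum recall among thresholds whose balanced precision is at
#' least `min_precision`; 0 when none qualifies.
#'
#' @param curve A `balanced_pr_curve`.
#' @param min_precision Balanced-precision floor (default 0.80).
#' @return Numeric in `[0, 1]`.
#' @export
r80bp <- function(curve, min_precision = 0.80) {
  ok <- curve$balanced_precision >= min_precision
  if (!any(ok)) return(0)
  max(curve$recall[ok])
}

# Canonical-bandwidth conversion from a Gaussian-kernel bandwidth to the
# Epanechnikov kernel: delta(Epa)/delta(Gauss) = 15^(1/5) / (1/(2*sqrt(pi)))^(1/5).
EPA_GAUSS_BW_RATIO <- 15^(1/5) / (1 / (2 * sqrt(pi)))^(1/5)

epanechnikov <- function(u) ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0)

#' Epanechnikov kernel density estimate with Sheather-Jones bandwidth
#'
#' Density `d(s) = (1/(n h)) * sum K((s - s_i)/h)` with the Epanechnikov
#' kernel `K(u) = 0.75 (1 - u^2)` on `|u| <= 1`. The bandwidth is the
#' Sheather-Jones solve-the-equation bandwidth for a Gaussian kernel
#' ([stats::bw.SJ()]) rescaled by the canonical-bandwidth ratio of the two
#' kernels (about 2.214).
#'
#' @param scores Numeric vector (at least 5 points, with spread, unless an
#'   explicit `bandwidth` is given).
#' @param bandwidth Optional explicit bandwidth.
#' @return An object of class `epa_kde`: a function evaluating the density
#'   at arbitrary points, with attributes `bandwidth`, `n` and `data`.
#' @export
kde_density <- function(scores, bandwidth = NULL) {
  scores <- scores[is.finite(scores)]
  n <- length(scores)
  if (is.null(bandwidth)) {
    if (n < 5)
      stop("fewer than 5 points: supply an explicit bandwidth")
    if (stats::sd(scores) == 0)
      stop("zero variance in scores: supply an explicit bandwidth")
    h_gauss <- tryCatch(stats::bw.SJ(scores, method = "ste"),
                        error = function(e) stats::bw.nrd0(scores))
    bandwidth <- h_gauss * EPA_GAUSS_BW_RATIO
  }
  stopifnot(bandwidth > 0)
  f <- function(s) {
    u <- outer(scores, s, function(a, b) (b - a) / bandwidth)
    colSums(epanechnikov(u)) / (n * bandwidth)
  }
  structure(f, bandwidth = bandwidth, n = n, data = scores,
            class = c("epa_kde", "function"))
}

llr_at <- function(s, d_pos, d_neg, floor_pos, floor_neg) {
  log10(pmax(d_pos(s), floor_pos) / pmax(d_neg(s), floor_neg))
}

#' Log likelihood ratio of pathogenicity for map scores
#'
#' Kernel density functions are estimated separately for the positive
#' (pathogenic) and negative (benign) reference score sets and the log10
#' density ratio is evaluated at every map score. Densities are floored at
#' `1/(10 * n * range)` (n = reference-set size, range = span of the
#' combined reference scores) so that scores outside one set's support give
#' finite, flagged values. Percentile bootstrap confidence intervals come
#' from resampling each reference set with replacement.
#'
#' @param map A `variant_effect_map`.
#' @param refs Reference set (`variant`, `label`).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @param prior,odds_pvst Calibration metadata passed to
#'   [assign_evidence()]: prior probability of pathogenicity and the
#'   combined odds of a "very strong" pathogenic classification.
#' @return An `llr_table` data frame: `variant`, `score`, `llr`, `ci_lo`,
#'   `ci_hi`, `floored`, `evidence`; attributes `prior`, `odds_pvst`,
#'   `bandwidths`, `n_pos`, `n_neg`.
#' @export
compute_llr <- function(map, refs, n_boot = 1000, seed = 1L, conf = 0.95,
                        prior = 0.1, odds_pvst = 350) {
  labeled <- assemble_labeled_scores(map, refs)
  pos <- labeled$score[labeled$label == "positive"]
  neg <- labeled$score[labeled$label == "negative"]
  if (length(pos) < 5 || length(neg) < 5)
    stop("need at least 5 scored variants per label for density estimation")
  rng <- diff(range(c(pos, neg)))
  floor_pos <- 1 / (10 * length(pos) * rng)
  floor_neg <- 1 / (10 * length(neg) * rng)
  d_pos <- kde_density(pos)
  d_neg <- kde_density(neg)
  eval_at <- map$score
  llr <- llr_at(eval_at, d_pos, d_neg, floor_pos, floor_neg)
  floored <- d_pos(eval_at) < floor_pos | d_neg(eval_at) < floor_neg

  ci_lo <- ci_hi <- rep(NA_real_, length(eval_at))
  if (n_boot > 0) {
    set.seed(seed)
    boots <- matrix(NA_real_, nrow = n_boot, ncol = length(eval_at))
    h_pos <- attr(d_pos, "bandwidth")
    h_neg <- attr(d_neg, "bandwidth")
    for (b in seq_len(n_boot)) {
      bp <- sample(pos, replace = TRUE)
      bn <- sample(neg, replace = TRUE)
      db_pos <- tryCatch(kde_density(bp), error = function(e)
        kde_density(bp, bandwidth = h_pos))
      db_neg <- tryCatch(kde_density(bn), error = function(e)
        kde_density(bn, bandwidth = h_neg))
      boots[b, ] <- llr_at(eval_at, db_pos, db_neg, floor_pos, floor_neg)
    }
    alpha <- (1 - conf) / 2
    ci <- apply(boots, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE)
    ci_lo <- ci[1, ]
    ci_hi <- ci[2, ]
  }
  out <- data.frame(
    variant = map$variant, score = map$score, llr = llr,
    ci_lo = ci_lo, ci_hi = ci_hi, floored = floored,
    evidence = assign_evidence(llr, odds_pvst = odds_pvst),
    stringsAsFactors = FALSE
  )
  structure(out, prior = prior, odds_pvst = odds_pvst,
            bandwidths = c(positive = attr(d_pos, "bandwidth"),
                           negative = attr(d_neg, "bandwidth")),
            n_pos = length(pos), n_neg = length(neg),
            class = c("llr_table", "data.frame"))
}

EVIDENCE_LEVELS <- c("BS3_strong", "BS3_moderate", "BS3_supporting",
                     "indeterminate",
                     "PS3_supporting", "PS3_moderate", "PS3_strong",
                     "PS3_very_strong")

#' ACMG/AMP-style evidence strength from a log likelihood ratio
#'
#' Thresholds follow the Tavtigian combined-odds ladder: with
#' `C = log10(odds_pvst)` (default odds 350), pathogenic evidence is
#' supporting / moderate / strong / very strong at `C/8`, `C/4`, `C/2`,
#' `C`, and benign evidence mirrors the first three with negative sign.
#' Values between the two supporting thresholds are indeterminate.
#'
#' @param llr Numeric vector of log10 likelihood ratios of pathogenicity.
#' @param odds_pvst Combined odds of pathogenicity for "very strong"
#'   evidence (default 350).
#' @return Ordered factor over the evidence ladder.
#' @export
assign_evidence <- function(llr, odds_pvst = 350) {
  if (any(!is.finite(llr))) stop("LLR values must be finite")
  C <- log10(odds_pvst)
  cuts <- c(-Inf, -C / 2, -C / 4, -C / 8, C / 8, C / 4, C / 2, C, Inf)
  factor(EVIDENCE_LEVELS[findInterval(llr, cuts, left.open = TRUE)],
         levels = EVIDENCE_LEVELS, ordered = TRUE)
}
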