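# Scoring pipeline: counts -> frequencies -> filters -> error-corrected
# enrichment -> rescaling to nonsense/synonymous anchors -> error
# regularization -> inverse-variance replicate combination.

MILLION <- 1e6

#' Convert read counts to frequencies (reads per million)
#'
#' @param counts A `counts_bundle` (columns `tile`, `condition`,
#'   `replicate`, `variant`, `count`, `depth`).
#' @return The same table with an added `freq` column (ppm).
#' @export
compute_frequencies <- function(counts) {
  bad <- counts$depth <= 0
  if (any(bad)) {
    b <- counts[which(bad)[1], ]
    stop(sprintf("zero depth in (tile %s, condition %s, replicate %s)",
                 b$tile, b$condition, b$replicate))
  }
  counts$freq <- counts$count / counts$depth * MILLION
  counts
}

# Reshape a frequency table into one row per (variant, replicate) with
# pre/post frequencies and the pooled wild-type-control frequency.
replicate_table <- function(freqs) {
  pre <- freqs[freqs$condition == "pre", ]
  post <- freqs[freqs$condition == "post", ]
  wt <- freqs[freqs$condition == "wt_control", ]
  if (nrow(wt) == 0) stop("empty wild-type control condition")
  # wild-type control frequency: mean over control replicates per variant
  agg <- stats::aggregate(cbind(freq, depth) ~ variant, data = wt, FUN = mean)
  n_wt <- stats::aggregate(freq ~ variant, data = wt, FUN = length)
  wt_tab <- data.frame(variant = agg$variant, f_wt = agg$freq,
                       wt_depth_total = agg$depth * n_wt$freq,
                       stringsAsFactors = FALSE)
  key <- c("variant", "replicate")
  m <- merge(
    pre[, c("tile", "variant", "replicate", "count", "depth", "freq")],
    post[, c("variant", "replicate", "count", "depth", "freq")],
    by = key, suffixes = c("_pre", "_post")
  )
  m <- merge(m, wt_tab, by = "variant", all.x = TRUE)
  m$f_wt[is.na(m$f_wt)] <- 0
  m$wt_depth_total[is.na(m$wt_depth_total)] <- sum(unique(wt$depth))
  names(m)[names(m) == "freq_pre"] <- "f_pre"
  names(m)[names(m) == "freq_post"] <- "f_post"
  m
}

#' Apply read-count and wild-type-background filters
#'
#' A variant is excluded within a replicate if its pre-selection read count
#' is below `min_count` or its pre-selection frequency does not exceed the
#' `wt_percentile`-th percentile of wild-type-control frequencies (the
#' base-call error background), stratified per tile by default since error
#' rates are tile specific. Variants are additionally flagged
#' `well_measured` when the pre-selection frequency reaches `min_pre_ppm`
#' reads per million.
#'
#' @param freqs Frequency table from [compute_frequencies()].
#' @param min_count Minimum pre-selection read count (default 10).
#' @param wt_percentile Percentile of the wild-type-control frequency
#'   distribution a variant must exceed (default 90).
#' @param min_pre_ppm Well-measured threshold in ppm (default 10).
#' @param wt_strata `"tile"` (default) computes the percentile within each
#'   tile; `"pooled"` uses all wild-type-control frequencies together.
#' @return One row per (variant, replicate): pre/post/wt frequencies,
#'   counts, depths, `excluded` and `well_measured` flags.
#' @export
apply_filters <- function(freqs, min_count = 10, wt_percentile = 90,
                          min_pre_ppm = 10, wt_strata = c("tile", "pooled")) {
  wt_strata <- match.arg(wt_strata)
  rt <- replicate_table(freqs)
  wt <- freqs[freqs$condition == "wt_control", ]
  if (wt_strata == "tile") {
    thr <- tapply(wt$freq, wt$tile, stats::quantile,
                  probs = wt_percentile / 100, names = FALSE)
    rt$wt_threshold <- as.numeric(thr[as.character(rt$tile)])
  } else {
    rt$wt_threshold <- stats::quantile(wt$freq, wt_percentile / 100, names = FALSE)
  }
  rt$wt_threshold[is.na(rt$wt_threshold)] <- 0
  rt$excluded <- rt$count_pre < min_count |
    (rt$wt_threshold > 0 & rt$f_pre <= rt$wt_threshold)
  rt$well_measured <- !rt$excluded & rt$f_pre >= min_pre_ppm
  rt
}

#' Error-corrected enrichment ratios with delta-method errors
#'
#' Subtracts the wild-type-control frequency from both the pre- and
#' post-selection frequencies, forms the enrichment ratio
#' `phi = f'_post / f'_pre`, and reports `log2(phi)` with a delta-method
#' standard error derived from Poisson count variances
#' (`Var(f) = f * 1e6 / depth` on the ppm scale) propagated through the
#' subtraction. A corrected post-selection frequency at or below zero is
#' floored at half a read (depletion to zero is informative); a corrected
#' pre-selection frequency at or below zero makes the variant unmeasurable
#' in that replicate.
#'
#' @param rt Replicate table from [apply_filters()].
#' @return `rt` with columns `f_pre_c`, `f_post_c`, `log_phi`, `se_log_phi`,
#'   `floored`, `unmeasurable` added. Excluded variants are unmeasurable.
#' @export
enrichment_scores <- function(rt) {
  f_pre_c <- rt$f_pre - rt$f_wt
  f_post_c <- rt$f_post - rt$f_wt
  floor_post <- 0.5 / rt$depth_post * MILLION
  floored <- f_post_c <= 0
  f_post_c[floored] <- floor_post[floored]
  unmeasurable <- rt$excluded | f_pre_c <= 0

  var_pre <- rt$f_pre * MILLION / rt$depth_pre + rt$f_wt * MILLION / rt$wt_depth_total
  var_post <- rt$f_post * MILLION / rt$depth_post + rt$f_wt * MILLION / rt$wt_depth_total
  log_phi <- log2(f_post_c / f_pre_c)
  se <- (1 / log(2)) * sqrt(var_post / f_post_c^2 + var_pre / f_pre_c^2)

  rt$f_pre_c <- f_pre_c
  rt$f_post_c <- f_post_c
  rt$log_phi <- ifelse(unmeasurable, NA_real_, log_phi)
  rt$se_log_phi <- ifelse(unmeasurable, NA_real_, se)
  rt$floored <- floored & !unmeasurable
  rt$unmeasurable <- unmeasurable
  rt
}

#' Rescale log-enrichments to nonsense/synonymous anchors
#'
#' Within each replicate, scores are rescaled so that the median of
#' nonsense variants is exactly 0 and the median of synonymous variants is
#' exactly 1:
#' `s = (log_phi - median_nonsense) / (median_synonymous - median_nonsense)`.
#' Standard errors are scaled by the same positive factor. Stop gains at the
#' final codon are not used as anchors when the table carries a
#' `terminal_stop` flag.
#'
#' @param enr Enrichment table from [enrichment_scores()], carrying a
#'   `klass` column (merge with the variant space or [parse_variant()]
#'   output beforehand; [score_pipeline()] does this).
#' @param min_anchor Minimum number of measurable nonsense and synonymous
#'   variants required per replicate (default 10).
#' @return `enr` with columns `score` and `se` added; attribute `anchors`
#'   records the per-replicate anchor medians.
#' @export
rescale_scores <- function(enr, min_anchor = 10) {
  if (is.null(enr$klass)) stop("enrichment table must carry a 'klass' column")
  usable_anchor <- !enr$unmeasurable &
    (if (is.null(enr$terminal_stop)) TRUE else !enr$terminal_stop)
  enr$score <- NA_real_
  enr$se <- NA_real_
  anchors <- list()
  for (r in sort(unique(enr$replicate))) {
    in_rep <- enr$replicate == r
    non <- enr$log_phi[in_rep & usable_anchor & enr$klass == "nonsense"]
    syn <- enr$log_phi[in_rep & usable_anchor & enr$klass == "synonymous"]
    if (length(non) < min_anchor || length(syn) < min_anchor)
      stop(sprintf("replicate %s has fewer than %d measurable nonsense or synonymous anchors",
                   r, min_anchor))
    med_non <- stats::median(non)
    med_syn <- stats::median(syn)
    delta <- med_syn - med_non
    if (delta <= 0)
      stop("no selection separation: synonymous median does not exceed nonsense median")
    enr$score[in_rep] <- (enr$log_phi[in_rep] - med_non) / delta
    enr$se[in_rep] <- enr$se_log_phi[in_rep] / delta
    anchors[[as.character(r)]] <- c(nonsense = med_non, synonymous = med_syn)
  }
  attr(enr, "anchors") <- anchors
  enr
}

# Least-absolute-deviations line fit via iteratively reweighted least
# squares; robust trend of log(se) against log10 pre-selection frequency.
lad_fit <- function(x, y, n_iter = 50, tol = 1e-10) {
  w <- rep(1, length(x))
  beta <- stats::coef(stats::lm(y ~ x))
  for (i in seq_len(n_iter)) {
    fit <- stats::lm(y ~ x, weights = w)
    new_beta <- stats::coef(fit)
    if (max(abs(new_beta - beta)) < tol) break
    beta <- new_beta
    r <- abs(stats::residuals(fit))
    w <- 1 / pmax(r, 1e-8)
  }
  beta
}

#' Regularize replicate standard errors against the frequency trend
#'
#' Fits a robust (least-absolute-deviations) linear trend of
#' `log(se)` against `log10(f_pre)` across variants and shrinks each
#' variant's error estimate toward the trend:
#' `var_reg = (m * se_model^2 + df * se_emp^2) / (m + df)` with prior
#' degrees of freedom `m`; the degrees of freedom are updated to `m + df`.
#' This removes spuriously small error estimates arising from chance
#' agreement at low read counts.
#'
#' @param rs Rescaled replicate table from [rescale_scores()].
#' @param prior_df Prior degrees of freedom `m` (default 2).
#' @param df_emp Degrees of freedom credited to each replicate's own
#'   estimate (default 1, one biological observation).
#' @param min_fit Minimum variants required for the trend fit; below this
#'   the table is returned unregularized with a warning.
#' @return `rs` with `se` replaced by the regularized value, plus columns
#'   `se_emp` (the input value) and `df`.
#' @export
regularize_errors <- function(rs, prior_df = 2, df_emp = 1, min_fit = 20) {
  ok <- !rs$unmeasurable & is.finite(rs$se) & rs$se > 0 & rs$f_pre_c > 0
  rs$se_emp <- rs$se
  if (sum(ok) < min_fit) {
    warning("too few variants for error-trend fit; standard errors left unregularized")
    rs$df <- ifelse(rs$unmeasurable, NA_real_, df_emp)
    return(rs)
  }
  beta <- lad_fit(log10(rs$f_pre_c[ok]), log(rs$se[ok]))
  se_model <- exp(beta[1] + beta[2] * log10(pmax(rs$f_pre_c, .Machine$double.eps)))
  var_reg <- (prior_df * se_model^2 + df_emp * rs$se_emp^2) / (prior_df + df_emp)
  rs$se <- ifelse(rs$unmeasurable, NA_real_, sqrt(var_reg))
  rs$df <- ifelse(rs$unmeasurable, NA_real_, prior_df + df_emp)
  attr(rs, "error_trend") <- c(intercept = unname(beta[1]), slope = unname(beta[2]))
  rs
}

#' Combine replicate scores into a variant-effect map
#'
#' Replicate scores are averaged with inverse-variance weights
#' (`w = 1/se^2`), the combined standard error is `sqrt(1/sum(w))`, and
#' combined degrees of freedom follow Welch-Satterthwaite. Variants with a
#' single measurable replicate pass their standard error and degrees of
#' freedom through unchanged; variants with none are absent from the map.
#'
#' @param rs Replicate table from [regularize_errors()] (or
#'   [rescale_scores()]; degrees of freedom then default to 1).
#' @return A `variant_effect_map` data frame: `variant`, `klass`, `score`,
#'   `se`, `df`, `n_replicates`, `well_measured` (true when any
#'   contributing replicate was well measured).
#' @export
combine_replicates <- function(rs) {
  if (is.null(rs$df)) rs$df <- 1
  keep <- !rs$unmeasurable & is.finite(rs$score) & is.finite(rs$se) & rs$se > 0
  rs <- rs[keep, ]
  if (nrow(rs) == 0) stop("no measurable replicate scores to combine")
  split_idx <- split(seq_len(nrow(rs)), rs$variant)
  out <- lapply(names(split_idx), function(v) {
    i <- split_idx[[v]]
    s <- rs$score[i]; se <- rs$se[i]; df <- rs$df[i]
    if (length(i) == 1) {
      comb <- c(s, se, df)
    } else {
      w <- 1 / se^2
      sw <- sum(w)
      score <- sum(w * s) / sw
      vcomb <- 1 / sw                      # = sum((w/sw)^2 * se^2)
      terms <- (w / sw)^2 * se^2
      df_ws <- vcomb^2 / sum(terms^2 / df)  # Welch-Satterthwaite
      comb <- c(score, sqrt(vcomb), df_ws)
    }
    data.frame(variant = v, klass = rs$klass[i][1],
               score = comb[1], se = comb[2], df = comb[3],
               n_replicates = length(i),
               well_measured = any(rs$well_measured[i]),
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, out)
  rownames(map) <- NULL
  class(map) <- c("variant_effect_map", "data.frame")
  map
}

#' Run the full scoring pipeline on a counts bundle
#'
#' Deterministic composition of [compute_frequencies()], [apply_filters()],
#' [enrichment_scores()], [rescale_scores()], [regularize_errors()] and
#' [combine_replicates()]. Variant classes are derived from the variant
#' notation itself via [parse_variant()] (or taken from `space` when
#' supplied, which also provides the terminal-stop anchor exclusion).
#'
#' @param counts A `counts_bundle`.
#' @param space Optional variant space from [enumerate_variant_space()].
#' @param min_count,wt_percentile,min_pre_ppm,wt_strata See [apply_filters()].
#' @param min_anchor See [rescale_scores()].
#' @param prior_df,min_fit See [regularize_errors()].
#' @param regularize Set `FALSE` to skip error regularization.
#' @return A `variant_effect_map`; attribute `stage_log` records variants
#'   in/out at each stage, attribute `anchors` the per-replicate anchor
#'   medians.
#' @export
score_pipeline <- function(counts, space = NULL,
                           min_count = 10, wt_percentile = 90,
                           min_pre_ppm = 10, wt_strata = "tile",
                           min_anchor = 10, prior_df = 2, min_fit = 20,
                           regularize = TRUE) {
  freqs <- compute_frequencies(counts)
  rt <- apply_filters(freqs, min_count = min_count,
                      wt_percentile = wt_percentile,
                      min_pre_ppm = min_pre_ppm, wt_strata = wt_strata)
  if (is.null(space)) {
    ann <- parse_variant(rt$variant)
    rt$klass <- ann$klass
  } else {
    idx <- match(rt$variant, space$variant)
    if (anyNA(idx)) stop("counts contain variants absent from the variant space")
    rt$klass <- space$klass[idx]
    rt$terminal_stop <- space$terminal_stop[idx]
  }
  enr <- enrichment_scores(rt)
  rsc <- rescale_scores(enr, min_anchor = min_anchor)
  if (regularize) rsc <- regularize_errors(rsc, prior_df = prior_df, min_fit = min_fit)
  map <- combine_replicates(rsc)
  attr(map, "anchors") <- attr(rsc, "anchors")
  attr(map, "stage_log") <- data.frame(
    stage = c("input", "post_filter", "measurable", "mapped"),
    n = c(length(unique(rt$variant)),
          length(unique(rt$variant[!rt$excluded])),
          length(unique(enr$variant[!enr$unmeasurable])),
          nrow(map))
  )
  map
}
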