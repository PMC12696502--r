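# Biological analyses of one or two variant-effect maps: joint quadrant
# classification, positional and substitution profiles, annotation-group
# contrasts, stability (ddG) concordance, population depletion odds ratios
# and genotype-phenotype correlation.

QUADRANT_LEVELS <- c("both_deleterious", "both_neutral",
                     "activity_only", "abundance_only")

variant_positions <- function(variant) parse_variant(variant)$position

#' Classify variants into activity/abundance quadrants
#'
#' Variants well measured in both maps are assigned to one of four
#' quadrants by thresholding each map's score at `threshold`
#' (strictly below the threshold counts as deleterious, the midpoint
#' between the nonsense and synonymous anchor medians by default):
#' `both_deleterious` (blue), `both_neutral` (white), `activity_only`
#' (purple, deleterious only in the activity map) and `abundance_only`
#' (teal).
#'
#' @param activity,abundance `variant_effect_map` objects sharing a variant
#'   namespace.
#' @param threshold Deleteriousness cutoff (default 0.5).
#' @param missense_only Restrict to missense variants (default TRUE).
#' @return A `quadrant_table` data frame (`variant`, `position`,
#'   `activity_score`, `abundance_score`, `quadrant`); attribute `summary`
#'   holds counts and percentages per quadrant.
#' @export
classify_quadrants <- function(activity, abundance, threshold = 0.5,
                               missense_only = TRUE) {
  a <- activity[activity$well_measured, c("variant", "klass", "score")]
  b <- abundance[abundance$well_measured, c("variant", "score")]
  m <- merge(a, b, by = "variant", suffixes = c("_activity", "_abundance"))
  if (missense_only) m <- m[m$klass == "missense", ]
  if (nrow(m) == 0) stop("no variants measured in both maps")
  del_act <- m$score_activity < threshold
  del_abn <- m$score_abundance < threshold
  quadrant <- ifelse(del_act & del_abn, "both_deleterious",
              ifelse(!del_act & !del_abn, "both_neutral",
              ifelse(del_act, "activity_only", "abundance_only")))
  out <- data.frame(
    variant = m$variant,
    position = variant_positions(m$variant),
    activity_score = m$score_activity,
    abundance_score = m$score_abundance,
    quadrant = factor(quadrant, levels = QUADRANT_LEVELS),
    stringsAsFactors = FALSE
  )
  counts <- table(out$quadrant)
  attr(out, "summary") <- data.frame(
    quadrant = names(counts),
    n = as.integer(counts),
    percent = 100 * as.integer(counts) / nrow(out)
  )
  class(out) <- c("quadrant_table", "data.frame")
  out
}

#' Dominant quadrant per residue position
#'
#' The label with a strict plurality among substitutions at the position;
#' ties yield `NA` (painted gray on a structure).
#'
#' @param q A `quadrant_table` from [classify_quadrants()].
#' @return Data frame `position`, `dominant` (factor, `NA` on ties), `n`.
#' @export
dominant_quadrant_by_position <- function(q) {
  pick <- function(labels) {
    tab <- table(labels)
    top <- max(tab)
    winners <- names(tab)[tab == top]
    if (length(winners) == 1) winners else NA_character_
  }
  sp <- split(as.character(q$quadrant), q$position)
  data.frame(
    position = as.integer(names(sp)),
    dominant = factor(vapply(sp, pick, ""), levels = QUADRANT_LEVELS),
    n = vapply(sp, length, 1L),
    row.names = NULL
  )
}

#' Positional aggregate profile of a map
#'
#' Aggregates measured missense scores at each residue position with the
#' median (structural analyses) or mean (genotype-phenotype comparisons).
#' Positions with no measured missense substitution are absent.
#'
#' @param map A `variant_effect_map`.
#' @param stat `"median"` or `"mean"`.
#' @param well_measured_only Use only well-measured variants (default TRUE).
#' @return Data frame `position`, `value`, `n`.
#' @export
positional_profile <- function(map, stat = c("median", "mean"),
                               well_measured_only = TRUE) {
  stat <- match.arg(stat)
  f <- if (stat == "median") stats::median else mean
  m <- map[map$klass == "missense", ]
  if (well_measured_only) m <- m[m$well_measured, ]
  if (nrow(m) == 0) stop("map has no measured missense variants")
  pos <- variant_positions(m$variant)
  sp <- split(m$score, pos)
  data.frame(
    position = as.integer(names(sp)),
    value = vapply(sp, f, 0),
    n = vapply(sp, length, 1L),
    row.names = NULL
  )
}

#' Substitution ("to"/"from" amino acid) profiles of a map
#'
#' For each amino acid, the median score over all missense variants
#' substituting *to* it, and over all variants substituting *from* it.
#' Amino acids absent from the reference sequence have an undefined
#' "from" entry (`NA`, flagged by `n_from = 0`), mirroring the reduced
#' power of from-residue analyses.
#'
#' @param map A `variant_effect_map`.
#' @param well_measured_only Use only well-measured variants (default TRUE).
#' @return Data frame with one row per amino acid: `aa`, `to_median`,
#'   `n_to`, `from_median`, `n_from`.
#' @export
substitution_profile <- function(map, well_measured_only = TRUE) {
  m <- map[map$klass == "missense", ]
  if (well_measured_only) m <- m[m$well_measured, ]
  if (nrow(m) == 0) stop("map has no measured missense variants")
  pv <- parse_variant(m$variant)
  aas <- unname(AA3[setdiff(names(AA3), "Ter")])
  med_or_na <- function(x) if (length(x)) stats::median(x) else NA_real_
  to_groups <- split(m$score, factor(pv$alt_aa, levels = aas))
  from_groups <- split(m$score, factor(pv$ref_aa, levels = aas))
  data.frame(
    aa = aas,
    to_median = vapply(to_groups, med_or_na, 0),
    n_to = vapply(to_groups, length, 1L),
    from_median = vapply(from_groups, med_or_na, 0),
    n_from = vapply(from_groups, length, 1L),
    row.names = NULL
  )
}

#' Rank correlation of a substitution profile with an external vector
#'
#' @param profile Output of [substitution_profile()].
#' @param external Named numeric vector (names are one-letter amino-acid
#'   codes) to correlate with.
#' @param which `"to"` or `"from"` profile.
#' @param method Correlation method (default Spearman).
#' @return `stats::cor.test` result.
#' @export
profile_correlation <- function(profile, external, which = c("to", "from"),
                                method = "spearman") {
  which <- match.arg(which)
  col <- paste0(which, "_median")
  x <- profile[[col]]
  names(x) <- profile$aa
  shared <- intersect(names(x)[!is.na(x)], names(external))
  if (length(shared) < 3) stop("fewer than 3 shared amino acids")
  stats::cor.test(x[shared], external[shared], method = method, exact = FALSE)
}

#' Read a per-position structural annotation table
#'
#' Expects TSV with a `position` column, optional logical feature columns
#' (e.g. `metal_binding`, `homodimer_interface`, `ccs_interface`,
#' `electrostatic_loop`) and optional `rel_solvent_exposure` (percent),
#' from which a burial class is derived: exposed above 35%, buried below
#' 20%, intermediate otherwise.
#'
#' @param path TSV path.
#' @param n_positions Optional protein length for validation.
#' @return Data frame with a `burial` factor added when exposure is present.
#' @export
read_annotation_table <- function(path, n_positions = NULL) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(ann$position)) stop("annotation table must have a 'position' column")
  if (!is.null(n_positions) && any(ann$position < 1 | ann$position > n_positions))
    stop("annotation positions fall outside the protein (length ", n_positions, ")")
  if (!is.null(ann$rel_solvent_exposure)) ann$burial <- burial_class(ann$rel_solvent_exposure)
  ann
}

#' Burial class from relative solvent exposure
#'
#' @param exposure Relative solvent exposure in percent.
#' @param exposed_above,buried_below Thresholds (35 and 20 by default).
#' @return Factor with levels `buried`, `intermediate`, `exposed`.
#' @export
burial_class <- function(exposure, exposed_above = 35, buried_below = 20) {
  factor(ifelse(exposure > exposed_above, "exposed",
         ifelse(exposure < buried_below, "buried", "intermediate")),
         levels = c("buried", "intermediate", "exposed"))
}

#' Compare positional score distributions between annotation groups
#'
#' For every pair of position groups, reports the difference of medians and
#' a two-sided Mann-Whitney U (Wilcoxon rank-sum) p value — exact for small
#' samples without ties, normal approximation otherwise — with
#' Benjamini-Hochberg adjustment across the tested pairs.
#'
#' @param profile Positional profile from [positional_profile()].
#' @param groups Named list of integer position vectors.
#' @param allow_overlap Permit groups sharing positions (default FALSE).
#' @return Data frame: `group1`, `group2`, `n1`, `n2`, `delta_median`
#'   (group1 - group2), `p`, `p_adj`.
#' @export
compare_feature_groups <- function(profile, groups, allow_overlap = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2, !is.null(names(groups)))
  vals <- lapply(groups, function(g) profile$value[profile$position %in% g])
  ns <- vapply(vals, length, 1L)
  if (any(ns < 2)) stop("each group needs at least 2 scored positions")
  if (!allow_overlap) {
    pairs0 <- utils::combn(names(groups), 2, simplify = FALSE)
    for (p in pairs0) {
      if (length(intersect(groups[[p[1]]], groups[[p[2]]])) > 0)
        stop(sprintf("groups '%s' and '%s' overlap", p[1], p[2]))
    }
  }
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  res <- lapply(pairs, function(p) {
    x <- vals[[p[1]]]; y <- vals[[p[2]]]
    identical_groups <- length(x) == length(y) && all(sort(x) == sort(y))
    pval <- if (identical_groups) 1 else
      stats::wilcox.test(x, y, alternative = "two.sided")$p.value
    data.frame(group1 = p[1], group2 = p[2],
               n1 = length(x), n2 = length(y),
               delta_median = stats::median(x) - stats::median(y),
               p = pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Read a per-variant predicted stability (ddG) table
#'
#' TSV/CSV with columns `variant` and `ddg` (kcal/mol; negative =
#' destabilizing). A stability class is derived: `stabilizing_or_neutral`
#' when ddG > -0.1, `destabilizing` when ddG < -0.5, else `intermediate`.
#'
#' @param path File path (tab- or comma-separated by extension).
#' @return Data frame with `stability` factor added.
#' @export
read_ddg_table <- function(path) {
  ddg <- if (grepl("\\.csv$", path)) utils::read.csv(path, stringsAsFactors = FALSE)
         else utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(ddg$variant) || is.null(ddg$ddg))
    stop("ddG table must have 'variant' and 'ddg' columns")
  ddg$stability <- stability_class(ddg$ddg)
  ddg
}

#' Stability class from predicted ddG
#' @param ddg Predicted ddG (negative = destabilizing).
#' @return Factor `stabilizing_or_neutral` / `intermediate` / `destabilizing`.
#' @export
stability_class <- function(ddg) {
  factor(ifelse(ddg > -0.1, "stabilizing_or_neutral",
         ifelse(ddg < -0.5, "destabilizing", "intermediate")),
         levels = c("destabilizing", "intermediate", "stabilizing_or_neutral"))
}

#' Concordance between map scores and predicted stability
#'
#' Moving-window comparison of mean map score against mean predicted ddG
#' across protein positions, plus identification of "stable-but-inactive"
#' variants: functionally deleterious (score below `threshold`) yet
#' stabilizing-or-neutral (ddG > -0.1), whose impact cannot be explained by
#' a loss of stability.
#'
#' @param map A `variant_effect_map`.
#' @param ddg Data frame with `variant` and `ddg` columns.
#' @param window Window size in positions (default 10, step 1).
#' @param threshold Deleteriousness cutoff (default 0.5).
#' @return List with `windows` (`start`, `end`, `mean_score`, `mean_ddg`,
#'   `n`), `stable_but_inactive` (character vector of variants), and
#'   `correlation` (Spearman rank correlation over shared variants).
#' @export
ddg_concordance <- function(map, ddg, window = 10, threshold = 0.5) {
  m <- merge(map[map$well_measured & map$klass == "missense",
                 c("variant", "score")],
             ddg[, c("variant", "ddg")], by = "variant")
  if (nrow(m) == 0) stop("no shared variants between map and ddG table")
  m$position <- variant_positions(m$variant)
  n_pos <- max(m$position)
  if (window > n_pos) stop("window larger than the protein")
  starts <- seq_len(n_pos - window + 1L)
  win <- lapply(starts, function(s) {
    in_w <- m$position >= s & m$position < s + window
    data.frame(start = s, end = s + window - 1L,
               mean_score = if (any(in_w)) mean(m$score[in_w]) else NA_real_,
               mean_ddg = if (any(in_w)) mean(m$ddg[in_w]) else NA_real_,
               n = sum(in_w))
  })
  sbi <- m$variant[m$score < threshold & m$ddg > -0.1]
  list(
    windows = do.call(rbind, win),
    stable_but_inactive = sbi,
    correlation = stats::cor(m$score, m$ddg, method = "spearman")
  )
}

#' Depletion odds ratio of damaging variants in a population database
#'
#' Builds the 2x2 table [damaging & present, damaging & absent;
#' neutral & present, neutral & absent], reports the natural-log odds
#' ratio (Haldane-Anscombe 0.5 correction when any cell is zero) and the
#' two-sided Fisher exact p value.
#'
#' @param map A `variant_effect_map`.
#' @param present Character vector of variants observed in the population.
#' @param threshold Damaging cutoff on the score (default 0.5).
#' @return List: `table`, `odds_ratio`, `log_odds_ratio`, `p`.
#' @export
population_depletion_odds <- function(map, present, threshold = 0.5) {
  m <- map[map$well_measured & map$klass == "missense", ]
  if (nrow(m) == 0) stop("empty map")
  damaging <- m$score < threshold
  in_pop <- m$variant %in% present
  tab <- matrix(c(sum(damaging & in_pop), sum(damaging & !in_pop),
                  sum(!damaging & in_pop), sum(!damaging & !in_pop)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("damaging", "neutral"),
                                c("present", "absent")))
  if (sum(tab) == 0) stop("empty contingency table")
  t2 <- tab
  if (any(t2 == 0)) t2 <- t2 + 0.5  # Haldane-Anscombe
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(table = tab, odds_ratio = or, log_odds_ratio = log(or), p = p)
}

#' Sample-size-weighted aggregation of multi-study phenotype values
#'
#' @param values Numeric study values for one variant and phenotype.
#' @param weights Sample sizes (equal weights when NULL).
#' @return Weighted mean.
#' @export
weighted_phenotype <- function(values, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(values))
  stopifnot(length(values) == length(weights), all(weights >= 0))
  sum(values * weights) / sum(weights)
}

#' Correlate positional map scores with literature phenotypes
#'
#' Phenotype tables carry one row per (variant, study); per-variant values
#' are aggregated by sample-size-weighted average, matched to the
#' positional mean score profile of the map, and correlated. P values are
#' Benjamini-Hochberg adjusted across phenotypes.
#'
#' @param profile Positional profile from
#'   `positional_profile(map, stat = "mean")`.
#' @param pheno Data frame with columns `variant`, `phenotype`, `value` and
#'   optional `n` (study sample size).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param min_shared Minimum shared positions per phenotype (default 3).
#' @return Data frame: `phenotype`, `n`, `r`, `p`, `p_adj`. Phenotypes with
#'   too little overlap are skipped with a warning.
#' @export
phenotype_association <- function(profile, pheno, method = c("spearman", "pearson"),
                                  min_shared = 3) {
  method <- match.arg(method)
  stopifnot(all(c("variant", "phenotype", "value") %in% names(pheno)))
  if (is.null(pheno$n)) pheno$n <- 1
  pheno$position <- variant_positions(pheno$variant)
  res <- list()
  for (ph in unique(pheno$phenotype)) {
    sub <- pheno[pheno$phenotype == ph, ]
    agg <- vapply(split(sub, sub$position),
                  function(d) weighted_phenotype(d$value, d$n), 0)
    pos <- as.integer(names(agg))
    shared <- intersect(pos, profile$position)
    if (length(shared) < min_shared) {
      warning("phenotype '", ph, "' skipped: fewer than ", min_shared,
              " shared positions")
      next
    }
    x <- profile$value[match(shared, profile$position)]
    y <- agg[as.character(shared)]
    ct <- stats::cor.test(x, y, method = method, exact = FALSE)
    res[[ph]] <- data.frame(phenotype = ph, n = length(shared),
                            r = unname(ct$estimate), p = ct$p.value,
                            stringsAsFactors = FALSE)
  }
  if (length(res) == 0) stop("no phenotype had sufficient overlap with the map")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
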