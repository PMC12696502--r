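# Synthetic multiplexed-screen generator. Produces ground-truth effect
# tables and per-tile read-count bundles for pre-selection, post-selection
# and wild-type-control conditions, under either a growth-competition
# (activity) or a sort-gate (abundance) selection model.

#' Simulation configuration for a synthetic variant-effect screen
#'
#' Default parameter values describe the study conditions the generator
#' emulates: a bimodal missense effect distribution anchored at nonsense = 0
#' and synonymous = 1, clone complexity of at least 50 independent clones
#' per variant, a mean per-cell codon-substitution load of 0.64 (growth
#' screens) or 0.83 (sort screens), and a per-tile sequencing depth scaled
#' down to 2e5 reads (full-scale screens exceed 1.3e6 reads per tile).
#'
#' @param seed Integer seed; every stochastic step derives from it.
#' @param n_replicates Number of biological replicates (>= 1).
#' @param depth Reads sampled per (tile, condition, replicate).
#' @param theta Fraction of missense variants drawn from the deleterious
#'   mixture component.
#' @param mode_deleterious,mode_neutral Centres of the two missense effect
#'   components on the 0 = null / 1 = wild-type scale.
#' @param sd_deleterious,sd_neutral Spreads of the two components.
#' @param lambda Mean codon substitutions per cell; sets the fraction of
#'   reads in a tile that carry a variant.
#' @param clones_per_variant Minimum clone multiplicity per variant; the
#'   pre-selection frequency of a variant is dispersed as the mean of this
#'   many log-normal clone sizes.
#' @param clone_cv Coefficient of variation of a single clone's size.
#' @param selection_fold Post/pre enrichment fold between a variant of
#'   effect 1 and a variant of effect 0 under growth selection.
#' @param gate_slope,gate_midpoint Logistic gate-pass model for sort-based
#'   selection: pass probability `plogis(gate_slope * (score - gate_midpoint))`.
#' @param error_rate Per-variant wild-type-control background frequency
#'   scale (fraction of reads miscalled as a given SNV-reachable variant).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_replicates = 2L,
                       depth = 2e5,
                       theta = 0.3,
                       mode_deleterious = 0,
                       mode_neutral = 1,
                       sd_deleterious = 0.15,
                       sd_neutral = 0.12,
                       lambda = 0.64,
                       clones_per_variant = 50L,
                       clone_cv = 1,
                       selection_fold = 16,
                       gate_slope = 8,
                       gate_midpoint = 0.5,
                       error_rate = 5e-6) {
  cfg <- list(seed = as.integer(seed), n_replicates = as.integer(n_replicates),
              depth = depth, theta = theta,
              mode_deleterious = mode_deleterious, mode_neutral = mode_neutral,
              sd_deleterious = sd_deleterious, sd_neutral = sd_neutral,
              lambda = lambda, clones_per_variant = as.integer(clones_per_variant),
              clone_cv = clone_cv, selection_fold = selection_fold,
              gate_slope = gate_slope, gate_midpoint = gate_midpoint,
              error_rate = error_rate)
  stopifnot(cfg$n_replicates >= 1, cfg$depth >= 1,
            cfg$theta >= 0, cfg$theta <= 1,
            cfg$sd_deleterious >= 0, cfg$sd_neutral >= 0,
            cfg$lambda > 0, cfg$clones_per_variant >= 1,
            cfg$selection_fold > 0, cfg$error_rate >= 0)
  class(cfg) <- "sim_config"
  cfg
}

# Effect support: clipped to [-0.5, 1.5] so that above-wild-type ("hyper")
# scores exist while the mixture stays proper.
EFFECT_SUPPORT <- c(-0.5, 1.5)

#' Draw ground-truth variant effects
#'
#' Synonymous variants have effect exactly 1, nonsense variants exactly 0,
#' and missense effects are drawn from a two-component normal mixture
#' (deleterious component centred near 0, neutral near 1) clipped to
#' `[-0.5, 1.5]`.
#'
#' @param space Variant space from [enumerate_variant_space()].
#' @param cfg A [sim_config()].
#' @return `space` with an added `true_score` column; class
#'   `true_effect_table`.
#' @export
simulate_true_effects <- function(space, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  eff <- numeric(nrow(space))
  eff[space$klass == "synonymous"] <- 1
  eff[space$klass == "nonsense"] <- 0
  mis <- which(space$klass == "missense")
  del <- stats::rbinom(length(mis), 1L, cfg$theta) == 1L
  draw <- numeric(length(mis))
  draw[del] <- stats::rnorm(sum(del), cfg$mode_deleterious, cfg$sd_deleterious)
  draw[!del] <- stats::rnorm(sum(!del), cfg$mode_neutral, cfg$sd_neutral)
  eff[mis] <- pmin(pmax(draw, EFFECT_SUPPORT[1]), EFFECT_SUPPORT[2])
  out <- space
  out$true_score <- eff
  class(out) <- c("true_effect_table", "data.frame")
  out
}

# Expected (noise-free) relative frequencies of variants within one tile,
# before sequencing error. `weights` is the clone-dispersion weight of each
# variant; the total variant read fraction of the tile is lambda_tile.
tile_expected_freqs <- function(weights, lambda_tile) {
  lambda_tile * weights / sum(weights)
}

selection_factor <- function(score, assay, cfg) {
  switch(assay,
    growth = cfg$selection_fold^score,
    gate = stats::plogis(cfg$gate_slope * (score - cfg$gate_midpoint)),
    stop("unknown assay tag: ", assay)
  )
}

#' Simulate per-tile sequencing counts for a screen
#'
#' Generates read counts for every (tile, condition, replicate) cell by
#' multinomial sampling at the configured depth. Pre-selection frequencies
#' carry clone-multiplicity dispersion (mean of log-normal clone sizes);
#' post-selection expected frequencies are pre-selection frequencies scaled
#' by `selection_fold^true_score` (growth) or by a logistic gate-pass
#' probability (gate), renormalised against the unmutated background, which
#' itself behaves as an effect-1 "variant". A wild-type control condition
#' measures the base-call error background, which is also added to the pre-
#' and post-selection expected frequencies of SNV-reachable variants.
#'
#' @param effects A `true_effect_table` from [simulate_true_effects()].
#' @param cfg A [sim_config()].
#' @param assay `"growth"` (competitive growth selection, activity-style) or
#'   `"gate"` (fluorescence sort gate, abundance-style).
#' @return A `counts_bundle` data frame with columns `tile`, `condition`
#'   (`pre`, `post`, `wt_control`), `replicate`, `variant`, `count`,
#'   `depth`.
#' @export
simulate_screen <- function(effects, cfg, assay = c("growth", "gate")) {
  assay <- match.arg(assay)
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$depth < 1) stop("sequencing depth must be at least 1")
  if (anyNA(effects$tile)) stop("every variant must have a tile assignment")
  set.seed(cfg$seed + 1L)

  n_pos_total <- length(unique(effects$position))
  sdlog <- sqrt(log(1 + cfg$clone_cv^2))
  rows <- list()
  for (tl in sort(unique(effects$tile))) {
    idx <- which(effects$tile == tl)
    v <- effects[idx, ]
    n_pos_tile <- length(unique(v$position))
    lambda_tile <- cfg$lambda * n_pos_tile / n_pos_total
    # clone-multiplicity dispersion: variant weight is the mean of
    # clones_per_variant log-normal clone sizes
    weights <- vapply(seq_len(nrow(v)), function(i)
      mean(stats::rlnorm(cfg$clones_per_variant, 0, sdlog)), 0)
    f_pre_sel <- tile_expected_freqs(weights, lambda_tile)
    sel <- selection_factor(v$true_score, assay, cfg)
    bg_sel <- selection_factor(1, assay, cfg)  # unmutated background: effect 1
    post_unnorm <- f_pre_sel * sel
    bg_post <- (1 - sum(f_pre_sel)) * bg_sel
    f_post_sel <- post_unnorm / (sum(post_unnorm) + bg_post)
    # sequencing-error background: SNV-reachable substitutions only
    err <- cfg$error_rate * as.numeric(v$snv_accessible)
    freq <- list(pre = f_pre_sel + err, post = f_post_sel + err, wt_control = err)
    for (cond in names(freq)) {
      for (rep_i in seq_len(cfg$n_replicates)) {
        p <- freq[[cond]]
        counts <- as.vector(stats::rmultinom(1, size = cfg$depth,
                                             prob = c(p, 1 - sum(p))))
        rows[[length(rows) + 1L]] <- data.frame(
          tile = tl, condition = cond, replicate = rep_i,
          variant = v$variant, count = counts[-length(counts)],
          depth = cfg$depth, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("counts_bundle", "data.frame")
  out
}

#' Simulate a clinical reference set from ground-truth effects
#'
#' Samples a positive (pathogenic-like) set preferentially from
#' low-true-effect missense variants and a negative (benign-like) set from
#' high-true-effect ones, with label noise controlled by `overlap`: at
#' `overlap = 0` every positive has a lower true effect than every negative
#' (perfect separability); at `overlap = 1` labels are assigned
#' independently of effect.
#'
#' @param effects A `true_effect_table`.
#' @param n_pos,n_neg Set sizes.
#' @param overlap Label-noise fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return Data frame with columns `variant`, `label`
#'   (`positive`/`negative`); class `reference_set`. Sets are disjoint.
#' @export
simulate_reference_set <- function(effects, n_pos, n_neg, overlap = 0, seed = 1L) {
  stopifnot(overlap >= 0, overlap <= 1)
  mis <- effects[effects$klass == "missense" & !effects$start_codon, ]
  if (n_pos + n_neg > nrow(mis))
    stop("requested reference-set sizes exceed the available variant pool")
  set.seed(seed)
  ord <- order(mis$true_score, stats::runif(nrow(mis)))  # random tie-break
  ranked <- mis$variant[ord]
  n <- length(ranked)
  available <- rep(TRUE, n)
  take <- function(pool_idx, k) {
    pool_idx <- pool_idx[available[pool_idx]]
    sel <- pool_idx[seq_len(k)]
    available[sel] <<- FALSE
    sel
  }
  n_pos_rand <- stats::rbinom(1, n_pos, overlap)
  n_neg_rand <- stats::rbinom(1, n_neg, overlap)
  # extremes first (lowest-ranked for positives, highest for negatives)
  pos_idx <- take(seq_len(n), n_pos - n_pos_rand)
  neg_idx <- take(rev(seq_len(n)), n_neg - n_neg_rand)
  rand_pool <- sample(which(available))
  pos_idx <- c(pos_idx, rand_pool[seq_len(n_pos_rand)])
  rand_pool <- setdiff(rand_pool, pos_idx)
  neg_idx <- c(neg_idx, rand_pool[seq_len(n_neg_rand)])
  out <- data.frame(
    variant = c(ranked[pos_idx], ranked[neg_idx]),
    label = rep(c("positive", "negative"), c(n_pos, n_neg)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("reference_set", "data.frame")
  out
}

#' Generate a synthetic ORF of a given length
#'
#' Deterministic, seeded random coding sequence used by examples, tests and
#' the simulator; 154 codons matches the size of a SOD1-like protein. The
#' sequence is synthetic, not any natural gene.
#'
#' @param n_codons Protein length including the initiator methionine.
#' @param seed Integer seed.
#' @return An [orf_sequence()].
#' @export
example_orf <- function(n_codons = 154, seed = 42L) {
  set.seed(seed)
  repeat {
    codons <- vapply(seq_len(n_codons - 1L), function(i)
      paste(sample(BASES, 3, replace = TRUE), collapse = ""), "")
    stops <- c("TAA", "TAG", "TGA")
    codons[codons %in% stops] <- "TGG"
    orf <- paste0("ATG", paste(codons, collapse = ""))
    return(orf_sequence(orf))
  }
}
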