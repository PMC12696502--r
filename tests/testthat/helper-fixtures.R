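# Fixture builders and independent oracles used across test files.
# Oracles deliberately use plain loops and closed forms, not the package's
# code paths.

# A tiny ORF whose protein is known exactly: M A G K P ...
toy_orf <- function(n_codons = 12) {
  codons <- rep(c("GCC", "GGT", "AAA", "CCG"), length.out = n_codons - 1)
  orf_sequence(paste0("ATG", paste(codons, collapse = "")))
}

# Build a counts bundle directly from a per-variant spec. `tab` has columns
# variant, pre, post, wt (counts, recycled across replicates unless given
# as list columns indexed by replicate).
toy_bundle <- function(tab, depth = 1e6, n_replicates = 1) {
  rows <- list()
  for (r in seq_len(n_replicates)) {
    for (cond in c("pre", "post", "wt_control")) {
      cnt <- switch(cond, pre = tab$pre, post = tab$post, wt_control = tab$wt)
      if (is.list(cnt)) cnt <- vapply(cnt, function(x) x[[min(r, length(x))]], 0)
      rows[[length(rows) + 1]] <- data.frame(
        tile = if (is.null(tab$tile)) 1L else tab$tile,
        condition = cond, replicate = r,
        variant = tab$variant, count = cnt, depth = depth,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("counts_bundle", "data.frame")
  out
}

# Spreadsheet-style recomputation of the scoring stages for a single-tile,
# equal-depth bundle: frequencies, wild-type correction, log2 enrichment,
# delta-method error, anchor rescaling, inverse-variance combination.
oracle_scores <- function(counts, klass, min_count = 10, min_anchor = 1) {
  depth <- counts$depth[1]
  reps <- sort(unique(counts$replicate))
  wt_reps <- reps
  per_rep <- list()
  for (r in reps) {
    res <- data.frame(variant = unique(counts$variant), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(res))) {
      v <- res$variant[i]
      get <- function(cond, rr) {
        counts$count[counts$variant == v & counts$condition == cond &
                     counts$replicate == rr]
      }
      f_pre <- get("pre", r) / depth * 1e6
      f_post <- get("post", r) / depth * 1e6
      f_wt <- mean(vapply(wt_reps, function(rr) get("wt_control", rr), 0)) /
        depth * 1e6
      fpc <- f_pre - f_wt
      fqc <- f_post - f_wt
      if (fqc <= 0) fqc <- 0.5 / depth * 1e6
      res$pre_count[i] <- get("pre", r)
      res$unmeasurable[i] <- get("pre", r) < min_count || fpc <= 0
      res$log_phi[i] <- if (res$unmeasurable[i]) NA else log2(fqc / fpc)
      var_pre <- f_pre * 1e6 / depth + f_wt * 1e6 / (depth * length(wt_reps))
      var_post <- f_post * 1e6 / depth + f_wt * 1e6 / (depth * length(wt_reps))
      res$se_log_phi[i] <- if (res$unmeasurable[i]) NA else
        (1 / log(2)) * sqrt(var_post / fqc^2 + var_pre / fpc^2)
    }
    res$klass <- klass[match(res$variant, names(klass))]
    med_non <- median(res$log_phi[res$klass == "nonsense" & !res$unmeasurable])
    med_syn <- median(res$log_phi[res$klass == "synonymous" & !res$unmeasurable])
    res$score <- (res$log_phi - med_non) / (med_syn - med_non)
    res$se <- res$se_log_phi / (med_syn - med_non)
    res$replicate <- r
    per_rep[[as.character(r)]] <- res
  }
  all <- do.call(rbind, per_rep)
  combined <- lapply(split(all, all$variant), function(d) {
    d <- d[!d$unmeasurable, ]
    if (nrow(d) == 0) return(NULL)
    if (nrow(d) == 1) {
      data.frame(variant = d$variant, score = d$score, se = d$se)
    } else {
      w <- 1 / d$se^2
      data.frame(variant = d$variant[1],
                 score = sum(w * d$score) / sum(w),
                 se = sqrt(1 / sum(w)))
    }
  })
  list(replicates = all, combined = do.call(rbind, combined))
}

# Exhaustive Mann-Whitney two-sided exact p by enumerating every
# assignment of the pooled ranks to group 1.
oracle_mann_whitney_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx)
    sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  if (u_obs > n1 * length(y) / 2) min(1, 2 * p_ge) else min(1, 2 * p_le)
}

# Fisher exact two-sided p by hypergeometric enumeration of all tables
# with the observed margins (sum of table probabilities not exceeding the
# observed table's).
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exhaustive threshold enumeration of the balanced precision-recall curve
# on a small labeled set.
oracle_balanced_pr <- function(scores, labels) {
  P <- sum(labels == "positive"); N <- sum(labels == "negative")
  thr <- sort(unique(scores))
  out <- data.frame(threshold = thr)
  for (i in seq_along(thr)) {
    called <- scores <= thr[i]
    out$recall[i] <- sum(called & labels == "positive") / P
    out$fpr[i] <- sum(called & labels == "negative") / N
    out$balanced_precision[i] <-
      if (out$recall[i] + out$fpr[i] == 0) NA else
        out$recall[i] / (out$recall[i] + out$fpr[i])
  }
  out
}

# Default simulated screen shared by several tests (seed-pinned).
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      orf <- example_orf()
      space <- enumerate_variant_space(orf)
      cfg <- sim_config(seed = 101L)
      effects <- simulate_true_effects(space, cfg)
      counts <- simulate_screen(effects, cfg, assay = "growth")
      cache <<- list(orf = orf, space = space, cfg = cfg,
                     effects = effects, counts = counts)
    }
    cache
  }
})
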