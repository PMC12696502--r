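# Toy 12-variant single-tile bundle with known anchors; klass is encoded
# in the variant notation itself.
toy_score_tab <- function() {
  data.frame(
    variant = c("p.Ala2Ter", "p.Gly3Ter",             # nonsense anchors
                "p.Ala2Ala", "p.Gly3Gly",             # synonymous anchors
                "p.Ala2Val", "p.Gly3Ser", "p.Lys4Glu", "p.Pro5Leu",
                "p.Ala6Asp", "p.Gly7Arg", "p.Lys8Asn", "p.Pro9Ser"),
    pre  = c(300, 280, 310, 290, 250, 260, 240, 9, 270, 255, 265, 245),
    post = c(30, 25, 610, 580, 60, 400, 120, 50, 0, 210, 330, 90),
    wt   = c(0, 2, 0, 0, 3, 0, 0, 0, 0, 5, 0, 0),
    stringsAsFactors = FALSE
  )
}

toy_klass <- function(tab) {
  kl <- parse_variant(tab$variant)$klass
  names(kl) <- tab$variant
  kl
}

run_toy_stages <- function(counts) {
  freqs <- compute_frequencies(counts)
  rt <- apply_filters(freqs, min_count = 10)
  rt$klass <- parse_variant(rt$variant)$klass
  enr <- enrichment_scores(rt)
  rescale_scores(enr, min_anchor = 1)
}

test_that("frequencies are reads per million and conserve depth", {
  counts <- toy_bundle(data.frame(variant = "p.Ala2Val", pre = 10,
                                  post = 0, wt = 0), depth = 1e6)
  f <- compute_frequencies(counts)
  expect_equal(f$freq[f$condition == "pre"], 10)
  expect_equal(f$freq[f$condition == "post"], 0)

  d <- default_sim()
  f2 <- compute_frequencies(d$counts)
  per_cell <- aggregate(freq ~ tile + condition + replicate, f2, sum)
  expect_true(all(per_cell$freq <= 1e6 + 1e-9))

  bad <- counts
  bad$depth[1] <- 0
  expect_error(compute_frequencies(bad), "zero depth")
})

test_that("every scoring stage matches the spreadsheet oracle to 1e-12", {
  tab <- toy_score_tab()
  counts <- toy_bundle(tab, depth = 1e6, n_replicates = 2)
  # perturb replicate 2 counts so replicates differ
  r2 <- counts$replicate == 2 & counts$condition == "post"
  counts$count[r2] <- counts$count[r2] + c(5, -3, 20, -10, 4, -12, 8, 2, 1, -6, 14, -4)

  rsc <- run_toy_stages(counts)
  oracle <- oracle_scores(counts, toy_klass(tab), min_count = 10)

  for (r in 1:2) {
    got <- rsc[rsc$replicate == r, ]
    want <- oracle$replicates[oracle$replicates$replicate == r, ]
    got <- got[match(want$variant, got$variant), ]
    expect_identical(got$unmeasurable, want$unmeasurable)
    ok <- !want$unmeasurable
    expect_equal(got$log_phi[ok], want$log_phi[ok], tolerance = 1e-12)
    expect_equal(got$se_log_phi[ok], want$se_log_phi[ok], tolerance = 1e-12)
    expect_equal(got$score[ok], want$score[ok], tolerance = 1e-12)
    expect_equal(got$se[ok], want$se[ok], tolerance = 1e-12)
  }

  map <- combine_replicates(rsc)
  comb <- oracle$combined
  m <- merge(map, comb, by = "variant", suffixes = c("", "_oracle"))
  expect_equal(nrow(m), nrow(comb))
  expect_equal(m$score, m$score_oracle, tolerance = 1e-12)
  expect_equal(m$se, m$se_oracle, tolerance = 1e-12)
})

test_that("read-count and wild-type filters behave as specified", {
  tab <- toy_score_tab()
  counts <- toy_bundle(tab, depth = 1e6)
  rt <- apply_filters(compute_frequencies(counts), min_count = 10)
  # pre count 9 -> excluded
  expect_true(rt$excluded[rt$variant == "p.Pro5Leu"])
  expect_false(rt$excluded[rt$variant == "p.Ala2Val"])
  # pre frequency >= 10 ppm, count >= 10, above background -> well measured
  expect_true(rt$well_measured[rt$variant == "p.Ala2Val"])

  # degenerate threshold: all wild-type-control frequencies zero excludes
  # nothing by the percentile rule
  tab0 <- tab
  tab0$wt <- 0
  rt0 <- apply_filters(compute_frequencies(toy_bundle(tab0)), min_count = 1)
  expect_false(any(rt0$excluded))

  # monotone: raising min_count never un-excludes a variant
  rt15 <- apply_filters(compute_frequencies(counts), min_count = 15)
  expect_true(all(rt$excluded <= rt15$excluded))

  # empty control is an error
  no_wt <- counts[counts$condition != "wt_control", ]
  expect_error(apply_filters(compute_frequencies(no_wt)), "control")
})

test_that("error-corrected enrichment handles floors and unmeasurables", {
  tab <- data.frame(
    variant = c("p.Ala2Val", "p.Gly3Ser", "p.Lys4Glu"),
    pre = c(100, 50, 200), post = c(100, 80, 0), wt = c(0, 50, 10),
    stringsAsFactors = FALSE
  )
  counts <- toy_bundle(tab, depth = 1e6)
  rt <- apply_filters(compute_frequencies(counts), min_count = 10)
  rt$klass <- parse_variant(rt$variant)$klass
  enr <- enrichment_scores(rt)
  # equal corrected frequencies -> log-ratio 0
  expect_equal(enr$log_phi[enr$variant == "p.Ala2Val"], 0)
  # wild-type frequency equal to pre frequency -> unmeasurable
  expect_true(enr$unmeasurable[enr$variant == "p.Gly3Ser"])
  # post depleted to zero is floored (half a read), not unmeasurable
  row3 <- enr[enr$variant == "p.Lys4Glu", ]
  expect_true(row3$floored)
  expect_false(row3$unmeasurable)
  expect_equal(row3$f_post_c, 0.5)
})

test_that("delta-method standard error agrees with a parametric bootstrap", {
  # single variant at f_pre 200 ppm, f_post 50 ppm, f_wt 10 ppm, depth 1e6
  tab <- data.frame(variant = "p.Ala2Val", pre = 200, post = 50, wt = 10)
  counts <- toy_bundle(tab, depth = 1e6)
  rt <- apply_filters(compute_frequencies(counts), min_count = 10)
  enr <- enrichment_scores(rt)
  se_delta <- enr$se_log_phi

  set.seed(20240901)
  n <- 1e5
  pre <- rpois(n, 200); post <- rpois(n, 50); wt <- rpois(n, 10)
  ok <- (pre - wt) > 0 & (post - wt) > 0
  lr <- log2((post[ok] - wt[ok]) / (pre[ok] - wt[ok]))
  expect_lt(abs(se_delta - sd(lr)) / sd(lr), 0.05)
})

test_that("rescaling anchors nonsense at 0 and synonymous at 1 exactly", {
  d <- default_sim()
  freqs <- compute_frequencies(d$counts)
  rt <- apply_filters(freqs)
  rt$klass <- d$space$klass[match(rt$variant, d$space$variant)]
  rt$terminal_stop <- d$space$terminal_stop[match(rt$variant, d$space$variant)]
  rsc <- rescale_scores(enrichment_scores(rt))
  for (r in unique(rsc$replicate)) {
    sub <- rsc[rsc$replicate == r & !rsc$unmeasurable & !rsc$terminal_stop, ]
    expect_equal(median(sub$score[sub$klass == "nonsense"]), 0, tolerance = 1e-12)
    expect_equal(median(sub$score[sub$klass == "synonymous"]), 1, tolerance = 1e-12)
  }
})

test_that("rescaled scores are invariant to affine transforms of log-enrichment", {
  tab <- toy_score_tab()
  counts <- toy_bundle(tab, depth = 1e6)
  rsc <- run_toy_stages(counts)
  shifted <- rsc
  shifted$log_phi <- 3 + 2 * shifted$log_phi
  shifted$se_log_phi <- 2 * shifted$se_log_phi
  rsc2 <- rescale_scores(shifted[, setdiff(names(shifted), c("score", "se"))],
                         min_anchor = 1)
  ok <- !rsc$unmeasurable
  expect_equal(rsc2$score[ok], rsc$score[ok], tolerance = 1e-12)
  expect_equal(rsc2$se[ok], rsc$se[ok], tolerance = 1e-12)
})

test_that("rescaling demands separation and sufficient anchors", {
  tab <- toy_score_tab()
  counts <- toy_bundle(tab, depth = 1e6)
  rsc_in <- run_toy_stages(counts)
  expect_error(rescale_scores(rsc_in[, setdiff(names(rsc_in), c("score", "se"))],
                              min_anchor = 10), "anchors")
  # inverted selection: synonymous median below nonsense median
  inv <- rsc_in[, setdiff(names(rsc_in), c("score", "se"))]
  inv$log_phi <- -inv$log_phi
  expect_error(rescale_scores(inv, min_anchor = 1), "separation")
})

make_rs <- function(variant, score, se, df = 1, klass = "missense",
                    f_pre_c = 100, well_measured = TRUE) {
  data.frame(variant = variant, replicate = seq_along(score), score = score,
             se = se, df = df, klass = klass, f_pre_c = f_pre_c,
             unmeasurable = FALSE, well_measured = well_measured,
             stringsAsFactors = FALSE)
}

test_that("error regularization shrinks toward the frequency trend", {
  # on-trend errors are a fixed point
  set.seed(1)
  f <- 10^runif(60, 1, 3)
  se <- exp(-1 - 0.5 * log(10) * log10(f))
  rs <- make_rs(sprintf("p.Ala%dVal", 2:61), score = rnorm(60), se = se)
  rs$f_pre_c <- f
  reg <- regularize_errors(rs)
  expect_equal(reg$se, se, tolerance = 1e-6)
  expect_true(all(reg$df == 3))

  # a zero empirical se (identical replicate draws by chance) becomes positive
  rs2 <- rs
  rs2$se[1] <- 0
  reg2 <- regularize_errors(rs2)
  expect_gt(reg2$se[1], 0)

  # slope recovered from heteroscedastic data with se ~ f^(-1/2)
  set.seed(2)
  f3 <- 10^runif(300, 1, 3)
  se3 <- 0.5 * f3^(-0.5) * exp(rnorm(300, 0, 0.1))
  rs3 <- make_rs(sprintf("p.Ala%dVal", 2:301), score = rnorm(300), se = se3)
  rs3$f_pre_c <- f3
  reg3 <- regularize_errors(rs3)
  slope <- attr(reg3, "error_trend")["slope"]
  expect_lt(abs(slope - (-0.5 * log(10))), 0.1)

  # too few variants: unregularized with a warning
  expect_warning(regularize_errors(rs[1:5, ]), "unregularized")
})

test_that("replicate combination uses inverse-variance weights", {
  # symmetric: equal errors average
  rs <- make_rs("p.Ala2Val", score = c(0.4, 0.6), se = c(0.1, 0.1))
  expect_equal(combine_replicates(rs)$score, 0.5)

  # closed form: scores 0 and 1 with se 1 and 2 -> 0.2
  rs2 <- make_rs("p.Ala2Val", score = c(0, 1), se = c(1, 2))
  map2 <- combine_replicates(rs2)
  expect_equal(map2$score, 0.2, tolerance = 1e-12)
  expect_equal(map2$se, sqrt(1 / (1 + 0.25)), tolerance = 1e-12)

  # single replicate passes through unchanged
  rs3 <- make_rs("p.Ala2Val", score = 0.7, se = 0.1, df = 1)
  map3 <- combine_replicates(rs3)
  expect_equal(map3$score, 0.7)
  expect_equal(map3$se, 0.1)
  expect_equal(map3$df, 1)
  expect_equal(map3$n_replicates, 1L)

  # combined score within replicate range; combined se below the smallest
  set.seed(3)
  for (i in 1:20) {
    s <- rnorm(3); e <- runif(3, 0.05, 0.5)
    m <- combine_replicates(make_rs("p.Ala2Val", score = s, se = e))
    expect_gte(m$score, min(s))
    expect_lte(m$score, max(s))
    expect_lte(m$se, min(e))
  }
})

test_that("the pipeline recovers simulated truth and keeps the bimodal shape", {
  d <- default_sim()
  map <- score_pipeline(d$counts, d$space)
  m <- merge(map, d$effects[, c("variant", "true_score")], by = "variant")
  expect_gte(cor(m$score, m$true_score), 0.9)

  mis <- map$score[map$klass == "missense" & map$well_measured]
  dens <- density(mis)
  peaks <- which(diff(sign(diff(dens$y))) == -2) + 1
  main_peaks <- peaks[dens$y[peaks] > 0.2 * max(dens$y)]
  expect_gte(length(main_peaks), 2)
  expect_lt(min(abs(dens$x[main_peaks] - 0)), 0.15)
  expect_lt(min(abs(dens$x[main_peaks] - 1)), 0.15)
})

test_that("a null screen is flagged as having no selection separation", {
  space <- enumerate_variant_space(example_orf(60))
  cfg <- sim_config(seed = 21, selection_fold = 1)
  eff <- simulate_true_effects(space, cfg)
  counts <- simulate_screen(eff, cfg, assay = "growth")
  # with no selection the synonymous and nonsense anchor medians are
  # statistically indistinguishable; the pipeline refuses to rescale
  # rather than emitting meaningless scores
  res <- tryCatch(score_pipeline(counts, space), error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "separation")
  } else {
    # anchor medians happened to fall in the right order: the map must
    # then be centred near the wild-type anchor with huge uncertainty
    expect_lt(abs(median(res$score[res$klass == "missense"]) - 1), 0.5)
  }
})
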