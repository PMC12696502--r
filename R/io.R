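# File formats: counts TSV, MaveDB-style score CSV, reference CSV, run
# configuration. Readers validate rather than silently coerce; writers
# produce files their readers accept.

COUNT_COLUMNS <- c("tile", "condition", "replicate", "variant", "count", "depth")
CONDITIONS <- c("pre", "post", "wt_control")

#' Read a counts bundle from TSV
#'
#' Expects a header `tile, condition, replicate, variant, count, depth`;
#' conditions restricted to `pre`, `post`, `wt_control`.
#'
#' @param path TSV path.
#' @return A `counts_bundle` data frame.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no records in counts file ", path)
  missing_cols <- setdiff(COUNT_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("counts file missing column(s): ", paste(missing_cols, collapse = ", "))
  bad <- !df$condition %in% CONDITIONS
  if (any(bad))
    stop(sprintf("unknown condition '%s' at line %d (allowed: %s)",
                 df$condition[which(bad)[1]], which(bad)[1] + 1L,
                 paste(CONDITIONS, collapse = ", ")))
  if (!is.numeric(df$count) || !is.numeric(df$depth))
    stop("count and depth must be numeric")
  if (any(df$count < 0)) {
    i <- which(df$count < 0)[1]
    stop("negative count at line ", i + 1L)
  }
  class(df) <- c("counts_bundle", "data.frame")
  df
}

#' Write a counts bundle to TSV
#' @param counts A `counts_bundle`.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts[, COUNT_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant-effect map from a MaveDB-style score CSV
#'
#' Required columns: `hgvs_pro`, `score`, `se`, `df`; `well_measured` is
#' assumed true when absent. Lines starting with `#` are comments.
#' Unrecognized columns are preserved.
#'
#' @param path CSV path.
#' @return A `variant_effect_map`.
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("hgvs_pro", "score", "se", "df")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("score file missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$hgvs_pro))
    stop("duplicate hgvs_pro entries: ",
         paste(unique(df$hgvs_pro[duplicated(df$hgvs_pro)]), collapse = ", "))
  names(df)[names(df) == "hgvs_pro"] <- "variant"
  if (is.null(df$well_measured)) df$well_measured <- TRUE
  if (is.null(df$klass)) df$klass <- parse_variant(df$variant)$klass
  class(df) <- c("variant_effect_map", "data.frame")
  df
}

#' Write a variant-effect map as a MaveDB-style score CSV
#'
#' Columns `hgvs_pro, score, se, df, well_measured` first; any extra
#' columns are preserved after them.
#'
#' @param map A `variant_effect_map`.
#' @param path Output path.
#' @export
write_scores <- function(map, path) {
  df <- as.data.frame(map)
  names(df)[names(df) == "variant"] <- "hgvs_pro"
  lead <- c("hgvs_pro", "score", "se", "df", "well_measured")
  lead <- lead[lead %in% names(df)]
  df <- df[, c(lead, setdiff(names(df), lead)), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a clinical reference CSV
#'
#' Columns `variant`, `label` (one of P, LP, B, LB, PB, or already
#' `positive`/`negative`), optional `source`. P/LP map to positive;
#' B/LB/PB to negative.
#'
#' @param path CSV path.
#' @return A `reference_set` data frame.
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (is.null(df$variant) || is.null(df$label))
    stop("reference file must have 'variant' and 'label' columns")
  lab_map <- c(P = "positive", LP = "positive",
               B = "negative", LB = "negative", PB = "negative",
               positive = "positive", negative = "negative")
  lab <- lab_map[df$label]
  if (anyNA(lab))
    stop("unknown label(s): ",
         paste(unique(df$label[is.na(lab)]), collapse = ", "))
  df$label <- unname(lab)
  if (anyDuplicated(df$variant)) {
    dup <- unique(df$variant[duplicated(df$variant)])
    both <- vapply(dup, function(v)
      length(unique(df$label[df$variant == v])) > 1, TRUE)
    if (any(both))
      stop("variant(s) with conflicting labels: ",
           paste(dup[both], collapse = ", "))
    df <- df[!duplicated(df$variant), ]
  }
  class(df) <- c("reference_set", "data.frame")
  df
}

#' Write an LLR calibration report
#'
#' CSV with `hgvs_pro, score, llr, ci_lo, ci_hi, evidence` plus a JSON
#' summary (AUBPRC, R80BP, set sizes, configuration echo) alongside when
#' `summary` is supplied.
#'
#' @param llr An `llr_table` from [compute_llr()].
#' @param path Output CSV path.
#' @param summary Optional named list written as JSON to
#'   `paste0(path, ".json")`.
#' @export
write_llr_report <- function(llr, path, summary = NULL) {
  df <- as.data.frame(llr)
  names(df)[names(df) == "variant"] <- "hgvs_pro"
  utils::write.csv(df[, c("hgvs_pro", "score", "llr", "ci_lo", "ci_hi",
                          "evidence")], path, row.names = FALSE, quote = FALSE)
  if (!is.null(summary))
    jsonlite::write_json(summary, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

RUN_CONFIG_KEYS <- c(
  "format_version", "seed", "n_replicates", "depth", "theta", "lambda",
  "clones_per_variant", "selection_fold", "error_rate", "assay",
  "min_count", "wt_percentile", "min_pre_ppm", "wt_strata", "min_anchor",
  "prior_df", "threshold", "window", "prior", "odds_pvst", "n_boot",
  "n_codons", "orf_seed"
)

#' Read a run configuration YAML
#'
#' Unknown keys are rejected so that typos cannot silently change a run.
#'
#' @param path YAML path.
#' @return Named list with class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  structure(cfg, class = "run_config")
}
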