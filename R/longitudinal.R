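#' Batch-level averages over days in vitro
#'
#' Averages each metric across cultures of the same batch, day by day:
#' mean and standard error (`sd / sqrt(n)`) over the cultures with data
#' that day. Days inside a batch's observed range with no recordings are
#' reported as gap rows (`recorded = FALSE`, no fabricated values) — gaps
#' are display-only and never interpolated into statistics.
#'
#' @param metrics wide per-culture-day metrics table (rows from
#'   [metrics_for_day()], possibly several windows).
#' @param metric_names metric columns to summarize; default the study's
#'   three.
#' @param single_culture_se standard error reported when only one culture
#'   contributes: `"zero"` (default) or `"missing"`.
#' @return data.frame: `batch_id`, `window_ms`, `day_in_vitro`,
#'   `metric_name`, `mean`, `se`, `n`, `recorded`.
#' @export
batch_average <- function(metrics,
                          metric_names = c("mean_connection_length_um",
                                           "n_incoming_supernodes",
                                           "n_outgoing_supernodes"),
                          single_culture_se = c("zero", "missing")) {
  single_culture_se <- match.arg(single_culture_se)
  out <- list()
  for (b in unique(metrics$batch_id)) {
    mb <- metrics[metrics$batch_id == b, , drop = FALSE]
    for (w in unique(mb$window_ms)) {
      mw <- mb[mb$window_ms == w, , drop = FALSE]
      days <- seq(min(mw$day_in_vitro), max(mw$day_in_vitro))
      for (metric in metric_names) {
        for (d in days) {
          v <- mw[[metric]][mw$day_in_vitro == d]
          v <- v[!is.na(v)]
          n <- length(v)
          if (n == 0) {
            row <- data.frame(batch_id = b, window_ms = w, day_in_vitro = d,
                              metric_name = metric, mean = NA_real_,
                              se = NA_real_, n = 0L, recorded = FALSE,
                              stringsAsFactors = FALSE)
          } else {
            se <- if (n == 1) {
              if (single_culture_se == "zero") 0 else NA_real_
            } else {
              sd(v) / sqrt(n)
            }
            row <- data.frame(batch_id = b, window_ms = w, day_in_vitro = d,
                              metric_name = metric, mean = mean(v), se = se,
                              n = n, recorded = TRUE,
                              stringsAsFactors = FALSE)
          }
          out[[length(out) + 1]] <- row
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA of `values` grouped by `groups`, fitted with
#' [stats::aov()]. Requires at least two groups with at least two
#' observations each.
#'
#' @param values numeric observations.
#' @param groups grouping factor (coerced).
#' @param label optional design label carried in the result.
#' @return a `mea_anova` list: `label`, `f_statistic`, `p_value`,
#'   `df_between`, `df_within`, `group_means`, `group_sizes`, and the
#'   underlying `fit`.
#' @export
anova_one_way <- function(values, groups, label = "one-way") {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  sizes <- table(groups)
  if (nlevels(groups) < 2) {
    stop("one-way ANOVA needs at least 2 groups, got ", nlevels(groups),
         call. = FALSE)
  }
  if (any(sizes < 2)) {
    stop("every group needs at least 2 observations; group(s) ",
         paste(names(sizes)[sizes < 2], collapse = ", "), " too small",
         call. = FALSE)
  }
  fit <- aov(values ~ groups)
  tab <- summary(fit)[[1]]
  f_stat <- tab[["F value"]][1]
  p_val <- tab[["Pr(>F)"]][1]
  if (var(values) == 0 ||
      (!is.finite(f_stat) && tab[["Sum Sq"]][1] == 0)) {
    # no variation at all: conventionally F = 0, p = 1
    f_stat <- 0
    p_val <- 1
  }
  structure(list(
    label = label,
    f_statistic = f_stat,
    p_value = p_val,
    df_between = tab[["Df"]][1],
    df_within = tab[["Df"]][2],
    group_means = tapply(values, groups, mean),
    group_sizes = as.integer(sizes),
    fit = fit
  ), class = "mea_anova")
}

#' @export
print.mea_anova <- function(x, ...) {
  cat("<mea_anova> ", x$label, ": F(", x$df_between, ", ", x$df_within,
      ") = ", signif(x$f_statistic, 4), ", p = ", signif(x$p_value, 4),
      "\n", sep = "")
  invisible(x)
}

#' Within- and across-batch variability of a metric
#'
#' Two one-way ANOVA designs probing whether cultures from the same batch
#' (brain tissue) evolve more similarly than cultures from different
#' batches:
#'
#' * **across**: one observation per culture — its metric averaged over
#'   recorded days — with batch as the factor. Significance means batches
#'   differ more than cultures within batches.
#' * **within**: per batch, the per-day metric values with culture as the
#'   factor; reported separately for each batch with at least two
#'   cultures. Non-significance means cultures within a batch track each
#'   other.
#'
#' @param metrics wide per-culture-day metrics table.
#' @param metric metric column, default mean connection length.
#' @param window_ms restrict to one counting window (`NULL` = use all rows
#'   as given).
#' @return list with elements `across` (a `mea_anova`) and `within` (named
#'   list of `mea_anova`, one per eligible batch).
#' @export
batch_variability_tests <- function(metrics,
                                    metric = "mean_connection_length_um",
                                    window_ms = NULL) {
  if (!is.null(window_ms)) {
    metrics <- metrics[metrics$window_ms == window_ms, , drop = FALSE]
  }
  v <- metrics[[metric]]
  keep <- !is.na(v)
  metrics <- metrics[keep, , drop = FALSE]
  v <- v[keep]

  per_culture <- tapply(v, metrics$culture_id, mean)
  culture_batch <- metrics$batch_id[match(names(per_culture),
                                          metrics$culture_id)]
  across <- anova_one_way(as.numeric(per_culture), culture_batch,
                          label = paste0("across-batch (units = cultures, ",
                                         "metric = ", metric, ")"))

  within <- list()
  for (b in unique(metrics$batch_id)) {
    mb <- metrics[metrics$batch_id == b, , drop = FALSE]
    if (length(unique(mb$culture_id)) < 2) next
    within[[b]] <- tryCatch(
      anova_one_way(mb[[metric]], mb$culture_id,
                    label = paste0("within-batch ", b,
                                   " (units = culture-days, metric = ",
                                   metric, ")")),
      error = function(e) NULL)
  }
  within <- within[!vapply(within, is.null, logical(1))]
  list(across = across, within = within)
}

#' Compare counting windows by ANOVA with Tukey multiple comparison
#'
#' For each batch, a one-way ANOVA of the per-day batch-averaged metric
#' with the counting window (50/100/150 ms) as the factor, followed by
#' Tukey-Kramer pairwise comparisons at the given confidence level. A pair
#' of windows is flagged `different` when its confidence interval excludes
#' zero (equivalently, when the groups' intervals do not overlap in the
#' usual multiple-comparison display).
#'
#' @param metrics wide per-culture-day metrics table containing several
#'   `window_ms` values.
#' @param metric metric column, default mean connection length.
#' @param conf_level confidence level for the Tukey intervals, default
#'   0.95.
#' @return named list (one element per batch): `anova` (a `mea_anova`) and
#'   `comparisons` (data.frame `window_a`, `window_b`, `diff`, `lwr`,
#'   `upr`, `p_adj`, `different`).
#' @export
window_comparison <- function(metrics, metric = "mean_connection_length_um",
                              conf_level = 0.95) {
  summ <- batch_average(metrics, metric_names = metric)
  summ <- summ[summ$recorded, , drop = FALSE]
  out <- list()
  for (b in unique(summ$batch_id)) {
    sb <- summ[summ$batch_id == b, , drop = FALSE]
    if (length(unique(sb$window_ms)) < 2) next
    an <- anova_one_way(sb$mean, sb$window_ms,
                        label = paste0("window comparison, batch ", b,
                                       " (units = per-day batch means)"))
    tk <- TukeyHSD(an$fit, conf.level = conf_level)$groups
    pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    comp <- data.frame(window_a = pairs[, 1], window_b = pairs[, 2],
                       diff = tk[, "diff"], lwr = tk[, "lwr"],
                       upr = tk[, "upr"], p_adj = tk[, "p adj"],
                       different = tk[, "lwr"] > 0 | tk[, "upr"] < 0,
                       stringsAsFactors = FALSE)
    rownames(comp) <- NULL
    out[[as.character(b)]] <- list(anova = an, comparisons = comp)
  }
  out
}
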