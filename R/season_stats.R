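# Group comparisons and seasonal summaries over quantified profiles and
# model predictions.

#' Two-sample comparison
#'
#' Two-sided two-sample t-test.  Welch (unequal variances) is the default;
#' `variant = "student"` gives the classical pooled-variance test.
#'
#' @param values_a,values_b Numeric samples, each with >= 2 finite values.
#' @param variant `"welch"` or `"student"`.
#' @param label_a,label_b Group labels carried into the result.
#' @return A one-row `data.frame`: `group_a`, `group_b`, `statistic`, `df`,
#'   `p_value`, `mean_a`, `mean_b`, `n_a`, `n_b`, `variant`.
#' @export
compare_groups <- function(values_a, values_b, variant = c("welch", "student"),
                           label_a = "a", label_b = "b") {
  variant <- match.arg(variant)
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (length(a) < 2 || length(b) < 2) {
    ps_error("both samples need at least 2 finite values",
             "phospec_sample_size")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    ps_error("both samples are constant: the t statistic is undefined",
             "phospec_degenerate")
  }
  tt <- stats::t.test(a, b, var.equal = (variant == "student"))
  data.frame(
    group_a = label_a, group_b = label_b,
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_a = mean(a), mean_b = mean(b),
    n_a = length(a), n_b = length(b),
    variant = variant,
    stringsAsFactors = FALSE
  )
}

#' Pairwise consecutive-timepoint comparisons
#'
#' Compares consecutive timepoint pairs (T1-T2, ..., T4-T5) of one signature
#' at one site, with Holm adjustment across the family.  Timepoints with
#' fewer than 2 plants are skipped with a message.
#'
#' @param profiles Profile `data.frame` with `site`, `timepoint` and the
#'   signature column.
#' @param signature Column name to compare (e.g. `"Pi"`, `"Po"`,
#'   `"cl_ratio"`).
#' @param site Site label to restrict to.
#' @param variant Passed to [compare_groups()].
#' @param adjust Multiplicity adjustment method (default `"holm"`).
#' @return A `data.frame` of comparisons with an added `p_adjusted` column.
#' @export
pairwise_timepoints <- function(profiles, signature, site,
                                variant = "welch", adjust = "holm") {
  stopifnot(signature %in% names(profiles),
            all(c("site", "timepoint") %in% names(profiles)))
  sub <- profiles[profiles$site == site, ]
  tps <- sort(unique(as.character(sub$timepoint)))
  usable <- tps[vapply(tps, function(tp) {
    sum(is.finite(sub[[signature]][sub$timepoint == tp])) >= 2
  }, logical(1))]
  skipped <- setdiff(tps, usable)
  if (length(skipped)) {
    message("skipping timepoint(s) with < 2 plants: ",
            paste(skipped, collapse = ", "))
  }
  if (length(usable) < 2) {
    ps_error("need >= 2 usable timepoints", "phospec_sample_size")
  }
  rows <- lapply(seq_len(length(usable) - 1), function(i) {
    va <- sub[[signature]][sub$timepoint == usable[i]]
    vb <- sub[[signature]][sub$timepoint == usable[i + 1]]
    cmp <- compare_groups(va, vb, variant = variant,
                          label_a = usable[i], label_b = usable[i + 1])
    cmp$signature <- signature
    cmp$site <- site
    cmp
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  out
}

#' Association between senescence Pi/Po ratio and next-year biomass
#'
#' Spearman rank correlation (two-sided) between each plant's
#' senescence-time (T5) inorganic/organic phosphate ratio and its
#' second-year biomass.
#'
#' @param t5_profiles Either a `data.frame` holding both columns, or a
#'   numeric vector of Pi/Po ratios.
#' @param biomass Numeric vector paired with the ratios (ignored when
#'   `t5_profiles` carries a `second_year_biomass` column).
#' @param ratio_col,biomass_col Column names used when `t5_profiles` is a
#'   data frame.
#' @return A one-row `data.frame`: `coefficient` (Spearman rho), `p_value`,
#'   `n`, `method`.
#' @export
ratio_biomass_association <- function(t5_profiles, biomass = NULL,
                                      ratio_col = "pi_po",
                                      biomass_col = "second_year_biomass") {
  if (is.data.frame(t5_profiles)) {
    stopifnot(ratio_col %in% names(t5_profiles),
              biomass_col %in% names(t5_profiles))
    ratio <- t5_profiles[[ratio_col]]
    biomass <- t5_profiles[[biomass_col]]
  } else {
    ratio <- as.numeric(t5_profiles)
  }
  ok <- is.finite(ratio) & is.finite(biomass)
  ratio <- ratio[ok]
  biomass <- biomass[ok]
  if (length(ratio) < 3) {
    ps_error("need >= 3 paired observations", "phospec_sample_size")
  }
  if (stats::var(ratio) == 0 || stats::var(biomass) == 0) {
    ps_error("constant input: rank correlation undefined",
             "phospec_degenerate")
  }
  ct <- suppressWarnings(
    stats::cor.test(ratio, biomass, method = "spearman", exact = FALSE)
  )
  data.frame(
    coefficient = unname(ct$estimate),
    p_value = ct$p.value,
    n = length(ratio),
    method = "spearman",
    stringsAsFactors = FALSE
  )
}

#' Site-by-timepoint season summary
#'
#' Means and standard deviations per site and timepoint for every signature
#' column of the profile table, plus the predicted available P when a
#' prediction table is supplied.
#'
#' @param profiles Profile `data.frame` with `sample_id`, `site`,
#'   `timepoint` and signature columns.
#' @param predictions Optional `data.frame` with `sample_id` and `predicted`
#'   (from [predict_available()]).  Every profile row must have a matching
#'   prediction; offenders are listed in the error.
#' @param signatures Signature columns to summarize; defaults to the
#'   numeric profile columns.
#' @return A `data.frame` with one row per site x timepoint and
#'   `<signature>_mean` / `<signature>_sd` columns.  When `predictions` is
#'   absent the attribute `has_predictions` is `FALSE`.
#' @export
season_table <- function(profiles, predictions = NULL, signatures = NULL) {
  stopifnot(all(c("sample_id", "site", "timepoint") %in% names(profiles)))
  if (is.null(signatures)) {
    numeric_cols <- vapply(profiles, is.numeric, logical(1))
    signatures <- setdiff(names(profiles)[numeric_cols],
                          c("residual_rms", "replicate"))
  }
  dat <- profiles
  has_pred <- !is.null(predictions) && nrow(predictions) > 0
  if (has_pred) {
    missing <- setdiff(profiles$sample_id, predictions$sample_id)
    if (length(missing)) {
      ps_error(
        sprintf("no prediction for sample(s): %s",
                paste(missing, collapse = ", ")),
        "phospec_metadata_error"
      )
    }
    dat$predicted_available_P <-
      predictions$predicted[match(dat$sample_id, predictions$sample_id)]
    signatures <- c(signatures, "predicted_available_P")
  }
  cells <- unique(dat[, c("site", "timepoint")])
  cells <- cells[order(cells$site, cells$timepoint), ]
  rownames(cells) <- NULL
  for (sig in signatures) {
    cells[[paste0(sig, "_mean")]] <- NA_real_
    cells[[paste0(sig, "_sd")]] <- NA_real_
  }
  cells$n <- NA_integer_
  for (r in seq_len(nrow(cells))) {
    sel <- dat$site == cells$site[r] & dat$timepoint == cells$timepoint[r]
    cells$n[r] <- sum(sel)
    for (sig in signatures) {
      v <- dat[[sig]][sel]
      cells[[paste0(sig, "_mean")]][r] <- mean(v, na.rm = TRUE)
      cells[[paste0(sig, "_sd")]][r] <- stats::sd(v[is.finite(v)])
    }
  }
  attr(cells, "has_predictions") <- has_pred
  cells
}
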