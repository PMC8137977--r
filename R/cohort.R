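#' Frequencies of qualitative OCTA features in a cohort
#'
#' Counts and percentages of the five qualitative mCNV features scored on
#' baseline angiograms: overall pattern (`OP`: organized interlacing `OI` vs
#' disorganized vascular loops `DVL`), exuberant capillaries (`EC`),
#' anastomoses and loops (`AL`), perilesional hypointense halo (`HH`) and
#' feeder vessel (`FV`), each coded `Y`/`N`.
#'
#' @param records Data frame with one row per eye and (any subset of) columns
#'   `OP`, `EC`, `AL`, `HH`, `FV`.
#' @return Data frame with columns `feature`, `level`, `count`, `n`, `pct`
#'   (percentage to 2 decimals). The `OP` rows enumerate both patterns and
#'   their percentages sum to 100.
#' @export
summarize_features <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop_validation("no records to summarize")
  out <- list()
  n <- nrow(records)
  if ("OP" %in% names(records)) {
    op <- records$OP
    if (!all(op %in% c("OI", "DVL")))
      stop_validation("OP must be 'OI' or 'DVL'")
    for (lv in c("OI", "DVL")) {
      out[[length(out) + 1L]] <- data.frame(
        feature = "OP", level = lv, count = sum(op == lv), n = n,
        pct = round(100 * sum(op == lv) / n, 2))
    }
  }
  for (f in intersect(c("EC", "AL", "HH", "FV"), names(records))) {
    v <- records[[f]]
    if (!all(v %in% c("Y", "N")))
      stop_validation(sprintf("%s must be coded Y/N", f))
    out[[length(out) + 1L]] <- data.frame(
      feature = f, level = "Y", count = sum(v == "Y"), n = n,
      pct = round(100 * sum(v == "Y") / n, 2))
  }
  if (!length(out)) stop_validation("no feature columns (OP/EC/AL/HH/FV) found")
  do.call(rbind, out)
}

#' Relative ratio of post-treatment to baseline group means
#'
#' The degree of variation between the baseline and post-injection groups,
#' expressed as the post-treatment mean as a percentage of the baseline mean
#' and reported to 2 decimals. `100 - RR` is the mean percent decrease.
#'
#' @param baseline_mean,post_mean Group means; `baseline_mean` must be
#'   nonzero.
#' @return Percentage, rounded to 2 decimals.
#' @export
relative_ratio <- function(baseline_mean, post_mean) {
  if (!is_scalar_number(baseline_mean) || baseline_mean == 0)
    stop_undefined("relative ratio is undefined for a zero baseline mean")
  round(100 * post_mean / baseline_mean, 2)
}

# Exact two-sided signed-rank p by enumeration over all 2^n sign assignments
# of the tie-averaged ranks of |d| (zero differences dropped first).
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  # distribution of W+ over all sign assignments, via polynomial expansion
  probs <- 1
  offsets <- 0
  for (r in rk) {
    offsets <- c(offsets, offsets + r)
    probs <- c(probs, probs)
  }
  tot <- 2^n
  lo <- sum(probs[offsets <= w_obs + 1e-9]) / tot
  hi <- sum(probs[offsets >= w_obs - 1e-9]) / tot
  min(1, 2 * min(lo, hi))
}

# Exact two-sided rank-sum (Mann-Whitney) p by enumeration over all
# choose(n1+n2, n1) assignments of the tie-averaged pooled ranks.
exact_rank_sum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  rk <- rank(c(x, y))
  w_obs <- sum(rk[seq_len(n1)])
  sets <- combn(n1 + n2, n1)
  w_all <- apply(sets, 2, function(s) sum(rk[s]))
  lo <- mean(w_all <= w_obs + 1e-9)
  hi <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

#' Rank tests for biomarker change
#'
#' Two-sided p-value for the difference between baseline and post-injection
#' biomarker values. `method = "rank_sum"` treats the two timepoints as
#' independent groups (Wilcoxon rank-sum / Mann-Whitney); `"signed_rank"` is
#' the paired Wilcoxon signed-rank test. Small samples use exact enumeration
#' of the null (all sign assignments for the signed-rank test with `n <= 12`
#' informative pairs; all rank assignments for the rank-sum test with
#' `n1 + n2 <= 12`), which stays exact under ties; larger samples use the
#' normal approximation with tie correction.
#'
#' @param baseline,post Numeric vectors of equal length (pairs with missing
#'   values are dropped).
#' @param method `"rank_sum"` (default) or `"signed_rank"`.
#' @return The two-sided p-value.
#' @export
paired_change_test <- function(baseline, post,
                               method = c("rank_sum", "signed_rank")) {
  method <- match.arg(method)
  if (length(baseline) != length(post))
    stop_validation("baseline and post must have equal length")
  ok <- is.finite(baseline) & is.finite(post)
  baseline <- baseline[ok]; post <- post[ok]
  if (length(baseline) < 3L) stop_validation("need at least 3 complete pairs")
  if (method == "signed_rank") {
    d <- post - baseline
    if (all(d == 0)) {
      warning("all paired differences are zero; p = 1")
      return(1)
    }
    if (sum(d != 0) <= 12L) return(exact_signed_rank_p(d))
    return(suppressWarnings(
      wilcox.test(post, baseline, paired = TRUE, exact = FALSE,
                  correct = TRUE)$p.value))
  }
  mann_whitney_p(baseline, post)
}

# Shared Mann-Whitney machinery (exact enumeration for small pooled n).
mann_whitney_p <- function(x, y) {
  if (length(x) + length(y) <= 12L) return(exact_rank_sum_p(x, y))
  suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
}

#' Compare a biomarker between the stable and unstable subgroups
#'
#' Eyes needing one or two injections over follow-up form the stable group;
#' more than two, the unstable group. The baseline biomarker values of the
#' two groups are compared with a two-sided Mann-Whitney U-test (exact for
#' small pooled samples).
#'
#' @param records Data frame with a `n_injections` column and the biomarker
#'   column named by `biomarker`.
#' @param biomarker Column name of the biomarker to compare.
#' @return List with `p_value`, group sizes and group means.
#' @export
group_compare <- function(records, biomarker) {
  records <- as.data.frame(records)
  if (!"n_injections" %in% names(records))
    stop_validation("records need an `n_injections` column")
  if (!biomarker %in% names(records))
    stop_validation(sprintf("no column '%s' in records", biomarker))
  stable <- records$n_injections <= 2
  x <- records[[biomarker]][stable]
  y <- records[[biomarker]][!stable]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y))
    stop_validation("both stable and unstable groups must be nonempty")
  list(p_value = mann_whitney_p(x, y),
       n_stable = length(x), n_unstable = length(y),
       mean_stable = mean(x), mean_unstable = mean(y))
}

#' Correlation strength label
#'
#' Maps the absolute magnitude of a Spearman coefficient to the conventional
#' strength bins: `>= 0.90` very strong, `0.70-0.89` strong, `0.40-0.69`
#' moderate, `0.10-0.39` weak, `< 0.10` negligible.
#'
#' @param r Correlation coefficient (vectorized).
#' @return Character vector of labels.
#' @export
correlation_strength <- function(r) {
  a <- abs(r)
  out <- character(length(r))
  out[a >= 0.90] <- "very strong"
  out[a >= 0.70 & a < 0.90] <- "strong"
  out[a >= 0.40 & a < 0.70] <- "moderate"
  out[a >= 0.10 & a < 0.40] <- "weak"
  out[a < 0.10] <- "negligible"
  out[is.na(r)] <- NA_character_
  out
}

#' Spearman rank correlation with a strength label
#'
#' Rank correlation with tie-averaged ranks, a two-sided p-value, and the
#' strength label of [correlation_strength()].
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return List with `r`, `p_value`, `label`, `n`.
#' @export
spearman_with_label <- function(x, y) {
  if (length(x) != length(y)) stop_validation("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_validation("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop_undefined("Spearman r is undefined for a constant vector")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  r <- unname(ct$estimate)
  list(r = r, p_value = ct$p.value, label = correlation_strength(r),
       n = length(x))
}

#' Percent change of a biomarker
#'
#' `100 * (post - baseline) / baseline`, per eye.
#'
#' @param baseline,post Numeric vectors.
#' @return Percent-change vector (NA where baseline is 0 or missing).
#' @export
percent_change <- function(baseline, post) {
  out <- 100 * (post - baseline) / baseline
  out[!is.finite(out)] <- NA_real_
  out
}

# p-value display convention: 3 decimals, floored at "<0.001".
format_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))

#' Paired baseline / post-injection change report
#'
#' For each biomarker, computes group means and SDs at baseline and after
#' injection, two-sided rank-test p-values (both the rank-sum convention and
#' the paired signed-rank test), the relative ratio `RR = 100 x post-mean /
#' baseline-mean` computed from group means, the percent decrease `100 - RR`,
#' and per-eye percent-change vectors for downstream correlation analysis.
#' Eyes lacking a post-injection panel (all post biomarkers missing) are
#' excluded, mirroring lesions that are unidentifiable after treatment.
#'
#' @param baseline,post Data frames of per-eye biomarker panels with identical
#'   column names and row order (one row per eye); see
#'   [as.data.frame.biomarker_panel()] for the conventional columns.
#' @param biomarkers Columns to report on (default: all shared numeric
#'   columns).
#' @return List of class `change_report`: `summary` (one row per biomarker:
#'   `biomarker, n, baseline_mean, baseline_sd, post_mean, post_sd,
#'   p_rank_sum, p_signed_rank, p_display, rr_pct, decrease_pct`),
#'   `percent_change` (eyes x biomarkers), `n_included`, `n_excluded`, and
#'   `p_method` metadata noting that the rank-sum column mirrors the
#'   published convention while the signed-rank column is the standard paired
#'   choice.
#' @export
build_change_report <- function(baseline, post, biomarkers = NULL) {
  baseline <- as.data.frame(baseline)
  post <- as.data.frame(post)
  if (nrow(baseline) != nrow(post))
    stop_validation("baseline and post must have one row per eye each")
  shared <- intersect(names(baseline), names(post))
  num <- shared[vapply(baseline[shared], is.numeric, logical(1)) &
                vapply(post[shared], is.numeric, logical(1))]
  biomarkers <- biomarkers %||% num
  missing_cols <- setdiff(biomarkers, num)
  if (length(missing_cols))
    stop_validation(sprintf("biomarkers not present in both panels: %s",
                            paste(missing_cols, collapse = ", ")))
  has_post <- rowSums(!is.na(post[biomarkers])) > 0
  if (sum(has_post) < 3L)
    stop_validation("need at least 3 eyes with both panels")
  b <- baseline[has_post, biomarkers, drop = FALSE]
  p <- post[has_post, biomarkers, drop = FALSE]
  rows <- lapply(biomarkers, function(m) {
    ok <- is.finite(b[[m]]) & is.finite(p[[m]])
    x <- b[[m]][ok]; y <- p[[m]][ok]
    if (length(x) < 3L)
      return(data.frame(biomarker = m, n = length(x), baseline_mean = NA,
                        baseline_sd = NA, post_mean = NA, post_sd = NA,
                        p_rank_sum = NA, p_signed_rank = NA, p_display = NA,
                        rr_pct = NA, decrease_pct = NA))
    rr <- relative_ratio(mean(x), mean(y))
    prs <- paired_change_test(x, y, "rank_sum")
    psr <- suppressWarnings(paired_change_test(x, y, "signed_rank"))
    data.frame(biomarker = m, n = length(x),
               baseline_mean = mean(x), baseline_sd = sd(x),
               post_mean = mean(y), post_sd = sd(y),
               p_rank_sum = prs, p_signed_rank = psr,
               p_display = format_p(prs),
               rr_pct = rr, decrease_pct = round(100 - rr, 2))
  })
  pc <- as.data.frame(lapply(biomarkers, function(m) percent_change(b[[m]], p[[m]])))
  names(pc) <- biomarkers
  structure(list(summary = do.call(rbind, rows), percent_change = pc,
                 n_included = sum(has_post), n_excluded = sum(!has_post),
                 p_method = paste("p_rank_sum follows the rank-sum convention of the",
                                  "source analysis; p_signed_rank is the standard",
                                  "paired signed-rank test")),
            class = "change_report")
}

#' @export
print.change_report <- function(x, ...) {
  cat(sprintf("<change_report> %d eyes included, %d excluded\n",
              x$n_included, x$n_excluded))
  s <- x$summary
  s[] <- lapply(s, function(v) if (is.numeric(v)) signif(v, 4) else v)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Correlate biomarker percent changes with the CRT percent change
#'
#' Spearman correlation (with strength label) of each biomarker's per-eye
#' percent change against the percent change of central retinal thickness.
#'
#' @param report A [build_change_report()] result whose panels included a
#'   `CRT` column, or a data.frame of percent changes containing `CRT`.
#' @param against Reference column (default `"CRT"`).
#' @return Data frame `biomarker, r, p_value, p_display, label, n`.
#' @export
correlate_percent_change <- function(report, against = "CRT") {
  pc <- if (inherits(report, "change_report")) report$percent_change else as.data.frame(report)
  if (!against %in% names(pc))
    stop_validation(sprintf("no '%s' column in the percent-change table", against))
  ref <- pc[[against]]
  marks <- setdiff(names(pc), against)
  rows <- lapply(marks, function(m) {
    s <- tryCatch(spearman_with_label(pc[[m]], ref),
                  octamorph_error = function(e) NULL)
    if (is.null(s))
      return(data.frame(biomarker = m, r = NA, p_value = NA, p_display = NA,
                        label = NA, n = sum(is.finite(pc[[m]]) & is.finite(ref))))
    data.frame(biomarker = m, r = s$r, p_value = s$p_value,
               p_display = format_p(s$p_value), label = s$label, n = s$n)
  })
  do.call(rbind, rows)
}
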