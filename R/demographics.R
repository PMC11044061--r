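#' Demographic and clinical comparison table
#'
#' Compares the two diagnosis groups variable by variable, mirroring the
#' layout of a clinical characteristics table: continuous variables get a
#' two-sample t test (pooled by default; Welch when an F variance-ratio
#' screen rejects equal variances at alpha = 0.05), categorical variables get
#' an uncorrected Pearson chi-square on the group x category count table.
#'
#' @param cohort Cohort data.frame with at least \code{diagnosis} plus the
#'   compared columns; both diagnosis groups must be non-empty.
#' @param continuous Continuous columns to compare.
#' @param categorical Categorical columns to compare.
#' @param var_alpha Significance level of the variance-ratio screen.
#' @return Data.frame with one row per variable: per-group summaries
#'   (\code{mean (sd)} or \code{n1/n2/...} counts), test name, statistic,
#'   df and p value.
#' @export
demographics_table <- function(cohort,
                               continuous = c("age", "education", "cdr_sb",
                                              "tiv", "days_mri_npiq"),
                               categorical = c("sex", "disinhibition_present",
                                               "disinhibition_severity",
                                               "scanner"),
                               var_alpha = 0.05) {
  if (!"diagnosis" %in% names(cohort)) stop("cohort needs a 'diagnosis' column")
  groups <- levels(factor(cohort$diagnosis))
  if (length(groups) != 2)
    stop("input error: demographics table needs exactly 2 diagnosis groups, got ",
         length(groups))
  g1 <- cohort[cohort$diagnosis == groups[1], , drop = FALSE]
  g2 <- cohort[cohort$diagnosis == groups[2], , drop = FALSE]
  if (nrow(g1) == 0 || nrow(g2) == 0) stop("input error: empty diagnosis group")

  rows <- list()
  for (v in intersect(continuous, names(cohort))) {
    x1 <- g1[[v]]; x2 <- g2[[v]]
    welch <- var.test(x1, x2)$p.value < var_alpha
    tt <- if (welch) {
      welch_t_test(mean(x1), sd(x1), length(x1), mean(x2), sd(x2), length(x2))
    } else {
      pooled_t_test(mean(x1), sd(x1), length(x1), mean(x2), sd(x2), length(x2))
    }
    rows[[v]] <- data.frame(
      variable = v,
      group1 = sprintf("%.2f (%.2f)", mean(x1), sd(x1)),
      group2 = sprintf("%.2f (%.2f)", mean(x2), sd(x2)),
      test = if (welch) "Welch t" else "pooled t",
      statistic = tt$t, df = tt$df, p = tt$p,
      stringsAsFactors = FALSE
    )
  }
  for (v in intersect(categorical, names(cohort))) {
    f <- factor(cohort[[v]])
    f <- droplevels(f)
    if (nlevels(f) < 2) next
    counts <- table(factor(cohort$diagnosis, levels = groups), f)
    cs <- pearson_chi_square(as.matrix(counts))
    rows[[v]] <- data.frame(
      variable = v,
      group1 = paste(counts[1, ], collapse = "/"),
      group2 = paste(counts[2, ], collapse = "/"),
      test = "Pearson chi-square",
      statistic = cs$chi2, df = cs$df, p = cs$p,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "group1"] <- groups[1]
  names(out)[names(out) == "group2"] <- groups[2]
  rownames(out) <- NULL
  out
}
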