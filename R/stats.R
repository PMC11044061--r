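#' Partial eta squared
#'
#' Effect size for an ANOVA/ANCOVA effect: \eqn{SS_{effect} /
#' (SS_{effect} + SS_{error})}.
#'
#' @param ss_effect Effect sum of squares (>= 0).
#' @param ss_error Error sum of squares (> 0).
#' @return Value in \[0, 1\].
#' @export
partial_eta_squared <- function(ss_effect, ss_error) {
  if (any(ss_effect < 0)) stop("ss_effect must be non-negative")
  if (any(ss_error <= 0)) stop("ss_error must be positive")
  ss_effect / (ss_effect + ss_error)
}

check_t_inputs <- function(sd1, n1, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
}

#' Pooled two-sample t test from summary statistics
#'
#' Equal-variance (Student) t test computed from group means, SDs and sizes,
#' as used for demographic comparison tables when only printed summaries are
#' available. df = n1 + n2 - 2; two-sided p.
#'
#' @param mean1,sd1,n1 First group's mean, SD and size.
#' @param mean2,sd2,n2 Second group's mean, SD and size.
#' @return List with \code{t}, \code{df}, \code{p}.
#' @export
#' @examples
#' pooled_t_test(74.15, 7.53, 111, 64.46, 7.03, 75)$t  # 8.84
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  check_t_inputs(sd1, n1, sd2, n2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Welch two-sample t test from summary statistics
#'
#' Unequal-variance t test with Welch-Satterthwaite fractional degrees of
#' freedom, computed from group summaries.
#'
#' @inheritParams pooled_t_test
#' @return List with \code{t}, \code{df}, \code{p}.
#' @export
welch_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  check_t_inputs(sd1, n1, sd2, n2)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson chi-square test for a contingency table
#'
#' Uncorrected (no continuity correction) Pearson chi-square on an r x c
#' count table; df = (r - 1)(c - 1). All row and column margins must be
#' positive.
#'
#' @param table Numeric count matrix, at least 2 x 2, non-negative.
#' @return List with \code{chi2}, \code{df}, \code{p}.
#' @export
#' @examples
#' pearson_chi_square(rbind(c(27, 84), c(62, 13)))$chi2  # 61.05
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) stop("table must be at least 2 x 2")
  if (any(table < 0) || anyNA(table)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("domain error: zero row or column margin")
  res <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Repeated-measures ANCOVA for subnetwork metrics
#'
#' Fits the 2 (disinhibition presence) x 2 (diagnosis) x D (density threshold)
#' design for one subnetwork metric. Density is a within-subject factor with a
#' complete measurement per subject; between-subject effects (diagnosis,
#' disinhibition, their interaction) are tested on the per-subject mean across
#' density levels, which is exact for between-subject effects in a balanced
#' repeated design with subject-constant covariates. Sums of squares are
#' Type III with effects (sum-to-zero) coding for the crossed factors;
#' scanner is dummy coded with Siemens as the reference. Within-subject
#' (threshold) means are reported descriptively.
#'
#' Returns, per effect: F, numerator/denominator df, p and partial eta
#' squared, plus an adjusted contrast estimate for the two-level factors
#' (bvFTD - DAT; disinhibited - non-disinhibited), whose sign gives the
#' direction of the effect.
#'
#' @param metrics Long-format metric table from [compute_metrics()].
#' @param cohort Cohort data.frame ([simulate_cohort()] schema).
#' @param response Metric column to analyse: \code{"global_efficiency"} or
#'   \code{"transitivity"} (or \code{"small_worldness"} if computed).
#' @param network Which subnetwork's rows to analyse (e.g. \code{"CCN"}).
#' @param covariates Covariate column names in \code{cohort}; default age,
#'   sex, TIV, days between MRI and symptom assessment, dementia severity
#'   (CDR-SB), scanner and education. Use \code{character(0)} for none.
#' @return Object of class \code{msn_ancova}: list with \code{effects} (one
#'   row per model term), \code{model} (the underlying \code{lm} fit),
#'   \code{threshold_means}, \code{response}, \code{network}, \code{n}.
#' @export
rm_ancova <- function(metrics, cohort, response = "global_efficiency",
                      network = "CCN",
                      covariates = c("age", "sex", "tiv", "days_mri_npiq",
                                     "cdr_sb", "scanner", "education")) {
  if (!response %in% names(metrics)) stop("no metric column '", response, "'")
  dat <- metrics[metrics$network == network, , drop = FALSE]
  if (nrow(dat) == 0) stop("no rows for network '", network, "'")
  densities <- sort(unique(dat$density))
  tab <- table(dat$subject_id)
  if (any(tab != length(densities)))
    stop("input error: unbalanced within-subject factor; every subject needs a ",
         "measurement at every density")
  if (anyNA(dat[[response]])) stop("input error: missing metric values")

  agg <- aggregate(dat[[response]], by = list(subject_id = dat$subject_id), FUN = mean)
  names(agg)[2] <- ".y"
  miss <- setdiff(agg$subject_id, cohort$subject_id)
  if (length(miss) > 0)
    stop("subjects missing from cohort: ", paste(head(miss, 5), collapse = ", "))
  d <- merge(agg, cohort, by = "subject_id", sort = TRUE)

  d$diagnosis <- factor(d$diagnosis, levels = c("DAT", "bvFTD"))
  d$disinhibition <- factor(d$disinhibition_present, levels = c(FALSE, TRUE))
  cells <- table(d$diagnosis, d$disinhibition)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("estimability error: empty design cell ",
         rownames(cells)[empty[1]], " x disinhibition=",
         colnames(cells)[empty[2]])
  }
  bad <- setdiff(covariates, names(d))
  if (length(bad) > 0)
    stop("input error: covariate(s) not in cohort: ", paste(bad, collapse = ", "))
  if (length(covariates) > 0 && !all(complete.cases(d[covariates])))
    stop("input error: missing covariate values")

  contr <- list(diagnosis = "contr.sum", disinhibition = "contr.sum")
  if ("sex" %in% covariates) {
    d$sex <- factor(d$sex, levels = intersect(c("M", "F"), unique(as.character(d$sex))))
    contr$sex <- "contr.sum"
  }
  if ("scanner" %in% covariates) {
    d$scanner <- droplevels(factor(d$scanner,
                                   levels = c("Siemens", "GE", "Philips")))
    if (nlevels(d$scanner) > 1) contr$scanner <- "contr.treatment"
    else covariates <- setdiff(covariates, "scanner")
  }
  rhs <- paste(c("diagnosis * disinhibition", covariates), collapse = " + ")
  fit <- lm(stats::as.formula(paste(".y ~", rhs)), data = d, contrasts = contr)
  if (any(is.na(coef(fit))))
    stop("estimability error: rank-deficient design (aliased coefficients: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "), ")")

  aov3 <- car::Anova(fit, type = 3)
  ss_err <- aov3["Residuals", "Sum Sq"]
  df_den <- aov3["Residuals", "Df"]
  terms <- setdiff(rownames(aov3), c("(Intercept)", "Residuals"))
  eff <- data.frame(
    effect = terms,
    ss = aov3[terms, "Sum Sq"],
    df_num = aov3[terms, "Df"],
    df_den = df_den,
    F = aov3[terms, "F value"],
    p = aov3[terms, "Pr(>F)"],
    partial_eta_sq = partial_eta_squared(aov3[terms, "Sum Sq"], ss_err),
    stringsAsFactors = FALSE
  )
  rownames(eff) <- NULL
  # adjusted contrasts for the sum-coded two-level factors:
  # level2 - level1 = -2 * beta under contr.sum
  cf <- coef(fit)
  eff$estimate <- NA_real_
  if ("diagnosis1" %in% names(cf))
    eff$estimate[eff$effect == "diagnosis"] <- -2 * cf[["diagnosis1"]]
  if ("disinhibition1" %in% names(cf))
    eff$estimate[eff$effect == "disinhibition"] <- -2 * cf[["disinhibition1"]]

  thr_means <- aggregate(dat[[response]], by = list(density = dat$density), FUN = mean)
  names(thr_means)[2] <- "mean"

  structure(list(effects = eff, model = fit, threshold_means = thr_means,
                 response = response, network = network, n = nrow(d),
                 densities = densities, ss_error = ss_err,
                 call = match.call()),
            class = "msn_ancova")
}

#' @export
print.msn_ancova <- function(x, digits = 4, ...) {
  cat("Repeated-measures ANCOVA:", x$response, "in", x$network,
      sprintf("(n = %d, %d density levels)\n", x$n, length(x$densities)))
  focal <- x$effects[x$effects$effect %in%
                       c("diagnosis", "disinhibition", "diagnosis:disinhibition"), ]
  for (i in seq_len(nrow(focal))) {
    e <- focal[i, ]
    cat(sprintf("  %-26s F(%.0f, %.0f) = %.2f, p = %.4g, partial eta^2 = %.3f\n",
                e$effect, e$df_num, e$df_den, e$F, e$p, e$partial_eta_sq))
  }
  invisible(x)
}

#' @export
summary.msn_ancova <- function(object, ...) {
  cat("Between-subject effects (Type III, response = per-subject mean over",
      length(object$densities), "densities):\n\n")
  eff <- object$effects
  eff$F <- round(eff$F, 3)
  eff$p <- signif(eff$p, 4)
  eff$partial_eta_sq <- round(eff$partial_eta_sq, 4)
  print(eff, row.names = FALSE)
  cat("\nThreshold (within-subject) means:\n")
  print(object$threshold_means, row.names = FALSE)
  invisible(object)
}

#' @export
coef.msn_ancova <- function(object, ...) coef(object$model)
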