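## The cohort statistical battery: normality and variance-homogeneity
## checks, pooled-variance t-tests on physical characteristics, two-way (or
## one-way) ANOVA of IntraMF with Tukey post-hoc, median tests and
## Kruskal-Wallis for SF/M and IMAT, and Pearson correlation matrices.
## Every test yields a uniform record (test, variables, groups, statistic,
## df, p, n per group) so a run's report is machine-readable.

statsRecord <- function(test, variables, groups, statistic, df = NA_real_,
                        p = NA_real_, n = NULL, extra = list()) {
  c(list(test = test, variables = variables, groups = groups,
         statistic = unname(statistic), df = unname(df), p = unname(p),
         n = n), extra)
}

#' Normality and variance-homogeneity checks
#'
#' Kolmogorov--Smirnov test of each group against a normal with that group's
#' estimated mean and SD, plus Levene's test (median-centred,
#' Brown--Forsythe form via \code{car::leveneTest}) of variance equality
#' across groups.  The flags inform the reader; they trigger no automatic
#' test switching, since parametric and rank-based tests are assigned per
#' variable by design.
#'
#' @param values numeric vector.
#' @param groups factor/character vector of group labels, same length.
#' @return List with per-group KS records and one Levene record.  A constant
#'   group is flagged (\code{normalityUndefined}) rather than tested.
#' @export
assumptionChecks <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  ks <- lapply(split(values, groups), function(v) {
    if (length(v) < 3)
      stop("normality check needs n >= 3 per group")
    if (stats::sd(v) == 0)
      return(list(statistic = NA_real_, p = NA_real_,
                  normalityUndefined = TRUE, n = length(v)))
    kt <- suppressWarnings(stats::ks.test(v, "pnorm", mean(v), stats::sd(v)))
    list(statistic = unname(kt$statistic), p = unname(kt$p.value),
         normalityUndefined = FALSE, n = length(v))
  })
  lev <- if (all(vapply(split(values, groups), stats::sd, 1) == 0) ||
             length(unique(groups)) < 2) {
    list(statistic = 0, df = NA_real_, p = NA_real_)
  } else {
    lt <- car::leveneTest(values ~ factor(groups))
    list(statistic = lt[1, "F value"],
         df = c(lt[1, "Df"], lt[2, "Df"]), p = lt[1, "Pr(>F)"])
  }
  list(ks = ks,
       levene = statsRecord("levene", "values", unique(groups),
                            lev$statistic, lev$df, lev$p,
                            n = lengths(split(values, groups))))
}

#' Two-group t-test on a cohort variable
#'
#' Two-sided pooled-variance (Student) t-test by default, Welch by flag.
#' Also computable from group summaries (means, SDs, n) alone, for checking
#' published group tables without subject-level data.
#'
#' @param variable column name in \code{cohort}, or NULL when summaries are
#'   given.
#' @param cohort data.frame with a \code{group} column, or NULL.
#' @param welch use the Welch unequal-variance form.
#' @param means,sds,ns optional length-2 summaries (used when cohort is NULL).
#' @return A record list with t, df and p.
#' @examples
#' groupTTest(means = c(64.0, 71.2), sds = c(11.5, 11.8), ns = c(10, 10))$p
#' @export
groupTTest <- function(variable = NULL, cohort = NULL, welch = FALSE,
                       means = NULL, sds = NULL, ns = NULL) {
  if (!is.null(cohort)) {
    v <- split(cohort[[variable]], cohort$group)
    if (length(v) != 2 || any(lengths(v) < 2))
      stop("t-test needs two groups with n >= 2 each")
    tt <- stats::t.test(v[[1]], v[[2]], var.equal = !welch)
    return(statsRecord(if (welch) "welch_t" else "pooled_t", variable,
                       names(v), tt$statistic, tt$parameter, tt$p.value,
                       n = lengths(v)))
  }
  stopifnot(length(means) == 2, length(sds) == 2, length(ns) == 2)
  if (welch) {
    se2 <- sds^2 / ns
    t <- (means[1] - means[2]) / sqrt(sum(se2))
    df <- sum(se2)^2 / sum(se2^2 / (ns - 1))
  } else {
    sp2 <- sum((ns - 1) * sds^2) / (sum(ns) - 2)
    t <- (means[1] - means[2]) / sqrt(sp2 * sum(1 / ns))
    df <- sum(ns) - 2
  }
  p <- 2 * stats::pt(-abs(t), df)
  statsRecord(if (welch) "welch_t_summary" else "pooled_t_summary",
              "summary", c("1", "2"), t, df, p, n = ns)
}

#' Reshape a quantified cohort to subject x muscle long form
#'
#' @param cohort quantified cohort data.frame (see [quantifyCohort()]).
#' @return data.frame with columns subject_id, group, gmfcs, muscle, intramf.
#' @export
intramfLong <- function(cohort) {
  cols <- paste0("intramf_", tolower(MUSCLE_NAMES))
  if (!all(cols %in% names(cohort)))
    stop("cohort table lacks per-muscle IntraMF columns (",
         paste(setdiff(cols, names(cohort)), collapse = ", "),
         "); quantify the cohort first")
  do.call(rbind, lapply(seq_along(MUSCLE_NAMES), function(k) {
    data.frame(subject_id = cohort$subject_id, group = cohort$group,
               gmfcs = cohort$gmfcs, muscle = MUSCLE_NAMES[k],
               intramf = cohort[[cols[k]]], stringsAsFactors = FALSE)
  }))
}

#' ANOVA of IntraMF by GMFCS level and muscle
#'
#' Two-way fixed-effects ANOVA (Type II sums of squares, so unbalanced
#' designs are handled) of intramuscular fat with GMFCS level and muscle
#' identity as factors, followed by a Tukey HSD post-hoc on GMFCS levels.
#' Rows without a GMFCS level (the TD group) are excluded.  A one-way form
#' (GMFCS only) is available because group-level contrasts are often
#' reported from it.
#'
#' @param long long-form table from [intramfLong()], or any data.frame with
#'   columns gmfcs, muscle, intramf.
#' @param twoWay include muscle identity as a second factor (default TRUE).
#' @return List with one record per factor and \code{tukey}, the pairwise
#'   GMFCS comparison table.
#' @export
anovaIntramf <- function(long, twoWay = TRUE) {
  d <- long[!is.na(long$gmfcs), , drop = FALSE]
  d$gmfcs <- factor(d$gmfcs)
  d$muscle <- factor(d$muscle)
  if (nlevels(d$gmfcs) < 2)
    stop("ANOVA needs >= 2 GMFCS levels, got ", nlevels(d$gmfcs))
  if (twoWay && nlevels(d$muscle) < 2)
    stop("ANOVA needs >= 2 muscles for the two-way form")
  form <- if (twoWay) intramf ~ gmfcs + muscle else intramf ~ gmfcs
  fit <- stats::aov(form, data = d)
  ## Type II sums of squares by explicit model comparison (SS of a factor
  ## adjusted for the other, no interaction), robust to zero residuals
  terms <- if (twoWay) c("gmfcs", "muscle") else "gmfcs"
  rssFull <- stats::deviance(fit)
  dfResid <- stats::df.residual(fit)
  recs <- lapply(terms, function(tm) {
    reducedForm <- if (twoWay)
      stats::reformulate(setdiff(terms, tm), response = "intramf")
    else intramf ~ 1
    rssRed <- stats::deviance(stats::lm(reducedForm, data = d))
    dfTerm <- nlevels(d[[tm]]) - 1L
    ss <- rssRed - rssFull
    fstat <- (ss / dfTerm) / (rssFull / dfResid)
    p <- stats::pf(fstat, dfTerm, dfResid, lower.tail = FALSE)
    statsRecord("anova_typeII", tm, levels(d$gmfcs),
                fstat, c(dfTerm, dfResid), p,
                n = as.integer(table(d$gmfcs)),
                extra = list(sumsq = ss, sumsqResid = rssFull))
  })
  names(recs) <- terms
  tk <- stats::TukeyHSD(fit, which = "gmfcs")$gmfcs
  list(effects = recs,
       tukey = data.frame(comparison = rownames(tk), tk,
                          row.names = NULL, check.names = FALSE))
}

#' Nonparametric two-group median test
#'
#' Dichotomises all values at the grand median (ties assigned to the
#' "<= median" cell) and tests group-by-side association on the 2x2 table:
#' Fisher's exact test for total n below 40, chi-square with continuity
#' correction otherwise.
#'
#' @param values numeric vector (combined n >= 4).
#' @param groups two-level group labels.
#' @return A record with p, the 2x2 table, and the convention used.
#' @export
medianTest <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  if (length(values) < 4) stop("median test needs combined n >= 4")
  if (length(unique(groups)) != 2) stop("median test compares two groups")
  if (length(unique(values)) == 1)
    return(statsRecord("median_test", "values", unique(groups),
                       NA_real_, p = NA_real_, n = lengths(split(values, groups)),
                       extra = list(undefined = TRUE,
                                    reason = "all values equal")))
  gm <- stats::median(values)
  side <- factor(values <= gm, levels = c(TRUE, FALSE),
                 labels = c("le_median", "gt_median"))
  tab <- table(factor(groups), side)
  n <- sum(tab)
  if (n < 40) {
    ft <- stats::fisher.test(tab)
    rec <- statsRecord("median_test_fisher", "values", rownames(tab),
                       NA_real_, p = ft$p.value,
                       n = as.integer(rowSums(tab)))
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab))
    rec <- statsRecord("median_test_chisq", "values", rownames(tab),
                       ct$statistic, ct$parameter, ct$p.value,
                       n = as.integer(rowSums(tab)))
  }
  rec$table <- unclass(tab)
  rec$grandMedian <- gm
  rec$tieConvention <- "values equal to the grand median count as <= median"
  rec
}

#' Kruskal--Wallis test across ordered groups
#'
#' Rank-based comparison (tie-corrected H, chi-square reference) of a
#' variable across GMFCS levels or any grouping.
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 non-empty groups, total n >= 5).
#' @return A record with H, df and p; all-tied input is flagged undefined.
#' @export
kruskalWallis <- function(values, groups) {
  groups <- as.character(groups)
  keep <- !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  if (length(unique(groups)) < 2) stop("Kruskal-Wallis needs >= 2 groups")
  if (length(values) < 5) stop("Kruskal-Wallis needs total n >= 5")
  if (length(unique(values)) == 1)
    return(statsRecord("kruskal_wallis", "values", unique(groups),
                       NA_real_, p = NA_real_,
                       n = lengths(split(values, groups)),
                       extra = list(undefined = TRUE,
                                    reason = "all values tied")))
  kt <- stats::kruskal.test(values, factor(groups))
  statsRecord("kruskal_wallis", "values", sort(unique(groups)),
              kt$statistic, kt$parameter, kt$p.value,
              n = lengths(split(values, groups)))
}

#' Pearson correlation matrix over cohort columns
#'
#' Pairwise Pearson r with two-sided t-distribution p-values (n - 2 df)
#' for the named columns, optionally within one group.  Zero-variance
#' columns yield flagged undefined records instead of numbers.
#'
#' @param cohort data.frame.
#' @param columns character vector of numeric column names (>= 2).
#' @param group optional group label to subset on.
#' @return data.frame with one row per pair: var1, var2, n, r, p, undefined.
#' @export
correlationMatrix <- function(cohort, columns, group = NULL) {
  if (!is.null(group)) cohort <- cohort[cohort$group == group, , drop = FALSE]
  stopifnot(length(columns) >= 2, all(columns %in% names(cohort)))
  pairs <- utils::combn(columns, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- cohort[[pairs[1, k]]]; b <- cohort[[pairs[2, k]]]
    ok <- stats::complete.cases(a, b)
    a <- a[ok]; b <- b[ok]
    if (sum(ok) < 3)
      stop("correlation needs >= 3 complete pairs for ",
           pairs[1, k], " vs ", pairs[2, k])
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      return(data.frame(var1 = pairs[1, k], var2 = pairs[2, k], n = sum(ok),
                        r = NA_real_, p = NA_real_, undefined = TRUE))
    ct <- stats::cor.test(a, b)
    data.frame(var1 = pairs[1, k], var2 = pairs[2, k], n = sum(ok),
               r = unname(ct$estimate), p = ct$p.value, undefined = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full cohort statistical battery
#'
#' Applies, to a quantified cohort table: (i) assumption checks and pooled
#' t-tests on the physical characteristics (age, mass, height, BMI);
#' (ii) the two-way ANOVA of IntraMF by GMFCS level and muscle with Tukey
#' post-hoc (plus the one-way GMFCS form); (iii) median tests of SF/M and
#' IMAT between groups; (iv) Kruskal--Wallis of SF/M and IMAT across GMFCS
#' levels; and (v) Pearson correlations — muscle-by-muscle IntraMF and the
#' SF/M--IMAT--IntraMF triangle — within each group.  No multiplicity
#' correction is applied by default; Holm adjustment over each family can be
#' switched on.
#'
#' @param cohort quantified cohort data.frame from [quantifyCohort()].
#' @param holm apply Holm adjustment within each record family.
#' @return A nested list of records, class \code{statsReport}.
#' @export
runStatsBattery <- function(cohort, holm = FALSE) {
  report <- list()
  phys <- intersect(c("age", "mass_kg", "height_m", "bmi"), names(cohort))
  report$physical <- lapply(phys, function(v) {
    list(assumptions = assumptionChecks(cohort[[v]], cohort$group),
         ttest = groupTTest(v, cohort))
  })
  names(report$physical) <- phys

  quantVars <- intersect(c("imat", "sf_m", "intramf_mean"), names(cohort))
  report$quantAssumptions <- lapply(quantVars, function(v)
    assumptionChecks(cohort[[v]], cohort$group))
  names(report$quantAssumptions) <- quantVars

  long <- intramfLong(cohort)
  report$anovaTwoWay <- anovaIntramf(long, twoWay = TRUE)
  report$anovaOneWay <- anovaIntramf(long, twoWay = FALSE)

  report$medianTests <- list(
    sf_m = medianTest(cohort$sf_m, cohort$group),
    imat = medianTest(cohort$imat, cohort$group))

  bscp <- cohort[cohort$group == "BSCP", , drop = FALSE]
  report$kruskalGmfcs <- list(
    sf_m = kruskalWallis(bscp$sf_m, bscp$gmfcs),
    imat = kruskalWallis(bscp$imat, bscp$gmfcs))

  muscleCols <- paste0("intramf_", tolower(MUSCLE_NAMES))
  report$correlations <- lapply(c("BSCP", "TD"), function(g) {
    list(intramfPairs = correlationMatrix(cohort, muscleCols, group = g),
         composition = correlationMatrix(
           cohort, c("sf_m", "imat", "intramf_mean"), group = g))
  })
  names(report$correlations) <- c("BSCP", "TD")

  if (holm) {
    adj <- function(df) { df$p_holm <- stats::p.adjust(df$p, "holm"); df }
    report$correlations <- lapply(report$correlations, function(x)
      lapply(x, adj))
  }
  class(report) <- "statsReport"
  report
}

#' Write a stats report as JSON
#'
#' @param report a \code{statsReport} from [runStatsBattery()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeStatsReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE, pretty = TRUE)
  invisible(path)
}
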