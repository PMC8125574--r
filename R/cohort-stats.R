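# Cohort statistics layer: sex comparisons (Student t, chi-square),
# reference comparisons (one-way ANOVA with Bonferroni pairwise ordering)
# and measurement reliability (ICC(2,1), two-way random effects, absolute
# agreement, single measurement). p-values come from the base R
# distribution functions; conventions are fixed here once: pooled-variance
# t, Pearson chi-square without continuity correction, Bonferroni as
# p-multiplication capped at 1.

#' Pooled-variance two-sample Student t test
#'
#' @param a,b numeric samples (each n >= 2).
#' @return A list with \code{statistic}, \code{df}, \code{p}, \code{method}.
#' @export
tTestTwoSample <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stopStats("t test needs at least 2 observations per group")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  if (se == 0) {
    ## zero pooled variance: identical constants give t = 0, p = 1 by convention
    if (mean(a) == mean(b))
      return(list(statistic = 0, df = na + nb - 2L, p = 1,
                  method = "Student t (pooled)"))
    stopStats("zero pooled variance with unequal means")
  }
  t <- (mean(a) - mean(b)) / se
  df <- na + nb - 2L
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df),
       method = "Student t (pooled)")
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' No continuity correction; df = 1. All margins must be positive.
#'
#' @param tab 2 x 2 matrix of nonnegative counts.
#' @return A list with \code{statistic}, \code{df}, \code{p}, \code{method}.
#' @export
chiSquare2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L)) || any(tab < 0))
    stopStats("need a 2 x 2 table of nonnegative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopStats("chi-square test undefined: a table margin is zero")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - E)^2 / E)
  list(statistic = x2, df = 1L, p = stats::pchisq(x2, 1L, lower.tail = FALSE),
       method = "Pearson chi-square (no continuity correction)")
}

#' One-way analysis of variance
#'
#' @param groups list of numeric samples (>= 2 groups, each n >= 2).
#' @return A list with \code{statistic} (F), \code{df} (df1, df2), \code{p},
#'   \code{method}.
#' @export
oneWayAnova <- function(groups) {
  if (length(groups) < 2L) stopStats("ANOVA needs at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stopStats("ANOVA needs at least 2 observations per group")
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  k <- length(groups); N <- length(x)
  gm <- mean(x)
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  df1 <- k - 1L; df2 <- N - k
  if (ssw == 0 && ssb == 0) stopStats("ANOVA undefined: all observations identical")
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, df = c(df1, df2), p = stats::pf(f, df1, df2, lower.tail = FALSE),
       method = "one-way ANOVA")
}

#' Bonferroni-corrected pairwise comparisons and group ordering
#'
#' All pairwise pooled t tests with p multiplied by the number of pairs
#' (capped at 1). The ordering string sorts groups by decreasing mean and
#' joins adjacent groups with ">" when their corrected p is below
#' \code{alpha}, "=" otherwise (e.g. "FEA > sTEA = WSL").
#'
#' @param groups named list of numeric samples.
#' @param alpha significance level (default 0.05).
#' @return A list with \code{ordering} (character) and \code{pairs}
#'   (data.frame of pairwise statistics, raw and corrected p).
#' @export
bonferroniPairwise <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stopStats("need at least 2 labeled groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stopStats("groups must be named")
  nm <- names(groups)
  cmb <- utils::combn(nm, 2L)
  m <- ncol(cmb)
  pairs <- do.call(rbind, lapply(seq_len(m), function(i) {
    tt <- tTestTwoSample(groups[[cmb[1L, i]]], groups[[cmb[2L, i]]])
    data.frame(groupA = cmb[1L, i], groupB = cmb[2L, i],
               statistic = tt$statistic, df = tt$df,
               p = tt$p, pAdj = min(tt$p * m, 1), stringsAsFactors = FALSE)
  }))
  means <- vapply(groups, mean, numeric(1))
  ord <- nm[order(means, decreasing = TRUE)]
  sep <- vapply(seq_len(length(ord) - 1L), function(i) {
    row <- pairs[(pairs$groupA == ord[i] & pairs$groupB == ord[i + 1L]) |
                   (pairs$groupB == ord[i] & pairs$groupA == ord[i + 1L]), ]
    if (row$pAdj[1L] < alpha) " > " else " = "
  }, character(1))
  ordering <- paste0(ord[1L], paste0(sep, ord[-1L], collapse = ""))
  list(ordering = ordering, pairs = pairs)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement, from the
#' classical mean squares: (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE)/n).
#'
#' @param ratings n_subjects x k_raters numeric matrix.
#' @return ICC estimate (numeric scalar).
#' @export
iccAbsoluteSingle <- function(ratings) {
  X <- as.matrix(ratings)
  n <- nrow(X); k <- ncol(X)
  if (n < 2L || k < 2L) stopStats("ICC needs >= 2 subjects and >= 2 ratings")
  if (stats::var(as.vector(X)) == 0) stopStats("ICC undefined: zero total variance")
  gm <- mean(X)
  rowM <- rowMeans(X); colM <- colMeans(X)
  msr <- k * sum((rowM - gm)^2) / (n - 1)
  msc <- n * sum((colM - gm)^2) / (k - 1)
  sse <- sum((X - outer(rowM, rep(1, k)) - outer(rep(1, n), colM) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Cohort summary tables: sex and reference comparisons
#'
#' Builds the three standard summary tables from per-knee measurement
#' records:
#' \itemize{
#'   \item \code{bySex}: MedL/LatL by sex for every reference, with the
#'     pooled t-test p (sex comparison per reference).
#'   \item \code{byReference}: per sex group (all/female/male), one-way
#'     ANOVA of MedL/LatL across references plus the Bonferroni pairwise
#'     ordering string.
#'   \item \code{widths}: ML, M'L', M'L'/ML, LD and LD/ML by sex (first
#'     reference), mean/sd/range and t-test p, plus the double/single peak
#'     2 x 2 chi-square (p is NA when one shape class is absent).
#' }
#'
#' @param records data.frame of per-knee measurements (rows as returned by
#'   \code{\link{measureResection}}) with additional columns \code{sex}
#'   ("female"/"male") and \code{knee} (id).
#' @param widthsReference reference used for the widths table (default the
#'   first reference present).
#' @return A list of data.frames \code{bySex}, \code{byReference},
#'   \code{widths}, \code{shapeCounts}.
#' @export
summarizeCohort <- function(records, widthsReference = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("MedL_LatL", "ML", "MpLp", "MpLp_ML_pct", "LD", "LD_ML_pct",
            "shape", "reference", "sex")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stopStats(paste0("records lack column(s): ", paste(missing, collapse = ", ")))
  refs <- unique(records$reference)
  if (is.null(widthsReference)) widthsReference <- refs[1L]
  if (!widthsReference %in% refs)
    stopStats(paste0("no records for widths reference ", widthsReference))
  if (min(table(records$sex[records$reference == refs[1L]])) < 2L)
    stopStats("need at least 2 knees per sex")

  bySex <- do.call(rbind, lapply(refs, function(r) {
    f <- records$MedL_LatL[records$reference == r & records$sex == "female"]
    m <- records$MedL_LatL[records$reference == r & records$sex == "male"]
    tt <- tTestTwoSample(f, m)
    data.frame(reference = r, nFemale = length(f), meanFemale = mean(f),
               sdFemale = stats::sd(f), nMale = length(m), meanMale = mean(m),
               sdMale = stats::sd(m), t = tt$statistic, p = tt$p,
               stringsAsFactors = FALSE)
  }))

  groupSets <- list(all = records, female = records[records$sex == "female", ],
                    male = records[records$sex == "male", ])
  byReference <- do.call(rbind, lapply(names(groupSets), function(g) {
    rr <- groupSets[[g]]
    groups <- lapply(refs, function(r) rr$MedL_LatL[rr$reference == r])
    names(groups) <- refs
    if (length(refs) >= 2L) {
      av <- oneWayAnova(groups)
      bp <- bonferroniPairwise(groups)
      data.frame(group = g, F = av$statistic, df1 = av$df[1L], df2 = av$df[2L],
                 p = av$p, ordering = bp$ordering, stringsAsFactors = FALSE)
    } else data.frame(group = g, F = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                      p = NA_real_, ordering = refs, stringsAsFactors = FALSE)
  }))

  w <- records[records$reference == widthsReference, ]
  wf <- w[w$sex == "female", ]; wm <- w[w$sex == "male", ]
  widths <- do.call(rbind, lapply(c("ML", "MpLp", "MpLp_ML_pct", "LD", "LD_ML_pct"),
                                  function(col) {
    tt <- tTestTwoSample(wf[[col]], wm[[col]])
    data.frame(parameter = col,
               meanFemale = mean(wf[[col]]), sdFemale = stats::sd(wf[[col]]),
               minFemale = min(wf[[col]]), maxFemale = max(wf[[col]]),
               meanMale = mean(wm[[col]]), sdMale = stats::sd(wm[[col]]),
               minMale = min(wm[[col]]), maxMale = max(wm[[col]]),
               t = tt$statistic, p = tt$p, stringsAsFactors = FALSE)
  }))

  shapeCounts <- data.frame(
    sex = c("female", "male"),
    double = c(sum(wf$shape == "double_peak"), sum(wm$shape == "double_peak")),
    single = c(sum(wf$shape == "single_peak"), sum(wm$shape == "single_peak")))
  tab <- as.matrix(shapeCounts[, c("double", "single")])
  shapeP <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) NA_real_
            else chiSquare2x2(tab)$p
  shapeCounts$p <- shapeP

  list(bySex = bySex, byReference = byReference, widths = widths,
       shapeCounts = shapeCounts)
}
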