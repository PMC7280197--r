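#' Holm-Sidak step-down adjustment of p-values
#'
#' Step-down Sidak procedure over a declared family of `m` comparisons: with
#' p-values sorted ascending, the i-th adjusted value is
#' \eqn{\max_{j \le i} \{ 1 - (1 - p_{(j)})^{m - j + 1} \}}, clipped at 1 and
#' returned in the input order. `m` may exceed the number of supplied
#' p-values when the family is larger than the tested subset.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @param m family size (defaults to `length(p)`).
#' @return adjusted p-values, same order as `p`.
#' @examples
#' holmSidakAdjust(c(0.01, 0.04, 0.03))
#' @export
holmSidakAdjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < length(p)) stop("family size m must be >= length(p)", call. = FALSE)
  ord <- order(p)
  ps <- p[ord]
  adj <- 1 - (1 - ps)^(m - seq_along(ps) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(length(p))
  out[ord] <- adj
  out
}

#' Per-timepoint two-arm group comparison with familywise correction
#'
#' For each parameter and timepoint, compares the two arms' subject-level
#' means with a two-sample t-test (equal-variance by default), then applies
#' the Holm-Sidak correction across the declared comparison family (default:
#' every parameter x timepoint cell present, e.g. 32 for 8 parameters at 4
#' timepoints).
#'
#' @param table cohort table: data.frame with columns `subject`, `arm`,
#'   `day`, `parameter`, `value`; exactly two arms.
#' @param familySize comparison family for the correction (default: number
#'   of parameter x timepoint cells).
#' @param alpha familywise significance level.
#' @param varEqual equal-variance t-tests (`TRUE`, default) or Welch.
#' @return data.frame with one row per parameter x timepoint: `t`, `df`,
#'   `p`, `pAdjusted`, `significant`.
#' @export
groupComparison <- function(table, familySize = NULL, alpha = 0.05,
                            varEqual = TRUE) {
  arms <- sort(unique(table$arm))
  if (length(arms) != 2L) stop("exactly two arms are required", call. = FALSE)
  cells <- unique(table[, c("parameter", "day")])
  cells <- cells[order(cells$parameter, cells$day), ]
  if (is.null(familySize)) familySize <- nrow(cells)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    d <- table[table$parameter == cells$parameter[i] & table$day == cells$day[i], ]
    x <- d$value[d$arm == arms[1]]
    y <- d$value[d$arm == arms[2]]
    if (length(x) < 2L || length(y) < 2L)
      stop("each arm needs >= 2 subjects per cell", call. = FALSE)
    tt <- stats::t.test(x, y, var.equal = varEqual)
    data.frame(parameter = cells$parameter[i], day = cells$day[i],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$pAdjusted <- holmSidakAdjust(out$p, m = familySize)
  out$significant <- out$pAdjusted < alpha
  rownames(out) <- NULL
  out
}

#' Consecutive-timepoint effect sizes and between-arm change tests
#'
#' For each parameter and consecutive timepoint interval (e.g. 3-0, 6-3,
#' 9-6): the arm-wise difference of mean parameter values, plus a two-sample
#' t-test comparing the per-subject longitudinal changes between the arms,
#' Holm-Sidak corrected across the declared family (default: parameter x
#' interval cells, e.g. 28 for 8 parameters over 3 intervals... the default
#' here is the number of cells present). Subjects missing either endpoint of
#' an interval are excluded from it with a warning.
#'
#' @inheritParams groupComparison
#' @return data.frame with one row per parameter x interval x arm-difference:
#'   columns `parameter`, `interval`, `effectControlArm`, `effectTreatedArm`
#'   (differences of arm means; names follow the sorted arm order), `t`,
#'   `p`, `pAdjusted`, `significant` for the between-arm test on per-subject
#'   changes.
#' @export
effectSizes <- function(table, familySize = NULL, alpha = 0.05,
                        varEqual = TRUE) {
  arms <- sort(unique(table$arm))
  if (length(arms) != 2L) stop("exactly two arms are required", call. = FALSE)
  days <- sort(unique(table$day))
  if (length(days) < 2L) stop("need at least two timepoints", call. = FALSE)
  params <- unique(table$parameter)
  intervals <- data.frame(from = days[-length(days)], to = days[-1])
  if (is.null(familySize)) familySize <- length(params) * nrow(intervals)
  res <- list()
  droppedAll <- character(0)
  for (p in params) {
    for (i in seq_len(nrow(intervals))) {
      d0 <- table[table$parameter == p & table$day == intervals$from[i], ]
      d1 <- table[table$parameter == p & table$day == intervals$to[i], ]
      common <- intersect(d0$subject, d1$subject)
      droppedAll <- union(droppedAll,
                          setdiff(union(d0$subject, d1$subject), common))
      d0 <- d0[match(common, d0$subject), ]
      d1 <- d1[match(common, d1$subject), ]
      change <- d1$value - d0$value
      arm <- d0$arm
      eff <- vapply(arms, function(a) mean(change[arm == a]), numeric(1))
      tt <- stats::t.test(change[arm == arms[1]], change[arm == arms[2]],
                          var.equal = varEqual)
      res[[length(res) + 1L]] <- data.frame(
        parameter = p,
        interval = sprintf("%g-%g", intervals$to[i], intervals$from[i]),
        effectArm1 = eff[1], effectArm2 = eff[2],
        t = unname(tt$statistic), p = tt$p.value)
    }
  }
  if (length(droppedAll))
    warning("excluding subjects missing a timepoint: ",
            paste(droppedAll, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, res)
  names(out)[names(out) == "effectArm1"] <- paste0("effect_", arms[1])
  names(out)[names(out) == "effectArm2"] <- paste0("effect_", arms[2])
  out$pAdjusted <- holmSidakAdjust(out$p, m = familySize)
  out$significant <- out$pAdjusted < alpha
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation between two parameters of a cohort table
#'
#' Pools per-subject ROI means across all timepoints and both arms, pairs
#' the two parameters by subject and timepoint, and computes Spearman's rho
#' with mid-ranked ties.
#'
#' @param table cohort table (see [groupComparison()]).
#' @param parameterX,parameterY parameter names to correlate.
#' @return list with `rho`, `n` and the paired data.
#' @export
spearmanCorrelation <- function(table, parameterX, parameterY) {
  x <- table[table$parameter == parameterX, c("subject", "day", "value")]
  y <- table[table$parameter == parameterY, c("subject", "day", "value")]
  merged <- merge(x, y, by = c("subject", "day"), suffixes = c("X", "Y"))
  if (nrow(merged) < 3L) stop("need >= 3 paired observations", call. = FALSE)
  if (stats::sd(merged$valueX) == 0 || stats::sd(merged$valueY) == 0)
    stop("undefined correlation: constant input", call. = FALSE)
  rho <- stats::cor(merged$valueX, merged$valueY, method = "spearman")
  list(rho = rho, n = nrow(merged), pairs = merged)
}

#' Test-retest repeatability coefficient and Wilcoxon matched-pairs test
#'
#' The repeatability coefficient
#' \deqn{RC = 1.96 \sqrt{\sum \Delta P^2 / (n - 1)} \times 100\% / \bar P}
#' expresses the 95% interval of the between-trial difference as a
#' percentage of the mean parameter estimate \eqn{\bar P} across both
#' trials. Systematic trial differences are tested with the exact Wilcoxon
#' matched-pairs signed-rank test for n <= 25 pairs.
#'
#' @param trial1,trial2 paired parameter estimates per subject.
#' @return list with `rc` (percent), `wilcoxonP`, `n`, `meanEstimate`.
#' @examples
#' repeatability(c(9, 11, 10), c(10, 10, 10.5))
#' @export
repeatability <- function(trial1, trial2) {
  if (length(trial1) != length(trial2))
    stop("trials must be paired", call. = FALSE)
  ok <- stats::complete.cases(trial1, trial2)
  trial1 <- trial1[ok]; trial2 <- trial2[ok]
  n <- length(trial1)
  if (n < 2L) stop("need >= 2 complete pairs", call. = FALSE)
  dP <- trial2 - trial1
  pBar <- mean(c(trial1, trial2))
  if (pBar == 0) stop("undefined RC: mean estimate is zero", call. = FALSE)
  rc <- 1.96 * sqrt(sum(dP^2) / (n - 1)) * 100 / pBar
  w <- if (all(dP == 0)) {
    list(p.value = 1)
  } else {
    suppressWarnings(stats::wilcox.test(trial1, trial2, paired = TRUE,
                                        exact = n <= 25))
  }
  list(rc = rc, wilcoxonP = w$p.value, n = n, meanEstimate = pBar)
}
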