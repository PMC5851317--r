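#' Ordinary least-squares regression between two methods
#'
#' @param x,y per-subject values under two reconstruction methods (equal
#'   lengths >= 2, finite).
#' @return list with `slope`, `intercept`, `r_squared` (the squared Pearson
#'   correlation) and `n`.
#' @export
linearRegression <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (sd(x) == 0) stop("undefined slope: zero variance in x")
  fit <- lm(y ~ x)
  cf <- coef(fit)
  r2 <- if (sd(y) == 0) 1 else unname(cor(x, y)^2)
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       r_squared = r2, n = length(x))
}

#' Paired and Welch t-tests between two methods
#'
#' Computes both readings of a "paired, two-sample t-test": the paired t on
#' the within-subject differences, and Welch's unequal-variance two-sample
#' t with Welch-Satterthwaite degrees of freedom. Both are two-sided at
#' `alpha = 0.05`.
#'
#' @param a,b numeric samples (paired variant requires equal lengths).
#' @return data.frame with one row per variant: `variant`, `statistic`,
#'   `df`, `p_value`, `alpha`.
#' @export
pairedTests <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need at least 2 values per sample")
  if (length(a) != length(b)) stop("paired test requires equal lengths")
  if (sd(a - b) == 0) stop("degenerate test: zero variance of differences")
  pt <- t.test(a, b, paired = TRUE)
  wt <- t.test(a, b, var.equal = FALSE)
  data.frame(variant = c("paired_t", "welch"),
             statistic = c(unname(pt$statistic), unname(wt$statistic)),
             df = c(unname(pt$parameter), unname(wt$parameter)),
             p_value = c(pt$p.value, wt$p.value),
             alpha = 0.05)
}

#' Group mean and standard deviation
#'
#' @param values numeric vector.
#' @param label group label (method x parameter x time point).
#' @return data.frame with `label`, `mean`, `sd`, `n`.
#' @export
groupSummary <- function(values, label = "") {
  data.frame(label = label, mean = mean(values), sd = sd(values),
             n = length(values))
}

#' Pairwise method-comparison report
#'
#' For every pair of reconstruction methods and every parameter, computes
#' the OLS regression between the per-subject values, the paired and Welch
#' t-tests (alpha = 0.05, no multiple-testing correction, matching the
#' per-test convention; a Bonferroni-adjusted Welch p-value is emitted
#' additionally for transparency), and group summaries per method.
#' Subjects missing any method are dropped with a warning. The report is a
#' pure function of its inputs.
#'
#' @param fits long data.frame with columns `subject`, `method`,
#'   `parameter`, `value` (e.g. K1, k2, and SUV at the four time points).
#' @return list with `pairwise` and `summaries` data frames.
#' @export
methodComparisonReport <- function(fits) {
  need <- c("subject", "method", "parameter", "value")
  if (!all(need %in% names(fits)))
    stop("fits must have columns ", paste(need, collapse = ", "))
  methods <- sort(unique(fits$method))
  params <- unique(fits$parameter)
  pw <- list(); sm <- list()
  for (par in params) {
    d <- fits[fits$parameter == par, ]
    wide <- tapply(d$value, list(d$subject, d$method), mean)
    complete <- stats::complete.cases(wide)
    if (any(!complete)) {
      warning(sprintf("%d subject(s) missing a method for %s; dropped",
                      sum(!complete), par))
      wide <- wide[complete, , drop = FALSE]
    }
    for (m in methods)
      sm[[paste(par, m)]] <- cbind(parameter = par, method = m,
                                   groupSummary(wide[, m]))
    pairs <- utils::combn(methods, 2, simplify = FALSE)
    rows <- lapply(pairs, function(pr) {
      x <- wide[, pr[1]]; y <- wide[, pr[2]]
      reg <- linearRegression(x, y)
      # identical columns carry no evidence of a difference: report p = 1
      tt <- tryCatch(pairedTests(x, y), error = function(e)
        data.frame(variant = c("paired_t", "welch"), statistic = 0,
                   df = NA_real_, p_value = 1, alpha = 0.05))
      data.frame(parameter = par, method_a = pr[1], method_b = pr[2],
                 n = reg$n, slope = reg$slope, intercept = reg$intercept,
                 r_squared = reg$r_squared,
                 p_paired = tt$p_value[tt$variant == "paired_t"],
                 p_welch = tt$p_value[tt$variant == "welch"])
    })
    tab <- do.call(rbind, rows)
    tab$p_welch_bonferroni <- pmin(1, tab$p_welch * nrow(tab))
    pw[[par]] <- tab
  }
  list(pairwise = do.call(rbind, c(pw, make.row.names = FALSE)),
       summaries = do.call(rbind, c(sm, make.row.names = FALSE)))
}

#' Write a comparison report to CSV and JSON
#'
#' @param report output of [methodComparisonReport()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeComparisonReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "pairwise_tests.csv"),
             file.path(dir, "group_summaries.csv"),
             file.path(dir, "report.json"))
  write.csv(report$pairwise, paths[1], row.names = FALSE)
  write.csv(report$summaries, paths[2], row.names = FALSE)
  jsonlite::write_json(report, paths[3], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(paths)
}

#' Simulate a cohort of per-method kinetic results
#'
#' Draws per-subject true parameters from normal inter-subject
#' distributions (truncated at a small positive floor) and, for every
#' reconstruction method, an independent multiplicative measurement error
#' of coefficient of variation `noiseCV`. With identical noise across
#' methods this is a null cohort: methods differ only by noise, so any
#' significant pairwise test is a type-I error. Useful for calibrating the
#' comparison machinery without running reconstructions.
#'
#' @param nSubjects cohort size (default 24).
#' @param methods method labels.
#' @param truthMean,truthSD named means/SDs of the inter-subject parameter
#'   distributions.
#' @param noiseCV per-measurement coefficient of variation.
#' @param seed RNG seed.
#' @return long data.frame (`subject`, `method`, `parameter`, `value`).
#' @export
simulateCohortFits <- function(nSubjects = 24,
                               methods = c("FBP", "OSEM", "TOF", "TPSF"),
                               truthMean = c(K1 = 0.7, k2 = 0.25),
                               truthSD = c(K1 = 0.15, k2 = 0.06),
                               noiseCV = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- list()
  for (par in names(truthMean)) {
    truth <- pmax(rnorm(nSubjects, truthMean[[par]], truthSD[[par]]),
                  0.05 * truthMean[[par]])
    for (m in methods) {
      val <- truth * (1 + noiseCV * rnorm(nSubjects))
      out[[paste(par, m)]] <- data.frame(
        subject = seq_len(nSubjects), method = m, parameter = par,
        value = val)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
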