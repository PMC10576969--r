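#' Per-label summary statistics
#'
#' Mean, sample SD (n-1 denominator, absent for singleton groups), min and
#' max of a per-image metric within each expert label group. Unlabelled
#' records are excluded from the groups and counted in the
#' \code{n_unlabelled} attribute.
#'
#' @param values numeric per-image metric.
#' @param labels character labels (\code{Yes}/\code{Maybe}/\code{No} or NA).
#' @param metric name tag carried into the output.
#' @return data.frame with one row per label present: \code{label},
#'   \code{n}, \code{mean}, \code{sd}, \code{min}, \code{max},
#'   \code{metric}.
#' @export
summarizeByLabel <- function(values, labels, metric = "metric") {
  stopifnot(length(values) == length(labels))
  keep <- !is.na(labels)
  if (!any(keep)) stop("all records are unlabelled")
  v <- values[keep]; l <- labels[keep]
  labs <- intersect(.LABELS, unique(l))
  out <- do.call(rbind, lapply(labs, function(g) {
    x <- v[l == g]
    data.frame(label = g, n = length(x), mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               min = min(x), max = max(x), metric = metric,
               stringsAsFactors = FALSE)
  }))
  attr(out, "n_unlabelled") <- sum(!keep)
  out
}

.check_groups <- function(values, labels) {
  keep <- !is.na(labels) & !is.na(values)
  v <- values[keep]; l <- factor(labels[keep])
  if (nlevels(l) < 2) stop("need at least two label groups")
  if (max(table(l)) < 2)
    stop("at least one group must have two or more values")
  list(v = v, l = droplevels(l))
}

#' One-way analysis of variance across label groups
#'
#' Tests whether the mean of a per-image metric differs between the expert
#' Yes/Maybe/No groups, via the standard between/within sum-of-squares F
#' statistic.
#'
#' @inheritParams summarizeByLabel
#' @return list with \code{F}, \code{df_between}, \code{df_within},
#'   \code{p}, \code{n}.
#' @examples
#' onewayAnova(c(0, 2, 4, 6), c("No", "No", "Yes", "Yes"))  # F = 8
#' @export
onewayAnova <- function(values, labels) {
  g <- .check_groups(values, labels)
  fit <- stats::aov(g$v ~ g$l)
  tab <- summary(fit)[[1]]
  Fv <- tab[["F value"]][1]
  # an all-constant response carries no signal; aov's 0/0 ratio is noise
  if (is.nan(Fv) || stats::var(g$v) == 0) Fv <- 0
  dfb <- as.integer(tab[["Df"]][1]); dfw <- as.integer(tab[["Df"]][2])
  list(F = Fv, df_between = dfb, df_within = dfw,
       p = stats::pf(Fv, dfb, dfw, lower.tail = FALSE),
       n = length(g$v))
}

#' Tukey HSD pairwise comparisons across label groups
#'
#' Adjusted p-values from the studentized-range distribution with pooled
#' within-group variance; unequal group sizes use the Tukey-Kramer form.
#'
#' @inheritParams summarizeByLabel
#' @param conf_level confidence level for the intervals.
#' @return data.frame with one row per unordered label pair:
#'   \code{label_a}, \code{label_b}, \code{diff} (mean of a minus mean of
#'   b), \code{lwr}, \code{upr}, \code{p_adj}.
#' @export
tukeyHsd <- function(values, labels, conf_level = 0.95) {
  g <- .check_groups(values, labels)
  hsd <- stats::TukeyHSD(stats::aov(g$v ~ g$l),
                         conf.level = conf_level)[[1]]
  # zero pooled variance: identical constant groups carry no evidence
  # against equality (p = 1); distinct constants are unambiguously apart
  nan <- is.nan(hsd[, "p adj"])
  hsd[nan, "p adj"] <- ifelse(hsd[nan, "diff"] == 0, 1, 0)
  pairs <- strsplit(rownames(hsd), "-", fixed = TRUE)
  data.frame(label_a = vapply(pairs, `[`, "", 1),
             label_b = vapply(pairs, `[`, "", 2),
             diff = hsd[, "diff"], lwr = hsd[, "lwr"], upr = hsd[, "upr"],
             p_adj = hsd[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Ordinary least-squares regression of a metric on a covariate
#'
#' Used to check whether a covariate (depth, percent soft substrate)
#' confounds the density analysis. Records with a missing covariate or
#' response are dropped and counted.
#'
#' @param values numeric response (per-image metric).
#' @param covariate numeric predictor.
#' @return list with \code{slope}, \code{intercept}, \code{p} (two-sided
#'   t-test on the slope), \code{n}, \code{n_dropped}.
#' @export
covariateRegression <- function(values, covariate) {
  stopifnot(length(values) == length(covariate))
  keep <- !is.na(values) & !is.na(covariate)
  y <- values[keep]; x <- covariate[keep]
  if (length(y) < 3) stop("need at least 3 paired observations")
  if (stats::var(x) == 0) stop("covariate has zero variance")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on an exactly-constant response ("perfect fit"); that
  # degenerate case is handled explicitly below
  cf <- suppressWarnings(summary(fit)$coefficients)
  # a constant response has an exactly-zero slope; report p = 1 rather than
  # the NaN a zero residual variance would produce
  p <- if (stats::var(y) == 0) 1 else cf["x", "Pr(>|t|)"]
  list(slope = unname(cf["x", "Estimate"]),
       intercept = unname(cf["(Intercept)", "Estimate"]),
       p = unname(p), n = length(y), n_dropped = sum(!keep))
}

#' Derive a candidate VME threshold from labelled densities
#'
#' Three estimators for turning labelled calibration data into a flow-chart
#' threshold: \describe{
#'   \item{midpoint_means}{\code{(mean(Yes) + mean(No)) / 2}.}
#'   \item{no_quantile}{the q-th quantile of the No group (lower
#'     interpolation, i.e. \code{quantile(type = 1)}); default q = 0.95.}
#'   \item{min_misclassification}{the cut c minimising
#'     \code{#\{No > c\} + #\{Yes <= c\}} over observed values (an image is
#'     called VME when its value exceeds the cut); ties broken toward the
#'     lower cut, so perfectly separated groups return \code{max(No)}, the
#'     infimum of the zero-error gap.}}
#' Maybe-labelled records are excluded: a threshold contrasts a clear Yes
#' against a clear No.
#'
#' @param values numeric per-image metric.
#' @param labels expert labels.
#' @param method one of \code{"midpoint_means"}, \code{"no_quantile"},
#'   \code{"min_misclassification"}.
#' @param q quantile for \code{no_quantile}.
#' @param metric name tag carried into the output.
#' @return list with \code{metric}, \code{method}, \code{value},
#'   \code{n_yes}, \code{n_no}.
#' @export
deriveThresholds <- function(values, labels,
                             method = c("midpoint_means", "no_quantile",
                                        "min_misclassification"),
                             q = 0.95, metric = "metric") {
  method <- match.arg(method)
  yes <- values[!is.na(labels) & labels == "Yes"]
  no <- values[!is.na(labels) & labels == "No"]
  if (!length(yes) || !length(no))
    stop("both Yes and No groups must be non-empty")
  value <- switch(method,
    midpoint_means = (mean(yes) + mean(no)) / 2,
    no_quantile = unname(stats::quantile(no, probs = q, type = 1)),
    min_misclassification = {
      cuts <- sort(unique(c(yes, no)))
      err <- vapply(cuts, function(cc)
        sum(no > cc) + sum(yes <= cc), numeric(1))
      cuts[which.min(err)]  # which.min takes the first, i.e. lowest cut
    })
  list(metric = metric, method = method, value = value,
       n_yes = length(yes), n_no = length(no))
}

#' Run the full calibration analysis
#'
#' Executes, in order: the area filter; density computation; depth and
#' substrate covariate regressions on overall density; then, for each
#' metric (richness per m^2, each indicator taxon present in the data, and
#' overall density), per-label summaries, one-way ANOVA and Tukey HSD;
#' finally candidate thresholds per configured estimator for each density
#' metric. No multiple-testing correction is applied across metrics — the
#' per-metric tests are reported as-is with the number of tests run, so the
#' caller can adjust.
#'
#' The substrate regression uses percent soft substrate, computed as 100
#' minus the recorded percent hard substrate.
#'
#' @param x a \linkS4class{VmeImageSet} with at least some labelled images.
#' @param registry a \linkS4class{VmeRegistry}.
#' @param min_area_m2 area filter threshold (m^2).
#' @param body body id, \code{"union"} or \code{"intersection"}.
#' @param policy \code{"qualified_counts"} or \code{"strict"}.
#' @param methods threshold estimators to run.
#' @param q quantile for the \code{no_quantile} estimator.
#' @return object of class \code{vme_calibration_report}: a list with
#'   \code{filter}, \code{regressions}, \code{summaries}, \code{anova},
#'   \code{tukey}, \code{thresholds}, \code{metrics}, \code{n_tests},
#'   \code{notes}.
#' @seealso [writeCalibrationReport()]
#' @export
runCalibrationReport <- function(x, registry = defaultRegistry(),
                                 min_area_m2 = 1, body = "union",
                                 policy = c("qualified_counts", "strict"),
                                 methods = c("midpoint_means", "no_quantile",
                                             "min_misclassification"),
                                 q = 0.95) {
  policy <- match.arg(policy)
  methods <- match.arg(methods, several.ok = TRUE)
  xf <- filterByArea(x, min_area_m2)
  dset <- computeDensities(xf, registry, body = body, policy = policy)
  lab <- colData(dset)$label
  D <- colData(dset)$overall_density
  notes <- character()

  reg_depth <- tryCatch(covariateRegression(D, colData(dset)$depth_m),
                        error = function(e) {
                          notes <<- c(notes, paste("depth regression:",
                                                   conditionMessage(e)))
                          NULL })
  soft <- 100 - colData(dset)$pct_hard_substrate
  reg_soft <- tryCatch(covariateRegression(D, soft),
                       error = function(e) {
                         notes <<- c(notes, paste("substrate regression:",
                                                  conditionMessage(e)))
                         NULL })

  dens <- assay(dset, "density")
  taxa <- rownames(dens)[rowSums(dens) > 0]
  metrics <- c(list(richness_per_m2 = colData(dset)$richness_density),
               stats::setNames(lapply(taxa, function(t) dens[t, ]), taxa),
               list(overall_density = D))

  summaries <- list(); anova <- list(); tukey <- list()
  thresholds <- list()
  for (m in names(metrics)) {
    v <- metrics[[m]]
    summaries[[m]] <- summarizeByLabel(v, lab, metric = m)
    anova[[m]] <- tryCatch(onewayAnova(v, lab), error = function(e) {
      notes <<- c(notes, sprintf("ANOVA skipped for %s: %s", m,
                                 conditionMessage(e))); NULL })
    tukey[[m]] <- tryCatch(tukeyHsd(v, lab), error = function(e) NULL)
    thresholds[[m]] <- stats::setNames(lapply(methods, function(meth)
      tryCatch(deriveThresholds(v, lab, method = meth, q = q, metric = m),
               error = function(e) NULL)), methods)
  }
  out <- list(filter = metadata(dset)$area_filter,
              excluded_taxa = metadata(dset)$excluded_taxa,
              regressions = list(depth = reg_depth,
                                 pct_soft_substrate = reg_soft),
              summaries = summaries, anova = anova, tukey = tukey,
              thresholds = thresholds, metrics = names(metrics),
              n_tests = sum(!vapply(anova, is.null, logical(1))),
              body = body, policy = policy, notes = notes)
  class(out) <- "vme_calibration_report"
  out
}

#' @export
print.vme_calibration_report <- function(x, ...) {
  cat("VME calibration report\n")
  f <- x$filter
  cat(sprintf("  images: %d in, %d removed by area filter (< %g m2), %d analysed\n",
              f$records_in, f$records_removed, f$min_area_m2,
              f$records_kept))
  for (nm in names(x$regressions)) {
    r <- x$regressions[[nm]]
    if (!is.null(r))
      cat(sprintf("  %s regression: slope %.4g, p = %.4f (n = %d)\n",
                  nm, r$slope, r$p, r$n))
  }
  for (m in x$metrics) {
    a <- x$anova[[m]]
    if (is.null(a)) next
    s <- x$summaries[[m]]
    means <- paste(sprintf("%s %.2f±%.2f", s$label, s$mean,
                           ifelse(is.na(s$sd), 0, s$sd)), collapse = ", ")
    cat(sprintf("  %s: %s; F(%d,%d) = %.3g, p = %.3g\n", m, means,
                a$df_between, a$df_within, a$F, a$p))
  }
  cat(sprintf("  ANOVA tests run: %d (no multiplicity correction applied)\n",
              x$n_tests))
  invisible(x)
}

#' Write a calibration report bundle
#'
#' Machine-readable outputs: \code{report.json} with every statistic, plus
#' CSV tables \code{summary_stats.csv}, \code{anova.csv} and
#' \code{tukey_hsd.csv} mirroring the conventional per-label summary /
#' ANOVA / Tukey layout.
#'
#' @param report a \code{vme_calibration_report}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCalibrationReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  summ <- do.call(rbind, report$summaries)
  utils::write.csv(summ, file.path(dir, "summary_stats.csv"),
                   row.names = FALSE)
  an <- do.call(rbind, lapply(names(report$anova), function(m) {
    a <- report$anova[[m]]
    if (is.null(a)) return(NULL)
    data.frame(metric = m, F = a$F, df_between = a$df_between,
               df_within = a$df_within, p = a$p, n = a$n)
  }))
  utils::write.csv(an, file.path(dir, "anova.csv"), row.names = FALSE)
  tk <- do.call(rbind, lapply(names(report$tukey), function(m) {
    t <- report$tukey[[m]]
    if (is.null(t)) return(NULL)
    cbind(data.frame(metric = m), t)
  }))
  utils::write.csv(tk, file.path(dir, "tukey_hsd.csv"), row.names = FALSE)
  invisible(dir)
}
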