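#' Classify a per-run correlation
#'
#' Thresholds the per-run Pearson correlation into the three interaction
#' regimes: \code{r < -0.25} is complementarity, \code{r > 0.25} synchrony,
#' anything in between (inclusive) neutral. Inequalities are strict; missing
#' values classify as missing.
#'
#' @param r Numeric vector of correlations (may contain \code{NA}).
#' @param threshold Positive threshold magnitude (default 0.25).
#' @return A factor with levels
#'   \code{complementarity, neutral, synchrony, missing}.
#' @examples
#' classify_r(c(-0.3, 0.25, 0.9, NA))
#' @export
classify_r <- function(r, threshold = 0.25) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  out <- ifelse(is.na(r), "missing",
         ifelse(r < -threshold, "complementarity",
         ifelse(r > threshold, "synchrony", "neutral")))
  factor(out, levels = c("complementarity", "neutral", "synchrony", "missing"))
}

#' Prevalence of inhibitory parameters in one tail of the sweep
#'
#' Among sweep rows classified to the requested side (complementarity or
#' synchrony), the fraction whose context matrix contains at least one -1
#' entry. Rows with missing \code{r} are excluded.
#'
#' @param table A \code{dyad_sweep} data frame.
#' @param side \code{"complementarity"} or \code{"synchrony"}.
#' @param threshold Classification threshold passed to [classify_r()].
#' @return A proportion in \[0, 1\].
#' @export
negative_rate <- function(table, side = c("complementarity", "synchrony"),
                          threshold = 0.25) {
  side <- match.arg(side)
  cls <- classify_r(table$r, threshold)
  sel <- cls == side
  if (!any(sel)) stop("no rows classified as ", side, call. = FALSE)
  neg <- table$s1 == -1 | table$o1 == -1 | table$o2 == -1 | table$s2 == -1
  mean(neg[sel])
}

#' Chi-square goodness-of-fit test for two categories
#'
#' Pearson goodness-of-fit statistic \eqn{\sum (O - E)^2 / E} against the
#' supplied expected proportions, 1 degree of freedom, no continuity
#' correction.
#'
#' @param observed Pair of non-negative counts.
#' @param expected_props Pair of positive proportions summing to 1.
#' @return A list of class \code{"chisq_result"} with \code{statistic},
#'   \code{dof}, \code{p_value}, \code{observed} and \code{expected}.
#' @examples
#' chisq_goodness_of_fit(c(90, 10), c(0.5, 0.5))$statistic  # 64
#' @export
chisq_goodness_of_fit <- function(observed, expected_props) {
  if (length(observed) != 2L || any(observed < 0) || sum(observed) <= 0)
    stop("observed must be two non-negative counts with positive total",
         call. = FALSE)
  if (length(expected_props) != 2L || any(expected_props <= 0) ||
      abs(sum(expected_props) - 1) > 1e-8)
    stop("invalid expectation: proportions must be positive and sum to 1",
         call. = FALSE)
  ht <- stats::chisq.test(observed, p = expected_props, correct = FALSE)
  structure(list(statistic = unname(ht$statistic), dof = unname(ht$parameter),
                 p_value = ht$p.value, observed = observed,
                 expected = unname(ht$expected)),
            class = "chisq_result")
}

#' Chi-square test comparing two proportions
#'
#' Pearson chi-square on the 2x2 contingency table formed by two groups'
#' (success, failure) counts, 1 degree of freedom, no continuity correction.
#'
#' @param count1,count2 Pairs of counts for the two groups.
#' @return A \code{"chisq_result"} (see [chisq_goodness_of_fit()]).
#' @export
chisq_two_proportions <- function(count1, count2) {
  if (length(count1) != 2L || length(count2) != 2L)
    stop("each group needs a pair of counts", call. = FALSE)
  tab <- rbind(count1, count2)
  if (any(rowSums(tab) <= 0) || any(colSums(tab) <= 0))
    stop("degenerate table: a margin is zero", call. = FALSE)
  ht <- stats::chisq.test(tab, correct = FALSE)
  structure(list(statistic = unname(ht$statistic), dof = unname(ht$parameter),
                 p_value = ht$p.value, observed = tab,
                 expected = ht$expected),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("chi-square = %.4f, df = %d, p = %.3g\n",
              x$statistic, x$dof, x$p_value))
  invisible(x)
}

.model_ids <- c("main_effects", "interactions", "overall", "initiator",
                "self_influence")
.k_printed <- c(main_effects = 8L, interactions = 48L, overall = 56L,
                initiator = 28L, self_influence = 28L)

.model_formula <- function(model_id) {
  switch(model_id,
    main_effects   = r ~ s1 + o1 + o2 + s2,
    interactions   = r ~ s1:o1 + s1:o2 + s1:s2 + o1:o2 + o1:s2 + o2:s2,
    overall        = r ~ (s1 + o1 + o2 + s2)^2,
    initiator      = r ~ s1 + o2 + s1:o1 + s1:o2 + s1:s2 + o2:o1 + o2:s2,
    self_influence = r ~ s1 + s2 + s1:o1 + s1:o2 + s1:s2 + s2:o1 + s2:o2,
    stop("unknown model_id: ", model_id, call. = FALSE))
}

#' Build one of the five regression designs
#'
#' Each ternary context parameter becomes a three-level factor with 0 as the
#' reference level, so a main effect contributes its positive and negative
#' indicators and a two-parameter interaction contributes the four products
#' of their indicators. The five designs are:
#' \describe{
#'   \item{main_effects}{the 8 dummy indicators (printed parameter count 8).}
#'   \item{interactions}{all cross-parameter pairwise interaction terms
#'     (printed count 48 = 8 dummies x 6 partner dummies, which double-counts
#'     each unordered product; the fitted span has 32 distinct non-intercept
#'     degrees of freedom). Because interaction terms between three-level
#'     factors span their margins, this model's fitted span contains the
#'     main effects, making it identical in fit to \code{overall}.}
#'   \item{overall}{main effects plus all pairwise interactions (printed
#'     count 56).}
#'   \item{initiator}{Person 1's self-influence and Person-1-to-Person-2
#'     dummies plus every interaction term involving them (printed 28).}
#'   \item{self_influence}{both agents' self-influence dummies plus every
#'     interaction term involving them (printed 28).}
#' }
#' Rows with missing \code{r} are excluded listwise.
#'
#' @param table A \code{dyad_sweep} data frame.
#' @param model_id One of \code{"main_effects", "interactions", "overall",
#'   "initiator", "self_influence"}.
#' @return A list of class \code{"dyad_design"}: \code{model_id},
#'   \code{formula}, \code{data} (factors plus response), \code{k_printed},
#'   \code{n}, \code{n_excluded}.
#' @export
build_design <- function(table, model_id) {
  model_id <- match.arg(model_id, .model_ids)
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("table must be a non-empty data frame", call. = FALSE)
  keep <- !is.na(table$r)
  dat <- data.frame(r = table$r[keep])
  for (v in c("s1", "o1", "o2", "s2")) {
    col <- table[[v]][keep]
    if (!all(col %in% c(-1, 0, 1)))
      stop("non-ternary context entries in sweep table", call. = FALSE)
    dat[[v]] <- factor(as.character(col), levels = c("0", "1", "-1"))
  }
  structure(list(model_id = model_id, formula = .model_formula(model_id),
                 data = dat, k_printed = .k_printed[[model_id]],
                 n = nrow(dat), n_excluded = sum(!keep)),
            class = "dyad_design")
}

#' Fit one regression design by ordinary least squares
#'
#' Rank-revealing least squares (QR with pivoting, via [stats::lm()]), so
#' exactly collinear columns are tolerated. Reports the coefficient of
#' determination, adjusted R-squared, the Gaussian log-likelihood at the MLE
#' variance, and AIC/BIC.
#'
#' Two parameter-counting conventions are available for the information
#' criteria and adjusted R-squared. \code{"unique"} (default) counts the
#' linearly distinct coefficients actually fitted plus the variance
#' parameter (the convention of R's \code{AIC()}, under which models with
#' identical fitted spans score identically). \code{"printed"} uses the
#' design's nominal parameter count \code{k_printed} plus intercept and
#' variance. Both counts are always reported.
#'
#' @param design A \code{dyad_design} from [build_design()].
#' @param y Optional response overriding the design's \code{r} column (must
#'   match its row count).
#' @param convention \code{"unique"} or \code{"printed"}.
#' @return A list of class \code{"fit_result"}: \code{model_id},
#'   \code{r_squared}, \code{adj_r_squared}, \code{loglik}, \code{aic},
#'   \code{bic}, \code{k_printed}, \code{k_unique}, \code{n},
#'   \code{convention}, and the underlying \code{fit}.
#' @export
fit_ols <- function(design, y = NULL, convention = c("unique", "printed")) {
  convention <- match.arg(convention)
  stopifnot(inherits(design, "dyad_design"))
  dat <- design$data
  if (!is.null(y)) {
    if (length(y) != nrow(dat)) stop("y length mismatch", call. = FALSE)
    dat$r <- y
  }
  if (stats::var(dat$r) == 0)
    stop("degenerate response: r has zero variance", call. = FALSE)
  fit <- stats::lm(design$formula, data = dat)
  n <- nrow(dat)
  k_unique <- fit$rank - 1L  # non-intercept distinct columns
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((dat$r - mean(dat$r))^2)
  r2 <- 1 - rss / tss
  ll <- as.numeric(stats::logLik(fit))
  p <- if (convention == "unique") k_unique else design$k_printed
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  k_ic <- p + 2L  # + intercept + variance
  structure(list(model_id = design$model_id, r_squared = r2,
                 adj_r_squared = adj_r2, loglik = ll,
                 aic = 2 * k_ic - 2 * ll, bic = k_ic * log(n) - 2 * ll,
                 k_printed = design$k_printed, k_unique = k_unique, n = n,
                 convention = convention, fit = fit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s: R2 = %.4f (adj %.4f), AIC = %.2f, BIC = %.2f, k = %d/%d, n = %d\n",
              x$model_id, x$r_squared, x$adj_r_squared, x$aic, x$bic,
              x$k_printed, x$k_unique, x$n))
  invisible(x)
}

#' Fit and compare the five regression models
#'
#' Fits all five designs on the same (non-missing) sweep rows and returns
#' their fit statistics in the standard order, as a model-comparison table.
#'
#' @param table A \code{dyad_sweep} data frame.
#' @param convention Parameter-counting convention, see [fit_ols()].
#' @return A data frame with one row per model: \code{model, k_printed,
#'   k_unique, r2, adj_r2, loglik, aic, bic, n}, plus attribute
#'   \code{fits} holding the full \code{fit_result} objects.
#' @export
table1_replica <- function(table, convention = c("unique", "printed")) {
  convention <- match.arg(convention)
  fits <- lapply(.model_ids, function(id)
    fit_ols(build_design(table, id), convention = convention))
  names(fits) <- .model_ids
  out <- data.frame(
    model = .model_ids,
    k_printed = vapply(fits, `[[`, integer(1), "k_printed"),
    k_unique = vapply(fits, `[[`, integer(1), "k_unique"),
    r2 = vapply(fits, `[[`, numeric(1), "r_squared"),
    adj_r2 = vapply(fits, `[[`, numeric(1), "adj_r_squared"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    n = vapply(fits, `[[`, numeric(1), "n"))
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "convention") <- convention
  out
}

#' Full statistical analysis of a sweep
#'
#' Runs the complete analysis pipeline on a sweep table: classification
#' counts at the +/- threshold, inhibitory-parameter prevalence in both
#' tails, the chi-square tests (goodness of fit of the complementarity-tail
#' prevalence under both candidate nulls, and the two-proportion comparison
#' between tails), and the five-model regression comparison.
#'
#' The goodness-of-fit null is under-determined scientifically, so two named
#' variants are computed: \code{fifty_fifty} (0.5/0.5) and \code{structural}
#' (65/81 vs 16/81, the fraction of ternary matrices with at least one
#' negative entry).
#'
#' @param table A \code{dyad_sweep} data frame.
#' @param threshold Classification threshold (default 0.25).
#' @param convention Parameter-counting convention for the model table.
#' @return A list of class \code{"sweep_analysis"}.
#' @export
analyze_sweep <- function(table, threshold = 0.25,
                          convention = c("unique", "printed")) {
  convention <- match.arg(convention)
  cls <- classify_r(table$r, threshold)
  counts <- table(cls)
  neg <- table$s1 == -1 | table$o1 == -1 | table$o2 == -1 | table$s2 == -1
  tails <- list()
  for (side in c("complementarity", "synchrony")) {
    sel <- cls == side
    tails[[side]] <- list(
      n = sum(sel),
      n_negative = sum(neg & sel),
      negative_rate = if (any(sel)) mean(neg[sel]) else NA_real_)
  }
  comp_counts <- c(tails$complementarity$n_negative,
                   tails$complementarity$n - tails$complementarity$n_negative)
  syn_counts <- c(tails$synchrony$n_negative,
                  tails$synchrony$n - tails$synchrony$n_negative)
  chisq <- list(
    fifty_fifty = if (sum(comp_counts) > 0)
      chisq_goodness_of_fit(comp_counts, c(0.5, 0.5)),
    structural = if (sum(comp_counts) > 0)
      chisq_goodness_of_fit(comp_counts, c(65, 16) / 81),
    two_proportions = if (sum(comp_counts) > 0 && sum(syn_counts) > 0 &&
                          all(colSums(rbind(comp_counts, syn_counts)) > 0))
      chisq_two_proportions(comp_counts, syn_counts))
  models <- table1_replica(table, convention = convention)
  structure(list(threshold = threshold,
                 n_rows = nrow(table),
                 n_missing = sum(is.na(table$r)),
                 class_counts = counts,
                 tails = tails,
                 chisq = chisq,
                 models = models),
            class = "sweep_analysis")
}

#' @export
print.sweep_analysis <- function(x, ...) {
  cat(sprintf("sweep analysis (threshold +/- %g): %d rows, %d missing r\n",
              x$threshold, x$n_rows, x$n_missing))
  print(x$class_counts)
  cat(sprintf("negative-parameter rate: complementarity %.1f%% (n=%d), synchrony %.1f%% (n=%d)\n",
              100 * x$tails$complementarity$negative_rate,
              x$tails$complementarity$n,
              100 * x$tails$synchrony$negative_rate, x$tails$synchrony$n))
  print(x$models[, c("model", "k_printed", "r2", "adj_r2", "aic", "bic")],
        digits = 6)
  invisible(x)
}

#' Write an analysis report
#'
#' Emits \code{analysis.json} (classification counts, tail prevalences, the
#' chi-square variants, and the model table) and a \code{table1.csv} with
#' header \code{model,k_printed,r2,adj_r2,aic,bic}.
#'
#' @param analysis A \code{sweep_analysis}.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "sweep_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  strip <- function(ch) if (is.null(ch)) NULL else
    list(statistic = ch$statistic, dof = ch$dof, p_value = ch$p_value,
         observed = as.vector(ch$observed), expected = as.vector(ch$expected))
  report <- list(
    threshold = analysis$threshold,
    n_rows = analysis$n_rows,
    n_missing = analysis$n_missing,
    class_counts = as.list(analysis$class_counts),
    tails = analysis$tails,
    chisq = lapply(analysis$chisq, strip),
    models = analysis$models[, setdiff(names(analysis$models), "fits")])
  json_path <- file.path(dir, "analysis.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  csv_path <- file.path(dir, "table1.csv")
  utils::write.csv(analysis$models[, c("model", "k_printed", "r2", "adj_r2",
                                       "aic", "bic")],
                   csv_path, row.names = FALSE, quote = FALSE)
  invisible(c(analysis = json_path, table1 = csv_path))
}
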