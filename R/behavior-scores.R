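#' Weekly MET-minutes from intensity-specific activity minutes
#'
#' IPAQ-style volume score: brisk walking weighted 3.5 MET, moderate
#' activity 4.0 MET, vigorous activity 8.0 MET. All arguments are weekly
#' minutes; the function is vectorized.
#'
#' @param walk_min,moderate_min,vigorous_min minutes per week, nonnegative.
#' @return MET-minutes per week.
#' @export
met_minutes <- function(walk_min, moderate_min, vigorous_min) {
  if (any(c(walk_min, moderate_min, vigorous_min) < 0, na.rm = TRUE))
    stop("activity minutes must be nonnegative", call. = FALSE)
  3.5 * walk_min + 4.0 * moderate_min + 8.0 * vigorous_min
}

#' Physical-activity level from weekly MET-minutes
#'
#' Cut-offs at 600 and 1500 MET-min/week: `[0, 600)` is low (below the
#' recommendation), `[600, 1500]` intermediate (meets it), `(1500, Inf)`
#' high (exceeds it). The printed ranges share their endpoints; both
#' boundary values are assigned to the intermediate class because the
#' recommendation is met at 600.
#'
#' @param met_min MET-minutes per week, nonnegative; vectorized.
#' @return factor with levels low, intermediate, high.
#' @export
classify_pa_level <- function(met_min) {
  if (any(met_min < 0, na.rm = TRUE))
    stop("MET-minutes must be nonnegative", call. = FALSE)
  lv <- ifelse(met_min < 600, "low",
               ifelse(met_min <= 1500, "intermediate", "high"))
  factor(lv, levels = c("low", "intermediate", "high"))
}

#' Score a weekly physical-activity log
#'
#' Builds the three physical-activity indicators from a per-participant log
#' of weekly minutes by intensity class and session counts: PA1 = total
#' duration (min/week), PA2 = frequency (sessions/week, summed across
#' intensity classes), PA3 = intensity as MET-min/week, plus the IPAQ
#' level.
#'
#' @param log data.frame with columns `participant_id`, `walk_min`,
#'   `moderate_min`, `vigorous_min`, `sessions`.
#' @return data.frame with `participant_id`, `PA1`, `PA2`, `PA3`, `level`.
#' @export
score_pa_log <- function(log) {
  need <- c("participant_id", "walk_min", "moderate_min", "vigorous_min", "sessions")
  if (!all(need %in% names(log)))
    stop("PA log must have columns ", paste(need, collapse = ", "), call. = FALSE)
  met <- met_minutes(log$walk_min, log$moderate_min, log$vigorous_min)
  data.frame(participant_id = log$participant_id,
             PA1 = log$walk_min + log$moderate_min + log$vigorous_min,
             PA2 = log$sessions,
             PA3 = met,
             level = classify_pa_level(met),
             stringsAsFactors = FALSE)
}

HEALTH_ITEMS <- list(ph = c("PH1", "PH2", "PH3"),
                     mh = c("MH1", "MH2", "MH3", "MH4", "MH5"),
                     sh = c("SH1", "SH2", "SH3", "SH4", "SH5"))

#' Prepare Likert health-scale items for modeling
#'
#' Validates that every item is an integer in 1..5, reverse-codes the
#' bodily-pain item PH1 (6 - x) so that higher always means healthier, and
#' returns the item-level table (the structural model consumes items, not
#' sums) together with per-scale means for reporting.
#'
#' @param responses data.frame with columns PH1-PH3, MH1-MH5, SH1-SH5 (and
#'   optionally `participant_id`, carried through).
#' @return list with `items` (reverse-coded item table) and `scale_means`
#'   (per-participant means of the physical, mental and social scales).
#' @export
scale_scores <- function(responses) {
  items <- unlist(HEALTH_ITEMS, use.names = FALSE)
  miss <- setdiff(items, names(responses))
  if (length(miss) > 0)
    stop("missing items: ", paste(miss, collapse = ", "), call. = FALSE)
  for (it in items) {
    v <- responses[[it]]
    if (any(!v %in% 1:5))
      stop(sprintf("item %s outside the 1-5 Likert range", it), call. = FALSE)
  }
  out <- responses
  out$PH1 <- 6L - as.integer(out$PH1) # bodily pain: reverse so high = healthy
  means <- data.frame(
    ph = rowMeans(out[HEALTH_ITEMS$ph]),
    mh = rowMeans(out[HEALTH_ITEMS$mh]),
    sh = rowMeans(out[HEALTH_ITEMS$sh]))
  if ("participant_id" %in% names(responses))
    means <- cbind(participant_id = responses$participant_id, means)
  list(items = out, scale_means = means)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability, (k/(k-1)) (1 - sum of item variances /
#' variance of the total score).
#'
#' @param item_matrix numeric matrix or data.frame, observations in rows,
#'   items in columns (k >= 2 columns, >= 3 rows).
#' @return alpha in (-Inf, 1].
#' @export
cronbach_alpha <- function(item_matrix) {
  x <- as.matrix(item_matrix)
  k <- ncol(x)
  if (k < 2 || nrow(x) < 3) stop("need >= 2 items and >= 3 observations", call. = FALSE)
  vt <- stats::var(rowSums(x))
  if (vt <= 0) stop("zero total-score variance: alpha undefined", call. = FALSE)
  (k / (k - 1)) * (1 - sum(apply(x, 2, stats::var)) / vt)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO: sum of squared off-diagonal correlations over that sum plus
#' the sum of squared anti-image (partial) correlations, computed from the
#' inverse correlation matrix.
#'
#' @param item_matrix numeric matrix or data.frame, observations in rows.
#' @return KMO in [0, 1].
#' @export
kmo <- function(item_matrix) {
  r <- stats::cor(as.matrix(item_matrix))
  ri <- tryCatch(solve(r), error = function(e)
    stop("correlation matrix is singular: KMO undefined", call. = FALSE))
  d <- 1 / sqrt(diag(ri))
  q <- -ri * outer(d, d) # anti-image partial correlations
  off <- upper.tri(r)
  sum(r[off]^2) / (sum(r[off]^2) + sum(q[off]^2))
}

#' Bartlett's test of sphericity
#'
#' Chi-squared test that the correlation matrix is the identity; reported
#' alongside KMO when judging whether the item set is factorable.
#'
#' @param item_matrix numeric matrix or data.frame.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(item_matrix) {
  x <- as.matrix(item_matrix)
  n <- nrow(x); p <- ncol(x)
  r <- stats::cor(x)
  stat <- -(n - 1 - (2 * p + 5) / 6) * determinant(r, logarithm = TRUE)$modulus[1]
  df <- p * (p - 1) / 2
  list(statistic = as.numeric(stat), df = df,
       p_value = stats::pchisq(as.numeric(stat), df, lower.tail = FALSE))
}

#' Reliability and validity summary for the pooled health items
#'
#' Pools the 13 health items (after reverse coding) and reports Cronbach's
#' alpha on the pooled set, per-scale alphas, KMO and Bartlett's test —
#' the pre-modeling checks run before fitting the structural model.
#'
#' @param items reverse-coded item table from [scale_scores()].
#' @return list with `alpha_pooled`, `alpha_by_scale`, `kmo`, `bartlett`.
#' @export
reliability_report <- function(items) {
  pooled <- as.matrix(items[unlist(HEALTH_ITEMS, use.names = FALSE)])
  list(alpha_pooled = cronbach_alpha(pooled),
       alpha_by_scale = vapply(HEALTH_ITEMS, function(cols)
         cronbach_alpha(as.matrix(items[cols])), numeric(1)),
       kmo = kmo(pooled),
       bartlett = bartlett_sphericity(pooled))
}
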