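SEM_LATENTS <- c("GE", "PA", "PH", "MH", "SH")
SEM_INDICATORS <- c("GE1", "GE2", "GE3", "PA1", "PA2", "PA3",
                    "PH1", "PH2", "PH3",
                    "MH1", "MH2", "MH3", "MH4", "MH5",
                    "SH1", "SH2", "SH3", "SH4", "SH5")
LIKERT_ITEMS <- c("PH1", "PH2", "PH3", "MH1", "MH2", "MH3", "MH4", "MH5",
                  "SH1", "SH2", "SH3", "SH4", "SH5")

#' Define the latent ground truth of a synthetic cohort
#'
#' Standardized measurement and structural parameters from which surveys
#' are simulated and against which recovery is judged. All latent variables
#' have unit variance; indicator error variances default to 1 - loading^2
#' so indicators are standardized too.
#'
#' @param loadings named numeric vector, one standardized loading per
#'   indicator (names from `GE1` ... `SH5`), each in [-1, 1].
#' @param paths 5 x 5 standardized structural coefficient matrix over
#'   latents GE, PA, PH, MH, SH; entry (i, j) is the path j -> i. Must be
#'   acyclic, entries in [-1, 1].
#' @param error_correlations list of `c(indicator, indicator, rho)` triples
#'   freeing correlated measurement errors.
#' @param noise_sd optional named vector of indicator error SDs; defaults
#'   to `sqrt(1 - loading^2)`.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(loadings, paths, error_correlations = list(),
                         noise_sd = NULL) {
  if (!all(SEM_INDICATORS %in% names(loadings)))
    stop("loadings must name every indicator", call. = FALSE)
  loadings <- loadings[SEM_INDICATORS]
  if (any(abs(loadings) > 1)) stop("standardized loadings must lie in [-1, 1]", call. = FALSE)
  paths <- as.matrix(paths)
  dimnames(paths) <- list(SEM_LATENTS, SEM_LATENTS)
  if (any(abs(paths) > 1)) stop("standardized paths must lie in [-1, 1]", call. = FALSE)
  if (is.null(noise_sd)) noise_sd <- sqrt(1 - loadings^2)
  tr <- structure(list(loadings = loadings, paths = paths,
                       error_correlations = error_correlations,
                       noise_sd = noise_sd[SEM_INDICATORS]),
                  class = "ground_truth")
  ev <- eigen(ground_truth_covariance(tr), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop(sprintf("implied covariance not positive definite (smallest eigenvalue %.3g)",
                 min(ev)), call. = FALSE)
  tr
}

#' The hypothesized-structure ground truth
#'
#' Default synthetic truth: the five-latent exposure/activity/health
#' structure with the reported standardized loadings for the exposure
#' (0.70, 0.87, 0.08) and activity (0.83, 0.14, 0.82) blocks, health-block
#' loadings in the 0.66-0.75 range typical of short well-being scales, the
#' five retained structural paths (GE->PA 0.14, GE->MH 0.21, GE->SH 0.17,
#' PA->PH 0.13, PA->MH 0.13; the two non-significant paths are zero), and
#' two small correlated errors (accessibility with frequency, frequency
#' with self-rated physical health).
#'
#' @return a [ground_truth()].
#' @export
default_ground_truth <- function() {
  loadings <- c(GE1 = 0.70, GE2 = 0.87, GE3 = 0.08,
                PA1 = 0.83, PA2 = 0.14, PA3 = 0.82,
                PH1 = 0.70, PH2 = 0.72, PH3 = 0.75,
                MH1 = 0.72, MH2 = 0.75, MH3 = 0.70, MH4 = 0.68, MH5 = 0.66,
                SH1 = 0.74, SH2 = 0.70, SH3 = 0.72, SH4 = 0.68, SH5 = 0.71)
  B <- matrix(0, 5, 5, dimnames = list(SEM_LATENTS, SEM_LATENTS))
  B["PA", "GE"] <- 0.14
  B["MH", "GE"] <- 0.21
  B["SH", "GE"] <- 0.17
  B["PH", "PA"] <- 0.13
  B["MH", "PA"] <- 0.13
  ground_truth(loadings, B,
               error_correlations = list(c("GE3", "PA2", 0.20),
                                         c("PA2", "PH3", 0.15)))
}

# latent covariance with unit variances: Phi = C Psi C' with psi solved
# from diag(Phi) = 1 via (C o C) psi = 1
truth_latent_cov <- function(truth) {
  m <- length(SEM_LATENTS)
  C <- solve(diag(m) - truth$paths)
  psi <- solve(C * C, rep(1, m))
  if (any(psi <= 0))
    stop("structural paths leave no residual latent variance; reduce coefficients",
         call. = FALSE)
  Phi <- C %*% diag(psi) %*% t(C)
  dimnames(Phi) <- list(SEM_LATENTS, SEM_LATENTS)
  list(Phi = Phi, psi = psi, C = C)
}

truth_theta <- function(truth) {
  th <- diag(truth$noise_sd^2)
  dimnames(th) <- list(SEM_INDICATORS, SEM_INDICATORS)
  for (ec in truth$error_correlations) {
    i <- ec[1]; j <- ec[2]; rho <- as.numeric(ec[3])
    th[i, j] <- th[j, i] <- rho * truth$noise_sd[[i]] * truth$noise_sd[[j]]
  }
  th
}

truth_lambda <- function(truth) {
  L <- matrix(0, length(SEM_INDICATORS), length(SEM_LATENTS),
              dimnames = list(SEM_INDICATORS, SEM_LATENTS))
  blocks <- list(GE = c("GE1", "GE2", "GE3"), PA = c("PA1", "PA2", "PA3"),
                 PH = c("PH1", "PH2", "PH3"),
                 MH = c("MH1", "MH2", "MH3", "MH4", "MH5"),
                 SH = c("SH1", "SH2", "SH3", "SH4", "SH5"))
  for (l in names(blocks)) L[blocks[[l]], l] <- truth$loadings[blocks[[l]]]
  L
}

#' Covariance matrix implied by a ground truth
#'
#' Lambda Phi Lambda' + Theta on the fully standardized scale (all latent
#' and indicator variances 1).
#'
#' @param truth a [ground_truth()].
#' @return 19 x 19 covariance matrix over the indicators.
#' @export
ground_truth_covariance <- function(truth) {
  lc <- truth_latent_cov(truth)
  L <- truth_lambda(truth)
  Sg <- L %*% lc$Phi %*% t(L) + truth_theta(truth)
  (Sg + t(Sg)) / 2
}

likert_discretize <- function(z) {
  # quintile cut points of the standard normal: keeps categories balanced
  # and the Pearson-covariance attenuation mild
  as.integer(cut(z, breaks = c(-Inf, stats::qnorm(c(0.2, 0.4, 0.6, 0.8)), Inf),
                 labels = FALSE))
}

# invert the MET formula: weekly minutes by intensity consistent with a
# target duration D and target MET volume M (3.5 D <= M <= 8 D)
pa_log_from_targets <- function(D, M, u) {
  m_max <- pmax(0, pmin(2 * (M - 3.5 * D), (8 * D - M) / 4, D))
  m <- 0.8 * u * m_max
  v <- (M - 3.5 * D - 0.5 * m) / 4.5
  w <- D - m - v
  data.frame(walk_min = w, moderate_min = m, vigorous_min = v)
}

#' Simulate survey responses from a ground truth
#'
#' Draws latent scores from the structural model, builds indicators as
#' loading x latent + correlated noise, and maps them to survey form:
#' the 13 health items are discretized to the 1-5 Likert range (the
#' bodily-pain item is stored pain-coded, i.e. reversed), and the physical
#' activity block is emitted as a weekly log (walking / moderate /
#' vigorous minutes and session count) whose scored indicators reproduce
#' the simulated duration, frequency and MET-volume targets exactly.
#'
#' When exposure profiles are supplied, the greenspace-exposure latent is
#' replaced by the standardized exposure composite
#' z(GE1) + z(GE2) - z(GE3) (distance lowers exposure), so the structural
#' effects act on the geometrically measured exposure; the GE columns then
#' carry the actual measured indicators, and error correlations involving
#' GE indicators do not apply. Without profiles the GE block is simulated
#' from the measurement model on plausible natural scales (coverage
#' fractions, meters).
#'
#' @param truth a [ground_truth()].
#' @param exposures optional data.frame with `participant_id`, `GE1`,
#'   `GE2`, `GE3` from [exposure_table()]; its row count overrides `n`.
#' @param n number of respondents when `exposures` is `NULL`.
#' @param seed integer RNG seed.
#' @return data.frame with `participant_id`, GE indicators, the weekly PA
#'   log and the 13 Likert items; the simulated latent scores are attached
#'   as attribute `latents`.
#' @export
generate_survey <- function(truth, exposures = NULL, n = NULL, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(as.integer(seed) + 3L)
  lc <- truth_latent_cov(truth)
  B <- truth$paths
  nlat <- length(SEM_LATENTS)

  if (!is.null(exposures)) {
    n <- nrow(exposures)
    g <- scale(exposures$GE1)[, 1] + scale(exposures$GE2)[, 1] -
         scale(exposures$GE3)[, 1]
    eta_ge <- as.numeric(scale(g))
  } else {
    if (is.null(n)) stop("n is required without exposure profiles", call. = FALSE)
    eta_ge <- stats::rnorm(n)
  }

  # propagate through the (acyclic) structural model in declaration order
  eta <- matrix(0, n, nlat, dimnames = list(NULL, SEM_LATENTS))
  eta[, "GE"] <- eta_ge
  for (l in SEM_LATENTS[-1]) {
    mu <- eta %*% B[l, ]
    eta[, l] <- mu + sqrt(lc$psi[[match(l, SEM_LATENTS)]]) * stats::rnorm(n)
  }

  # indicator errors with the truth's correlation structure
  Th <- truth_theta(truth)
  if (!is.null(exposures)) { # GE indicators are measured, not simulated
    ge_idx <- c("GE1", "GE2", "GE3")
    Th[ge_idx, ] <- 0; Th[, ge_idx] <- 0
    diag(Th)[match(ge_idx, SEM_INDICATORS)] <- 1 # placeholder, unused
  }
  eps <- rmvnorm_chol(n, Th + diag(1e-12, nrow(Th)))
  colnames(eps) <- SEM_INDICATORS

  L <- truth_lambda(truth)
  y <- eta %*% t(L) + eps # standardized indicator scores

  ids <- if (!is.null(exposures)) exposures$participant_id
         else sprintf("P%04d", seq_len(n))
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)

  if (!is.null(exposures)) {
    out$GE1 <- exposures$GE1; out$GE2 <- exposures$GE2; out$GE3 <- exposures$GE3
  } else {
    out$GE1 <- pmax(0.001, 0.18 + 0.06 * y[, "GE1"])
    out$GE2 <- pmax(0.001, 0.06 + 0.018 * y[, "GE2"])
    out$GE3 <- pmax(0, 350 + 120 * y[, "GE3"])
  }

  D <- pmax(20, 200 + 80 * y[, "PA1"])
  M <- pmin(pmax(900 + 450 * y[, "PA3"], 3.5 * D + 1), 8 * D - 1)
  log3 <- pa_log_from_targets(D, M, stats::runif(n))
  out$walk_min <- log3$walk_min
  out$moderate_min <- log3$moderate_min
  out$vigorous_min <- log3$vigorous_min
  out$sessions <- pmin(28, pmax(1, round(4.5 + 1.8 * y[, "PA2"])))

  for (it in LIKERT_ITEMS) {
    v <- likert_discretize(y[, it])
    if (it == "PH1") v <- 6L - v # stored pain-coded, as asked in the survey
    out[[it]] <- v
  }
  attr(out, "latents") <- eta
  attr(out, "truth") <- truth
  out
}

#' Assemble the indicator table the structural model consumes
#'
#' Scores the weekly PA log (duration, frequency, MET-minutes), validates
#' and reverse-codes the Likert items, and binds the greenspace-exposure
#' indicators: one row per participant, columns `GE1` ... `SH5`.
#'
#' @param survey a survey table from [generate_survey()] (or real data in
#'   the same layout).
#' @return data.frame of the 19 indicators plus `participant_id`.
#' @export
sem_input_table <- function(survey) {
  pa <- score_pa_log(survey[c("participant_id", "walk_min", "moderate_min",
                              "vigorous_min", "sessions")])
  sc <- scale_scores(survey[c("participant_id", LIKERT_ITEMS)])
  cbind(survey[c("participant_id", "GE1", "GE2", "GE3")],
        pa[c("PA1", "PA2", "PA3")],
        sc$items[LIKERT_ITEMS])
}
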