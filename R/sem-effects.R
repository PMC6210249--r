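#' Zero out nonsignificant structural paths
#'
#' Paths whose two-sided p-value exceeds `alpha` keep their reported
#' estimate but have their standardized effect set to 0.00 for the effect
#' decomposition, mirroring the convention of treating invalid hypotheses
#' as zero in further analysis.
#'
#' @param fit a `sem_fit`.
#' @param alpha significance level.
#' @return the fit with an added `B_std_pruned` matrix and a `paths` table
#'   listing each structural path with its status.
#' @export
prune_paths <- function(fit, alpha = 0.05) {
  if (!fit$converged)
    warning("pruning paths of a non-converged fit")
  Bp <- fit$B_std
  drop <- !is.na(fit$path_p) & fit$path_p > alpha
  Bp[drop] <- 0
  idx <- which(fit$B_std != 0 | !is.na(fit$path_p), arr.ind = TRUE)
  lat <- fit$model$latents
  paths <- data.frame(
    from = lat[idx[, 2]], to = lat[idx[, 1]],
    std = fit$B_std[idx], p_value = fit$path_p[idx],
    pruned = drop[idx], effect = Bp[idx],
    stringsAsFactors = FALSE)
  fit$B_std_pruned <- Bp
  fit$paths <- paths
  fit$alpha <- alpha
  fit
}

#' Direct, indirect, and total standardized effects
#'
#' Path algebra on the standardized structural coefficients: with B the
#' (acyclic) latent path matrix, total effects are (I - B)^-1 - I, direct
#' effects are B itself, and indirect effects are the difference — for a
#' single mediator this is exactly the product of the two path
#' coefficients. Effects are reported for the exposure toward each
#' outcome.
#'
#' @param paths standardized structural path matrix (latents x latents,
#'   entry (i, j) = path j -> i), e.g. `fit$B_std_pruned`, or a `sem_fit`
#'   that has been through [prune_paths()].
#' @param exposure name of the exposure latent.
#' @param outcomes names of the outcome latents.
#' @return data.frame of class `effect_table` with unrounded `direct`,
#'   `indirect`, `total` per outcome; `total = direct + indirect` holds
#'   exactly. Use [format_effect_table()] for the 3-decimal report form.
#' @export
effect_decomposition <- function(paths, exposure = "GE",
                                 outcomes = c("PH", "MH", "SH")) {
  B <- if (inherits(paths, "sem_fit")) {
    if (is.null(paths$B_std_pruned))
      stop("run prune_paths() first or pass a path matrix", call. = FALSE)
    paths$B_std_pruned
  } else as.matrix(paths)
  m <- nrow(B)
  # acyclicity: B must be nilpotent
  P <- B
  for (k in seq_len(m)) P <- P %*% B
  if (max(abs(P)) > 1e-12)
    stop("structural graph is cyclic: effect decomposition undefined", call. = FALSE)
  total <- solve(diag(m) - B) - diag(m)
  out <- data.frame(
    exposure = exposure, outcome = outcomes,
    direct = B[outcomes, exposure],
    indirect = total[outcomes, exposure] - B[outcomes, exposure],
    total = total[outcomes, exposure],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("effect_table", "data.frame")
  out
}

#' Round an effect table for reporting
#'
#' Half-up rounding to the given number of decimals (report convention;
#' banker's rounding would differ at ties).
#'
#' @param et an `effect_table`.
#' @param digits decimals to keep.
#' @export
format_effect_table <- function(et, digits = 3) {
  for (cl in c("direct", "indirect", "total"))
    et[[cl]] <- round_half_up(et[[cl]], digits)
  et
}

#' @export
print.effect_table <- function(x, digits = 3, ...) {
  y <- format_effect_table(x, digits)
  cat("standardized effects of", x$exposure[1], "\n")
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
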