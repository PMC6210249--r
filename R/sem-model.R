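#' Specify a structural equation model
#'
#' Parses a small model syntax into a `sem_model`: `L =~ x1 + x2` defines a
#' latent with its indicators, `Y ~ X1 + X2` a structural regression among
#' latents, and `a ~~ b` a freed error covariance (between indicators) or
#' latent covariance (between exogenous latents). Identification follows
#' the anchor convention: the first loading of every latent is fixed to 1
#' and latent (disturbance) variances are free. Indicator error variances
#' are always free; error covariances only where declared.
#'
#' @param syntax model syntax, one statement per line (`#` comments allowed).
#' @return an object of class `sem_model`.
#' @examples
#' m <- sem_model("
#'   F =~ y1 + y2 + y3
#'   G =~ y4 + y5 + y6
#'   G ~ F
#' ")
#' @export
sem_model <- function(syntax) {
  lines <- strsplit(syntax, "\n")[[1]]
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]

  latents <- character(0); indicators <- list()
  paths <- list(); covs <- list()
  for (ln in lines) {
    if (grepl("=~", ln, fixed = TRUE)) {
      pr <- strsplit(ln, "=~", fixed = TRUE)[[1]]
      lat <- trimws(pr[1])
      ind <- trimws(strsplit(pr[2], "+", fixed = TRUE)[[1]])
      latents <- union(latents, lat)
      indicators[[lat]] <- c(indicators[[lat]], ind)
    } else if (grepl("~~", ln, fixed = TRUE)) {
      pr <- trimws(strsplit(ln, "~~", fixed = TRUE)[[1]])
      covs[[length(covs) + 1]] <- pr
    } else if (grepl("~", ln, fixed = TRUE)) {
      pr <- strsplit(ln, "~", fixed = TRUE)[[1]]
      lhs <- trimws(pr[1])
      rhs <- trimws(strsplit(pr[2], "+", fixed = TRUE)[[1]])
      for (r in rhs) paths[[length(paths) + 1]] <- c(lhs, r)
    } else stop("unparseable model line: ", ln, call. = FALSE)
  }
  if (length(latents) == 0) stop("model defines no latent variables", call. = FALSE)
  obs <- unlist(indicators, use.names = FALSE)
  if (anyDuplicated(obs)) stop("an indicator loads on two latents", call. = FALSE)
  p <- length(obs); m <- length(latents)

  lambda_free <- matrix(FALSE, p, m, dimnames = list(obs, latents))
  lambda_fixed <- matrix(0, p, m, dimnames = list(obs, latents))
  for (lat in latents) {
    ind <- indicators[[lat]]
    lambda_fixed[ind[1], lat] <- 1 # anchor
    if (length(ind) > 1) lambda_free[ind[-1], lat] <- TRUE
  }

  b_free <- matrix(FALSE, m, m, dimnames = list(latents, latents))
  for (pth in paths) {
    if (!all(pth %in% latents))
      stop("structural path references non-latent: ", paste(pth, collapse = " ~ "),
           call. = FALSE)
    b_free[pth[1], pth[2]] <- TRUE
  }

  endo <- rownames(b_free)[rowSums(b_free) > 0]
  exo <- setdiff(latents, endo)
  psi_free <- diag(m) == 1
  dimnames(psi_free) <- list(latents, latents)
  if (length(exo) > 1) # exogenous latents covary freely
    psi_free[exo, exo] <- TRUE

  theta_free <- diag(p) == 1
  dimnames(theta_free) <- list(obs, obs)
  for (cv in covs) {
    if (all(cv %in% obs)) {
      theta_free[cv[1], cv[2]] <- theta_free[cv[2], cv[1]] <- TRUE
    } else if (all(cv %in% latents)) {
      psi_free[cv[1], cv[2]] <- psi_free[cv[2], cv[1]] <- TRUE
    } else stop("covariance references unknown variables: ",
                paste(cv, collapse = " ~~ "), call. = FALSE)
  }

  mod <- structure(list(obs = obs, latents = latents, indicators = indicators,
                        exogenous = exo, endogenous = endo,
                        lambda_free = lambda_free, lambda_fixed = lambda_fixed,
                        b_free = b_free, psi_free = psi_free,
                        theta_free = theta_free),
                   class = "sem_model")
  mod$param_table <- build_param_table(mod)
  ndof <- p * (p + 1) / 2 - nrow(mod$param_table)
  if (ndof < 0)
    stop(sprintf("model is underidentified (df = %d)", ndof), call. = FALSE)
  mod$df <- ndof
  mod
}

build_param_table <- function(mod) {
  rows <- list()
  add <- function(mat, i, j, label, type)
    rows[[length(rows) + 1]] <<- data.frame(matrix = mat, i = i, j = j,
                                            label = label, type = type,
                                            stringsAsFactors = FALSE)
  obs <- mod$obs; lat <- mod$latents
  for (l in seq_along(lat)) for (k in seq_along(obs))
    if (mod$lambda_free[k, l])
      add("lambda", k, l, sprintf("%s=~%s", lat[l], obs[k]), "loading")
  for (i in seq_along(lat)) for (j in seq_along(lat))
    if (mod$b_free[i, j])
      add("b", i, j, sprintf("%s~%s", lat[i], lat[j]), "path")
  for (i in seq_along(lat)) for (j in i:length(lat))
    if (mod$psi_free[i, j])
      add("psi", i, j,
          if (i == j) sprintf("%s~~%s", lat[i], lat[i])
          else sprintf("%s~~%s", lat[i], lat[j]),
          if (i == j) "latent_variance" else "latent_covariance")
  for (i in seq_along(obs)) for (j in i:length(obs))
    if (mod$theta_free[i, j])
      add("theta", i, j,
          sprintf("%s~~%s", obs[i], obs[j]),
          if (i == j) "error_variance" else "error_covariance")
  do.call(rbind, rows)
}

#' @export
print.sem_model <- function(x, ...) {
  cat(sprintf("sem model: %d latents, %d indicators, %d free parameters, df = %d\n",
              length(x$latents), length(x$obs), nrow(x$param_table), x$df))
  invisible(x)
}

# Assemble Lambda, B, Psi, Theta from a parameter vector (in param_table order).
sem_matrices <- function(mod, theta) {
  pt <- mod$param_table
  if (length(theta) != nrow(pt))
    stop("parameter vector not conformable with the free-parameter map", call. = FALSE)
  p <- length(mod$obs); m <- length(mod$latents)
  L <- mod$lambda_fixed
  B <- matrix(0, m, m); Psi <- matrix(0, m, m); Th <- matrix(0, p, p)
  for (k in seq_len(nrow(pt))) {
    i <- pt$i[k]; j <- pt$j[k]; v <- theta[k]
    switch(pt$matrix[k],
           lambda = { L[i, j] <- v },
           b = { B[i, j] <- v },
           psi = { Psi[i, j] <- v; Psi[j, i] <- v },
           theta = { Th[i, j] <- v; Th[j, i] <- v })
  }
  dimnames(L) <- list(mod$obs, mod$latents)
  dimnames(B) <- dimnames(Psi) <- list(mod$latents, mod$latents)
  dimnames(Th) <- list(mod$obs, mod$obs)
  list(Lambda = L, B = B, Psi = Psi, Theta = Th)
}

#' Model-implied covariance matrix
#'
#' Sigma(theta) = Lambda (I - B)^-1 Psi (I - B)^-T Lambda' + Theta, the
#' covariance structure implied by the measurement and structural parts.
#'
#' @param model a `sem_model`.
#' @param theta free-parameter vector in the order of `model$param_table`.
#' @return the implied covariance matrix (indicators x indicators).
#' @export
implied_covariance <- function(model, theta) {
  mm <- sem_matrices(model, theta)
  C <- solve(diag(length(model$latents)) - mm$B)
  Phi <- C %*% mm$Psi %*% t(C)
  Sg <- mm$Lambda %*% Phi %*% t(mm$Lambda) + mm$Theta
  (Sg + t(Sg)) / 2
}

#' The greenspace-exposure / physical-activity / health model
#'
#' The hypothesized five-latent structure: greenspace exposure (GE,
#' measured by vegetation coverage, PA-site coverage, and accessibility)
#' predicts physical activity (PA: duration, frequency, MET intensity) and
#' all three health dimensions; physical activity predicts the three health
#' dimensions (the mediation paths). Two indicator error covariances are
#' freed: accessibility with frequency, and frequency with self-rated
#' physical health.
#'
#' @return a `sem_model` with 19 indicators and 5 latents.
#' @export
default_sem_model <- function() {
  sem_model("
    GE =~ GE1 + GE2 + GE3
    PA =~ PA1 + PA2 + PA3
    PH =~ PH1 + PH2 + PH3
    MH =~ MH1 + MH2 + MH3 + MH4 + MH5
    SH =~ SH1 + SH2 + SH3 + SH4 + SH5
    PA ~ GE
    PH ~ GE + PA
    MH ~ GE + PA
    SH ~ GE + PA
    GE3 ~~ PA2
    PA2 ~~ PH3
  ")
}
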