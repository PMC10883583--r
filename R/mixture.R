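#' Two-component Gaussian mixture fit by EM
#'
#' Fits a two-component normal mixture to a vector of log2 activities by
#' expectation-maximization, starting from the supplied component means/SDs
#' with equal weights. Iteration stops when the log-likelihood changes by at
#' most `tol` (default 1e-8) or after `max_iter` iterations. Components are
#' relabeled post hoc so the active component is the one with the larger
#' mean, making the result invariant to the initialization order.
#'
#' A fit is flagged `degenerate-fallback` when the mixture cannot support two
#' separated components: fewer than two distinct values, a variance falling
#' below the floor (1e-3 in log2 units squared), a component claiming fewer
#' than one expected observation, or post-fit means closer than half the
#' pooled SD. Degenerate CEs are the uniformly active/inactive class and are
#' resolved against the global priors by [assign_states()].
#'
#' @param values numeric vector of log2 activities (one per cell line).
#' @param init initialization: a `GlobalPriors` object from
#'   [fit_global_priors()] or a list with `mu` (length-2, inactive then
#'   active), `sigma` (length-2) and optionally `pi`.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations; hitting it logs a warning, not an
#'   error.
#' @param var_floor variance floor preventing singular likelihoods.
#' @param ce_id optional identifier carried on the result.
#' @return a `MixtureFit` list: `ce_id`, `mu` and `sigma` (named inactive /
#'   active), `pi` (mixing weights), `posterior_active`, `loglik_trace`
#'   (non-decreasing), `n_iter`, `converged`, `fit_class`
#'   (`"mixed"`/`"degenerate-fallback"`), `values`.
#' @export
em_fit <- function(values, init, tol = 1e-8, max_iter = 1000,
                   var_floor = 1e-3, ce_id = NA_character_) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 2L) stop("need at least 2 values to fit a mixture")
  init <- .as_init(init)
  mu <- sort(init$mu)                 # c(inactive, active)
  var <- pmax(init$sigma^2, var_floor)
  pi1 <- if (is.null(init$pi)) 0.5 else init$pi[2]

  degenerate <- length(unique(x)) < 2L
  loglik <- numeric(0)
  post <- rep(NA_real_, n)
  iter <- 0L
  converged <- FALSE

  if (!degenerate) {
    repeat {
      iter <- iter + 1L
      ## E step (log-space for stability)
      la <- log(pi1) + stats::dnorm(x, mu[2], sqrt(var[2]), log = TRUE)
      li <- log1p(-pi1) + stats::dnorm(x, mu[1], sqrt(var[1]), log = TRUE)
      m <- pmax(la, li)
      ll <- sum(m + log(exp(la - m) + exp(li - m)))
      post <- exp(la - m) / (exp(la - m) + exp(li - m))
      loglik <- c(loglik, ll)
      if (iter > 1L && abs(ll - loglik[iter - 1L]) <= tol) {
        converged <- TRUE
        break
      }
      if (iter >= max_iter) break
      ## M step
      n1 <- sum(post); n0 <- n - n1
      if (n1 < .Machine$double.eps || n0 < .Machine$double.eps) {
        degenerate <- TRUE
        break
      }
      new_mu <- c(sum((1 - post) * x) / n0, sum(post * x) / n1)
      new_var <- c(sum((1 - post) * (x - new_mu[1])^2) / n0,
                   sum(post * (x - new_mu[2])^2) / n1)
      if (any(new_var < var_floor)) {
        degenerate <- TRUE
        break
      }
      mu <- new_mu; var <- new_var; pi1 <- n1 / n
    }
    if (!converged && !degenerate && iter >= max_iter)
      warning("EM did not converge in ", max_iter, " iterations",
              if (!is.na(ce_id)) paste0(" (", ce_id, ")"))
    ## post-fit degeneracy checks
    pooled_sd <- sqrt(mean(var))
    if (!degenerate &&
        (abs(mu[2] - mu[1]) < 0.5 * pooled_sd ||
         min(pi1, 1 - pi1) * n < 1))
      degenerate <- TRUE
  }

  ## relabel so the active component has the larger mean
  if (mu[2] < mu[1]) {
    mu <- rev(mu); var <- rev(var); pi1 <- 1 - pi1; post <- 1 - post
  }
  structure(list(
    ce_id = ce_id,
    mu = c(inactive = mu[1], active = mu[2]),
    sigma = c(inactive = sqrt(var[1]), active = sqrt(var[2])),
    pi = c(inactive = 1 - pi1, active = pi1),
    posterior_active = if (degenerate) rep(NA_real_, n) else post,
    loglik_trace = loglik,
    n_iter = iter,
    converged = converged && !degenerate,
    fit_class = if (degenerate) "degenerate-fallback" else "mixed",
    values = x), class = "MixtureFit")
}

.as_init <- function(init) {
  if (inherits(init, "GlobalPriors"))
    return(list(mu = c(init$mu_inactive, init$mu_active),
                sigma = c(init$sd_inactive, init$sd_active), pi = c(0.5, 0.5)))
  if (!is.list(init) || is.null(init$mu) || is.null(init$sigma))
    stop("'init' must be a GlobalPriors object or list(mu=, sigma=)")
  init
}

#' Posterior probability of the active component
#'
#' Evaluates P(active | x) under a fitted two-component mixture. With equal
#' component SDs and equal weights this posterior crosses 0.5 exactly at the
#' midpoint of the two means; in general [activity_cutoff()] locates the
#' crossing (the model-derived activity cutoff separating active from
#' inactive), which always lies strictly between the component means.
#'
#' @param fit `MixtureFit` (only `mu`, `sigma`, `pi` are used).
#' @param x log2 activity value(s).
#' @return posterior probabilities in `[0, 1]`.
#' @export
posterior_active <- function(fit, x) {
  la <- log(fit$pi[["active"]]) +
    stats::dnorm(x, fit$mu[["active"]], fit$sigma[["active"]], log = TRUE)
  li <- log(fit$pi[["inactive"]]) +
    stats::dnorm(x, fit$mu[["inactive"]], fit$sigma[["inactive"]], log = TRUE)
  m <- pmax(la, li)
  exp(la - m) / (exp(la - m) + exp(li - m))
}

#' @rdname posterior_active
#' @export
activity_cutoff <- function(fit) {
  stats::uniroot(function(x) posterior_active(fit, x) - 0.5,
                 lower = fit$mu[["inactive"]], upper = fit$mu[["active"]],
                 tol = 1e-10)$root
}

#' @export
print.MixtureFit <- function(x, ...) {
  cat(sprintf("MixtureFit%s [%s] mu=(%.2f, %.2f) sigma=(%.2f, %.2f) pi_active=%.2f, %d iterations\n",
              if (is.na(x$ce_id)) "" else paste0(" ", x$ce_id),
              x$fit_class, x$mu[1], x$mu[2], x$sigma[1], x$sigma[2],
              x$pi[2], x$n_iter))
  invisible(x)
}

#' Genome-wide activity priors per cell line
#'
#' For each cell line, fits a two-component mixture to the log2 activities of
#' all genome-wide CEs (excluding occurrences that were zero before
#' imputation), labels the larger-mean component active, and averages the
#' component means and SDs unweighted across cell lines into global priors
#' used to initialize the per-CE fits. Cell lines whose global fit collapses
#' are excluded from the average with a warning.
#'
#' The per-cell-line fit is initialized deterministically from the 25th/75th
#' percentiles of the values with SD = half the overall SD.
#'
#' @param m log2-stage [activity_matrix()] over genome-wide CEs.
#' @param zero_mask logical matrix of pre-imputation zeros (defaults to the
#'   mask carried on `m`).
#' @param ... passed to [em_fit()].
#' @return a `GlobalPriors` list: `mu_active`, `mu_inactive`, `sd_active`,
#'   `sd_inactive`, and `per_cell` (the per-cell-line component estimates,
#'   for audit).
#' @export
fit_global_priors <- function(m, zero_mask = m$zero_mask, ...) {
  stopifnot(inherits(m, "ActivityMatrix"))
  if (m$stage != "log2")
    stop("global priors are fit on the log2-stage matrix")
  v <- m$values
  if (is.null(zero_mask)) zero_mask <- matrix(FALSE, nrow(v), ncol(v))
  per_cell <- lapply(seq_len(ncol(v)), function(j) {
    cl <- colnames(v)[j]
    x <- v[!zero_mask[, j], j]
    if (length(x) < 10L || length(unique(x)) < 2L)
      return(NULL)
    init <- list(mu = as.numeric(stats::quantile(x, c(0.25, 0.75))),
                 sigma = rep(max(stats::sd(x) / 2, 0.1), 2), pi = c(0.5, 0.5))
    fit <- em_fit(x, init, ...)
    if (fit$fit_class != "mixed") return(NULL)
    data.frame(cell_line = cl, mu_inactive = fit$mu[["inactive"]],
               mu_active = fit$mu[["active"]],
               sd_inactive = fit$sigma[["inactive"]],
               sd_active = fit$sigma[["active"]],
               pi_active = fit$pi[["active"]], stringsAsFactors = FALSE)
  })
  dropped <- colnames(v)[vapply(per_cell, is.null, logical(1))]
  if (length(dropped) == ncol(v))
    stop("global mixture fit collapsed for every cell line")
  if (length(dropped))
    warning("global fit collapsed and was excluded for: ",
            paste(dropped, collapse = ", "))
  per_cell <- do.call(rbind, per_cell)
  structure(list(
    mu_active = mean(per_cell$mu_active),
    mu_inactive = mean(per_cell$mu_inactive),
    sd_active = mean(per_cell$sd_active),
    sd_inactive = mean(per_cell$sd_inactive),
    per_cell = per_cell), class = "GlobalPriors")
}

#' @export
print.GlobalPriors <- function(x, ...) {
  cat(sprintf("GlobalPriors over %d cell lines: active N(%.2f, %.2f^2), inactive N(%.2f, %.2f^2) [log2]\n",
              nrow(x$per_cell), x$mu_active, x$sd_active,
              x$mu_inactive, x$sd_inactive))
  invisible(x)
}

#' Per-cell-line active/inactive states from a mixture fit
#'
#' For a clean (`mixed`) fit, a cell line is active iff its posterior
#' probability of the active component is strictly greater than 0.5 (a
#' posterior of exactly 0.5 is inactive). For a `degenerate-fallback` fit,
#' every cell line is assigned to whichever global prior mean (active vs
#' inactive) is closer to its value, which yields the uniformly
#' active/inactive CE classes.
#'
#' @param fit `MixtureFit` from [em_fit()].
#' @param priors `GlobalPriors` from [fit_global_priors()]; required for
#'   degenerate fits.
#' @return logical vector (TRUE = active) with attribute `provenance`
#'   (`"model"` or `"fallback"`).
#' @export
assign_states <- function(fit, priors = NULL) {
  stopifnot(inherits(fit, "MixtureFit"))
  if (fit$fit_class == "mixed") {
    states <- fit$posterior_active > 0.5
    attr(states, "provenance") <- "model"
  } else {
    if (is.null(priors))
      stop("degenerate fit requires global priors for the fallback assignment")
    states <- abs(fit$values - priors$mu_active) <
      abs(fit$values - priors$mu_inactive)
    attr(states, "provenance") <- "fallback"
  }
  states
}

#' Fit mixtures and call states for every CE
#'
#' Runs [em_fit()] (initialized at the global priors) and [assign_states()]
#' row-wise over the log2 activity matrix.
#'
#' @param m log2-stage [activity_matrix()] restricted to the candidate CEs.
#' @param priors `GlobalPriors`.
#' @param ... passed to [em_fit()].
#' @return list with `fits` (named list of `MixtureFit`) and `states` (a
#'   `StateMatrix`: logical CE x cell-line matrix, TRUE = active, with a
#'   `provenance` matrix attribute).
#' @export
fit_ce_states <- function(m, priors, ...) {
  stopifnot(inherits(m, "ActivityMatrix"), inherits(priors, "GlobalPriors"))
  if (m$stage != "log2") stop("per-CE mixtures are fit on log2 activities")
  v <- m$values
  fits <- lapply(rownames(v), function(ce)
    em_fit(v[ce, ], priors, ce_id = ce, ...))
  names(fits) <- rownames(v)
  states <- t(vapply(fits, assign_states, logical(ncol(v)), priors = priors))
  dimnames(states) <- dimnames(v)
  prov <- matrix(vapply(fits, function(f)
    if (f$fit_class == "mixed") "model" else "fallback", character(1)),
    nrow = nrow(v), ncol = ncol(v), dimnames = dimnames(v))
  attr(states, "provenance") <- prov
  list(fits = fits, states = states)
}

#' Three-way CE classification from state calls
#'
#' `all_active` if the CE is active in every cell line, `all_inactive` if in
#' none, otherwise `mixed`.
#'
#' @param states logical state matrix (CE x cell lines) or a single CE's
#'   logical state vector.
#' @return character vector of classes, one per CE.
#' @export
classify_ce <- function(states) {
  if (is.vector(states)) states <- matrix(states, nrow = 1)
  if (anyNA(states)) stop("state matrix must be complete")
  n_active <- rowSums(states)
  cls <- rep("mixed", nrow(states))
  cls[n_active == ncol(states)] <- "all_active"
  cls[n_active == 0] <- "all_inactive"
  stats::setNames(cls, rownames(states))
}

#' Tabulate per-CE mixture fits
#'
#' @param fits list of `MixtureFit` objects.
#' @return data.frame with one row per CE (means, SDs, active weight, fit
#'   class, iterations).
#' @export
mixture_fit_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) data.frame(
    ce_id = f$ce_id, mu_inactive = f$mu[["inactive"]],
    mu_active = f$mu[["active"]], sigma_inactive = f$sigma[["inactive"]],
    sigma_active = f$sigma[["active"]], pi_active = f$pi[["active"]],
    fit_class = f$fit_class, n_iter = f$n_iter, converged = f$converged,
    stringsAsFactors = FALSE, row.names = NULL)))
}
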