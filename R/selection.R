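# Information-criterion model comparison, relative likelihood, and the
# solution-landscape stability regression.

#' Information criteria for a fitted model
#'
#' Standard forms with NLL the negative log-likelihood, `k` free parameters
#' and `n` observations (trials):
#' AIC = 2 NLL + 2k; AICc = AIC + 2k(k+1)/(n-k-1); HQC = 2 NLL + 2k ln(ln n);
#' BIC = 2 NLL + k ln n. The per-parameter penalty ordering at large n is
#' BIC > HQC > AIC. AICc is undefined (NA) when n <= k + 1.
#'
#' @param nll Negative log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of observations.
#' @return List with `AIC`, `AICc`, `HQC`, `BIC`.
#' @export
information_criteria <- function(nll, k, n) {
  aic <- 2 * nll + 2 * k
  list(
    AIC = aic,
    AICc = if (n > k + 1) aic + 2 * k * (k + 1) / (n - k - 1) else NA_real_,
    HQC = 2 * nll + 2 * k * log(log(n)),
    BIC = 2 * nll + k * log(n)
  )
}

#' Relative likelihood of a model against the AICc-best model
#'
#' `exp((AICc_min - AICc_j) / 2)`: the likelihood that model j actually
#' explains the data as well as the best model. Lies in (0, 1]; equals 1
#' for the best model itself.
#'
#' @param aicc_min AICc of the best model.
#' @param aicc_j AICc of the model under comparison (>= `aicc_min`).
#' @return A probability-like evidence ratio.
#' @export
relative_likelihood <- function(aicc_min, aicc_j) {
  if (aicc_min > aicc_j)
    stop("argument-order error: aicc_min must not exceed aicc_j")
  exp((aicc_min - aicc_j) / 2)
}

#' Rank fitted models by information criteria
#'
#' @param fits Named list of `dbn_fit` objects (best solution per model).
#' @param n Number of observations shared by all fits; defaults to the
#'   trial count recorded in the fits.
#' @return An object of class `selection_report`: a data frame with one row
#'   per model (k, NLL, AIC, AICc, HQC, BIC, relative likelihood vs the
#'   AICc-best model) plus a `ranking` attribute listing the model order
#'   under each criterion.
#' @export
rank_models <- function(fits, n = NULL) {
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$model$name, "")
  if (is.null(n)) {
    ns <- unique(vapply(fits, `[[`, 0L, "n_obs"))
    if (length(ns) != 1L) stop("fits were computed on differing numbers of trials")
    n <- ns
  }
  rows <- lapply(fits, function(f) {
    k <- count_free_parameters(f$model)
    nll <- -f$final_loglik
    ic <- information_criteria(nll, k, n)
    data.frame(model = f$model$name, k = k, n = n, NLL = nll,
               AIC = ic$AIC, AICc = ic$AICc, HQC = ic$HQC, BIC = ic$BIC,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$rel_likelihood <- relative_likelihood_vec(tab$AICc)
  ranking <- lapply(c(AIC = "AIC", AICc = "AICc", HQC = "HQC", BIC = "BIC"),
                    function(cr) tab$model[order(tab[[cr]])])
  structure(tab, ranking = ranking, class = c("selection_report", "data.frame"))
}

relative_likelihood_vec <- function(aicc) {
  m <- min(aicc)
  vapply(aicc, function(a) relative_likelihood(m, a), 0)
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Model comparison over", x$n[1], "trials\n")
  df <- as.data.frame(x)
  df$rel_likelihood <- format(df$rel_likelihood, digits = 3, scientific = TRUE)
  for (cc in c("NLL", "AIC", "AICc", "HQC", "BIC")) df[[cc]] <- round(df[[cc]], 2)
  print(df, row.names = FALSE)
  rk <- attr(x, "ranking")
  cat("AICc ranking (best first):", paste(rk$AICc, collapse = " > "), "\n")
  invisible(x)
}

#' Stability of the solution landscape
#'
#' Ordinary least-squares regression of each restart's final log-likelihood
#' on its summed squared parameter distance from the best solution (distance
#' over all CPT entries exactly as stored, including redundant last
#' columns). A negative slope indicates that better-fitting solutions lie
#' nearer the optimum.
#'
#' @param restarts A `dbn_restarts` object, or a list of `dbn_fit`s.
#' @param best The reference `dbn_params`; defaults to the best-ranked fit's.
#' @return List with `slope`, `p` (two-sided), `intercept`, `n_solutions`.
#' @export
stability_regression <- function(restarts, best = NULL) {
  fits <- if (inherits(restarts, "dbn_restarts")) restarts$fits else restarts
  if (length(fits) < 3L) stop("need at least 3 solutions")
  if (is.null(best)) best <- fits[[1]]$params
  ll <- vapply(fits, `[[`, 0, "final_loglik")
  d <- vapply(fits, function(f) param_distance(f$params, best), 0)
  if (stats::var(d) == 0) stop("zero variance in parameter distances")
  fit <- stats::lm(ll ~ d)
  sm <- suppressWarnings(summary(fit))$coefficients  # exact fits warn harmlessly
  slope <- unname(sm["d", "Estimate"])
  p <- unname(sm["d", "Pr(>|t|)"])
  if (is.nan(p)) p <- if (abs(slope) < 1e-12) 1 else 0  # exact-fit degeneracies
  list(slope = slope, p = p,
       intercept = unname(sm["(Intercept)", "Estimate"]),
       n_solutions = length(fits))
}
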