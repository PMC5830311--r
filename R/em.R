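# Baum-Welch EM with constrained multi-restart initialization, and the
# `dbn_fit` object returned by the fitting functions.

# Normalize expected counts into CPTs. A small additive floor keeps rows
# away from absorbing zeros; rows never visited in expectation become
# uniform.
mstep_update <- function(eng, counts) {
  fams <- eng$fams
  sT <- rowsum(rep.int(as.vector(counts$N), eng$n_trans),
               eng$big_A_trans, reorder = TRUE)
  sI <- rowsum(rep.int(as.vector(counts$N0), length(eng$init_fams)),
               eng$big_A_init, reorder = TRUE)
  tabs <- list()
  for (nm in names(fams)) {
    f <- fams[[nm]]
    nr <- prod(c(f$parent_cards, 1L))
    nc <- eng$n_cells[[nm]]
    cnt <- if (f$kind == "trans") sT[eng$trans_off[[nm]] + seq_len(nc)] else 0
    if (nm %in% eng$init_fams)                  # chain-start counts:
      cnt <- cnt + sI[eng$init_off[[nm]] + seq_len(nc)]  # same family when no cross parents
    tab <- matrix(cnt, nr, f$card) + 1e-9
    tabs[[nm]] <- tab / rowSums(tab)
  }
  tabs
}

#' Fit a model by Baum-Welch EM from one initialization
#'
#' The E-step accumulates expected family counts over all chains by scaled
#' forward-backward on the flattened hidden-configuration chain; the M-step
#' renormalizes counts per CPT row (additive floor 1e-9). Iteration stops
#' when the log-likelihood improves by less than `tol` or after `max_iter`
#' iterations. The log-likelihood trajectory is non-decreasing up to
#' numerical tolerance (EM guarantee).
#'
#' @param model A `dbn_model`.
#' @param chains A `dbn_evidence` (or list of combo vectors).
#' @param init Initial `dbn_params`; see [sample_constrained_prior()].
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param max_iter Iteration cap.
#' @param vet Decode the training chains and populate the vetting record
#'   (see [vet_solution()]).
#' @return An object of class `dbn_fit`.
#' @export
em_fit <- function(model, chains, init, tol = 1e-6, max_iter = 500L, vet = TRUE) {
  eng <- get_engine(model)
  cl <- as_chain_list(chains)
  if (!length(cl)) stop("no evidence chains supplied")
  n_obs <- sum(lengths(cl))
  tabs <- lapply(init$cpts, `[[`, "table")
  traj <- numeric(max_iter)
  converged <- FALSE
  n_it <- 0L
  for (it in seq_len(max_iter)) {
    kern <- build_kernels(eng, tabs)
    es <- fb_estep(kern$trans, kern$init, cl, eng$gmap, eng$G, eng$H, eng$E)
    if (!is.finite(es$loglik))
      stop("non-finite log-likelihood during EM (model '", model$name,
           "', iteration ", it, "); evidence has probability zero under the current parameters")
    traj[it] <- es$loglik
    n_it <- it
    if (it > 1L && es$loglik - traj[it - 1L] < tol) { converged <- TRUE; break }
    if (it < max_iter) tabs <- mstep_update(eng, es)
  }
  traj <- traj[seq_len(n_it)]
  params <- dbn_params(model, tabs)
  fit <- structure(list(
    model = model, params = params,
    loglik_trajectory = traj,
    final_loglik = traj[length(traj)],
    n_iterations = length(traj),
    converged = converged,
    n_obs = n_obs, n_chains = length(cl),
    seed = attr(init, "prior_seed"),
    vetting = NULL
  ), class = "dbn_fit")
  if (vet) fit$vetting <- vet_solution(fit, model, chains)
  fit
}

#' Vet a fitted solution for interpretability
#'
#' Decodes the chains by Viterbi, pools the hidden-node timecourses, and
#' (a) flags a trivial solution if any pair of hidden nodes has an absolute
#' Pearson correlation above 0.80 (pairs with a constant timecourse are
#' recorded as undefined, not flagged), and (b) checks the off/on interpretation by requiring each
#' detector's decoded timecourse to correlate positively with its driving
#' stimulus. The strict initialization inequalities ([check_orientation()])
#' are reported as `orientation_strict_ok` for reference; selection among
#' restarts uses the decoded-timecourse checks.
#'
#' @param fit A `dbn_fit`.
#' @param model The `dbn_model`.
#' @param chains The evidence used for fitting.
#' @return A list with `orientation_ok`, `orientation_strict_ok`,
#'   `max_abs_node_corr`, `trivial_solution_flag`, `detector_corr`,
#'   `undefined_pairs`.
#' @export
vet_solution <- function(fit, model, chains) {
  eng <- get_engine(model)
  cl <- as_chain_list(chains)
  dec <- decode_chains(model, fit$params, cl)
  tc <- do.call(rbind, dec)                 # pooled trials x hidden nodes, 0/1
  nh <- ncol(tc)
  max_r <- NA_real_; undef <- 0L
  if (nh >= 2L) {
    sds <- apply(tc, 2L, stats::sd)
    rs <- c()
    for (i in 1:(nh - 1)) for (j in (i + 1):nh) {
      if (sds[i] == 0 || sds[j] == 0) { undef <- undef + 1L; next }
      rs <- c(rs, abs(stats::cor(tc[, i], tc[, j])))
    }
    if (length(rs)) max_r <- max(rs)
  }
  dmap <- detector_map(model)
  combo_all <- unlist(cl)
  det_corr <- vapply(names(dmap), function(d) {
    stim <- eng$ecfg[combo_all, dmap[[d]]]
    x <- tc[, d]
    if (stats::sd(x) == 0 || stats::sd(stim) == 0) return(NA_real_)
    stats::cor(x, stim)
  }, 0)
  list(
    orientation_ok = length(det_corr) > 0 && all(!is.na(det_corr)) && all(det_corr > 0),
    orientation_strict_ok = check_orientation(fit$params, model)$ok,
    max_abs_node_corr = max_r,
    trivial_solution_flag = isTRUE(max_r > 0.80),
    detector_corr = det_corr,
    undefined_pairs = undef
  )
}

detector_map <- function(model) {
  switch(model$name,
    cohen = , cohen_mod = , wyble = c(D1 = "F", D2 = "S"),
    mathews = , mathews_mod = c(DT = "T", DD = "Dv"))
}

#' Multi-restart constrained EM
#'
#' Runs [em_fit()] from `n_restarts` constrained random priors (seeds are a
#' deterministic stream derived from `seed`, so restart sets are nested:
#' the first 5 priors of a 50-restart run equal those of a 5-restart run).
#' Results are ranked by final log-likelihood, best first; the selected
#' solution is the best-ranked fit that passes vetting.
#'
#' @inheritParams em_fit
#' @param n_restarts Number of random restarts (the study-scale default is
#'   3000; tests and examples use far fewer).
#' @param seed Base integer seed.
#' @param vet Decode and vet every restart and select the best-ranked
#'   interpretable solution. With `vet = FALSE` only the negative
#'   log-likelihood ranking is computed and the best-ranked fit is selected
#'   (used when only the ranking is needed, e.g. for model comparison).
#' @return An object of class `dbn_restarts`: list with ranked `fits`,
#'   `selected` (a `dbn_fit`, or `NULL` if no interpretable solution was
#'   found), `selected_index`, and `n_obs`.
#' @export
multi_restart_fit <- function(model, chains, n_restarts = 50L, seed = 1L,
                              tol = 1e-6, max_iter = 500L, vet = TRUE) {
  stopifnot(n_restarts >= 1L)
  fits <- vector("list", n_restarts)
  for (i in seq_len(n_restarts)) {
    ps <- seed + 7919L * i
    prior <- sample_constrained_prior(model, seed = ps)
    attr(prior, "prior_seed") <- ps
    fits[[i]] <- em_fit(model, chains, prior, tol = tol, max_iter = max_iter,
                        vet = vet)
  }
  ord <- order(vapply(fits, `[[`, 0, "final_loglik"), decreasing = TRUE)
  fits <- fits[ord]
  sel <- NA_integer_
  if (vet) {
    for (i in seq_along(fits)) {
      v <- fits[[i]]$vetting
      if (isTRUE(v$orientation_ok) && !isTRUE(v$trivial_solution_flag)) { sel <- i; break }
    }
  } else sel <- 1L
  if (is.na(sel))
    warning("no interpretable solution: every restart failed vetting for model '",
            model$name, "'")
  structure(list(model = model, fits = fits,
                 selected_index = sel,
                 selected = if (!is.na(sel)) fits[[sel]] else NULL,
                 n_obs = fits[[1]]$n_obs, seed = seed,
                 n_restarts = n_restarts),
            class = "dbn_restarts")
}

#' @export
print.dbn_restarts <- function(x, ...) {
  lls <- vapply(x$fits, `[[`, 0, "final_loglik")
  cat("Multi-restart EM for model '", x$model$name, "': ", length(lls),
      " restarts\n", sep = "")
  cat("  best loglik ", format(lls[1]), ", worst ", format(lls[length(lls)]), "\n", sep = "")
  if (is.na(x$selected_index)) cat("  no interpretable solution passed vetting\n")
  else cat("  selected solution: rank", x$selected_index, "\n")
  invisible(x)
}

#' Fit a cognitive model to an emotional-Stroop trial table
#'
#' The main fitting interface: converts a discretized trial table to
#' evidence chains (one per subject-run; runs are separate recording blocks,
#' so chains reset at run boundaries), runs constrained multi-restart
#' Baum-Welch EM at the group level, and returns the best interpretable
#' solution.
#'
#' @param model A `dbn_model` or model name.
#' @param trials Discretized trial table.
#' @inheritParams multi_restart_fit
#' @return A `dbn_fit` whose `restarts` field holds the full
#'   `dbn_restarts` object.
#' @export
fit_dbn <- function(model, trials, n_restarts = 50L, seed = 1L,
                    tol = 1e-6, max_iter = 500L) {
  if (is.character(model)) model <- build_model(model)
  ev <- trials_to_evidence(trials, model)
  mr <- multi_restart_fit(model, ev, n_restarts = n_restarts, seed = seed,
                          tol = tol, max_iter = max_iter)
  if (is.null(mr$selected))
    stop("no interpretable solution for model '", model$name,
         "': all ", n_restarts, " restarts failed vetting")
  fit <- mr$selected
  fit$restarts <- mr
  fit$evidence <- ev
  fit
}

# ---- dbn_fit methods --------------------------------------------------------

#' @export
print.dbn_fit <- function(x, ...) {
  cat("Fitted DBN model '", x$model$name, "'\n", sep = "")
  cat(sprintf("  log-likelihood %.4f (NLL %.4f) over %d trials in %d chains\n",
              x$final_loglik, -x$final_loglik, x$n_obs, x$n_chains))
  cat(sprintf("  %d EM iterations; converged: %s\n", x$n_iterations, x$converged))
  if (!is.null(x$vetting)) {
    v <- x$vetting
    cat(sprintf("  vetting: interpretable %s; max |r| between hidden nodes %s%s\n",
                v$orientation_ok,
                ifelse(is.na(v$max_abs_node_corr), "undefined",
                       sprintf("%.3f", v$max_abs_node_corr)),
                if (isTRUE(v$trivial_solution_flag)) " (TRIVIAL)" else ""))
  }
  invisible(x)
}

#' @export
summary.dbn_fit <- function(object, ...) {
  print(object)
  k <- count_free_parameters(object$model)
  ic <- information_criteria(-object$final_loglik, k, object$n_obs)
  cat(sprintf("  k = %d free parameters, n = %d\n", k, object$n_obs))
  cat(sprintf("  AIC %.2f  AICc %.2f  HQC %.2f  BIC %.2f\n",
              ic$AIC, ic$AICc, ic$HQC, ic$BIC))
  if (!is.null(object$vetting$detector_corr)) {
    cat("  detector-stimulus correlations:",
        paste(names(object$vetting$detector_corr),
              sprintf("%.3f", object$vetting$detector_corr), collapse = ", "), "\n")
  }
  invisible(object)
}

#' @export
coef.dbn_fit <- function(object, ...) lapply(object$params$cpts, `[[`, "table")

#' @export
logLik.dbn_fit <- function(object, ...) {
  structure(object$final_loglik, df = count_free_parameters(object$model),
            nobs = object$n_obs, class = "logLik")
}

#' Decode hidden-state trajectories for a trial table
#'
#' Applies Viterbi decoding with the fitted parameters to `newdata` (or the
#' training trials) and returns the table augmented with one 0/1 column per
#' hidden node, named `viterbi_<node>`.
#'
#' @param object A `dbn_fit`.
#' @param newdata Discretized trial table; defaults to the training data if
#'   the fit was produced by [fit_dbn()].
#' @param ... Unused.
#' @return The augmented trial table.
#' @export
predict.dbn_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stop("supply a discretized trial table as newdata")
  ev <- trials_to_evidence(newdata, object$model)
  dec <- decode_chains(object$model, object$params, ev)
  for (nd in object$model$hidden) newdata[[paste0("viterbi_", nd)]] <- NA_integer_
  for (i in seq_along(ev$chains)) {
    rows <- ev$chains[[i]]$rows
    for (nd in object$model$hidden)
      newdata[[paste0("viterbi_", nd)]][rows] <- dec[[i]][, nd]
  }
  newdata
}

#' @export
plot.dbn_fit <- function(x, ...) {
  plot(seq_along(x$loglik_trajectory), x$loglik_trajectory, type = "b",
       xlab = "EM iteration", ylab = "log-likelihood",
       main = paste0("EM trajectory: ", x$model$name), ...)
  invisible(x)
}

#' Simulate trials from a fitted model
#'
#' Forward-samples responses (and hidden states) from the fitted parameters
#' over the design columns of `trials`; see [forward_sample()].
#'
#' @param object A `dbn_fit`.
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param trials Trial table providing the stimulus/instruction design.
#' @param ... Unused.
#' @return A simulated trial table, or a list of them if `nsim > 1`.
#' @export
simulate.dbn_fit <- function(object, nsim = 1, seed = 1L, trials, ...) {
  out <- lapply(seq_len(nsim), function(i)
    forward_sample(object$model, object$params, trials, seed = seed + i - 1L))
  if (nsim == 1) out[[1]] else out
}
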