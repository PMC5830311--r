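# Forward-sampling data generator: responses (and hidden states) drawn from
# any model's CPTs over a task design, continuous reaction times consistent
# with the median-split discretization, and the reference parameter preset
# for the modified Mathews model.

#' Forward-sample a behavioral dataset from a model
#'
#' For every subject-run chain, hidden nodes and the response are sampled in
#' topological order, respecting cross-trial edges (with initial-slice CPTs
#' at run starts). True hidden states are recorded alongside the
#' observables.
#'
#' @param model A `dbn_model` or model name.
#' @param params A matching `dbn_params`.
#' @param trials Trial table holding the design columns the model observes
#'   (e.g. from [build_group_design()]).
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @return The trial table with `response_class` plus one 0/1 column
#'   `state_<node>` per hidden node (for detectors, 0 = neutral,
#'   1 = threat).
#' @export
forward_sample <- function(model, params, trials, seed = 1L) {
  if (is.character(model)) model <- build_model(model)
  stopifnot(inherits(params, "dbn_params"), params$model == model$name)
  need <- unname(model$obs_map[model$inputs])
  if (!all(need %in% names(trials)))
    stop("trial table lacks columns: ", paste(setdiff(need, names(trials)), collapse = ", "))
  key <- interaction(trials$subject_id, trials$run, drop = TRUE)
  ord <- order(key, trials$trial_index)
  chain_rows <- split(ord, key[ord])
  L <- max(lengths(chain_rows))
  C <- length(chain_rows)
  rowmat <- matrix(NA_integer_, L, C)
  for (i in seq_len(C)) rowmat[seq_along(chain_rows[[i]]), i] <- chain_rows[[i]]

  inval <- lapply(model$inputs, function(nd)
    state_code(model, nd, trials[[model$obs_map[[nd]]]]))
  names(inval) <- model$inputs

  n <- nrow(trials)
  hid_out <- matrix(NA_integer_, n, length(model$hidden),
                    dimnames = list(NULL, model$hidden))
  resp_out <- integer(n)

  withr_seed(seed, {
    prev <- list()
    for (t in seq_len(L)) {
      act <- which(!is.na(rowmat[t, ]))
      rows_t <- rowmat[t, act]
      cur <- list()
      for (nd_name in model$order) {
        nd <- model$nodes[[nd_name]]
        use_init <- t == 1L && length(nd$parents_prev)
        fam_name <- if (use_init) paste0(nd_name, ".init") else nd_name
        fam <- params$cpts[[fam_name]]
        row <- rep(1L, length(act))
        if (length(fam$parents)) {
          mult <- rev(cumprod(rev(c(fam$parent_cards[-1], 1))))
          for (i in seq_along(fam$parents)) {
            p <- fam$parents[i]
            s <- if (p %in% model$inputs) inval[[p]][rows_t]
                 else if (!use_init && p %in% nd$parents_prev) prev[[p]][act]
                 else cur[[p]]
            row <- row + (s - 1L) * mult[i]
          }
        }
        u <- stats::runif(length(act))
        tab <- fam$table
        st <- if (ncol(tab) == 2L) 1L + (u < tab[row, 2L])
              else 1L + (u >= tab[row, 1L]) + (u >= tab[row, 1L] + tab[row, 2L])
        if (nd_name == model$response) resp_out[rows_t] <- st
        else { cur[[nd_name]] <- st; hid_out[rows_t, nd_name] <- st }
      }
      # carry all hidden states forward (padded chains keep their own slots)
      prev_full <- prev
      for (h in model$hidden) {
        if (is.null(prev_full[[h]])) prev_full[[h]] <- rep(1L, C)
        prev_full[[h]][act] <- cur[[h]]
      }
      prev <- prev_full
    }
  })
  trials$response_class <- RESPONSE_CLASSES[resp_out]
  for (h in model$hidden) trials[[paste0("state_", h)]] <- hid_out[, h] - 1L
  trials
}

#' Reference parameter preset for the modified Mathews model
#'
#' A `dbn_params` whose entries are fixed at the group-level conditional
#' probabilities reported for this task design: fast-response probabilities
#' 0.90 (both detectors neutral) and 0.73 (threat target detected, neutral
#' distractor), slow-response probability 0.83 (neutral target, threat
#' distractor); threat evaluation high after dual detected threat 0.94; task
#' effort high after detected conflict 0.68 (threat target) / 0.74 (threat
#' distractor); distractor-detector threat-hit rates 0.725 (threat
#' evaluation high) / 0.463 (low). Entries not reported default to 0.5
#' (maximal entropy) or to the complement of a reported entry; the
#' provenance of every entry is recorded in the `flags` matrices
#' ("reported", "complement", "default", "ambiguous").
#'
#' The reported description of the target detector admits two readings,
#' selected by `target_reading`:
#' \describe{
#'   \item{"false_alarm"}{(default) 0.70/0.60 are threat false-alarm rates on
#'     neutral targets at low/high effort (so effort improves matching), and
#'     0.83 is the threat-hit rate regardless of effort.}
#'   \item{"literal"}{0.83 is the neutral-hit rate regardless of effort, and
#'     0.70/0.60 are threat-hit rates at low/high effort.}
#' }
#'
#' @param target_reading Which reading of the target-detector description to
#'   use.
#' @return A `dbn_params` for model `mathews_mod`.
#' @export
preset_params <- function(target_reading = c("false_alarm", "literal")) {
  target_reading <- match.arg(target_reading)
  model <- build_model("mathews_mod")
  rows2 <- function(p_on, fl) {
    list(tab = cbind(1 - p_on, p_on),
         fl = cbind(ifelse(fl == "reported", "complement", fl), fl))
  }
  # transition rows ordered (prev DT, prev DD): (n,n), (n,t), (t,n), (t,t)
  E_tr <- rows2(c(0.5, 0.74, 0.68, 0.5), c("default", "reported", "reported", "default"))
  V_tr <- rows2(c(0.5, 0.5, 0.5, 0.94), c("default", "default", "default", "reported"))
  E_in <- rows2(0.5, "default")
  V_in <- rows2(0.5, "default")
  # DT rows ordered (T, E): (n,off), (n,on), (t,off), (t,on)
  DT <- if (target_reading == "false_alarm")
    rows2(c(0.70, 0.60, 0.83, 0.83), rep("ambiguous", 4))
  else
    rows2(c(0.17, 0.17, 0.70, 0.60), rep("ambiguous", 4))
  # DD rows ordered (Dv, V): (n,off), (n,on), (t,off), (t,on)
  DD <- rows2(c(0.5, 0.5, 0.463, 0.725), c("default", "default", "reported", "reported"))
  # response rows ordered (DT, DD); columns fast, slow, error
  R_tab <- rbind(c(0.90, 0.05, 0.05),
                 c(0.085, 0.83, 0.085),
                 c(0.73, 0.135, 0.135),
                 c(1, 1, 1) / 3)
  R_fl <- rbind(c("reported", "complement", "complement"),
                c("complement", "reported", "complement"),
                c("reported", "complement", "complement"),
                c("default", "default", "default"))
  tabs <- list(E = E_tr$tab, E.init = E_in$tab, V = V_tr$tab, V.init = V_in$tab,
               DT = DT$tab, DD = DD$tab, R = R_tab)
  flags <- list(E = E_tr$fl, E.init = E_in$fl, V = V_tr$fl, V.init = V_in$fl,
                DT = DT$fl, DD = DD$fl, R = R_fl)
  dbn_params(model, tabs, flags = flags)
}

#' Reaction-time model for attaching continuous RTs
#'
#' Fast responses are placed at or below the nominal median and slow
#' responses strictly above it, so that re-running the median-split
#' discretization recovers the classes (see [attach_rts()]).
#'
#' @param median_ms Nominal per-subject median RT.
#' @param spread_ms Width of the uniform jitter on either side of the
#'   median.
#' @param p_missing_error Probability that an error trial has no recorded
#'   RT.
#' @return A list of class `rt_model`.
#' @export
rt_model <- function(median_ms = 650, spread_ms = 150, p_missing_error = 0.1) {
  stopifnot(median_ms > spread_ms, spread_ms > 1)
  structure(list(median_ms = median_ms, spread_ms = spread_ms,
                 p_missing_error = p_missing_error), class = "rt_model")
}

#' Attach continuous reaction times consistent with a class sequence
#'
#' Fast trials receive RTs in `(median - spread, median]`, slow trials in
#' `(median, median + spread]`, and error trials `correct = FALSE` with an
#' RT (or missing, with probability `p_missing_error`). When a subject has
#' more fast than slow correct responses, the excess fast responses are
#' placed exactly at the nominal median so that the empirical median of the
#' correct RTs reproduces the split (the `<=`-median tie rule keeps them
#' fast). A median split can never produce more slow than fast responses,
#' so a subject sampled that way (rare) is flagged with a warning and
#' round-trips inexactly.
#'
#' @param trials Trial table with `response_class`.
#' @param rt An [rt_model()].
#' @param seed Integer seed.
#' @return The table with `rt_ms` and `correct` columns.
#' @export
attach_rts <- function(trials, rt = rt_model(), seed = 1L) {
  stopifnot(inherits(rt, "rt_model"), "response_class" %in% names(trials))
  m <- rt$median_ms; w <- rt$spread_ms
  trials$rt_ms <- NA_real_
  trials$correct <- trials$response_class != "error"
  withr_seed(seed, {
    for (s in unique(trials$subject_id)) {
      i_f <- which(trials$subject_id == s & trials$response_class == "fast")
      i_s <- which(trials$subject_id == s & trials$response_class == "slow")
      i_e <- which(trials$subject_id == s & trials$response_class == "error")
      nf <- length(i_f); ns <- length(i_s)
      fast <- m - stats::runif(nf, 0, w - 1) - 1     # in [m - w, m - 1]
      slow <- m + stats::runif(ns, 0, w - 1) + 1     # in [m + 1, m + w]
      d <- nf - ns
      if (d >= 1L) {
        j <- d %/% 2L + 1L
        fast[order(fast, decreasing = TRUE)[seq_len(min(j, nf))]] <- m
      } else if (d < 0L) {
        warning("subject ", s, " sampled more slow than fast correct responses; ",
                "a median split cannot reproduce this sequence exactly")
      }
      trials$rt_ms[i_f] <- fast
      trials$rt_ms[i_s] <- slow
      if (length(i_e)) {
        has_rt <- stats::runif(length(i_e)) >= rt$p_missing_error
        ert <- m + stats::runif(length(i_e), -w, w)
        trials$rt_ms[i_e] <- ifelse(has_rt, ert, NA_real_)
      }
    }
  })
  trials
}

#' Simulate a full synthetic study
#'
#' Convenience wrapper: builds the default group design, forward-samples a
#' model (by default the reference preset of the modified Mathews model),
#' attaches RTs and discretizes them back.
#'
#' @param n_subjects,n_runs,n_trials_per_block Design counts.
#' @param model,params Generating model and parameters.
#' @param rt An [rt_model()].
#' @param seed Integer seed.
#' @return A discretized trial table with recorded true hidden states.
#' @export
simulate_study <- function(n_subjects = 24L, n_runs = 3L, n_trials_per_block = 32L,
                           model = build_model("mathews_mod"),
                           params = preset_params(),
                           rt = rt_model(), seed = 1L) {
  design <- build_group_design(n_subjects, n_runs, n_trials_per_block, seed = seed)
  dat <- forward_sample(model, params, design, seed = seed + 1L)
  dat <- attach_rts(dat, rt, seed = seed + 2L)
  discretize_responses(dat)
}
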