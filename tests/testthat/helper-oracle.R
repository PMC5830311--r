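# Independent brute-force oracle for chain likelihoods and Viterbi paths:
# enumerates every joint hidden-configuration path and computes each path's
# probability by direct per-node CPT lookups. Shares no recursion, scaling,
# grouping or kernel code with the package's inference engine.

brute_slice <- function(model, params, obs_t, hp, hcur, init) {
  p <- 1
  for (nd_name in model$order) {
    nd <- model$nodes[[nd_name]]
    use_init <- init && length(nd$parents_prev)
    fam <- params$cpts[[if (use_init) paste0(nd_name, ".init") else nd_name]]
    row <- 1L
    if (length(fam$parents)) {
      mult <- rev(cumprod(rev(c(fam$parent_cards[-1], 1))))
      for (i in seq_along(fam$parents)) {
        pa <- fam$parents[i]
        s <- if (pa %in% model$inputs) obs_t[[pa]]
             else if (!use_init && pa %in% nd$parents_prev) hp[[pa]]
             else hcur[[pa]]
        row <- row + (s - 1L) * mult[i]
      }
    }
    child <- if (nd_name == model$response) obs_t[["R"]] else hcur[[nd_name]]
    p <- p * fam$table[row, child]
  }
  p
}

brute_path_probs <- function(model, params, obs) {
  cards <- vapply(model$hidden, function(n) model$nodes[[n]]$card, 0L)
  hcfg <- as.matrix(do.call(expand.grid, lapply(cards, seq_len)))
  H <- nrow(hcfg); T_ <- nrow(obs)
  hl <- function(h) as.list(stats::setNames(hcfg[h, ], model$hidden))
  pi0 <- vapply(seq_len(H), function(h)
    brute_slice(model, params, as.list(obs[1, ]), NULL, hl(h), TRUE), 0)
  Ss <- vector("list", T_)
  if (T_ > 1) for (t in 2:T_) {
    S <- matrix(0, H, H)
    for (hp in seq_len(H)) for (h in seq_len(H))
      S[hp, h] <- brute_slice(model, params, as.list(obs[t, ]), hl(hp), hl(h), FALSE)
    Ss[[t]] <- S
  }
  paths <- as.matrix(do.call(expand.grid, rep(list(seq_len(H)), T_)))
  pr <- pi0[paths[, 1]]
  if (T_ > 1) for (t in 2:T_) pr <- pr * Ss[[t]][cbind(paths[, t - 1], paths[, t])]
  list(paths = paths, pr = pr, hcfg = hcfg)
}

brute_loglik <- function(model, params, obs) {
  log(sum(brute_path_probs(model, params, obs)$pr))
}

brute_viterbi <- function(model, params, obs) {
  bp <- brute_path_probs(model, params, obs)
  best <- bp$paths[which.max(bp$pr), ]
  out <- bp$hcfg[best, , drop = FALSE] - 1L
  colnames(out) <- model$hidden
  out
}

# Random observed chains and their trial-table form.
rand_obs <- function(model, T_, seed) {
  set.seed(seed)
  obs <- data.frame(matrix(0L, T_, 0))
  for (nd in model$inputs) obs[[nd]] <- sample.int(model$nodes[[nd]]$card, T_, TRUE)
  obs$R <- sample.int(3L, T_, TRUE)
  obs
}

obs_to_trials <- function(model, obs, subject = "s1", run = 1L) {
  dec <- function(nd, v) {
    if (nd == "I") c("attend_face", "attend_scene")[v]
    else if (nd == "R") c("fast", "slow", "error")[v]
    else c("neutral", "threat")[v]
  }
  tr <- data.frame(subject_id = subject, run = run, trial_index = seq_len(nrow(obs)),
                   stringsAsFactors = FALSE)
  for (nd in model$inputs) tr[[model$obs_map[[nd]]]] <- dec(nd, obs[[nd]])
  tr$response_class <- dec("R", obs$R)
  tr
}
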