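# Exact inference machinery. The joint hidden configuration of a trial is
# flattened into a single super-state (<= 2^7 = 128 states); cross-trial
# edges enter through the projection of the previous configuration onto the
# cross-edge source nodes (<= 4 joint states), so every per-trial kernel is a
# small G x H matrix indexed by the trial's observed evidence combination
# (stimuli, instruction if applicable, and response). Forward recursions are
# scaled per trial; log-likelihoods accumulate the log normalizers, which is
# numerically equivalent to log-domain arithmetic.

# Precompute everything that depends on the model wiring but not on
# parameter values: configuration tables, the cross-source projection, the
# evidence-combination grid, and per-family cell-index arrays mapping each
# (group, configuration, evidence) triple to a CPT cell.
compile_engine <- function(model) {
  hidden <- model$hidden
  cards <- vapply(hidden, function(n) model$nodes[[n]]$card, 0L)
  hcfg <- as.matrix(do.call(expand.grid, lapply(cards, seq_len)))  # first hidden fastest
  H <- nrow(hcfg)
  cross <- model$cross_src
  if (length(cross)) {
    ccards <- vapply(cross, function(n) model$nodes[[n]]$card, 0L)
    gcfg <- as.matrix(do.call(expand.grid, lapply(ccards, seq_len)))
    G <- nrow(gcfg)
    mult <- cumprod(c(1L, ccards[-length(ccards)]))
    gmap <- as.integer(1L + (hcfg[, cross, drop = FALSE] - 1L) %*% mult)
  } else {
    gcfg <- matrix(0L, 1, 0); G <- 1L; gmap <- rep(1L, H)
  }
  in_cards <- vapply(model$inputs, function(n) model$nodes[[n]]$card, 0L)
  ecfg <- as.matrix(do.call(expand.grid, c(lapply(in_cards, seq_len), list(R = 1:3))))
  colnames(ecfg) <- c(model$inputs, "R")
  E <- nrow(ecfg)

  fams <- model_families(model)
  # kernel arrays are laid out (H, G, E): contiguous in the configuration
  # index for cache-friendly recursions
  Hi <- slice.index(array(0L, c(H, G, E)), 1L)
  Gi <- slice.index(array(0L, c(H, G, E)), 2L)
  Ei <- slice.index(array(0L, c(H, G, E)), 3L)
  state_of <- function(p, slice, Hix, Gix, Eix) {
    if (p %in% model$inputs) return(array(ecfg[Eix, p], dim = dim(Eix)))
    if (slice == "prev") return(array(gcfg[Gix, p], dim = dim(Gix)))
    array(hcfg[Hix, p], dim = dim(Hix))
  }
  cell_index <- function(fam, Hix, Gix, Eix) {
    nr <- prod(c(fam$parent_cards, 1L))
    row <- array(1L, dim = dim(Hix))
    if (length(fam$parents)) {
      mult <- rev(cumprod(rev(c(fam$parent_cards[-1], 1))))
      nd <- model$nodes[[fam$node]]
      for (i in seq_along(fam$parents)) {
        slice <- if (fam$kind == "trans" && fam$parents[i] %in% nd$parents_prev) "prev" else "cur"
        row <- row + (state_of(fam$parents[i], slice, Hix, Gix, Eix) - 1L) * mult[i]
      }
    }
    child <- if (fam$node == model$response) array(ecfg[Eix, "R"], dim = dim(Eix))
             else state_of(fam$node, "cur", Hix, Gix, Eix)
    (child - 1L) * nr + row
  }
  # transition kernel: every node's trans family
  trans_fams <- names(fams)[vapply(fams, function(f) f$kind == "trans", TRUE)]
  A_trans <- lapply(fams[trans_fams], cell_index, Hix = Hi, Gix = Gi, Eix = Ei)
  # initial kernel: nodes with cross parents use their .init family
  Hi0 <- slice.index(array(0L, c(H, E)), 1L)
  Ei0 <- slice.index(array(0L, c(H, E)), 2L)
  G0 <- array(1L, c(H, E))
  init_fams <- vapply(model$order, function(nd) {
    if (length(model$nodes[[nd]]$parents_prev)) paste0(nd, ".init") else nd
  }, "")
  A_init <- lapply(fams[init_fams], cell_index, Hix = Hi0, Gix = G0, Eix = Ei0)
  names(A_init) <- init_fams

  # concatenated index vectors so the M-step accumulates every family's
  # expected counts with a single rowsum() call
  n_cells <- vapply(fams, function(f)
    as.integer(prod(c(f$parent_cards, 1L)) * f$card), 0L)
  toff <- c(0L, cumsum(n_cells[names(A_trans)]))[seq_along(A_trans)]
  names(toff) <- names(A_trans)
  big_A_trans <- unlist(lapply(names(A_trans), function(nm)
    as.vector(A_trans[[nm]]) + toff[[nm]]), use.names = FALSE)
  ioff <- c(0L, cumsum(n_cells[init_fams]))[seq_along(init_fams)]
  names(ioff) <- init_fams
  big_A_init <- unlist(lapply(init_fams, function(nm)
    as.vector(A_init[[nm]]) + ioff[[nm]]), use.names = FALSE)

  list(model = model, hcfg = hcfg, gcfg = gcfg, ecfg = ecfg,
       H = H, G = G, E = E, gmap = gmap,
       fams = fams, A_trans = A_trans, A_init = A_init,
       n_cells = n_cells,
       big_A_trans = big_A_trans, trans_off = toff, n_trans = length(A_trans),
       big_A_init = big_A_init, init_off = ioff, init_fams = init_fams)
}

# Memoize compiled engines per model name within a session.
engine_cache <- new.env(parent = emptyenv())
get_engine <- function(model) {
  key <- model$name
  if (is.null(engine_cache[[key]])) engine_cache[[key]] <- compile_engine(model)
  engine_cache[[key]]
}

# Build the numeric kernels for a parameter set: Ktrans is (G, H, E), Kinit
# is (H, E); entries are joint probabilities of the hidden configuration and
# the response given the inputs (and the previous cross-source states).
build_kernels <- function(eng, params) {
  tabs <- if (inherits(params, "dbn_params"))
    lapply(params$cpts, `[[`, "table") else params
  Ktrans <- array(1, c(eng$H, eng$G, eng$E))
  for (nm in names(eng$A_trans))
    Ktrans <- Ktrans * tabs[[nm]][eng$A_trans[[nm]]]
  Kinit <- array(1, c(eng$H, eng$E))
  for (nm in names(eng$A_init))
    Kinit <- Kinit * tabs[[nm]][eng$A_init[[nm]]]
  list(trans = Ktrans, init = Kinit)
}

# ---- evidence ---------------------------------------------------------------

state_code <- function(model, node, values) {
  if (node == "I") match(values, INSTRUCTIONS)
  else if (node == "R") match(values, RESPONSE_CLASSES)
  else match(values, VALENCES)
}

#' Convert a discretized trial table into per-run evidence chains
#'
#' Each subject-run becomes one chain of observed assignments: face/scene
#' valences plus instruction for the Cohen-family and Wyble models, or the
#' derived target/distractor valences for the Mathews-family models, together
#' with the discretized response. Chains reset at run boundaries.
#'
#' @param trials Trial table with `response_class` present (see
#'   [discretize_responses()]).
#' @param model A `dbn_model`.
#' @return An object of class `dbn_evidence`: a list of chains, each with
#'   `subject_id`, `run`, `rows` (trial-table row indices) and `combo`
#'   (per-trial evidence-combination index).
#' @export
trials_to_evidence <- function(trials, model) {
  if (!"response_class" %in% names(trials) || anyNA(trials$response_class))
    stop("trials must be discretized (response_class present) before evidence conversion")
  eng <- get_engine(model)
  need <- unname(model$obs_map)
  if (!all(need %in% names(trials)))
    stop("trial table lacks columns: ", paste(setdiff(need, names(trials)), collapse = ", "))
  obs_nodes <- names(model$obs_map)
  states <- matrix(0L, nrow(trials), length(obs_nodes),
                   dimnames = list(NULL, obs_nodes))
  for (nd in obs_nodes)
    states[, nd] <- state_code(model, nd, trials[[model$obs_map[[nd]]]])
  if (anyNA(states)) stop("malformed evidence token in trial table")
  # combo index consistent with eng$ecfg enumeration (first column fastest)
  cards <- c(vapply(model$inputs, function(n) model$nodes[[n]]$card, 0L), 3L)
  mult <- cumprod(c(1L, cards[-length(cards)]))
  combo <- as.integer(1L + (states[, c(model$inputs, "R"), drop = FALSE] - 1L) %*% mult)
  key <- interaction(trials$subject_id, trials$run, drop = TRUE)
  ord <- order(key, trials$trial_index)
  chains <- lapply(split(ord, key[ord]), function(rows)
    list(subject_id = trials$subject_id[rows[1]], run = trials$run[rows[1]],
         rows = rows, combo = combo[rows]))
  structure(list(model = model$name, chains = unname(chains),
                 n_trials = nrow(trials)), class = "dbn_evidence")
}

#' @export
print.dbn_evidence <- function(x, ...) {
  cat("Evidence for model '", x$model, "': ", length(x$chains), " chains, ",
      x$n_trials, " trials\n", sep = "")
  invisible(x)
}

as_chain_list <- function(chains) {
  if (inherits(chains, "dbn_evidence")) lapply(chains$chains, `[[`, "combo")
  else if (is.list(chains) && !is.null(chains$combo)) list(chains$combo)
  else if (is.list(chains)) lapply(chains, function(ch) if (is.list(ch)) ch$combo else ch)
  else list(chains)
}

# ---- likelihood and decoding ------------------------------------------------

#' Exact log-likelihood of evidence chains
#'
#' Forward recursion over the joint hidden configuration per trial, with
#' cross-trial edges as structured transitions and initial-slice CPTs at
#' chain starts. Zero-probability evidence yields `-Inf`, not an error.
#'
#' @param model A `dbn_model`.
#' @param params A matching `dbn_params`.
#' @param chains A `dbn_evidence`, a single integer combo vector, or a list
#'   of such vectors.
#' @return Total log-likelihood (sum over chains).
#' @export
sequence_loglik <- function(model, params, chains) {
  eng <- get_engine(model)
  kern <- build_kernels(eng, params)
  sum(vapply(as_chain_list(chains), function(cv)
    forward_loglik_r(eng, kern, cv), 0))
}

forward_loglik_r <- function(eng, kern, combo) {
  alpha <- kern$init[, combo[1]]
  c1 <- sum(alpha)
  if (c1 <= 0) return(-Inf)
  ll <- log(c1)
  alpha <- alpha / c1
  if (length(combo) > 1) for (t in 2:length(combo)) {
    ag <- as.vector(rowsum(alpha, eng$gmap, reorder = TRUE))
    slice <- matrix(kern$trans[, , combo[t]], eng$H, eng$G)
    alpha <- as.vector(slice %*% ag)
    ct <- sum(alpha)
    if (ct <= 0) return(-Inf)
    ll <- ll + log(ct)
    alpha <- alpha / ct
  }
  ll
}

#' Viterbi decoding of the hidden-state trajectory
#'
#' Max-product computation of the jointly most probable assignment of all
#' hidden nodes over a whole chain. Ties are broken toward the lowest
#' configuration index (configurations are enumerated with the first hidden
#' node in declaration order varying fastest).
#'
#' @inheritParams sequence_loglik
#' @param chain A single chain (integer combo vector, or one element of a
#'   `dbn_evidence`).
#' @return Matrix (trials x hidden nodes) of decoded states coded 0/1
#'   (off/on; for detectors neutral/threat), with attribute `"config"`
#'   holding the configuration indices.
#' @export
viterbi_decode <- function(model, params, chain) {
  eng <- get_engine(model)
  kern <- build_kernels(eng, params)
  combo <- as_chain_list(chain)[[1]]
  viterbi_path(eng, kern, combo)
}

viterbi_path <- function(eng, kern, combo) {
  T_ <- length(combo)
  H <- eng$H; G <- eng$G
  logK <- log(kern$trans); logI <- log(kern$init)
  delta <- logI[, combo[1]]
  if (all(!is.finite(delta)))
    stop("zero-probability evidence at trial 1")
  arg_g <- matrix(0L, T_, H)     # chosen previous group per (t, config)
  best_in_g <- matrix(0L, T_, G) # argmax config within each group at t-1
  members <- split(seq_len(H), eng$gmap)
  if (T_ > 1) for (t in 2:T_) {
    mg <- rep(-Inf, G); bg <- integer(G)
    for (g in seq_len(G)) {
      hs <- members[[g]]
      j <- hs[which.max(delta[hs])]
      mg[g] <- delta[j]; bg[g] <- j
    }
    best_in_g[t, ] <- bg
    sc <- matrix(logK[, , combo[t]], H, G)
    cand <- sc + rep(mg, each = H)        # H x G
    pick <- max.col(cand, ties.method = "first")
    delta <- cand[cbind(seq_len(H), pick)]
    arg_g[t, ] <- pick
    if (all(!is.finite(delta)))
      stop("zero-probability evidence at trial ", t)
  }
  path <- integer(T_)
  path[T_] <- which.max(delta)
  if (T_ > 1) for (t in T_:2)
    path[t - 1L] <- best_in_g[t, arg_g[t, path[t]]]
  states <- eng$hcfg[path, , drop = FALSE] - 1L
  colnames(states) <- eng$model$hidden
  attr(states, "config") <- path
  states
}

#' Decode every chain of an evidence set
#'
#' @inheritParams sequence_loglik
#' @return List of per-chain decoded matrices (see [viterbi_decode()]).
#' @export
decode_chains <- function(model, params, chains) {
  eng <- get_engine(model)
  kern <- build_kernels(eng, params)
  lapply(as_chain_list(chains), function(cv) viterbi_path(eng, kern, cv))
}
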