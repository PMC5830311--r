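# The five competing cognitive models, declared as discrete dynamic Bayesian
# networks over per-trial slices. All hidden nodes are binary (state 1 =
# off/suppressed/neutral-detected, state 2 = on/enhanced/threat-detected);
# the response node has three states (fast, slow, error). Stimulus and
# instruction nodes are observed inputs and carry no estimated CPT: the
# likelihood is that of the responses given the stimulus stream, with hidden
# nodes marginalized.

MODEL_NAMES <- c("cohen", "cohen_mod", "mathews", "mathews_mod", "wyble")

new_node <- function(name, card, type, parents = character(), parents_prev = character()) {
  list(name = name, card = card, type = type,
       parents = parents, parents_prev = parents_prev)
}

#' Declare one of the five competing models
#'
#' Returns the wiring of the requested model:
#' \describe{
#'   \item{cohen}{Parallel stimulus processing: observed face `F`, scene `S`
#'     and instruction `I`; hidden attention `A` (driven by `I`) biases two
#'     feature detectors `D1` (face) and `D2` (scene), which jointly produce
#'     the response. No cross-trial edges.}
#'   \item{cohen_mod}{Adds a conflict-monitoring node `C` reading both
#'     detectors; the previous trial's `C` feeds the current attention node,
#'     giving conflict adaptation.}
#'   \item{mathews}{Implicit emotion regulation: observed target valence `T`
#'     and distractor valence `Dv`; hidden task effort `E` sharpens the
#'     target detector `DT`, threat evaluation `V` biases the distractor
#'     detector `DD` toward threat; the detectors interact at the level of
#'     response generation. No cross-trial edges.}
#'   \item{mathews_mod}{The previous trial's detector states drive the
#'     current trial's `E` and `V`, capturing conflict adaptation and slow
#'     emotional interference.}
#'   \item{wyble}{Seven hidden nodes: task demand `TD` biases detectors `D1`,
#'     `D2` and a categorical layer `C1`, `C2`; categorical conflict `X` and
#'     detected negative information `N` from the previous trial feed `TD`;
#'     the categorical layer produces the response.}
#' }
#'
#' @param name One of `"cohen"`, `"cohen_mod"`, `"mathews"`, `"mathews_mod"`,
#'   `"wyble"`.
#' @return An object of class `dbn_model`.
#' @export
build_model <- function(name) {
  name <- match.arg(name, MODEL_NAMES)
  nodes <- switch(name,
    cohen = list(
      new_node("F", 2L, "input"), new_node("S", 2L, "input"), new_node("I", 2L, "input"),
      new_node("A", 2L, "hidden", parents = "I"),
      new_node("D1", 2L, "hidden", parents = c("F", "A")),
      new_node("D2", 2L, "hidden", parents = c("S", "A")),
      new_node("R", 3L, "response", parents = c("D1", "D2"))),
    cohen_mod = list(
      new_node("F", 2L, "input"), new_node("S", 2L, "input"), new_node("I", 2L, "input"),
      new_node("A", 2L, "hidden", parents = "I", parents_prev = "C"),
      new_node("D1", 2L, "hidden", parents = c("F", "A")),
      new_node("D2", 2L, "hidden", parents = c("S", "A")),
      new_node("C", 2L, "hidden", parents = c("D1", "D2")),
      new_node("R", 3L, "response", parents = c("D1", "D2"))),
    mathews = list(
      new_node("T", 2L, "input"), new_node("Dv", 2L, "input"),
      new_node("E", 2L, "hidden"),
      new_node("V", 2L, "hidden"),
      new_node("DT", 2L, "hidden", parents = c("T", "E")),
      new_node("DD", 2L, "hidden", parents = c("Dv", "V")),
      new_node("R", 3L, "response", parents = c("DT", "DD"))),
    mathews_mod = list(
      new_node("T", 2L, "input"), new_node("Dv", 2L, "input"),
      new_node("E", 2L, "hidden", parents_prev = c("DT", "DD")),
      new_node("V", 2L, "hidden", parents_prev = c("DT", "DD")),
      new_node("DT", 2L, "hidden", parents = c("T", "E")),
      new_node("DD", 2L, "hidden", parents = c("Dv", "V")),
      new_node("R", 3L, "response", parents = c("DT", "DD"))),
    wyble = list(
      new_node("F", 2L, "input"), new_node("S", 2L, "input"), new_node("I", 2L, "input"),
      new_node("TD", 2L, "hidden", parents = "I", parents_prev = c("X", "N")),
      new_node("D1", 2L, "hidden", parents = c("F", "TD")),
      new_node("D2", 2L, "hidden", parents = c("S", "TD")),
      new_node("C1", 2L, "hidden", parents = c("D1", "TD")),
      new_node("C2", 2L, "hidden", parents = c("D2", "TD")),
      new_node("X", 2L, "hidden", parents = c("C1", "C2")),
      new_node("N", 2L, "hidden", parents = c("D1", "D2")),
      new_node("R", 3L, "response", parents = c("C1", "C2"))))
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  obs_map <- if (name %in% c("mathews", "mathews_mod")) {
    c(T = "target_valence", Dv = "distractor_valence", R = "response_class")
  } else {
    c(F = "face_valence", S = "scene_valence", I = "instruction", R = "response_class")
  }
  m <- structure(list(
    name = name,
    nodes = nodes,
    inputs = names(nodes)[vapply(nodes, function(n) n$type == "input", TRUE)],
    hidden = names(nodes)[vapply(nodes, function(n) n$type == "hidden", TRUE)],
    response = "R",
    obs_map = obs_map
  ), class = "dbn_model")
  m$order <- c(m$hidden, m$response)   # declaration order is topological
  m$cross_src <- sort(unique(unlist(lapply(nodes, `[[`, "parents_prev"))))
  m$constraints <- model_constraints(m)
  m
}

#' @export
print.dbn_model <- function(x, ...) {
  cat("Discrete DBN model '", x$name, "'\n", sep = "")
  cat("  inputs:  ", paste(x$inputs, collapse = ", "), "\n")
  cat("  hidden:  ", paste(x$hidden, collapse = ", "), "\n")
  for (nd in x$nodes[x$order]) {
    cross <- if (length(nd$parents_prev))
      paste0(" + prev(", paste(nd$parents_prev, collapse = ","), ")") else ""
    cat(sprintf("  %s (%d states) <- {%s}%s\n", nd$name, nd$card,
                paste(nd$parents, collapse = ","), cross))
  }
  cat("  free parameters:", count_free_parameters(x), "\n")
  invisible(x)
}

# ---- CPT families -----------------------------------------------------------
# Every non-input node owns a "transition" family whose parents are its
# within-slice parents followed by its previous-slice parents. Nodes with
# cross-trial parents additionally own an "init" family (within-slice parents
# only) used at chain starts; it is independently estimated and counted.

model_families <- function(model) {
  fams <- list()
  for (nd in model$nodes[model$order]) {
    parents <- c(nd$parents, nd$parents_prev)
    fams[[nd$name]] <- list(
      node = nd$name, kind = "trans", parents = parents,
      parent_cards = vapply(parents, function(p) model$nodes[[p]]$card, 0L),
      card = nd$card)
    if (length(nd$parents_prev)) {
      nm <- paste0(nd$name, ".init")
      fams[[nm]] <- list(
        node = nd$name, kind = "init", parents = nd$parents,
        parent_cards = vapply(nd$parents, function(p) model$nodes[[p]]$card, 0L),
        card = nd$card)
    }
  }
  fams
}

# Row index into a CPT for given parent states; the first parent varies
# slowest (a single parent's state 1 is row 1, matching the usual written
# form of a CPT).
cpt_row <- function(parent_cards, states) {
  if (!length(parent_cards)) return(rep(1L, max(1L, NROW(states))))
  states <- rbind(states)
  mult <- rev(cumprod(rev(c(parent_cards[-1], 1))))
  as.integer(1L + states %*% mult - sum(mult))
}

#' Count a model's free parameters
#'
#' Each conditional probability table with `x` rows (joint parent
#' configurations) over a child with `y` states contributes `x * (y - 1)`
#' free parameters. Initial-slice tables that differ structurally from their
#' transition counterparts (those of nodes with cross-trial parents) are
#' independently estimated and counted separately. Observed input nodes carry
#' no parameters.
#'
#' @param model A `dbn_model`.
#' @return Integer parameter count.
#' @export
count_free_parameters <- function(model) {
  fams <- model_families(model)
  sum(vapply(fams, function(f) prod(c(f$parent_cards, 1)) * (f$card - 1L), 0))
}

# ---- orientation constraints ------------------------------------------------
# Symmetry-breaking inequalities that pin the off/on reading of the hidden
# nodes: each detector reports "on"/threat with probability above 0.5 when
# its driving stimulus is threatening and below 0.5 when neutral, at every
# state of its modulator; the effort/threat-evaluation modulators of the
# Mathews family increase the probability that their detector matches (or
# detects) its stimulus. Response CPTs are left unconstrained.

bound_con <- function(node, row, col, op, label)
  list(type = "bound", node = node, row = row, col = col, op = op, bound = 0.5, label = label)
pair_con <- function(node, row_hi, row_lo, col, label)
  list(type = "pair", node = node, row_hi = row_hi, row_lo = row_lo, col = col, label = label)

detector_cons <- function(model, node, stim, modulator) {
  pc <- c(model$nodes[[stim]]$card, model$nodes[[modulator]]$card)
  cons <- list()
  for (m in seq_len(pc[2])) {
    cons[[length(cons) + 1L]] <- bound_con(node, cpt_row(pc, c(2L, m)), 2L, ">",
      sprintf("P(%s=on | %s=threat, %s=%d) > 0.5", node, stim, modulator, m))
    cons[[length(cons) + 1L]] <- bound_con(node, cpt_row(pc, c(1L, m)), 2L, "<",
      sprintf("P(%s=on | %s=neutral, %s=%d) < 0.5", node, stim, modulator, m))
  }
  cons
}

model_constraints <- function(model) {
  switch(model$name,
    cohen = ,
    cohen_mod = c(detector_cons(model, "D1", "F", "A"),
                  detector_cons(model, "D2", "S", "A")),
    wyble = c(detector_cons(model, "D1", "F", "TD"),
              detector_cons(model, "D2", "S", "TD")),
    mathews = ,
    mathews_mod = {
      pc <- c(2L, 2L)
      c(detector_cons(model, "DT", "T", "E"),
        detector_cons(model, "DD", "Dv", "V"),
        list(
          pair_con("DT", cpt_row(pc, c(2L, 2L)), cpt_row(pc, c(2L, 1L)), 2L,
                   "E=on increases P(DT=threat | T=threat)"),
          pair_con("DT", cpt_row(pc, c(1L, 2L)), cpt_row(pc, c(1L, 1L)), 1L,
                   "E=on increases P(DT=neutral | T=neutral)"),
          pair_con("DD", cpt_row(pc, c(2L, 2L)), cpt_row(pc, c(2L, 1L)), 2L,
                   "V=on increases P(DD=threat | Dv=threat)")))
    })
}

#' Check the symmetry-breaking orientation constraints
#'
#' Evaluates every orientation inequality of the model on a parameter set.
#' All inequalities are strict, so a uniform CPT fails. These constraints
#' gate the random priors used to initialize EM; post-fit interpretability is
#' assessed on decoded timecourses by [vet_solution()].
#'
#' @param params A `dbn_params` parameter set.
#' @param model The matching `dbn_model`.
#' @return A list with `ok` (logical) and `violated` (labels of failed
#'   constraints).
#' @export
check_orientation <- function(params, model) {
  violated <- character()
  for (cn in model$constraints) {
    tab <- params$cpts[[cn$node]]$table   # constraints address transition families
    pass <- if (cn$type == "bound") {
      if (cn$op == ">") tab[cn$row, cn$col] > cn$bound else tab[cn$row, cn$col] < cn$bound
    } else {
      tab[cn$row_hi, cn$col] > tab[cn$row_lo, cn$col]
    }
    if (!isTRUE(pass)) violated <- c(violated, cn$label)
  }
  list(ok = length(violated) == 0L, violated = violated)
}
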