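# Parameter sets: one row-stochastic CPT per (node, slice-kind) family.
# Tables are stored as matrices with rows = joint parent configurations
# (first parent varying slowest) and columns = child states; an optional
# `flags` matrix of the same shape records provenance ("reported",
# "default", "ambiguous") for preset parameters.

#' Construct a parameter set for a model
#'
#' @param model A `dbn_model`.
#' @param tables Named list of CPT matrices, one per family (families are the
#'   node names, plus `"<node>.init"` for nodes with cross-trial parents).
#' @param flags Optional named list of character matrices mirroring `tables`.
#' @return An object of class `dbn_params`.
#' @export
dbn_params <- function(model, tables, flags = NULL) {
  fams <- model_families(model)
  stopifnot(setequal(names(tables), names(fams)))
  cpts <- lapply(names(fams), function(nm) {
    f <- fams[[nm]]
    tab <- tables[[nm]]
    nr <- prod(c(f$parent_cards, 1L))
    if (!is.matrix(tab) || nrow(tab) != nr || ncol(tab) != f$card)
      stop("CPT '", nm, "' must be a ", nr, " x ", f$card, " matrix")
    if (any(tab < 0) || any(tab > 1) || any(abs(rowSums(tab) - 1) > 1e-12))
      stop("CPT '", nm, "' rows must be probabilities summing to 1 within 1e-12")
    dimnames(tab) <- NULL
    fl <- if (!is.null(flags)) flags[[nm]] else NULL
    if (!is.null(fl)) dimnames(fl) <- NULL
    list(node = f$node, kind = f$kind, parents = f$parents,
         parent_cards = f$parent_cards, table = tab, flags = fl)
  })
  names(cpts) <- names(fams)
  structure(list(model = model$name, cpts = cpts), class = "dbn_params")
}

#' @export
print.dbn_params <- function(x, digits = 3, ...) {
  cat("Parameter set for model '", x$model, "'\n", sep = "")
  for (nm in names(x$cpts)) {
    f <- x$cpts[[nm]]
    cat("\n", nm, ": P(", f$node, " | ", paste(f$parents, collapse = ", "),
        if (f$kind == "init") ") [chain start]" else ")", "\n", sep = "")
    tab <- round(f$table, digits)
    rownames(tab) <- parent_config_labels(f)
    print(tab)
  }
  invisible(x)
}

parent_config_labels <- function(fam) {
  if (!length(fam$parents)) return("(root)")
  grid <- do.call(expand.grid, rev(lapply(fam$parent_cards, seq_len)))
  grid <- grid[, rev(seq_along(fam$parents)), drop = FALSE]
  apply(grid, 1L, function(s) paste0(fam$parents, "=", s, collapse = ","))
}

# Flat Dirichlet rows (uniform over the simplex).
rdirichlet_rows <- function(n, k) {
  g <- matrix(stats::rgamma(n * k, shape = 1), n, k)
  g / rowSums(g)
}

#' Sample a random valid parameter set
#'
#' Rows are drawn uniformly from the probability simplex; no orientation
#' constraints are imposed. Useful for randomized property tests.
#'
#' @param model A `dbn_model`.
#' @param seed Integer seed.
#' @return A `dbn_params`.
#' @export
random_params <- function(model, seed = 1L) {
  fams <- model_families(model)
  tabs <- withr_seed(seed, lapply(fams, function(f)
    rdirichlet_rows(prod(c(f$parent_cards, 1L)), f$card)))
  dbn_params(model, tabs)
}

#' Sample a constrained random prior for EM initialization
#'
#' Draws every CPT row uniformly from the simplex, then redraws the
#' constrained families until all orientation inequalities of the model hold,
#' so that initialization starts inside the interpretable (off/on) portion of
#' the parameter space.
#'
#' @param model A `dbn_model`.
#' @param seed Integer seed; deterministic given the seed.
#' @return A `dbn_params` that passes [check_orientation()].
#' @export
sample_constrained_prior <- function(model, seed = 1L) {
  fams <- model_families(model)
  cons_by_node <- split(model$constraints,
                        vapply(model$constraints, `[[`, "", "node"))
  node_ok <- function(tab, cons) {
    all(vapply(cons, function(cn) {
      if (cn$type == "bound") {
        if (cn$op == ">") tab[cn$row, cn$col] > cn$bound else tab[cn$row, cn$col] < cn$bound
      } else tab[cn$row_hi, cn$col] > tab[cn$row_lo, cn$col]
    }, TRUE))
  }
  withr_seed(seed, {
    tabs <- lapply(names(fams), function(nm) {
      f <- fams[[nm]]
      nr <- prod(c(f$parent_cards, 1L))
      tab <- rdirichlet_rows(nr, f$card)
      cons <- cons_by_node[[nm]]   # constraints address transition families only
      if (!is.null(cons)) while (!node_ok(tab, cons)) tab <- rdirichlet_rows(nr, f$card)
      tab
    })
    names(tabs) <- names(fams)
    dbn_params(model, tabs)
  })
}

# Sum of squared differences between all CPT entries of two parameter sets
# (including the redundant last columns, exactly as stored).
param_distance <- function(a, b) {
  stopifnot(identical(names(a$cpts), names(b$cpts)))
  sum(vapply(names(a$cpts), function(nm)
    sum((a$cpts[[nm]]$table - b$cpts[[nm]]$table)^2), 0))
}

# ---- JSON serialization -----------------------------------------------------

#' Save / load parameter sets as JSON
#'
#' The schema records the model name and, per family, the node, parent order,
#' row-major table entries and provenance flags; loading re-validates row
#' sums and shapes.
#'
#' @param params A `dbn_params`.
#' @param path File path.
#' @return `load_params` returns a `dbn_params`; `save_params` its path,
#'   invisibly.
#' @export
save_params <- function(params, path) {
  obj <- list(
    model = params$model,
    families = lapply(params$cpts, function(f) {
      out <- list(node = f$node, kind = f$kind, parents = as.list(f$parents),
                  n_row = nrow(f$table), n_col = ncol(f$table),
                  entries = as.vector(t(f$table)))
      if (!is.null(f$flags)) out$flags <- as.vector(t(f$flags))
      out
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_params
#' @param model The `dbn_model` the file is expected to parameterize.
#' @export
load_params <- function(path, model) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$model, model$name))
    stop("file parameterizes model '", obj$model, "', not '", model$name, "'")
  tabs <- lapply(obj$families, function(f)
    matrix(unlist(f$entries), f$n_row, f$n_col, byrow = TRUE))
  flags <- lapply(obj$families, function(f) {
    if (is.null(f$flags)) NULL else matrix(unlist(f$flags), f$n_row, f$n_col, byrow = TRUE)
  })
  dbn_params(model, tabs, flags = if (all(vapply(flags, is.null, TRUE))) NULL else flags)
}
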