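# Shared fixtures: a sharply identified modified-Mathews parameter set (all
# orientation inequalities hold with wide margins, so hidden-state labels
# are strongly pinned by the data) and small simulated datasets.

sharp_mathews_mod <- function() {
  m <- build_model("mathews_mod")
  mk <- function(p) cbind(1 - p, p)
  dbn_params(m, list(
    E = mk(c(0.15, 0.85, 0.75, 0.2)), E.init = mk(0.4),
    V = mk(c(0.2, 0.3, 0.3, 0.9)),   V.init = mk(0.5),
    DT = mk(c(0.08, 0.03, 0.75, 0.95)),
    DD = mk(c(0.1, 0.2, 0.55, 0.9)),
    R = rbind(c(0.8, 0.15, 0.05), c(0.1, 0.8, 0.1),
              c(0.7, 0.2, 0.1), c(0.2, 0.6, 0.2))))
}

# Flip a hidden node's off/on labelling: reverse its CPT columns and the
# corresponding row blocks of every CPT that has the node as a parent.
# The model likelihood must be invariant under this relabelling.
flip_hidden_node <- function(model, params, node) {
  fams <- params$cpts
  for (nm in names(fams)) {
    f <- fams[[nm]]
    if (f$node == node) f$table <- f$table[, rev(seq_len(ncol(f$table))), drop = FALSE]
    if (node %in% f$parents) {
      i <- which(f$parents == node)
      cards <- f$parent_cards
      grid <- as.matrix(do.call(expand.grid, rev(lapply(cards, seq_len))))
      grid <- grid[, rev(seq_along(cards)), drop = FALSE]   # rows in CPT row order
      flipped <- grid
      flipped[, i] <- cards[i] + 1L - flipped[, i]
      mult <- rev(cumprod(rev(c(cards[-1], 1))))
      new_row <- as.integer(1L + (flipped - 1L) %*% mult)
      f$table <- f$table[order(new_row), , drop = FALSE]
    }
    fams[[nm]] <- f
  }
  dbn_params(model, lapply(fams, `[[`, "table"))
}
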