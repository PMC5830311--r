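# Contrast-based task-validation statistics: per-subject median-RT biases
# over trial conditions (correct trials only), robust one-tailed group
# tests, and the group-level detector-interpretability tests.

#' Built-in contrast specifications
#'
#' Conditions are trial predicates over the current and (within-run)
#' previous trial; "conflict" means the target and distractor valences
#' differ. The implemented contrasts (A minus B, with the hypothesized
#' one-tailed direction):
#' \describe{
#'   \item{conflict_main}{conflict vs non-conflict trials (+: slowing).}
#'   \item{threat_distractor}{neutral target with threat distractor vs both
#'     neutral (+).}
#'   \item{threat_target}{threat target with neutral distractor vs both
#'     neutral (-: speeding).}
#'   \item{gratton_all}{conflict preceded by non-conflict vs conflict
#'     preceded by conflict (+: conflict adaptation).}
#'   \item{gratton_post_threat_distractor}{as gratton_all, but the preceding
#'     conflict trial had a threat distractor (+).}
#'   \item{gratton_post_threat_target}{as gratton_all, but the preceding
#'     conflict trial had a threat target (+ hypothesized adaptation).}
#'   \item{slow_interference}{both-neutral trials preceded by both-threat vs
#'     preceded by both-neutral (-: post-threat speeding).}
#' }
#' Previous-trial predicates never cross run boundaries, so no first trial
#' of a run enters a sequential condition.
#'
#' @param name Contrast name.
#' @return A list with `name`, predicate functions `A` and `B`, and
#'   `direction` (+1 or -1).
#' @export
contrast_spec <- function(name = c("conflict_main", "threat_distractor",
                                   "threat_target", "gratton_all",
                                   "gratton_post_threat_distractor",
                                   "gratton_post_threat_target",
                                   "slow_interference")) {
  name <- match.arg(name)
  cf <- function(d) d$target_valence != d$distractor_valence
  ncf <- function(d) d$target_valence == "neutral" & d$distractor_valence == "neutral"
  prev_cf <- function(d) !is.na(d$prev_target) & d$prev_target != d$prev_distractor
  prev_ncf <- function(d) !is.na(d$prev_target) & d$prev_target == d$prev_distractor
  spec <- switch(name,
    conflict_main = list(A = cf, B = function(d) !cf(d), dir = +1),
    threat_distractor = list(
      A = function(d) d$target_valence == "neutral" & d$distractor_valence == "threat",
      B = ncf, dir = +1),
    threat_target = list(
      A = function(d) d$target_valence == "threat" & d$distractor_valence == "neutral",
      B = ncf, dir = -1),
    gratton_all = list(
      A = function(d) cf(d) & prev_ncf(d),
      B = function(d) cf(d) & prev_cf(d), dir = +1),
    gratton_post_threat_distractor = list(
      A = function(d) cf(d) & prev_ncf(d),
      B = function(d) cf(d) & prev_cf(d) & d$prev_distractor == "threat", dir = +1),
    gratton_post_threat_target = list(
      A = function(d) cf(d) & prev_ncf(d),
      B = function(d) cf(d) & prev_cf(d) & d$prev_target == "threat", dir = +1),
    slow_interference = list(
      A = function(d) ncf(d) & !is.na(d$prev_target) &
        d$prev_target == "threat" & d$prev_distractor == "threat",
      B = function(d) ncf(d) & !is.na(d$prev_target) &
        d$prev_target == "neutral" & d$prev_distractor == "neutral", dir = -1))
  list(name = name, A = spec$A, B = spec$B, direction = spec$dir)
}

# Previous-trial columns within each subject-run (NA at run starts).
add_prev_columns <- function(trials) {
  ord <- order(trials$subject_id, trials$run, trials$trial_index)
  t2 <- trials[ord, , drop = FALSE]
  same_chain <- c(FALSE, t2$subject_id[-1] == t2$subject_id[-nrow(t2)] &
                           t2$run[-1] == t2$run[-nrow(t2)])
  for (cc in c("target_valence", "distractor_valence", "correct")) {
    v <- c(t2[[cc]][1], t2[[cc]][-nrow(t2)])
    v[!same_chain] <- NA
    t2[[paste0("prev_", sub("_valence", "", cc))]] <- v
  }
  t2[match(seq_len(nrow(trials)), ord), , drop = FALSE]
}

#' Per-subject median-RT bias for a contrast
#'
#' Bias = median RT in condition A minus median RT in condition B, over
#' correct trials with a recorded RT only. Subjects with an empty cell are
#' excluded with a warning.
#'
#' @param trials Trial table with RTs, correctness and derived valences.
#' @param spec A [contrast_spec()] (or contrast name).
#' @param exclude_post_error Also drop trials immediately following an
#'   incorrect trial (within run).
#' @return Named numeric vector of per-subject biases (ms).
#' @export
contrast_bias <- function(trials, spec, exclude_post_error = FALSE) {
  if (is.character(spec)) spec <- contrast_spec(spec)
  d <- add_prev_columns(trials)
  usable <- !is.na(d$correct) & d$correct & !is.na(d$rt_ms)
  if (exclude_post_error)
    usable <- usable & !(!is.na(d$prev_correct) & !d$prev_correct)
  inA <- spec$A(d) & usable
  inB <- spec$B(d) & usable
  subjects <- unique(d$subject_id)
  bias <- vapply(subjects, function(s) {
    a <- d$rt_ms[inA & d$subject_id == s]
    b <- d$rt_ms[inB & d$subject_id == s]
    if (!length(a) || !length(b)) return(NA_real_)
    stats::median(a) - stats::median(b)
  }, 0)
  names(bias) <- subjects
  if (anyNA(bias)) {
    warning(sum(is.na(bias)), " subject(s) excluded from contrast '",
            spec$name, "' (empty condition cell)")
    bias <- bias[!is.na(bias)]
  }
  bias
}

#' Robust one-tailed one-sample test of per-subject biases
#'
#' Yuen-style one-sample t on the 20%-trimmed mean against zero (winsorized
#' variance, df = n - 2g - 1 with g trimmed per tail), one-tailed in the
#' stated direction. `robust = FALSE` gives the plain Student t for
#' comparison.
#'
#' @param biases Per-subject values (ms).
#' @param direction +1 (greater than zero) or -1 (less than zero).
#' @param trim Trimming proportion per tail.
#' @param robust Use the trimmed statistic (default) or plain t.
#' @return List with `t`, `p`, `df`, `estimate` (trimmed or plain mean),
#'   `se`, `n`, `method`.
#' @export
robust_one_tailed_t <- function(biases, direction = +1, trim = 0.2, robust = TRUE) {
  x <- biases[is.finite(biases)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 finite values")
  if (robust) {
    g <- floor(trim * n)
    xs <- sort(x)
    win <- pmin(pmax(xs, xs[g + 1L]), xs[n - g])
    sw2 <- stats::var(win)
    if (sw2 <= 0) stop("degenerate sample: zero winsorized variance")
    est <- mean(xs[(g + 1L):(n - g)])
    se <- sqrt(sw2) / ((1 - 2 * trim) * sqrt(n))
    df <- n - 2L * g - 1L
    method <- sprintf("Yuen one-sample trimmed t (trim = %g)", trim)
  } else {
    if (stats::var(x) <= 0) stop("degenerate sample: zero variance")
    est <- mean(x)
    se <- stats::sd(x) / sqrt(n)
    df <- n - 1L
    method <- "Student one-sample t"
  }
  tval <- est / se
  p <- if (direction >= 0) stats::pt(tval, df, lower.tail = FALSE)
       else stats::pt(tval, df, lower.tail = TRUE)
  list(t = tval, p = p, df = df, estimate = est, se = se, n = n, method = method)
}

#' Run the full battery of task-validation contrasts
#'
#' @inheritParams contrast_bias
#' @inheritParams robust_one_tailed_t
#' @return Data frame with one row per contrast: mean bias (ms), SE, t, p
#'   (one-tailed in the contrast's direction), df and subject count.
#' @export
run_contrasts <- function(trials, exclude_post_error = FALSE, robust = TRUE) {
  specs <- eval(formals(contrast_spec)$name)
  rows <- lapply(specs, function(nm) {
    sp <- contrast_spec(nm)
    b <- suppressWarnings(contrast_bias(trials, sp, exclude_post_error))
    tt <- robust_one_tailed_t(b, sp$direction, robust = robust)
    data.frame(contrast = nm, direction = sp$direction,
               mean_bias_ms = mean(b), estimate_ms = tt$estimate,
               se = tt$se, t = tt$t, p = tt$p, df = tt$df, n_subjects = tt$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group-level detector-interpretability tests
#'
#' For each detector node, computes within each subject the Pearson
#' correlation between the decoded (or simulated) 0/1 node timecourse and
#' the actual stimulus valence, then a simple one-tailed t-test of the
#' per-subject correlations against zero (greater). Subjects with a
#' constant node or stimulus timecourse have an undefined correlation and
#' are dropped; the count is reported.
#'
#' @param trials Trial table containing the node columns (e.g.
#'   `viterbi_DT` from [predict.dbn_fit()]) and valence columns.
#' @param nodes Named character vector mapping node columns to valence
#'   columns.
#' @return Data frame with one row per node: mean r, t, one-tailed p,
#'   subjects used and dropped.
#' @export
detector_interpretability <- function(trials,
    nodes = c(viterbi_DT = "target_valence", viterbi_DD = "distractor_valence")) {
  rows <- lapply(names(nodes), function(nd) {
    stim_col <- nodes[[nd]]
    rs <- vapply(unique(trials$subject_id), function(s) {
      i <- trials$subject_id == s
      x <- trials[[nd]][i]
      y <- as.integer(trials[[stim_col]][i] == "threat")
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
      stats::cor(x, y)
    }, 0)
    used <- rs[!is.na(rs)]
    degenerate <- function() {        # e.g. a perfect detector in every subject
      list(t = sign(mean(used)) * Inf,
           p = if (mean(used) > 0) 0 else if (mean(used) < 0) 1 else 0.5)
    }
    res <- tryCatch({
      tt <- stats::t.test(used, alternative = "greater")
      list(t = unname(tt$statistic), p = tt$p.value)
    }, error = function(e) degenerate())
    tval <- res$t; pval <- res$p
    data.frame(node = nd, mean_r = mean(used), t = tval,
               p = pval, n_subjects = length(used),
               n_dropped = sum(is.na(rs)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
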