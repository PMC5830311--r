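# Emotional-Stroop task structure: factorial face/scene valences, two
# attend-instruction blocks per run, jittered event-related timing, and the
# median-split discretization of responses into fast/slow/error.

VALENCES <- c("neutral", "threat")
INSTRUCTIONS <- c("attend_face", "attend_scene")
RESPONSE_CLASSES <- c("fast", "slow", "error")

#' Generate a balanced stimulus sequence
#'
#' Draws a pseudo-random trial sequence in which the four face-valence by
#' scene-valence cells each occur exactly `n_trials / 4` times (so the two
#' valences are exactly uncorrelated) and no face or scene image identity
#' repeats on consecutive trials. Valences may repeat; only image identities
#' are constrained, so consecutive neutral/neutral compounds (needed for the
#' slow-interference contrast) remain possible.
#'
#' @param n_trials Number of trials; must be divisible by 4.
#' @param seed Integer seed; the sequence is deterministic given the seed.
#' @param image_pool_sizes Named integer vector with elements `face` and
#'   `scene`: number of distinct images available per valence class (>= 2).
#' @return A data frame with columns `face_valence`, `scene_valence`,
#'   `face_image_id`, `scene_image_id`. Image ids are labels like `"face_threat_3"`.
#' @export
generate_stimulus_sequence <- function(n_trials = 64L, seed = 1L,
                                       image_pool_sizes = c(face = 8L, scene = 8L)) {
  if (n_trials %% 4L != 0L)
    stop("design error: n_trials must be divisible by 4 for exact cell balance")
  if (any(image_pool_sizes < 2L))
    stop("feasibility error: image pools must hold >= 2 images per valence to avoid repeats")
  withr_seed(seed, {
    cells <- expand.grid(face_valence = VALENCES, scene_valence = VALENCES,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    idx <- sample(rep(seq_len(4L), n_trials / 4L))
    seq_df <- cells[idx, , drop = FALSE]
    rownames(seq_df) <- NULL
    seq_df$face_image_id <- pick_images("face", seq_df$face_valence, image_pool_sizes[["face"]])
    seq_df$scene_image_id <- pick_images("scene", seq_df$scene_valence, image_pool_sizes[["scene"]])
    seq_df
  })
}

# Sample image labels of the given valences, never repeating the immediately
# preceding trial's label in the same field.
pick_images <- function(kind, valences, pool_size) {
  n <- length(valences)
  ids <- character(n)
  prev <- ""
  for (i in seq_len(n)) {
    pool <- paste0(kind, "_", valences[i], "_", seq_len(pool_size))
    pool <- setdiff(pool, prev)
    ids[i] <- pool[sample.int(length(pool), 1L)]
    prev <- ids[i]
  }
  ids
}

# Evaluate `expr` under a local RNG seed without disturbing the caller's RNG.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Build the timing and block structure of one run
#'
#' A run holds two instruction blocks of `n_trials_per_block` trials each;
#' within blocks the design is event-related with interstimulus intervals
#' drawn uniformly from `isi_range_s`. Stimuli are modeled as impulses at
#' onset.
#'
#' @param n_trials_per_block Trials per block (>= 1).
#' @param instruction_order Length-2 character vector ordering the
#'   `attend_face` / `attend_scene` blocks.
#' @param isi_range_s Numeric pair `(min, max)` of the ISI jitter in seconds.
#' @param seed Integer seed for the jitter.
#' @return An object of class `run_design`: list with `n_trials`, `blocks`
#'   (data frame `start`, `end`, `instruction`), `onsets` (seconds from run
#'   start), `instruction` (per trial) and `isi_range_s`.
#' @export
build_run_design <- function(n_trials_per_block = 32L,
                             instruction_order = c("attend_face", "attend_scene"),
                             isi_range_s = c(3, 7), seed = 1L) {
  if (length(isi_range_s) != 2L || isi_range_s[1] >= isi_range_s[2] || isi_range_s[1] < 0)
    stop("invalid ISI range: need 0 <= min < max")
  if (n_trials_per_block < 1L) stop("n_trials_per_block must be >= 1")
  instruction_order <- match.arg(instruction_order, INSTRUCTIONS, several.ok = TRUE)
  if (length(unique(instruction_order)) != 2L)
    stop("instruction_order must contain both instructions")
  n <- 2L * n_trials_per_block
  isis <- withr_seed(seed, stats::runif(n, isi_range_s[1], isi_range_s[2]))
  onsets <- cumsum(c(0, isis[-n]))
  structure(list(
    n_trials = n,
    blocks = data.frame(
      start = c(1L, n_trials_per_block + 1L),
      end = c(n_trials_per_block, n),
      instruction = instruction_order,
      stringsAsFactors = FALSE),
    onsets = onsets,
    instruction = rep(instruction_order, each = n_trials_per_block),
    isi_range_s = isi_range_s
  ), class = "run_design")
}

#' @export
print.run_design <- function(x, ...) {
  cat("Emotional-Stroop run design:", x$n_trials, "trials,",
      "blocks", paste(x$blocks$instruction, collapse = " then "),
      sprintf("; ISI U(%g, %g) s\n", x$isi_range_s[1], x$isi_range_s[2]))
  invisible(x)
}

#' Recode face/scene valences into target/distractor valences
#'
#' Under `attend_face` the face is the target and the scene the distractor;
#' under `attend_scene` the roles swap. Vectorized.
#'
#' @param face_valence,scene_valence Character vectors in `{"neutral","threat"}`.
#' @param instruction Character vector in `{"attend_face","attend_scene"}`.
#' @return A data frame with columns `target_valence`, `distractor_valence`.
#' @export
derive_target_distractor <- function(face_valence, scene_valence, instruction) {
  stopifnot(all(face_valence %in% VALENCES), all(scene_valence %in% VALENCES),
            all(instruction %in% INSTRUCTIONS))
  face_is_target <- instruction == "attend_face"
  data.frame(
    target_valence = ifelse(face_is_target, face_valence, scene_valence),
    distractor_valence = ifelse(face_is_target, scene_valence, face_valence),
    stringsAsFactors = FALSE)
}

#' Assemble the full group trial table
#'
#' Builds the default study design: `n_subjects` subjects times `n_runs` runs
#' of two blocks. The stimulus sequence and timing of each run are shared by
#' all subjects (the trial-type sequence is pseudo-randomized once and
#' administered identically to every participant); the attend-block order
#' alternates across runs (face-first on odd runs) as a counterbalancing
#' stand-in.
#'
#' @param n_subjects,n_runs,n_trials_per_block Design counts; defaults give
#'   24 x 3 x 64 = 4608 trials.
#' @param isi_range_s ISI jitter range in seconds.
#' @param seed Integer seed.
#' @return A trial table: one row per trial with subject/run/trial
#'   identifiers, stimulus descriptors, instruction, onset, and the derived
#'   target/distractor valences. Response columns (`rt_ms`, `correct`,
#'   `response_class`) are absent until responses are simulated or ingested.
#' @export
build_group_design <- function(n_subjects = 24L, n_runs = 3L,
                               n_trials_per_block = 32L,
                               isi_range_s = c(3, 7), seed = 1L) {
  runs <- lapply(seq_len(n_runs), function(r) {
    ord <- if (r %% 2L == 1L) c("attend_face", "attend_scene") else c("attend_scene", "attend_face")
    rd <- build_run_design(n_trials_per_block, ord, isi_range_s, seed = seed + 101L * r)
    stim <- generate_stimulus_sequence(rd$n_trials, seed = seed + 211L * r)
    cbind(data.frame(run = r, trial_index = seq_len(rd$n_trials),
                     instruction = rd$instruction, onset_s = rd$onsets,
                     stringsAsFactors = FALSE),
          stim)
  })
  run_tab <- do.call(rbind, runs)
  out <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    cbind(data.frame(subject_id = sprintf("sub%02d", s), stringsAsFactors = FALSE), run_tab)
  }))
  td <- derive_target_distractor(out$face_valence, out$scene_valence, out$instruction)
  out$target_valence <- td$target_valence
  out$distractor_valence <- td$distractor_valence
  rownames(out) <- NULL
  out
}

#' Median-split discretization of responses
#'
#' For each subject, the median of the correct reaction times is computed and
#' correct trials are classed `fast` (rt <= median; the tie goes to fast so
#' every correct trial is classified) or `slow` (rt > median). Incorrect
#' trials and trials with a missing reaction time are classed `error`.
#'
#' @param trials Trial table with columns `subject_id`, `rt_ms`, `correct`.
#' @return The table with a `response_class` column added and a per-subject
#'   `rt_median_ms` column holding the split point used.
#' @export
discretize_responses <- function(trials) {
  stopifnot(all(c("subject_id", "rt_ms", "correct") %in% names(trials)))
  trials$response_class <- NA_character_
  trials$rt_median_ms <- NA_real_
  for (s in unique(trials$subject_id)) {
    i <- trials$subject_id == s
    ok <- i & !is.na(trials$correct) & trials$correct & !is.na(trials$rt_ms)
    if (!any(ok))
      stop("discretization error: subject ", s, " has no correct trial with a reaction time")
    med <- stats::median(trials$rt_ms[ok])
    trials$rt_median_ms[i] <- med
    trials$response_class[i] <- "error"
    trials$response_class[ok] <- ifelse(trials$rt_ms[ok] <= med, "fast", "slow")
  }
  trials
}
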