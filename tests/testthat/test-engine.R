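# Exact inference: likelihoods and Viterbi paths against the brute-force
# enumeration oracle, evidence recoding, degenerate evidence, tie-breaking,
# and chain exchangeability.

test_that("evidence conversion recodes trials per model family", {
  tr <- data.frame(subject_id = "s1", run = 1, trial_index = 1,
                   face_valence = "threat", scene_valence = "neutral",
                   instruction = "attend_scene",
                   target_valence = "neutral", distractor_valence = "threat",
                   response_class = "slow", stringsAsFactors = FALSE)
  mm <- build_model("mathews")
  em <- trials_to_evidence(tr, mm)
  eng <- stroopdbn:::get_engine(mm)
  st <- eng$ecfg[em$chains[[1]]$combo, ]
  expect_equal(unname(st[c("T", "Dv", "R")]), c(1, 2, 2))  # T=neutral, Dv=threat, slow
  mc <- build_model("cohen")
  ec <- trials_to_evidence(tr, mc)
  engc <- stroopdbn:::get_engine(mc)
  stc <- engc$ecfg[ec$chains[[1]]$combo, ]
  expect_equal(unname(stc[c("F", "S", "I", "R")]), c(2, 1, 2, 2))
  expect_error(trials_to_evidence(tr[, setdiff(names(tr), "response_class")], mm),
               "discretized")
})

test_that("likelihood and Viterbi match brute-force enumeration on short chains", {
  for (mn in c("cohen", "cohen_mod", "mathews", "mathews_mod")) {
    m <- build_model(mn)
    for (rep in 1:3) {
      T_ <- 2 + (rep %% 3)
      p <- random_params(m, seed = 50 * rep + T_)
      obs <- rand_obs(m, T_, seed = rep + 7)
      ev <- trials_to_evidence(obs_to_trials(m, obs), m)
      expect_equal(sequence_loglik(m, p, ev), brute_loglik(m, p, obs),
                   tolerance = 1e-10)
      expect_equal(unclass(viterbi_decode(m, p, ev))[, m$hidden],
                   brute_viterbi(m, p, obs)[, m$hidden])
    }
  }
  m <- build_model("wyble")  # 128 configurations: enumerable for length-2 chains here
  p <- random_params(m, seed = 4)
  obs <- rand_obs(m, 2, seed = 4)
  ev <- trials_to_evidence(obs_to_trials(m, obs), m)
  expect_equal(sequence_loglik(m, p, ev), brute_loglik(m, p, obs), tolerance = 1e-10)
  expect_equal(unclass(viterbi_decode(m, p, ev))[, m$hidden],
               brute_viterbi(m, p, obs)[, m$hidden])
})

test_that("degenerate likelihoods behave as documented", {
  m <- build_model("mathews")
  p <- random_params(m, seed = 1)
  # uniform response CPT: hidden nodes marginalize out, loglik = n log(1/3)
  p$cpts$R$table[] <- 1 / 3
  obs <- rand_obs(m, 6, seed = 2)
  ev <- trials_to_evidence(obs_to_trials(m, obs), m)
  expect_equal(sequence_loglik(m, p, ev), 6 * log(1 / 3), tolerance = 1e-12)
  # impossible evidence: -Inf from the likelihood, an error (naming the
  # trial) from the decoder
  p2 <- sharp_mathews_mod()
  p2$cpts$R$table <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0), c(0, 1, 0))
  p2$cpts$DT$table <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))  # DT copies T
  p2$cpts$DD$table <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  m2 <- build_model("mathews_mod")
  tr <- obs_to_trials(m2, data.frame(T = 1L, Dv = 1L, R = 3L))  # error impossible
  ev2 <- trials_to_evidence(tr, m2)
  expect_equal(sequence_loglik(m2, p2, ev2), -Inf)
  expect_error(viterbi_decode(m2, p2, ev2), "zero-probability evidence at trial 1")
})

test_that("deterministic parameters decode to the generating states; full ties pick the lowest configuration", {
  m <- build_model("mathews_mod")
  p <- sharp_mathews_mod()
  onehot <- function(tab) t(apply(tab, 1, function(r) {
    o <- numeric(length(r)); o[which.max(r)] <- 1; o
  }))
  p <- dbn_params(m, lapply(p$cpts, function(f) onehot(f$table)))  # determinize
  des <- build_group_design(1, 1, 8, seed = 3)
  dat <- forward_sample(m, p, des, seed = 4)
  ev <- trials_to_evidence(dat, m)
  expect_equal(sequence_loglik(m, p, ev), 0)   # probability-1 evidence
  v <- viterbi_decode(m, p, ev)
  expect_equal(unclass(v)[, m$hidden],
               as.matrix(dat[, paste0("state_", m$hidden)]),
               ignore_attr = TRUE)
  # all-uniform CPTs tie every configuration: the first (all-off) one wins
  pu <- random_params(m, 1)
  for (nm in names(pu$cpts)) pu$cpts[[nm]]$table[] <- 1 / ncol(pu$cpts[[nm]]$table)
  pu <- dbn_params(m, lapply(pu$cpts, `[[`, "table"))
  vu <- viterbi_decode(m, pu, ev)
  expect_true(all(vu == 0L))
})

test_that("chains are exchangeable: permuting chain order leaves results identical", {
  m <- build_model("mathews_mod")
  p <- sharp_mathews_mod()
  des <- build_group_design(3, 2, 8, seed = 9)
  dat <- forward_sample(m, p, des, seed = 10)
  ev <- trials_to_evidence(dat, m)
  ev_perm <- ev
  ev_perm$chains <- rev(ev$chains)
  expect_identical(sequence_loglik(m, p, ev), sequence_loglik(m, p, ev_perm))
  init <- sample_constrained_prior(m, 3)
  f1 <- em_fit(m, ev, init, max_iter = 20, vet = FALSE)
  f2 <- em_fit(m, ev_perm, init, max_iter = 20, vet = FALSE)
  # identical up to floating-point summation order across chains
  expect_equal(f1$final_loglik, f2$final_loglik, tolerance = 1e-12)
  expect_equal(f1$params$cpts$R$table, f2$params$cpts$R$table, tolerance = 1e-10)
})
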