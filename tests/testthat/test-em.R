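# Baum-Welch EM: monotonicity, fixed points, constrained priors,
# multi-restart behavior, vetting, and parameter recovery on a sharply
# identified generating model.

test_that("constrained priors satisfy the orientation constraints and are seeded", {
  for (mn in c("cohen", "mathews_mod", "wyble")) {
    m <- build_model(mn)
    p1 <- sample_constrained_prior(m, seed = 11)
    p2 <- sample_constrained_prior(m, seed = 11)
    p3 <- sample_constrained_prior(m, seed = 12)
    expect_true(check_orientation(p1, m)$ok)
    expect_identical(p1$cpts$D1, p2$cpts$D1)
    expect_false(identical(p1, p3))
    for (f in p1$cpts) expect_true(all(abs(rowSums(f$table) - 1) < 1e-12))
  }
})

test_that("EM log-likelihood is non-decreasing from random starts", {
  for (mn in c("mathews", "mathews_mod", "cohen_mod")) {
    m <- build_model(mn)
    truth <- random_params(m, seed = 21)
    des <- build_group_design(2, 1, 16, seed = 22)
    dat <- forward_sample(m, truth, des, seed = 23)
    ev <- trials_to_evidence(dat, m)
    for (s in 1:3) {
      f <- em_fit(m, ev, sample_constrained_prior(m, s), max_iter = 40, vet = FALSE)
      expect_true(all(diff(f$loglik_trajectory) >= -1e-8))
    }
  }
})

test_that("a deterministic fixed point converges immediately with unchanged loglik", {
  m <- build_model("mathews")
  pdet <- dbn_params(m, list(
    E = cbind(0, 1), V = cbind(0, 1),                 # modulators pinned on
    DT = cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)),         # detectors copy stimuli
    DD = cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)),
    R = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 1, 0), c(0, 0, 1))))
  des <- build_group_design(1, 1, 8, seed = 31)
  dat <- forward_sample(m, pdet, des, seed = 32)
  ev <- trials_to_evidence(dat, m)
  f <- em_fit(m, ev, pdet, tol = 1e-6, max_iter = 50, vet = FALSE)
  expect_lte(f$n_iterations, 2)
  expect_true(f$converged)
  # the additive M-step floor perturbs a fully deterministic optimum by ~1e-8
  expect_equal(f$final_loglik, f$loglik_trajectory[1], tolerance = 1e-7)
})

test_that("multi-restart reduces to a single fit, is nested-monotone, and vets the selection", {
  m <- build_model("mathews_mod")
  p <- sharp_mathews_mod()
  des <- build_group_design(3, 1, 16, seed = 41)
  dat <- forward_sample(m, p, des, seed = 42)
  ev <- trials_to_evidence(dat, m)
  mr1 <- multi_restart_fit(m, ev, n_restarts = 1, seed = 5, max_iter = 30)
  single <- em_fit(m, ev, sample_constrained_prior(m, 5 + 7919L), max_iter = 30)
  expect_equal(mr1$fits[[1]]$final_loglik, single$final_loglik)
  mr3 <- multi_restart_fit(m, ev, n_restarts = 3, seed = 5, max_iter = 30)
  mr8 <- multi_restart_fit(m, ev, n_restarts = 8, seed = 5, max_iter = 30)
  expect_gte(mr8$fits[[1]]$final_loglik, mr3$fits[[1]]$final_loglik)
  if (!is.na(mr8$selected_index)) {
    v <- mr8$selected$vetting
    expect_true(v$orientation_ok)
    expect_false(v$trivial_solution_flag)
  }
})

test_that("vetting flags duplicated hidden timecourses and records undefined pairs", {
  # Cohen parameters where both detectors deterministically copy the
  # attention node: decoded D1 and D2 are identical (r = 1) -> trivial
  m <- build_model("cohen")
  copyA <- cbind(c(1, 0, 1, 0), c(0, 1, 0, 1))   # rows (F/S, A): child = A
  tabs <- list(A = cbind(c(1, 0), c(0, 1)),       # A copies instruction
               D1 = copyA, D2 = copyA,
               R = matrix(1 / 3, 4, 3))
  p <- dbn_params(m, tabs)
  des <- build_group_design(2, 1, 8, seed = 51)
  dat <- forward_sample(m, p, des, seed = 52)
  ev <- trials_to_evidence(dat, m)
  fit <- structure(list(params = p), class = "dbn_fit")
  v <- vet_solution(fit, m, ev)
  expect_true(v$trivial_solution_flag)
  expect_equal(v$max_abs_node_corr, 1)
  # constant node timecourses give undefined correlations, recorded not flagged
  tabs2 <- tabs
  tabs2$A <- cbind(c(1, 1), c(0, 0))              # A always off
  tabs2$D1 <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)) # D1 copies F
  tabs2$D2 <- cbind(c(1, 1, 1, 1), c(0, 0, 0, 0)) # D2 always off
  p2 <- dbn_params(m, tabs2)
  dat2 <- forward_sample(m, p2, des, seed = 53)
  v2 <- vet_solution(structure(list(params = p2), class = "dbn_fit"),
                     m, trials_to_evidence(dat2, m))
  expect_gt(v2$undefined_pairs, 0)
  expect_false(v2$trivial_solution_flag)
})

test_that("EM recovers a sharply identified generating model as data grow", {
  m <- build_model("mathews_mod")
  truth <- sharp_mathews_mod()
  mae <- function(fit) {
    mean(abs(unlist(lapply(names(truth$cpts), function(nm)
      fit$params$cpts[[nm]]$table - truth$cpts[[nm]]$table))))
  }
  des1 <- build_group_design(24, 3, 32, seed = 10)
  dat1 <- forward_sample(m, truth, des1, seed = 11)
  f1 <- em_fit(m, trials_to_evidence(dat1, m), truth, tol = 1e-6,
               max_iter = 400, vet = FALSE)
  des2 <- build_group_design(48, 10, 32, seed = 20)   # 30720 trials
  dat2 <- forward_sample(m, truth, des2, seed = 21)
  f2 <- em_fit(m, trials_to_evidence(dat2, m), truth, tol = 1e-6,
               max_iter = 400, vet = FALSE)
  expect_lt(mae(f2), mae(f1))        # estimates concentrate with n
  expect_lt(mae(f2), 0.05)
  # response CPT (the least constrained family) is recovered closely
  expect_lt(max(abs(f2$params$cpts$R$table - truth$cpts$R$table)), 0.05)
})
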