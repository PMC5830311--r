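# Synthetic BOLD generation and the amplitude-modulated GLM: canonical
# double-gamma HRF, impulse event regressors weighted by mean-centered
# trial modulators, per-voxel OLS, robust group tests, and cluster-extent
# thresholding.

#' Canonical double-gamma hemodynamic response function
#'
#' `h(t) = g(t; 6, 1) - g(t; 16, 1) / 6` with `g` the gamma density: peak
#' near 6 s, undershoot near 16 s, undershoot ratio 1/6. Scaled to unit
#' peak.
#'
#' @param t Time in seconds (vector).
#' @return HRF values.
#' @export
hrf_double_gamma <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) - stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  tt <- seq(0, 32, by = 0.01)
  pk <- max(stats::dgamma(tt, 6, 1) - stats::dgamma(tt, 16, 1) / 6)
  h / pk
}

#' Build an amplitude-modulated design matrix
#'
#' Events are impulses at their onsets. The matrix holds an intercept, a
#' linear drift, an unmodulated event regressor (carrying condition-average
#' activity), and one amplitude-modulated regressor per modulator whose
#' trial weights are mean-centered before convolution (so each AM column's
#' pre-convolution weights sum to zero). All regressors are convolved with
#' the canonical HRF on a fine grid and sampled at the volume times.
#'
#' @param onsets Event onsets in seconds.
#' @param modulators Numeric matrix (trials x modulators) with column
#'   names; e.g. 0/1 hidden-state timecourses, RTs, stimulus valences.
#' @param TR Repetition time in seconds.
#' @param n_volumes Number of volumes.
#' @param dt Fine-grid resolution for convolution (s).
#' @return Object of class `am_design`: list with `X` (n_volumes x
#'   columns), `am_weights` (the centered weights), `onsets`, `TR`.
#' @export
build_design_matrix <- function(onsets, modulators, TR = 2, n_volumes, dt = 0.1) {
  if (TR <= 0) stop("TR must be positive")
  modulators <- as.matrix(modulators)
  if (nrow(modulators) != length(onsets))
    stop("modulators must have one row per event onset")
  scan_end <- n_volumes * TR
  if (any(onsets >= scan_end)) stop("onset beyond scan end")
  grid_n <- ceiling(scan_end / dt) + 1L
  hrf <- hrf_double_gamma(seq(0, 32, by = dt))
  bins <- pmin(grid_n, floor(onsets / dt) + 1L)
  conv_col <- function(w) {
    u <- numeric(grid_n)
    for (i in seq_along(bins)) u[bins[i]] <- u[bins[i]] + w[i]
    v <- stats::convolve(u, rev(hrf), type = "open")[seq_len(grid_n)]
    v[floor((0:(n_volumes - 1L)) * TR / dt) + 1L]
  }
  centered <- scale(modulators, center = TRUE, scale = FALSE)
  X <- cbind(
    intercept = 1,
    drift = seq_len(n_volumes) / n_volumes - 0.5,
    event = conv_col(rep(1, length(onsets))))
  for (j in seq_len(ncol(centered)))
    X <- cbind(X, conv_col(centered[, j]))
  colnames(X) <- c("intercept", "drift", "event", colnames(modulators))
  structure(list(X = X, am_weights = centered, onsets = onsets, TR = TR,
                 n_volumes = n_volumes), class = "am_design")
}

#' Synthesize a BOLD dataset with planted modulator effects
#'
#' Voxel signal = baseline + sum over modulators of beta[voxel, r] times the
#' HRF-convolved mean-centered modulator-r regressor + AR(1) Gaussian noise
#' (marginal standard deviation `sigma`). Ground-truth betas are stored for
#' recovery tests.
#'
#' @param onsets Event onsets (s).
#' @param modulators Trials x modulators matrix (see
#'   [build_design_matrix()]).
#' @param betas n_voxels x n_modulators matrix of true effects.
#' @param noise List with `sigma` (marginal SD) and `ar1` (lag-1
#'   autocorrelation).
#' @param TR,n_volumes Scan timing; defaults cover the last onset + 20 s.
#' @param grid Voxel grid dimensions (length 3).
#' @param baseline Constant baseline signal.
#' @param event_amplitude Shared amplitude of the unmodulated event
#'   response.
#' @param seed Integer seed.
#' @return Object of class `bold_dataset`: `signal` (voxels x time),
#'   `grid`, `TR`, `onsets`, `modulators`, `betas_true`, `design` (the
#'   `am_design`).
#' @export
synthesize_bold <- function(onsets, modulators, betas,
                            noise = list(sigma = 1, ar1 = 0.3),
                            TR = 2, n_volumes = NULL, grid = c(10, 10, 10),
                            baseline = 0, event_amplitude = 0, seed = 1L) {
  if (TR <= 0) stop("TR must be positive")
  modulators <- as.matrix(modulators)
  if (is.null(n_volumes)) n_volumes <- ceiling((max(onsets) + 20) / TR)
  nv <- prod(grid)
  betas <- as.matrix(betas)
  if (nrow(betas) != nv || ncol(betas) != ncol(modulators))
    stop("betas must be ", nv, " voxels x ", ncol(modulators), " modulators")
  des <- build_design_matrix(onsets, modulators, TR, n_volumes)
  Xam <- des$X[, -(1:3), drop = FALSE]
  clean <- betas %*% t(Xam) + baseline +
    if (event_amplitude != 0) rep(event_amplitude, nv) %o% des$X[, "event"] else 0
  sig <- withr_seed(seed, {
    innov_sd <- noise$sigma * sqrt(1 - noise$ar1^2)
    eps <- matrix(stats::rnorm(nv * n_volumes, sd = innov_sd), nv, n_volumes)
    if (noise$ar1 != 0) {
      eps[, 1] <- stats::rnorm(nv, sd = noise$sigma)
      for (t in 2:n_volumes) eps[, t] <- noise$ar1 * eps[, t - 1] + eps[, t]
    }
    clean + eps
  })
  structure(list(signal = sig, grid = grid, TR = TR, onsets = onsets,
                 modulators = modulators, betas_true = betas,
                 noise = noise, design = des), class = "bold_dataset")
}

#' @export
print.bold_dataset <- function(x, ...) {
  cat("Synthetic BOLD dataset:", paste(x$grid, collapse = "x"), "voxels,",
      ncol(x$signal), "volumes at TR", x$TR, "s;",
      length(x$onsets), "events\n")
  invisible(x)
}

#' Fit the amplitude-modulated GLM per voxel
#'
#' Ordinary least squares of every voxel timecourse on the design matrix;
#' t statistics use the residual variance with n - p degrees of freedom.
#' (The study-scale analogue used restricted-maximum-likelihood
#' prewhitening; OLS is the documented simplification here. With
#' `ar1_correct = TRUE` the standard errors are inflated by the
#' lag-1-autocorrelation effective-sample-size factor.)
#'
#' @param bold A `bold_dataset` (or a voxels x time matrix).
#' @param design An `am_design` (defaults to the one stored in `bold`).
#' @param ar1_correct Apply an AR(1) variance correction to the standard
#'   errors.
#' @return List with `beta`, `se`, `t` (voxels x regressors), `df`,
#'   `terms`.
#' @export
fit_am_glm <- function(bold, design = NULL, ar1_correct = FALSE) {
  if (inherits(bold, "bold_dataset")) {
    if (is.null(design)) design <- bold$design
    Y <- bold$signal
  } else Y <- bold
  X <- design$X
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(drop, collapse = ", "))
  }
  if (ncol(Y) != nrow(X)) stop("time dimension mismatch")
  bt <- t(qr.coef(qx, t(Y)))                      # voxels x p
  res <- Y - bt %*% t(X)
  df <- nrow(X) - ncol(X)
  s2 <- rowSums(res^2) / df
  if (ar1_correct) {
    rho <- rowSums(res[, -1, drop = FALSE] * res[, -ncol(res), drop = FALSE]) /
      pmax(rowSums(res^2), .Machine$double.eps)
    s2 <- s2 * (1 + rho) / pmax(1 - rho, .Machine$double.eps)
  }
  xtxi <- chol2inv(qr.R(qx))
  se <- sqrt(outer(s2, diag(xtxi)))
  list(beta = bt, se = se, t = bt / se, df = df, terms = colnames(X))
}

#' Group-level one-tailed test of subject beta maps
#'
#' Voxelwise one-sample test of the per-subject betas against zero using
#' the 20%-trimmed (Yuen) statistic, one-tailed in each requested
#' direction (positive and negative maps are both returned, as encoding
#' effects of either sign are of interest).
#'
#' @param beta_mat Subjects x voxels matrix for one regressor.
#' @param trim Trimming proportion (0 gives the plain t).
#' @return List with `t` (voxel vector), `df`, `p_pos` (greater), `p_neg`
#'   (less), `n_subjects`.
#' @export
group_test <- function(beta_mat, trim = 0.2) {
  beta_mat <- as.matrix(beta_mat)
  n <- nrow(beta_mat)
  if (n < 3L) stop("need at least 3 subjects")
  g <- floor(trim * n)
  stat <- apply(beta_mat, 2L, function(x) {
    xs <- sort(x)
    if (g > 0) {
      win <- pmin(pmax(xs, xs[g + 1L]), xs[n - g])
      est <- mean(xs[(g + 1L):(n - g)])
      se <- sqrt(stats::var(win)) / ((1 - 2 * trim) * sqrt(n))
    } else {
      est <- mean(xs); se <- stats::sd(xs) / sqrt(n)
    }
    est / se
  })
  df <- n - 2L * g - 1L
  list(t = stat, df = df,
       p_pos = stats::pt(stat, df, lower.tail = FALSE),
       p_neg = stats::pt(stat, df, lower.tail = TRUE),
       n_subjects = n)
}

#' Cluster-extent thresholding of a statistical map
#'
#' Thresholds the voxelwise p map at `p_thresh`, finds 6-connected
#' components of suprathreshold voxels on the 3D grid, and retains
#' components of size >= `k` (the cluster-extent threshold is
#' user-supplied; smoothness-based estimation is out of scope).
#'
#' @param t_map Voxel vector of statistics.
#' @param p_map Voxel vector of p values.
#' @param grid Grid dimensions (length 3, `prod(grid) == length(t_map)`).
#' @param p_thresh Uncorrected voxelwise threshold (e.g. 0.005).
#' @param k Minimum cluster size in voxels (e.g. 23).
#' @return Data frame with one row per surviving cluster: `size`, `peak_t`,
#'   peak coordinates, `sign`; plus attribute `"labels"` (voxel cluster
#'   labels, 0 = none).
#' @export
cluster_threshold <- function(t_map, p_map, grid, p_thresh = 0.005, k = 23L) {
  stopifnot(k >= 1L, length(t_map) == prod(grid), length(p_map) == prod(grid))
  mask <- array(p_map < p_thresh, dim = grid)
  lab <- array(0L, dim = grid)
  nxt <- 0L
  idx <- which(mask)
  dims <- grid
  neighbors <- function(v) {
    co <- arrayInd(v, dims)
    out <- integer(0)
    for (d in 1:3) for (s in c(-1L, 1L)) {
      nb <- co; nb[d] <- nb[d] + s
      if (nb[d] >= 1L && nb[d] <= dims[d])
        out <- c(out, (nb[3] - 1L) * dims[1] * dims[2] + (nb[2] - 1L) * dims[1] + nb[1])
    }
    out
  }
  for (v in idx) {
    if (lab[v] != 0L) next
    nxt <- nxt + 1L
    queue <- v; lab[v] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in neighbors(cur)) if (mask[nb] && lab[nb] == 0L) {
        lab[nb] <- nxt; queue <- c(queue, nb)
      }
    }
  }
  rows <- list()
  if (nxt > 0L) for (cl in seq_len(nxt)) {
    vox <- which(lab == cl)
    if (length(vox) < k) { lab[vox] <- 0L; next }
    pk <- vox[which.max(abs(t_map[vox]))]
    co <- arrayInd(pk, dims)
    rows[[length(rows) + 1L]] <- data.frame(
      size = length(vox), peak_t = t_map[pk],
      x = co[1], y = co[2], z = co[3],
      sign = ifelse(t_map[pk] >= 0, "+", "-"))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(size = integer(0), peak_t = numeric(0), x = integer(0),
               y = integer(0), z = integer(0), sign = character(0))
  rownames(out) <- NULL
  attr(out, "labels") <- lab
  out
}
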