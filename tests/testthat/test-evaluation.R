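test_that("smoothing is causal, bounded and scale invariant", {
  # constant input maps to all zeros (guarded min-max)
  expect_true(all(smooth_and_normalize(matrix(2, 50, 2)) == 0))

  # impulse: causal Gaussian bump whose peak maps to 1 at the impulse
  x <- rep(0, 400); x[200] <- 1
  y <- smooth_and_normalize(matrix(x, ncol = 1), sd_ms = 20)
  expect_true(all(y >= 0 & y <= 1))
  expect_true(all(y[1:199] == 0))        # nothing before the impulse
  expect_equal(which.max(y[, 1]), 200)   # kernel peak is at lag 0
  expect_equal(max(y), 1)
  # the causal tail follows the Gaussian shape
  expect_equal(y[220, 1], exp(-0.5 * (20 / 20)^2), tolerance = 1e-6)

  # min-max normalization is invariant to amplitude scaling
  set.seed(1)
  r <- rnorm(300)
  expect_equal(smooth_and_normalize(r), smooth_and_normalize(7.5 * r),
               tolerance = 1e-10)
})

test_that("epoch scoring picks the dominant unit or no-response", {
  ann <- data.frame(label = c("apple", "random", "grape"),
                    onset_ms = c(0, 100, 200), offset_ms = c(100, 200, 300))
  o <- matrix(0, 300, 3)
  o[1:100, 2] <- 1          # unit 2 saturated in epoch 1
  o[201:300, 1] <- 0.2      # weak response in epoch 3
  o[201:300, 3] <- 0.9      # strong response of unit 3 in epoch 3
  sm <- smooth_and_normalize(o)
  w <- score_epochs(sm, ann, threshold = 0.3)
  expect_equal(w, c("2", "no_response", "3"))

  cm <- confusion_matrix(w, ann$label, c("apple", "grape"), 3)
  expect_equal(sum(cm), 3)
  expect_equal(cm["apple", "2"], 1L)
  expect_equal(cm["random", "no_response"], 1L)
  expect_equal(cm["grape", "3"], 1L)
})

test_that("accuracy maximizes the diagonal over unit assignments", {
  # perfectly diagonal matrix
  cm <- rbind(cbind(diag(c(5L, 4L, 6L)), 0L), c(0L, 0L, 0L, 7L))
  dimnames(cm) <- list(c("apple", "grape", "banana", "random"),
                       c("1", "2", "3", "no_response"))
  expect_equal(accuracy(cm), 1.0)

  # uniform 3x3 chunk block: any assignment scores 3/9
  cmu <- rbind(cbind(matrix(1L, 3, 3), 0L), c(0L, 0L, 0L, 0L))
  dimnames(cmu) <- dimnames(cm)
  expect_equal(accuracy(cmu), 3 / 9)

  # a column swap is rescued by the assignment
  cms <- cm[, c(2, 1, 3, 4)]
  colnames(cms) <- colnames(cm)
  expect_equal(accuracy(cms), 1.0)
})

test_that("accuracy equals the exhaustive-permutation oracle on random matrices", {
  # independent oracle: enumerate permutations explicitly
  all_perms <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(all_perms(v[-i]), function(p) c(v[i], p))))
  }
  set.seed(2)
  for (rep in 1:20) {
    cm <- matrix(rpois(16, 3), 4, 4,
                 dimnames = list(c("a", "b", "c", "random"),
                                 c("1", "2", "3", "no_response")))
    oracle <- max(vapply(all_perms(1:3), function(p)
      sum(cm[cbind(1:3, p)]), numeric(1))) + cm[4, 4]
    expect_equal(accuracy(cm), oracle / sum(cm))
    # invariance under permutation of the unit columns
    p <- sample(3)
    cmp <- cm[, c(p, 4)]
    colnames(cmp) <- colnames(cm)
    expect_equal(accuracy(cmp), accuracy(cm))
  }
})

test_that("activation phase recovers concentration time and shift equivariance", {
  T <- 200
  # activity concentrated at the midpoint
  r <- matrix(0, T, 1); r[100, 1] <- 1
  expect_equal(activation_phase(r)[1], 100, tolerance = 1)

  # uniform (flat) activity: undefined phase flagged as NA
  expect_true(is.na(activation_phase(matrix(1, T, 1))[1]))

  # a circularly shifted profile shifts the phase equally (Fourier shift)
  set.seed(3)
  prof <- pmax(rnorm(T, sd = 0.1) + dnorm(seq_len(T), 60, 15), 0)
  shift <- 40
  prof2 <- c(prof[(T - shift + 1):T], prof[1:(T - shift)])
  ph1 <- activation_phase(matrix(prof, ncol = 1))
  ph2 <- activation_phase(matrix(prof2, ncol = 1))
  expect_equal((ph2 - ph1) %% T, shift, tolerance = 1)
})

test_that("PCA trajectories match the eigendecomposition oracle", {
  set.seed(4)
  # planar data: two independent directions embedded in 5 dims
  basis <- qr.Q(qr(matrix(rnorm(25), 5)))[, 1:2]
  hist2 <- matrix(rnorm(400 * 2), 400, 2) %*% t(basis)
  ann <- data.frame(label = "apple", onset_ms = 0, offset_ms = 400)
  pc <- pca_trajectories(hist2, ann, half_window = 50)
  expect_equal(pc$n_pc, 2)  # third variance direction is numerically zero
  expect_equal(sum(pc$eigenvalues[-(1:2)]), 0, tolerance = 1e-8)

  # eigenvalues agree with prcomp on a random instance
  hist5 <- matrix(rnorm(300 * 5), 300, 5)
  pc5 <- pca_trajectories(hist5, ann[rep(1, 1), ], half_window = 20)
  pr <- prcomp(hist5)
  expect_equal(pc5$eigenvalues, pr$sdev^2 / sum(pr$sdev^2),
               tolerance = 1e-10)
  # projection of mean-centered data has zero mean
  proj <- sweep(hist5, 2, colMeans(hist5)) %*% pc5$rotation
  expect_equal(colMeans(proj), rep(0, 3), tolerance = 1e-12)
})

test_that("trajectory separation implements the distance/deviation ratio", {
  half <- 10
  L <- 2 * half + 1
  # two zero-variance clouds at distance D: r_XY = 0
  mk <- function(center, jitter = 0, n = 4) {
    a <- array(rep(center, each = L), dim = c(L, 3, n))
    a + array(rnorm(L * 3 * n, 0, jitter), dim = c(L, 3, n))
  }
  tr <- list(apple = mk(c(0, 0, 0)), grape = mk(c(3, 0, 0)))
  sep <- trajectory_separation(tr)
  expect_equal(sep$pairs$r_XY, 0)
  expect_true(all(sep$d[, 1] == 3))

  # identical trials for X and Y: d = 0, flagged degenerate
  set.seed(5)
  same <- mk(c(1, 1, 1), jitter = 0.1)
  sep0 <- trajectory_separation(list(apple = same, grape = same))
  expect_true(sep0$pairs$degenerate)
  expect_equal(sep0$pairs$r_XY, Inf)

  # Gaussian clouds against the direct formula oracle
  set.seed(6)
  tr2 <- list(apple = mk(c(0, 0, 0), 0.3, n = 6),
              grape = mk(c(2, 1, 0), 0.3, n = 6),
              banana = mk(c(0, 2, 2), 0.3, n = 6))
  sep2 <- trajectory_separation(tr2)
  oracle_r <- function(A, B) {
    cA <- apply(A, c(1, 2), mean); cB <- apply(B, c(1, 2), mean)
    sA <- sqrt(rowSums(apply(A, c(1, 2), var) * (dim(A)[3] - 1) / dim(A)[3]))
    sB <- sqrt(rowSums(apply(B, c(1, 2), var) * (dim(B)[3] - 1) / dim(B)[3]))
    d <- sqrt(rowSums((cA - cB)^2))
    sum((sA + sB) / d)
  }
  for (j in seq_len(nrow(sep2$pairs))) {
    X <- sep2$pairs$X[j]; Y <- sep2$pairs$Y[j]
    expect_equal(sep2$pairs$r_XY[j], oracle_r(tr2[[X]], tr2[[Y]]),
                 tolerance = 1e-10)
  }
  # symmetry: r_XY = r_YX
  swapped <- trajectory_separation(tr2[c("grape", "apple")])
  expect_equal(swapped$pairs$r_XY[1], sep2$pairs$r_XY[1], tolerance = 1e-10)
})

test_that("effective dimension satisfies the equal-share identity and bounds", {
  for (n in 1:10) {
    lam <- c(rep(1 / n, n), rep(0, 12 - n))
    expect_equal(effective_dimension(lam), n, tolerance = 1e-12)
  }
  expect_equal(effective_dimension(c(5, 0, 0)), 1)
  set.seed(7)
  for (i in 1:20) {
    lam <- runif(15)
    ne <- effective_dimension(lam)
    expect_equal(ne, 1 / sum((lam / sum(lam))^2), tolerance = 1e-12)
    expect_gte(ne, 1)
    expect_lte(ne, sum(lam > 0))
  }
  expect_error(effective_dimension(rep(0, 4)), "zero")
})

test_that("cumulative contribution is a monotone curve ending at 1", {
  expect_equal(cumulative_contribution(rep(2, 5)), seq(0.2, 1, by = 0.2))
  expect_equal(cumulative_contribution(c(3, 0, 0)), c(1, 1, 1))
  set.seed(8)
  lam <- sort(runif(10), decreasing = TRUE)
  cc <- cumulative_contribution(lam)
  expect_true(all(diff(cc) >= 0))
  expect_equal(cc[10], 1)
  expect_equal(cc, cumsum(lam) / sum(lam), tolerance = 1e-12)
})
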