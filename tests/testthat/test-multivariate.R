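test_that("PCA selection retains by the Kaiser rule and imputes sensibly", {
  set.seed(1)
  # rank-1 signal plus tiny noise: exactly one dominant retained component
  u <- rnorm(100)
  X <- outer(u, rnorm(12)) * 3 + matrix(rnorm(1200, sd = 0.05), 100)
  X <- scale(X)
  pc <- pca_select(X)
  expect_equal(sum(pc$eigenvalues > 1), 1)
  expect_equal(length(pc$retained), 1)
  # pure noise, p << n: about half the eigenvalues exceed 1 (Marchenko-
  # Pastur: the bulk is centred at 1 for small p/n)
  Xn <- scale(matrix(rnorm(400 * 30), 400))
  pcn <- pca_select(Xn)
  frac <- length(pcn$retained) / 30
  expect_gt(frac, 0.3)
  expect_lt(frac, 0.7)
  # loadings orthonormal
  Q <- crossprod(pcn$loadings)
  expect_equal(unname(Q), diag(nrow(Q)), tolerance = 1e-8)
  # imputation draws follow the observed feature's (mu, sd)
  Xm <- matrix(rnorm(200 * 4, mean = 5, sd = 2), 200)
  Xm[1, 2] <- NA
  draws <- vapply(1:200, function(s) {
    pca_select(Xm, seed = s)  # value deterministic given seed
    imp <- with_seed(s, impute_gaussian(Xm))
    imp$X[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(draws) - mean(Xm[-1, 2])), 0.5)
  expect_lt(abs(sd(draws) - sd(Xm[-1, 2])), 0.5)
  expect_true(all(abs(draws - mean(Xm[-1, 2])) < 6 * sd(Xm[-1, 2])))
  # all-missing feature errors with its index
  Xbad <- Xm
  Xbad[, 3] <- NA
  expect_error(pca_select(Xbad), "no observed values")
})

test_that("FDR keeps the false-discovery proportion at its level", {
  set.seed(2)
  fdp <- replicate(1000, {
    p <- runif(30)
    mean(stats::p.adjust(p, "BH") < 0.05) > 0
  })
  # under the global null, any BH discovery is false; rate <= q
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 * 0.95 / 1000))
})

test_that("loading topography flags planted posterior-theta structure", {
  set.seed(3)
  montage <- build_montage(16)
  scalp <- montage$name[!montage$eog]
  freqs <- log_freqs(4, 40, 8)
  fi <- data.frame(channel = rep(scalp, times = length(freqs)),
                   freq = rep(freqs, each = length(scalp)))
  posterior <- montage$y[match(fi$channel, montage$name)] < 0
  theta <- fi$freq >= 5 & fi$freq <= 7
  pcs <- lapply(1:8, function(p) {
    L <- matrix(rnorm(nrow(fi) * 5, sd = 0.02), nrow(fi))
    L[posterior & theta, ] <- L[posterior & theta, ] + 0.3
    structure(list(loadings = L, feature_index = fi,
                   retained = 1:5, eigenvalues = rep(2, 5)),
              class = "pc_space")
  })
  lt <- loading_topography(pcs, montage)
  theta_rows <- lt$frequency$freq >= 5 & lt$frequency$freq <= 7
  expect_true(all(lt$frequency$significant[theta_rows]))
  expect_false(any(lt$frequency$significant[!theta_rows]))
  ap <- lt$roi_anova[lt$roi_anova$term == "ap", ]
  expect_lt(ap$p, 0.05)
  expect_gt(mean(lt$roi_scores[, c("left_posterior", "right_posterior")]),
            mean(lt$roi_scores[, c("left_anterior", "right_anterior")]))
  # identically zero loadings: nothing significant
  pcs0 <- lapply(pcs, function(pc) {
    pc$loadings <- pc$loadings * 0
    pc
  })
  lt0 <- loading_topography(pcs0, montage)
  expect_false(any(lt0$frequency$significant, na.rm = TRUE))
})

test_that("decoding is calibrated under the null and detects separation", {
  set.seed(4)
  X <- matrix(rnorm(160 * 8), 160)
  y <- rep(c(TRUE, FALSE), 80)
  null_auc <- classify_conditions(X, y, pca = FALSE)$auc
  expect_lt(abs(null_auc - 0.5), 0.15)
  Xs <- X
  Xs[y, 1] <- Xs[y, 1] + 3
  res <- classify_conditions(Xs, y, pca = FALSE)
  expect_gt(res$auc, 0.9)
  expect_length(res$auc_per_penalty, 8)
  # stronger penalties shrink a weak signal towards chance
  Xw <- X
  Xw[y, 1] <- Xw[y, 1] + 0.4
  pen <- classify_conditions(Xw, y, pca = FALSE)$auc_per_penalty
  expect_lte(pen[8], pen[1] + 0.02)
  expect_error(classify_conditions(X, rep(TRUE, 160), pca = FALSE),
               "both classes")
  expect_error(classify_conditions(X[1:8, ], y[c(1:4, 81:84)], pca = FALSE),
               "at least 5")
  # AUC is invariant to monotone transforms of the scores
  sc <- res$scores[, 1]
  expect_equal(eventseg:::auc_score(res$labels, sc),
               eventseg:::auc_score(res$labels, exp(sc / 2)))
})

test_that("a duplicated trial does not inflate null AUC via fold leakage", {
  set.seed(5)
  X <- matrix(rnorm(40 * 60), 40)  # p > n, with per-fold PCA + imputation
  X[sample(length(X), 30)] <- NA
  y <- rep(c(TRUE, FALSE), 20)
  Xd <- rbind(X, X[7, ])
  yd <- c(y, y[7])
  auc <- classify_conditions(Xd, yd, pca = TRUE, seed = 6)$auc
  se <- 0.6 / sqrt(41)
  expect_lt(auc, 0.5 + 3 * se)
})

test_that("the univariate classifier matches its closed-form separability", {
  x <- c(rnorm(30), rnorm(30) + 8)
  y <- rep(c(FALSE, TRUE), each = 30)
  expect_equal(univariate_pz_classifier(x, y)$auc, 1)
  set.seed(7)
  xn <- rnorm(80)
  yn <- sample(rep(c(TRUE, FALSE), 40))
  expect_lt(abs(univariate_pz_classifier(xn, yn)$auc - 0.5), 0.2)
})

test_that("covariance-based importance recovers planted activation patterns", {
  set.seed(8)
  # diagonal covariance: closed form A proportional to sigma^2 * w
  sds <- c(1, 2, 3)
  X <- sapply(sds, function(s) rnorm(20000, sd = s))
  w <- c(0.5, -1, 2)
  imp <- haufe_importance(X, w)
  expected <- sds^2 * w
  expect_equal(imp$A / sqrt(sum(imp$A^2)),
               (expected / stats::var(drop(X %*% w))) /
                 sqrt(sum((expected / stats::var(drop(X %*% w)))^2)),
               tolerance = 0.05)
  # two-class Gaussian with known pattern
  n <- 2000
  p <- 12
  pat <- rnorm(p)
  y <- rep(c(0, 1), each = n / 2)
  X2 <- matrix(rnorm(n * p), n) + outer(y, pat)
  w2 <- stats::glm(y ~ X2, family = stats::binomial())$coefficients[-1]
  imp2 <- haufe_importance(X2, w2)
  expect_gt(stats::cor(imp2$A, pat), 0.95)
  # scaling the data leaves the importance direction invariant
  imp3 <- haufe_importance(X2 * 3, w2)
  expect_gt(abs(stats::cor(imp2$A, imp3$A)), 0.9999)
  expect_error(haufe_importance(X2, w2, y = rep(1, n)), "zero variance")
})

test_that("projected importance lands in the right bands and ROIs", {
  montage <- build_montage(16)
  scalp <- montage$name[!montage$eog]
  freqs <- c(4, 6, 10, 20, 50, 70)
  fi <- data.frame(channel = rep(scalp, times = length(freqs)),
                   freq = rep(freqs, each = length(scalp)))
  L <- diag(nrow(fi))[, 1:10]
  pc <- structure(list(loadings = L, feature_index = fi), class = "pc_space")
  imp <- structure(list(A = rnorm(10)), class = "importance_map")
  pr <- project_importance(imp, pc)
  expect_equal(nrow(pr), nrow(fi))
  expect_equal(pr$importance[1:10], imp$A)
  bands <- importance_bands(pr, montage)
  expect_setequal(unique(bands$band), c("theta", "alpha", "beta", "gamma"))
  expect_equal(nrow(bands), 16)
})

test_that("predictive decoding filters repeat boundary visits by lag", {
  g <- std_graph()
  nodes <- c("b", "c", "a", "b", "a", "c", "d", "a")
  trials <- data.frame(index = 0:7, node = nodes, swapped = FALSE,
                       stringsAsFactors = FALSE)
  idx <- eventseg:::predictive_test_trials(trials, g, held_out = 1, lag = 2)
  # visits to boundary node a at rows 3, 5, 8 (1-based); the visit at row 5
  # is within two trials of row 3 and must be excluded
  expect_equal(idx, c(3L, 8L))
  # swapped (novel) boundary visits are excluded
  trials$swapped[8] <- TRUE
  expect_equal(eventseg:::predictive_test_trials(trials, g, 1, 2), 3L)
})

test_that("rotation relabelling permutes but preserves per-rotation AUCs", {
  ses <- small_session()
  fw <- zscore_features(spectral_power(ses$epochs, freqs = log_freqs(4, 30, 4),
                                       output = "windowed"))
  pd <- predictive_decode(fw, ses$graph, trials = ses$trials)
  ok <- setdiff(1:3, pd$skipped)
  expect_true(length(ok) >= 1)
  expect_true(all(pd$per_rotation[ok, ] >= 0 & pd$per_rotation[ok, ] <= 1,
                  na.rm = TRUE))
  expect_equal(length(pd$window_auc), length(fw$window_start_ms))
})

test_that("permuted labels destroy decodable signal and are reproducible", {
  set.seed(9)
  X <- matrix(rnorm(60 * 6), 60)
  y <- rep(c(TRUE, FALSE), 30)
  X[y, 1] <- X[y, 1] + 2.5
  true_auc <- classify_conditions(X, y, pca = FALSE)$auc
  perm <- permuted_label_control(X, y, n_perm = 12, pca = FALSE, seed = 10)
  expect_lt(abs(perm$mean - 0.5), 0.1)
  expect_gt(true_auc, stats::quantile(perm$auc, 0.975))
  perm2 <- permuted_label_control(X, y, n_perm = 12, pca = FALSE, seed = 10)
  expect_identical(perm$auc, perm2$auc)
})
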