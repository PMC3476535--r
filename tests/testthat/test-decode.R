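mkspec <- function(v, nt = 20, nf = 20) structure(list(
  values = matrix(v, nt, nf), times = seq(-1, 4, length.out = nt),
  freqs = log_freq_grid(3, 150, nf), kind = "normalized", offset = 3,
  baseline = c(-1, -0.5)), class = "spectrogram")

test_that("block-mean reduction matches a brute-force loop oracle", {
  set.seed(1)
  sp <- mkspec(stats::rnorm(23 * 17), nt = 23, nf = 17)
  rd <- reduce_resolution(sp, 10)
  expect_equal(dim(rd$values), c(3L, 2L))
  oracle <- matrix(0, 3, 2)
  for (i in 1:3) for (j in 1:2) {
    ri <- ((i - 1) * 10 + 1):min(i * 10, 23)
    rj <- ((j - 1) * 10 + 1):min(j * 10, 17)
    oracle[i, j] <- mean(sp$values[ri, rj])
  }
  expect_equal(rd$values, oracle, tolerance = 1e-12)
  ## constant map stays constant; 20x20 -> 2x2
  spc <- mkspec(3.5)
  rdc <- reduce_resolution(spc, 10)
  expect_equal(dim(rdc$values), c(2L, 2L))
  expect_true(all(abs(rdc$values - 3.5) < 1e-12))
})

test_that("naive Bayes posterior matches the closed-form Gaussian rule", {
  x <- rbind(c(0, 0), c(1, 1), c(2, 0))
  y <- c("a", "b", "b")
  m <- train_nb(x, y)
  xt <- rbind(c(0.5, 0.2))
  p <- predict(m, xt)$posterior
  ## hand-computed: pooled variances, means, priors 1/3 and 2/3
  mu_a <- c(0, 0); mu_b <- c(1.5, 0.5)
  v <- (c(0, 0) * 0 + c(0.5, 0.5) * 1) / (3 - 2)   # pooled within-class
  v <- pmax(v, 1e-6 * apply(x, 2, stats::var))
  lg <- function(mu, pr) log(pr) - sum((xt - mu)^2 / (2 * v)) -
    0.5 * sum(log(2 * pi * v))
  la <- lg(mu_a, 1 / 3); lb <- lg(mu_b, 2 / 3)
  pa <- exp(la - max(la, lb)) / (exp(la - max(la, lb)) +
                                   exp(lb - max(la, lb)))
  expect_equal(unname(p[1, "a"]), pa, tolerance = 1e-12)
})

test_that("symmetric two-class problem puts the boundary at zero", {
  x <- matrix(c(-1, 1), 2, 1)
  y <- c("neg", "pos")
  m <- train_nb(x, y)
  p <- predict(m, matrix(c(-0.01, 0.01), 2, 1))
  expect_equal(p$class, c("neg", "pos"))
  peq <- predict(m, matrix(0, 1, 1))$posterior
  expect_equal(unname(peq[1, 1]), 0.5, tolerance = 1e-9)
})

test_that("training is deterministic in the data", {
  set.seed(2)
  x <- matrix(stats::rnorm(80), 20)
  y <- rep(c("a", "b"), 10)
  m1 <- train_nb(x, y); m2 <- train_nb(x, y)
  expect_identical(m1, m2)
})

test_that("per-class-variance predictions agree with an independent
          reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(3)
  x <- matrix(stats::rnorm(400 * 3), 400)
  y <- sample(c("a", "b", "c"), 400, replace = TRUE)
  x[y == "b", 1] <- x[y == "b", 1] + 2
  x[y == "c", 2] <- x[y == "c", 2] - 2
  m <- train_nb(x[1:200, ], y[1:200], pooled = FALSE)
  ref <- e1071::naiveBayes(data.frame(x[1:200, ]), factor(y[1:200]))
  mine <- predict(m, x[201:400, ])$class
  theirs <- as.character(predict(ref, data.frame(x[201:400, ])))
  expect_gte(mean(mine == theirs), 0.999)
})

test_that("stratified cross-validation partitions trials and is seeded", {
  set.seed(4)
  x <- matrix(stats::rnorm(200 * 2), 200)
  y <- rep(c("a", "b"), each = 100)
  x[y == "b", ] <- x[y == "b", ] + 4
  cv <- crossvalidate(x, y, k = 10, seed = 9)
  expect_equal(sort(unique(cv$folds)), 1:10)
  expect_equal(as.vector(table(cv$folds)), rep(20, 10))
  expect_equal(cv$accuracy, 1)
  for (cm in cv$confusion) expect_equal(sum(cm), 20)
  cv2 <- crossvalidate(x, y, k = 10, seed = 9)
  expect_identical(cv$folds, cv2$folds)
  few <- c(1:5, 101:105)                 # five trials per class
  expect_error(crossvalidate(x[few, ], y[few], k = 10), "at least k")
})

test_that("label-independent features decode at chance", {
  set.seed(5)
  accs <- replicate(12, {
    x <- matrix(stats::rnorm(120 * 4), 120)
    y <- sample(rep(c("a", "b"), each = 60))
    crossvalidate(x, y, k = 10, seed = 1)$accuracy
  })
  ## 99% binomial band around 0.5 for the mean of 12 x 120 trials
  ## slight pessimism relative to 0.5 is expected from CV on null data
  expect_lt(abs(mean(accs) - 0.5), 2.58 * sqrt(0.25 / (12 * 120)) + 0.04)
})

test_that("feature building takes the union of per-condition masks and
          excludes clusters on request", {
  set.seed(6)
  nt <- 48
  labels <- rep(c("c1", "c2", "c3", "c4"), each = nt / 4)
  mk <- function(shift_cols) lapply(seq_len(nt), function(j) {
    v <- matrix(stats::rnorm(100, sd = 0.3), 10, 10)
    if (labels[j] %in% names(shift_cols))
      v[6:9, shift_cols[[labels[j]]]] <- v[6:9, shift_cols[[labels[j]]]] - 6
    structure(list(values = v, times = seq(-1, 4, length.out = 10),
                   freqs = log_freq_grid(3, 150, 10), kind = "normalized",
                   offset = 3, baseline = c(-1, -0.5)),
              class = "spectrogram")
  })
  specs <- list(one = mk(list(c1 = 2, c2 = 5)),
                vis = mk(list(c3 = 7)))
  bf <- build_features(specs, labels, alpha = 0.05, n_boot = 100, seed = 1)
  expect_equal(nrow(bf$features), nt)
  expect_true(all(c("one", "vis") %in% names(bf$spec)))
  bf2 <- build_features(specs, labels, alpha = 0.05, n_boot = 100,
                        seed = 1, exclude = "vis")
  expect_false("vis" %in% names(bf2$spec))
  expect_error(build_features(specs, labels, exclude = c("one", "vis")),
               "no clusters")
  ## selected values equal direct lookup
  sel <- bf$spec$one
  expect_equal(bf$features[3, seq_len(sum(sel))],
               specs$one[[3]]$values[sel])
})

test_that("grand confusion aggregation normalises to 100% and matches a
          manual average", {
  m1 <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  m2 <- matrix(c(6, 4, 0, 10), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  g <- aggregate_confusion(list(m1, m2))
  expect_equal(sum(g$normalized), 100, tolerance = 1e-9)
  expect_equal(g$counts, m1 + m2)
  expect_equal(unname(g$normalized["a", "a"]), 100 * 14 / 40)
  expect_equal(g$accuracy, (14 + 19) / 40)
  ## identical diagonal inputs stay diagonal
  d <- matrix(c(10, 0, 0, 10), 2, dimnames = list(c("a", "b"), c("a", "b")))
  gd <- aggregate_confusion(list(d, d))
  expect_equal(unname(gd$normalized["a", "b"]), 0)
})
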