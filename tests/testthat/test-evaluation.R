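test_that("AUC matches the exhaustive pair-count oracle and handles ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(41)
  for (rep in 1:10) {
    scores <- sample(seq(0, 1, by = 0.1), 12, replace = TRUE)
    labels <- c(rep(1, 5), rep(0, 7))
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(42)
  scores <- rnorm(30)
  labels <- rbinom(30, 1, 0.5)
  labels[1:2] <- c(0, 1)
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), a)
  expect_equal(roc_auc(qlogis(plogis(scores)), labels), a)
  expect_equal(roc_auc(rank(scores), labels), a)
})

test_that("confusion counts partition the sample", {
  scores <- c(0.9, 0.8, 0.6, 0.4, 0.3, 0.1)
  labels <- c(1, 1, 0, 1, 0, 0)
  cm <- confusion(scores, labels)
  expect_equal(sum(cm$table), 6)
  expect_equal(cm$table["positive", "positive"], 2)
  expect_equal(cm$table["positive", "negative"], 1)
  expect_equal(cm$accuracy, 4 / 6)
  # all correct: off-diagonal zeros
  cm2 <- confusion(c(0.9, 0.1), c(1, 0))
  expect_equal(cm2$table["positive", "negative"] + cm2$table["negative", "positive"], 0)
  # flipping labels transposes the table
  cm3 <- confusion(1 - scores, 1 - labels)
  expect_equal(cm3$table, t(cm$table), ignore_attr = TRUE)
})

test_that("DeLong components match the direct double-loop formula", {
  set.seed(43)
  scores <- rnorm(10)
  labels <- c(rep(1, 4), rep(0, 6))
  got <- stfc:::delong_components(scores, labels)
  want <- oracle_delong_components(scores, labels)
  expect_equal(got$auc, want$auc)
  expect_equal(got$v10, want$v10)
  expect_equal(got$v01, want$v01)
})

test_that("DeLong test: identical models give p = 1, swaps negate z", {
  set.seed(44)
  labels <- rbinom(30, 1, 0.5); labels[1:2] <- c(0, 1)
  s <- rnorm(30)
  res <- delong_test(s, s, labels)
  expect_equal(res$auc_a, res$auc_b)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
  s2 <- s + rnorm(30, sd = 0.6)
  a <- delong_test(s, s2, labels)
  b <- delong_test(s2, s, labels)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
})

test_that("DeLong agrees with the reference implementation in pROC", {
  skip_if_not_installed("pROC")
  set.seed(45)
  labels <- c(rep(1, 20), rep(0, 20))
  base <- rnorm(40, mean = labels)
  sa <- base + rnorm(40, sd = 0.8)
  sb <- 0.7 * base + rnorm(40, sd = 0.9)
  got <- delong_test(sa, sb, labels)
  ref <- pROC::roc.test(pROC::roc(labels, sa, quiet = TRUE),
                        pROC::roc(labels, sb, quiet = TRUE), method = "delong")
  expect_equal(got$p, as.numeric(ref$p.value), tolerance = 1e-8)
})

test_that("attention extraction is deterministic with validated indices", {
  coh <- tiny_cohort(n_per_class = 2, n_nodes = 4, L = 20)
  batches <- assemble_batches(coh$records, 5, 1, 10, seed = 1, cheb_order = 2)
  model <- build_model(tiny_config(), 4)
  m1 <- extract_attention(model, batches[1], block = 1, scope = "spatial")
  m2 <- extract_attention(model, batches[1], block = 1, scope = "spatial")
  expect_identical(m1, m2)
  expect_lt(max(abs(apply(m1[[1]], c(1, 2, 3, 4), sum) - 1)), 1e-6)
  mt <- extract_attention(model, batches[1], block = 1, head = 2, scope = "temporal")
  expect_equal(dim(mt[[1]]), c(dim(batches[[1]]$series)[1], 4, 5, 5))
  expect_error(extract_attention(model, batches[1], block = 2), "block")
  expect_error(extract_attention(model, batches[1], head = 3), "head")
})

test_that("attention averaging matches a brute-force loop", {
  set.seed(46)
  maps <- list(array(runif(2 * 3 * 4 * 5 * 5), c(2, 3, 4, 5, 5)),
               array(runif(2 * 2 * 4 * 5 * 5), c(2, 2, 4, 5, 5)))
  got <- average_attention(maps, query_nodes = c(2, 4))
  want <- matrix(0, 2, 5)
  cnt <- 0
  for (m in maps) {
    d <- dim(m)
    for (h in 1:d[1]) for (b in 1:d[2]) for (t in 1:d[3]) {
      want[1, ] <- want[1, ] + m[h, b, t, 2, ]
      want[2, ] <- want[2, ] + m[h, b, t, 4, ]
      cnt <- cnt + 1
    }
  }
  expect_equal(got, want / cnt)
  # averaging identical maps reproduces the map rows
  same <- average_attention(list(maps[[1]], maps[[1]]), query_nodes = 1)
  expect_equal(same, average_attention(maps[1], query_nodes = 1))
  # top-half cutoff zeroes the weaker half
  th <- average_attention(maps, query_nodes = c(2, 4), top_half = TRUE)
  expect_equal(sum(th == 0), 5)
})

test_that("MPE similarity follows its defining formula and ordering", {
  set.seed(47)
  a <- matrix(runif(16, 0.2, 1), 4, 4)
  expect_equal(mpe_similarity(a, a), 0)
  expect_equal(mpe_similarity(a, 2 * a), 100, tolerance = 1e-5)
  b <- matrix(runif(16, 0.2, 1), 4, 4)
  expect_equal(mpe_similarity(a, b), 100 * mean(abs(a - b) / (abs(a) + 1e-8)))
  expect_false(isTRUE(all.equal(mpe_similarity(a, b), mpe_similarity(b, a))))
  expect_error(mpe_similarity(a, matrix(0, 3, 3)), "identical dimensions")
})

test_that("the window sweep covers exactly the valid grid cells", {
  coh <- tiny_cohort(n_per_class = 7, n_nodes = 4, L = 40)
  cfg <- tiny_config(n_features = 4, max_epochs = 1, batch_size = 50)
  # the oversized window is skipped once per overlap it pairs with
  expect_warning(expect_warning(
    grid <- window_sweep(coh$records, windows = c(8, 10, 64), overlaps = c(0, 8),
                         trials = 1, config = cfg, seed = 3),
    "skipped"), "skipped")
  # valid cells: (8,0), (10,0), (10,8) -- overlap >= window and window > L drop out
  expect_equal(nrow(grid), 3)
  expect_true(all(grid$overlap < grid$window_length))
  expect_true(all(grid$n == 1))
  expect_true(all(grid$mean_auc >= 0 & grid$mean_auc <= 1))
})
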