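test_that("config validation enforces divisibility and ranges", {
  expect_error(model_config(n_features = 6, n_heads = 4), "divisible")
  expect_error(model_config(n_blocks = 0), "n_blocks")
  expect_error(model_config(ablation = "bogus"))
  expect_error(model_config(lr_decay = 0), "lr_decay")
  expect_s3_class(model_config(), "model_config")
})

test_that("initialization is seed-deterministic and ablations drop parameters", {
  cfg <- tiny_config(seed = 5)
  m1 <- build_model(cfg, 6)
  m2 <- build_model(cfg, 6)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(tiny_config(seed = 6), 6)
  expect_false(identical(m1$params, m3$params))

  no_gcn <- build_model(tiny_config(ablation = "no_gcn"), 6)
  expect_null(no_gcn$params$blocks[[1]]$spatial$theta)
  expect_false(is.null(no_gcn$params$blocks[[1]]$spatial$W_q))
  no_att <- build_model(tiny_config(ablation = "no_attention"), 6)
  expect_null(no_att$params$blocks[[1]]$spatial$W_q)
  expect_false(is.null(no_att$params$blocks[[1]]$spatial$theta))
  no_sp <- build_model(tiny_config(ablation = "no_spatial"), 6)
  expect_identical(names(no_sp$params$blocks[[1]]$spatial),
                   c("embed_W", "embed_b", "dw_W"))
  no_tmp <- build_model(tiny_config(ablation = "no_temporal"), 6)
  expect_null(no_tmp$params$blocks[[1]]$temporal)
})

test_that("forward emits normalized probabilities and N x T score matrices", {
  coh <- tiny_cohort(n_per_class = 3, n_nodes = 4, L = 20)
  batches <- assemble_batches(coh$records, 5, 1, 10, seed = 1, cheb_order = 2)
  model <- build_model(tiny_config(), 4)
  out <- forward(model, batches[[1]], collect_maps = TRUE)
  B <- dim(batches[[1]]$series)[1]
  expect_equal(dim(out$probabilities), c(B, 2))
  expect_equal(rowSums(out$probabilities), rep(1, B), tolerance = 1e-6)
  expect_equal(dim(out$scores), c(B, 4, 5, 2))  # entry x N x T_tau x class
  expect_equal(dim(out$features), c(B, 5, 4, 8))
  # duplicating entries duplicates outputs exactly
  b2 <- stfc:::entries_batch(batches[[1]]$entries[c(1, 1, 2)])
  out2 <- forward(model, b2)
  expect_equal(out2$probabilities[1, ], out2$probabilities[2, ], tolerance = 1e-12)
  expect_equal(out2$probabilities[1, ], out$probabilities[1, ], tolerance = 1e-12)
})

test_that("ablated forward passes run end to end", {
  coh <- tiny_cohort(n_per_class = 2, n_nodes = 4, L = 20)
  batches <- assemble_batches(coh$records, 5, 1, 10, seed = 1, cheb_order = 2)
  for (ab in c("no_attention", "no_gcn", "no_spatial", "no_temporal")) {
    model <- build_model(tiny_config(ablation = ab), 4)
    out <- forward(model, batches[[1]])
    expect_equal(rowSums(out$probabilities), rep(1, dim(batches[[1]]$series)[1]),
                 tolerance = 1e-6, info = ab)
  }
})

test_that("first-epoch loss sits near ln 2 for balanced binary data", {
  coh <- tiny_cohort(n_per_class = 4, n_nodes = 4, L = 30)
  batches <- assemble_batches(coh$records, 5, 1, 16, seed = 1, cheb_order = 2)
  model <- build_model(tiny_config(max_epochs = 1), 4)
  fit <- train_st(model, batches)
  expect_lt(abs(fit$log$train_loss[1] - log(2)), 0.2)
})

test_that("the model can overfit a separable toy cohort", {
  coh <- tiny_cohort(n_per_class = 4, n_nodes = 8, L = 60, seed = 17,
                     coupling = c(0.9, 0), planted = 0:3)
  batches <- assemble_batches(coh$records, 20, 5, 32, seed = 1, cheb_order = 2)
  cfg <- tiny_config(window_length = 20, window_overlap = 5, batch_size = 32,
                     learning_rate = 5e-3, max_epochs = 50, lr_patience = 25)
  model <- build_model(cfg, 8)
  fit <- train_st(model, batches)
  preds <- predict_entries(fit$model, batches)
  expect_equal(mean(preds$pred == preds$label), 1.0)
  expect_lte(nrow(fit$log), 50)
})

test_that("training is seed-reproducible and invariant to batch order", {
  coh <- tiny_cohort(n_per_class = 3, n_nodes = 4, L = 30)
  batches <- assemble_batches(coh$records, 5, 1, 12, seed = 1, cheb_order = 2)
  cfg <- tiny_config(max_epochs = 3, batch_size = 12)
  f1 <- train_st(build_model(cfg, 4), batches)
  f2 <- train_st(build_model(cfg, 4), batches)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$model$params, f2$model$params)
  f3 <- train_st(build_model(cfg, 4), rev(batches))
  expect_identical(f1$log, f3$log)
})

test_that("training aborts with the epoch number on divergence", {
  coh <- tiny_cohort(n_per_class = 2, n_nodes = 4, L = 20)
  batches <- assemble_batches(coh$records, 5, 1, 8, seed = 1, cheb_order = 2)
  cfg <- tiny_config(learning_rate = 1e200, max_epochs = 5)
  expect_error(train_st(build_model(cfg, 4), batches), "epoch")
})

test_that("entry predictions are deterministic and agree with forward", {
  coh <- tiny_cohort(n_per_class = 2, n_nodes = 4, L = 20)
  batches <- assemble_batches(coh$records, 5, 1, 10, seed = 1, cheb_order = 2)
  model <- build_model(tiny_config(), 4)
  tab <- predict_entries(model, batches[1])
  expect_true(all(tab$prob1 >= 0 & tab$prob1 <= 1))
  out <- forward(model, batches[[1]])
  expect_equal(tab$prob1, out$probabilities[, 2], tolerance = 1e-12)
  b2 <- stfc:::entries_batch(batches[[1]]$entries[c(3, 3)])
  tab2 <- predict_entries(model, list(b2))
  expect_equal(tab2$prob1[1], tab2$prob1[2])
})

test_that("subject aggregation means entry probabilities", {
  tab <- data.frame(entry = c("a_w1", "a_w2", "b_w1"),
                    subject_id = c("a", "a", "b"),
                    prob1 = c(0.9, 0.8, 0.5),
                    pred = c(1L, 1L, 0L), label = c(1L, 1L, 0L))
  subj <- predict_subject(tab)
  expect_equal(subj$score[subj$subject_id == "a"], 0.85)
  expect_equal(subj$pred[subj$subject_id == "a"], 1L)
  expect_equal(subj$score[subj$subject_id == "b"], 0.5)
  expect_equal(subj$pred[subj$subject_id == "b"], 0L)  # 0.5 threshold is strict
})

test_that("ensemble voting takes the majority with score-based tie breaks", {
  expect_equal(ensemble_vote(matrix(c(1, 1, 0), 3, 1)), 1L)
  expect_equal(ensemble_vote(matrix(c(1, 0), 2, 1),
                             matrix(c(0.9, 0.4), 2, 1)), 1L)
  expect_error(ensemble_vote(matrix(integer(0), 0, 1)), "empty")
  # random committees against a counting oracle
  set.seed(23)
  for (rep in 1:10) {
    votes <- matrix(rbinom(7 * 5, 1, 0.5), 7, 5)
    got <- ensemble_vote(votes)
    want <- as.integer(colSums(votes) > 3.5)
    expect_equal(got, want)
  }
})

test_that("models survive a save/load round trip", {
  dir <- withr::local_tempdir()
  model <- build_model(tiny_config(), 4)
  p <- save_model(model, file.path(dir, "m.rds"))
  back <- load_model(p)
  expect_identical(back$params, model$params)
  expect_identical(back$config, model$config)
})
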