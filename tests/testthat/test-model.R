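# A minimal hand-built model object: zeroed network with a fixed output bias,
# used to test prediction plumbing without training.
const_model <- function(enc, value = 0.45, L = 48L) {
  net <- ccs_network(L = L, global_length = ncol(enc$global), seed = 1)
  for (nm in names(net$params)) net$params[[nm]][] <- 0
  net$params$head2_b[] <- value
  structure(list(params = net$params, config = net$config,
                 encoding_config = enc$config,
                 training_config = training_config()),
            class = "ccs_model")
}

test_that("convolution stack shapes follow valid-convolution arithmetic", {
  # independent shape oracle: walk the stack by hand
  shape_oracle <- function(L) {
    p <- L
    out <- integer(6)
    for (l in 1:6) {
      p <- p - 6L + 1L          # valid convolution, kernel 6, stride 1
      if (l == 3) p <- p %/% 2L  # subsampling kernel/stride 2
      out[l] <- p
    }
    out
  }
  for (L in c(47L, 50L, 57L, 96L, 128L)) {
    s <- conv_stack_shapes(L)
    expect_identical(s$positions, shape_oracle(L))
    expect_identical(s$flatten_per_channel, shape_oracle(L)[6])
  }
  # published geometry at the default L = 96: flatten 25 positions x 50 channels
  expect_identical(conv_stack_shapes(96L)$flatten_per_channel, 25L)
  net <- ccs_network(L = 96L)
  expect_identical(net$config$flatten_length, 1250L)
  expect_error(ccs_network(L = 46L), "too short")
})

test_that("the network has the published two-branch architecture", {
  net <- ccs_network(L = 48L)
  cfg <- net$config
  expect_identical(cfg$conv_channels, c(150L, 150L, 150L, 150L, 150L, 50L))
  expect_identical(cfg$kernel, 6L)
  expect_identical(cfg$pool_after, 3L)
  expect_identical(cfg$dense_branch, c(250L, 250L))
  expect_identical(cfg$head, 600L)
  # full variant: dense branch feeds the merge
  expect_identical(cfg$merge_length, cfg$flatten_length + 250L)
  expect_identical(dim(net$params$head1_W), c(cfg$merge_length, 600L))
  expect_identical(dim(net$params$head2_W), c(600L, 1L))
  expect_identical(dim(net$params$conv1_W), c(6L * 323L, 150L))
  expect_identical(dim(net$params$conv6_W), c(6L * 150L, 50L))

  # reduced variant: no dense branch, six scalars join the flatten output
  red <- ccs_network(L = 48L, global_length = 6L, variant = "reduced")
  expect_identical(red$config$merge_length, red$config$flatten_length + 6L)
  expect_false("dense1_W" %in% names(red$params))
  expect_error(ccs_network(L = 48L, global_length = 10L, variant = "reduced"),
               "reduced variant requires")

  # forward pass produces one prediction per peptide
  peps <- rand_peptides(5, c(4L, 7L), seed = 2)
  enc <- encode_dataset(peps, L = 48L)
  pred <- pepccs:::.net_forward(net$params, cfg, enc$spatial, enc$global)$pred
  expect_length(pred, 5)
  expect_true(all(is.finite(pred)))
})

test_that("training is deterministic, selects the argmin checkpoint, and fails on divergence", {
  fx <- tiny_trained()
  tc <- fx$model$training_config
  m2 <- train_ccs_model(ccs_network(L = 48L, global_length = ncol(fx$enc$global),
                                    seed = 99),
                        fx$enc, fx$enc, tc)
  # same seed, identical histories (seed re-initializes the weights)
  expect_identical(fx$model$history, m2$history)
  expect_identical(predict(fx$model, fx$enc), predict(m2, fx$enc))

  # checkpoint contract: recorded argmin, exactly
  h <- fx$model$history
  expect_equal(fx$model$best_val_mae, min(h$val_mae))
  expect_identical(fx$model$best_iteration,
                   h$iteration[which.min(h$val_mae)])

  # a different seed gives a different model
  tc3 <- tc; tc3$seed <- 1234L
  m3 <- train_ccs_model(ccs_network(L = 48L, global_length = ncol(fx$enc$global)),
                        fx$enc, fx$enc, tc3)
  expect_false(identical(predict(m3, fx$enc), predict(fx$model, fx$enc)))

  # absurd learning rate drives the loss non-finite -> diverged error
  tcbad <- training_config(learning_rate = 1e155, batch_size = 8L,
                           max_epochs = 2L, validate_every = 100L,
                           validate_at_epoch_end = FALSE, seed = 1)
  expect_error(train_ccs_model(ccs_network(L = 48L, global_length = ncol(fx$enc$global)),
                               fx$enc, fx$enc, tcbad),
               "training-diverged")

  # missing labels are rejected
  enc_nolab <- encode_dataset(fx$peptides, L = 48L)
  expect_error(train_ccs_model(ccs_network(L = 48L, global_length = ncol(fx$enc$global)),
                               enc_nolab, fx$enc, tc),
               "reference CCS")
})

test_that("predictions are rescaled network outputs, batch-invariant and order-preserving", {
  peps <- rand_peptides(6, c(4L, 7L), seed = 31)
  enc <- encode_dataset(peps, L = 48L)
  # raw network output 0.45 must be reported as 450 square angstroms
  cm <- const_model(enc, value = 0.45)
  expect_equal(predict(cm, enc), rep(450, 6), tolerance = 1e-12)

  fx <- tiny_trained()
  pred_all <- predict(fx$model, fx$enc)
  expect_length(pred_all, 24)
  expect_true(all(is.finite(pred_all)))
  # single-peptide prediction equals its slot in the batch prediction
  p1 <- predict(fx$model, fx$peptides[1])
  expect_equal(p1, pred_all[1], tolerance = 1e-12)
  # encoding with a different configuration is rejected
  enc_other <- encode_dataset(fx$peptides, L = 50L)
  expect_error(predict(fx$model, enc_other), "incompatible-encoding")
})

test_that("ensembles average member predictions exactly", {
  fx <- tiny_trained()
  tc2 <- fx$model$training_config; tc2$seed <- 77L
  m2 <- train_ccs_model(ccs_network(L = 48L, global_length = ncol(fx$enc$global)),
                        fx$enc, fx$enc, tc2)
  # ensemble of one behaves exactly like the single model
  e1 <- ccs_ensemble(list(fx$model))
  expect_identical(predict(e1, fx$enc), predict(fx$model, fx$enc))
  # ensemble of identical members is the member
  eK <- ccs_ensemble(list(fx$model, fx$model, fx$model))
  expect_equal(predict(eK, fx$enc), predict(fx$model, fx$enc), tolerance = 1e-12)
  # mean oracle
  e2 <- ccs_ensemble(list(fx$model, m2))
  expect_equal(predict(e2, fx$enc),
               (predict(fx$model, fx$enc) + predict(m2, fx$enc)) / 2,
               tolerance = 1e-9)
  expect_error(ccs_ensemble(list()), "at least one")
  # members with different encodings are rejected
  peps <- fx$peptides
  encL <- encode_dataset(peps, vapply(peps, ground_truth_ccs, numeric(1)), L = 50L)
  tcL <- fx$model$training_config
  mL <- train_ccs_model(ccs_network(L = 50L, global_length = ncol(encL$global)),
                        encL, encL, tcL)
  expect_error(ccs_ensemble(list(fx$model, mL)), "incompatible-encoding")
})

test_that("models survive a serialization round trip bit-identically", {
  fx <- tiny_trained()
  path <- tempfile(fileext = ".rds")
  save_ccs_model(fx$model, path)
  m <- load_ccs_model(path)
  expect_identical(predict(m, fx$enc), predict(fx$model, fx$enc))
  # ensembles persist too
  pe <- tempfile(fileext = ".rds")
  save_ccs_model(ccs_ensemble(list(fx$model)), pe)
  expect_identical(predict(load_ccs_model(pe), fx$enc),
                   predict(fx$model, fx$enc))
  bad <- tempfile(fileext = ".rds"); saveRDS(1:3, bad)
  expect_error(load_ccs_model(bad), "does not contain")
})
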