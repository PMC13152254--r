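test_that("cross_entropy matches closed forms and a scalar oracle", {
  ## uniform logits -> log C
  for (C in c(2, 5, 16)) {
    logits <- matrix(0, 4, C)
    expect_equal(cross_entropy(logits, rep(1, 4)), log(C), tolerance = 1e-12)
  }
  ## near-one-hot logits -> loss near 0
  logits <- matrix(-50, 3, 4)
  y <- c(2, 1, 4)
  logits[cbind(1:3, y)] <- 50
  expect_lt(cross_entropy(logits, y), 1e-10)
  ## 3-node, 2-class toy against a hand computation
  logits <- rbind(c(1, -1), c(0.5, 0.5), c(-2, 2))
  y <- c(1, 2, 2)
  want <- mean(-log(c(
    exp(1) / (exp(1) + exp(-1)),
    exp(0.5) / (exp(0.5) + exp(0.5)),
    exp(2) / (exp(-2) + exp(2)))))
  expect_equal(cross_entropy(logits, y), want, tolerance = 1e-12)
  ## masked version only sees masked rows
  expect_equal(cross_entropy(logits, y, c(1, 3)),
               mean(-log(c(exp(1) / (exp(1) + exp(-1)),
                           exp(2) / (exp(-2) + exp(2))))), tolerance = 1e-12)
  expect_error(cross_entropy(logits, y, integer()), "empty")
})

test_that("multitask_loss is the stated weighted combination and linear", {
  expect_equal(multitask_loss(1, 2), 0.7 * 1 + 0.3 * 2)
  expect_equal(multitask_loss(1, 2), 1.3)
  expect_equal(multitask_loss(3, 100, alpha = 1, beta = 0), 3)
  ## linearity in each argument
  set.seed(2)
  a <- runif(1); b <- runif(1)
  expect_equal(multitask_loss(2 * a, b) - multitask_loss(a, b),
               multitask_loss(a, 0))
  expect_error(multitask_loss(1, 1, alpha = -1), "non-negative")
})

test_that("split_cells is stratified, exact-sized, and seed-stable", {
  lab <- small_multiome()$labels
  sp <- split_cells(lab, c(0.6, 0.2, 0.2), seed = 4)
  n <- nrow(lab)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), seq_len(n))
  expect_equal(length(sp$train), 0.6 * n, tolerance = 0.02 * n)
  ## stratification: every composite class appears in train
  expect_true(all(table(lab$composite[sp$train]) > 0))
  ## determinism
  expect_identical(sp, split_cells(lab, c(0.6, 0.2, 0.2), seed = 4))
  expect_false(identical(sp, split_cells(lab, c(0.6, 0.2, 0.2), seed = 5)))
  ## donor-grouped: no donor spans partitions
  spd <- split_cells(lab, mode = "donor_grouped", seed = 4)
  donors <- lapply(spd, function(idx) unique(lab$donor_id[idx]))
  expect_length(intersect(donors$train, donors$test), 0)
  expect_length(intersect(donors$train, donors$val), 0)
  expect_length(intersect(donors$val, donors$test), 0)
  ## too few donors errors
  lab2 <- lab
  lab2$donor_id <- factor(rep("d1", n))
  expect_error(split_cells(lab2, mode = "donor_grouped", seed = 1),
               "3 donors")
})

test_that("evaluate_predictions reproduces confusion-matrix arithmetic", {
  ## all correct
  ev <- evaluate_predictions(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(ev$summary$accuracy, 1)
  expect_equal(ev$summary$f1_macro, 1)
  ## binary confusion TP=9 FP=1 FN=1 TN=9 -> precision/recall/F1/acc all 0.9
  truth <- c(rep("pos", 10), rep("neg", 10))
  pred <- truth
  pred[10] <- "neg"      # one FN for pos
  pred[20] <- "pos"      # one FP for pos
  ev <- evaluate_predictions(pred, truth)
  pos <- ev$per_class[ev$per_class$class == "pos", ]
  expect_equal(pos$precision, 0.9)
  expect_equal(pos$recall, 0.9)
  expect_equal(pos$f1, 0.9)
  expect_equal(ev$summary$accuracy, 0.9)
  ## permutation invariance over cells
  set.seed(8)
  perm <- sample(20)
  ev2 <- evaluate_predictions(pred[perm], truth[perm])
  expect_equal(ev2$summary, ev$summary)
  ## uniform random 16-class predictions sit at the analytic baseline
  set.seed(123)
  n <- 10000
  truth16 <- sample(letters[1:16], n, TRUE)
  pred16 <- sample(letters[1:16], n, TRUE)
  ev16 <- evaluate_predictions(pred16, truth16)
  expect_equal(ev16$summary$accuracy, 1 / 16, tolerance = 0.01 * 16)
  ## absent class excluded from macro with warning
  expect_warning(
    ev3 <- evaluate_predictions(factor(c("a", "a"), levels = c("a", "z")),
                                factor(c("a", "a"), levels = c("a", "z"))),
    "excluded")
  expect_equal(ev3$summary$f1_macro, 1)
})

test_that("fit learns the SBM task, is seeded, and respects lr = 0", {
  sb <- sbm_fixture(seed = 1)
  lab <- label_set(sb$labels, rep("s", 200))
  split <- split_cells(lab, seed = 3)
  cfg <- desk_config(epochs = 60, seed = 5)
  fit <- fit_hamgcn(sb$x, sb$graph, sb$labels, split, cfg, "hgcn")
  expect_s3_class(fit, "hamgcn_fit")
  expect_gt(glance(fit)$test_accuracy, 0.8)
  ## bit-reproducibility under identical seeds
  fit2 <- fit_hamgcn(sb$x, sb$graph, sb$labels, split, cfg, "hgcn")
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$history, fit2$history)
  ## learning rate 0 leaves parameters at initialization
  cfg0 <- desk_config(epochs = 3, learning_rate = 0, weight_decay = 0,
                      seed = 5)
  fit0 <- fit_hamgcn(sb$x, sb$graph, sb$labels, split, cfg0, "hgcn")
  init <- hamgcn:::init_params("hgcn", ncol(sb$x), cfg0,
                               nlevels(sb$labels))
  ## best params are from some epoch, but with lr 0 all epochs equal init
  expect_equal(fit0$params$w_enc, init$w_enc, tolerance = 1e-12)
  expect_equal(fit0$params$ham_w1, init$ham_w1, tolerance = 1e-12)
})

test_that("multi-task training with two heads works and weights the losses", {
  sb <- sbm_fixture(seed = 2)
  lab <- label_set(cell_type = sb$labels,
                   disease_state = rep(c("x", "y"), 100))
  split <- split_cells(lab, seed = 3)
  cfg <- desk_config(epochs = 30, task = "multi", seed = 5)
  fit <- fit_hamgcn(sb$x, sb$graph, lab, split, cfg, "hgcn")
  expect_length(fit$tasks, 2)
  expect_equal(fit$tasks[[1]]$weight, 0.7)
  expect_equal(fit$tasks[[2]]$weight, 0.3)
  pred <- predict(fit)
  expect_true(all(c(".pred_cell_type", ".pred_disease_state") %in%
                    names(pred)))
})

test_that("tidiers return well-formed tibbles", {
  sb <- sbm_fixture(seed = 3)
  lab <- label_set(sb$labels, rep("s", 200))
  split <- split_cells(lab, seed = 3)
  fit <- fit_hamgcn(sb$x, sb$graph, sb$labels, split,
                    desk_config(epochs = 10, seed = 2), "gcn_baseline")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("epoch", "train_loss", "val_loss", "val_accuracy"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("mode", "best_epoch", "test_accuracy") %in% names(gl)))
})
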