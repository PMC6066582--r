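test_that("softmax probabilities follow the closed form", {
  head <- softmax_model(rbind(c(1, 0.5), c(1, 0.5)))   # theta1 == theta2
  P <- softmax_predict(head, matrix(runif(6), 3, 2))
  expect_equal(unname(P), matrix(0.5, 3, 2))   # identical rows of theta

  # (theta1 - theta2)'z = ln 3  ->  (0.75, 0.25)
  head2 <- softmax_model(matrix(c(log(3), 0), 2, 1))
  expect_equal(as.numeric(softmax_predict(head2, matrix(1))), c(0.75, 0.25))

  # shift invariance: adding one vector to every class row changes nothing
  set.seed(1)
  th <- matrix(rnorm(6), 2, 3); z <- matrix(rnorm(9), 3, 3)
  shift <- rnorm(3)
  P1 <- softmax_predict(softmax_model(th), z)
  P2 <- softmax_predict(softmax_model(sweep(th, 2, shift, "+")), z)
  expect_equal(P1, P2)
  expect_equal(rowSums(P1), rep(1, 3), tolerance = 1e-12)
  expect_error(softmax_predict(softmax_model(th), matrix(NaN, 1, 3)), "NaN")
})

test_that("cross-entropy matches hand evaluations", {
  head <- softmax_model(matrix(c(40, -40), 2, 1))
  Z <- matrix(c(1, 1), 2, 1)
  Y <- rbind(c(1, 0), c(1, 0))
  expect_lt(cross_entropy(head, Z, Y), 1e-10)   # confident and correct

  # uniform predictions cost 2*ln(2) per sample under the both-terms form
  head0 <- softmax_model(matrix(0, 2, 2))
  Zr <- matrix(rnorm(8), 4, 2)
  Yr <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  expect_equal(cross_entropy(head0, Zr, Yr), 2 * log(2))

  # duplicating every sample leaves the mean unchanged
  set.seed(2)
  headr <- softmax_model(matrix(rnorm(4), 2, 2), rnorm(2))
  expect_equal(cross_entropy(headr, Zr, Yr),
               cross_entropy(headr, rbind(Zr, Zr), rbind(Yr, Yr)))
})

test_that("softmax training fits separable data and honors priors", {
  set.seed(3)
  Z <- rbind(matrix(rnorm(20, -2, 0.3), 10, 2),
             matrix(rnorm(20,  2, 0.3), 10, 2))
  Y <- rbind(matrix(rep(c(1, 0), each = 10), 10, 2)[, 1:2],
             matrix(rep(c(0, 1), each = 10), 10, 2)[, 1:2])
  hp <- hyperparams(c(2), max_epochs = 300, cost_goal = 1e-4)
  head <- train_softmax(Z, Y, hp)
  P <- softmax_predict(head, Z)
  expect_equal(as.numeric(apply(P, 1, which.max)),
               as.numeric(apply(Y, 1, which.max)))
  expect_lte(cross_entropy(head, Z, Y),
             cross_entropy(dtlconn:::unpack_head(numeric(6), 2, 2, TRUE),
                           Z, Y))

  # uninformative features: optimum predicts the class prior (0.5)
  set.seed(4)
  Zu <- matrix(rnorm(40), 20, 2)
  Yu <- cbind(rep(c(1, 0), 10), rep(c(0, 1), 10))
  headu <- train_softmax(Zu, Yu, hyperparams(c(2), max_epochs = 500,
                                             cost_goal = 0))
  expect_equal(mean(softmax_predict(headu, Zu)[, 1]), 0.5, tolerance = 0.1)

  expect_error(train_softmax(Z, cbind(rep(1, 20), 0), hp), "class")
})

test_that("end-to-end fine-tuning gradient matches finite differences", {
  set.seed(5)
  X <- matrix(runif(8 * 6, -1, 1), 8, 6)             # 6-4-3-2 toy
  labels <- rep(c("HC", "ASD"), 4)
  hp <- hyperparams(c(4, 3), max_epochs = 2, seed = 6)
  proto <- train_ssae(X, hp, "offline")
  model <- train_dtl_nn(proto, X, labels, hp, positive = "ASD",
                        do_fine_tune = FALSE)
  Y <- dtlconn:::one_hot(labels, model$classes)
  w <- dtlconn:::flatten_dtlnn(model)
  an <- dtlconn:::dtlnn_cost_grad(model, X, Y)$grad
  num <- numeric_gradient(function(ww)
    dtlconn:::dtlnn_cost_grad(dtlconn:::unflatten_dtlnn(ww, model), X, Y)$cost,
    w)
  expect_lt(max_rel_err(an, num), 1e-6)
})

test_that("fine-tuning is a descent no-op at zero epochs", {
  set.seed(7)
  X <- matrix(runif(10 * 5, -1, 1), 10, 5)
  labels <- rep(c("HC", "ASD"), 5)
  hp <- hyperparams(c(3), max_epochs = 30, seed = 8)
  proto <- train_ssae(X, hp, "offline")
  m0 <- train_dtl_nn(proto, X, labels, hp, do_fine_tune = FALSE)
  Y <- dtlconn:::one_hot(labels, m0$classes)

  hp0 <- hp; hp0$max_epochs <- 0L
  same <- fine_tune(m0, X, Y, hp0)
  expect_identical(dtlconn:::flatten_dtlnn(same), dtlconn:::flatten_dtlnn(m0))
  expect_false(same$fine_tuned)

  tuned <- fine_tune(m0, X, Y, hp)
  expect_true(tuned$fine_tuned)
  expect_lte(cross_entropy(tuned$head, ssae_extract(tuned$ssae, X), Y),
             cross_entropy(m0$head, ssae_extract(m0$ssae, X), Y))
  expect_true(length(tuned$training_log) >= 1)
})

test_that("the transfer pipeline composes extract -> softmax -> predict", {
  set.seed(9)
  X <- matrix(runif(12 * 5, -1, 1), 12, 5)
  labels <- rep(c("HC", "ASD"), 6)
  hp <- hyperparams(c(3), max_epochs = 40, seed = 10)
  proto <- train_ssae(X, hp, "offline")
  frozen <- train_dtl_nn(proto, X, labels, hp, do_fine_tune = FALSE)
  # with fine-tuning disabled, predictions equal softmax on frozen features
  P <- softmax_predict(frozen$head, ssae_extract(proto, X))
  pr <- predict(frozen, X)
  expect_equal(pr$prob, unname(P[, 2]))
  expect_equal(rowSums(P), rep(1, 12), tolerance = 1e-12)
  expect_identical(frozen$mode, "DTL-NN")
  expect_identical(frozen$ssae$provenance, "offline")
})

test_that("DNN baseline differs only by its pretraining corpus", {
  set.seed(10)
  X <- matrix(runif(10 * 5, -1, 1), 10, 5)
  labels <- rep(c("HC", "ASD"), 5)
  hp <- hyperparams(c(3, 2), max_epochs = 10, seed = 12)
  dnn <- train_dnn_baseline(X, labels, hp, do_fine_tune = FALSE)
  expect_identical(dnn$mode, "DNN")
  expect_identical(dnn$ssae$provenance, "target-pretrained")
  # same corpus for offline and target => identical initialization
  proto <- train_ssae(X, hp, "offline")
  dtl <- train_dtl_nn(proto, X, labels, hp, do_fine_tune = FALSE)
  expect_identical(dtl$ssae$encoders, dnn$ssae$encoders)
  expect_equal(predict(dtl, X), predict(dnn, X))
  # determinism of the full training path
  dnn2 <- train_dnn_baseline(X, labels, hp, do_fine_tune = FALSE)
  expect_identical(dtlconn:::flatten_dtlnn(dnn), dtlconn:::flatten_dtlnn(dnn2))
})

test_that("two-class softmax is equivalent to a single-logit sigmoid", {
  set.seed(11)
  th <- matrix(rnorm(6), 2, 3); ic <- rnorm(2)
  Z <- matrix(rnorm(15), 5, 3)
  P <- softmax_predict(softmax_model(th, ic), Z)
  logit <- Z %*% (th[2, ] - th[1, ]) + (ic[2] - ic[1])
  expect_equal(P[, 2], as.numeric(plogis(logit)))
})

test_that("prediction ties at probability 0.5 go to the positive class", {
  head <- softmax_model(matrix(0, 2, 3))
  ssae <- dtlconn:::new_ssae(list(list(W = matrix(0, 3, 4), b = numeric(3))),
                             c(4L, 3L), hyperparams(c(3)), "offline", 1L)
  model <- dtlconn:::new_dtlnn(ssae, head, c("HC", "ASD"), "DTL-NN")
  pr <- predict(model, matrix(runif(8, -1, 1), 2, 4))
  expect_equal(pr$prob, c(0.5, 0.5))
  expect_equal(pr$label, c("ASD", "ASD"))
})
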