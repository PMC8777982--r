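test_that("generalized Dice loss matches hand-evaluated cases", {
  # perfect overlap: loss 0
  r <- cbind(c(1, 0, 1), c(0, 1, 0))
  expect_equal(generalized_dice_loss(r, r), 0)
  # 2 pixels, 2 classes, uniform prediction: w = (1, 1), num = 1, den = 4
  r2 <- rbind(c(1, 0), c(0, 1))
  p2 <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(generalized_dice_loss(r2, p2), 0.5)
  # validation
  expect_error(generalized_dice_loss(r2, rbind(c(0.7, 0.7), c(0.5, 0.5))),
               "sum to 1")
  expect_error(generalized_dice_loss(rbind(c(0.5, 0.5), c(0, 1)), p2),
               "one-hot")
})

test_that("generalized Dice loss is invariant to balanced duplication", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    r <- t(vapply(sample(1:2, n, replace = TRUE),
                  function(l) as.numeric(seq_len(2) == l), numeric(2)))
    p <- matrix(runif(2 * n), n, 2)
    p <- p / rowSums(p)
    l1 <- generalized_dice_loss(r, p)
    l2 <- generalized_dice_loss(rbind(r, r), rbind(p, p))
    expect_equal(l1, l2, tolerance = 1e-12)
    expect_gte(l1, 0)
    expect_lte(l1, 1)
  }
})

test_that("generalized Dice loss decreases toward the reference", {
  set.seed(8)
  for (rep in 1:5) {
    n <- sample(4:10, 1)
    r <- t(vapply(sample(1:2, n, replace = TRUE),
                  function(l) as.numeric(seq_len(2) == l), numeric(2)))
    losses <- vapply(seq(0, 1, by = 0.1), function(t) {
      generalized_dice_loss(r, (1 - t) * (1 - r) + t * r)
    }, numeric(1))
    expect_true(all(diff(losses) < 0))
    expect_equal(losses[11], 0)
  }
})

test_that("confusion counts enumerate pixels correctly", {
  pred <- c(1, 1, 1, 0, 0, 0, 0, 0, 1, 0)
  ref  <- c(1, 1, 0, 0, 0, 0, 0, 1, 1, 0)
  cc <- confusion(pred, ref)
  expect_equal(cc$TP, 3)
  expect_equal(cc$FP, 1)
  expect_equal(cc$FN, 1)
  expect_equal(cc$TN, 5)
  # identical and complementary predictions
  same <- confusion(ref, ref)
  expect_equal(same$FP + same$FN, 0)
  opp <- confusion(1 - ref, ref)
  expect_equal(opp$TP + opp$TN, 0)
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 2, 3)), "shapes differ")
  # roi restriction
  roi <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  expect_equal(confusion(pred, ref, roi)$TN, 2)
})

test_that("accuracy, sensitivity and specificity follow their ratios", {
  cc <- list(TP = 3, FP = 1, FN = 1, TN = 5)
  expect_equal(accuracy(cc), 0.8)
  expect_equal(sensitivity(cc), 0.75)
  expect_equal(specificity(cc), 5 / 6)
  expect_equal(accuracy(list(TP = 4, FP = 0, FN = 0, TN = 6)), 1)
  expect_equal(accuracy(list(TP = 0, FP = 5, FN = 5, TN = 0)), 0)
  expect_equal(sensitivity(list(TP = 2, FP = 0, FN = 0, TN = 1)), 1)
  expect_equal(sensitivity(list(TP = 0, FP = 0, FN = 3, TN = 1)), 0)
  expect_equal(specificity(list(TP = 1, FP = 0, FN = 0, TN = 2)), 1)
  expect_equal(specificity(list(TP = 1, FP = 4, FN = 0, TN = 0)), 0)
  expect_error(accuracy(list(TP = 0, FP = 0, FN = 0, TN = 0)), "domain")
  expect_error(sensitivity(list(TP = 0, FP = 1, FN = 0, TN = 1)),
               "undefined-signal")
  expect_error(specificity(list(TP = 1, FP = 0, FN = 1, TN = 0)),
               "undefined-signal")
  # accuracy decomposes as prevalence-weighted SE and SP
  set.seed(9)
  for (rep in 1:20) {
    cc <- as.list(stats::setNames(sample(1:50, 4, replace = TRUE),
                                  c("TP", "FP", "FN", "TN")))
    P <- cc$TP + cc$FN
    N <- cc$TN + cc$FP
    expect_equal(accuracy(cc),
                 (sensitivity(cc) * P + specificity(cc) * N) / (P + N))
  }
})

test_that("ROC AUC equals the pairwise Mann-Whitney oracle", {
  # perfectly separating scores
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  # class-independent scores sit on the chance line
  expect_equal(roc_auc(rep(0.5, 8), rep(c(0, 1), 4)), 0.5)
  # 6-pixel case evaluated by brute force: 8 of 9 pairs ordered correctly
  s <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  l <- c(1, 1, 1, 0, 0, 0)
  expect_equal(roc_auc(s, l), brute_force_auc(s, l))
  expect_equal(roc_auc(s, l), 8 / 9)
  expect_error(roc_auc(c(0.2, 0.4), c(1, 1)), "both classes")
  # property: midrank implementation == brute force, with heavy ties
  set.seed(10)
  for (rep in 1:25) {
    n <- sample(10:1000, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    labels <- sample(0:1, n, replace = TRUE, prob = c(0.8, 0.2))
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(roc_auc(scores, labels), brute_force_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("paired two-tailed t-test matches the textbook formula", {
  xs <- c(0.91, 0.87, 0.95, 0.90, 0.88)
  ys <- c(0.89, 0.86, 0.92, 0.91, 0.85)
  got <- paired_two_tailed_ttest(xs, ys)
  d <- xs - ys
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(got$statistic, t_hand)
  expect_equal(got$df, 4)
  expect_equal(got$p_value, 2 * pt(-abs(t_hand), df = 4))
  # degenerate difference variance
  expect_error(paired_two_tailed_ttest(xs, xs), "zero variance")
  expect_error(paired_two_tailed_ttest(1, 1), "size >= 2")
  # near-constant positive differences give a tiny p
  expect_lt(paired_two_tailed_ttest(c(2, 2.0011, 1.9990, 2.0002),
                                    c(1, 1.001, 0.999, 1))$p_value, 1e-5)
})
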