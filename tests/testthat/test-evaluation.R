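# a small hand-made ground truth for evaluation tests: 6 neurons,
# synapses with assorted weights including weak and inhibitory ones
toy_truth <- function() {
  w <- matrix(0, 6, 6)
  d <- matrix(0L, 6, 6)
  w[1, 2] <- 8; d[1, 2] <- 3L    # strong excitatory
  w[1, 3] <- 0.5; d[1, 3] <- 5L  # weak -> excluded
  w[2, 4] <- 10; d[2, 4] <- 1L
  w[3, 4] <- 0; d[3, 4] <- 2L    # zero-weight synapse -> excluded
  w[5, 1] <- -5; d[5, 1] <- 1L   # inhibitory
  w[5, 2] <- -5; d[5, 2] <- 1L
  structure(list(weight_mV = w, delay_ms = d, adjacency = d > 0,
                 neuron_type = c(rep("exc", 4), "inh", "exc"),
                 neuron_ids = 1:6),
            class = "spk_truth")
}

test_that("pair labeling separates positives, negatives and excluded", {
  lab <- classify_pairs(toy_truth())
  expect_equal(nrow(lab), 30)  # 6*5 ordered pairs
  get <- function(p, q) lab$label[lab$pre == p & lab$post == q]
  expect_equal(get(1, 2), "positive")
  expect_equal(get(1, 3), "excluded")
  expect_equal(get(3, 4), "excluded")
  expect_equal(get(5, 1), "positive")   # inhibitory magnitude 5 > 1
  expect_equal(get(4, 1), "negative")
  expect_equal(sum(lab$label == "positive"), 4)
  expect_equal(sum(lab$label == "excluded"), 2)
})

test_that("an all-empty network labels every pair negative", {
  tr <- structure(list(weight_mV = matrix(0, 4, 4),
                       delay_ms = matrix(0L, 4, 4),
                       adjacency = matrix(FALSE, 4, 4),
                       neuron_type = rep("exc", 4), neuron_ids = 1:4),
                  class = "spk_truth")
  lab <- classify_pairs(tr)
  expect_true(all(lab$label == "negative"))
})

test_that("ROC sweep matches the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(501)
  for (rep in 1:5) {
    n <- 300
    label <- ifelse(stats::runif(n) < 0.2, "positive", "negative")
    score <- stats::rnorm(n) + (label == "positive") * 1.5
    score[sample(n, 20)] <- score[sample(n, 20)]  # introduce ties
    roc <- roc_curve(score, label)
    ref <- pROC::roc(response = label, predictor = score,
                     levels = c("negative", "positive"),
                     direction = "<", quiet = TRUE)
    ours <- unique(data.frame(fpr = roc$fpr, tpr = roc$tpr))
    theirs <- unique(data.frame(fpr = rev(1 - ref$specificities),
                                tpr = rev(ref$sensitivities)))
    expect_equal(ours$fpr, theirs$fpr, tolerance = 1e-12)
    expect_equal(ours$tpr, theirs$tpr, tolerance = 1e-12)
  }
})

test_that("a perfect oracle reaches TPR 1 at FPR 0.01", {
  set.seed(502)
  tr <- toy_truth()
  lab <- classify_pairs(tr)
  scores <- data.frame(pre = lab$pre, post = lab$post,
                       score = abs(lab$weight_mV) +
                         stats::runif(nrow(lab), 0, 1e-6))
  ev <- evaluate_scores(scores, tr)
  expect_equal(ev$tpr, 1)
  # at the FPR = 0.01 operating point a hundredth of the negatives is
  # admitted, so purity is high but not exactly 1
  expect_gt(ev$purity, 0.9)
})

test_that("random scores give a near-diagonal ROC", {
  set.seed(503)
  n_neur <- 40
  w <- matrix(0, n_neur, n_neur)
  d <- matrix(0L, n_neur, n_neur)
  conn <- which(matrix(stats::runif(n_neur^2) < 0.1 &
                         !diag(n_neur), n_neur), arr.ind = TRUE)
  w[conn] <- 8
  d[conn] <- 1L
  tr <- structure(list(weight_mV = w, delay_ms = d, adjacency = d > 0,
                       neuron_type = rep("exc", n_neur),
                       neuron_ids = 1:n_neur),
                  class = "spk_truth")
  lab <- classify_pairs(tr)
  scores <- data.frame(pre = lab$pre, post = lab$post,
                       score = stats::runif(nrow(lab)))
  ev <- evaluate_scores(scores, tr)
  expect_lt(abs(ev$tpr - 0.01), 0.05)
  auc <- sum(diff(ev$roc$fpr) * (utils::head(ev$roc$tpr, -1) +
                                   utils::tail(ev$roc$tpr, -1)) / 2)
  expect_lt(abs(auc - 0.5), 0.1)
})

test_that("weight fraction accounts weights at the operating point", {
  tr <- toy_truth()
  lab <- classify_pairs(tr)
  # oracle scores: all positives found before any negative
  scores <- data.frame(pre = lab$pre, post = lab$post,
                       score = abs(lab$weight_mV))
  ev <- evaluate_scores(scores, tr)
  total <- sum(abs(tr$weight_mV))
  excluded_w <- 0.5
  expect_equal(ev$weight_fraction, (total - excluded_w) / total)
})

test_that("type breakdown splits true positives by presynaptic type", {
  tr <- toy_truth()
  lab <- classify_pairs(tr)
  scores <- data.frame(pre = lab$pre, post = lab$post,
                       score = abs(lab$weight_mV))
  ev <- evaluate_scores(scores, tr)
  expect_equal(ev$breakdown$exc_tp, 2)
  expect_equal(ev$breakdown$inh_tp, 2)
  expect_equal(ev$breakdown$inhibitory_fraction, 0.5)
  # at FPR = 0.01 a hundredth of the 24 negatives is admitted
  expect_equal(ev$breakdown$fp, 0.24)
})

test_that("missing scores are ranked last, not dropped", {
  tr <- toy_truth()
  lab <- classify_pairs(tr)
  scores <- data.frame(pre = lab$pre, post = lab$post,
                       score = abs(lab$weight_mV))
  scores$score[scores$pre == 5 & scores$post == 1] <- NA
  ev <- evaluate_scores(scores, tr)
  expect_lt(ev$tpr, 1)  # the NA positive cannot be recovered early
  expect_equal(ev$n_positive, 4)
})

test_that("ROC refuses degenerate label pools", {
  expect_error(roc_curve(c(1, 2), c("positive", "positive")), "negative")
})
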