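test_that("confusion matrices tally truth rows against prediction columns", {
  perfect <- tibble::tibble(label = c("a", "b", "b"), predicted_label = c("a", "b", "b"))
  cm <- confusion_matrix(perfect)
  expect_equal(unclass(cm), matrix(c(1L, 0L, 0L, 2L), 2,
                                   dimnames = list(true = c("a", "b"),
                                                   predicted = c("a", "b"))))
  onecol <- tibble::tibble(label = c("a", "b", "b"), predicted_label = "a")
  cm2 <- confusion_matrix(onecol)
  expect_equal(sum(cm2[, "b"]), 0)
  expect_equal(sum(cm2), 3)
  expect_error(
    confusion_matrix(tibble::tibble(label = "a", predicted_label = "zzz")),
    "outside the class set"
  )
})

test_that("random confusion tallies match a brute-force count", {
  withr::local_seed(77)
  for (i in 1:10) {
    df <- tibble::tibble(
      label = sample(c("x", "y", "z"), 50, replace = TRUE),
      predicted_label = sample(c("x", "y", "z"), 50, replace = TRUE)
    )
    cm <- confusion_matrix(df)
    for (ti in c("x", "y", "z")) for (pj in c("x", "y", "z")) {
      expect_equal(cm[ti, pj], sum(df$label == ti & df$predicted_label == pj))
    }
  }
})

test_that("diagnostic metrics follow the one-vs-rest formulas", {
  # sensitivity 0.90, specificity 0.98 style arithmetic: TP=90 FN=10 TN=98 FP=2
  df <- tibble::tibble(
    label = rep(c("case", "noncase"), c(100, 100)),
    predicted_label = c(rep("case", 90), rep("noncase", 10),
                        rep("case", 2), rep("noncase", 98))
  )
  rep_ <- compute_metrics(confusion_matrix(df))
  case_row <- rep_$by_class[rep_$by_class$class == "case", ]
  expect_equal(case_row$sensitivity, 0.90)
  expect_equal(case_row$specificity, 0.98)
  expect_equal(case_row$ppv, 90 / 92)
  expect_equal(case_row$npv, 98 / 108)
  expect_equal(rep_$accuracy, 188 / 200)
  expect_true(is.na(rep_$auroc))  # no scores supplied: omitted, not guessed
})

test_that("zero-denominator metrics are missing, never zero", {
  df <- tibble::tibble(label = c("case", "case", "noncase"),
                       predicted_label = "case")  # nothing predicted negative
  rep_ <- compute_metrics(confusion_matrix(df))
  case_row <- rep_$by_class[rep_$by_class$class == "case", ]
  expect_true(is.na(case_row$npv))
  expect_true(is.na(case_row$specificity) || case_row$specificity == 0)
  non_row <- rep_$by_class[rep_$by_class$class == "noncase", ]
  expect_true(is.na(non_row$ppv))
})

test_that("AUROC equals the all-pairs concordance oracle, ties at half credit", {
  df <- tibble::tibble(
    label = c("case", "case", "case", "noncase", "noncase", "noncase"),
    case = c(0.9, 0.6, 0.5, 0.5, 0.3, 0.1)
  )
  df$noncase <- 1 - df$case
  expected <- oracle_auroc(df$case, df$label == "case")
  expect_equal(expected, (3 + 3 + 2.5) / 9)  # hand count: one tied pair
  expect_equal(auroc(df), expected)

  sep <- tibble::tibble(label = rep(c("case", "noncase"), each = 4),
                        case = c(0.9, 0.8, 0.75, 0.7, 0.3, 0.2, 0.1, 0.05))
  sep$noncase <- 1 - sep$case
  expect_equal(auroc(sep), 1.0)
})

test_that("AUROC matches the oracle (and pROC) on random score sets", {
  withr::local_seed(99)
  for (i in 1:20) {
    n <- sample(4:40, 1)
    df <- tibble::tibble(
      label = sample(c("case", "noncase"), n, replace = TRUE),
      case = round(stats::runif(n), 2)  # rounding forces ties
    )
    df$noncase <- 1 - df$case
    if (length(unique(df$label)) < 2) next
    expected <- oracle_auroc(df$case, df$label == "case")
    expect_equal(auroc(df), expected)
    proc <- suppressMessages(pROC::auc(pROC::roc(
      response = df$label, predictor = df$case,
      levels = c("noncase", "case"), direction = "<"
    )))
    expect_equal(auroc(df), as.numeric(proc))
  }
})

test_that("multi-class metrics equal the dedicated binary one-vs-rest collapse", {
  withr::local_seed(5)
  classes <- c("pcd", "cf", "bronchiectasis", "control")
  df <- tibble::tibble(
    label = sample(classes, 120, replace = TRUE, prob = c(0.1, 0.2, 0.2, 0.5)),
    predicted_label = sample(classes, 120, replace = TRUE,
                             prob = c(0.1, 0.2, 0.2, 0.5))
  )
  multi <- compute_metrics(confusion_matrix(df))
  # collapse to target-vs-rest and recompute with a plain binary matrix
  bin <- dplyr::mutate(df,
    label = ifelse(label == "pcd", "pcd", "rest"),
    predicted_label = ifelse(predicted_label == "pcd", "pcd", "rest"))
  binary <- compute_metrics(confusion_matrix(bin))
  for (metric in c("sensitivity", "specificity", "ppv", "npv", "f1")) {
    expect_equal(multi$by_class[[metric]][multi$by_class$class == "pcd"],
                 binary$by_class[[metric]][binary$by_class$class == "pcd"],
                 label = metric)
  }
})

test_that("confidence filtering partitions exactly at the threshold", {
  preds <- tibble::tibble(patient_id = c("a", "b", "c"),
                          confidence = c(0.9, 0.5, 0.6),
                          predicted_label = "case")
  flt <- confidence_filter(preds, 0.55)
  expect_equal(flt$accepted$patient_id, c("a", "c"))
  expect_equal(flt$abstained$patient_id, "b")
  expect_equal(nrow(confidence_filter(preds, 0)$abstained), 0)
  expect_equal(nrow(confidence_filter(preds, 1)$accepted), 0)
  expect_equal(nrow(flt$accepted) + nrow(flt$abstained), nrow(preds))
})

test_that("the confidence curve is monotone in acceptances and handles perfection", {
  withr::local_seed(12)
  preds <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:30),
    label = sample(c("case", "noncase"), 30, replace = TRUE),
    confidence = stats::runif(30, 0.5, 1)
  )
  preds$predicted_label <- preds$label  # all correct
  curve <- confidence_curve(preds)
  expect_true(all(diff(curve$n_accepted) <= 0))
  expect_true(all(curve$accuracy_accepted[curve$n_accepted > 0] == 1))

  preds$predicted_label[1:10] <- "case"  # some wrong now
  curve2 <- confidence_curve(preds)
  expect_true(all(diff(curve2$n_accepted) <= 0))
  expect_equal(curve2$n_accepted[1], 30)  # cutoff 0 accepts everyone
})
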