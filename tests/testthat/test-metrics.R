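test_that("binary metrics follow their definitions, NA on zero denominators", {
  m <- binary_metrics(tp = 9, fp = 1, fn = 1, tn = 9)
  expect_equal(unlist(m), c(sensitivity = 0.9, specificity = 0.9,
                            ppv = 0.9, npv = 0.9))
  m <- binary_metrics(tp = 5, fp = 0, fn = 0, tn = 5)
  expect_true(all(unlist(m) == 1))
  m <- binary_metrics(tp = 97, fp = 10, fn = 3, tn = 90)
  expect_equal(m$sensitivity, 0.97)
  expect_equal(m$specificity, 0.90)
  # undefined, not zero
  m <- binary_metrics(tp = 0, fp = 0, fn = 3, tn = 7)
  expect_true(is.na(m$ppv))
  expect_equal(m$npv, 0.7)
  expect_error(binary_metrics(0, 0, 0, 0), "total")
})

test_that("swapping the positive label swaps sens<->spec and ppv<->npv", {
  set.seed(5)
  for (i in 1:50) {
    cm <- as.list(setNames(sample(0:20, 4, replace = TRUE),
                           c("tp", "fp", "fn", "tn")))
    if (sum(unlist(cm)) == 0) next
    a <- binary_metrics(cm$tp, cm$fp, cm$fn, cm$tn)
    b <- binary_metrics(cm$tn, cm$fn, cm$fp, cm$tp)
    expect_equal(a$sensitivity, b$specificity)
    expect_equal(a$ppv, b$npv)
  }
})

test_that("the 'possible' group collapses to either side of the dichotomy", {
  labs <- c("none", "possible", "diabetes")
  expect_identical(collapse_labels(labs, "possible_as_negative"),
                   c(FALSE, FALSE, TRUE))
  expect_identical(collapse_labels(labs, "possible_as_positive"),
                   c(FALSE, TRUE, TRUE))
  expect_error(collapse_labels("borderline"), "unknown")
})

test_that("Cohen's kappa matches a definitional brute-force computation", {
  # hand cases
  expect_equal(cohen_kappa(diag(c(5, 3, 2))), 1)
  expect_equal(cohen_kappa(diag(c(5, 3, 2)), "linear"), 1)
  # observed agreement equal to chance agreement
  tab <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(cohen_kappa(tab), 0)
  # randomized 3x3 tables vs the po/pe double loop
  set.seed(91)
  for (i in 1:200) {
    tab <- matrix(sample(0:6, 9, replace = TRUE), 3)
    if (sum(tab) == 0) next
    expect_equal(cohen_kappa(tab, "unweighted"), oracle_kappa(tab, FALSE))
    expect_equal(cohen_kappa(tab, "linear"), oracle_kappa(tab, TRUE))
  }
})

test_that("linear-weighted kappa equals unweighted kappa on 2x2 tables", {
  set.seed(17)
  for (i in 1:200) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    k_u <- cohen_kappa(tab, "unweighted")
    k_l <- cohen_kappa(tab, "linear")
    expect_equal(k_l, k_u)
  }
})

test_that("kappa agrees with caret's independent implementation", {
  skip_if_not_installed("caret")
  set.seed(23)
  for (i in 1:20) {
    pred <- factor(sample(c("a", "b"), 40, replace = TRUE),
                   levels = c("a", "b"))
    truth <- factor(sample(c("a", "b"), 40, replace = TRUE),
                    levels = c("a", "b"))
    if (length(unique(pred)) < 2 || length(unique(truth)) < 2) next
    ours <- cohen_kappa(table(pred, truth))
    ref <- unname(caret::confusionMatrix(pred, truth)$overall["Kappa"])
    expect_equal(ours, ref)
  }
})

test_that("degenerate marginals give an undefined kappa", {
  tab <- matrix(c(10, 0, 0, 0), 2)  # everyone in one cell
  expect_true(is.na(cohen_kappa(tab)))
})

test_that("ROC sweep matches exhaustive enumeration, pROC, and Mann-Whitney", {
  # perfect separation
  roc <- roc_over_thresholds(c(1, 1, 1, 0, 0), c(TRUE, TRUE, TRUE, FALSE,
                                                 FALSE),
                             thresholds = c(0.5, 1))
  expect_equal(roc$auc, 1)
  # uninformative scores
  roc <- roc_over_thresholds(rep(0.75, 6), c(TRUE, TRUE, TRUE, FALSE,
                                             FALSE, FALSE))
  expect_equal(roc$auc, 0.5)
  # six-patient hand-built set: enumerate every threshold's matrix by hand
  totals <- c(0, 0.4, 0.75, 1.0, 1.15, 1.5)
  gold <- c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE)
  roc <- roc_over_thresholds(totals, gold)
  for (i in seq_len(nrow(roc$points))) {
    t <- roc$points$threshold[i]
    expect_equal(roc$points$sensitivity[i],
                 sum(totals >= t & gold) / sum(gold))
    expect_equal(roc$points$specificity[i],
                 sum(totals < t & !gold) / sum(!gold))
  }
  expect_equal(roc$auc, oracle_auc_mw(totals, gold))
  # random score sets: trapezoidal AUC over all observed thresholds equals
  # the tie-corrected Mann-Whitney probability, and pROC agrees
  set.seed(41)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    totals <- sample(seq(0, 2, by = 0.25), n, replace = TRUE)
    gold <- runif(n) < 0.5
    if (!any(gold) || all(gold)) next
    roc <- roc_over_thresholds(totals, gold)
    expect_equal(roc$auc, oracle_auc_mw(totals, gold))
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- suppressMessages(as.numeric(
        pROC::auc(pROC::roc(gold, totals, quiet = TRUE,
                            levels = c(FALSE, TRUE), direction = "<"))))
      expect_equal(roc$auc, ref)
    }
  }
  # sensitivity is non-increasing as the threshold rises
  expect_true(all(diff(roc$points$sensitivity) <= 0))
  expect_error(roc_over_thresholds(c(1, 2), c(TRUE, TRUE)), "negative")
})

test_that("date agreement counts exact and windowed pairs correctly", {
  d <- date_agreement(as.Date(c("2009-04-01", "2009-01-15")),
                      as.Date(c("2009-04-01", "2009-01-15")))
  expect_equal(d$n_exact, d$n_pairs)
  # 76-day delay is inside the 92-day window
  d <- date_agreement(as.Date("2009-04-01"), as.Date("2009-01-15"))
  expect_equal(d$delays, 76L)
  expect_equal(d$n_within_window, 1L)
  expect_equal(d$n_exact, 0L)
  # 200 days late is outside
  d <- date_agreement(as.Date("2009-08-19"), as.Date("2009-01-31"))
  expect_equal(d$n_within_window, 0L)
  # one-sided mode rejects a model date that precedes gold
  d <- date_agreement(as.Date("2009-01-01"), as.Date("2009-02-01"),
                      sided = "model_late")
  expect_equal(d$n_within_window, 0L)
  d <- date_agreement(as.Date("2009-01-01"), as.Date("2009-02-01"),
                      sided = "symmetric")
  expect_equal(d$n_within_window, 1L)
  # empty input: an empty report, not an error
  d <- date_agreement(as.Date(character()), as.Date(character()))
  expect_equal(d$n_pairs, 0L)
  # pairs with a missing date are excluded
  d <- date_agreement(as.Date(c("2009-01-01", NA)),
                      as.Date(c("2009-01-01", "2009-01-01")))
  expect_equal(d$n_pairs, 1L)
})

test_that("date agreement is translation-invariant", {
  set.seed(3)
  model <- as.Date("2009-01-01") + sample(0:400, 30, replace = TRUE)
  gold <- model + sample(-150:150, 30, replace = TRUE)
  base <- date_agreement(model, gold)
  for (k in c(-365L, 17L, 1000L)) {
    shifted <- date_agreement(model + k, gold + k)
    expect_equal(shifted$n_exact, base$n_exact)
    expect_equal(shifted$n_within_window, base$n_within_window)
    expect_equal(shifted$delays, base$delays)
  }
})

test_that("the composite validation report reproduces hand computation", {
  # 30-patient fixture with planted errors:
  #   20 gold diabetics: 18 found (16 exact dates, 1 late 30d, 1 late 200d),
  #      2 missed as possible;
  #   6 gold negatives: 5 scored none, 1 false positive diabetes;
  #   4 gold negatives scored possible.
  gold_date <- as.Date("2009-06-01")
  scores <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:30),
    total_points = c(rep(1.5, 18), rep(0.75, 2), rep(0, 5), 1.0,
                     rep(0.4, 4)),
    category = c(rep("diabetes", 18), rep("possible", 2), rep("none", 5),
                 "diabetes", rep("possible", 4)),
    diagnosis_date = c(rep(gold_date, 16), gold_date + 30, gold_date + 200,
                       rep(as.Date(NA), 2), rep(as.Date(NA), 5),
                       as.Date("2010-01-01"), rep(as.Date(NA), 4)))
  gold <- tibble::tibble(
    patient_id = scores$patient_id,
    gold_category = c(rep("diabetes", 20), rep("none", 10)),
    gold_date = c(rep(gold_date, 20), rep(as.Date(NA), 10)))
  rep <- validate_scores(scores, gold)
  # binary collapse (possible -> negative): tp 18, fn 2, fp 1, tn 9
  b <- rep$binary$possible_as_negative
  expect_equal(b$sensitivity, 18 / 20)
  expect_equal(b$specificity, 9 / 10)
  expect_equal(b$ppv, 18 / 19)
  expect_equal(b$npv, 9 / 11)
  # alternate collapse (possible -> positive): tp 20, fn 0, fp 5, tn 5
  b <- rep$binary$possible_as_positive
  expect_equal(b$sensitivity, 1)
  expect_equal(b$specificity, 5 / 10)
  # agreement table margins
  expect_equal(sum(rep$agreement_table), 30)
  expect_equal(rep$agreement_table["diabetes", "diabetes"], 18)
  expect_equal(rep$kappa_unweighted,
               oracle_kappa(rep$agreement_table, FALSE))
  expect_equal(rep$kappa_linear, oracle_kappa(rep$agreement_table, TRUE))
  # dates: 18 pairs, 16 exact, 17 within 92 days
  expect_equal(rep$date_agreement$n_pairs, 18L)
  expect_equal(rep$date_agreement$n_exact, 16L)
  expect_equal(rep$date_agreement$n_within_window, 17L)
  # perfect agreement edge: kappa 1, all metrics 1
  idx <- c(1:18, 19, 21)  # diabetes, possible and none all represented
  perfect <- validate_scores(
    scores[idx, ],
    tibble::tibble(patient_id = scores$patient_id[idx],
                   gold_category = scores$category[idx],
                   gold_date = scores$diagnosis_date[idx]))
  expect_equal(perfect$kappa_unweighted, 1)
  expect_equal(perfect$date_agreement$n_exact,
               perfect$date_agreement$n_pairs)
  # systematic disagreement: flipped labels give negative kappa
  flipped <- gold
  flipped$gold_category <- ifelse(gold$gold_category == "diabetes",
                                  "none", "diabetes")
  flipped$gold_date <- as.Date(NA)
  flipped$gold_date[flipped$gold_category == "diabetes"] <- gold_date
  expect_lt(validate_scores(scores, flipped)$kappa_unweighted, 0)
  # id misalignment is an error listing offenders
  bad <- gold; bad$patient_id[1] <- "zz"
  expect_error(validate_scores(scores, bad), "zz")
})

test_that("validation report files are written and internally consistent", {
  sim <- generate_cohort(cohort_spec(80, seed = 9))
  scores <- score_cohort(sim$cohort)
  rep <- validate_scores(scores, sim$gold,
                         claims = claims_cohort(sim$cohort))
  dir <- withr::local_tempdir()
  write_validation_report(rep, dir)
  expect_true(file.exists(file.path(dir, "validation_report.json")))
  expect_true(file.exists(file.path(dir, "dates.csv")))
  json <- jsonlite::read_json(file.path(dir, "validation_report.json"))
  expect_equal(json$n, 80)
  expect_equal(json$date_agreement$n_exact, rep$date_agreement$n_exact)
  if (!is.null(rep$roc)) {
    expect_true(file.exists(file.path(dir, "roc.csv")))
    expect_equal(json$auc, rep$roc$auc)
  }
})
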