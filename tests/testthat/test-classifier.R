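test_that("the packaged model reproduces its defining prediction values", {
  expect_equal(round(predictMotion(c(10, 2, 2, 6)), 2), 0.55)
  expect_equal(round(predictMotion(c(0, 0, 0, 1)), 3), 0.411)
  expect_equal(round(predictMotion(c(1, 0, 0, 1)), 3), 0.470)
  expect_equal(round(predictMotion(c(1, 0, 0, 0)), 3), 0.523)
  expect_equal(predictMotion(c(0, 0, 0, 0)), 1 / (1 + exp(0.1467)))
  # logit inversion recovers the linear predictor
  m <- publishedModel()
  n <- c(3, 1, 2, 4)
  y <- predictMotion(n, m)
  expect_equal(log(y / (1 - y)), -(sum(m@w * n) + m@b), tolerance = 1e-10)
})

test_that("prediction is monotone in each count with the published signs", {
  m <- publishedModel()
  base <- c(2, 2, 2, 2)
  bump <- function(i) { v <- base; v[i] <- v[i] + 1; v }
  expect_gt(predictMotion(bump(1), m), predictMotion(base, m))  # maintained
  expect_gt(predictMotion(bump(2), m), predictMotion(base, m))  # exch-partner
  expect_lt(predictMotion(bump(3), m), predictMotion(base, m))  # exch-pair
  expect_lt(predictMotion(bump(4), m), predictMotion(base, m))  # new
})

test_that("class boundaries are inclusive and no-contact precedes prediction", {
  expect_equal(as.character(classifyMotion(c(0, 0, 0, 0))$class), "no_contact")
  expect_true(is.na(classifyMotion(c(0, 0, 0, 0))$y))
  expect_equal(as.character(classifyMotion(c(0, 0, 0, 5))$class), "hinge")
  # citrate synthase's exact y ~ 0.5470 < 0.55: mixed, despite printing 0.55
  cs <- classifyMotion(c(10, 2, 2, 6))
  expect_equal(as.character(cs$class), "mixed")
  expect_lt(cs$y, 0.55)
  # boundary inclusivity probed with a model giving y exactly 0.5
  null <- new("LogisticModel", w = rep(0, 4), b = 0, converged = TRUE)
  expect_equal(as.character(classifyMotion(c(1, 1, 1, 1), null,
                                           lower = 0.5, upper = 0.6)$class),
               "hinge")
  expect_equal(as.character(classifyMotion(c(1, 1, 1, 1), null,
                                           lower = 0.4, upper = 0.5)$class),
               "shear")
  expect_equal(as.character(classifyMotion(c(1, 1, 1, 1), null)$class),
               "mixed")
  expect_error(classifyMotion(c(1, 0, 0, 0), lower = 0.6, upper = 0.5),
               "boundaries")
})

test_that("fitting recovers predictions and is invariant to duplication", {
  data <- makeTrainingSet(300, seed = 51)
  fit <- fitLogistic(data)
  twice <- TrainingSet(rbind(data@counts, data@counts),
                       c(data@label, data@label))
  fit2 <- fitLogistic(twice)
  expect_equal(fit2@w, fit@w, tolerance = 1e-8)
  expect_equal(fit2@b, fit@b, tolerance = 1e-8)
  # deterministic: same data, same coefficients
  expect_identical(fitLogistic(data)@w, fit@w)
  allSame <- TrainingSet(data@counts, rep(0L, length(data@label)))
  expect_error(fitLogistic(allSame), "both hinge and shear")
})

test_that("complete separation is detected and warned about", {
  counts <- rbind(matrix(rep(c(8, 1, 0, 0), 10), ncol = 4, byrow = TRUE),
                  matrix(rep(c(0, 0, 1, 8), 10), ncol = 4, byrow = TRUE))
  sep <- TrainingSet(counts, c(rep(1L, 10), rep(0L, 10)))
  expect_warning(m <- fitLogistic(sep), "separation")
  expect_false(m@converged)
  expect_true(all(is.finite(m@w)))
})

test_that("ROC/AUC follow threshold sweeping and the pairwise-comparison oracle", {
  sep <- TrainingSet(rbind(c(9, 0, 0, 0), c(8, 0, 0, 0),
                           c(0, 0, 0, 8), c(0, 0, 0, 9)),
                     c(1L, 1L, 0L, 0L))
  expect_equal(rocCurve(sep)$auc, 1.0)
  same <- TrainingSet(matrix(rep(c(1, 1, 1, 1), 4), ncol = 4, byrow = TRUE),
                      c(1L, 1L, 0L, 0L))
  expect_equal(rocCurve(same)$auc, 0.5)
  # hand-worked 4-item set via explicit scores
  d4 <- TrainingSet(matrix(1, 4, 4), c(1L, 1L, 0L, 0L))
  scores <- c(0.9, 0.8, 0.85, 0.7)
  r <- rocCurve(d4, model = NULL, scores = scores)
  expect_equal(r$auc, aucByPairs(scores, d4@label))
  expect_equal(r$auc, 0.75)
  expect_gte(r$aucHull, r$auc)
  # AUC is invariant under strictly monotone transforms of the scores
  r2 <- rocCurve(d4, model = NULL, scores = qlogis(scores))
  expect_equal(r2$auc, r$auc)
  expect_error(rocCurve(TrainingSet(matrix(1, 2, 4), c(0L, 0L))),
               "both hinge and shear")
})

test_that("package ROC agrees with an independent ROC implementation", {
  data <- makeTrainingSet(80, seed = 4)
  y <- predictMotion(data@counts)
  ours <- rocCurve(data)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(data@label, y, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("leave-one-out predictions come from models that never saw the item", {
  set.seed(6)
  wide <- TrainingSet(
    rbind(matrix(rep(c(12, 2, 0, 0), 8), ncol = 4, byrow = TRUE) +
            matrix(rpois(32, 1), ncol = 4),
          matrix(rep(c(0, 0, 2, 12), 8), ncol = 4, byrow = TRUE) +
            matrix(rpois(32, 1), ncol = 4)),
    c(rep(1L, 8), rep(0L, 8)))
  cv <- suppressWarnings(loocv(wide))
  expect_equal(cv$auc, 1.0)
  expect_equal(sum(is.na(cv$y)), 0L)
  # labels independent of the counts: chance-level discrimination
  set.seed(9)
  rand <- TrainingSet(matrix(rpois(400, 3), ncol = 4),
                      sample(rep(c(0L, 1L), 50)))
  cvRand <- suppressWarnings(loocv(rand))
  expect_equal(cvRand$auc, 0.5, tolerance = 0.15)
  # degenerate identical features show the known leave-one-out pessimism:
  # each held-out score is the mean of the other labels, anti-correlated
  # with the item's own label, so discrimination collapses to 0
  flat <- TrainingSet(matrix(2, 20, 4), rep(c(0L, 1L), 10))
  cvFlat <- suppressWarnings(loocv(flat))
  expect_equal(cvFlat$auc, 0)
  expect_error(loocv(TrainingSet(matrix(1, 2, 4), c(0L, 1L))),
               "at least 3")
})

test_that("precision is correct divided by predicted, undefined when empty", {
  hingeN <- matrix(rep(c(0, 0, 0, 5), 10), ncol = 4, byrow = TRUE)
  shearN <- matrix(rep(c(9, 1, 0, 0), 5), ncol = 4, byrow = TRUE)
  data <- TrainingSet(rbind(hingeN, shearN),
                      c(rep(0L, 8), rep(1L, 2), rep(1L, 5)))
  rep <- precisionReport(data)
  hi <- rep[rep$class == "hinge", ]
  sh <- rep[rep$class == "shear", ]
  expect_equal(hi$predicted, 10)
  expect_equal(hi$correct, 8)
  expect_equal(hi$precision, 0.8)
  expect_equal(sh$precision, 1.0)
  # nothing predicted shear -> undefined, not zero
  onlyHinge <- TrainingSet(hingeN, rep(0L, 10))
  rep2 <- precisionReport(onlyHinge)
  expect_true(is.na(rep2[rep2$class == "shear", "precision"]))
})

test_that("training sets and models round-trip through their file formats", {
  data <- makeTrainingSet(25, seed = 13)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTrainingSet(data, path)
  expect_identical(readLines(path)[1],
                   "id\tn_maint\tn_exchpart\tn_exchpair\tn_new\tlabel")
  back <- readTrainingSet(path)
  expect_equal(back@counts, data@counts)
  expect_equal(back@label, data@label)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tn_maint\tn_exchpart\tn_exchpair\tn_new\tlabel",
               "x1\t1\t0\t0\t0\tsliding"), bad)
  expect_error(readTrainingSet(bad), "sliding")
  mpath <- withr::local_tempfile()
  writeModel(publishedModel(), mpath)
  m <- readModel(mpath)
  expect_equal(m@w, publishedModel()@w)
  expect_equal(m@b, publishedModel()@b)
  expect_equal(readModel("published")@w, publishedModel()@w)
})
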