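## The hinge/shear predictor: a logistic model on the elemental contact-change
## counts N = (N_maint, N_exchpart, N_exchpair, N_new). The model is stored in
## the convention y(N) = 1 / (1 + exp(alpha)), alpha = w . N + b, so that
## maintained and exchanged-partner contacts (negative weights) push y towards
## 1 (shear) and exchanged-pair and new contacts (positive weights) push y
## towards 0 (hinge). Labels: 0 = predominantly hinge, 1 = predominantly
## shear.

#' The published hinge/shear logistic model
#'
#' The logistic model trained on 77 expert-labelled domain movements
#' (54 predominantly hinge, 23 predominantly shear):
#' \deqn{y(N) = 1 / (1 + e^{\alpha}),\quad
#'   \alpha = -0.2387 N_{maint} - 0.0356 N_{exchpart} + 0.4249 N_{exchpair}
#'   + 0.2122 N_{new} + 0.1467.}
#'
#' @return a \linkS4class{LogisticModel}.
#' @export
publishedModel <- function() {
  new("LogisticModel",
      w = c(nMaint = -0.2387, nExchpart = -0.0356,
            nExchpair = 0.4249, nNew = 0.2122),
      b = 0.1467, converged = TRUE)
}

# Coerce counts input (ElementalCounts, Decomposition, numeric(4) or n x 4
# matrix) to an n x 4 matrix.
countsMatrix <- function(n) {
  if (is(n, "Decomposition")) n <- n@counts
  if (is(n, "ElementalCounts")) n <- countsVector(n)
  if (is(n, "TrainingSet")) return(n@counts)
  m <- if (is.matrix(n)) n else matrix(as.numeric(n), nrow = 1L)
  if (ncol(m) != 4L) stop("expected 4 elemental counts per item")
  m
}

#' Prediction value of the hinge/shear model
#'
#' Evaluates y(N) = 1 / (1 + exp(w . N + b)). Values towards 0 indicate a
#' hinge (interface-creating) movement, values towards 1 a shear
#' (interface-preserving) movement.
#'
#' @param n an \linkS4class{ElementalCounts}, \linkS4class{Decomposition},
#'   numeric(4), or an n x 4 matrix of counts.
#' @param model a \linkS4class{LogisticModel}; defaults to the published one.
#' @return numeric vector of prediction values in (0, 1).
#' @export
predictMotion <- function(n, model = publishedModel()) {
  m <- countsMatrix(n)
  alpha <- as.numeric(m %*% model@w + model@b)
  1 / (1 + exp(alpha))
}

#' Classify a domain movement from its elemental counts
#'
#' A movement with no interdomain contacts in either conformation (all
#' counts zero) is classed \code{no_contact} without evaluating the model.
#' Otherwise the full-precision prediction value is compared against the
#' class boundaries: hinge for y <= lower, shear for y >= upper, mixed in
#' between.
#'
#' @param n counts, as in \code{\link{predictMotion}}.
#' @param model a \linkS4class{LogisticModel}.
#' @param lower,upper class boundaries, defaults 0.45 and 0.55.
#' @return data.frame with columns \code{y} (NA for no_contact) and
#'   \code{class} (factor: no_contact/hinge/mixed/shear), one row per item.
#' @export
classifyMotion <- function(n, model = publishedModel(), lower = 0.45,
                           upper = 0.55) {
  if (!(is.numeric(lower) && is.numeric(upper) && length(lower) == 1L &&
        length(upper) == 1L && lower > 0 && upper < 1 && lower <= upper))
    stop("class boundaries must satisfy 0 < lower <= upper < 1")
  m <- countsMatrix(n)
  y <- predictMotion(m, model)
  cls <- ifelse(y <= lower, "hinge", ifelse(y >= upper, "shear", "mixed"))
  none <- rowSums(m) == 0
  cls[none] <- "no_contact"
  y[none] <- NA_real_
  data.frame(y = y,
             class = factor(cls, levels = c("no_contact", "hinge", "mixed",
                                            "shear")))
}

#' Construct a TrainingSet
#'
#' @param counts n x 4 matrix (or data.frame) of elemental counts.
#' @param label labels: 0/1 integers or "hinge"/"shear" strings.
#' @param id optional identifiers (default "item<i>").
#' @return a validated \linkS4class{TrainingSet}.
#' @export
TrainingSet <- function(counts, label, id = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  colnames(counts) <- c("nMaint", "nExchpart", "nExchpair", "nNew")
  if (is.character(label) || is.factor(label)) {
    label <- as.character(label)
    bad <- !label %in% c("hinge", "shear")
    if (any(bad)) stop("unknown label value: '", label[bad][1], "'")
    label <- ifelse(label == "shear", 1L, 0L)
  }
  if (is.null(id)) id <- paste0("item", seq_len(nrow(counts)))
  new("TrainingSet", id = as.character(id), counts = counts,
      label = as.integer(label))
}

#' Cross-entropy of a model on a training set
#'
#' E = -1/2 * sum[t log y + (1 - t) log(1 - y)], the training criterion the
#' fit minimizes (the 1/2 factor does not affect the optimum).
#'
#' @param model a \linkS4class{LogisticModel}.
#' @param data a \linkS4class{TrainingSet}.
#' @return numeric scalar.
#' @export
crossEntropy <- function(model, data) {
  y <- predictMotion(data@counts, model)
  t <- data@label
  -0.5 * sum(t * log(y) + (1 - t) * log(1 - y))
}

#' Fit the hinge/shear logistic model
#'
#' Minimizes the cross-entropy criterion by iteratively reweighted least
#' squares (Newton's method on the convex objective), which is deterministic
#' for a given data set. Complete separation is detected from divergence of
#' the linear predictor and reported as a warning; the returned model then
#' carries \code{converged = FALSE}.
#'
#' @param data a \linkS4class{TrainingSet} with both labels present.
#' @param maxIter iteration cap (default 200).
#' @param tol convergence tolerance on the gradient norm (default 1e-8).
#' @return a \linkS4class{LogisticModel} in the published sign convention.
#' @export
fitLogistic <- function(data, maxIter = 200L, tol = 1e-8) {
  t <- data@label
  if (length(unique(t)) < 2L)
    stop("training data must contain both hinge and shear labels")
  x <- data@counts
  storage.mode(x) <- "double"
  # glm's IRLS solves the same convex problem Newton from zero would reach;
  # note glm models P(t = 1) = 1/(1+exp(-eta)) while the package stores
  # y = 1/(1+exp(alpha)), so alpha = -eta
  sawSaturation <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, x), t, family = stats::binomial(),
                   control = stats::glm.control(epsilon = tol,
                                                maxit = maxIter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sawSaturation <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients
  # aliased coefficients (collinear count columns) are fixed at zero
  beta[!is.finite(beta)] <- 0
  yhat <- fit$fitted.values
  sep <- isTRUE(sawSaturation || !fit$converged || any(abs(beta) > 1e3) ||
                  (all(yhat[t == 1L] > 1 - 1e-6) &&
                     all(yhat[t == 0L] < 1e-6)))
  if (sep)
    warning("complete (or quasi-complete) separation detected; ",
            "coefficients capped at the iteration limit", call. = FALSE)
  w <- -beta[-1L]
  names(w) <- c("nMaint", "nExchpart", "nExchpair", "nNew")
  new("LogisticModel", w = w, b = as.numeric(-beta[1L]),
      converged = !sep)
}

#' ROC curve and AUC for a model on labelled data
#'
#' Sweeps the decision threshold over all distinct prediction values (an
#' item is predicted shear when y >= threshold), giving one
#' (false-positive rate, true-positive rate) point per threshold plus the
#' (0,0) and (1,1) endpoints. A true positive is a shear correctly predicted
#' shear; a false positive is a hinge predicted shear. The area under the
#' curve is computed by the trapezoidal rule; the area under the curve's
#' upper convex hull is also reported.
#'
#' @param data a \linkS4class{TrainingSet}.
#' @param model a \linkS4class{LogisticModel}, or NULL when \code{scores} is
#'   given.
#' @param scores optional numeric vector of scores overriding the model's
#'   predictions (used for cross-validated ROC).
#' @return list with \code{points} (data.frame fpr, tpr, threshold),
#'   \code{auc}, and \code{aucHull}.
#' @export
rocCurve <- function(data, model = publishedModel(), scores = NULL) {
  t <- data@label
  if (length(unique(t)) < 2L)
    stop("ROC requires both hinge and shear labels")
  y <- if (is.null(scores)) predictMotion(data@counts, model) else scores
  thr <- sort(unique(y), decreasing = TRUE)
  nPos <- sum(t == 1L); nNeg <- sum(t == 0L)
  tpr <- vapply(thr, function(s) sum(y >= s & t == 1L) / nPos, 0)
  fpr <- vapply(thr, function(s) sum(y >= s & t == 0L) / nNeg, 0)
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, thr))
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1)
    pts <- rbind(pts, data.frame(fpr = 1, tpr = 1, threshold = -Inf))
  o <- order(pts$fpr, pts$tpr)
  pts <- pts[o, , drop = FALSE]
  rownames(pts) <- NULL
  trap <- function(x, yv) sum(diff(x) * (utils::head(yv, -1) + utils::tail(yv, -1)) / 2)
  auc <- trap(pts$fpr, pts$tpr)
  # upper convex hull of the ROC points
  hullIdx <- grDevices::chull(c(pts$fpr, 1), c(pts$tpr, 0))
  hx <- c(pts$fpr, 1)[hullIdx]; hy <- c(pts$tpr, 0)[hullIdx]
  keep <- order(hx, hy)
  hx <- hx[keep]; hy <- hy[keep]
  upper <- !(hx == 1 & hy == 0)
  aucHull <- trap(hx[upper], hy[upper])
  list(points = pts, auc = auc, aucHull = aucHull)
}

#' Leave-one-out cross-validation of the logistic fit
#'
#' Each item's prediction value comes from a model fitted on all other
#' items; folds whose training part loses a label class are skipped with a
#' warning. Aggregate ROC/AUC are computed over the held-out predictions.
#'
#' @param data a \linkS4class{TrainingSet} with at least 3 items and both
#'   labels.
#' @param maxIter,tol passed to \code{\link{fitLogistic}}.
#' @return list with \code{y} (held-out predictions, NA for skipped folds),
#'   \code{roc} (as \code{\link{rocCurve}}), and \code{auc}.
#' @export
loocv <- function(data, maxIter = 200L, tol = 1e-8) {
  n <- length(data@id)
  if (n < 3L) stop("leave-one-out cross-validation needs at least 3 items")
  if (length(unique(data@label)) < 2L)
    stop("training data must contain both hinge and shear labels")
  yOut <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rest <- new("TrainingSet", id = data@id[-i],
                counts = data@counts[-i, , drop = FALSE],
                label = data@label[-i])
    if (length(unique(rest@label)) < 2L) {
      warning("fold ", i, " skipped: training part single-class")
      next
    }
    m <- suppressWarnings(fitLogistic(rest, maxIter, tol))
    yOut[i] <- predictMotion(data@counts[i, , drop = FALSE], m)
  }
  keep <- !is.na(yOut)
  sub <- new("TrainingSet", id = data@id[keep],
             counts = data@counts[keep, , drop = FALSE],
             label = data@label[keep])
  roc <- rocCurve(sub, model = NULL, scores = yOut[keep])
  list(y = yOut, roc = roc, auc = roc$auc)
}

#' Per-class precision of hinge/shear predictions
#'
#' Precision of a class is the proportion of cases correctly predicted to be
#' in that class among all cases predicted to be in it. Mixed and no-contact
#' predictions enter neither tally. A class with no predicted cases gets
#' precision NA (undefined), not 0.
#'
#' @param data a labelled \linkS4class{TrainingSet}.
#' @param model a \linkS4class{LogisticModel}.
#' @param lower,upper class boundaries (defaults 0.45 / 0.55).
#' @return data.frame with columns class, predicted, correct,
#'   precision (proportion) and precisionPercent.
#' @export
precisionReport <- function(data, model = publishedModel(), lower = 0.45,
                            upper = 0.55) {
  cls <- classifyMotion(data@counts, model, lower, upper)$class
  trueCls <- ifelse(data@label == 1L, "shear", "hinge")
  row <- function(k) {
    pred <- sum(cls == k)
    corr <- sum(cls == k & trueCls == k)
    data.frame(class = k, predicted = pred, correct = corr,
               precision = if (pred > 0) corr / pred else NA_real_,
               precisionPercent = if (pred > 0) 100 * corr / pred
                                  else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(row("hinge"), row("shear"))
  rownames(out) <- NULL
  out
}

#' Read a training set TSV
#'
#' Expects a header line
#' \code{id n_maint n_exchpart n_exchpair n_new label} (tab-separated) with
#' label values \code{hinge} or \code{shear}.
#'
#' @param path input path.
#' @return a \linkS4class{TrainingSet}.
#' @export
readTrainingSet <- function(path) {
  if (!file.exists(path)) stop("cannot read training set: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "n_maint", "n_exchpart", "n_exchpair", "n_new", "label")
  if (!all(need %in% names(df)))
    stop("training TSV must have columns: ", paste(need, collapse = ", "))
  bad <- !df$label %in% c("hinge", "shear")
  if (any(bad))
    stop("unknown label value '", df$label[bad][1], "' at line ",
         which(bad)[1] + 1L)
  TrainingSet(df[, c("n_maint", "n_exchpart", "n_exchpair", "n_new")],
              df$label, df$id)
}

#' Write a training set TSV
#'
#' @param data a \linkS4class{TrainingSet}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeTrainingSet <- function(data, path) {
  df <- data.frame(id = data@id,
                   n_maint = data@counts[, 1L],
                   n_exchpart = data@counts[, 2L],
                   n_exchpair = data@counts[, 3L],
                   n_new = data@counts[, 4L],
                   label = ifelse(data@label == 1L, "shear", "hinge"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a model file
#'
#' Key/value text with a format-version line.
#'
#' @param model a \linkS4class{LogisticModel}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeModel <- function(model, path) {
  writeLines(c("format_version 1",
               paste("w_maint", format(model@w[1L], digits = 17)),
               paste("w_exchpart", format(model@w[2L], digits = 17)),
               paste("w_exchpair", format(model@w[3L], digits = 17)),
               paste("w_new", format(model@w[4L], digits = 17)),
               paste("b", format(model@b, digits = 17))), path)
  invisible(path)
}

#' Read a model file
#'
#' @param path input path, or the string "published" for the packaged model.
#' @return a \linkS4class{LogisticModel}.
#' @export
readModel <- function(path) {
  if (identical(path, "published")) return(publishedModel())
  if (!file.exists(path)) stop("cannot read model file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  kv <- strsplit(lines, "[ \t]+")
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  need <- c("w_maint", "w_exchpart", "w_exchpair", "w_new", "b")
  miss <- setdiff(need, names(vals))
  if (length(miss)) stop("model file missing key(s): ", toString(miss))
  new("LogisticModel",
      w = c(nMaint = as.numeric(vals["w_maint"]),
            nExchpart = as.numeric(vals["w_exchpart"]),
            nExchpair = as.numeric(vals["w_exchpair"]),
            nNew = as.numeric(vals["w_new"])),
      b = as.numeric(vals["b"]), converged = TRUE)
}
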