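#' Affine two-class discriminant model
#'
#' A linear decision function over dye-amount (or RGB) features,
#' `D(x) = w . x + b`. The side a sample falls on decides its class: a
#' sample is assigned `positive_label` when `D >= 0` (ties included) and
#' the other class when `D < 0`. The orientation is an explicit model
#' field rather than a fixed convention because a fitted `w` and a flipped
#' `-w` describe the same boundary; see [preset_discriminants()] for why
#' this matters for the bundled models.
#'
#' @param feature_names ordered character vector of feature labels (dye
#'   names such as `c("EY", "OG")`, or `c("R", "G", "B")`).
#' @param weights numeric vector `w`, same length as `feature_names`.
#' @param bias scalar intercept `b`.
#' @param positive_label class assigned where `D >= 0`; `"LEGH"` (default,
#'   the convention of [fit_fisher()]) or `"EC"`.
#' @param name optional model label used in printing.
#' @return Object of class `discriminant_model`.
#' @seealso [fit_fisher()], [preset_discriminants()], [classify()]
#' @export
discriminant_model <- function(feature_names, weights, bias,
                               positive_label = "LEGH", name = NULL) {
  feature_names <- as.character(feature_names)
  weights <- as.numeric(weights)
  if (length(weights) != length(feature_names))
    stop("weights and feature_names must have the same length", call. = FALSE)
  if (length(bias) != 1L || !is.finite(bias))
    stop("bias must be a finite scalar", call. = FALSE)
  if (anyNA(weights) || any(!is.finite(weights)))
    stop("weights must be finite", call. = FALSE)
  if (length(positive_label) != 1L || !positive_label %in% c("EC", "LEGH"))
    stop('positive_label must be "EC" or "LEGH"', call. = FALSE)
  structure(list(feature_names = feature_names, weights = weights,
                 bias = as.numeric(bias), positive_label = positive_label,
                 name = name),
            class = "discriminant_model")
}

negative_label <- function(model)
  setdiff(c("EC", "LEGH"), model$positive_label)

#' @export
print.discriminant_model <- function(x, digits = 4, ...) {
  terms <- paste(sprintf("%+.*g %s", digits, x$weights, x$feature_names),
                 collapse = " ")
  cat(sprintf("discriminant_model%s: D = %s %+.*g\n",
              if (is.null(x$name)) "" else paste0(" [", x$name, "]"),
              terms, digits, x$bias))
  cat(sprintf("  D >= 0 -> %s, D < 0 -> %s\n", x$positive_label,
              negative_label(x)))
  invisible(x)
}

#' @export
coef.discriminant_model <- function(object, ...) {
  c(stats::setNames(object$weights, object$feature_names),
    "(bias)" = object$bias)
}

# decision values D(x) for a feature matrix (columns matched by name when
# present, otherwise by position)
decision_values <- function(model, x) {
  x <- feature_matrix(model, x)
  drop(x %*% model$weights) + model$bias
}

feature_matrix <- function(model, x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  p <- length(model$feature_names)
  if (!is.null(colnames(x)) && all(model$feature_names %in% colnames(x))) {
    x <- x[, model$feature_names, drop = FALSE]
  } else if (ncol(x) != p) {
    stop("feature matrix has ", ncol(x), " columns; model expects ", p,
         " (", paste(model$feature_names, collapse = ", "), ")",
         call. = FALSE)
  }
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("features contain NA", call. = FALSE)
  x
}

#' Classify feature vectors with a discriminant model
#'
#' Applies the decision rule `D(x) = w . x + b`; `D >= 0` (including exact
#' ties) yields the model's `positive_label`, `D < 0` the other class.
#'
#' @param model a [discriminant_model].
#' @param features numeric vector (one sample), matrix or data frame (one
#'   sample per row). Columns are matched to the model's features by name
#'   when named, otherwise by position.
#' @return Character vector of `"EC"` / `"LEGH"` labels.
#' @export
classify <- function(model, features) {
  stopifnot(inherits(model, "discriminant_model"))
  ifelse(decision_values(model, features) >= 0, model$positive_label,
         negative_label(model))
}

#' @export
predict.discriminant_model <- function(object, newdata,
                                       type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (type == "score") decision_values(object, newdata)
  else classify(object, newdata)
}

#' Fit a two-class Fisher linear discriminant
#'
#' Classical Fisher discriminant between EC and LEGH feature samples:
#' `w` is proportional to `S_W^{-1} (mu_LEGH - mu_EC)` with `S_W` the
#' pooled within-class scatter matrix, oriented so that the LEGH class lies
#' on the nonnegative side, with the equal-prior midpoint intercept
#' `b = -w . (mu_EC + mu_LEGH) / 2`.
#'
#' A singular scatter matrix (e.g. constant features) falls back to a
#' ridge-regularized solve with a warning.
#'
#' @param samples_ec,samples_legh numeric matrices or data frames, one
#'   sample per row, at least 2 rows each, same columns.
#' @param feature_names feature labels; defaults to the column names of the
#'   samples.
#' @param ridge relative ridge added to `S_W` when it is singular.
#' @return A [discriminant_model].
#' @examples
#' m <- fit_fisher(matrix(c(0, 0)), matrix(c(2, 2)), feature_names = "x")
#' predict(m, matrix(c(0.5, 1.5), ncol = 1))  # "EC" "LEGH"
#' @export
fit_fisher <- function(samples_ec, samples_legh, feature_names = NULL,
                       ridge = 1e-8) {
  xe <- as.matrix(samples_ec); xl <- as.matrix(samples_legh)
  if (is.null(dim(samples_ec))) xe <- matrix(samples_ec, ncol = 1)
  if (is.null(dim(samples_legh))) xl <- matrix(samples_legh, ncol = 1)
  storage.mode(xe) <- storage.mode(xl) <- "double"
  if (nrow(xe) < 2L || nrow(xl) < 2L)
    stop("need at least 2 samples per class", call. = FALSE)
  if (ncol(xe) != ncol(xl))
    stop("EC and LEGH samples must have the same features", call. = FALSE)
  if (is.null(feature_names))
    feature_names <- colnames(xe) %||% paste0("x", seq_len(ncol(xe)))
  mu_e <- colMeans(xe); mu_l <- colMeans(xl)
  sw <- crossprod(sweep(xe, 2L, mu_e)) + crossprod(sweep(xl, 2L, mu_l))
  w <- tryCatch(solve(sw, mu_l - mu_e), error = function(e) {
    warning("within-class scatter is singular; using a ridge-regularized solve")
    lam <- ridge * max(mean(diag(sw)), .Machine$double.eps)
    solve(sw + diag(lam, ncol(sw)), mu_l - mu_e)
  })
  # orient toward LEGH-positive (guards against a numerically flipped solve)
  if (sum(w * (mu_l - mu_e)) < 0) w <- -w
  bias <- -sum(w * (mu_e + mu_l)) / 2
  discriminant_model(feature_names, w, bias, name = "fisher")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundled reference discriminants
#'
#' The three fixed linear discriminants shipped with the package, trained
#' on clinical EC/LEGH mucin patch samples in the study that established
#' this method and stored in `presets/discriminants.json`:
#'
#' * `"2D"`: `D = 15.01 EY - 43.55 OG + 1.454` over normalized dye amounts;
#' * `"3D"`: `D = 41.52 EY - 55.34 LG - 46.79 OG + 3.263`;
#' * `"sRGB"`: `D = 83.41 R - 368.9 G + 365.8 B - 74.22` over mean
#'   gamma-encoded sRGB in `[0, 1]`.
#'
#' @section Orientation:
#' The published description of these functions states "`D >= 0` is LEGH",
#' but that reading contradicts both the accompanying evaluation tables and
#' the dye chemistry: the weight vectors point toward the eosin-Y-rich /
#' orange-G-free side (e.g. any OG-free EC sample has
#' `D = 15.01 EY + 1.454 > 0`), yet the published confusion tables report
#' essentially all EC samples predicted EC. The positive side of the
#' printed coefficients is therefore the EC class, and the presets default
#' to `positive_label = "EC"` so that [classify()] reproduces the published
#' classification behavior (LEGH mucin has more OG and less EY). Pass
#' `positive_label = "LEGH"` to obtain the literal printed decision rule
#' instead. Models fitted with [fit_fisher()] are unaffected: their
#' orientation is set from the training data.
#'
#' @param positive_label class assigned where `D >= 0` for all three
#'   models: `"EC"` (default, matches the published evaluation) or
#'   `"LEGH"` (the printed rule verbatim).
#' @return Named list of [discriminant_model] objects.
#' @export
preset_discriminants <- function(positive_label = c("EC", "LEGH")) {
  positive_label <- match.arg(positive_label)
  path <- system.file("presets", "discriminants.json", package = "papunmix",
                      mustWork = TRUE)
  models <- read_discriminants(path)
  lapply(models, function(m) {
    m$positive_label <- positive_label
    m
  })
}

#' Classification quality report
#'
#' Builds the 2 x 2 confusion matrix (rows = true EC/LEGH, columns =
#' predicted EC/LEGH) and the four standard quality measures. Precision,
#' recall and F depend on which class is treated as positive, so
#' `positive_class` is a required, explicit argument. A metric whose
#' denominator is zero is reported as 0 and flagged in `degenerate`.
#'
#' @param truth,predicted equal-length character vectors with values in
#'   `{"EC", "LEGH"}`.
#' @param positive_class `"LEGH"` or `"EC"`.
#' @return Object of class `eval_report`: list with `confusion`,
#'   `accuracy`, `precision`, `recall`, `f_value`, `positive_class`,
#'   `degenerate`.
#' @examples
#' rep <- evaluate_classification(c("EC", "EC", "LEGH"), c("EC", "LEGH", "LEGH"),
#'                                positive_class = "LEGH")
#' rep$accuracy
#' @export
evaluate_classification <- function(truth, predicted, positive_class) {
  lv <- c("EC", "LEGH")
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have the same length", call. = FALSE)
  if (length(truth) == 0L) stop("no samples", call. = FALSE)
  bad <- setdiff(unique(c(truth, predicted)), lv)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (length(positive_class) != 1L || !positive_class %in% lv)
    stop('positive_class must be "EC" or "LEGH"', call. = FALSE)
  confusion <- table(factor(truth, lv), factor(predicted, lv))
  confusion <- matrix(as.integer(confusion), 2, 2,
                      dimnames = list(true = lv, predicted = lv))
  eval_report_from_confusion(confusion, positive_class)
}

#' @rdname evaluate_classification
#' @param confusion 2 x 2 integer matrix, rows = true `c("EC","LEGH")`,
#'   columns = predicted, for computing the report directly from printed
#'   confusion tables.
#' @export
eval_report_from_confusion <- function(confusion, positive_class) {
  lv <- c("EC", "LEGH")
  confusion <- as.matrix(confusion)
  if (!identical(dim(confusion), c(2L, 2L)) &&
      !identical(dim(confusion), c(2L, 2L) * 1))
    stop("confusion must be a 2 x 2 matrix", call. = FALSE)
  if (any(confusion < 0)) stop("negative counts", call. = FALSE)
  if (length(positive_class) != 1L || !positive_class %in% lv)
    stop('positive_class must be "EC" or "LEGH"', call. = FALSE)
  dimnames(confusion) <- list(true = lv, predicted = lv)
  pos <- match(positive_class, lv)
  tp <- confusion[pos, pos]
  fp <- confusion[3 - pos, pos]
  fn <- confusion[pos, 3 - pos]
  total <- sum(confusion)
  degenerate <- character()
  safe_div <- function(num, den, what) {
    if (den == 0) { degenerate <<- c(degenerate, what); 0 } else num / den
  }
  accuracy <- sum(diag(confusion)) / total
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f_value <- if (precision + recall == 0) {
    degenerate <- c(degenerate, "f_value"); 0
  } else 2 * precision * recall / (precision + recall)
  structure(list(confusion = confusion, accuracy = accuracy,
                 precision = precision, recall = recall, f_value = f_value,
                 positive_class = positive_class, degenerate = degenerate),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report (positive class:", x$positive_class, ")\n")
  print(x$confusion)
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  F %.4f\n",
              x$accuracy, x$precision, x$recall, x$f_value))
  if (length(x$degenerate))
    cat("zero-denominator metrics reported as 0:",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}
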