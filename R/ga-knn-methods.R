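#' Classify new samples with a fitted GA-kNN model
#'
#' Blinded application of the classifier: the model's selected peaks are
#' matched against the new peak matrix by m/z (within relative tolerance),
#' features are standardized with the training-set parameters, and each
#' sample gets the majority label of its k nearest training samples. Group
#' labels in `newdata`, if any, are never read.
#'
#' @param object a fitted [ga_knn()] model.
#' @param newdata a [peak_matrix()] or numeric matrix carrying the model's
#'   selected peaks.
#' @param ... unused.
#' @return a character vector of predicted labels
#'   (`"response"`/`"progression"`), one per sample.
#' @export
predict.ga_knn <- function(object, newdata, ...) {
  q <- extract_model_features(object, newdata)
  if (nrow(q) == 0L) return(character(0))
  tr <- apply_standardization(object$training_areas, object$standardization)
  knn_classify(tr, object$training_labels,
               apply_standardization(q, object$standardization), object$k)
}

#' @export
print.ga_knn <- function(x, ...) {
  cat("GA-selected kNN curative-efficacy classifier\n")
  cat(sprintf("  peaks (%d): %s\n", length(x$selected_mz),
              paste(sprintf("%.2f", x$selected_mz), collapse = ", ")))
  cat(sprintf("  k = %d neighbors, %d training samples\n",
              x$k, nrow(x$training_areas)))
  cat(sprintf("  cross-validation rate %.2f%%, recognition rate %.2f%%\n",
              x$cv_report$cross_validation_rate, x$cv_report$recognition_rate))
  invisible(x)
}

#' @export
summary.ga_knn <- function(object, ...) {
  cat("GA-selected kNN curative-efficacy classifier\n\n")
  tab <- table(object$training_labels)
  cat(sprintf("Training cohort: %d response, %d progression\n",
              tab["response"], tab["progression"]))
  cat(sprintf("Selected panel (%d peaks), k = %d:\n",
              length(object$selected_mz), object$k))
  mu <- object$standardization$mean
  sg <- object$standardization$sd
  df <- data.frame(mz = sprintf("%.2f", object$selected_mz),
                   train_mean = round(mu, 2), train_sd = round(sg, 2))
  print(df, row.names = FALSE)
  cat(sprintf("\nCross-validation rate: %.2f%% (%d x %.0f%% stratified holdout)\n",
              object$cv_report$cross_validation_rate,
              object$config$holdout_iterations,
              100 * object$config$holdout_fraction))
  cat(sprintf("Recognition rate:      %.2f%% (resubstitution)\n",
              object$cv_report$recognition_rate))
  cat(sprintf("GA: %d generations, population %d, final best fitness %.2f%%\n",
              nrow(object$history), object$config$population_size,
              utils::tail(object$history$best, 1)))
  invisible(object)
}

#' @export
coef.ga_knn <- function(object, ...) {
  stats::setNames(rep(1, length(object$selected_mz)),
                  sprintf("%.2f", object$selected_mz))
}

#' Plot the GA fitness trace
#'
#' Best and mean population fitness (cross-validation rate, percent) per
#' generation; the elitist best line is non-decreasing by construction.
#'
#' @param x a fitted [ga_knn()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ga_knn <- function(x, ...) {
  h <- x$history
  graphics::plot(h$generation, h$best, type = "s", ylim = range(h$mean, h$best),
                 xlab = "generation", ylab = "cross-validation rate (%)",
                 main = "GA fitness trace", ...)
  graphics::lines(h$generation, h$mean, lty = 2, col = "grey40")
  graphics::legend("bottomright", c("best", "population mean"),
                   lty = c(1, 2), col = c("black", "grey40"), bty = "n")
  invisible(x)
}
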