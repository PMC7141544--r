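#' Per-class confusion counts between two masks
#'
#' One-vs-rest pixel tallies for every class: true positives, false
#' positives, false negatives, true negatives. For each class the four
#' counts sum to the total pixel count.
#'
#' @param pred,truth Integer `[H, W]` class masks of equal shape with
#'   labels in `0:(num_classes - 1)`.
#' @param num_classes Number of classes (default 4).
#' @return A `confusion_counts` data frame with columns `class`, `TP`,
#'   `FP`, `FN`, `TN`.
#' @export
confusion <- function(pred, truth, num_classes = 4L) {
  pred <- as_mask(pred); truth <- as_mask(truth)
  if (!identical(dim(pred), dim(truth))) {
    stopf("pred (%s) and truth (%s) shapes differ",
          paste(dim(pred), collapse = "x"), paste(dim(truth), collapse = "x"))
  }
  labs <- 0:(num_classes - 1L)
  bad <- setdiff(unique(c(pred, truth)), labs)
  if (length(bad)) stopf("mask labels %s exceed num_classes = %d",
                         paste(bad, collapse = ", "), num_classes)
  total <- length(truth)
  tab <- table(factor(pred, levels = labs), factor(truth, levels = labs))
  TP <- diag(tab)
  FP <- rowSums(tab) - TP   # predicted c, truth other
  FN <- colSums(tab) - TP
  structure(data.frame(class = labs, TP = as.integer(TP),
                       FP = as.integer(FP), FN = as.integer(FN),
                       TN = as.integer(total - TP - FP - FN),
                       row.names = NULL),
            class = c("confusion_counts", "data.frame"))
}

#' Accuracy, Jaccard and Dice from confusion counts
#'
#' Per class: `Acc = (TP + TN) / (TP + FP + FN + TN)`,
#' `J = TP / (TP + FP + FN)`, `D = 2 TP / (2 TP + FP + FN)`, so that
#' `D = 2 J / (1 + J)` identically. A class absent from both masks
#' (`TP = FP = FN = 0`) scores `J = D = 1`: a correctly absent
#' structure is a perfect prediction rather than a 0/0.
#'
#' @param counts A [confusion()] result.
#' @param mean_over Which classes enter the summary means:
#'   `"foreground"` (default, classes > 0) or `"all"`.
#' @return A `seg_metrics` list: `per_class` data frame (`class`,
#'   `Acc`, `J`, `D`) plus `mean_acc`, `mean_j`, `mean_d`.
#' @export
score <- function(counts, mean_over = c("foreground", "all")) {
  mean_over <- match.arg(mean_over)
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN; TN <- counts$TN
  total <- TP + FP + FN + TN
  acc <- (TP + TN) / total
  denom <- TP + FP + FN
  J <- ifelse(denom == 0, 1, TP / denom)
  D <- ifelse(denom == 0, 1, 2 * TP / (2 * TP + FP + FN))
  per <- data.frame(class = counts$class, Acc = acc, J = J, D = D)
  sel <- if (mean_over == "foreground") per$class > 0 else rep(TRUE, nrow(per))
  structure(list(per_class = per,
                 mean_acc = mean(per$Acc[sel]),
                 mean_j = mean(per$J[sel]),
                 mean_d = mean(per$D[sel]),
                 mean_over = mean_over),
            class = "seg_metrics")
}

#' Average segmentation metrics over two folds
#'
#' Arithmetic mean of every per-class and summary field, as used to
#' report two-fold cross-validation results.
#'
#' @param metrics_fold1,metrics_fold2 `seg_metrics` with identical
#'   class structure.
#' @return A `seg_metrics` object of fold-averaged values.
#' @export
twofold_average <- function(metrics_fold1, metrics_fold2) {
  m1 <- metrics_fold1; m2 <- metrics_fold2
  if (!identical(m1$per_class$class, m2$per_class$class)) {
    stopf("fold metrics have different class structure")
  }
  per <- m1$per_class
  for (col in c("Acc", "J", "D")) {
    per[[col]] <- (m1$per_class[[col]] + m2$per_class[[col]]) / 2
  }
  structure(list(per_class = per,
                 mean_acc = (m1$mean_acc + m2$mean_acc) / 2,
                 mean_j = (m1$mean_j + m2$mean_j) / 2,
                 mean_d = (m1$mean_d + m2$mean_d) / 2,
                 mean_over = m1$mean_over),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, digits = 4, ...) {
  cat("segmentation metrics (per class):\n")
  print(format(x$per_class, digits = digits), row.names = FALSE)
  cat(sprintf("means over %s classes: Acc %.4f  J %.4f  D %.4f\n",
              x$mean_over, x$mean_acc, x$mean_j, x$mean_d))
  invisible(x)
}

#' Write a metrics report as CSV
#'
#' Per-class rows keyed by anatomical class name plus a summary row.
#'
#' @param metrics A `seg_metrics` object.
#' @param path Output CSV path.
#' @param class_names Names for the class indices.
#' @return Invisibly, the written data frame.
#' @export
write_metrics_csv <- function(metrics, path,
                              class_names = c("background", "lungs",
                                              "heart", "clavicles")) {
  per <- metrics$per_class
  per$name <- class_names[per$class + 1L]
  out <- rbind(per[, c("name", "Acc", "J", "D")],
               data.frame(name = paste0("mean_", metrics$mean_over),
                          Acc = metrics$mean_acc, J = metrics$mean_j,
                          D = metrics$mean_d))
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
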