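#' Error matrix from predicted labels and reference points
#'
#' Cross-tabulates predicted against reference class at the reference point
#' locations. Orientation: rows are the predicted class, columns the
#' reference class, so row totals drive user's accuracy and column totals
#' producer's accuracy. Reference points falling on nodata predicted pixels
#' are skipped with their count reported in a warning.
#'
#' @param predicted A [label_map].
#' @param reference Data frame with columns `row`, `col`, `label` (reference
#'   class name; must be one of the map's classes).
#'
#' @return A K x K integer matrix of class `error_matrix` with
#'   `dimnames = list(predicted, reference)`.
#' @export
build_error_matrix <- function(predicted, reference) {
  stopifnot(inherits(predicted, "label_map"))
  reference <- as.data.frame(reference)
  if (nrow(reference) == 0L)
    stop("reference point set is empty", call. = FALSE)
  if (!all(c("row", "col", "label") %in% names(reference)))
    stop("reference must have columns row, col, label", call. = FALSE)
  cls <- predicted$class_names
  ref_lab <- as.character(reference$label)
  if (!all(ref_lab %in% cls))
    stop("unknown reference class(es): ",
         paste(setdiff(ref_lab, cls), collapse = ", "), call. = FALSE)
  pred_idx <- predicted$labels[cbind(reference$row, reference$col)]
  ok <- !is.na(pred_idx)
  if (any(!ok))
    warning(sum(!ok), " reference point(s) on nodata pixels skipped",
            call. = FALSE)
  m <- table(factor(cls[pred_idx[ok]], levels = cls),
             factor(ref_lab[ok], levels = cls))
  m <- unclass(m)
  dimnames(m) <- list(predicted = cls, reference = cls)
  structure(m, class = c("error_matrix", "matrix"))
}

#' Error matrix from counts
#'
#' Wraps a K x K count matrix (rows = predicted, columns = reference) as an
#' `error_matrix`, e.g. for hand-tallied tables.
#'
#' @param counts Square matrix of non-negative integer counts.
#' @param class_names Optional class names (default: existing dimnames or
#'   `"class1"..."classK"`).
#' @return An `error_matrix`.
#' @export
error_matrix <- function(counts, class_names = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop("error matrix must be square", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0) stop("error matrix has zero total", call. = FALSE)
  if (is.null(class_names))
    class_names <- if (!is.null(rownames(counts))) rownames(counts)
                   else paste0("class", seq_len(nrow(counts)))
  dimnames(counts) <- list(predicted = class_names, reference = class_names)
  structure(counts, class = c("error_matrix", "matrix"))
}

#' Accuracy statistics from an error matrix
#'
#' `producers_accuracy()` is the percentage of each reference class
#' correctly classified (100% minus omission error; diagonal over column
#' total). `users_accuracy()` is the percentage of each predicted class that
#' matches the reference (100% minus commission error; diagonal over row
#' total). `overall_accuracy()` is 100 x trace / total.
#' `kappa_coefficient()` is Cohen's chance-corrected agreement
#' `(po - pe) / (1 - pe)` with `po = trace/total` and
#' `pe = sum(row_k * col_k) / total^2`, ranging from -1 to +1.
#'
#' Classes absent from the relevant margin yield `NA`; a degenerate matrix
#' with expected agreement `pe = 1` yields `NA` Kappa.
#'
#' @param m An [error_matrix].
#' @return `producers_accuracy()` and `users_accuracy()`: named numeric
#'   vector of percentages; `overall_accuracy()`: a percentage;
#'   `kappa_coefficient()`: a dimensionless coefficient.
#' @examples
#' m <- error_matrix(rbind(c(40, 10), c(5, 45)))
#' overall_accuracy(m)   # 85
#' kappa_coefficient(m)  # 0.7
#' @export
producers_accuracy <- function(m) {
  stopifnot(inherits(m, "error_matrix"))
  tot <- colSums(m)
  out <- ifelse(tot > 0, 100 * diag(m) / tot, NA_real_)
  names(out) <- rownames(m)
  out
}

#' @rdname producers_accuracy
#' @export
users_accuracy <- function(m) {
  stopifnot(inherits(m, "error_matrix"))
  tot <- rowSums(m)
  out <- ifelse(tot > 0, 100 * diag(m) / tot, NA_real_)
  names(out) <- rownames(m)
  out
}

#' @rdname producers_accuracy
#' @export
overall_accuracy <- function(m) {
  stopifnot(inherits(m, "error_matrix"))
  100 * sum(diag(m)) / sum(m)
}

#' @rdname producers_accuracy
#' @export
kappa_coefficient <- function(m) {
  stopifnot(inherits(m, "error_matrix"))
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (1 - pe <= .Machine$double.eps) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Per-class accuracy table
#'
#' Assembles producer's and user's accuracy per class plus overall accuracy
#' and Kappa into one data frame (full precision; round for display).
#'
#' @param m An [error_matrix].
#' @return Data frame with columns `class`, `producers_accuracy_pct`,
#'   `users_accuracy_pct`; overall accuracy and Kappa are attached as
#'   attributes `overall_accuracy_pct` and `kappa`.
#' @export
accuracy_summary <- function(m) {
  out <- data.frame(class = rownames(m),
                    producers_accuracy_pct = unname(producers_accuracy(m)),
                    users_accuracy_pct = unname(users_accuracy(m)),
                    stringsAsFactors = FALSE)
  attr(out, "overall_accuracy_pct") <- overall_accuracy(m)
  attr(out, "kappa") <- kappa_coefficient(m)
  out
}
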