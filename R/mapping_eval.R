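# Mapping-quality metrics between real and estimated intracranial segments:
# per-sensor MSE, Pearson correlation (PCORR) and cosine similarity (COSSIM),
# aggregated sensors -> segments -> subjects, plus the least-squares sanity
# baseline and the printed-table aggregation helper.

#' Mean squared error between two single-sensor series
#'
#' @param y,y_est numeric vectors of equal length
#' @return `(1/L) * sum((y - y_est)^2)`
#' @export
mse <- function(y, y_est) {
  if (length(y) != length(y_est)) stop("series lengths differ")
  mean((y - y_est)^2)
}

#' Cosine similarity between two single-sensor series
#'
#' Inner product over the product of Euclidean norms; 1 for identical
#' vectors, -1 for opposite-phase vectors.
#'
#' @param y,y_est numeric vectors of equal length and nonzero norm
#' @return scalar in `[-1, 1]`, or `NA` (with a warning) for a zero-norm
#'   input
#' @export
cossim <- function(y, y_est) {
  if (length(y) != length(y_est)) stop("series lengths differ")
  ny <- sqrt(sum(y^2))
  ne <- sqrt(sum(y_est^2))
  if (ny == 0 || ne == 0) {
    warning("cosine similarity undefined for zero-norm input")
    return(NA_real_)
  }
  sum(y * y_est) / (ny * ne)
}

#' Pearson correlation between two single-sensor series
#'
#' Covariance over the product of standard deviations (population, 1/L,
#' convention; the normalization cancels in the ratio).
#'
#' @param y,y_est numeric vectors of equal length and nonzero variance
#' @return scalar in `[-1, 1]`, or `NA` (with a warning) for a
#'   zero-variance input
#' @export
pcorr <- function(y, y_est) {
  if (length(y) != length(y_est)) stop("series lengths differ")
  cy <- y - mean(y)
  ce <- y_est - mean(y_est)
  sy <- sqrt(mean(cy^2))
  se <- sqrt(mean(ce^2))
  if (sy == 0 || se == 0) {
    warning("correlation undefined for zero-variance input")
    return(NA_real_)
  }
  mean(cy * ce) / (sy * se)
}

#' Evaluate mapping quality over paired real/estimated segments
#'
#' Metrics are computed per sensor within each segment, averaged over sensors
#' to give per-segment values, over segments for per-subject means, and over
#' subjects for the cohort mean.
#'
#' @param pairs list of `list(Y, Y_est)` pairs of `L x M_bar` matrices, or a
#'   named list of such lists (one per subject)
#' @return an object of class `mapping_report`: `per_segment` data frame,
#'   `per_subject` data frame, and `cohort_mean` named vector
#' @export
evaluate_mapping <- function(pairs) {
  if (!length(pairs)) stop("no pairs to evaluate")
  is_pair <- function(p) is.list(p) && length(p) >= 2 &&
    (is.matrix(p[[1]]) || inherits(p[[1]], "intracranial_segment"))
  subjects <- if (is_pair(pairs[[1]])) list(all = pairs) else pairs
  seg_rows <- list()
  for (sid in names(subjects)) {
    for (k in seq_along(subjects[[sid]])) {
      p <- subjects[[sid]][[k]]
      Y <- if (inherits(p[[1]], "intracranial_segment")) p[[1]]$samples else p[[1]]
      Ye <- if (inherits(p[[2]], "intracranial_segment")) p[[2]]$samples else p[[2]]
      if (!identical(dim(Y), dim(Ye)))
        stop("pair ", k, " of subject ", sid, " has mismatched shapes")
      per_sensor <- vapply(seq_len(ncol(Y)), function(j) {
        c(mse(Y[, j], Ye[, j]), pcorr(Y[, j], Ye[, j]), cossim(Y[, j], Ye[, j]))
      }, numeric(3))
      seg_rows[[length(seg_rows) + 1L]] <-
        data.frame(subject = sid, segment = k,
                   MSE = mean(per_sensor[1, ]),
                   PCORR = mean(per_sensor[2, ]),
                   COSSIM = mean(per_sensor[3, ]))
    }
  }
  per_segment <- do.call(rbind, seg_rows)
  per_subject <- do.call(rbind, lapply(split(per_segment, per_segment$subject),
                                       function(d) {
    data.frame(subject = d$subject[1], MSE = mean(d$MSE),
               PCORR = mean(d$PCORR), COSSIM = mean(d$COSSIM))
  }))
  rownames(per_subject) <- NULL
  cohort_mean <- c(MSE = mean(per_subject$MSE), PCORR = mean(per_subject$PCORR),
                   COSSIM = mean(per_subject$COSSIM))
  structure(list(per_segment = per_segment, per_subject = per_subject,
                 cohort_mean = cohort_mean),
            class = "mapping_report")
}

#' @export
print.mapping_report <- function(x, ...) {
  cat("Mapping quality (", nrow(x$per_segment), " segments, ",
      nrow(x$per_subject), " subject(s))\n", sep = "")
  print(transform(x$per_subject, MSE = round(MSE, 4), PCORR = round(PCORR, 3),
                  COSSIM = round(COSSIM, 3)))
  cat(sprintf("cohort mean: MSE %.4f  PCORR %.3f  COSSIM %.3f\n",
              x$cohort_mean["MSE"], x$cohort_mean["PCORR"],
              x$cohort_mean["COSSIM"]))
  invisible(x)
}

#' Column mean with half-away-from-zero rounding
#'
#' The aggregation used for the "Mean" rows of printed per-subject tables.
#'
#' @param values numeric vector
#' @param rounding decimal places (half rounds away from zero, as in the
#'   printed tables; base R `round()` rounds half to even)
#' @return rounded arithmetic mean
#' @export
mean_of_column <- function(values, rounding = 1) {
  if (!length(values)) stop("empty column")
  m <- mean(values)
  sign(m) * floor(abs(m) * 10^rounding + 0.5) / 10^rounding
}

#' Least-squares mapping baseline
#'
#' Fits one ordinary least-squares linear map per intracranial sensor from
#' the instantaneous scalp sample vector (plus intercept), pooling all time
#' samples of the training pairs; the sanity reference against which the
#' adversarial mapping is compared.
#'
#' @param train_pairs list of `list(X, Y)` training pairs (`L x M` scalp,
#'   `L x M_bar` intracranial)
#' @param test_inputs list of scalp matrices (or a single matrix / batch
#'   array) to map
#' @return list of estimated intracranial matrices (single matrix in, single
#'   matrix out); attribute `coefficients` holds the `(M + 1) x M_bar` map
#' @export
lsq_baseline <- function(train_pairs, test_inputs) {
  stack <- function(getter) do.call(rbind, lapply(train_pairs, getter))
  X <- stack(function(p) as.matrix(p[[1]]))
  Y <- stack(function(p) as.matrix(p[[2]]))
  Xd <- cbind(1, X)
  if (nrow(Xd) < ncol(Xd))
    message("lsq_baseline: fewer samples than regressors; ",
            "minimum-norm solution used")
  fit <- tryCatch(qr.solve(Xd, Y), error = function(e) {
    # rank deficient: minimum-norm solution via the pseudoinverse
    message("lsq_baseline: rank-deficient design; minimum-norm solution used")
    sv <- svd(Xd)
    keep <- sv$d > max(dim(Xd)) * .Machine$double.eps * sv$d[1]
    sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% Y) / sv$d[keep])
  })
  single <- is.matrix(test_inputs)
  ins <- if (single) list(test_inputs)
  else if (is.array(test_inputs) && length(dim(test_inputs)) == 3)
    lapply(seq_len(dim(test_inputs)[1]), function(i)
      matrix(test_inputs[i, , ], dim(test_inputs)[2], dim(test_inputs)[3]))
  else test_inputs
  out <- lapply(ins, function(Xt) cbind(1, as.matrix(Xt)) %*% fit)
  attr(out, "coefficients") <- fit
  if (single) out[[1]] else out
}

#' Export a mapping or classification table as CSV
#'
#' Writes subject rows, metric columns and a final `Mean` row computed with
#' [mean_of_column()].
#'
#' @param per_subject data frame with a `subject` column and numeric metric
#'   columns
#' @param path output CSV path
#' @param rounding decimal places per metric column (recycled)
#' @return `path`, invisibly
#' @export
write_metric_table <- function(per_subject, path, rounding = 3) {
  num_cols <- names(per_subject)[vapply(per_subject, is.numeric, logical(1))]
  rounding <- rep_len(rounding, length(num_cols))
  mean_row <- per_subject[1, , drop = FALSE]
  mean_row$subject <- "Mean"
  for (i in seq_along(num_cols)) {
    mean_row[[num_cols[i]]] <- mean_of_column(per_subject[[num_cols[i]]],
                                              rounding[i])
  }
  utils::write.csv(rbind(per_subject, mean_row), path, row.names = FALSE)
  invisible(path)
}
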