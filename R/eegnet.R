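# Compact convolutional IED/non-IED classifier in the EEGNet style, with the
# two modifications used for estimated intracranial input: no batch
# normalization anywhere, and max pooling instead of average pooling.
# Pipeline: shared temporal convolution per sensor -> depthwise spatial
# combination across sensors -> max pool -> separable temporal convolution
# (depthwise + pointwise) -> max pool -> dense sigmoid output.
# Depthwise/grouped convolutions are realized as dense parameter matrices
# multiplied by fixed 0/1 block masks.

#' Classifier configuration
#'
#' @param temporal_kernel_len first-stage temporal filter length (samples)
#' @param n_temporal_filters temporal filters per sensor (F1)
#' @param depth_multiplier spatial filters per temporal filter (D)
#' @param separable_kernel_len depthwise temporal filter length of the
#'   separable stage
#' @param pool pooling factor of each of the two max-pool stages
#' @param dropout_rate dropout probability after each pool during training
#' @param epochs,batch_size,lr Adam training settings
#' @param seed seed fixing initialization, shuffling and dropout
#' @return an object of class `eegnet_config`
#' @export
eegnet_config <- function(temporal_kernel_len = 17, n_temporal_filters = 4,
                          depth_multiplier = 2, separable_kernel_len = 9,
                          pool = 4, dropout_rate = 0.25, epochs = 40,
                          batch_size = 16, lr = 2e-3, seed = 1) {
  structure(list(temporal_kernel_len = temporal_kernel_len,
                 n_temporal_filters = n_temporal_filters,
                 depth_multiplier = depth_multiplier,
                 separable_kernel_len = separable_kernel_len,
                 pool = pool, dropout_rate = dropout_rate, epochs = epochs,
                 batch_size = batch_size, lr = lr, seed = seed,
                 pooling = "max", normalization = "none"),
            class = "eegnet_config")
}

# block-diagonal mask tying depthwise weights to their own group
depthwise_mask <- function(n_groups, per_group_in, per_group_out) {
  m <- matrix(0, n_groups * per_group_in, n_groups * per_group_out)
  for (g in seq_len(n_groups)) {
    rows <- (g - 1) * per_group_in + seq_len(per_group_in)
    cols <- (g - 1) * per_group_out + seq_len(per_group_out)
    m[rows, cols] <- 1
  }
  m
}

# conv-weight mask for a per-channel (depthwise) temporal convolution laid
# out as (k*Cin, Cout = Cin*mult): channel c's taps map only to its outputs
depthwise_conv_mask <- function(k, c_in, mult = 1) {
  m <- matrix(0, k * c_in, c_in * mult)
  for (cc in seq_len(c_in)) {
    rows <- (cc - 1) * k + seq_len(k)
    cols <- (cc - 1) * mult + seq_len(mult)
    m[rows, cols] <- 1
  }
  m
}

init_eegnet_params <- function(cfg, L, n_ch) {
  f1 <- cfg$n_temporal_filters
  d <- cfg$depth_multiplier
  f2 <- f1 * d
  l_pooled <- L %/% cfg$pool
  l_final <- l_pooled %/% cfg$pool
  stopifnot(l_final >= 1)
  list(temporal = init_conv1d(cfg$temporal_kernel_len, 1L, f1),
       spatial = init_dense(n_ch * f1, f1 * d),
       sep_depth = init_conv1d(cfg$separable_kernel_len, f2, f2),
       sep_point = init_conv1d(1L, f2, f2),
       out = init_dense(l_final * f2, 1L))
}

eegnet_graph <- function(x, wp, cfg, n_ch, dropout_masks = NULL) {
  d <- dim(ad_value(x)) # (B, L, C)
  B <- d[1]; L <- d[2]
  f1 <- cfg$n_temporal_filters
  f2 <- f1 * cfg$depth_multiplier
  # per-sensor shared temporal filters: fold sensors into the batch
  h <- ad_reshape(ad_permute(x, c(1, 3, 2)), c(B * n_ch, L, 1))
  h <- conv1d_fwd(h, wp$temporal, cfg$temporal_kernel_len,
                  pad = same_pad(cfg$temporal_kernel_len))
  # (B*C, L, F1) -> (B, L, C*F1): sensors become grouped channels
  h <- ad_reshape(h, c(B, n_ch, L, f1))
  h <- ad_permute(h, c(1, 3, 2, 4))
  h <- ad_reshape(h, c(B, L, n_ch * f1))
  # depthwise spatial combination within each temporal filter group
  sp_w <- ad_mul(wp$spatial$w, ad_const(spatial_mask_for(n_ch, f1,
                                                         cfg$depth_multiplier)))
  h2 <- ad_reshape(h, c(B * L, n_ch * f1))
  h2 <- ad_add_rowvec(ad_matmul(h2, sp_w), wp$spatial$b)
  h <- ad_lrelu(ad_reshape(h2, c(B, L, f2)), 0.01)
  h <- ad_maxpool_time(h, cfg$pool)
  if (!is.null(dropout_masks)) h <- ad_mul(h, ad_const(dropout_masks[[1]]))
  # separable convolution: depthwise temporal then pointwise mixing
  sd_w <- ad_mul(wp$sep_depth$w,
                 ad_const(depthwise_conv_mask(cfg$separable_kernel_len, f2)))
  h <- ad_conv1d(h, sd_w, wp$sep_depth$b, cfg$separable_kernel_len,
                 pad = same_pad(cfg$separable_kernel_len))
  h <- ad_lrelu(conv1d_fwd(h, wp$sep_point, 1L), 0.01)
  h <- ad_maxpool_time(h, cfg$pool)
  if (!is.null(dropout_masks)) h <- ad_mul(h, ad_const(dropout_masks[[2]]))
  dh <- dim(ad_value(h))
  flat <- ad_reshape(h, c(B, dh[2] * dh[3]))
  dense_fwd(flat, wp$out) # logits
}

# spatial mask: the flattened channel axis orders sensors fastest within each
# temporal filter (index c + (f-1)*n_ch); each filter's sensors map only to
# that filter's d spatial outputs
spatial_mask_for <- function(n_ch, f1, d) {
  m <- matrix(0, n_ch * f1, f1 * d)
  for (f in seq_len(f1)) {
    rows <- (f - 1) * n_ch + seq_len(n_ch)
    cols <- (f - 1) * d + seq_len(d)
    m[rows, cols] <- 1
  }
  m
}

#' Train the IED/non-IED classifier
#'
#' @param x segments: `(n, L, C)` array (typically estimated intracranial
#'   segments), or a list of matrices
#' @param y labels: `"IED"`/`"nonIED"` character, factor, or 0/1 numeric
#'   (1 = IED)
#' @param cfg an [eegnet_config()]
#' @return an object of class `eegnet` with `params`, `cfg`, geometry, and
#'   the per-epoch training-loss history
#' @export
eegnet <- function(x, y, cfg = eegnet_config()) {
  if (is.list(x) && !is.array(x)) {
    x <- do.call(abind_first, x)
  }
  y <- label_to_numeric(y)
  if (length(unique(y)) < 2) stop("both classes must be present for training")
  d <- dim(x)
  stopifnot(length(d) == 3, d[1] == length(y))
  set.seed(cfg$seed %% 2147483647)
  params <- init_eegnet_params(cfg, d[2], d[3])
  state <- adam_init(params)
  n <- d[1]
  hist <- numeric(cfg$epochs)
  l_pool1 <- d[2] %/% cfg$pool
  l_pool2 <- l_pool1 %/% cfg$pool
  f2 <- cfg$n_temporal_filters * cfg$depth_multiplier
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    tot <- 0
    for (b in batches) {
      xb <- x[b, , , drop = FALSE]
      yb <- y[b]
      wp <- wrap_params(params)
      p <- cfg$dropout_rate
      masks <- if (p > 0) {
        keep1 <- array(stats::rbinom(length(b) * l_pool1 * f2, 1, 1 - p) / (1 - p),
                       c(length(b), l_pool1, f2))
        keep2 <- array(stats::rbinom(length(b) * l_pool2 * f2, 1, 1 - p) / (1 - p),
                       c(length(b), l_pool2, f2))
        list(keep1, keep2)
      } else NULL
      logit <- eegnet_graph(ad_const(xb), wp, cfg, d[3], masks)
      # stable binary cross-entropy on logits
      loss <- ad_mean(ad_sub(ad_softplus(logit),
                             ad_mul(logit, ad_const(matrix(yb, length(b), 1)))))
      ad_backward(loss)
      upd <- adam_step(params, collect_grads(wp), state, lr = cfg$lr)
      params <- upd$params
      state <- upd$state
      tot <- tot + loss$value * length(b)
    }
    hist[ep] <- tot / n
    if (!is.finite(hist[ep])) stop("classifier training diverged at epoch ", ep)
  }
  structure(list(params = params, cfg = cfg, L = d[2], n_ch = d[3],
                 loss_history = hist),
            class = "eegnet")
}

abind_first <- function(...) {
  mats <- list(...)
  out <- array(0, c(length(mats), dim(mats[[1]])))
  for (i in seq_along(mats)) out[i, , ] <- mats[[i]]
  out
}

label_to_numeric <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) as.numeric(y == "IED") else as.numeric(y)
}

#' Predict IED probabilities
#'
#' @param object a fitted [eegnet()]
#' @param newdata `(n, L, C)` array or single `L x C` matrix
#' @param ... ignored
#' @return numeric vector of IED probabilities in `[0, 1]`, one per segment
#' @export
predict.eegnet <- function(object, newdata, ...) {
  single <- is.matrix(newdata)
  xb <- if (single) array(newdata, c(1, dim(newdata))) else newdata
  if (dim(xb)[2] != object$L || dim(xb)[3] != object$n_ch)
    stop("segment shape (", dim(xb)[2], ", ", dim(xb)[3],
         ") does not match the classifier (", object$L, ", ", object$n_ch, ")")
  wp <- wrap_params(object$params, trainable = FALSE)
  logit <- ad_value(eegnet_graph(ad_const(xb), wp, object$cfg, object$n_ch))
  as.numeric(1 / (1 + exp(-logit)))
}

#' @export
print.eegnet <- function(x, ...) {
  cat("EEGNet-style IED classifier (no batch norm, max pooling)\n")
  cat(sprintf("  input (%d, %d); F1=%d, D=%d; trained %d epochs, final BCE %.4f\n",
              x$L, x$n_ch, x$cfg$n_temporal_filters, x$cfg$depth_multiplier,
              length(x$loss_history), x$loss_history[length(x$loss_history)]))
  invisible(x)
}

# ---- metrics ---------------------------------------------------------------

#' Classification metrics for IED detection
#'
#' IED is the positive class. Deterministic threshold rule: probability >=
#' `threshold` is classified IED. The ROC curve sweeps all distinct scores;
#' AUC is the trapezoidal area.
#'
#' @param labels true labels (as in [eegnet()])
#' @param probabilities predicted IED probabilities
#' @param threshold decision threshold
#' @return an object of class `classification_metrics` with fields ACC, SEN,
#'   SPC, PRC, F1, AUC and `roc_points`
#' @export
classification_metrics <- function(labels, probabilities, threshold = 0.5) {
  y <- label_to_numeric(labels)
  stopifnot(length(y) == length(probabilities))
  pred <- as.numeric(probabilities >= threshold)
  tp <- sum(pred == 1 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spc <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prc <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prc) && !is.na(sen) && prc + sen > 0)
    2 * prc * sen / (prc + sen) else NA_real_
  if (is.na(sen) || is.na(spc))
    warning("single-class ground truth: SEN or SPC undefined")
  roc <- roc_points(y, probabilities)
  auc <- if (nrow(roc) >= 2 && !anyNA(roc))
    sum(diff(roc$FPR) * (utils::head(roc$TPR, -1) + utils::tail(roc$TPR, -1)) / 2)
  else NA_real_
  structure(list(ACC = (tp + tn) / length(y), SEN = sen, SPC = spc,
                 PRC = prc, F1 = f1, AUC = auc, roc_points = roc,
                 confusion = c(TP = tp, FP = fp, TN = tn, FN = fn)),
            class = "classification_metrics")
}

roc_points <- function(y, p) {
  if (length(unique(y)) < 2) return(data.frame(FPR = NA_real_, TPR = NA_real_))
  th <- c(Inf, sort(unique(p), decreasing = TRUE))
  pts <- t(vapply(th, function(t) {
    pred <- p >= t
    c(FPR = sum(pred & y == 0) / sum(y == 0),
      TPR = sum(pred & y == 1) / sum(y == 1))
  }, numeric(2)))
  as.data.frame(pts)
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("ACC %.3f  SEN %.3f  SPC %.3f  PRC %.3f  F1 %.3f  AUC %.3f\n",
              x$ACC, x$SEN, x$SPC, x$PRC, x$F1, x$AUC))
  invisible(x)
}

# ---- cross-validation protocols -------------------------------------------

#' Cross-validation plan
#'
#' @param mode `"intra"` (within-subject 70/10/20 split) or `"inter"`
#'   (leave-one-subject-out with ensemble voting)
#' @param train_frac,val_frac,test_frac intra-subject split fractions
#' @param selection_threshold intra-subject accuracy a subject must exceed
#'   (strictly) to join the inter-subject training ensemble
#' @return an object of class `cv_plan`
#' @export
cv_plan <- function(mode = c("intra", "inter"), train_frac = 0.70,
                    val_frac = 0.10, test_frac = 0.20,
                    selection_threshold = 0.70) {
  mode <- match.arg(mode)
  if (abs(train_frac + val_frac + test_frac - 1) > 1e-9)
    stop("split fractions must sum to 1")
  structure(list(mode = mode, train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac,
                 selection_threshold = selection_threshold),
            class = "cv_plan")
}

# label-stratified three-way split; exact sizes per class, seeded
stratified_split <- function(labels, plan, seed = 1) {
  y <- label_to_numeric(labels)
  set.seed(seed %% 2147483647)
  assign <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    n <- length(idx)
    n_tr <- round(plan$train_frac * n)
    n_va <- round(plan$val_frac * n)
    assign[idx[seq_len(n_tr)]] <- 1L
    assign[idx[n_tr + seq_len(n_va)]] <- 2L
    assign[idx[(n_tr + n_va + 1):n]] <- 3L
  }
  list(train = which(assign == 1L), val = which(assign == 2L),
       test = which(assign == 3L))
}

#' Intra-subject evaluation
#'
#' Maps the subject's scalp segments to estimated intracranial segments with
#' the fitted translation model (`mode = "mean"`), splits them 70/10/20
#' (stratified by label, seeded), trains the classifier on the training
#' split, monitors accuracy on the validation split, and reports metrics on
#' the held-out test split.
#'
#' @param segments the subject's [paired_segment()]s (or [subject_record()])
#' @param mapping_model the subject's fitted [vaecgan()] (`NULL` to classify
#'   real intracranial segments instead)
#' @param plan a [cv_plan()]
#' @param cfg an [eegnet_config()]
#' @param seed split seed
#' @param input `"estimated"` (translate scalp), `"scalp"` (raw scalp) or
#'   `"real"` (recorded intracranial) segments as classifier input
#' @return list with `metrics` ([classification_metrics()]), the fitted
#'   `classifier`, and the `split`
#' @export
intra_subject_eval <- function(segments, mapping_model, plan = cv_plan("intra"),
                               cfg = eegnet_config(), seed = 1,
                               input = c("estimated", "scalp", "real")) {
  input <- match.arg(input)
  arr <- seg_input(segments)
  feats <- switch(input,
    estimated = translate(mapping_model, arr$scalp, mode = "mean"),
    scalp = arr$scalp,
    real = arr$intracranial)
  y <- arr$labels
  sp <- stratified_split(y, plan, seed)
  if (!length(sp$test) || length(unique(y[sp$test])) < 2)
    stop("test split is empty or single-class; use a larger cohort")
  cls <- eegnet(feats[sp$train, , , drop = FALSE], y[sp$train], cfg)
  val_p <- predict(cls, feats[sp$val, , , drop = FALSE])
  test_p <- predict(cls, feats[sp$test, , , drop = FALSE])
  list(metrics = classification_metrics(y[sp$test], test_p),
       val_acc = if (length(sp$val))
         classification_metrics(y[sp$val], val_p)$ACC else NA_real_,
       classifier = cls, split = sp)
}

#' Select ensemble training subjects by intra-subject accuracy
#'
#' @param intra_results named numeric vector or list mapping subject id to
#'   intra-subject accuracy
#' @param threshold strict lower bound on accuracy
#' @return character vector of selected subject ids (sorted); may be empty
#' @export
select_training_subjects <- function(intra_results, threshold = 0.70) {
  acc <- unlist(intra_results)
  if (!length(acc)) stop("empty intra-subject result map")
  sort(names(acc)[acc > threshold])
}

#' Inter-subject evaluation with average voting
#'
#' The held-out subject's scalp segments are mapped through every selected
#' training subject's translation model and scored by that subject's
#' classifier; the ensemble's IED probabilities are averaged elementwise
#' (average voting) and thresholded at 0.5 (ties classified IED).
#'
#' @param test_segments held-out subject's [paired_segment()]s (or record)
#' @param members named list (one per selected subject) of
#'   `list(model = vaecgan, classifier = eegnet)`
#' @param test_subject_id id of the held-out subject (must not be a member)
#' @return list with `metrics`, the averaged `probabilities`, and the
#'   per-member probability matrix
#' @export
inter_subject_eval <- function(test_segments, members, test_subject_id = NULL) {
  stopifnot(length(members) >= 1)
  if (!is.null(test_subject_id) && test_subject_id %in% names(members))
    stop("test subject ", test_subject_id, " overlaps the training ensemble")
  arr <- seg_input(test_segments)
  probs <- vapply(members, function(m) {
    est <- translate(m$model, arr$scalp, mode = "mean")
    predict(m$classifier, est)
  }, numeric(dim(arr$scalp)[1]))
  probs <- matrix(probs, ncol = length(members))
  avg <- rowMeans(probs)
  list(metrics = classification_metrics(arr$labels, avg, threshold = 0.5),
       probabilities = avg, member_probabilities = probs)
}
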