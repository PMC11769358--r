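# Classifier and evaluation protocols: separable-task sanity, architecture
# introspection (no normalization, max pooling only), metric arithmetic, ROC
# invariances, split stratification, subject selection and ensemble voting.

make_spike_task <- function(n = 60, L = 64, C = 6, seed = 3) {
  set.seed(seed)
  x <- array(rnorm(n * L * C, sd = 0.1), c(n, L, C))
  y <- rep(c(1, 0), each = n / 2)
  tmpl <- render_ied_template(ied_template(), L, 200, 32)
  for (i in which(y == 1)) {
    for (ch in sample(C, 3)) x[i, , ch] <- x[i, , ch] + 0.15 * tmpl
  }
  list(x = x, y = y)
}

test_that("the classifier separates spike from background segments", {
  task <- make_spike_task()
  accs <- vapply(1:3, function(s) {
    m <- eegnet(task$x, task$y, eegnet_config(epochs = 30, seed = s))
    mean((predict(m, task$x) >= 0.5) == task$y)
  }, numeric(1))
  expect_gte(sum(accs >= 0.95), 2) # majority of 3 seeds
})

test_that("the classifier has no normalization layers and only max pooling", {
  cfg <- eegnet_config()
  expect_identical(cfg$pooling, "max")
  expect_identical(cfg$normalization, "none")
  # parameter introspection: exactly the five declared layer groups, no
  # normalization parameters anywhere
  params <- eegtranslate:::init_eegnet_params(cfg, 64, 12)
  expect_setequal(names(params),
                  c("temporal", "spatial", "sep_depth", "sep_point", "out"))
  # the forward graph uses ad_maxpool_time and never ad_avgpool_time/ad_norm
  body_txt <- paste(deparse(body(eegtranslate:::eegnet_graph)), collapse = "")
  expect_true(grepl("ad_maxpool_time", body_txt))
  expect_false(grepl("ad_avgpool_time", body_txt))
  expect_false(grepl("ad_norm", body_txt))
})

test_that("training is deterministic per seed and predictions are bounded and aligned", {
  task <- make_spike_task(n = 24)
  m1 <- eegnet(task$x, task$y, eegnet_config(epochs = 4, seed = 9))
  m2 <- eegnet(task$x, task$y, eegnet_config(epochs = 4, seed = 9))
  p1 <- predict(m1, task$x)
  expect_identical(p1, predict(m2, task$x))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_length(p1, 24)
  # duplicated segment gets an identical probability
  dup <- task$x[c(1, 1, 2), , , drop = FALSE]
  pd <- predict(m1, dup)
  expect_identical(pd[1], pd[2])
  expect_error(eegnet(task$x, rep(1, 24)), "both classes")
  expect_error(predict(m1, matrix(0, 32, 6)), "match")
})

test_that("classification metrics match direct confusion-matrix arithmetic", {
  perfect <- classification_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(perfect$ACC, 1)
  expect_equal(perfect$SEN, 1)
  expect_equal(perfect$SPC, 1)
  expect_equal(perfect$PRC, 1)
  expect_equal(perfect$F1, 1)
  expect_equal(perfect$AUC, 1)
  # TP=3, FN=1, TN=2, FP=2
  lab <- c(1, 1, 1, 1, 0, 0, 0, 0)
  pr <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.7, 0.1, 0.2)
  cm <- classification_metrics(lab, pr)
  expect_identical(unname(cm$confusion), c(3L, 2L, 2L, 1L))
  expect_equal(cm$SEN, 0.75)
  expect_equal(cm$SPC, 0.5)
  expect_equal(cm$ACC, 0.625)
  # ACC is the prevalence-weighted convex combination of SEN and SPC
  expect_equal(cm$ACC, 0.5 * cm$SEN + 0.5 * cm$SPC)
  expect_warning(classification_metrics(rep(1, 4), runif(4)), "single-class")
})

test_that("AUC is near chance for random scores and invariant to monotone transforms", {
  set.seed(64)
  n <- 2000
  y <- rbinom(n, 1, 0.5)
  p <- runif(n)
  auc <- classification_metrics(y, p)$AUC
  expect_lt(abs(auc - 0.5), 0.05)
  y2 <- rbinom(300, 1, 0.5)
  p2 <- runif(300)
  a1 <- classification_metrics(y2, p2)$AUC
  a2 <- classification_metrics(y2, plogis(5 * p2 - 1))$AUC
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("stratified splits respect the 70/10/20 fractions and the seed", {
  labels <- rep(c("IED", "nonIED"), each = 50)
  sp <- eegtranslate:::stratified_split(labels, cv_plan("intra"), seed = 7)
  expect_length(sp$train, 70)
  expect_length(sp$val, 10)
  expect_length(sp$test, 20)
  # stratification within one segment per class
  y <- as.numeric(labels == "IED")
  for (part in sp) expect_lte(abs(sum(y[part]) - length(part) / 2), 1)
  sp2 <- eegtranslate:::stratified_split(labels, cv_plan("intra"), seed = 7)
  expect_identical(sp, sp2)
  expect_error(cv_plan(train_frac = 0.8, val_frac = 0.1, test_frac = 0.2),
               "sum to 1")
})

test_that("subject selection is strict at the 70% boundary", {
  expect_identical(select_training_subjects(c(A = 0.80, B = 0.70, C = 0.71)),
                   c("A", "C"))
  expect_identical(select_training_subjects(c(A = 0.5, B = 0.69)),
                   character(0))
  expect_identical(select_training_subjects(c(B = 0.9, A = 0.8)),
                   c("A", "B"))
})

test_that("classifying translated segments beats classifying the raw scalp", {
  # a cohort whose scalp stream is degraded (saturating mixing, halved gain,
  # partial spike transmission): the translation acts as a learned denoiser,
  # so the classifier on estimated intracranial segments should outperform
  # one trained on the raw scalp in the majority of classifier seeds
  cfg <- simulation_config(n_subjects = 1, segments_per_subject = 128,
                           target_visible_fraction = NULL, snr_db = 10)
  fwd <- forward_model(default_mixing(20, 12), nonlinearity = "saturating",
                       attenuation = 0.5, spike_leakage = 0.35)
  rec <- simulate_subject(cfg, fwd, subject_seed = 5)
  model <- vaecgan(rec, recovery_arch(),
                   train_control(epochs = 30, batch_size = 8, lr_g = 5e-3,
                                 lr_d = 2e-3, g_steps = 2, seed = 1,
                                 weights = loss_weights(0.05, 100, 1)))
  wins <- vapply(1:3, function(s) {
    mapped <- intra_subject_eval(rec, model,
                                 cfg = eegnet_config(epochs = 30, seed = s),
                                 seed = 2)
    scalp <- intra_subject_eval(rec, NULL,
                                cfg = eegnet_config(epochs = 30, seed = s),
                                seed = 2, input = "scalp")
    mapped$metrics$ACC > scalp$metrics$ACC
  }, logical(1))
  expect_gte(sum(wins), 2)
})

test_that("average voting equals the probability mean and degenerates at N = 1", {
  task <- make_spike_task(n = 20, C = 12, seed = 5)
  rec <- easy_subject(n_segments = 20, subject_seed = 6)
  arch <- tiny_arch()
  ctrl <- train_control(epochs = 1, batch_size = 10, seed = 2)
  model <- vaecgan(rec, arch, ctrl)
  cls1 <- eegnet(task$x, task$y, eegnet_config(epochs = 3, seed = 1))
  cls2 <- eegnet(task$x, task$y, eegnet_config(epochs = 3, seed = 2))
  members2 <- list(S1 = list(model = model, classifier = cls1),
                   S2 = list(model = model, classifier = cls2))
  out2 <- inter_subject_eval(rec, members2, "S9")
  # brute-force mean of the member probability vectors
  expect_equal(out2$probabilities, rowMeans(out2$member_probabilities))
  # permutation invariance of the ensemble
  out2r <- inter_subject_eval(rec, rev(members2), "S9")
  expect_equal(out2$probabilities, out2r$probabilities)
  # N = 1 equals the single classifier
  out1 <- inter_subject_eval(rec, members2[1], "S9")
  expect_equal(out1$probabilities, out2$member_probabilities[, 1])
  expect_error(inter_subject_eval(rec, members2, "S1"), "overlaps")
  # tie rule: averaged probability exactly 0.5 is classified IED
  cmx <- classification_metrics(c(1, 0), c(0.5, 0.5))
  expect_identical(unname(cmx$confusion[c("TP", "FP")]), c(1L, 1L))
})
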