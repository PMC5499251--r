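# End-to-end workflow pieces at deliberately small scale.

small_config <- function(seed = 123) {
  pipeline_config(n_freq = 10, n_time = 12, sda_layer_sizes = c(8),
                  sda_epochs = 3, dnn_epochs = 10, n_adapt = 20,
                  max_iter = 30, seed = seed)
}

test_that("configuration validation catches inconsistent settings", {
  expect_s3_class(pipeline_config(), "pipeline_config")
  expect_error(pipeline_config(pre_ms = 350), "not TRUE")
  expect_error(pipeline_config(sda_layer_sizes = c(64, 128)),
               "strictly decreasing")
  expect_error(pipeline_config(n_adapt = -1), "not TRUE")
})

test_that("records preprocess into labelled image matrices", {
  cfg <- small_config()
  rec <- clean_record(rep(c("N", "V"), 6))
  prep <- record_to_images(rec, cfg)
  expect_equal(ncol(prep$images), 10 * 12)
  expect_equal(nrow(prep$images), length(prep$labels))
  expect_true(all(prep$labels %in% c("N", "V")))
  expect_true(all(prep$images >= 0 & prep$images <= 1))
})

test_that("stage 1 is seeded-reproducible and persists with a manifest", {
  cfg <- small_config()
  imgs <- toy_images(40, 120)
  s1 <- run_stage1_pretrain(cfg, imgs)
  s2 <- run_stage1_pretrain(cfg, imgs)
  expect_identical(s1$layers[[1]]$W, s2$layers[[1]]$W)
  expect_error(run_stage1_pretrain(cfg, imgs[0, , drop = FALSE]), "empty")

  path <- file.path(withr::local_tempdir(), "sda.json")
  run_stage1_pretrain(cfg, imgs, out = path)
  back <- load_model(path)
  expect_s3_class(back, "sda_model")
  expect_equal(back$layers[[1]]$W, s1$layers[[1]]$W)
  manifest <- attr(back, "manifest")
  expect_equal(manifest$stage, 1)
  expect_equal(manifest$seed, 123)
  expect_equal(manifest$config$sda_layer_sizes, 8)
  expect_equal(ncol(sda_features(back, imgs)), 8)
})

test_that("stage 2 trains an interpatient classifier without touching stage 1", {
  cfg <- small_config()
  set.seed(21)
  n <- 60
  imgs <- rbind(matrix(runif(n * 120, 0, 0.4), n, 120),
                matrix(runif(n * 120, 0.6, 1), n, 120))
  labels <- rep(c("N", "V"), each = n)
  sda <- run_stage1_pretrain(cfg, imgs)
  W0 <- sda$layers[[1]]$W
  fit <- run_stage2_interpatient(cfg, sda, imgs, labels)
  expect_identical(sda$layers[[1]]$W, W0)
  expect_gt(tail(fit$history$accuracy, 1), 0.9)
  again <- run_stage2_interpatient(cfg, sda, imgs, labels)
  expect_identical(fit$classifier, again$classifier)
  expect_error(run_stage2_interpatient(cfg, sda, imgs, labels[-1]),
               "not TRUE")
})

test_that("stage 3 adapts, evaluates the remainder, and flags empty sets", {
  cfg <- small_config()
  rec <- clean_record(rep(c("N", "V", "N", "N"), 15), seed = 31)
  prep <- record_to_images(rec, cfg)
  sda <- run_stage1_pretrain(cfg, prep$images)
  inter <- run_stage2_interpatient(cfg, sda, prep$images, prep$labels)

  # geometric-mean warnings are expected: the two-class fixture leaves S/F
  # undefined
  res <- suppressWarnings(
    run_stage3_patient(cfg, inter$classifier, prep$images, prep$labels)
  )
  expect_false(res$empty_evaluation)
  expect_equal(res$n_eval, nrow(prep$images) - cfg$n_adapt)
  expect_equal(sum(res$confusion), res$n_eval)

  # n_adapt = 0 reproduces the interpatient evaluation
  cfg0 <- small_config(); cfg0$n_adapt <- 0
  res0 <- suppressWarnings(
    run_stage3_patient(cfg0, inter$classifier, prep$images,
                       prep$labels, eval_from = cfg$n_adapt)
  )
  pred <- dnn_predict(inter$classifier,
                      prep$images[-seq_len(cfg$n_adapt), , drop = FALSE])
  expect_equal(sum(diag(res0$confusion)),
               sum(pred == prep$labels[-seq_len(cfg$n_adapt)]))

  # record with fewer beats than the evaluation start is flagged
  few <- run_stage3_patient(cfg, inter$classifier,
                            prep$images[1:10, , drop = FALSE],
                            prep$labels[1:10])
  expect_true(few$empty_evaluation)
  expect_gt(few$shortfall, 0)
})

test_that("classifier models survive a save/load round trip", {
  cfg <- small_config()
  imgs <- toy_images(30, 120, seed = 41)
  labels <- sample(c("N", "S", "V", "F"), 30, replace = TRUE)
  sda <- run_stage1_pretrain(cfg, imgs)
  fit <- run_stage2_interpatient(cfg, sda, imgs, labels)
  path <- file.path(withr::local_tempdir(), "dnn.json")
  save_model(fit$classifier, path, config = cfg, stage = 2L)
  back <- load_model(path)
  expect_s3_class(back, "dnn_classifier")
  expect_equal(dnn_predict_proba(back, imgs),
               dnn_predict_proba(fit$classifier, imgs))
})

test_that("reference tables reproduce the reported percentages", {
  rep_ <- report_reference_tables()
  expect_true(all(abs(rep_$diff) <= 0.05))
})
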