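# Configuration and the three-stage training workflow: unsupervised
# pretraining, interpatient fine-tuning, patient-specific adaptation.

#' Pipeline configuration
#'
#' Collects and validates every tunable constant of the pipeline. All
#' durations are in ms, frequencies in Hz.
#'
#' @param fs sampling rate (Hz).
#' @param window_ms,pre_ms,post_ms segmentation window and its split around
#'   the R peak; `pre_ms + post_ms` must equal `window_ms`.
#' @param f_max,n_freq,n_time,q_min time-frequency image parameters, see
#'   [tf_image()] and [scale_q()].
#' @param sda_layer_sizes strictly decreasing hidden layer sizes.
#' @param sda_P,sda_lr,sda_epochs,sda_batch pretraining hyperparameters.
#' @param dnn_lr,dnn_epochs,dnn_batch fine-tuning hyperparameters.
#' @param patience,max_iter early-stopping rule of the adaptation stage.
#' @param n_adapt number of initial per-patient beats used for adaptation.
#' @param seed optional integer; fans out to per-stage substreams
#'   (`seed + stage`) so stages can be rerun independently.
#' @return object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(fs = 360,
                            window_ms = 700, pre_ms = 300, post_ms = 400,
                            f_max = 64, n_freq = 45, n_time = 64,
                            q_min = 0.5,
                            sda_layer_sizes = c(1024),
                            sda_P = 0.25, sda_lr = 0.1, sda_epochs = 30,
                            sda_batch = 32,
                            dnn_lr = 0.1, dnn_epochs = 30, dnn_batch = 32,
                            patience = 10, max_iter = 200, n_adapt = 300,
                            seed = NULL) {
  stopifnot(fs > 0, window_ms > 0, pre_ms > 0, post_ms > 0,
            pre_ms + post_ms == window_ms,
            f_max > 0, n_freq >= 2, n_time >= 2, q_min > 0,
            sda_P >= 0, sda_P <= 1, n_adapt >= 0,
            patience >= 1, max_iter >= 1)
  if (length(sda_layer_sizes) > 1 && any(diff(sda_layer_sizes) >= 0)) {
    stop("sda_layer_sizes must be strictly decreasing", call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Preprocess a record into labelled time-frequency images
#'
#' Baseline removal, R-peak detection, annotation pairing, segmentation and
#' time-frequency imaging of one record. Detections without a matched
#' annotation are labelled `"unknown"`.
#'
#' @param record a [synth_record()] or [read_record()] result.
#' @param config a [pipeline_config()].
#' @return list with `images` (one row per kept beat), `labels`,
#'   `r_peaks`, `dropped` (boundary-dropped peaks), `patient_id`.
#' @export
record_to_images <- function(record, config = pipeline_config()) {
  corrected <- remove_baseline(record$signal, record$fs)
  peaks <- detect_r_peaks(corrected, record$fs)
  labels <- pair_labels(peaks, record$annotations$sample,
                        record$annotations$aami_class, record$fs)
  seg <- segment_beats(corrected, record$fs, peaks)
  kept <- peaks %in% seg$r_peaks
  images <- beat_images(seg$segments, record$fs,
                        n_freq = config$n_freq, n_time = config$n_time,
                        f_max = config$f_max, q_min = config$q_min)
  list(images = images, labels = labels[kept], r_peaks = seg$r_peaks,
       dropped = seg$dropped, patient_id = record$patient_id)
}

#' Stage 1: unsupervised pretraining
#'
#' Trains the stacked denoising auto-encoder on unlabeled images and
#' optionally persists it with a manifest.
#'
#' @param config a [pipeline_config()].
#' @param images matrix of images in \[0, 1\], one row per beat.
#' @param out optional file path for [save_model()].
#' @return the pretrained `sda_model`.
#' @export
run_stage1_pretrain <- function(config, images, out = NULL) {
  if (is.null(dim(images)) || nrow(images) == 0) {
    stop("empty pretraining data", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  sda <- sda_pretrain(images, config$sda_layer_sizes, P = config$sda_P,
                      lr = config$sda_lr, epochs = config$sda_epochs,
                      batch_size = config$sda_batch)
  if (!is.null(out)) save_model(sda, out, config = config, stage = 1L)
  sda
}

#' Stage 2: interpatient fine-tuning
#'
#' Initializes the classifier from the pretrained stack and fine-tunes it
#' on labelled training-set images.
#'
#' @param config a [pipeline_config()].
#' @param sda the stage-1 `sda_model` (left unmodified).
#' @param images training images.
#' @param labels AAMI labels, one per row of `images`.
#' @param out optional file path for [save_model()].
#' @return list with the interpatient `classifier` and training `history`.
#' @export
run_stage2_interpatient <- function(config, sda, images, labels,
                                    out = NULL) {
  stopifnot(nrow(images) == length(labels))
  if (!is.null(config$seed)) set.seed(config$seed + 2L)
  clf <- dnn_from_sda(sda)
  fit <- dnn_fine_tune(clf, images, labels, lr = config$dnn_lr,
                       epochs = config$dnn_epochs,
                       batch_size = config$dnn_batch)
  if (!is.null(out)) save_model(fit$classifier, out, config = config,
                                stage = 2L)
  fit
}

#' Stage 3: patient-specific adaptation and evaluation
#'
#' Adapts a copy of the interpatient classifier on the first `n_adapt`
#' beats of one patient (time order) and evaluates it on the remaining
#' beats. With `n_adapt = 0` this reproduces the interpatient evaluation.
#'
#' @param config a [pipeline_config()].
#' @param clf the interpatient classifier.
#' @param images patient beat images in time order.
#' @param labels AAMI labels per beat.
#' @param eval_from evaluate on beats after this index; defaults to
#'   `config$n_adapt` (so evaluation excludes the adaptation beats).
#' @return list with the adapted `classifier`, `confusion`, `metrics`,
#'   `n_eval`, `empty_evaluation`, `shortfall`.
#' @export
run_stage3_patient <- function(config, clf, images, labels,
                               eval_from = NULL) {
  stopifnot(nrow(images) == length(labels))
  if (is.null(eval_from)) eval_from <- config$n_adapt
  if (!is.null(config$seed)) set.seed(config$seed + 3L)
  fit <- patient_adapt(clf, images, labels, n_adapt = config$n_adapt,
                       lr = config$dnn_lr, batch_size = config$dnn_batch,
                       patience = config$patience,
                       max_iter = config$max_iter)
  eval_idx <- seq_len(nrow(images)) > eval_from
  if (!any(eval_idx)) {
    return(list(classifier = fit$classifier, confusion = NULL,
                metrics = NULL, n_eval = 0L, empty_evaluation = TRUE,
                shortfall = fit$shortfall))
  }
  pred <- dnn_predict(fit$classifier, images[eval_idx, , drop = FALSE])
  cm <- confusion_matrix(labels[eval_idx], pred)
  list(classifier = fit$classifier, confusion = cm,
       metrics = classification_metrics(cm), n_eval = sum(eval_idx),
       empty_evaluation = FALSE, shortfall = fit$shortfall)
}

#' Adaptation-curve experiment on a synthetic cohort
#'
#' End-to-end surrogate of the patient-adaptation study: generates a cohort
#' with inter-patient morphology variability, pretrains and fine-tunes an
#' interpatient classifier on the training patients, then adapts it to each
#' test patient using increasing numbers of initial beats and evaluates on
#' a fixed held-out tail (the beats after the largest adaptation count).
#'
#' @param n_patients cohort size; the first half are training patients.
#' @param beats_per_patient beats per record.
#' @param n_adapt_grid adaptation-beat counts to evaluate (0 = interpatient).
#' @param config a [pipeline_config()]; its `n_adapt` is overridden by the
#'   grid. Defaults to a reduced-scale configuration (24 x 32 images, one
#'   64-unit layer) suitable for desk-scale runs.
#' @param patient_shift_sd inter-patient template variability, see
#'   [synth_cohort()].
#' @param seed integer seed for the whole experiment.
#' @return list with `results` (data frame: `n_adapt`, `patient`,
#'   `accuracy`), `mean_accuracy` (named by adaptation count),
#'   `interpatient_history`.
#' @export
run_adaptation_experiment <- function(n_patients = 10,
                                      beats_per_patient = 400,
                                      n_adapt_grid = c(0, 40, 80, 160, 300),
                                      config = NULL,
                                      patient_shift_sd = 0.3,
                                      seed = 1) {
  if (is.null(config)) {
    config <- pipeline_config(n_freq = 24, n_time = 32,
                              sda_layer_sizes = c(64), sda_epochs = 15)
  }
  set.seed(seed)
  cohort <- synth_cohort(n_patients = n_patients,
                         beats_per_patient = beats_per_patient,
                         patient_shift_sd = patient_shift_sd)
  prepped <- lapply(cohort, record_to_images, config = config)
  known <- lapply(prepped, function(p) {
    keep <- p$labels != "unknown"
    list(images = p$images[keep, , drop = FALSE], labels = p$labels[keep],
         patient_id = p$patient_id)
  })
  train_idx <- seq_len(n_patients %/% 2)
  train_images <- do.call(rbind, lapply(known[train_idx], `[[`, "images"))
  train_labels <- unlist(lapply(known[train_idx], `[[`, "labels"))

  set.seed(seed + 1L)
  sda <- sda_pretrain(train_images, config$sda_layer_sizes, P = config$sda_P,
                      lr = config$sda_lr, epochs = config$sda_epochs,
                      batch_size = config$sda_batch)
  set.seed(seed + 2L)
  inter <- dnn_fine_tune(dnn_from_sda(sda), train_images, train_labels,
                         lr = config$dnn_lr, epochs = config$dnn_epochs,
                         batch_size = config$dnn_batch)

  eval_from <- max(n_adapt_grid)
  rows <- list()
  for (pi in setdiff(seq_len(n_patients), train_idx)) {
    pat <- known[[pi]]
    eval_idx <- seq_along(pat$labels) > eval_from
    for (na in n_adapt_grid) {
      set.seed(seed + 1000L + 17L * pi + na)
      fit <- patient_adapt(inter$classifier, pat$images, pat$labels,
                           n_adapt = na, lr = config$dnn_lr,
                           batch_size = config$dnn_batch,
                           patience = config$patience,
                           max_iter = config$max_iter)
      pred <- dnn_predict(fit$classifier,
                          pat$images[eval_idx, , drop = FALSE])
      rows[[length(rows) + 1]] <- data.frame(
        n_adapt = na, patient = pat$patient_id,
        accuracy = mean(pred == pat$labels[eval_idx])
      )
    }
  }
  results <- do.call(rbind, rows)
  mean_acc <- tapply(results$accuracy, results$n_adapt, mean)
  list(results = results, mean_accuracy = mean_acc,
       interpatient_history = inter$history)
}

#' Persist a model with a manifest
#'
#' Writes the model arrays and a manifest (model type, dimensions, stage,
#' seed and configuration) as a single JSON file with full numeric
#' precision.
#'
#' @param model an `sda_model` or `dnn_classifier`.
#' @param path output file path.
#' @param config optional [pipeline_config()] recorded in the manifest.
#' @param stage optional training stage recorded in the manifest.
#' @return invisibly, `path`.
#' @export
save_model <- function(model, path, config = NULL, stage = NULL) {
  type <- if (inherits(model, "sda_model")) "sda_model" else
    if (inherits(model, "dnn_classifier")) "dnn_classifier" else
      stop("unsupported model class", call. = FALSE)
  manifest <- list(type = type, stage = stage,
                   seed = if (!is.null(config)) config$seed,
                   config = if (!is.null(config)) unclass(config))
  model <- unclass(model)
  model$layers <- lapply(model$layers, unclass)
  payload <- list(manifest = manifest, model = model)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path file path.
#' @return the restored `sda_model` or `dnn_classifier` with the manifest
#'   attached as attribute `"manifest"`.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  m <- payload$model
  as_matrix <- function(x) do.call(rbind, lapply(x, unlist))
  as_num <- function(x) as.numeric(unlist(x))
  if (payload$manifest$type == "sda_model") {
    layers <- lapply(m$layers, function(l) {
      structure(list(W = as_matrix(l$W), b = as_num(l$b),
                     b_prime = as_num(l$b_prime), P = l$P),
                class = "dae_layer")
    })
    out <- structure(
      list(layers = layers, input_dim = m$input_dim,
           loss_histories = lapply(m$loss_histories, as_num)),
      class = "sda_model"
    )
  } else {
    layers <- lapply(m$layers, function(l) {
      list(W = as_matrix(l$W), b = as_num(l$b))
    })
    out <- structure(
      list(layers = layers, softmax_W = as_matrix(m$softmax_W),
           softmax_b = as_num(m$softmax_b),
           classes = as.character(unlist(m$classes)),
           input_dim = m$input_dim),
      class = "dnn_classifier"
    )
  }
  attr(out, "manifest") <- payload$manifest
  out
}
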