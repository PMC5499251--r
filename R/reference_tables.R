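# Published reference confusion matrices for this architecture on the
# MIT-BIH arrhythmia database test split, bundled for regression-testing the
# metric computations against the reported percentages.

.reference_data <- function() {
  cls <- aami_classes()
  inter <- matrix(
    c(41873, 300, 947, 810,
      1520, 282, 9, 25,
      1240, 13, 1943, 23,
      376, 1, 9, 2),
    nrow = 4, byrow = TRUE, dimnames = list(true = cls, predicted = cls)
  )
  patient <- matrix(
    c(37622, 68, 175, 119,
      448, 1143, 7, 3,
      106, 0, 2644, 85,
      52, 0, 9, 292),
    nrow = 4, byrow = TRUE, dimnames = list(true = cls, predicted = cls)
  )
  list(
    interpatient = list(
      confusion = inter,
      reported = list(
        SE = c(N = 95.3, S = 15.4, V = 60.4, F = 0.5),
        PPV = c(N = 93.0, S = 47.3, V = 66.8, F = 0.2),
        overall_accuracy = 89.3
      )
    ),
    patient_specific = list(
      confusion = patient,
      reported = list(
        SE = c(N = 99.0, S = 71.4, V = 93.3, F = 82.7),
        PPV = c(N = 98.4, S = 94.4, V = 93.3, F = 58.5),
        overall_accuracy = 97.5,
        ACC = c(S = 98.8, V = 99.1),
        g_mean_se = 85.9,
        g_mean_ppv = 84.4
      )
    )
  )
}

#' Bundled reference confusion matrix
#'
#' The published MIT-BIH test-split confusion matrices of this
#' architecture: the interpatient classifier evaluated on the full testing
#' set, and the patient-specific classifier evaluated on the testing set
#' excluding each record's first 300 beats.
#'
#' @param scenario `"interpatient"` or `"patient_specific"`.
#' @return 4 x 4 integer confusion matrix (true rows, predicted columns).
#' @export
reference_confusion <- function(scenario = c("patient_specific",
                                             "interpatient")) {
  scenario <- match.arg(scenario)
  .reference_data()[[scenario]]$confusion
}

#' Recompute the reference-table metrics and compare to the reported values
#'
#' Recomputes every per-class sensitivity and positive predictive value,
#' the overall accuracies, the class-wise accuracies of S and V, and the
#' geometric means from the bundled reference confusion counts, and diffs
#' them against the percentages reported alongside those tables.
#'
#' @return data frame with columns `scenario`, `metric`, `computed`
#'   (rounded half-up to one decimal), `reported`, `diff`.
#' @export
report_reference_tables <- function() {
  ref <- .reference_data()
  rows <- list()
  for (scenario in names(ref)) {
    m <- classification_metrics(ref[[scenario]]$confusion)
    rep_ <- ref[[scenario]]$reported
    add <- function(metric, computed, reported) {
      rows[[length(rows) + 1]] <<- data.frame(
        scenario = scenario, metric = metric,
        computed = round_half_up(computed, 1), reported = reported
      )
    }
    for (cl in aami_classes()) {
      add(paste0("SE_", cl), m$per_class$SE[m$per_class$class == cl],
          rep_$SE[[cl]])
      add(paste0("PPV_", cl), m$per_class$PPV[m$per_class$class == cl],
          rep_$PPV[[cl]])
    }
    add("overall_accuracy", m$overall_accuracy, rep_$overall_accuracy)
    if (!is.null(rep_$ACC)) {
      for (cl in names(rep_$ACC)) {
        add(paste0("ACC_", cl), m$per_class$ACC[m$per_class$class == cl],
            rep_$ACC[[cl]])
      }
    }
    if (!is.null(rep_$g_mean_se)) add("g_mean_SE", m$g_mean_se, rep_$g_mean_se)
    if (!is.null(rep_$g_mean_ppv)) {
      add("g_mean_PPV", m$g_mean_ppv, rep_$g_mean_ppv)
    }
  }
  out <- do.call(rbind, rows)
  out$diff <- out$computed - out$reported
  out
}
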