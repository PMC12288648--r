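#' AUROC of a hard binary predictor
#'
#' The pipeline emits hard labels, not scores, so the ROC curve induced by a
#' binary predictor has three points: (0,0), (1-specificity, sensitivity),
#' (1,1). Its trapezoidal area is exactly (sensitivity + specificity)/2 —
#' the balanced accuracy. Both classes must be present in the truth or the
#' metric is undefined.
#'
#' @param pred,truth logical vectors (or coercible 0/1) of predictions and
#'   ground truth.
#' @return AUROC in `[0, 1]`.
#' @examples
#' binary_prediction_auroc(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
#' @export
binary_prediction_auroc <- function(pred, truth) {
  pred <- as.logical(pred)
  truth <- as.logical(truth)
  stopifnot(length(pred) == length(truth), !anyNA(pred), !anyNA(truth))
  if (all(truth) || !any(truth)) {
    rlang::abort("AUROC undefined: truth contains a single class",
      class = "resppheno_undefined_metric"
    )
  }
  sens <- sum(pred & truth) / sum(truth)
  spec <- sum(!pred & !truth) / sum(!truth)
  (sens + spec) / 2
}

#' One-vs-rest metrics for a phenotype class
#'
#' Binarises predictions and truth on membership in `cls` and computes the
#' confusion-table metrics. Classes with no true members are reported as
#' not-applicable (NA metrics) rather than 0 or 1.
#'
#' @param pred_labels,true_labels character vectors of phenotype labels.
#' @param cls the class to score.
#' @return One-row tibble: `class`, `n_true`, `n_predicted`, `auroc`,
#'   `sensitivity`, `specificity`.
#' @export
one_vs_rest_metrics <- function(pred_labels, true_labels, cls) {
  stopifnot(length(pred_labels) == length(true_labels))
  pred <- pred_labels == cls
  truth <- true_labels == cls
  n_true <- sum(truth)
  n_pred <- sum(pred)
  if (n_true == 0 || n_true == length(truth)) {
    return(tibble::tibble(
      class = cls, n_true = n_true, n_predicted = n_pred,
      auroc = NA_real_, sensitivity = NA_real_, specificity = NA_real_
    ))
  }
  sens <- sum(pred & truth) / n_true
  spec <- sum(!pred & !truth) / sum(!truth)
  tibble::tibble(
    class = cls, n_true = n_true, n_predicted = n_pred,
    auroc = (sens + spec) / 2, sensitivity = sens, specificity = spec
  )
}

#' Unweighted macro-average AUROC
#'
#' @param aurocs numeric vector of per-class AUROCs (non-empty; NAs from
#'   not-applicable classes may be removed with `na.rm`).
#' @param na.rm drop NA entries before averaging.
#' @return The unweighted arithmetic mean (report to 3 decimals).
#' @examples
#' macro_average_auroc(c(0.881, 0.809, 0.825, 0.896)) # 0.85275 -> 0.853
#' @export
macro_average_auroc <- function(aurocs, na.rm = FALSE) {
  if (na.rm) aurocs <- aurocs[!is.na(aurocs)]
  if (length(aurocs) == 0) {
    rlang::abort("macro_average_auroc needs at least one AUROC",
      class = "resppheno_undefined_metric"
    )
  }
  mean(aurocs)
}

#' Summarise response latencies
#'
#' @param decisions a tibble with columns `prompt` (prompt/task name) and
#'   `latency_seconds`.
#' @return Tibble of per-prompt means plus a pooled `"overall"` row
#'   (`prompt`, `n_calls`, `mean_latency_seconds`).
#' @export
latency_summary <- function(decisions) {
  stopifnot(all(decisions$latency_seconds >= 0))
  per <- decisions |>
    dplyr::summarise(
      n_calls = dplyr::n(),
      mean_latency_seconds = mean(.data$latency_seconds),
      .by = "prompt"
    )
  dplyr::bind_rows(per, tibble::tibble(
    prompt = "overall",
    n_calls = nrow(decisions),
    mean_latency_seconds = mean(decisions$latency_seconds)
  ))
}

# phenotype groups used for macro-average reporting
phenotype_groups <- function() {
  list(
    single_or_none = c("IMV Only", "NIPPV Only", "HFNI Only", "None"),
    multi_therapy = c("NIPPV Failure", "HFNI Failure", "IMV to NIPPV", "IMV to HFNI")
  )
}

#' Evaluate predicted phenotypes against ground truth
#'
#' Computes one-vs-rest AUROC, sensitivity and specificity for each of the
#' eight phenotype classes, unweighted macro-average AUROCs for the
#' single-therapy/no-therapy group (IMV/NIPPV/HFNI Only, None) and the
#' multi-therapy group (the failure and transition sequences), overall
#' agreement, and optional latency summaries.
#'
#' @param data a data frame holding predictions and truth, one row per
#'   evaluated encounter.
#' @param truth,estimate columns of `data` (tidy-eval) with true and
#'   predicted labels.
#' @param latencies optional tibble passed to [latency_summary()].
#' @return A `phenotype_eval` object; see [tidy.phenotype_eval()],
#'   [glance.phenotype_eval()] and [autoplot.phenotype_eval()].
#' @examples
#' df <- data.frame(truth = c("None", "IMV Only", "None"), pred = c("None", "IMV Only", "None"))
#' evaluate_phenotypes(df, truth, pred)
#' @export
evaluate_phenotypes <- function(data, truth, estimate, latencies = NULL) {
  true_labels <- dplyr::pull(data, {{ truth }})
  pred_labels <- dplyr::pull(data, {{ estimate }})
  per_class <- purrr::map_dfr(
    phenotype_levels(),
    ~ one_vs_rest_metrics(pred_labels, true_labels, .x)
  )
  groups <- phenotype_groups()
  macro <- purrr::imap_dfr(groups, function(classes, name) {
    a <- per_class$auroc[per_class$class %in% classes]
    tibble::tibble(
      group = name,
      n_classes = sum(!is.na(a)),
      macro_auroc = if (all(is.na(a))) NA_real_ else macro_average_auroc(a, na.rm = TRUE)
    )
  })
  structure(
    list(
      per_class = per_class,
      macro = macro,
      agreement = mean(pred_labels == true_labels),
      n = length(true_labels),
      latency = if (!is.null(latencies)) latency_summary(latencies)
    ),
    class = "phenotype_eval"
  )
}

#' @export
print.phenotype_eval <- function(x, ...) {
  cat("Phenotype evaluation over", x$n, "encounters\n")
  cat(sprintf("Agreement with truth: %.1f%%\n\n", 100 * x$agreement))
  tab <- dplyr::mutate(x$per_class, dplyr::across(
    c("auroc", "sensitivity", "specificity"), ~ round(.x, 3)
  ))
  print(as.data.frame(tab), row.names = FALSE)
  cat("\nMacro-average AUROC (unweighted):\n")
  m <- dplyr::mutate(x$macro, macro_auroc = round(.data$macro_auroc, 3))
  print(as.data.frame(m), row.names = FALSE)
  if (!is.null(x$latency)) {
    cat("\nLatency (seconds):\n")
    print(as.data.frame(x$latency), row.names = FALSE)
  }
  invisible(x)
}

#' Tidy a phenotype evaluation
#'
#' @param x a `phenotype_eval` object.
#' @param ... unused.
#' @return `tidy()` returns the per-class metric tibble; `glance()` a one-row
#'   summary with agreement and the two macro-average AUROCs.
#' @method tidy phenotype_eval
#' @export
tidy.phenotype_eval <- function(x, ...) {
  x$per_class
}

#' @rdname tidy.phenotype_eval
#' @method glance phenotype_eval
#' @export
glance.phenotype_eval <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    agreement = x$agreement,
    macro_auroc_single_or_none = x$macro$macro_auroc[x$macro$group == "single_or_none"],
    macro_auroc_multi_therapy = x$macro$macro_auroc[x$macro$group == "multi_therapy"]
  )
}

#' @rdname tidy.phenotype_eval
#' @param object a `phenotype_eval` object.
#' @return `autoplot()` returns a ggplot of per-class AUROC, sensitivity and
#'   specificity.
#' @method autoplot phenotype_eval
#' @export
autoplot.phenotype_eval <- function(object, ...) {
  df <- object$per_class |>
    tidyr::pivot_longer(
      c("auroc", "sensitivity", "specificity"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::mutate(class = factor(.data$class, levels = phenotype_levels()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
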