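#' k-mer spectrum features
#'
#' Represents each sequence by the frequency of every possible k-mer:
#' sliding-window counts over the `len - k + 1` windows, divided by the
#' window count, in lexicographic A<C<G<T column order. Windows containing
#' ambiguous bases are skipped (so rows containing `N`s sum to less than
#' one).
#'
#' @param sequences Character vector of DNA sequences (optionally named),
#'   or a data frame with `element_id` and `sequence`.
#' @param k Word size (default 4).
#' @returns Numeric matrix, one row per sequence, `4^k` named columns.
#' @export
kmer_features <- function(sequences, k = 4L) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(as.character(sequences$sequence),
                          as.character(sequences$element_id))
  }
  stopifnot(k >= 1L)
  if (any(nchar(sequences) < k)) {
    stop(sprintf("all sequences must be at least %d nt for k = %d", k, k),
         call. = FALSE)
  }
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(sequences), width = k
  )
  freq <- counts / (nchar(sequences) - k + 1L)
  rownames(freq) <- names(sequences)
  freq
}

#' Select extreme-activity elements for classification
#'
#' Labels the `n_per_tail` highest- and lowest-activity elements as
#' `high` / `low`; ties at either boundary are broken by `element_id` so
#' the selection is deterministic.
#'
#' @param activity Tibble with `element_id` and `estimate` (e.g. from
#'   [quantify()]).
#' @param n_per_tail Elements per tail (default 200).
#' @returns Tibble: `element_id`, `activity`, `label` (factor low < high).
#' @export
select_extremes <- function(activity, n_per_tail = 200L) {
  activity <- activity[is.finite(activity$estimate), ]
  if (nrow(activity) < 2L * n_per_tail) {
    stop(sprintf("need at least %d elements with finite activity, have %d",
                 2L * n_per_tail, nrow(activity)), call. = FALSE)
  }
  high <- activity |>
    dplyr::arrange(dplyr::desc(.data$estimate), .data$element_id) |>
    head(n_per_tail)
  low <- activity |>
    dplyr::arrange(.data$estimate, .data$element_id) |>
    head(n_per_tail)
  if (any(high$element_id %in% low$element_id)) {
    stop("tails overlap: too few distinct elements", call. = FALSE)
  }
  dplyr::bind_rows(
    dplyr::mutate(low, label = "low"),
    dplyr::mutate(high, label = "high")
  ) |>
    dplyr::mutate(
      label = factor(.data$label, levels = c("low", "high")),
      activity = .data$estimate
    ) |>
    dplyr::select("element_id", "activity", "label")
}

# Seeded stratified fold assignment preserving class balance per fold.
stratified_folds <- function(labels, folds) {
  assignment <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds) {
      stop(sprintf("class '%s' has fewer members (%d) than folds (%d)",
                   cl, length(idx), folds), call. = FALSE)
    }
    assignment[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assignment
}

# Average precision (step-interpolated area under the precision-recall
# curve), computed from scores for the positive class.
average_precision <- function(labels, scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  y <- as.integer(labels[ord] == positive)
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  recall <- tp / sum(y)
  sum(diff(c(0, recall)) * precision)
}

# AUROC from scores (higher score should indicate the positive class).
auroc <- function(labels, scores, positive) {
  as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c(setdiff(levels(labels), positive), positive),
    direction = "<", quiet = TRUE
  )))
}

#' Train a k-mer SVM classifier with stratified cross-validation
#'
#' Fits a linear-kernel soft-margin SVM (cost 1) on standardized k-mer
#' spectrum features to separate high- from low-activity elements, with
#' seeded stratified cross-validation; reports per-fold and pooled
#' held-out AUROC and AUPRC. With `permute_labels = TRUE` the labels are
#' shuffled once before folding, providing the chance-level reference.
#' A final model on all data is kept for [score_kmers()].
#'
#' @param labelled Tibble from [select_extremes()] (`element_id`, `label`).
#' @param sequences Named character vector (or `element_id`/`sequence`
#'   data frame) supplying the element sequences.
#' @param k Word size (default 4).
#' @param folds Cross-validation folds (default 5).
#' @param permute_labels Shuffle labels before folding (default `FALSE`).
#' @param cost Soft-margin cost parameter (default 1).
#' @param seed Integer seed for folding (and permutation).
#' @returns List of class `mpra_cv`: `metrics` (per fold), `mean_auroc`,
#'   `mean_auprc`, `pooled_auroc`, `pooled_auprc`, `scores` (held-out
#'   decision values), `folds`, `label_mode`, `model`, `center`, `scale`,
#'   `k`.
#' @export
train_classifier <- function(labelled, sequences, k = 4L, folds = 5L,
                             permute_labels = FALSE, cost = 1, seed = NULL) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(as.character(sequences$sequence),
                          as.character(sequences$element_id))
  }
  missing_seq <- setdiff(labelled$element_id, names(sequences))
  if (length(missing_seq)) {
    stop(sprintf("no sequence for %d labelled element(s)", length(missing_seq)),
         call. = FALSE)
  }
  labels <- factor(labelled$label)
  if (nlevels(labels) != 2L) stop("need exactly two classes", call. = FALSE)
  positive <- levels(labels)[2L]

  X <- kmer_features(sequences[labelled$element_id], k = k)
  center <- colMeans(X)
  scale_ <- apply(X, 2L, sd)
  scale_[scale_ == 0] <- 1
  Xs <- scale(X, center = center, scale = scale_)

  with_seed(seed, {
    if (permute_labels) labels <- sample(labels)
    fold_id <- stratified_folds(labels, folds)

    held_scores <- numeric(length(labels))
    metrics <- purrr::map_dfr(seq_len(folds), function(f) {
      test <- fold_id == f
      fit <- e1071::svm(Xs[!test, , drop = FALSE], labels[!test],
                        kernel = "linear", cost = cost, scale = FALSE)
      sc <- svm_scores(fit, Xs[test, , drop = FALSE], positive)
      held_scores[test] <<- sc
      tibble::tibble(
        fold = f,
        auroc = auroc(labels[test], sc, positive),
        auprc = average_precision(labels[test], sc, positive)
      )
    })

    final <- e1071::svm(Xs, labels, kernel = "linear", cost = cost,
                        scale = FALSE)
    structure(
      list(
        metrics = metrics,
        mean_auroc = mean(metrics$auroc),
        mean_auprc = mean(metrics$auprc),
        pooled_auroc = auroc(labels, held_scores, positive),
        pooled_auprc = average_precision(labels, held_scores, positive),
        scores = tibble::tibble(
          element_id = labelled$element_id, label = labels,
          fold = fold_id, score = held_scores
        ),
        folds = fold_id,
        label_mode = if (permute_labels) "permuted" else "true",
        model = final, center = center, scale = scale_,
        positive = positive, k = k
      ),
      class = "mpra_cv"
    )
  })
}

# Decision scores oriented so larger = more `positive`.
svm_scores <- function(fit, X, positive) {
  pred <- stats::predict(fit, X, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  sc <- dv[, 1L]
  # e1071 orients decision values toward the first class in the colname
  first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  if (!identical(first, positive)) sc <- -sc
  unname(sc)
}

#' @export
print.mpra_cv <- function(x, ...) {
  cat(sprintf(
    "<mpra_cv> %d-mer SVM, %d-fold CV (%s labels): mean AUROC %.3f, mean AUPRC %.3f\n",
    x$k, max(x$folds), x$label_mode, x$mean_auroc, x$mean_auprc
  ))
  invisible(x)
}

#' @method tidy mpra_cv
#' @export
tidy.mpra_cv <- function(x, ...) x$metrics

#' @method glance mpra_cv
#' @export
glance.mpra_cv <- function(x, ...) {
  tibble::tibble(
    k = x$k, folds = max(x$folds), label_mode = x$label_mode,
    mean_auroc = x$mean_auroc, mean_auprc = x$mean_auprc,
    pooled_auroc = x$pooled_auroc, pooled_auprc = x$pooled_auprc
  )
}

#' @method autoplot mpra_cv
#' @export
autoplot.mpra_cv <- function(object, ...) {
  curves <- object$scores |>
    dplyr::group_by(.data$fold) |>
    dplyr::group_modify(function(df, key) {
      r <- pROC::roc(df$label, df$score,
                     levels = c(setdiff(levels(df$label), object$positive),
                                object$positive),
                     direction = "<", quiet = TRUE)
      tibble::tibble(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr,
                                       group = .data$fold)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("%d-mer SVM held-out ROC (mean AUROC %.3f)",
                      object$k, object$mean_auroc)
    ) +
    ggplot2::theme_minimal()
}

#' Score all k-mers against a trained classifier
#'
#' Encodes each of the `4^k` possible k-mers as its own (one-hot) k-mer
#' frequency vector, standardizes it with the training parameters, and
#' passes it through the fitted decision function. High scores mark words
#' the classifier associates with high activity.
#'
#' @param fit An `mpra_cv` from [train_classifier()].
#' @returns Tibble (`kmer`, `score`), sorted by descending score.
#' @export
score_kmers <- function(fit) {
  stopifnot(inherits(fit, "mpra_cv"))
  kmers <- names(fit$center)
  X <- diag(length(kmers))
  colnames(X) <- kmers
  rownames(X) <- kmers
  Xs <- scale(X, center = fit$center, scale = fit$scale)
  tibble::tibble(
    kmer = kmers,
    score = svm_scores(fit$model, Xs, fit$positive)
  ) |>
    dplyr::arrange(dplyr::desc(.data$score))
}
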