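#' Load labeled evaluation records
#'
#' Reads a CSV or JSON file of evaluation rows: `district`, `dominant_crop`
#' (the reference label) and `predicted_crops`, a semicolon-separated ranked
#' crop list (rank 1 first).
#'
#' @param path CSV or JSON file path.
#' @return a tibble with `district`, `dominant_crop` and a list-column
#'   `predicted_crops`.
#' @export
load_records <- function(path) {
  if (!file.exists(path)) stop("no such records file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  need <- c("district", "dominant_crop", "predicted_crops")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("records file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.list(df$predicted_crops)) {
    df$predicted_crops <- strsplit(as.character(df$predicted_crops), ";",
                                   fixed = TRUE)
  }
  df$predicted_crops <- purrr::map(df$predicted_crops, trimws)
  if (any(lengths(df$predicted_crops) == 0)) {
    stop("every record needs a non-empty predicted crop list", call. = FALSE)
  }
  tibble::as_tibble(df[, need])
}

#' Top-1 match indicator
#'
#' 1 iff the first-ranked predicted crop equals the dominant (reference)
#' crop; this is the 0/1 "Result" convention of the dominant-crop
#' comparison.
#'
#' @param records record tibble (see [load_records()]).
#' @return integer vector of 0/1 per record.
#' @export
top1_match <- function(records) {
  as.integer(purrr::map_chr(records$predicted_crops, 1) ==
               records$dominant_crop)
}

#' Confusion matrix of dominant vs top-1 predicted crop
#'
#' Rows are true (dominant) labels, columns the top-1 predictions; the label
#' set is the union of observed labels in canonical crop order (unknown
#' names appended alphabetically).
#'
#' @param records record tibble.
#' @return a `crop_confusion` object: integer matrix with `labels`
#'   attribute.
#' @export
confusion_matrix <- function(records) {
  if (nrow(records) == 0) stop("no records to evaluate", call. = FALSE)
  truth <- records$dominant_crop
  pred <- purrr::map_chr(records$predicted_crops, 1)
  seen <- union(truth, pred)
  canon <- intersect(crop_canon(), seen)
  labels <- c(canon, sort(setdiff(seen, canon)))
  cm <- matrix(0L, length(labels), length(labels),
               dimnames = list(truth = labels, predicted = labels))
  for (i in seq_along(truth)) {
    cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  }
  structure(cm, class = c("crop_confusion", "matrix", "array"))
}

#' @export
print.crop_confusion <- function(x, ...) {
  cat("<crop_confusion> rows = truth, cols = top-1 prediction\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class classification report
#'
#' For each class: `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `f1 = 2 * precision * recall / (precision + recall)`, with any 0/0
#' quotient defined as 0. Overall accuracy is the diagonal sum over the
#' total.
#'
#' @param cm a `crop_confusion` matrix.
#' @return a `class_report`: tibble with `crop`, `precision`, `recall`,
#'   `f1`, `support`, carrying `accuracy`, `match_count` and `total`
#'   attributes (see [glance.class_report()]).
#' @export
classification_report <- function(cm) {
  stopifnot(inherits(cm, "crop_confusion"))
  m <- unclass(cm)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  out <- tibble::tibble(
    crop = rownames(m),
    precision = unname(precision),
    recall = unname(recall),
    f1 = unname(f1),
    support = unname(as.integer(rowSums(m)))
  )
  structure(out,
            accuracy = sum(tp) / sum(m),
            match_count = as.integer(sum(tp)),
            total = as.integer(sum(m)),
            macro_precision = mean(precision),
            macro_recall = mean(recall),
            macro_f1 = mean(f1),
            class = c("class_report", class(out)))
}

#' Evaluate ranked predictions against the dominant-crop reference
#'
#' Combines the top-1 match list, confusion matrix and classification
#' report, and additionally reports the fraction of records whose dominant
#' crop appears anywhere in the top-`k` prediction list (dominant crops
#' sometimes sit at the second or third rank; this is reported separately
#' and never mixed into accuracy).
#'
#' @param records record tibble (see [load_records()]).
#' @param k rank depth for the top-k hit rate (default 1).
#' @return a `crop_eval` list: `report` (the [classification_report()]),
#'   `confusion` (the matrix), `matches` (per-record tibble with `match`
#'   and `topk_hit`), `match_count`, `accuracy`, `topk_hit_rate`, `k`.
#' @export
evaluate <- function(records, k = 1) {
  stopifnot(k >= 1)
  cm <- confusion_matrix(records)
  rep <- classification_report(cm)
  match <- top1_match(records)
  topk <- purrr::map2_int(records$predicted_crops, records$dominant_crop,
                          ~ as.integer(.y %in% utils::head(.x, k)))
  structure(list(
    report = rep,
    confusion = cm,
    matches = tibble::tibble(district = records$district,
                             dominant_crop = records$dominant_crop,
                             predicted_top1 = purrr::map_chr(
                               records$predicted_crops, 1),
                             match = match, topk_hit = topk),
    match_count = attr(rep, "match_count"),
    accuracy = attr(rep, "accuracy"),
    topk_hit_rate = mean(topk),
    k = k
  ), class = "crop_eval")
}

#' @export
print.crop_eval <- function(x, ...) {
  cat(sprintf("<crop_eval> %d records: %d top-1 matches (accuracy %.3f), top-%d hit rate %.3f\n",
              attr(x$report, "total"), x$match_count, x$accuracy, x$k,
              x$topk_hit_rate))
  print(tibble::as_tibble(x$report))
  invisible(x)
}

#' Tidy a classification report
#'
#' @param x a `class_report`.
#' @param ... unused.
#' @return the per-class tibble (crop, precision, recall, f1, support).
#' @method tidy class_report
#' @export
tidy.class_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a classification report
#'
#' @param x a `class_report`.
#' @param ... unused.
#' @return tibble with `accuracy`, `match_count`, `total`, macro-averaged
#'   precision/recall/F1.
#' @method glance class_report
#' @export
glance.class_report <- function(x, ...) {
  tibble::tibble(
    accuracy = attr(x, "accuracy"),
    match_count = attr(x, "match_count"),
    total = attr(x, "total"),
    macro_precision = attr(x, "macro_precision"),
    macro_recall = attr(x, "macro_recall"),
    macro_f1 = attr(x, "macro_f1")
  )
}

#' @rdname tidy.class_report
#' @method tidy crop_eval
#' @export
tidy.crop_eval <- function(x, ...) tidy(x$report)

#' @rdname glance.class_report
#' @method glance crop_eval
#' @export
glance.crop_eval <- function(x, ...) {
  dplyr::mutate(glance(x$report), topk_hit_rate = x$topk_hit_rate, k = x$k)
}
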