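#' Label an encoded cohort under one of the two classification schemes
#'
#' `"limb3"` labels each recording by upper-limb type: `HUL` (healthy upper
#' limb, all control recordings), `NPUL` (non-paretic limb of stroke
#' participants) and `PUL` (paretic limb). `"group2"` labels by participant
#' group: `G1` (stroke, both limbs) vs `G2` (control). For the default
#' study-shaped cohort the class sizes are 114/105/105 (limb3) and 210/114
#' (group2).
#'
#' @param encoded an `encoded_cohort` from [encode_cohort()].
#' @param scheme `"limb3"` or `"group2"`.
#' @return an object of class `labeled_dataset`: `images`
#'   (12 x 32 x C x n), `labels` (factor), `meta`, `scheme`, `markers`.
#' @export
label_dataset <- function(encoded, scheme = c("limb3", "group2")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(encoded, "encoded_cohort"))
  meta <- encoded$meta
  n <- nrow(meta)
  if (n) {
    if (any(is.na(meta$role)) || any(is.na(meta$group))) {
      stop_invalid("recording with missing limb role or group")
    }
  }
  labels <- if (scheme == "limb3") {
    out <- character(n)
    out[meta$group == "G2"] <- "HUL"
    out[meta$role == "non-paresis"] <- "NPUL"
    out[meta$role == "paresis"] <- "PUL"
    if (n && any(!nzchar(out))) stop_invalid("recording with missing limb role")
    factor(out, levels = c("HUL", "NPUL", "PUL"))
  } else {
    factor(meta$group, levels = c("G1", "G2"))
  }
  structure(
    list(images = encoded$images, labels = labels, meta = meta,
         scheme = scheme, markers = encoded$markers),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labeled dataset (%s): %d images, depth %d [%s]\n",
              x$scheme, length(x$labels), dim(x$images)[3L],
              paste(x$markers, collapse = ",")))
  print(table(x$labels))
  invisible(x)
}

#' Restrict a labelled dataset to a subset of marker channels
#'
#' Feature rows are min-max normalized per marker and per recording, so
#' subsetting channels of a 4-marker encoding is exactly the encoding of
#' the subset.
#'
#' @param dataset a `labeled_dataset`.
#' @param markers ordered subset of the dataset's markers.
#' @return a `labeled_dataset` with depth `length(markers)`.
#' @export
subset_channels <- function(dataset, markers) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  pos <- match(markers, dataset$markers)
  if (anyNA(pos)) {
    stop_invalid(paste0("markers not in dataset: ",
                        paste(markers[is.na(pos)], collapse = ", ")))
  }
  dataset$images <- dataset$images[, , pos, , drop = FALSE]
  dataset$markers <- markers
  dataset
}

#' The eight marker configurations of the ablation experiment
#'
#' Single markers FN, LEP, MPH, ACR, then the combinations (LEP, MPH),
#' (FN, LEP, MPH), (LEP, MPH, ACR) and all four.
#' @return list of character vectors.
#' @export
default_marker_sets <- function() {
  list("FN", "LEP", "MPH", "ACR",
       c("LEP", "MPH"), c("FN", "LEP", "MPH"), c("LEP", "MPH", "ACR"),
       c("FN", "LEP", "MPH", "ACR"))
}

#' Marker-ablation experiment
#'
#' Re-runs classification with subsets of the four upper-limb markers to
#' localize which body segment carries the discriminative information. The
#' cohort is encoded once with all requested markers; for every marker set
#' the channels are subset, and the CNN plus (optionally) the three flat
#' baselines are trained and evaluated on one frozen train/validation split
#' shared across all rows, so differences between rows reflect marker
#' information rather than split luck.
#'
#' @param cohort a `mocap_cohort`, or a prebuilt `labeled_dataset`
#'   containing every marker used by `marker_sets`.
#' @param scheme `"limb3"` or `"group2"` (ignored when `cohort` is already
#'   labelled).
#' @param marker_sets list of marker subsets (default the eight-row study
#'   matrix).
#' @param hyper a single [hyperparameters()] used for every row, or a list
#'   of one per marker set (e.g. from per-row [optimize_hyperparameters()]).
#' @param group_by,frac,seed split protocol, as in [train_cnn()].
#' @param baselines if `TRUE` also run RF, LSV and LR on each row.
#' @param batch_size CNN mini-batch size.
#' @return an object of class `ablation_report`: a data frame with columns
#'   `markers`, `model`, `auc`, `accuracy`, `precision`, `recall`,
#'   `n_train`, `n_val`.
#' @export
run_ablation <- function(cohort, scheme = c("limb3", "group2"),
                         marker_sets = default_marker_sets(),
                         hyper = hyperparameters(), group_by = NULL,
                         frac = 0.8, seed = 1L, baselines = TRUE,
                         batch_size = 32L) {
  scheme <- match.arg(scheme)
  all_markers <- unique(unlist(marker_sets))
  bad <- setdiff(all_markers, upper_limb_markers())
  if (length(bad)) {
    stop_invalid(paste0("marker sets must be drawn from FN, LEP, MPH, ACR; got ",
                        paste(bad, collapse = ", ")))
  }
  dataset <- if (inherits(cohort, "labeled_dataset")) {
    cohort
  } else {
    label_dataset(encode_cohort(cohort, markers = all_markers), scheme)
  }
  hyper_list <- if (inherits(hyper, "hyperparameters")) {
    rep(list(hyper), length(marker_sets))
  } else {
    stopifnot(length(hyper) == length(marker_sets))
    hyper
  }
  split <- make_split(dataset$labels, dataset_groups(dataset, group_by),
                      frac = frac, seed = seed)
  rows <- list()
  for (s in seq_along(marker_sets)) {
    ms <- marker_sets[[s]]
    ds <- subset_channels(dataset, ms)
    run <- train_cnn(ds, hyper_list[[s]], split = split, seed = seed,
                     batch_size = batch_size)
    add_row <- function(model_name, m) {
      rows[[length(rows) + 1L]] <<- data.frame(
        markers = paste(ms, collapse = ","), model = model_name,
        auc = m$auc, accuracy = m$accuracy, precision = m$precision,
        recall = m$recall, n_train = length(split$train),
        n_val = length(split$val), stringsAsFactors = FALSE
      )
    }
    add_row("CNN", run$metrics)
    if (baselines) {
      for (k in c("RF", "LSV", "LR")) {
        bl <- train_baseline(k, ds, split = split, seed = seed)
        add_row(k, bl$metrics)
      }
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("ablation_report", "data.frame")
  report
}

#' @export
print.ablation_report <- function(x, digits = 4, ...) {
  cat("Marker-ablation report\n")
  y <- as.data.frame(x)
  y[c("auc", "accuracy", "precision", "recall")] <-
    lapply(y[c("auc", "accuracy", "precision", "recall")], round,
           digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}
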