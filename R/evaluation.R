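#' Cross-day identification protocol and one-vs-rest metrics
#'
#' Models are trained on all trials from one recording day and evaluated on
#' the other day, which removes within-session priming/muscle-memory bias.
#' Identification quality is summarized by macro F1 plus one-vs-rest (OvR)
#' AUC, false acceptance rate (FAR) and false rejection rate (FRR), each
#' averaged without weights over classes.  FAR and FRR are derived from the
#' argmax confusion matrix: for balanced test sets this pins the identity
#' mean FAR = mean FRR / (K - 1), which the reported reference tables obey.
#'
#' @name evaluation
NULL

#' Split a manifest by recording day
#'
#' @param manifest manifest data frame.
#' @param train_day,test_day day labels (defaults 1 and 2; swap them to
#'   exchange the splits exactly).
#' @return list with integer row indices `train` and `test`.  Errors,
#'   naming the subjects, if any subject lacks either day.
#' @export
cross_day_split <- function(manifest, train_day = 1, test_day = 2) {
  for (d in c(train_day, test_day)) {
    present <- unique(manifest$subject_id[manifest$day == d])
    missing <- setdiff(unique(manifest$subject_id), present)
    if (length(missing)) {
      stop(sprintf("subject(s) %s have no day-%s recordings",
                   paste(missing, collapse = ", "), d), call. = FALSE)
    }
  }
  list(train = which(manifest$day == train_day),
       test = which(manifest$day == test_day))
}

#' Macro-averaged F1 score
#'
#' Unweighted mean of per-class F1 over the classes present in `true`.
#' A class never predicted (or with no true positives) contributes 0.
#'
#' @param true,pred equal-length label vectors.
#' @return scalar in \[0, 1\].
#' @export
macro_f1 <- function(true, pred) {
  if (length(true) == 0L) stop("empty label vector")
  stopifnot(length(true) == length(pred))
  classes <- levels(factor(true))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

# rank-based ROC AUC (equivalent to the trapezoidal rule on the empirical
# ROC curve, with tied scores contributing 1/2)
binary_auc <- function(scores, positive) {
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' One-vs-rest identification metrics
#'
#' Per class `c`: AUC from score column `c` against binary membership;
#' FAR and FRR from the argmax decision (`FAR = FP / (FP + TN)`,
#' `FRR = FN / (FN + TP)`).  Argmax ties break toward the lowest class
#' index.  Classes with no positive trials are excluded from the AUC mean
#' with a warning.  Means are unweighted over classes.
#'
#' @param true label vector (coercible to the factor levels of `scores`
#'   columns).
#' @param scores n x K matrix of class probabilities (rows sum to 1),
#'   columns named by class.
#' @return list with scalars `auc`, `far`, `frr`, the predicted labels
#'   `pred`, and the `per_class` data frame.
#' @export
ovr_metrics <- function(true, scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2L) stop("need at least 2 classes")
  classes <- colnames(scores)
  if (is.null(classes)) classes <- as.character(seq_len(ncol(scores)))
  true <- as.character(true)
  if (!all(true %in% classes)) {
    stop("true labels outside the score columns: ",
         paste(setdiff(unique(true), classes), collapse = ", "))
  }
  pred <- classes[apply(scores, 1L, which.max)]  # ties -> lowest index
  per <- lapply(seq_along(classes), function(k) {
    cl <- classes[k]
    pos <- true == cl
    tp <- sum(pos & pred == cl)
    fn <- sum(pos & pred != cl)
    fp <- sum(!pos & pred == cl)
    tn <- sum(!pos & pred != cl)
    data.frame(
      class = cl,
      n_pos = sum(pos),
      auc = if (any(pos) && any(!pos)) binary_auc(scores[, k], pos)
            else NA_real_,
      far = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
      frr = if (fn + tp > 0) fn / (fn + tp) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  per <- do.call(rbind, per)
  if (anyNA(per$auc)) {
    warning(sprintf("%d class(es) without positive trials excluded from AUC",
                    sum(is.na(per$auc))))
  }
  list(auc = mean(per$auc, na.rm = TRUE),
       far = mean(per$far, na.rm = TRUE),
       frr = mean(per$frr, na.rm = TRUE),
       pred = pred, per_class = per)
}

parse_modality_string <- function(s) {
  s <- tolower(trimws(s))
  parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
  cutoff <- if (length(parts) > 1L) as.numeric(parts[2L]) else NULL
  sets <- toupper(strsplit(parts[1L], "+", fixed = TRUE)[[1L]])
  list(sets = sets, cutoff = cutoff)
}

#' Run the model x modality experiment grid
#'
#' For every (model family, modality) cell: assemble features (branched
#' 100 x 3 pairs for the multi-input family, stacked 128 x 3k otherwise),
#' z-score on the training day, train `reps` independently seeded
#' repetitions, and score the held-out day.  Modalities are strings such as
#' `"pos+euler"`, `"acc+gyro"`, `"acc+gyro:3"`, `"acc+gyro:6"` (the suffix
#' is the low-pass cutoff in Hz).
#'
#' @param manifest manifest data frame (with `base_dir` attribute or
#'   `base_dir` given).
#' @param models character vector of model families (short names
#'   `"vanilla"`, `"attention"`, `"multi_input"` accepted).
#' @param modalities character vector of modality strings.
#' @param cfg a [train_config()]; `cfg$repetitions` repetitions per cell
#'   unless `reps` overrides it.
#' @param seed master seed; repetition r of every cell uses `seed + r`.
#' @param reps optional repetition-count override.
#' @param base_dir recordings directory.
#' @param train_day,test_day passed to [cross_day_split()].
#' @param out_csv optional path; the tidy per-repetition table is written
#'   there as CSV.
#' @return tidy data frame with one row per (model, modality, repetition):
#'   columns `model, modality, cutoff, repetition, f1, auc, far, frr`.
#'   A failing cell yields NA metric rows (with a warning) rather than
#'   aborting the grid.
#' @export
run_experiment_grid <- function(manifest, models, modalities,
                                cfg = train_config(), seed = 1,
                                reps = cfg$repetitions, base_dir = NULL,
                                train_day = 1, test_day = 2,
                                out_csv = NULL) {
  models <- vapply(models, canonical_family, "")
  split <- cross_day_split(manifest, train_day, test_day)
  rows <- list()
  cache <- new.env(parent = emptyenv())
  for (fam in models) {
    for (mstr in modalities) {
      mod <- parse_modality_string(mstr)
      layout <- if (fam == "multi_input_cnn") "branched" else "stacked"
      key <- paste(layout, mstr)
      feats <- tryCatch({
        if (is.null(cache[[key]])) {
          mc <- modality_config(mod$sets, lowpass_cutoff = mod$cutoff,
                                layout = layout)
          cache[[key]] <- assemble_features(manifest, mc,
                                            base_dir = base_dir)
        }
        normalize_features(cache[[key]], split$train)
      }, error = function(e) e)
      for (r in seq_len(reps)) {
        res <- if (inherits(feats, "error")) feats else tryCatch({
          run_one(feats, fam, split, cfg, seed + r)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          warning(sprintf("cell (%s, %s) rep %d failed: %s",
                          fam, mstr, r, conditionMessage(res)))
          res <- list(f1 = NA_real_, auc = NA_real_, far = NA_real_,
                      frr = NA_real_)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          model = fam, modality = paste(mod$sets, collapse = "+"),
          cutoff = if (is.null(mod$cutoff)) NA_real_ else mod$cutoff,
          repetition = r, f1 = res$f1, auc = res$auc, far = res$far,
          frr = res$frr, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

canonical_family <- function(m) {
  m <- tolower(m)
  if (m %in% c("vanilla", "vanilla_cnn", "cnn")) return("vanilla_cnn")
  if (m %in% c("attention", "attention_cnn")) return("attention_cnn")
  if (m %in% c("multi_input", "multi-input", "multi_input_cnn")) {
    return("multi_input_cnn")
  }
  stop("unknown model family: ", m)
}

# one repetition of one grid cell
run_one <- function(feats, family, split, cfg, rep_seed) {
  tr <- subset_features(feats, split$train)
  te <- subset_features(feats, split$test)
  if (family == "multi_input_cnn") {
    if (length(tr$branches) != 2L) {
      stop("multi_input_cnn needs a 2-set branched modality")
    }
    shape <- lapply(tr$branches, function(b) dim(b)[2:3])
  } else {
    shape <- dim(tr$x)[2:3]
  }
  spec <- model_spec(family, shape, n_classes = nlevels(droplevels(tr$labels)),
                     seed = rep_seed)
  fitted <- train(build_model(spec), tr, cfg = cfg, seed = rep_seed)
  scores <- predict_scores(fitted, te)
  m <- ovr_metrics(te$labels, scores)
  list(f1 = macro_f1(te$labels, m$pred), auc = m$auc, far = m$far,
       frr = m$frr)
}

#' Aggregate a grid result over repetitions
#'
#' @param grid the tidy table from [run_experiment_grid()].
#' @return one row per (model, modality, cutoff) with repetition means.
#' @export
summarize_grid <- function(grid) {
  key <- paste(grid$model, grid$modality,
               ifelse(is.na(grid$cutoff), "none", grid$cutoff))
  agg <- lapply(split(grid, key), function(g) {
    data.frame(model = g$model[1L], modality = g$modality[1L],
               cutoff = g$cutoff[1L], reps = nrow(g),
               f1 = mean(g$f1), auc = mean(g$auc), far = mean(g$far),
               frr = mean(g$frr), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$model, out$modality, out$cutoff, na.last = TRUE), ]
}
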