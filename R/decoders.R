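#' Leave-one-out accuracy of a linear support-vector classifier
#'
#' Linear-kernel maximum-margin binary classifier (cost fixed at 1, no
#' feature standardisation) under an empirical class prior: each class's
#' misclassification weight is its prior probability divided by its
#' training frequency, which for the empirical prior cancels to uniform
#' observation weights (a plain soft-margin fit — anything else would
#' re-weight the classes away from their observed frequencies). One model
#' is fit per held-out trial; accuracy is the share of correct held-out
#' predictions. A fold whose training set contains a single class predicts
#' that class.
#'
#' @param features Numeric matrix, one row per trial.
#' @param labels Two-level factor/character vector, one per trial.
#' @return Accuracy in \[0, 1\], or `NA` with attribute `reason` when a
#'   class has fewer than 2 trials.
#' @export
loo_svm_accuracy <- function(features, labels) {
  features <- as.matrix(features)
  labels <- factor(labels)
  stopifnot(nrow(features) == length(labels))
  if (nlevels(labels) != 2L || any(table(labels) < 2L)) {
    return(structure(NA_real_, reason = "a class has fewer than 2 trials"))
  }
  n <- nrow(features)
  correct <- logical(n)
  for (i in seq_len(n)) {
    ytr <- droplevels(labels[-i])
    if (nlevels(ytr) == 1L) {
      correct[i] <- levels(ytr) == as.character(labels[i])
      next
    }
    pred <- fit_predict_svm(features[-i, , drop = FALSE], ytr,
                            features[i, , drop = FALSE])
    correct[i] <- pred == as.character(labels[i])
  }
  mean(correct)
}

fit_predict_svm <- function(xtr, ytr, xte) {
  fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = 1, scale = FALSE)
  as.character(stats::predict(fit, xte))
}

# sin/cos feature matrix from a cells x trials angle matrix (degrees);
# undefined angles are zero-imputed.
angle_features <- function(angles, trial_ids) {
  a <- angles[, trial_ids, drop = FALSE] * pi / 180
  s <- sin(a); cc <- cos(a)
  s[is.na(s)] <- 0
  cc[is.na(cc)] <- 0
  feat <- rbind(s, cc)
  t(feat)
}

#' Heading prediction from place-field alignment
#'
#' Predicts the first-dig corner on a geometric axis (C vs G, or N vs F
#' for error trials) from each cell's per-trial center-out angle, encoded
#' as (sin, cos) features (undefined angles zero-imputed), with
#' leave-one-out linear SVM validation. Chance is 50%.
#'
#' @param angles Cells x trials matrix of center-out angles in degrees
#'   (from [session_center_out_angles()]).
#' @param trials Trial metadata with `trial_id` and `dig1`.
#' @param trial_filter The two dig labels defining the classes
#'   (`c("C", "G")` or `c("N", "F")`).
#' @return List with `accuracy`, `n_trials`, `labels`.
#' @export
predict_heading_from_alignment <- function(angles, trials,
                                           trial_filter = c("C", "G")) {
  stopifnot(length(trial_filter) == 2L)
  sel <- trials$trial_id[!is.na(trials$dig1) &
                           trials$dig1 %in% trial_filter]
  labels <- trials$dig1[match(sel, trials$trial_id)]
  feats <- angle_features(angles, sel)
  list(accuracy = loo_svm_accuracy(feats, labels),
       n_trials = length(sel), labels = labels)
}

#' Cross-day heading prediction from registered cells
#'
#' Trains one linear SVM on a training day's C/G trials and predicts every
#' C/G trial of a test day, using only cells active (at least one defined
#' center-out angle) in both sessions — the registered-cell intersection.
#'
#' @param angles_train,angles_test Cells x trials angle matrices for the
#'   two days, with shared cell ids in the row names (the cross-day
#'   identity map).
#' @param trials_train,trials_test Trial metadata for the two days.
#' @param trial_filter Dig labels defining the classes.
#' @return List with `accuracy` (`NA` with `reason` when the registered
#'   intersection is empty or a class is missing), `n_cells`, `n_test`.
#' @export
predict_heading_across_days <- function(angles_train, trials_train,
                                        angles_test, trials_test,
                                        trial_filter = c("C", "G")) {
  common <- intersect(rownames(angles_train), rownames(angles_test))
  active <- common[rowSums(!is.na(angles_train[common, , drop = FALSE])) >
                     0 &
                   rowSums(!is.na(angles_test[common, , drop = FALSE])) > 0]
  if (length(active) == 0L) {
    return(list(accuracy = structure(NA_real_,
                                     reason = "no registered active cells"),
                n_cells = 0L, n_test = 0L))
  }
  sel_tr <- trials_train$trial_id[!is.na(trials_train$dig1) &
                                    trials_train$dig1 %in% trial_filter]
  sel_te <- trials_test$trial_id[!is.na(trials_test$dig1) &
                                   trials_test$dig1 %in% trial_filter]
  y_tr <- factor(trials_train$dig1[match(sel_tr, trials_train$trial_id)],
                 levels = trial_filter)
  y_te <- trials_test$dig1[match(sel_te, trials_test$trial_id)]
  if (nlevels(droplevels(y_tr)) != 2L || length(sel_te) == 0L) {
    return(list(accuracy = structure(NA_real_,
                                     reason = "a class is missing"),
                n_cells = length(active), n_test = length(sel_te)))
  }
  x_tr <- angle_features(angles_train[active, , drop = FALSE], sel_tr)
  x_te <- angle_features(angles_test[active, , drop = FALSE], sel_te)
  pred <- fit_predict_svm(x_tr, droplevels(y_tr), x_te)
  list(accuracy = mean(pred == y_te), n_cells = length(active),
       n_test = length(sel_te))
}

#' Mean-rate matrix for a session
#'
#' Per-cell, per-trial mean firing rate (speed-filtered event weight over
#' speed-filtered time).
#'
#' @param bundle A `session_bundle`.
#' @param speed_cutoff Movement threshold (cm/s).
#' @return Numeric matrix cells x trials.
#' @export
session_mean_rates <- function(bundle, speed_cutoff = 2) {
  trial_ids <- bundle$trials$trial_id
  cell_ids <- bundle$cells$cell_id
  out <- matrix(NA_real_, length(cell_ids), length(trial_ids),
                dimnames = list(cell_ids, trial_ids))
  for (t in trial_ids) {
    traj <- bundle$trajectories[[t]]
    for (cid in cell_ids) {
      out[cid, t] <- trial_rate_stats(bundle$activity[[t]][[cid]], traj,
                                      "mean", speed_cutoff = speed_cutoff)
    }
  }
  out
}

#' Context or heading prediction from mean firing rates
#'
#' Restricts to trials with a C or G first dig, uses each eligible cell's
#' mean rate per trial as a feature, and classifies context (A vs B) or
#' dig side (C vs G) with a leave-one-out linear SVM. Eligible cells must
#' have place fields in at least 4 trials, two in each context (pass a
#' field-presence matrix), unless `permissive = TRUE`, which admits every
#' cell with defined rates.
#'
#' @param rates Cells x trials mean-rate matrix
#'   (from [session_mean_rates()]).
#' @param trials Trial metadata with `trial_id`, `context`, `dig1`.
#' @param target "context" or "heading".
#' @param field_presence Optional logical cells x trials matrix (field
#'   detected on that trial) used for the inclusion rule.
#' @param permissive Skip the field-count inclusion rule.
#' @return List with `accuracy` (`NA` with `reason` when no eligible
#'   cells), `n_cells`, `n_trials`.
#' @export
predict_from_rates <- function(rates, trials,
                               target = c("context", "heading"),
                               field_presence = NULL, permissive = FALSE) {
  target <- match.arg(target)
  sel <- trials$trial_id[!is.na(trials$dig1) & trials$dig1 %in% c("C", "G")]
  labels <- if (target == "context") {
    trials$context[match(sel, trials$trial_id)]
  } else {
    trials$dig1[match(sel, trials$trial_id)]
  }
  cells <- rownames(rates)
  if (!permissive) {
    if (is.null(field_presence)) {
      stop("field_presence is required unless permissive = TRUE",
           call. = FALSE)
    }
    ctx <- stats::setNames(trials$context, trials$trial_id)
    in_A <- colnames(field_presence)[ctx[colnames(field_presence)] == "A"]
    in_B <- colnames(field_presence)[ctx[colnames(field_presence)] == "B"]
    cells <- cells[rowSums(field_presence[cells, , drop = FALSE]) >= 4 &
                     rowSums(field_presence[cells, in_A, drop = FALSE]) >=
                       2 &
                     rowSums(field_presence[cells, in_B, drop = FALSE]) >=
                       2]
  }
  cells <- cells[rowSums(is.na(rates[cells, sel, drop = FALSE])) == 0]
  if (length(cells) == 0L) {
    return(list(accuracy = structure(NA_real_, reason = "no eligible cells"),
                n_cells = 0L, n_trials = length(sel)))
  }
  feats <- t(rates[cells, sel, drop = FALSE])
  list(accuracy = loo_svm_accuracy(feats, labels),
       n_cells = length(cells), n_trials = length(sel))
}

#' Field-presence matrix for a session
#'
#' @param maps Output of [session_rate_maps()].
#' @return Logical cells x trials matrix: a place field was detected.
#' @export
session_field_presence <- function(maps) {
  trial_ids <- names(maps)
  cell_ids <- names(maps[[1]])
  out <- matrix(FALSE, length(cell_ids), length(trial_ids),
                dimnames = list(cell_ids, trial_ids))
  for (t in trial_ids) {
    for (cid in cell_ids) {
      out[cid, t] <- length(detect_place_fields(maps[[t]][[cid]])) > 0L
    }
  }
  out
}

#' Chance calibration of a decoder by independent relabelling
#'
#' Replaces the labels by independent equal-probability draws from the two
#' classes (breaking any label-feature association while leaving the
#' features untouched) and returns the mean leave-one-out accuracy over
#' replicates. Under independent relabelling the expected accuracy is
#' exactly 0.5 for any classifier.
#'
#' @param features Trials x features matrix.
#' @param labels Original two-level labels (defines the label alphabet).
#' @param n_rep Number of relabelled replicates.
#' @param seed Integer seed.
#' @return Mean accuracy over replicates. Every draw is evaluated
#'   (single-class training folds predict that class); skipping or
#'   redrawing degenerate label vectors would condition the held-out
#'   label on the training counts and bias the mean below 0.5.
#' @export
chance_calibration <- function(features, labels, n_rep = 100, seed = 1L) {
  lv <- levels(factor(labels))
  stopifnot(length(lv) == 2L)
  features <- as.matrix(features)
  n <- nrow(features)
  withr_seed(seed, {
    accs <- vapply(seq_len(n_rep), function(r) {
      y <- factor(sample(lv, n, replace = TRUE), levels = lv)
      correct <- vapply(seq_len(n), function(i) {
        ytr <- droplevels(y[-i])
        if (nlevels(ytr) == 1L) {
          return(levels(ytr) == as.character(y[i]))
        }
        fit_predict_svm(features[-i, , drop = FALSE], ytr,
                        features[i, , drop = FALSE]) ==
          as.character(y[i])
      }, logical(1))
      mean(correct)
    }, numeric(1))
    mean(accs)
  })
}
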