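# Orchestration: channel-level augmentation, normalization, per-channel
# PCA compression, the multi-domain feature bank, decision fusion, and the
# cross-subject / single-subject evaluation protocols.

ALL_FAMILIES <- c("stats", "hjorth", "nsi", "fd", "hoc", "powerlaw",
                  "bandpower", "hos", "msce", "dasm", "rasm", "dwt", "hhs")

#' Channel-level data augmentation
#'
#' Treats every channel of every (trimmed) trial as a separate instance:
#' 32 instances per trial for EEG, 8 for the peripheral modality, 40
#' fused. All channels of a trial inherit the trial's ratings, so at the
#' full 32 x 40 scale the EEG modality yields 40,960 instances.
#'
#' @param dataset A `physio_dataset` whose trials are trimmed to 3840
#'   samples.
#' @param modality "eeg", "periphery", or "fused".
#' @return An `augmented_set`: `instances` (matrix n x 3840), `origin`
#'   (data frame subject/trial/channel), `modality`.
#' @export
augment_by_channel <- function(dataset, modality = c("eeg", "periphery", "fused")) {
  modality <- match.arg(modality)
  chans <- switch(modality, eeg = 1:32, periphery = 33:40, fused = 1:40)
  if (ncol(dataset$trials[[1]]$signal) != 3840)
    stopf("trials must be trimmed to 3840 samples first (got %d)",
          ncol(dataset$trials[[1]]$signal))
  n <- length(dataset$trials) * length(chans)
  inst <- matrix(0, n, 3840)
  origin <- data.frame(subject = integer(n), trial = integer(n),
                       channel = integer(n))
  i <- 0
  for (tr in dataset$trials) {
    for (ch in chans) {
      i <- i + 1
      inst[i, ] <- tr$signal[ch, ]
      origin$subject[i] <- tr$subject_id
      origin$trial[i] <- tr$trial_id
      origin$channel[i] <- ch
    }
  }
  structure(list(instances = inst, origin = origin, modality = modality),
            class = "augmented_set")
}

#' Per-instance z-normalization
#'
#' Each instance (channel trace) is scaled to mean 0 and standard
#' deviation 1 over its 3840 samples; zero-variance instances become
#' all-zero with a warning. Idempotent.
#'
#' @param aug An `augmented_set`.
#' @return The normalized `augmented_set`.
#' @export
normalize_channels <- function(aug) {
  aug$instances <- zscore_rows(aug$instances, warn = TRUE)
  aug
}

#' Labels for an augmented set
#'
#' Every instance inherits the binary label of its trial.
#'
#' @param aug An `augmented_set`.
#' @param dataset The `physio_dataset` it came from.
#' @param scale Rating scale to binarize.
#' @return Integer 0/1 vector aligned with the instances.
#' @export
augmented_labels <- function(aug, dataset, scale) {
  ratings <- dataset_ratings(dataset)
  labs <- binarize_ratings(ratings, scale)$labels
  key <- paste(ratings$subject, ratings$trial)
  labs[match(paste(aug$origin$subject, aug$origin$trial), key)]
}

# ---- Per-channel PCA -------------------------------------------------------

#' Fit per-channel principal components
#'
#' For each channel, PCA over the (training) trials of that channel's
#' 3840-sample traces; the top `n_components` scores per channel are the
#' compressed representation (25 x 32 = 800 values for EEG, 25 x 8 = 200
#' for the periphery).
#'
#' @param dataset A trimmed `physio_dataset` (training split only).
#' @param modality "eeg" or "periphery".
#' @param n_components Components per channel (default 25).
#' @return A `pca_model` to pass to [pca_transform()].
#' @export
pca_fit <- function(dataset, modality = c("eeg", "periphery"),
                    n_components = 25) {
  modality <- match.arg(modality)
  chans <- if (modality == "eeg") 1:32 else 33:40
  n_tr <- length(dataset$trials)
  if (n_components > 3840) stopf("n_components exceeds samples per channel")
  models <- lapply(chans, function(ch) {
    m <- t(vapply(dataset$trials, function(tr) tr$signal[ch, ], numeric(3840)))
    pc <- stats::prcomp(m, center = TRUE, rank. = min(n_components, n_tr))
    list(center = pc$center, rotation = pc$rotation)
  })
  structure(list(models = models, chans = chans, modality = modality,
                 n_components = n_components),
            class = "pca_model")
}

#' Project trials onto fitted per-channel components
#'
#' @param model A `pca_model` from [pca_fit()].
#' @param dataset A trimmed `physio_dataset`.
#' @return A `feature_table`, one row per trial, `n_components` columns
#'   per channel.
#' @export
pca_transform <- function(model, dataset) {
  blocks <- lapply(seq_along(model$chans), function(i) {
    ch <- model$chans[i]
    m <- t(vapply(dataset$trials, function(tr) tr$signal[ch, ], numeric(3840)))
    scores <- sweep(m, 2, model$models[[i]]$center) %*% model$models[[i]]$rotation
    colnames(scores) <- paste0(model$modality, ".ch", ch, ".pc",
                               seq_len(ncol(scores)))
    scores
  })
  feature_table(do.call(cbind, blocks), family = "pca")
}

# ---- Feature bank ----------------------------------------------------------

per_channel_features <- function(x, fs, label, is_eeg, families) {
  vals <- numeric(); fams <- character(); nms <- character()
  add <- function(v, fam, nm) {
    vals <<- c(vals, v); fams <<- c(fams, rep(fam, length(v)))
    nms <<- c(nms, nm)
  }
  want <- function(f) f %in% families
  if (want("stats")) {
    ts <- time_stats(x)
    add(c(ts$power, ts$mean, ts$sd, ts$norm_first_diff, ts$norm_second_diff),
        "stats", paste0(label, ".stat.",
                        c("power", "mean", "sd", "nfd", "nsd")))
  }
  if (want("hjorth")) {
    hj <- tryCatch(hjorth(x), error = function(e) list(mobility = NA, complexity = NA))
    add(c(hj$mobility, hj$complexity), "hjorth",
        paste0(label, ".hjorth.", c("mobility", "complexity")))
  }
  if (want("nsi")) add(nsi(x)$value, "nsi", paste0(label, ".nsi"))
  if (is_eeg && want("fd")) {
    fd <- tryCatch(higuchi_fd(x)$dimension, error = function(e) NA_real_)
    add(fd, "fd", paste0(label, ".fd"))
  }
  if (want("hoc"))
    add(as.numeric(hoc_features(x)), "hoc", paste0(label, ".hoc.k", 1:10))
  if (want("powerlaw")) {
    eta <- tryCatch(power_law_index(welch_psd(x, fs))$eta,
                    error = function(e) NA_real_)
    add(eta, "powerlaw", paste0(label, ".powerlaw"))
  }
  if (is_eeg && want("bandpower")) {
    bp <- band_power_features(x, fs)
    add(c(as.numeric(t(bp$per_band)), bp$power_variance, bp$ratio_beta_alpha),
        "bandpower",
        c(paste0(label, ".bp.", rep(band_names(), each = 3), ".",
                 rep(c("logavg", "logmax", "logmin"), 4)),
          paste0(label, ".bp.", c("powervar", "ratio_ba"))))
  }
  if (is_eeg && want("hos")) {
    hs <- tryCatch({
      b <- bispectrum_estimate(x, fs)
      s <- bispectral_summaries(b)
      c(s$BE1, s$BE2, s$MMOB, s$FOSM)
    }, error = function(e) rep(NA_real_, 4))
    add(hs, "hos", paste0(label, ".hos.", c("be1", "be2", "mmob", "fosm")))
  }
  if (want("dwt")) {
    dw <- tryCatch(dwt_features(x)$features, error = function(e)
      matrix(NA_real_, 4, 3, dimnames = list(band_names(),
                                             c("entropy", "rms", "abs_log_ree"))))
    if (is_eeg) {
      add(as.numeric(t(dw)), "dwt",
          paste0(label, ".dwt.", rep(band_names(), each = 3), ".",
                 rep(c("entropy", "rms", "ree"), 4)))
    } else {
      add(c(dw[, "entropy"], dw[, "abs_log_ree"]), "dwt",
          paste0(label, ".dwt.", c(paste0(band_names(), ".entropy"),
                                   paste0(band_names(), ".ree"))))
    }
  }
  if (want("hhs")) {
    he <- tryCatch(
      hilbert_spectrum(emd_decompose(x), fs)$band_energy,
      error = function(e) stats::setNames(rep(NA_real_, 4), band_names()))
    add(as.numeric(he), "hhs", paste0(label, ".hhs.", band_names()))
  }
  list(values = vals, family = fams, names = nms)
}

#' Extract the multi-domain feature bank for one trial
#'
#' Per EEG channel: 5 time statistics, 2 Hjorth parameters, the
#' non-stationary index, the Higuchi fractal dimension, 10 higher-order
#' crossings, the power-law index, 14 band-power features, 4 bispectral
#' summaries, 12 wavelet features and 4 Hilbert-Huang band energies (54);
#' plus 56 coherence, 56 differential- and 56 rational-asymmetry features
#' over the 14 symmetric pairs: 54 x 32 + 168 = 1896 features. Per
#' peripheral channel: 31 features (no fractal dimension, no band
#' power/bispectrum/pair features; wavelet entropy and |ln REE| only),
#' 8 x 31 = 248.
#'
#' @param trial A trimmed `trial_recording`.
#' @param modality "eeg" or "periphery".
#' @param families Feature families to compute (default: all); others are
#'   omitted from the table.
#' @return List with `values`, `names`, `family` vectors.
#' @export
extract_trial_features <- function(trial, modality = c("eeg", "periphery"),
                                   families = ALL_FAMILIES) {
  modality <- match.arg(modality)
  fs <- trial$fs
  vals <- numeric(); fams <- character(); nms <- character()
  if (modality == "eeg") {
    for (ch in 1:32) {
      pc <- per_channel_features(trial$signal[ch, ], fs,
                                 paste0("eeg.ch", ch), TRUE, families)
      vals <- c(vals, pc$values); fams <- c(fams, pc$family); nms <- c(nms, pc$names)
    }
    prs <- symmetric_pairs()
    pair_lab <- paste0("eeg.pair", prs[, 1], "-", prs[, 2])
    if ("msce" %in% families) {
      mc <- msce_features(trial, prs)$band_coherence
      vals <- c(vals, as.numeric(t(mc)))
      fams <- c(fams, rep("msce", length(mc)))
      nms <- c(nms, paste0(rep(pair_lab, each = 4), ".msce.", band_names()))
    }
    if (any(c("dasm", "rasm") %in% families)) {
      af <- asymmetry_features(trial, prs)
      if ("dasm" %in% families) {
        vals <- c(vals, as.numeric(t(af$dasm)))
        fams <- c(fams, rep("dasm", length(af$dasm)))
        nms <- c(nms, paste0(rep(pair_lab, each = 4), ".dasm.", band_names()))
      }
      if ("rasm" %in% families) {
        vals <- c(vals, as.numeric(t(af$rasm)))
        fams <- c(fams, rep("rasm", length(af$rasm)))
        nms <- c(nms, paste0(rep(pair_lab, each = 4), ".rasm.", band_names()))
      }
    }
  } else {
    for (ch in 33:40) {
      pc <- per_channel_features(trial$signal[ch, ], fs,
                                 paste0("per.ch", ch), FALSE, families)
      vals <- c(vals, pc$values); fams <- c(fams, pc$family); nms <- c(nms, pc$names)
    }
  }
  list(values = vals, names = nms, family = fams)
}

#' Extract the feature bank for a whole dataset
#'
#' Applies [extract_trial_features()] to every (trimmed) trial and stacks
#' the rows into a `feature_table`. Failed individual features become
#' missing values; impute them with [impute_missing()] using
#' training-split medians before classification.
#'
#' @param dataset A trimmed `physio_dataset`.
#' @param modality "eeg" or "periphery".
#' @param families Feature families to include (default: all).
#' @return A `feature_table` with one row per trial.
#' @export
extract_feature_bank <- function(dataset, modality = c("eeg", "periphery"),
                                 families = ALL_FAMILIES) {
  modality <- match.arg(modality)
  first <- extract_trial_features(dataset$trials[[1]], modality, families)
  m <- matrix(NA_real_, length(dataset$trials), length(first$values))
  m[1, ] <- first$values
  if (length(dataset$trials) > 1)
    for (i in 2:length(dataset$trials))
      m[i, ] <- extract_trial_features(dataset$trials[[i]], modality,
                                       families)$values
  feature_table(m, first$names, first$family)
}

# ---- Decision fusion -------------------------------------------------------

#' Weighted average of two modalities' class probabilities
#'
#' @param p_eeg,p_per Matrices n x 2 of class probabilities (rows sum
#'   to 1).
#' @param w EEG weight in \[0, 1\] (scalar or `fusion_weights`); the
#'   peripheral weight is 1 - w.
#' @return Fused probability matrix n x 2.
#' @export
fuse_decisions <- function(p_eeg, p_per, w) {
  if (inherits(w, "fusion_weights")) w <- w$w_eeg
  if (nrow(p_eeg) != nrow(p_per)) stopf("misaligned probability matrices")
  w * p_eeg + (1 - w) * p_per
}

#' Exhaustive search for the optimal fusion weight
#'
#' Evaluates classification accuracy of the fused probabilities at
#' w in {0, 0.01, ..., 1} and returns the argmax (ties: smallest w).
#'
#' @param p_eeg,p_per Class-probability matrices on a validation set.
#' @param labels 0/1 labels of that set.
#' @param step Grid step (default 0.01, giving 101 candidates).
#' @return A `fusion_weights`: `w_eeg`, `accuracy`, `search_trace`.
#' @export
search_fusion_weights <- function(p_eeg, p_per, labels, step = 0.01) {
  grid <- seq(0, 1, by = step)
  acc <- vapply(grid, function(w) {
    f <- fuse_decisions(p_eeg, p_per, w)
    mean((f[, 2] > f[, 1]) == (labels == 1))
  }, numeric(1))
  best <- which.max(acc)  # first max = smallest weight on ties
  structure(list(w_eeg = grid[best], accuracy = acc[best],
                 search_trace = data.frame(w = grid, accuracy = acc),
                 step = step),
            class = "fusion_weights")
}

# ---- Evaluation protocols --------------------------------------------------

eval_report <- function(task, protocol, model, per_fold, seed, extra = list()) {
  structure(c(list(task = task, protocol = protocol, model = model,
                   per_fold_accuracy = per_fold,
                   mean_accuracy = mean(per_fold), seed = seed), extra),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s / %s / %s: mean accuracy %.3f over %d folds\n",
              x$task, x$protocol, x$model, x$mean_accuracy,
              length(x$per_fold_accuracy)))
  invisible(x)
}

#' Cross-subject evaluation
#'
#' Mixes all subjects' trials and evaluates by stratified seeded k-fold
#' cross-validation, or by a fixed stratified train/validation/test split
#' in proportions 0.6/0.2/0.2 (768/256/256 at the full 1280-trial scale).
#'
#' @param features A `feature_table` (or plain matrix), one row per
#'   instance.
#' @param labels A `label_set` or 0/1 vector.
#' @param model Classifier name (see [fit_classifier()]).
#' @param folds Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param split "kfold" or "fixed".
#' @param groups Optional grouping vector (e.g. trial ids for augmented
#'   sets): groups are never split across folds.
#' @param task Label for the report.
#' @return An `eval_report`.
#' @export
crossval_cross_subject <- function(features, labels, model, folds = 5,
                                   seed = 1, split = c("kfold", "fixed"),
                                   groups = NULL, task = "unspecified") {
  split <- match.arg(split)
  x <- if (inherits(features, "feature_table")) features$values else features
  y <- if (inherits(labels, "label_set")) labels$labels else labels
  if (min(table(y)) < folds && split == "kfold")
    stopf("fewer instances (%d) in a class than folds (%d)", min(table(y)), folds)
  if (split == "kfold") {
    fold_id <- make_folds(y, folds, seed, groups)
    acc <- cv_accuracy(x, y, model, fold_id)
    eval_report(task, "cross_subject_kfold", model, acc, seed)
  } else {
    part <- make_folds(y, 5, seed, groups)  # 5 strata -> 3/1/1 partition
    tr <- part <= 3; va <- part == 4; te <- part == 5
    fit <- fit_classifier(model, x[tr, , drop = FALSE], y[tr])
    acc_te <- mean(predict_classifier(fit, x[te, , drop = FALSE])$class == y[te])
    acc_va <- mean(predict_classifier(fit, x[va, , drop = FALSE])$class == y[va])
    eval_report(task, "cross_subject_fixed", model, acc_te, seed,
                extra = list(val_accuracy = acc_va,
                             split_sizes = c(train = sum(tr), val = sum(va),
                                             test = sum(te))))
  }
}

#' Single-subject leave-one-out evaluation
#'
#' One subject's trials are evaluated by leave-one-out cross-validation
#' (40-fold at the reference scale): each trial is held out once and the
#' accuracy is the fraction of correctly classified held-out trials.
#'
#' @param features `feature_table` or matrix of the subject's trials.
#' @param labels A `label_set` or 0/1 vector.
#' @param model Classifier name.
#' @param task Label for the report.
#' @return An `eval_report` (per-fold accuracies are 0/1), or NULL with a
#'   warning when a class has fewer than 2 trials.
#' @export
loocv_single_subject <- function(features, labels, model, task = "unspecified") {
  x <- if (inherits(features, "feature_table")) features$values else features
  y <- if (inherits(labels, "label_set")) labels$labels else labels
  if (min(table(factor(y, levels = 0:1))) < 2) {
    warning("degenerate subject: a class has fewer than 2 trials; task skipped")
    return(NULL)
  }
  hits <- vapply(seq_len(nrow(x)), function(i) {
    fit <- fit_classifier(model, x[-i, , drop = FALSE], y[-i])
    as.numeric(predict_classifier(fit, x[i, , drop = FALSE])$class == y[i])
  }, numeric(1))
  eval_report(task, "single_subject_loocv", model, hits, seed = NA)
}

# ---- End-to-end pipeline ---------------------------------------------------

#' Run the full recognition pipeline from a configuration
#'
#' Generates (or reads) a dataset, trims the stimulus window, and for each
#' requested rating scale runs the configured branch: `bank` (feature
#' extraction, low-variance filter, chi-square + mutual-information top-k
#' union, classifier cross-validation with optional decision fusion of the
#' EEG and peripheral modalities) and/or `sda` (channel augmentation,
#' normalization, grouped train/test split, greedy pre-training, supervised
#' fine-tuning, top-code classification). Reports are written as CSV under
#' `out_dir`; runs are deterministic in the seed.
#'
#' @param config Nested list (or path to a YAML file) with sections
#'   `dataset` (n_subjects, n_trials, seed, effect_size), `tasks`
#'   (character vector of scales), `branch` ("bank" or "sda") and
#'   branch-specific settings: for bank — `families`, `top_k`, `models`,
#'   `folds`, `fusion`; for sda — `dims`, `epochs`, `model`.
#' @param out_dir Output directory for report CSVs (default: not written).
#' @return List of `eval_report`s (one per task x model).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  ds_cfg <- config$dataset
  for (f in c("n_subjects", "n_trials", "seed"))
    if (is.null(ds_cfg[[f]])) stopf("config$dataset$%s is required", f)
  tasks <- config$tasks %||% "arousal"
  branch <- config$branch %||% "bank"
  seed <- ds_cfg$seed
  dataset <- generate_dataset(ds_cfg$n_subjects, ds_cfg$n_trials, seed,
                              ds_cfg$effect_size %||% 1)
  dataset <- trim_dataset(dataset)
  reports <- list()
  if (branch == "bank") {
    fams <- config$families %||% ALL_FAMILIES
    banks <- list(eeg = extract_feature_bank(dataset, "eeg", fams),
                  periphery = extract_feature_bank(dataset, "periphery", fams))
    for (task in tasks) {
      labels <- binarize_ratings(dataset, task)
      sel <- lapply(banks, function(bank) {
        bank <- impute_missing(bank)$table
        keep <- rflv(bank, config$rflv_threshold %||% 0.01)$mask
        bank <- subset_features(bank, keep)
        u <- union_topk(score_features(bank, labels, "chi2"),
                        score_features(bank, labels, "mutual_info"),
                        config$top_k %||% 200)
        subset_features(bank, u$mask)
      })
      for (model in config$models %||% "knn") {
        folds <- config$folds %||% 5
        rep_eeg <- crossval_cross_subject(sel$eeg, labels, model, folds,
                                          seed, task = task)
        rep_per <- crossval_cross_subject(sel$periphery, labels, model, folds,
                                          seed, task = task)
        rep_eeg$modality <- "eeg"; rep_per$modality <- "periphery"
        reports <- c(reports, list(rep_eeg, rep_per))
        if (isTRUE(config$fusion)) {
          fus <- decision_fusion_cv(sel$eeg$values, sel$periphery$values,
                                    labels$labels, model, folds, seed)
          reports <- c(reports, list(
            eval_report(task, "cross_subject_kfold", model, fus$acc_optimal,
                        seed, extra = list(modality = "fusion_optimal",
                                           weights = fus$weights)),
            eval_report(task, "cross_subject_kfold", model, fus$acc_equal,
                        seed, extra = list(modality = "fusion_equal"))))
        }
      }
    }
  } else if (branch == "sda") {
    for (task in tasks) {
      res <- sda_classify(dataset, task,
                          dims = config$dims %||% c(3840, 1000, 200, 40),
                          epochs = config$epochs %||% 20,
                          model = config$model %||% "svm", seed = seed)
      reports <- c(reports, list(res$report))
    }
  } else stopf("unknown branch '%s'", branch)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    df <- do.call(rbind, lapply(reports, function(r)
      data.frame(task = r$task, protocol = r$protocol, model = r$model,
                 modality = r$modality %||% "eeg",
                 mean_accuracy = r$mean_accuracy,
                 folds = length(r$per_fold_accuracy), seed = r$seed)))
    utils::write.csv(df, file.path(out_dir, "eval_report.csv"),
                     row.names = FALSE)
  }
  reports
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-fold decision fusion: both modality models are fit on the training
# folds, the fusion weight is searched on *out-of-fold* training
# predictions (an inner 3-fold CV; probabilities from a model's own
# training data are near-degenerate and make the search meaningless) and
# applied to the held-out fold. No test leakage.
decision_fusion_cv <- function(x_eeg, x_per, y, model, folds, seed) {
  fold_id <- make_folds(y, folds, seed)
  oof_probs <- function(x, y, inner_id) {
    pr <- matrix(NA_real_, length(y), 2)
    for (g in unique(inner_id)) {
      ho <- inner_id == g
      fit <- fit_classifier(model, x[!ho, , drop = FALSE], y[!ho])
      pr[ho, ] <- predict_classifier(fit, x[ho, , drop = FALSE])$prob
    }
    pr
  }
  acc_opt <- numeric(folds); acc_eq <- numeric(folds); ws <- numeric(folds)
  for (f in seq_len(folds)) {
    te <- fold_id == f
    fe <- fit_classifier(model, x_eeg[!te, , drop = FALSE], y[!te])
    fp <- fit_classifier(model, x_per[!te, , drop = FALSE], y[!te])
    inner <- make_folds(y[!te], 3, derive_seed(seed, 5, f))
    pe_tr <- oof_probs(x_eeg[!te, , drop = FALSE], y[!te], inner)
    pp_tr <- oof_probs(x_per[!te, , drop = FALSE], y[!te], inner)
    w <- search_fusion_weights(pe_tr, pp_tr, y[!te])
    pe <- predict_classifier(fe, x_eeg[te, , drop = FALSE])$prob
    pp <- predict_classifier(fp, x_per[te, , drop = FALSE])$prob
    fo <- fuse_decisions(pe, pp, w)
    feq <- fuse_decisions(pe, pp, 0.5)
    acc_opt[f] <- mean((fo[, 2] > fo[, 1]) == (y[te] == 1))
    acc_eq[f] <- mean((feq[, 2] > feq[, 1]) == (y[te] == 1))
    ws[f] <- w$w_eeg
  }
  list(acc_optimal = acc_opt, acc_equal = acc_eq, weights = ws)
}

#' Channel-augmented SDA classification of one rating scale
#'
#' Augments by channel, z-normalizes, splits train/test (grouped by trial
#' by default so sibling channels never straddle the split; `grouped =
#' FALSE` reproduces instance-level splitting), pre-trains and fine-tunes
#' the stack on the training side, then classifies the top-layer codes
#' with a stand-alone model.
#'
#' @param dataset A trimmed `physio_dataset`.
#' @param task Rating scale.
#' @param dims Stack widths (default `c(3840, 1000, 200, 40)`).
#' @param epochs Epochs for each pre-training layer and for fine-tuning.
#' @param model Stand-alone classifier on the codes ("svm" or "knn").
#' @param seed Seed.
#' @param modality Augmentation modality.
#' @param test_frac Held-out fraction (default 0.25).
#' @param grouped Group the split by trial (default TRUE).
#' @return List with the `eval_report` and the trained `sda_stack`.
#' @export
sda_classify <- function(dataset, task, dims = c(3840, 1000, 200, 40),
                         epochs = 20, model = "svm", seed = 1,
                         modality = "eeg", test_frac = 0.25,
                         grouped = TRUE) {
  aug <- normalize_channels(augment_by_channel(dataset, modality))
  y <- augmented_labels(aug, dataset, task)
  grp <- if (grouped) paste(aug$origin$subject, aug$origin$trial) else NULL
  nfold <- max(2L, as.integer(round(1 / test_frac)))
  fold_id <- make_folds(y, nfold, derive_seed(seed, 13), grp)
  te <- fold_id == 1
  stack <- sda_stack(dims, corruption = 0.2, seed = seed)
  stack <- sda_pretrain(stack, aug$instances[!te, , drop = FALSE],
                        epochs_per_layer = epochs, seed = seed)
  stack <- fine_tune(stack, aug$instances[!te, , drop = FALSE], y[!te],
                     epochs = epochs, seed = seed)
  codes_tr <- encode_features(stack, aug$instances[!te, , drop = FALSE])
  codes_te <- encode_features(stack, aug$instances[te, , drop = FALSE])
  fit <- fit_classifier(model, codes_tr$values, y[!te])
  acc <- mean(predict_classifier(fit, codes_te$values)$class == y[te])
  list(report = eval_report(task, "cross_subject_holdout",
                            paste0("sda+", model), acc, seed,
                            extra = list(modality = modality,
                                         grouped = grouped,
                                         n_train = sum(!te),
                                         n_test = sum(te))),
       stack = stack)
}
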