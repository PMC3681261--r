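#' Correct classification rates
#'
#' `ccr_normal` and `ccr_pathological` are the per-class accuracies in
#' percent; `ccr` is their unweighted mean, so a balanced measure even when
#' the classes are unbalanced.
#'
#' @param correct_normal,total_normal correct / total counts for the normal
#'   class.
#' @param correct_path,total_path correct / total counts for the pathological
#'   class.
#' @return named numeric vector `c(ccr_normal, ccr_pathological, ccr)`.
#' @examples
#' ccr(9, 10, 8, 10) # 90, 80, 85
#' @export
ccr <- function(correct_normal, total_normal, correct_path, total_path) {
  if (total_normal <= 0 || total_path <= 0)
    stop("class totals must be positive")
  if (correct_normal > total_normal || correct_path > total_path ||
      correct_normal < 0 || correct_path < 0)
    stop("correct counts must lie in [0, total]")
  cn <- 100 * correct_normal / total_normal
  cp <- 100 * correct_path / total_path
  c(ccr_normal = cn, ccr_pathological = cp, ccr = (cn + cp) / 2)
}

#' Stratified train/test split
#'
#' Splits a labeled dataset class by class, preserving class proportions;
#' deterministic under `seed`; the two parts are disjoint and exhaustive.
#'
#' @param dataset a `voice_dataset` (or any list of items with a `label`).
#' @param train_fraction fraction assigned to training (default 0.75).
#' @param seed integer seed.
#' @return a list with elements `train` and `test`, each a `voice_dataset`.
#' @export
split_dataset <- function(dataset, train_fraction = 0.75, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  labels <- dataset_labels(dataset)
  classes <- unique(labels)
  tr_idx <- integer(0)
  for (cl in classes) {
    idx <- which(labels == cl)
    if (length(idx) < 4L)
      stop(sprintf("class '%s' has only %d items; at least 4 required",
                   cl, length(idx)))
    n_tr <- max(1L, min(length(idx) - 1L,
                        as.integer(round(train_fraction * length(idx)))))
    pick <- withr::with_seed(as.integer(seed) + match(cl, classes),
                             sample(idx, n_tr))
    tr_idx <- c(tr_idx, pick)
  }
  tr_idx <- sort(tr_idx)
  te_idx <- setdiff(seq_along(dataset), tr_idx)
  keep <- function(ix) structure(dataset[ix], class = "voice_dataset")
  list(train = keep(tr_idx), test = keep(te_idx))
}

labels01 <- function(dataset) {
  as.integer(dataset_labels(dataset) == "pathological")
}

condition_label <- function(snr_db) {
  if (is.infinite(snr_db)) "clean" else sprintf("%g dB", snr_db)
}

noisy_copy <- function(dataset, snr_db, noise_seed, cond_index) {
  if (is.infinite(snr_db)) return(dataset)
  items <- lapply(seq_along(dataset), function(j) {
    it <- dataset[[j]]
    sd <- as.integer((as.double(noise_seed) * 104729 + j * 7919 +
                        cond_index * 31L) %% 2147483646 + 1)
    it$signal <- mix_noise_at_snr(it$signal, snr_db, seed = sd)
    it
  })
  structure(items, class = "voice_dataset")
}

#' Noise-robustness evaluation sweep
#'
#' The full experiment: 75/25 stratified split, per-front-end training on
#' the (by default clean) training partition, then test-set correct
#' classification rates in the clean condition and with white noise mixed
#' into the test waveforms at each SNR level before feature extraction.
#'
#' @param dataset a labeled `voice_dataset` containing both classes.
#' @param feature_kinds character vector among `"mfcc"`, `"mtecc"`,
#'   `"gtecc"`.
#' @param snr_levels_db noise conditions in dB (default `c(15, 10, 5, 0)`);
#'   the clean condition is always evaluated first.
#' @param config a [feature_config()].
#' @param train_config an [mlp_config()].
#' @param train_fraction passed to [split_dataset()].
#' @param split_seed seed of the stratified split.
#' @param noise_seed master seed for the test-noise realizations (each
#'   utterance/condition gets a seed derived from it).
#' @param train_noisy if `TRUE`, matched-condition training: for each noisy
#'   condition the classifier is retrained on training waveforms mixed at the
#'   same SNR. Default `FALSE` (train clean, test noisy).
#' @return an `evaluation_report`: a data frame with one row per
#'   (feature_kind, condition) holding `ccr_normal`, `ccr_pathological`,
#'   `ccr` and the underlying counts; attributes record seeds, partition
#'   sizes and the configuration fingerprint.
#' @export
run_noise_sweep <- function(dataset,
                            feature_kinds = c("mfcc", "mtecc", "gtecc"),
                            snr_levels_db = c(15, 10, 5, 0),
                            config = feature_config(),
                            train_config = mlp_config(),
                            train_fraction = 0.75,
                            split_seed = 1L, noise_seed = 1L,
                            train_noisy = FALSE) {
  labels <- dataset_labels(dataset)
  if (length(unique(labels)) < 2L)
    stop("dataset must contain both normal and pathological voices")
  parts <- split_dataset(dataset, train_fraction, split_seed)
  if (length(parts$test) == 0L) stop("empty test partition")
  ytr <- labels01(parts$train)
  yte <- labels01(parts$test)
  snrs <- c(Inf, snr_levels_db)

  rows <- list()
  for (kind in feature_kinds) {
    xtr_clean <- pooled_feature_matrix(parts$train, kind, config)
    fit_clean <- train_mlp(xtr_clean, ytr, train_config)
    for (ci in seq_along(snrs)) {
      snr <- snrs[ci]
      fit <- fit_clean
      if (train_noisy && !is.infinite(snr)) {
        tr_noisy <- noisy_copy(parts$train, snr,
                               noise_seed + 499979L, ci)
        fit <- train_mlp(pooled_feature_matrix(tr_noisy, kind, config),
                         ytr, train_config)
      }
      te <- noisy_copy(parts$test, snr, noise_seed, ci)
      pred <- predict(fit$model, pooled_feature_matrix(te, kind, config))
      cn <- sum(pred$label == 0L & yte == 0L)
      cp <- sum(pred$label == 1L & yte == 1L)
      r <- ccr(cn, sum(yte == 0L), cp, sum(yte == 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        feature_kind = toupper(kind), condition = condition_label(snr),
        snr_db = snr, ccr_normal = r[["ccr_normal"]],
        ccr_pathological = r[["ccr_pathological"]], ccr = r[["ccr"]],
        correct_normal = cn, total_normal = sum(yte == 0L),
        correct_path = cp, total_path = sum(yte == 1L),
        train_mse = fit$report$final_mse,
        train_converged = fit$report$converged,
        stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  structure(report,
            class = c("evaluation_report", "data.frame"),
            split_seed = as.integer(split_seed),
            noise_seed = as.integer(noise_seed),
            n_train = length(parts$train), n_test = length(parts$test),
            train_noisy = train_noisy,
            config_fingerprint = config_fingerprint(config))
}

#' @export
print.evaluation_report <- function(x, ...) {
  conds <- unique(x$condition)
  cat(sprintf("Noise-robustness evaluation (train %d / test %d voices)\n",
              attr(x, "n_train"), attr(x, "n_test")))
  cat(sprintf("%-8s %-10s %s\n", "Feature", "Rate",
              paste(sprintf("%8s", conds), collapse = " ")))
  for (kind in unique(x$feature_kind)) {
    sub <- x[x$feature_kind == kind, ]
    for (metric in c("ccr_normal", "ccr_pathological", "ccr")) {
      lab <- c(ccr_normal = "CCR_Norm", ccr_pathological = "CCR_Path",
               ccr = "CCR")[[metric]]
      vals <- vapply(conds, function(cc) sub[[metric]][sub$condition == cc],
                     numeric(1))
      cat(sprintf("%-8s %-10s %s\n", kind, lab,
                  paste(sprintf("%8.2f", vals), collapse = " ")))
    }
  }
  invisible(x)
}

#' Write an evaluation report to CSV
#'
#' @param report an `evaluation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
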