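#' Desk-scale end-to-end benchmark on synthetic cephalograms
#'
#' Runs the whole protocol at desk scale: generates a synthetic train/test
#' split, trains one coarse (LRS) and one fine (HRS) classifier per landmark
#' under the desk profile (reduced architecture, 2000 optimisation steps,
#' 5 landmarks, ROI pixels strided by 2), detects every landmark on the
#' held-out frames with 17 Monte-Carlo passes, and measures the detection
#' errors against the exact synthetic truth.
#'
#' @param n_train,n_test Cases in the training and held-out splits.
#' @param seed Master seed; all sampling, initialisation, dropout and
#'   generator streams derive from it.
#' @param synthetic_cfg,sampling_cfg,arch,train_cfg Study-condition configs;
#'   desk defaults.
#' @param T Monte-Carlo passes at detection time.
#' @param verbose Print per-model progress?
#' @return List with `results` (data frame: case, landmark, error_mm,
#'   n_true_lrs, inside_roi, fallback), `report` (an
#'   `evaluation_report` over the held-out split), `registry`, and
#'   `median_error_mm`.
#' @export
desk_benchmark <- function(n_train = 8, n_test = 3, seed = 1L,
                           synthetic_cfg = desk_synthetic_config(
                             rng_seed = as.integer(seed) * 37L + 11L),
                           sampling_cfg = desk_sampling_config(),
                           arch = desk_architecture(),
                           train_cfg = desk_training_config(),
                           T = 17L, verbose = FALSE) {
  cases <- lapply(seq_len(n_train + n_test), generate_case,
                  cfg = synthetic_cfg)
  train <- cases[seq_len(n_train)]
  test <- cases[n_train + seq_len(n_test)]
  reg <- train_detector(lapply(train, `[[`, "image"),
                        lapply(train, `[[`, "truth"),
                        sampling_cfg = sampling_cfg, arch = arch,
                        train_cfg = train_cfg,
                        master_seed = as.integer(seed), verbose = verbose)
  rows <- list()
  preds <- list()
  for (i in seq_along(test)) {
    tc <- test[[i]]
    res <- detect_all(tc$image, reg, sampling_cfg = sampling_cfg, T = T,
                      seed = as.integer(seed) + i)
    preds[[i]] <- res$landmarks
    for (nm in tc$truth$name) {
      p <- res$predictions[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        case = n_train + i, landmark = nm,
        error_mm = sqrt(sum((p$point_mm - landmark_xy(tc$truth, nm))^2)),
        n_true_lrs = p$n_true_lrs,
        inside_roi = all(abs(p$point_mm - p$lrs_center_mm) <=
                           sampling_cfg$roi_side_mm / 2 + 1e-6),
        fallback = p$fallback_used, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  report <- evaluate_landmarks(lapply(test, `[[`, "truth"), preds)
  list(results = results, report = report, registry = reg,
       median_error_mm = stats::median(results$error_mm))
}
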