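# Random up/down resampling for class balance, applied to training
# partitions only (callers enforce that; evaluation rows never pass here).

#' Rebalance a training set by random resampling
#'
#' `"down"` subsamples every class without replacement to the minimum
#' class count; `"up"` keeps all original rows and adds rows sampled with
#' replacement until every class reaches the maximum class count;
#' `"none"` returns the input unchanged. Resampled rows are exact copies
#' of original rows -- no interpolation or synthesis.
#'
#' @param features Data frame of predictors (one row per instance).
#' @param labels Class vector aligned with `features` rows.
#' @param strategy `"none"`, `"up"` or `"down"`.
#' @param seed Optional integer seed.
#' @return List with elements `features` (tibble) and `labels`.
#' @examples
#' x <- tibble::tibble(v = 1:6)
#' y <- c(1, 1, 1, 1, 2, 2)
#' table(resample_training_set(x, y, "down", seed = 1)$labels)
#' @export
resample_training_set <- function(features, labels,
                                  strategy = c("none", "up", "down"),
                                  seed = NULL) {
  strategy <- match.arg(strategy)
  if (!is.data.frame(features) || nrow(features) == 0 || length(labels) == 0) {
    abort("`features` and `labels` must be non-empty.")
  }
  assert_same_length(seq_len(nrow(features)), labels, "features rows", "labels")
  if (strategy == "none") {
    return(list(features = as_tibble(features), labels = labels))
  }
  counts <- table(labels)
  target <- if (strategy == "down") min(counts) else max(counts)
  idx <- with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      rows <- which(labels == cl)
      if (strategy == "down") {
        sample(rows, target, replace = FALSE)
      } else if (length(rows) < target) {
        c(rows, sample(rows, target - length(rows), replace = TRUE))
      } else {
        rows
      }
    }), use.names = FALSE)
  })
  list(features = as_tibble(features[idx, , drop = FALSE]), labels = labels[idx])
}
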