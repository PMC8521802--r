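# Stage coding used throughout: 1 = deep, 2 = light, 3 = REM, 4 = wake.
STAGES <- 1:4
STAGE_LABELS <- c("deep", "light", "rem", "wake")

stage_label <- function(code) STAGE_LABELS[code]

assert_stages <- function(x, arg = "stages", allow_empty = TRUE) {
  if (!allow_empty && length(x) == 0) {
    abort(sprintf("`%s` must be non-empty.", arg))
  }
  if (length(x) > 0 && (!is.numeric(x) || anyNA(x) || !all(x %in% STAGES))) {
    abort(sprintf("`%s` must contain only stage codes 1-4 (deep/light/rem/wake).", arg))
  }
  as.integer(x)
}

assert_same_length <- function(x, y, xarg = "pred", yarg = "truth") {
  if (length(x) != length(y)) {
    abort(sprintf("`%s` (%d) and `%s` (%d) must have equal length.",
                  xarg, length(x), yarg, length(y)))
  }
  invisible(TRUE)
}

# Validate a 4x4 row-stochastic matrix (transition or device-error matrix).
assert_stochastic <- function(m, arg = "matrix", tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != 4 || ncol(m) != 4) {
    abort(sprintf("`%s` must be a 4x4 matrix.", arg))
  }
  if (anyNA(m) || any(m < 0)) {
    abort(sprintf("`%s` must have non-negative entries with no missing values.", arg))
  }
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol)) {
    abort(sprintf("Every row of `%s` must sum to 1 (max deviation %.3g).",
                  arg, max(abs(rs - 1))))
  }
  invisible(TRUE)
}

# Deterministic per-stream seed derivation from a master seed. Kept inside
# 32-bit integer range so set.seed() accepts the result.
derive_seed <- function(master_seed, index, stream = 0L) {
  master_seed <- as.double(master_seed)
  s <- (master_seed %% 2147483647) * 48271 + index * 9973 + stream * 104729
  as.integer(s %% 2147483629) + 1L
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Number of 30-second epochs in a sleep period
#'
#' Nights are scored in fixed 30-second epochs, so an `h`-hour sleep period
#' contains `h * 120` epochs (a 9.8 h night yields 1,176 epochs; a 4.0 h
#' night yields 480).
#'
#' @param hours Sleep period duration in hours.
#' @return Integer epoch count.
#' @examples
#' epochs_per_night(8)
#' @export
epochs_per_night <- function(hours) {
  if (any(hours < 0)) abort("`hours` must be non-negative.")
  as.integer(round(hours * 3600 / 30))
}
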