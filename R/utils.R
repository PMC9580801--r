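#' Round half away from zero
#'
#' Reported percentages use commercial (half-up) rounding rather than the
#' IEEE half-to-even rule of [round()], so that e.g. 72.55 prints as 72.6.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(2.25, 2.35), 1)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # tiny relative nudge guards against 72.5 stored as 72.4999999...
  floor(x * scale + 0.5 + sqrt(.Machine$double.eps) * abs(x) * scale) / scale
}

# Deterministic per-sample substream: a counter-based child seed so that
# subsetting or reordering samples never shifts another sample's draws.
child_seed <- function(seed, index, stage = 0L) {
  a <- 48271
  m <- 2147483647 # 2^31 - 1
  s <- (as.numeric(seed) %% m) + 1
  s <- (s * a + as.numeric(index) * 104729 + as.numeric(stage) * 7919) %% m
  as.integer(s)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

abort_ovmb <- function(msg) stop(msg, call. = FALSE)

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_ovmb(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
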