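#' Per-group sample size for a two-proportion comparison
#'
#' Computes the required number of participants per arm when the primary
#' endpoint is a binary success proportion compared between two arms, using
#' the classical normal-approximation formula
#' \deqn{m = c \frac{\pi_1(1-\pi_1) + \pi_2(1-\pi_2)}{(\pi_1-\pi_2)^2}}
#' where \eqn{c} is a power constant (7.9 corresponds to 80% power at a
#' two-sided 5% level).
#'
#' @param p1,p2 Anticipated success proportions in the two arms, each in
#'   \[0, 1\]. They must differ: equal proportions make the required size
#'   undefined (zero denominator).
#' @param c Power constant (dimensionless), default 7.9 for 80% power.
#' @return The unrounded per-group size (a positive real number). Callers
#'   typically round up to a whole participant.
#' @examples
#' sample_size_per_group(0.25, 0.65) # 20.49 -> 21 per group
#' @seealso [adjust_for_attrition()] for inflating the total for dropout.
#' @export
sample_size_per_group <- function(p1, p2, c = 7.9) {
  stopifnot(is.numeric(p1), is.numeric(p2), is.numeric(c),
            length(p1) == 1L, length(p2) == 1L, length(c) == 1L)
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1)
    stop("proportions must lie in [0, 1]", call. = FALSE)
  if (c <= 0) stop("power constant `c` must be positive", call. = FALSE)
  if (p1 == p2)
    stop("undefined sample size: the two proportions are equal", call. = FALSE)
  c * (p1 * (1 - p1) + p2 * (1 - p2)) / (p1 - p2)^2
}

#' Inflate a total sample size for anticipated attrition
#'
#' Multiplies the calculated total by `1 + rate` and rounds. The default
#' rounding mode is "nearest" (ties away from zero), so a 10% allowance on
#' 42 gives 46.2 and hence 46; mode "ceiling" always rounds up (47 in that
#' example).
#'
#' @param n_total Calculated total sample size (positive integer).
#' @param rate Anticipated attrition fraction in \[0, 1).
#' @param mode Rounding mode, `"nearest"` (default) or `"ceiling"`.
#' @return Integer adjusted sample size, never smaller than `n_total`.
#' @examples
#' adjust_for_attrition(42, 0.10) # 46
#' @export
adjust_for_attrition <- function(n_total, rate, mode = c("nearest", "ceiling")) {
  mode <- match.arg(mode)
  stopifnot(length(n_total) == 1L, length(rate) == 1L)
  if (!is.numeric(n_total) || n_total <= 0 || n_total != round(n_total))
    stop("`n_total` must be a positive integer", call. = FALSE)
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stop("`rate` must be a fraction in [0, 1)", call. = FALSE)
  x <- n_total * (1 + rate)
  n <- switch(mode,
    nearest = floor(x + 0.5), # ties away from zero for positive x
    ceiling = ceiling(x)
  )
  as.integer(max(n, n_total))
}

#' Permuted-block randomization sequence
#'
#' Generates an allocation sequence in fixed-size blocks, each containing
#' equal numbers of every arm in random within-block order, so that arm
#' counts are exactly balanced after every complete block. For two arms and
#' block size 4 there are exactly 6 distinct balanced blocks (4!/(2!2!)),
#' and each block is drawn uniformly from them. A trailing partial block is
#' truncated from a freshly drawn full block, bounding the final imbalance
#' by half the block size.
#'
#' @param n Number of participants to allocate.
#' @param block_size Block length; must be divisible by the number of arms.
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @param arms Character vector of arm labels (default `c("A", "B")`).
#' @return Character vector of length `n` with one arm label per participant.
#' @examples
#' permuted_block_sequence(8, 4, seed = 1)
#' @export
permuted_block_sequence <- function(n, block_size = 4L, seed, arms = c("A", "B")) {
  stopifnot(length(n) == 1L, n >= 1, n == round(n),
            length(block_size) == 1L, block_size >= 1, block_size == round(block_size))
  arms <- as.character(arms)
  if (length(arms) < 2L || anyDuplicated(arms))
    stop("`arms` must contain at least two distinct labels", call. = FALSE)
  if (block_size %% length(arms) != 0L)
    stop("`block_size` must be divisible by the number of arms", call. = FALSE)
  if (missing(seed) || !is.numeric(seed))
    stop("an integer `seed` is required for a reproducible sequence", call. = FALSE)

  per_arm <- block_size %/% length(arms)
  template <- rep(arms, each = per_arm)
  n_blocks <- ceiling(n / block_size)
  out <- withr_seed(seed, {
    unlist(lapply(seq_len(n_blocks), function(i) sample(template)))
  })
  out[seq_len(n)]
}

# Evaluate `expr` under a local RNG seed without disturbing the caller's
# RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Write an allocation sequence to delimited text
#'
#' Exports a randomization list as two-column tab-separated text
#' (`participant_index`, `arm_label`), the layout handed to the person
#' enrolling participants.
#'
#' @param allocation Character vector of arm labels, as returned by
#'   [permuted_block_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_allocation <- function(allocation, path) {
  if (length(allocation) == 0L) stop("empty allocation sequence", call. = FALSE)
  df <- data.frame(participant_index = seq_along(allocation),
                   arm_label = as.character(allocation))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
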