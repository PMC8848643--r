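#' Build a position weight matrix (log-odds) from a PFM
#'
#' Log-odds entries follow the usual pseudocount-regularized form
#' `log2((counts[b,i] + pseudocount*background[b]) / (n_sites + pseudocount) /
#' background[b])`. Entries are then snapped to a fixed score grid whose step
#' is the achievable score range divided by `n_bins` (integer scoring, as
#' FIMO-class scanners do): every window score is an exact multiple of the
#' grid step, which lets [score_pvalue()] compute the exact null tail of the
#' reported scores by dynamic programming rather than an approximation.
#'
#' @param x A [pfm()].
#' @param background Background base probabilities (A,C,G,T), summing to 1.
#' @param pseudocount Total pseudocount distributed by background frequency.
#' @param n_bins Resolution of the score grid (default 10000).
#' @return An object of class `PWM` with elements `log_odds` (grid-snapped
#'   `4 x w` matrix), `q` (integer score matrix), `delta` (grid step),
#'   `background`, `pseudocount`, `width`, `tf_name`.
#' @export
pwm_from_pfm <- function(x, background = rep(0.25, 4), pseudocount = 0.1,
                         n_bins = 10000L) {
  stopifnot(inherits(x, "PFM"))
  if (abs(sum(background) - 1) > 1e-9)
    stop_regsnp("regsnp_format_error", "background must sum to 1")
  n <- sum(x$counts[, 1])
  lo <- log2(sweep(x$counts + pseudocount * background, 1, background, "/") /
               (n + pseudocount))
  score_range <- sum(apply(lo, 2, max)) - sum(apply(lo, 2, min))
  delta <- if (score_range > 0) score_range / n_bins else 1e-9
  q <- round(lo / delta)
  storage.mode(q) <- "integer"
  structure(list(tf_name = x$tf_name, log_odds = q * delta, q = q,
                 delta = delta, background = background,
                 pseudocount = pseudocount, width = ncol(lo),
                 cache = new.env(parent = emptyenv())),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d, score grid step %.3g bits\n",
              x$tf_name, x$width, x$delta))
  invisible(x)
}

# Integer window scores of one strand; NA codes (N bases) give NA.
window_scores_int <- function(q, codes) {
  w <- ncol(q); n_off <- length(codes) - w + 1L
  s <- integer(n_off)
  has_na <- logical(n_off)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n_off - 1L)]
    na_j <- is.na(cj)
    has_na <- has_na | na_j
    cj[na_j] <- 1L
    s <- s + q[cj + (j - 1L) * 4L]
  }
  list(s = s, has_na = has_na)
}

#' Score every window of a sequence against a PWM
#'
#' Every offset on both strands is scored as the sum of log-odds entries over
#' the window (the log-likelihood ratio of the window under the motif versus
#' the background). Windows containing an N score `-Inf`.
#'
#' @param pwm A `PWM`.
#' @param seq A DNA string at least `pwm$width` long.
#' @return A `data.frame` with columns `offset` (0-based window start on the
#'   given sequence), `strand` (`"+"`/`"-"`), and `score`.
#' @export
score_windows <- function(pwm, seq) {
  codes <- encode_dna(seq)
  w <- pwm$width
  if (length(codes) < w)
    stop_regsnp("regsnp_input_error", "sequence shorter than motif width")
  q_rc <- pwm$q[4:1, w:1, drop = FALSE]
  fwd <- window_scores_int(pwm$q, codes)
  rev <- window_scores_int(q_rc, codes)
  n_off <- length(fwd$s)
  sc_f <- fwd$s * pwm$delta; sc_f[fwd$has_na] <- -Inf
  sc_r <- rev$s * pwm$delta; sc_r[rev$has_na] <- -Inf
  data.frame(offset = rep(0:(n_off - 1L), 2L),
             strand = rep(c("+", "-"), each = n_off),
             score = c(sc_f, sc_r))
}

#' Exact null distribution of PWM window scores
#'
#' Computes, by per-position convolution of the integer column score
#' distributions, the exact probability mass function of the window score
#' when bases are drawn i.i.d. from the PWM's background model.
#'
#' @param pwm A `PWM`.
#' @param n_bins Retained for interface compatibility; the resolution is set
#'   when the PWM is built (see [pwm_from_pfm()]) and the distribution is
#'   exact on that grid, so no further binning happens here.
#' @return An object of class `ScoreDistribution` with `bin_edges` (the grid
#'   scores), `probabilities`, `delta`, and integer support bounds.
#' @export
build_score_distribution <- function(pwm, n_bins = NULL) {
  q <- pwm$q
  s_min <- sum(apply(q, 2, min)); s_max <- sum(apply(q, 2, max))
  p <- 1
  off <- 0L
  for (j in seq_len(ncol(q))) {
    cmin <- min(q[, j]); cmax <- max(q[, j])
    newp <- numeric(length(p) + (cmax - cmin))
    for (b in 1:4) {
      sh <- q[b, j] - cmin
      idx <- seq_along(p) + sh
      newp[idx] <- newp[idx] + pwm$background[b] * p
    }
    p <- newp
    off <- off + cmin
  }
  stopifnot(off == s_min, length(p) == s_max - s_min + 1L)
  structure(list(q_min = s_min, q_max = s_max, delta = pwm$delta,
                 bin_edges = (s_min:s_max) * pwm$delta,
                 probabilities = p,
                 survival = rev(cumsum(rev(p)))),
            class = "ScoreDistribution")
}

#' Exact p-value of a PWM match score
#'
#' Probability, under bases drawn i.i.d. from the PWM's background, that a
#' single window scores at least `score`. Monotone non-increasing in `score`;
#' 1 at or below the minimum achievable score, 0 above the maximum.
#'
#' @param pwm A `PWM`.
#' @param score Numeric score(s) as produced by [score_windows()].
#' @param dist Optional precomputed [build_score_distribution()] result; when
#'   omitted the distribution is computed once and cached on the PWM.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
score_pvalue <- function(pwm, score, dist = NULL) {
  if (is.null(dist)) {
    if (is.null(pwm$cache$dist)) pwm$cache$dist <- build_score_distribution(pwm)
    dist <- pwm$cache$dist
  }
  vapply(score, function(s) {
    if (s == -Inf) return(1)
    k <- ceiling(s / dist$delta - 1e-6)
    if (k <= dist$q_min) return(1)
    if (k > dist$q_max) return(0)
    dist$survival[k - dist$q_min + 1L]
  }, numeric(1))
}
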