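#' @title Spearman-Karber median lethal dose estimation
#' @description The serial-dilution toxicity design and the untrimmed
#'   Spearman-Karber LD50 estimator on log10 dose, with explicit boundary
#'   completion when mortality does not bracket 0 and 100%, a binomial
#'   standard error, an optional trim, and an optional isotonic (pooled
#'   adjacent violators) pre-adjustment for non-monotone mortality.
#' @name toxicity
NULL

#' Serial dilution dose design
#'
#' doses[k] = top_dose / factor^(k-1), k = 1..n_doses.
#'
#' @param top_dose Highest dose (> 0).
#' @param n_doses Number of doses (>= 2, default 5).
#' @param factor Dilution factor (> 1, default 2).
#' @return Numeric vector of doses in decreasing order.
#' @export
design_dilution_series <- function(top_dose, n_doses = 5L, factor = 2.0) {
  if (!(top_dose > 0)) stop("top_dose must be positive")
  if (n_doses < 2) stop("n_doses must be at least 2")
  if (!(factor > 1)) stop("dilution factor must exceed 1")
  top_dose / factor^(seq_len(n_doses) - 1L)
}

#' Construct a dose-response table
#'
#' @param dose Strictly monotone positive doses (mg/kg).
#' @param n Positive group sizes.
#' @param deaths Non-negative death counts, at most `n`.
#' @return A data frame of class `dose_response_table`.
#' @export
dose_response_table <- function(dose, n, deaths) {
  stopifnot(length(dose) == length(n), length(dose) == length(deaths))
  if (any(dose <= 0)) stop("doses must be positive")
  d <- diff(dose)
  if (!(all(d > 0) || all(d < 0))) stop("doses must be strictly monotone")
  if (any(n < 1)) stop("group sizes must be positive")
  if (any(deaths < 0 | deaths > n)) stop("deaths must lie in [0, n]")
  structure(data.frame(dose = dose, n = as.integer(n),
                       deaths = as.integer(deaths)),
            class = c("dose_response_table", "data.frame"))
}

# Weighted pooled-adjacent-violators algorithm toward nondecreasing values.
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  val <- y
  wt <- w
  size <- rep(1L, n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    val[m] <- y[i]; wt[m] <- w[i]; size[m] <- 1L
    while (m > 1L && val[m - 1L] > val[m]) {
      tot <- wt[m - 1L] + wt[m]
      val[m - 1L] <- (wt[m - 1L] * val[m - 1L] + wt[m] * val[m]) / tot
      wt[m - 1L] <- tot
      size[m - 1L] <- size[m - 1L] + size[m]
      m <- m - 1L
    }
  }
  rep(val[seq_len(m)], size[seq_len(m)])
}

#' Isotonic adjustment of mortality proportions
#'
#' Pooled-adjacent-violators regression toward proportions nondecreasing
#' with dose, weighted by group size. Off by default in
#' [spearman_karber_ld50()]; the estimator itself tolerates mild
#' non-monotonicity.
#'
#' @param p Proportions in [0, 1], ordered by ascending dose.
#' @param weights Group sizes (default equal).
#' @return Adjusted nondecreasing proportions.
#' @export
monotone_adjust <- function(p, weights = rep(1, length(p))) {
  stopifnot(all(p >= 0 & p <= 1), length(weights) == length(p))
  pava(p, weights)
}

#' Spearman-Karber LD50 estimate
#'
#' Works on log10 dose. With proportions p_i at ascending log-doses x_i and
#' equal spacing d, the untrimmed estimator is log10 LD50 =
#' x_max + d/2 - d * sum(p_i), computed here in its trapezoid form
#' sum over i of (p_{i+1} - p_i) (x_i + x_{i+1}) / 2, which also covers
#' unequal spacing (a warning notes the generalization). When mortality
#' does not span 0 to 1, boundary proportions are completed by assumption
#' (p = 0 one dilution step below the lowest dose, p = 1 one step above the
#' highest) and a warning records the extrapolation. The standard error on
#' log10 LD50 is the binomial Spearman-Karber form
#' sqrt(sum p_i (1 - p_i) / (n_i - 1) * d_i^2), available when all group
#' sizes exceed 1.
#'
#' @param table A [dose_response_table()].
#' @param trim Symmetric trim fraction in [0, 0.1]; 0 (default) gives the
#'   untrimmed estimator. Proportions are rescaled to
#'   (p - trim) / (1 - 2 trim) and clipped to [0, 1] before integration.
#' @param isotonic Apply [monotone_adjust()] first (default FALSE).
#' @return A list of class `ld50_estimate`: `ld50` (same units as the
#'   doses), `log10_se`, `warnings`.
#' @export
spearman_karber_ld50 <- function(table, trim = 0, isotonic = FALSE) {
  stopifnot(inherits(table, "dose_response_table"), trim >= 0, trim <= 0.1)
  if (nrow(table) < 2L) stop("at least two doses are required")
  tab <- table[order(table$dose), ]
  x <- log10(tab$dose)
  p <- tab$deaths / tab$n
  warnings <- character(0)
  if (all(p == 0) || all(p == 1))
    stop("LD50 outside tested range: mortality is ",
         if (all(p == 0)) "0%" else "100%", " at every dose")
  if (isotonic) p <- monotone_adjust(p, tab$n)
  spacing <- diff(x)
  equal <- max(spacing) - min(spacing) < 1e-6
  if (!equal)
    warnings <- c(warnings,
                  "unequal log-dose spacing; trapezoid generalization used")
  # boundary completion one dilution step outside the tested range
  if (p[1L] > 0) {
    x <- c(x[1L] - spacing[1L], x)
    p <- c(0, p)
    warnings <- c(warnings,
                  "mortality above 0% at the lowest dose; assumed p = 0 one step below")
  }
  if (p[length(p)] < 1) {
    x <- c(x, x[length(x)] + spacing[length(spacing)])
    p <- c(p, 1)
    warnings <- c(warnings,
                  "mortality below 100% at the highest dose; assumed p = 1 one step above")
  }
  if (trim > 0) p <- pmin(1, pmax(0, (p - trim) / (1 - 2 * trim)))
  k <- length(p)
  m <- sum(diff(p) * (x[-k] + x[-1L]) / 2)
  log10_se <- if (all(tab$n > 1L)) {
    po <- tab$deaths / tab$n
    xo <- log10(tab$dose)
    half_span <- if (length(xo) == 2L) rep(diff(xo), 2L) else
      c(xo[2L] - xo[1L],
        (xo[-(1:2)] - xo[seq_len(length(xo) - 2L)]) / 2,
        xo[length(xo)] - xo[length(xo) - 1L])
    sqrt(sum(po * (1 - po) / (tab$n - 1L) * half_span^2))
  } else {
    warnings <- c(warnings, "group size 1 at some dose; no standard error")
    NA_real_
  }
  structure(list(ld50 = 10^m, log10_se = log10_se, warnings = warnings),
            class = "ld50_estimate")
}

#' @export
print.ld50_estimate <- function(x, ...) {
  cat(sprintf("LD50 = %.4g (log10 SE %.3g)\n", x$ld50, x$log10_se))
  for (w in x$warnings) cat(" note:", w, "\n")
  invisible(x)
}
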