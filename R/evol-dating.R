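# Ks-based divergence dating and printed-arithmetic consistency reports.

#' Peak of a Ks distribution
#'
#' Gaussian-kernel density estimate (Silverman's rule by default) over
#' `[0, cutoff)`; values at or above the saturation cutoff are excluded.
#' The global mode is returned; all local maxima are listed by height.
#'
#' @param ks Ks samples (synonymous substitutions per synonymous site).
#' @param bandwidth Bandwidth passed to [stats::density()] (default
#'   `"nrd0"`, Silverman's rule).
#' @param cutoff Saturation cutoff (default 3).
#' @param n_min Minimum usable samples (default 50).
#' @return List with `peak` and `modes` (data frame `ks, density`, ordered
#'   by decreasing density).
#' @export
ks_peak <- function(ks, bandwidth = "nrd0", cutoff = 3, n_min = 50) {
  x <- ks[!is.na(ks) & ks >= 0 & ks < cutoff]
  if (length(x) < n_min)
    stop("need at least ", n_min, " Ks samples below the saturation cutoff")
  if (length(unique(x)) == 1)
    return(list(peak = x[1], modes = data.frame(ks = x[1], density = Inf)))
  d <- density(x, bw = bandwidth, from = 0, to = cutoff, n = 2048)
  y <- d$y
  loc <- which(y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf))
  modes <- data.frame(ks = d$x[loc], density = y[loc])
  modes <- modes[order(-modes$density), , drop = FALSE]
  rownames(modes) <- NULL
  list(peak = modes$ks[1], modes = modes)
}

#' Divergence time from Ks under a molecular clock
#'
#' `T = Ks / (2 r)` in million years, with `r` the synonymous substitution
#' rate per site per year (default 1.4e-8; the factor 2 accounts for the
#' two lineages accumulating substitutions independently).
#'
#' @param ks Ks value(s), non-negative.
#' @param rate Substitution rate per site per year.
#' @return Time(s) in Mya.
#' @export
divergence_time <- function(ks, rate = 1.4e-8) {
  if (any(ks < 0)) stop("negative ks")
  if (rate <= 0) stop("rate must be > 0")
  ks / (2 * rate) / 1e6
}

#' Derived proportions and ratios from summary counts
#'
#' Pure arithmetic over numerator/denominator pairs, rounded half-up at the
#' printed precision for each kind: `ratio` (2 decimals), `percent`
#' (value 100*num/denom, 2 decimals), `fold` (1 decimal).
#'
#' @param counts Data frame with columns `name, numerator, denominator,
#'   kind` (`kind` in `ratio, percent, fold`).
#' @return Data frame `name, value`.
#' @export
consistency_report <- function(counts) {
  stopifnot(all(c("name", "numerator", "denominator", "kind") %in%
                  names(counts)))
  if (any(counts$denominator == 0)) stop("zero denominator")
  if (!all(counts$kind %in% c("ratio", "percent", "fold")))
    stop("kind must be ratio, percent or fold")
  raw <- counts$numerator / counts$denominator
  value <- ifelse(counts$kind == "percent",
                  round_half_up(100 * raw, 2),
                  ifelse(counts$kind == "fold",
                         round_half_up(raw, 1), round_half_up(raw, 2)))
  data.frame(name = counts$name, value = value, stringsAsFactors = FALSE)
}
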