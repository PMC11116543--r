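#' Read a two-concentration assay table
#'
#' Expected CSV columns: \code{compound_id}, \code{concentration_uM},
#' \code{inhibition_pct} (mean \% inhibition; may exceed the 0-100 window
#' experimentally), \code{sem_pct}, \code{n} (replicates).
#'
#' @param path CSV file path.
#' @return data.frame of assay measurements.
#' @export
readAssayTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("compound_id", "concentration_uM", "inhibition_pct", "sem_pct")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop(sprintf("assay CSV lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (any(d$concentration_uM <= 0)) stop("concentrations must be positive")
  if (any(d$sem_pct < 0)) stop("SEM must be non-negative")
  d
}

#' Call hits from a percent-inhibition screen
#'
#' A compound is a hit at a concentration when its effective inhibition
#' crosses the threshold (default 20\%). The default rule credits the
#' standard error: mean + SEM >= threshold; \code{rule = "mean"} uses the
#' mean alone, \code{"mean_minus_sem"} the most conservative reading. A
#' compound is an overall hit when it is a hit at any concentration.
#'
#' @param measurements data.frame as from \code{\link{readAssayTable}}.
#' @param thresholdPct inclusive inhibition threshold in percent.
#' @param rule \code{"mean_plus_sem"} (default), \code{"mean"} or
#'   \code{"mean_minus_sem"}.
#' @return data.frame with one row per compound: \code{compound_id}, one
#'   logical \code{hit_<conc>} column per concentration, and \code{hit_any}.
#' @export
callHits <- function(measurements, thresholdPct = 20,
                     rule = c("mean_plus_sem", "mean", "mean_minus_sem")) {
  rule <- match.arg(rule)
  key <- paste(measurements$compound_id, measurements$concentration_uM)
  if (anyDuplicated(key)) {
    stop("duplicate (compound, concentration) rows in assay table")
  }
  eff <- switch(rule,
                mean_plus_sem = measurements$inhibition_pct + measurements$sem_pct,
                mean = measurements$inhibition_pct,
                mean_minus_sem = measurements$inhibition_pct - measurements$sem_pct)
  hit <- eff >= thresholdPct
  concs <- sort(unique(measurements$concentration_uM))
  ids <- unique(measurements$compound_id)
  out <- data.frame(compound_id = ids, stringsAsFactors = FALSE)
  for (cc in concs) {
    col <- rep(NA, length(ids))
    rows <- measurements$concentration_uM == cc
    col[match(measurements$compound_id[rows], ids)] <- hit[rows]
    out[[sprintf("hit_%g", cc)]] <- col
  }
  hitcols <- grep("^hit_", names(out), value = TRUE)
  out$hit_any <- apply(out[, hitcols, drop = FALSE], 1L,
                       function(r) any(r, na.rm = TRUE))
  out
}

#' Hit rates per concentration and overall
#'
#' @param flags data.frame from \code{\link{callHits}}.
#' @return named numeric vector of percentages at 1 decimal: one entry per
#'   \code{hit_<conc>} column plus \code{overall}.
#' @examples
#' # 61 hits of 66 assayed -> 92.4%
#' @export
hitRate <- function(flags) {
  hitcols <- grep("^hit_", names(flags), value = TRUE)
  rates <- vapply(hitcols, function(col) {
    v <- flags[[col]]
    round(100 * sum(v, na.rm = TRUE) / sum(!is.na(v)), 1)
  }, numeric(1))
  names(rates) <- sub("^hit_any$", "overall", hitcols)
  rates
}

#' Two-point IC50 estimation under the three-parameter logistic model
#'
#' With the bottom fixed at 0\% and the top at 100\% (defined by vehicle
#' and reference-inhibitor controls), the three-parameter logistic
#' \deqn{y = 100 / (1 + (IC_{50}/x)^h)} is exactly determined by two
#' (concentration, inhibition) points, giving the closed form
#' \deqn{h = \ln[(100/y_1 - 1)/(100/y_2 - 1)] / \ln(x_2/x_1)}
#' \deqn{IC_{50} = x_1 (100/y_1 - 1)^{1/h}.}
#' Flags: \code{no_inhibition} when both responses are <= 0;
#' \code{out_of_range} when any response is outside (0, 100) or the pair is
#' non-increasing (no finite solution); \code{ok} otherwise.
#'
#' @param yLow inhibition (\%) at the lower concentration.
#' @param yHigh inhibition (\%) at the higher concentration.
#' @param xLow,xHigh the two concentrations (uM), \code{xLow < xHigh}.
#' @return data.frame with \code{ic50} (uM), \code{hill} and \code{flag}
#'   (\code{ok}, \code{no_inhibition}, \code{out_of_range}); estimates are
#'   NA unless \code{flag == "ok"}. Vectorized over \code{yLow}/\code{yHigh}.
#' @examples
#' estimateIC50TwoPoint(50, 250/3, 10, 50)  # IC50 = 10 uM, hill = 1
#' @export
estimateIC50TwoPoint <- function(yLow, yHigh, xLow = 10, xHigh = 50) {
  if (!(xLow > 0 && xHigh > xLow)) {
    stop("need 0 < xLow < xHigh")
  }
  n <- max(length(yLow), length(yHigh))
  yLow <- rep_len(yLow, n); yHigh <- rep_len(yHigh, n)
  flag <- rep("ok", n)
  flag[yLow >= 100 | yHigh >= 100] <- "out_of_range"
  flag[yLow <= 0 | yHigh <= 0] <- "out_of_range"
  flag[yHigh <= yLow] <- "out_of_range"
  flag[yLow <= 0 & yHigh <= 0] <- "no_inhibition"
  ic50 <- hill <- rep(NA_real_, n)
  ok <- flag == "ok"
  if (any(ok)) {
    fl <- 100 / yLow[ok] - 1
    fh <- 100 / yHigh[ok] - 1
    h <- log(fl / fh) / log(xHigh / xLow)
    ic50[ok] <- xLow * fl^(1 / h)
    hill[ok] <- h
  }
  data.frame(ic50 = ic50, hill = hill, flag = flag, stringsAsFactors = FALSE)
}

#' Forward three-parameter logistic response
#'
#' @param x concentration (uM).
#' @param ic50 half-maximal inhibitory concentration (uM).
#' @param hill Hill slope.
#' @return inhibition in percent.
#' @export
logistic3pl <- function(x, ic50, hill) {
  100 / (1 + (ic50 / x)^hill)
}

#' Fraction of potent estimates
#'
#' Share of successfully estimated (\code{flag == "ok"}) compounds whose
#' IC50 falls strictly below the cutoff; the denominator is the active
#' compounds only.
#'
#' @param estimates data.frame from \code{\link{estimateIC50TwoPoint}}, or
#'   any data.frame with \code{ic50} and \code{flag} columns.
#' @param cutoff potency cutoff in uM (strict \code{<}).
#' @return percentage at 1 decimal.
#' @export
potencySummary <- function(estimates, cutoff = 50) {
  ok <- estimates$flag == "ok"
  if (!any(ok)) stop("no successfully estimated compounds")
  round(100 * sum(estimates$ic50[ok] < cutoff) / sum(ok), 1)
}
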