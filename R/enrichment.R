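#' Co-localisation flags between two channels
#'
#' A channel-A localisation is co-localised (TRUE) iff its nearest channel-B
#' localisation lies within `threshold` (same units as the coordinates; 10 nm
#' is the reference threshold for phosphorylation scoring).
#'
#' @param channelA,channelB `kna_locs` tables (B may be empty: all FALSE).
#' @param threshold Non-negative distance threshold.
#' @return Logical vector over the rows of `channelA`.
#' @export
colocalise <- function(channelA, channelB, threshold = 10) {
  if (threshold < 0) stop("threshold must be non-negative")
  if (nrow(channelB) == 0) return(rep(FALSE, nrow(channelA)))
  d <- .nn_cross(channelA$x, channelA$y, channelB$x, channelB$y)
  d <= threshold
}

#' Per-group enrichment scores for a co-localised subset
#'
#' For each localisation group k, Freq(k) is the share of all channel-A
#' localisations in k and Freq(k AND TRUE) the share of the co-localised ones;
#' the enrichment score is `log10(Freq(k AND TRUE) / Freq(k))`. Positive
#' scores mean the second channel (e.g. phosphorylation) is over-represented
#' in group k, negative under-represented. Base-10 logs make a doubled share
#' score log10(2) = 0.301.
#'
#' Groups with zero co-localised members get `pseudocount` added to their
#' co-localised count before normalisation (and are flagged); under
#' `zero_policy = "strict"` they score -Inf instead.
#'
#' @param groups Integer/factor group label per channel-A localisation (NAs
#'   dropped).
#' @param flags Logical co-localisation flags (same length).
#' @param pseudocount Added to zero co-localised counts (default 0.5).
#' @param zero_policy `"pseudocount"` or `"strict"`.
#' @return Object of class `kna_enrichment`: data frame with `group`, `Freq`,
#'   `FreqTRUE`, `score`, `pseudocount_applied`, plus attributes `n_p`
#'   (co-localised count) and `levels`.
#' @export
enrichment_scores <- function(groups, flags, pseudocount = 0.5,
                              zero_policy = c("pseudocount", "strict")) {
  zero_policy <- match.arg(zero_policy)
  keep <- !is.na(groups)
  groups <- factor(groups[keep])
  flags <- flags[keep]
  if (!any(flags)) stop("no co-localised localisations (all flags FALSE)")
  n_p <- sum(flags)
  freq_all <- as.vector(table(groups)) / length(groups)
  cnt_true <- as.vector(table(groups[flags]))
  flagged <- cnt_true == 0
  if (any(flagged) && zero_policy == "pseudocount")
    cnt_true[flagged] <- pseudocount
  freq_true <- cnt_true / sum(cnt_true)
  score <- log10(freq_true / freq_all)
  if (zero_policy == "strict") score[flagged] <- -Inf
  out <- data.frame(group = levels(groups), Freq = freq_all,
                    FreqTRUE = freq_true, score = score,
                    pseudocount_applied = flagged)
  attr(out, "n_p") <- n_p
  attr(out, "levels") <- levels(groups)
  class(out) <- c("kna_enrichment", "data.frame")
  out
}

#' Multinomial null band for enrichment scores
#'
#' Under random assignment of co-localisation, the co-localised group counts
#' are multinomial(n_p, Freq). Each replicate draws such a vector, normalises
#' it to sum to one and scores it against Freq with the same scoring rule (and
#' zero policy) as the observed data; the per-group 5th and 95th percentiles
#' of the replicate scores form the null band. Across an ensemble of images,
#' report per group the minimum of the 5th and the maximum of the 95th
#' percentiles (see [ensemble_null_band()]).
#'
#' @param freq Group frequency vector (sums to 1).
#' @param n_p Number of co-localised localisations (>= 1).
#' @param reps Replicates (default 10000).
#' @param seed Integer seed.
#' @param pseudocount,zero_policy As in [enrichment_scores()].
#' @return Data frame with per-group `null_lo` (5th) and `null_hi` (95th).
#' @export
null_enrichment <- function(freq, n_p, reps = 10000, seed = 1,
                            pseudocount = 0.5,
                            zero_policy = c("pseudocount", "strict")) {
  zero_policy <- match.arg(zero_policy)
  if (abs(sum(freq) - 1) > 1e-8) stop("freq must sum to 1")
  if (n_p < 1) stop("n_p must be >= 1")
  if (reps < 100) warning("fewer than 100 replicates gives unstable percentiles")
  draws <- with_seed(seed, rmultinom(reps, n_p, freq))  # groups x reps
  draws <- matrix(as.numeric(draws), nrow = length(freq))
  if (zero_policy == "pseudocount") {
    draws[draws == 0] <- pseudocount
  }
  props <- sweep(draws, 2, colSums(draws), "/")
  scores <- log10(props / freq)                         # recycles freq by row
  qs <- apply(scores, 1, quantile, probs = c(0.05, 0.95), names = FALSE)
  data.frame(null_lo = qs[1, ], null_hi = qs[2, ])
}

#' Ensemble summary of per-image null bands
#'
#' @param bands List of per-image data frames from [null_enrichment()].
#' @return Data frame with the per-group minimum `null_lo` and maximum
#'   `null_hi` over all images.
#' @export
ensemble_null_band <- function(bands) {
  lo <- do.call(cbind, lapply(bands, `[[`, "null_lo"))
  hi <- do.call(cbind, lapply(bands, `[[`, "null_hi"))
  data.frame(null_lo = apply(lo, 1, min), null_hi = apply(hi, 1, max))
}

#' Enrichment scores across co-localisation thresholds
#'
#' Recomputes [enrichment_scores()] for each threshold (sorted ascending in
#' the output). As the threshold exceeds the pattern's extent every channel-A
#' localisation co-localises and all scores approach zero.
#'
#' @param channelA,channelB `kna_locs` tables.
#' @param groups Group label per channel-A localisation.
#' @param thresholds Distance thresholds (default `c(10, 20, 30, 500)` nm).
#' @param ... Passed to [enrichment_scores()].
#' @return Numeric matrix thresholds x groups of scores, with thresholds as
#'   rownames.
#' @export
multi_threshold_profile <- function(channelA, channelB, groups,
                                    thresholds = c(10, 20, 30, 500), ...) {
  thresholds <- sort(thresholds)
  d <- if (nrow(channelB) > 0)
    .nn_cross(channelA$x, channelA$y, channelB$x, channelB$y)
  else rep(Inf, nrow(channelA))
  lev <- levels(factor(groups[!is.na(groups)]))
  out <- matrix(NA_real_, nrow = length(thresholds), ncol = length(lev),
                dimnames = list(format(thresholds, trim = TRUE), lev))
  for (i in seq_along(thresholds)) {
    sc <- enrichment_scores(groups, d <= thresholds[i], ...)
    out[i, match(sc$group, lev)] <- sc$score
  }
  out
}
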