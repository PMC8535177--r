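#' Bin an attention profile onto a fixed time-normalized grid
#'
#' Utterance `t` (0-indexed) of a length-`L` profile assigns its weight to
#' bin `floor(t * n_bins / L)`; the binned mass is rescaled by `n_bins`, so a
#' perfectly uniform profile maps to the constant 1.0 regardless of session
#' length. This makes curves from sessions of different lengths directly
#' averageable.
#'
#' @param profile A `ctrs_attention` (list with `weights`) or a bare
#'   nonnegative weight vector summing to 1.
#' @param n_bins Number of time bins (default 100).
#' @return Numeric vector of length `n_bins`; its mean is 1 whenever the
#'   input weights sum to 1.
#' @export
normalize_attention_time <- function(profile, n_bins = 100L) {
  w <- if (is.list(profile)) profile$weights else profile
  L <- length(w)
  stopifnot(L >= 1L, n_bins >= 1L)
  bin <- pmin(floor((seq_len(L) - 1L) * n_bins / L), n_bins - 1L) + 1L
  out <- numeric(n_bins)
  agg <- rowsum(w, bin)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out * n_bins
}

#' Aggregate attention profiles into mean saliency curves
#'
#' Per head, the element-wise mean of the time-binned profiles over sessions
#' (only held-out, test-fold profiles should be aggregated, so the curves
#' describe generalization rather than training fit). For multi-task input an
#' additional `mean-of-codes` curve — the unweighted average of the 11
#' per-code curves — is emitted.
#'
#' @param profiles_by_session List over sessions, each a list of
#'   `ctrs_attention` profiles (as in the `attention` fields produced by
#'   [predict_sessions()] or [crossvalidate_model()]).
#' @param n_bins Number of time bins.
#' @return Object of class `ctrs_saliency`: a list of curves, each with
#'   `head_id`, `bins` (length-`n_bins` mean mass) and `n_sessions`.
#' @export
aggregate_saliency <- function(profiles_by_session, n_bins = 100L) {
  heads <- unique(unlist(lapply(profiles_by_session, function(pl)
    vapply(pl, `[[`, "", "head_id"))))
  curves <- list()
  for (h in heads) {
    binned <- list()
    for (pl in profiles_by_session) {
      hit <- Filter(function(p) p$head_id == h, pl)
      if (length(hit))
        binned[[length(binned) + 1L]] <- normalize_attention_time(hit[[1L]],
                                                                  n_bins)
    }
    if (!length(binned)) {
      warning("no profiles for head ", h, "; head omitted")
      next
    }
    curves[[h]] <- structure(
      list(head_id = h, bins = colMeans(do.call(rbind, binned)),
           n_sessions = length(binned)),
      class = "ctrs_saliency_curve")
  }
  code_heads <- intersect(CTRS_CODES, names(curves))
  if (length(code_heads) == 11L) {
    curves[["mean-of-codes"]] <- structure(
      list(head_id = "mean-of-codes",
           bins = colMeans(do.call(rbind, lapply(curves[code_heads],
                                                 `[[`, "bins"))),
           n_sessions = curves[[code_heads[[1L]]]]$n_sessions),
      class = "ctrs_saliency_curve")
  }
  structure(curves, class = "ctrs_saliency")
}

#' Decile means of a saliency curve
#'
#' @param curve A `ctrs_saliency_curve`.
#' @return Length-10 vector of decile means (1.0 = uniform attention level).
#' @export
saliency_deciles <- function(curve) {
  b <- curve$bins
  dec <- cut(seq_along(b), 10L, labels = FALSE)
  as.vector(tapply(b, dec, mean))
}

#' Write saliency curves as CSV
#'
#' @param saliency A `ctrs_saliency`.
#' @param path Output path (columns head_id, bin, value).
#' @return The data frame, invisibly.
#' @export
write_saliency_csv <- function(saliency, path) {
  df <- do.call(rbind, lapply(saliency, function(cu)
    data.frame(head_id = cu$head_id, bin = seq_along(cu$bins),
               value = cu$bins)))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Plot saliency curves
#'
#' Line plot of mean time-normalized attention mass, one line per requested
#' head, with the uniform level 1.0 marked.
#'
#' @param x A `ctrs_saliency`.
#' @param heads Head ids to draw (default: all).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ctrs_saliency <- function(x, heads = names(x), ...) {
  heads <- intersect(heads, names(x))
  stopifnot(length(heads) > 0)
  Y <- do.call(cbind, lapply(x[heads], `[[`, "bins"))
  graphics::matplot(seq_len(nrow(Y)) / nrow(Y), Y, type = "l", lty = 1,
                    lwd = 2, col = seq_along(heads),
                    xlab = "normalized session time",
                    ylab = "mean attention mass (1 = uniform)", ...)
  graphics::abline(h = 1, lty = 3, col = "grey40")
  graphics::legend("topright", legend = heads, col = seq_along(heads),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}
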