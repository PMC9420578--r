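#' EEG rhythm band edges
#'
#' The five clinical EEG rhythms and their frequency edges in Hz. This one
#' table is shared by the synthetic generator, the harmonic wavelet packet
#' transform and the band-energy-ratio features, so simulated band placement
#' and measured band energy always refer to the same edges.
#'
#' @details Edges follow the standard clinical convention:
#' delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-45 Hz.
#' Bands are half-open `[low, high)`, non-overlapping and ascending.
#'
#' @param bands optional named list overriding the defaults; names must be
#'   exactly the five rhythms, each a numeric `c(low, high)`.
#' @return a named list of `c(low, high)` pairs (Hz), in ascending order.
#' @examples
#' rhythmBands()$alpha
#' @export
rhythmBands <- function(bands = NULL) {
  default <- list(
    delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
    beta  = c(13, 30), gamma = c(30, 45)
  )
  if (is.null(bands)) return(default)
  validateBands(bands)
  bands
}

rhythmNames <- function() c("delta", "theta", "alpha", "beta", "gamma")

validateBands <- function(bands) {
  if (!is.list(bands) || !identical(sort(names(bands)), sort(rhythmNames())))
    stop("bands must be a named list covering exactly: ",
         paste(rhythmNames(), collapse = ", "), call. = FALSE)
  edges <- do.call(rbind, bands[rhythmNames()])
  if (any(edges[, 2] <= edges[, 1]))
    stop("each band needs high > low", call. = FALSE)
  ord <- bands[rhythmNames()]
  for (i in seq_len(length(ord) - 1))
    if (ord[[i + 1]][1] < ord[[i]][2])
      stop("bands must be non-overlapping and ascending", call. = FALSE)
  invisible(TRUE)
}

## Highest band edge; fs must exceed twice this for generation/analysis.
maxBandEdge <- function(bands = rhythmBands()) max(vapply(bands, `[`, 0, 2))
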