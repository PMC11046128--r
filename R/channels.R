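#' Cell Painting channel-to-organelle map
#'
#' The five fluorescent channels of the Cell Painting assay and the organelle
#' compartments they report: Hoechst (nucleus), concanavalin A (endoplasmic
#' reticulum), SYTO 14 (cytoplasmic RNA / nucleolus), phalloidin + WGA
#' (F-actin, Golgi, cell membrane) and MitoTracker (mitochondria). The row
#' order is the fixed channel order used everywhere in the package, including
#' tie-breaking during organelle attribution.
#'
#' @return A data.frame with columns `name` (channel identifier) and `index`
#'   (0-based channel index, bijective with 0..4).
#' @export
#' @examples
#' channel_specs()
channel_specs <- function() {
  data.frame(
    name = c("nucleus", "endoplasmic_reticulum", "rna_nucleolus",
             "actin_membrane_golgi", "mitochondria"),
    index = 0:4,
    stringsAsFactors = FALSE
  )
}

#' @rdname channel_specs
#' @export
channel_names <- function() channel_specs()$name

n_channels <- function() 5L

#' Resolve a channel name to its 1-based array slot
#'
#' @param channel Channel name (see [channel_names()]) or a 1-based integer.
#' @return 1-based integer index into the channel dimension of a field or crop.
#' @export
channel_slot <- function(channel) {
  if (is.numeric(channel)) {
    channel <- as.integer(channel)
    stopifnot(channel >= 1L, channel <= n_channels())
    return(channel)
  }
  i <- match(channel, channel_names())
  if (is.na(i)) {
    stop("unknown channel '", channel, "'; expected one of: ",
         paste(channel_names(), collapse = ", "))
  }
  i
}

# deterministic 31-bit seed mixer for deriving stream seeds from a master seed;
# exact in double arithmetic (intermediates < 2^53)
mix_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  h <- 17
  for (v in parts) {
    h <- (h * 31 + abs(v) + 1) %% 2147483629
  }
  as.integer(h %% 2147483587 + 1)
}
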