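#' Encode a Boolean activity pattern as an integer state label
#'
#' A network state is the Boolean activation pattern over the ten encoded
#' populations (see \code{\link{encodedPopulations}}).  The label is the
#' base-2 value of the pattern under the fixed bit order (MSB to LSB)
#' dSPN-L, dSPN-R, iSPN-L, iSPN-R, GPi-L, GPi-R, GPeP-L, GPeP-R, Th-L,
#' Th-R, so labels run from 0 (all silent) to 1023 (all active).  Under
#' this order the pre-stimulated launch state (GPi and GPeP active
#' bilaterally) is state 60.
#'
#' @param pattern Logical or 0/1 vector of length 10, ordered as
#'   \code{encodedPopulations()}.  A named vector is re-ordered by name.
#' @return Integer label in [0, 1023].
#' @seealso \code{\link{decodeState}}, \code{\link{mirrorState}}
#' @examples
#' p <- setNames(rep(0, 10), encodedPopulations())
#' p[c("GPi-L", "GPi-R", "GPeP-L", "GPeP-R")] <- 1
#' encodeState(p)  # 60
#' @export
encodeState <- function(pattern) {
  if (!is.null(names(pattern))) {
    if (!setequal(names(pattern), .encodedOrder))
      stop("named pattern must cover exactly the 10 encoded populations")
    pattern <- pattern[.encodedOrder]
  }
  if (length(pattern) != 10L)
    stop("pattern must have length 10, got ", length(pattern))
  bits <- as.integer(as.logical(pattern))
  if (anyNA(bits)) stop("pattern contains non-Boolean values")
  as.integer(sum(bits * 2^(9:0)))
}

#' Decode an integer state label into its Boolean pattern
#'
#' Inverse of \code{\link{encodeState}}.
#'
#' @param label Integer in [0, 1023].
#' @return Named integer 0/1 vector over \code{encodedPopulations()}.
#' @export
decodeState <- function(label) {
  label <- as.integer(label)
  if (is.na(label) || label < 0L || label > 1023L)
    stop("state label must be an integer in [0, 1023]")
  bits <- as.integer(bitwAnd(label, 2L^(9:0)) > 0L)
  names(bits) <- .encodedOrder
  bits
}

#' Mirror a state label across action channels
#'
#' Exchanges the left- and right-channel bits of the pattern, mapping e.g.
#' left-commitment states onto their right-channel counterparts.
#'
#' @param label Integer state label (vectorized).
#' @return Integer label(s) of the channel-swapped pattern.
#' @examples
#' mirrorState(575)  # right-channel counterpart of the left dSPN state
#' @export
mirrorState <- function(label) {
  vapply(label, function(l) {
    bits <- decodeState(l)
    names(bits) <- swapChannels(names(bits))
    encodeState(bits)
  }, integer(1))
}
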