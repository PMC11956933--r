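#' CBGT population table
#'
#' The model circuit contains 18 population instances: eight lateralized
#' populations (cortex Cx, direct and indirect striatal projection neurons
#' dSPN/iSPN, prototypic and arkypallidal external pallidum GPeP/GPeA,
#' subthalamic nucleus STN, internal pallidum GPi, thalamus Th), each
#' duplicated into a left and a right action channel, plus two populations
#' shared across channels (cortical interneurons CxI and striatal
#' fast-spiking interneurons FSI).
#'
#' @return A data.frame with columns \code{name} (e.g. \code{"dSPN-L"}),
#'   \code{region} (e.g. \code{"dSPN"}) and \code{channel}
#'   (\code{"left"}, \code{"right"} or \code{"shared"}).
#' @examples
#' cbgtPopulations()
#' @export
cbgtPopulations <- function() {
  region <- c("Cx", "Cx", "CxI", "FSI",
              "dSPN", "dSPN", "iSPN", "iSPN",
              "GPeP", "GPeP", "GPeA", "GPeA",
              "STN", "STN", "GPi", "GPi", "Th", "Th")
  channel <- c("left", "right", "shared", "shared",
               rep(c("left", "right"), 7))
  name <- ifelse(channel == "shared", region,
                 paste0(region, "-", ifelse(channel == "left", "L", "R")))
  data.frame(name = name, region = region, channel = channel,
             stringsAsFactors = FALSE)
}

#' Names of the 18 CBGT populations in canonical order
#' @return Character vector of length 18.
#' @export
populationNames <- function() cbgtPopulations()$name

# Encoded populations in the fixed bit order (MSB -> LSB).  This order is the
# one that reproduces every integer state label quoted for the decision graph
# (60 = GPi + GPeP bilaterally, 63 adds both thalamic bits, 575 = 63 + dSPN-L,
# 543 = 575 - GPi-L, and so on).
.encodedOrder <- c("dSPN-L", "dSPN-R", "iSPN-L", "iSPN-R",
                   "GPi-L", "GPi-R", "GPeP-L", "GPeP-R",
                   "Th-L", "Th-R")

#' Populations entering the integer state code
#'
#' Ten populations (dSPN, iSPN, GPi, GPeP and Th for both channels) define
#' the Boolean state of the network.  The returned order is the fixed bit
#' order of the encoding, most significant bit first.
#'
#' @return Character vector of length 10.
#' @export
encodedPopulations <- function() .encodedOrder

# Auxiliary populations whose bits are tracked alongside states but do not
# enter the label (their activation probabilities are reported per state).
.auxOrder <- c("STN-L", "STN-R", "GPeA-L", "GPeA-R")

#' Auxiliary binarized populations (STN and GPeA, both channels)
#' @return Character vector of length 4.
#' @export
auxPopulations <- function() .auxOrder

#' Swap the left and right action channels of a population name vector
#'
#' @param names Character vector of population names.
#' @return Character vector with \code{-L} and \code{-R} suffixes exchanged;
#'   shared populations are returned unchanged.
#' @export
swapChannels <- function(names) {
  out <- names
  isL <- grepl("-L$", names)
  isR <- grepl("-R$", names)
  out[isL] <- sub("-L$", "-R", names[isL])
  out[isR] <- sub("-R$", "-L", names[isR])
  out
}
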