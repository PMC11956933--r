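#' Canonical zone membership of the decision graph
#'
#' Zone I is the launching region (pre-stimulated state 60 plus the
#' thalamic-bit states 61, 62, 63); zone II the initial deliberation loop;
#' zone V the second deliberation loop; zone VI the neutral
#' both-dSPN state 783; zones III and IV the left and right commitment arms
#' of the outer walk, mirror images of one another under the channel swap.
#'
#' @return Named list of integer label vectors for zones I, II, III, IV, V,
#'   VI.
#' @export
canonicalZoneMap <- function() {
  zIII <- c(575L, 543L, 535L, 663L, 759L)
  list(I = c(60L, 61L, 62L, 63L),
       II = c(55L, 59L, 183L, 191L, 123L, 127L),
       III = zIII,
       IV = mirrorState(zIII),
       V = c(247L, 243L, 251L),
       VI = 783L)
}

#' Partition of CLAW states into functional zones
#'
#' @slot map Named character vector: state label (name) to zone.
#' @slot zoneEdges data.frame(from, to, count, probability) over zones.
#' @slot zoneStay data.frame(zone, stay_probability) where staying counts
#'   within-zone transitions plus trial ends (absorption).
#' @slot activation data.frame of per-zone activation probabilities of the
#'   encoded (and, when state statistics are attached, auxiliary)
#'   populations.
#' @export
setClass("ZonePartition", representation(map = "character",
                                         zoneEdges = "data.frame",
                                         zoneStay = "data.frame",
                                         activation = "data.frame"))

setMethod("show", "ZonePartition", function(object) {
  zs <- table(object@map)
  cat("ZonePartition:", paste(names(zs), zs, sep = ":", collapse = " "),
      "\n")
})

#' Zone of each state
#' @param partition A \linkS4class{ZonePartition}.
#' @param states Integer labels (default: all mapped states).
#' @return Character vector of zones (\code{"unassigned"} when absent).
#' @export
stateZone <- function(partition, states = NULL) {
  if (is.null(states)) return(partition@map)
  z <- partition@map[as.character(states)]
  z[is.na(z)] <- "unassigned"
  unname(z)
}

#' Partition a CLAW graph into zones
#'
#' Assigns each graph state to a zone.  The default map is the canonical
#' one; commitment arms (III and IV) are optionally closed under retained
#' outgoing edges, i.e. an unassigned successor of an arm state joins that
#' arm (and its mirror joins the other), so terminal commitment states
#' found only in a particular run are absorbed into the arms.  Remaining
#' states are \code{"unassigned"}.  Zone-level transition probabilities
#' aggregate the raw (unpruned) transition counts; a zone's stay
#' probability pools its within-zone transition and end mass.
#'
#' @param graph A \linkS4class{ClawGraph}.
#' @param zoneMap Optional named list of integer vectors replacing the
#'   canonical map.  A state assigned to two zones is an error.
#' @param closure Extend zones III/IV along retained edges (default TRUE).
#' @return A \linkS4class{ZonePartition}.
#' @export
partitionZones <- function(graph, zoneMap = NULL, closure = TRUE) {
  zm <- if (is.null(zoneMap)) canonicalZoneMap() else zoneMap
  all <- unlist(zm)
  if (anyDuplicated(all)) {
    dup <- all[duplicated(all)]
    stop("state(s) assigned to two zones: ", paste(unique(dup), collapse = ", "))
  }
  states <- clawStates(graph)
  map <- setNames(rep("unassigned", length(states)), states)
  for (z in names(zm)) {
    hit <- as.character(zm[[z]])
    map[intersect(hit, names(map))] <- z
  }

  if (closure && all(c("III", "IV") %in% names(zm))) {
    edges <- clawEdges(graph)
    repeat {
      added <- FALSE
      for (arm in c("III", "IV")) {
        src <- as.integer(names(map)[map == arm])
        succ <- unique(edges$to[edges$from %in% src])
        new <- succ[map[as.character(succ)] == "unassigned"]
        new <- new[!is.na(new)]
        # an arm only absorbs successors whose direct pathway is dominant
        # on that arm's side (dSPN bit on ipsilaterally, off contralaterally)
        if (length(new)) {
          bits <- vapply(new, decodeState, integer(10))
          lead <- if (arm == "III") bits["dSPN-L", ] == 1L & bits["dSPN-R", ] == 0L
                  else bits["dSPN-R", ] == 1L & bits["dSPN-L", ] == 0L
          new <- new[lead]
        }
        if (length(new)) {
          map[as.character(new)] <- arm
          other <- if (arm == "III") "IV" else "III"
          mir <- as.character(mirrorState(new))
          mirIn <- mir[mir %in% names(map)]
          mirIn <- mirIn[map[mirIn] == "unassigned"]
          if (length(mirIn)) map[mirIn] <- other
          added <- TRUE
        }
      }
      if (!added) break
    }
  }

  zoneOf <- function(st) unname(map[as.character(st)])
  e <- graph@edges
  zFrom <- zoneOf(e$from); zTo <- zoneOf(e$to)
  endZone <- zoneOf(graph@ends$state)
  zones <- unique(c(names(zm), "unassigned"))
  zones <- zones[zones %in% c(zFrom, zTo, endZone)]

  rowsE <- list(); rowsS <- list()
  for (z in zones) {
    outMask <- zFrom == z
    total <- sum(e$count[outMask]) +
      sum(graph@ends$count[endZone == z])
    stay <- sum(e$count[outMask & zTo == z]) +
      sum(graph@ends$count[endZone == z])
    rowsS[[z]] <- data.frame(zone = z, stay_probability = stay / total)
    for (z2 in setdiff(zones, z)) {
      cnt <- sum(e$count[outMask & zTo == z2])
      if (cnt > 0)
        rowsE[[paste(z, z2)]] <- data.frame(from = z, to = z2, count = cnt,
                                            probability = cnt / total)
    }
  }
  zoneEdges <- if (length(rowsE)) do.call(rbind, rowsE)
               else data.frame(from = character(0), to = character(0),
                               count = integer(0), probability = numeric(0))
  rownames(zoneEdges) <- NULL
  zoneStay <- do.call(rbind, rowsS); rownames(zoneStay) <- NULL

  # occupancy-weighted activation probability of each encoded bit per zone
  occ <- if (nrow(graph@stats)) {
    setNames(graph@stats$occupancy, graph@stats$state)
  } else {
    tot <- tapply(c(e$count, graph@ends$count),
                  c(e$from, graph@ends$state), sum)
    setNames(as.numeric(tot), names(tot))
  }
  act <- lapply(zones, function(z) {
    st <- as.integer(names(map)[map == z])
    w <- occ[as.character(st)]; w[is.na(w)] <- 0
    if (sum(w) == 0) w <- rep(1, length(st))
    bits <- vapply(st, decodeState, integer(10))
    prob <- as.numeric(bits %*% (w / sum(w)))
    row <- as.data.frame(t(prob))
    names(row) <- encodedPopulations()
    if (nrow(graph@stats)) {
      sIdx <- match(st, graph@stats$state)
      auxP <- graph@stats[sIdx, c("p_stn_l", "p_stn_r", "p_gpea_l", "p_gpea_r"),
                          drop = FALSE]
      auxW <- colSums(auxP * (w / sum(w)))
      row[c("STN-L", "STN-R", "GPeA-L", "GPeA-R")] <- as.list(auxW)
    }
    cbind(data.frame(zone = z), row, row.names = NULL)
  })
  activation <- do.call(rbind, act)

  new("ZonePartition", map = map, zoneEdges = zoneEdges,
      zoneStay = zoneStay, activation = activation)
}
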