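test_that("encode and decode round-trip over all 1024 labels", {
  for (l in 0:1023) expect_identical(encodeState(decodeState(l)), l)
  expect_identical(encodeState(rep(0, 10)), 0L)
  expect_identical(encodeState(rep(1, 10)), 1023L)
  expect_error(encodeState(rep(1, 9)), "length 10")
})

test_that("the fixed bit order reproduces every printed state label", {
  # independent oracle: hand base-2 arithmetic over the documented bit
  # weights dSPN-L 512, dSPN-R 256, iSPN-L 128, iSPN-R 64, GPi-L 32,
  # GPi-R 16, GPeP-L 8, GPeP-R 4, Th-L 2, Th-R 1
  lbl <- function(...) {
    p <- setNames(rep(0, 10), encodedPopulations())
    p[c(...)] <- 1
    encodeState(p)
  }
  base <- c("GPi-L", "GPi-R", "GPeP-L", "GPeP-R")
  expect_identical(lbl(base), 32L + 16L + 8L + 4L)              # 60
  expect_identical(lbl(base, "Th-R"), 61L)
  expect_identical(lbl(base, "Th-L"), 62L)
  expect_identical(lbl(base, "Th-L", "Th-R"), 63L)
  launch <- c(base, "Th-L", "Th-R")
  expect_identical(lbl(launch, "dSPN-L"), 575L)
  expect_identical(lbl("dSPN-L", "GPi-R", "GPeP-L", "GPeP-R", "Th-L",
                       "Th-R"), 543L)
  expect_identical(lbl("iSPN-L", "GPi-L", "GPi-R", "GPeP-R", "Th-L",
                       "Th-R"), 183L)
  expect_identical(lbl("iSPN-L", "GPi-L", "GPi-R", "GPeP-L", "GPeP-R",
                       "Th-L", "Th-R"), 191L)
  expect_identical(lbl("GPi-L", "GPi-R", "GPeP-R", "Th-L", "Th-R"), 55L)
  expect_identical(lbl("GPi-L", "GPi-R", "GPeP-L", "Th-L", "Th-R"), 59L)
  expect_identical(lbl("iSPN-R", "GPi-L", "GPi-R", "GPeP-L", "Th-L",
                       "Th-R"), 123L)
  expect_identical(lbl("iSPN-R", "GPi-L", "GPi-R", "GPeP-L", "GPeP-R",
                       "Th-L", "Th-R"), 127L)
  expect_identical(lbl("dSPN-L", "GPi-R", "GPeP-R", "Th-L", "Th-R"), 535L)
  expect_identical(lbl("dSPN-L", "iSPN-L", "GPi-R", "GPeP-R", "Th-L",
                       "Th-R"), 663L)
  expect_identical(lbl("iSPN-L", "iSPN-R", "GPi-L", "GPi-R", "GPeP-R",
                       "Th-L", "Th-R"), 247L)
  expect_identical(lbl("iSPN-L", "iSPN-R", "GPi-L", "GPi-R", "Th-L",
                       "Th-R"), 243L)
  expect_identical(lbl("iSPN-L", "iSPN-R", "GPi-L", "GPi-R", "GPeP-L",
                       "Th-L", "Th-R"), 251L)
  expect_identical(lbl("dSPN-L", "dSPN-R", "GPeP-L", "GPeP-R", "Th-L",
                       "Th-R"), 783L)
  expect_identical(lbl("dSPN-L", "iSPN-L", "iSPN-R", "GPi-L", "GPi-R",
                       "GPeP-R", "Th-L", "Th-R"), 759L)
  expect_identical(lbl("dSPN-R", "iSPN-L", "iSPN-R", "GPi-L", "GPi-R",
                       "GPeP-L", "Th-L", "Th-R"), 507L)
})

test_that("mirrorState swaps the action channels", {
  expect_identical(mirrorState(575L), 319L)  # dSPN-L -> dSPN-R
  expect_identical(mirrorState(60L), 60L)    # bilaterally symmetric
  expect_identical(mirrorState(mirrorState(183L)), 183L)
  expect_identical(mirrorState(759L), 507L)  # the two commitment states
})

test_that("sequence extraction matches hand base-2 arithmetic on a built trial", {
  pops <- populationNames()
  bits <- matrix(FALSE, 18, 5, dimnames = list(pops, NULL))
  bits[c("GPi-L", "GPi-R", "GPeP-L", "GPeP-R"), ] <- TRUE
  bits["Th-L", 3:5] <- TRUE
  bits["Th-R", 4:5] <- TRUE
  bits["dSPN-L", 5] <- TRUE
  bits["STN-L", 2:5] <- TRUE
  bin <- new("BinaryTraceSet",
             networks = list(list(thresholds = flatThresholds(),
                                  trials = list(list(bits = bits,
                                                     choice = "left",
                                                     decisionTime = 50,
                                                     phaseMarks = c(stimOnset = 0L,
                                                                    decision = 5L,
                                                                    consolidationEnd = 5L))),
                                  nTimeouts = 0L)),
             binWidth = 10)
  sq <- extractSequences(bin)[[1]]
  expect_identical(sq$labels, c(60L, 60L, 62L, 63L, 575L))
  expect_identical(unname(sq$aux["STN-L", ]), c(0L, 1L, 1L, 1L, 1L))
})

test_that("transition estimation reproduces the worked examples", {
  seqs <- asSequences(list(c(60, 63, 575), c(60, 63, 543)))
  raw <- estimateTransitions(seqs, mode = "per_change")
  p <- function(f, t) raw$edges$probability[raw$edges$from == f &
                                              raw$edges$to == t]
  expect_equal(p(60, 63), 1)
  expect_equal(p(63, 575), 0.5)
  expect_equal(p(63, 543), 0.5)

  one <- estimateTransitions(asSequences(list(c(60, 60, 60))))
  expect_equal(one$ends$state, 60L)
  expect_equal(one$ends$probability, 1)

  pb <- estimateTransitions(asSequences(list(c(60, 60, 63))), mode = "per_bin")
  expect_equal(pb$edges$probability[pb$edges$from == 60 & pb$edges$to == 60],
               0.5)
  expect_equal(pb$edges$probability[pb$edges$from == 60 & pb$edges$to == 63],
               0.5)
  expect_error(estimateTransitions(seqs, mode = "bogus"))
})

test_that("transition estimation equals the brute-force pair-count oracle", {
  set.seed(31)
  for (mode in c("per_change", "per_bin")) {
    for (rep in 1:5) {
      labs <- lapply(seq_len(sample(2:10, 1)), function(i)
        sample(c(60L, 61L, 63L, 183L, 575L), sample(2:12, 1), replace = TRUE))
      got <- estimateTransitions(asSequences(labs), mode = mode)
      want <- bruteForceTransitions(labs, mode)
      gotE <- got$edges[order(got$edges$from, got$edges$to), ]
      rownames(gotE) <- rownames(want$edges) <- NULL
      expect_equal(gotE[c("from", "to", "count", "probability")],
                   want$edges[c("from", "to", "count", "probability")])
      gotEnd <- got$ends[order(got$ends$state), ]
      rownames(gotEnd) <- rownames(want$ends) <- NULL
      expect_equal(gotEnd, want$ends)
    }
  }
})

test_that("probability mass per state is conserved before pruning and bounded after", {
  set.seed(7)
  labs <- lapply(1:20, function(i) sample(0:8, sample(3:15, 1), replace = TRUE))
  raw <- estimateTransitions(asSequences(labs), mode = "per_bin")
  for (st in unique(raw$edges$from)) {
    mass <- sum(raw$edges$probability[raw$edges$from == st]) +
      sum(raw$ends$probability[raw$ends$state == st])
    expect_equal(mass, 1, tolerance = 1e-9)
  }
  g <- pruneGraph(raw)
  for (st in unique(g@edges$from)) {
    keep <- g@edges$from == st & g@edges$retained
    expect_lte(sum(g@edges$probability[keep]) +
                 sum(g@ends$probability[g@ends$state == st]), 1 + 1e-9)
  }
})

test_that("the pruning rule applies the 25% relative gap", {
  mk <- function(probs) {
    edges <- data.frame(from = 1L, to = seq_along(probs) + 1L,
                        count = as.integer(probs * 100),
                        probability = probs)
    list(edges = edges,
         ends = data.frame(state = integer(0), count = integer(0),
                           probability = numeric(0)),
         mode = "per_change", nSequences = 1L)
  }
  g1 <- pruneGraph(mk(c(0.4, 0.3, 0.2, 0.1)))
  expect_equal(clawEdges(g1)$probability, 0.4)    # (0.4-0.3)/0.4 = 0.25
  g2 <- pruneGraph(mk(rep(0.25, 4)))
  expect_equal(nrow(clawEdges(g2)), 4L)           # no qualifying gap
  g3 <- pruneGraph(mk(1))
  expect_equal(nrow(clawEdges(g3)), 1L)           # single edge retained
})

test_that("KL divergence matches the closed form and is a proper divergence", {
  expect_equal(klDivergence(c(0.5, 0.5), c(0.9, 0.1)),
               0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1))
  expect_equal(klDivergence(c(0.5, 0.5), c(0.9, 0.1)), 0.5108, tolerance = 1e-4)
  expect_equal(klDivergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  set.seed(2)
  for (i in 1:20) {
    p <- runif(6); q <- runif(6)
    expect_gte(klDivergence(p, q), 0)
    expect_gte(klDivergence(p, q, symmetrized = TRUE), 0)
  }
  expect_equal(klDivergence(c(0.2, 0.8), c(0.2, 0.8), symmetrized = TRUE), 0)
})

test_that("per-state statistics count visits and flag one-sided KL", {
  seqs <- c(asSequences(list(c(60, 63), c(60, 63, 575)), choice = "left",
                        dt = 100),
            asSequences(list(c(60, 61))[1], choice = "right", dt = 200))
  seqs[[3]]$trial <- 3L
  st <- computeStateStats(seqs)
  s575 <- st[st$state == 575, ]
  expect_equal(s575$n_left, 1L)
  expect_equal(s575$n_right, 0L)
  expect_false(s575$kl_defined)
  expect_true(is.na(s575$kl_nats))
  s60 <- st[st$state == 60, ]
  expect_equal(s60$n_left, 2L)
  expect_equal(s60$n_right, 1L)
  expect_equal(s60$mean_dt_ms, mean(c(100, 100, 200)))
})

test_that("decision-time tertiles are equal-mass", {
  t1 <- dtTertiles(1:9)
  expect_equal(unname(t1$cuts), c(3, 6))
  expect_equal(as.vector(table(t1$class)), c(3, 3, 3))

  expect_warning(t2 <- dtTertiles(rep(5, 10)), "tied")
  expect_error(dtTertiles(c(1, 2)), "at least 3")

  set.seed(12)
  t3 <- dtTertiles(runif(300))
  expect_true(all(abs(table(t3$class) - 100) <= 1))
})

test_that("the canonical zone partition places the printed states", {
  script <- list(list(pattern = 60, dwell = 2), list(pattern = 63, dwell = 1),
                 list(pattern = 575, dwell = 1), list(pattern = 543, dwell = 1))
  script2 <- list(list(pattern = 60, dwell = 1), list(pattern = 63, dwell = 1),
                  list(pattern = 783, dwell = 1), list(pattern = 243, dwell = 1),
                  list(pattern = 63, dwell = 1))
  ts <- scriptedTraceSet(list(script, script2))
  bin <- binarizeTraces(ts, thresholds = flatThresholds())
  g <- pruneGraph(estimateTransitions(extractSequences(bin)))
  pz <- partitionZones(g)
  expect_identical(stateZone(pz, 63), "I")
  expect_identical(stateZone(pz, 60), "I")
  expect_identical(stateZone(pz, 783), "VI")
  expect_identical(stateZone(pz, 243), "V")
  expect_identical(stateZone(pz, 575), "III")
  expect_identical(stateZone(pz, 1000), "unassigned")
})

test_that("zone III and IV are mirror images and zones never overlap", {
  report <- deskReport()
  pz <- report$partition
  zIII <- as.integer(names(pz@map)[pz@map == "III"])
  zIV <- as.integer(names(pz@map)[pz@map == "IV"])
  mir <- mirrorState(zIII)
  inGraph <- mir %in% as.integer(names(pz@map))
  expect_true(all(pz@map[as.character(mir[inGraph])] == "IV"))
  counts <- table(names(pz@map))
  expect_true(all(counts == 1))  # a partition: no label twice
  expect_error(partitionZones(report$graph,
                              zoneMap = list(I = c(60L, 63L), II = 63L)),
               "two zones")
})

test_that("graph export round-trips and matches retained structure", {
  report <- deskReport()
  g <- report$graph
  tmp <- tempfile(fileext = ".json")
  exportGraph(g, tmp, "json")
  g2 <- importGraph(tmp)
  expect_equal(g2@edges, g@edges)
  expect_equal(g2@ends, g@ends)
  expect_equal(g2@gap, g@gap)

  dotFile <- tempfile(fileext = ".dot")
  exportGraph(g, dotFile, "dot")
  dot <- readLines(dotFile)
  expect_equal(sum(grepl("->", dot, fixed = TRUE)), nrow(clawEdges(g)))

  gml <- tempfile(fileext = ".graphml")
  exportGraph(g, gml, "graphml")
  doc <- xml2::read_xml(gml)  # well-formed XML with graphml root
  expect_identical(xml2::xml_name(doc), "graphml")
  g3 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g3), nrow(clawEdges(g)))
  expect_equal(igraph::vcount(g3), length(clawStates(g)))

  expect_error(exportGraph(g, tmp, "bogus"))
})
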