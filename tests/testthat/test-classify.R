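# Complete-genome screen: the decision rules on constructed assemblies
# whose GC contents are exact by construction.

completeFixture <- function(secondaryGc, profile) {
  assembly <- RepliconSet(
    c(chr = exactGcSeq(3000000L, 60.0),
      sec = exactGcSeq(1000000L, secondaryGc)), "fix")
  profiles <- rbind(profileRow("chr", n_core = 1L, n_dnaa = 1L), profile)
  classifyCompleteGenome(assembly, profiles)
}

test_that("single-replicon assemblies are UNASSIGNED by the >=2 rule", {
  res <- classifyCompleteGenome(
    RepliconSet(c(only = exactGcSeq(1000000L, 55)), "solo"),
    profileRow("only", n_dnaa = 1L))
  expect_identical(roleCalls(res)$role, "UNASSIGNED")
  expect_match(roleCalls(res)$evidence, "fewer than 2")
})

test_that("a marker-complete secondary within 1 GC point is a chromid", {
  res <- completeFixture(60.3, profileRow("sec", 1L, 1L, 2L))
  calls <- roleCalls(res)
  expect_identical(calls$role[calls$replicon_id == "chr"], "CHROMOSOME")
  expect_identical(calls$role[calls$replicon_id == "sec"], "CHROMID")
  expect_equal(calls$delta_gc[calls$replicon_id == "sec"], 0.3)
})

test_that("a secondary missing core genes is OTHER with that evidence", {
  res <- completeFixture(60.3, profileRow("sec", 1L, 1L, 0L))
  sec <- roleCalls(res)[roleCalls(res)$replicon_id == "sec", ]
  expect_identical(sec$role, "OTHER")
  expect_match(sec$evidence, "CORE")
})

test_that("a 1.4-point GC delta forces OTHER with GC evidence", {
  res <- completeFixture(61.4, profileRow("sec", 1L, 1L, 2L))
  sec <- roleCalls(res)[roleCalls(res)$replicon_id == "sec", ]
  expect_identical(sec$role, "OTHER")
  expect_match(sec$evidence, "GC delta")
})

test_that("the one-point GC band is absolute, with boundary included", {
  passing <- completeFixture(61.0, profileRow("sec", 1L, 1L, 1L))
  expect_identical(roleCalls(passing)$role[2], "CHROMID")
  failing <- completeFixture(61.1, profileRow("sec", 1L, 1L, 1L))
  expect_identical(roleCalls(failing)$role[2], "OTHER")
})

test_that("exactly one chromosome is called per multi-replicon assembly", {
  res <- completeFixture(60.5, profileRow("sec", 1L, 1L, 1L))
  expect_identical(sum(roleCalls(res)$role == "CHROMOSOME"), 1L)
})

test_that("length ties break by DnaA presence and are warned about", {
  assembly <- RepliconSet(c(a = exactGcSeq(100000L, 60),
                            b = exactGcSeq(100000L, 60)), "tie")
  profiles <- rbind(profileRow("a"), profileRow("b", n_dnaa = 1L))
  expect_warning(res <- classifyCompleteGenome(assembly, profiles), "tie")
  expect_identical(
    roleCalls(res)$role[roleCalls(res)$replicon_id == "b"], "CHROMOSOME")
})

test_that("the dinucleotide pre-screen rejects divergent composition", {
  set.seed(17)
  chr <- randomDNA(40000, gc = 0.5)
  alien <- strrep("AG", 10000)  # 20 kb, GC 0.5 but extreme signature
  kin <- randomDNA(20000, gc = 0.5)
  assembly <- RepliconSet(c(chr = chr, alien = alien, kin = kin), "din")
  profiles <- rbind(profileRow("chr", n_core = 1L, n_dnaa = 1L),
                    profileRow("alien", 1L, 1L, 1L),
                    profileRow("kin", 1L, 1L, 1L))
  th <- chromidThresholds(dinucDistMax = 0.4, markerRule = "strict")
  calls <- roleCalls(classifyCompleteGenome(assembly, profiles, th))
  expect_identical(calls$role[calls$replicon_id == "alien"], "OTHER")
  expect_match(calls$evidence[calls$replicon_id == "alien"], "dinucleotide")
  expect_identical(calls$role[calls$replicon_id == "kin"], "CHROMID")

  # without the pre-screen the alien's GC and markers would pass
  off <- roleCalls(classifyCompleteGenome(assembly, profiles,
                                          chromidThresholds(markerRule = "strict")))
  expect_identical(off$role[off$replicon_id == "alien"], "CHROMID")
})

# DnaA-centered clustering -----------------------------------------------

clusterFixture <- function() {
  pool <- RepliconSet(
    c(ctr = exactGcSeq(2000000L, 60.0),
      cand = exactGcSeq(1500000L, 60.5),
      long = exactGcSeq(2500000L, 60.2),
      far = exactGcSeq(1000000L, 62.0)), "pool")
  profiles <- rbind(profileRow("ctr", n_core = 1L, n_dnaa = 1L),
                    profileRow("cand", 1L, 1L, 1L),
                    profileRow("long", 1L, 1L, 1L),
                    profileRow("far", 1L, 1L, 1L))
  list(pool = pool, profiles = profiles)
}

test_that("cluster membership follows the shorter/GC/marker rules", {
  fx <- clusterFixture()
  cls <- findClusters(fx$pool, fx$profiles)
  expect_length(cls, 1L)
  expect_identical(cls[[1]]$center, "ctr")
  expect_identical(cls[[1]]$members$replicon_id, "cand")
  expect_equal(cls[[1]]$members$delta_gc, 0.5)
})

test_that("a short marker-bearing replicon joins several centers", {
  pool <- RepliconSet(
    c(c1 = exactGcSeq(2000000L, 60.0), c2 = exactGcSeq(1800000L, 60.4),
      memb = exactGcSeq(500000L, 60.2)), "pool")
  profiles <- rbind(profileRow("c1", n_core = 1L, n_dnaa = 1L),
                    profileRow("c2", n_core = 1L, n_dnaa = 1L),
                    profileRow("memb", 1L, 1L, 1L))
  cls <- findClusters(pool, profiles)
  expect_length(cls, 2L)
  expect_true(all(vapply(cls, function(cl)
    "memb" %in% cl$members$replicon_id, logical(1))))
})

test_that("DnaA-bearing replicons are centers, never members", {
  pool <- RepliconSet(
    c(big = exactGcSeq(2000000L, 60.0), small = exactGcSeq(1000000L, 60.2)),
    "pool")
  profiles <- rbind(profileRow("big", 1L, 1L, 1L, 1L),
                    profileRow("small", 1L, 1L, 1L, 1L))
  cls <- findClusters(pool, profiles)
  expect_length(cls, 2L)
  expect_true(all(vapply(cls, function(cl) nrow(cl$members), integer(1)) == 0L))
})

test_that("a pool without DnaA yields no clusters, with a warning", {
  pool <- RepliconSet(c(a = exactGcSeq(100000L, 60)), "pool")
  expect_warning(cls <- findClusters(pool, profileRow("a", 1L, 1L, 1L)),
                 "DnaA")
  expect_length(cls, 0L)
})

test_that("the distance filter marks members against the center signature", {
  set.seed(29)
  ctr <- randomDNA(30000, gc = 0.6)
  near <- randomDNA(20000, gc = 0.6)
  cluster <- list(center = "ctr",
                  members = data.frame(replicon_id = c("same", "near"),
                                       delta_gc = c(0, 0.1),
                                       tetra_dist = NA_real_, passed = NA,
                                       stringsAsFactors = FALSE))
  sigs <- list(ctr = relativeAbundance(ctr, 4),
               same = relativeAbundance(ctr, 4),
               near = relativeAbundance(near, 4))
  out <- applyDistanceFilter(cluster, sigs, chromidThresholds())
  expect_identical(out$members$tetra_dist[1], 0)
  expect_true(out$members$passed[1])
  expect_equal(out$members$tetra_dist[2],
               oracleDistance(ctr, near, 4), tolerance = 1e-12)

  # strict comparison: at threshold 0 even a zero-distance member fails
  zero <- applyDistanceFilter(cluster, sigs,
                              chromidThresholds(tetraDistMax = 0))
  expect_false(any(zero$members$passed))

  expect_error(applyDistanceFilter(cluster, sigs["ctr"], chromidThresholds()),
               "missing")
})

test_that("the filtered member set matches a brute-force recomputation", {
  sim <- generateAssembly(smallParams(seed = 37, chromidCount = 2L))
  res <- runChromidFinder(sim$assembly, toyMarkerDatabase())
  seqs <- repliconSequences(sim$assembly)
  for (cl in clusters(res)) {
    for (i in seq_len(nrow(cl$members))) {
      d <- oracleDistance(seqs[[cl$members$replicon_id[i]]],
                          seqs[[cl$center]], 4)
      expect_equal(cl$members$tetra_dist[i], d, tolerance = 1e-10)
      expect_identical(cl$members$passed[i], d < 1.6)
    }
  }
})

# end-to-end pooled pipeline ----------------------------------------------

test_that("pooled pipeline separates chromid from plasmid (seeded fixture)", {
  sim <- generateAssembly(generatorParams(seed = 7), id = "s")
  res <- runChromidFinder(sim$assembly, toyMarkerDatabase())
  calls <- roleCalls(res)
  expect_identical(calls$role[calls$replicon_id == "s_chromosome"],
                   "CHROMOSOME")
  expect_identical(calls$role[calls$replicon_id == "s_chromid1"], "CHROMID")
  expect_identical(calls$role[calls$replicon_id == "s_plasmid1"], "OTHER")
  # audit trail: the chromid call names its center and distance
  ev <- calls$evidence[calls$replicon_id == "s_chromid1"]
  expect_match(ev, "s_chromosome")
  expect_match(ev, "tetra dist")
})

test_that("a pool without DnaA produces zero chromid calls", {
  sim <- generateAssembly(smallParams(seed = 8))
  pool <- sim$assembly[c("synth_chromid1", "synth_plasmid1")]
  res <- runChromidFinder(pool, toyMarkerDatabase())
  expect_identical(sum(roleCalls(res)$role == "CHROMID"), 0L)
})

test_that("a lone DnaA replicon forms one empty cluster and no chromids", {
  sim <- generateAssembly(smallParams(seed = 9))
  pool <- sim$assembly["synth_chromosome"]
  res <- runChromidFinder(pool, toyMarkerDatabase())
  expect_length(clusters(res), 1L)
  expect_equal(nrow(clusters(res)[[1]]$members), 0L)
  expect_identical(sum(roleCalls(res)$role == "CHROMID"), 0L)
})

test_that("raising thresholds never removes calls or members", {
  bench <- generateBenchmark(4, smallParams(), seed = 51)
  grids <- c(0.4, 1.6, 3.2)
  chromids <- lapply(grids, function(g) {
    res <- runChromidFinder(bench$pool, bench$db,
                            chromidThresholds(tetraDistMax = g))
    calls <- roleCalls(res)
    calls$replicon_id[calls$role == "CHROMID"]
  })
  expect_true(all(chromids[[1]] %in% chromids[[2]]))
  expect_true(all(chromids[[2]] %in% chromids[[3]]))

  memberSet <- function(gcMax) {
    cls <- withCallingHandlers(
      runChromidFinder(bench$pool, bench$db,
                       chromidThresholds(gcDeltaMax = gcMax)),
      warning = function(w) invokeRestart("muffleWarning"))
    sort(unlist(lapply(clusters(cls), function(cl)
      paste(cl$center, cl$members$replicon_id))))
  }
  expect_true(all(memberSet(0.5) %in% memberSet(1.0)))
  expect_true(all(memberSet(1.0) %in% memberSet(2.0)))
})

test_that("calls are invariant under permutation of input order", {
  bench <- generateBenchmark(3, smallParams(), seed = 61)
  ids <- repliconIds(bench$pool)
  set.seed(62)
  shuffled <- bench$pool[sample(ids)]
  r1 <- roleCalls(runChromidFinder(bench$pool, bench$db))
  r2 <- roleCalls(runChromidFinder(shuffled, bench$db))
  r2 <- r2[match(r1$replicon_id, r2$replicon_id), ]
  expect_identical(r1$role, r2$role)
  expect_identical(r1$center_id, r2$center_id)
})

test_that("complete-genome and pooled modes agree on a compliant genome", {
  sim <- generateAssembly(smallParams(seed = 71))
  genes <- predictGenes(sim$assembly, backend = "naive")
  hits <- scanMarkers(genes, toyMarkerDatabase())
  profiles <- profileReplicons(hits, repliconIds(sim$assembly))
  complete <- roleCalls(classifyCompleteGenome(sim$assembly, profiles))
  mag <- roleCalls(runChromidFinder(sim$assembly, toyMarkerDatabase()))
  mag <- mag[match(complete$replicon_id, mag$replicon_id), ]
  expect_identical(complete$role, mag$role)
})

test_that("discarded and unclustered replicons carry audit evidence", {
  sim <- generateAssembly(smallParams(seed = 81, plasmidMode = "no_markers"))
  res <- runChromidFinder(sim$assembly, toyMarkerDatabase())
  calls <- roleCalls(res)
  plasmid <- calls[calls$replicon_id == "synth_plasmid1", ]
  expect_identical(plasmid$role, "OTHER")
  expect_match(plasmid$evidence, "discarded")
})
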