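# classify: the two decision procedures — the complete-genome chromid
# screen and the 4-step pooled (MAG) pipeline.

#' Construct a set of classification thresholds
#'
#' @param gcDeltaMax Max |GC delta| in absolute percentage points
#'   (default 1.0; 60.0 vs 61.0 passes, 60.0 vs 61.01 fails — the band is
#'   absolute, not relative).
#' @param tetraDistMax Tetranucleotide distance cutoff on the configured
#'   scale, compared strictly (`<`); default 1.6. `Inf` disables the filter.
#' @param dinucDistMax Dinucleotide pre-screen cutoff, compared inclusively
#'   (`<=`); `NA` (default) disables the pre-screen, 0.4 is the
#'   conventional value when enabled.
#' @param markerRule `"strict"` (Rep AND Par AND core) or `"relaxed"`
#'   ((Rep OR Par) AND core). The complete-genome screen defaults to
#'   strict, the pooled pipeline to relaxed — see the respective functions.
#' @param scale Signature-distance scale multiplier (default 10); cutoffs
#'   are read on this scale.
#' @return A [ChromidThresholds-class].
#' @export
chromidThresholds <- function(gcDeltaMax = 1.0, tetraDistMax = 1.6,
                              dinucDistMax = NA_real_,
                              markerRule = c("relaxed", "strict"),
                              scale = 10) {
  markerRule <- match.arg(markerRule)
  new("ChromidThresholds", gcDeltaMax = as.numeric(gcDeltaMax),
      tetraDistMax = as.numeric(tetraDistMax),
      dinucDistMax = as.numeric(dinucDistMax),
      markerRule = markerRule, scale = as.numeric(scale))
}

setMethod("show", "ChromidThresholds", function(object) {
  cat(sprintf(
    "ChromidThresholds: |dGC| <= %.2f pp; tetra dist < %.2f (scale x%g); %s\n",
    object@gcDeltaMax, object@tetraDistMax, object@scale,
    if (is.na(object@dinucDistMax)) "dinucleotide pre-screen off"
    else sprintf("dinucleotide dist <= %.2f", object@dinucDistMax)))
  cat(sprintf("  marker rule: %s\n", object@markerRule))
})

#' @rdname classificationAccessors
#' @param x A [ChromidClassification-class].
#' @return `roleCalls`: the per-replicon calls data.frame; `clusters`: the
#'   list of DnaA-centered clusters.
#' @name classificationAccessors
#' @aliases roleCalls clusters
NULL

#' @rdname classificationAccessors
#' @export
setMethod("roleCalls", "ChromidClassification", function(x) x@calls)

#' @rdname classificationAccessors
#' @export
setMethod("clusters", "ChromidClassification", function(x) x@clusters)

setMethod("show", "ChromidClassification", function(object) {
  tab <- table(factor(object@calls$role, levels = VALID_ROLES))
  cat(sprintf("ChromidClassification (%s mode): %d replicon(s)\n",
              object@mode, nrow(object@calls)))
  cat(sprintf("  %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  if (length(object@clusters))
    cat(sprintf("  %d DnaA-centered cluster(s)\n", length(object@clusters)))
})

.markerPass <- function(profiles, rule) {
  if (rule == "strict")
    profiles$n_rep > 0L & profiles$n_par > 0L & profiles$n_core > 0L
  else
    (profiles$n_rep > 0L | profiles$n_par > 0L) & profiles$n_core > 0L
}

.missingMarkerEvidence <- function(profile, rule) {
  missing <- character(0)
  if (rule == "strict") {
    if (profile$n_rep == 0L) missing <- c(missing, "REP")
    if (profile$n_par == 0L) missing <- c(missing, "PAR")
  } else if (profile$n_rep == 0L && profile$n_par == 0L) {
    missing <- c(missing, "REP|PAR")
  }
  if (profile$n_core == 0L) missing <- c(missing, "CORE")
  paste("missing", paste(missing, collapse = ","))
}

.newCalls <- function(x, gcPct, profiles) {
  ids <- repliconIds(x)
  idx <- match(ids, profiles$replicon_id)
  data.frame(
    replicon_id = ids,
    source = as.character(repliconSource(x)),
    length = as.integer(repliconLengths(x)),
    gc_pct = as.numeric(gcPct[ids]),
    role = "OTHER",
    center_id = NA_character_,
    delta_gc = NA_real_,
    tetra_dist = NA_real_,
    n_rep = ifelse(is.na(idx), 0L, profiles$n_rep[idx]),
    n_par = ifelse(is.na(idx), 0L, profiles$n_par[idx]),
    n_core = ifelse(is.na(idx), 0L, profiles$n_core[idx]),
    n_dnaa = ifelse(is.na(idx), 0L, profiles$n_dnaa[idx]),
    evidence = "",
    stringsAsFactors = FALSE)
}

#' Complete-genome chromid screen
#'
#' The screening procedure for a fully assembled genome of two or more
#' replicons: the longest replicon is designated the chromosome; every
#' other replicon is called CHROMID when its GC content is within
#' `gcDeltaMax` percentage points of the chromosome's and its marker
#' profile passes the marker rule (strict by default: Rep, Par and core
#' markers all present), and OTHER otherwise. Assemblies with fewer than
#' two replicons are UNASSIGNED. An optional dinucleotide
#' relative-abundance pre-screen (distance to the chromosome `<=
#' dinucDistMax`) is applied before the marker checks when enabled.
#'
#' Length ties for the chromosome are broken by DnaA presence, then by
#' lexicographic id, with a warning.
#'
#' @param assembly A [RepliconSet-class] (one genome).
#' @param profiles Marker profiles from [profileReplicons()] covering every
#'   replicon of the assembly.
#' @param thresholds A [ChromidThresholds-class]; defaults to the strict
#'   marker rule used for complete genomes.
#' @return A [ChromidClassification-class] with `mode = "complete_genome"`.
#' @export
classifyCompleteGenome <- function(assembly, profiles,
                                   thresholds =
                                     chromidThresholds(markerRule = "strict")) {
  stopifnot(is(assembly, "RepliconSet"), is(thresholds, "ChromidThresholds"))
  ids <- repliconIds(assembly)
  if (!all(ids %in% profiles$replicon_id))
    stop("missing marker profile(s) for: ",
         paste(setdiff(ids, profiles$replicon_id), collapse = ", "))
  gc <- gcContent(assembly)
  gcPct <- 100 * gc
  calls <- .newCalls(assembly, gcPct, profiles)

  if (length(ids) < 2L) {
    calls$role <- "UNASSIGNED"
    calls$evidence <- "assembly has fewer than 2 replicons"
    return(new("ChromidClassification", mode = "complete_genome",
               calls = calls, clusters = list(), thresholds = thresholds))
  }

  lens <- repliconLengths(assembly)
  hasDnaa <- setNames(calls$n_dnaa > 0L, calls$replicon_id)
  ord <- order(-lens, -as.integer(hasDnaa[ids]), ids)
  chrom <- ids[ord[1L]]
  if (sum(lens == lens[chrom]) > 1L)
    warning("length tie for longest replicon in assembly '",
            assemblyId(assembly), "'; broken by DnaA presence then id: ",
            chrom)
  calls$role[calls$replicon_id == chrom] <- "CHROMOSOME"
  calls$evidence[calls$replicon_id == chrom] <- "longest replicon"

  dinucSigs <- NULL
  if (!is.na(thresholds@dinucDistMax)) {
    seqs <- repliconSequences(assembly)
    dinucSigs <- lapply(seqs, relativeAbundance, k = 2)
  }

  for (id in setdiff(ids, chrom)) {
    i <- which(calls$replicon_id == id)
    dGC <- abs(gcPct[id] - gcPct[chrom])
    calls$delta_gc[i] <- dGC
    calls$center_id[i] <- chrom
    prof <- calls[i, c("n_rep", "n_par", "n_core")]
    if (!is.null(dinucSigs)) {
      d2 <- signatureDistance(dinucSigs[[id]], dinucSigs[[chrom]],
                              scale = thresholds@scale)
      if (!(d2 <= thresholds@dinucDistMax)) {
        calls$evidence[i] <- sprintf(
          "dinucleotide distance %.4f > %.2f", d2, thresholds@dinucDistMax)
        next
      }
    }
    if (dGC > thresholds@gcDeltaMax) {
      calls$evidence[i] <- sprintf("GC delta %.2f > %.2f pp",
                                   dGC, thresholds@gcDeltaMax)
      next
    }
    if (!.markerPass(prof, thresholds@markerRule)) {
      calls$evidence[i] <- .missingMarkerEvidence(prof, thresholds@markerRule)
      next
    }
    calls$role[i] <- "CHROMID"
    calls$evidence[i] <- sprintf(
      "GC delta %.2f <= %.2f pp; markers pass (%s rule) vs chromosome %s",
      dGC, thresholds@gcDeltaMax, thresholds@markerRule, chrom)
  }
  new("ChromidClassification", mode = "complete_genome", calls = calls,
      clusters = list(), thresholds = thresholds)
}

#' DnaA-centered clustering of pooled replicons
#'
#' Forms one cluster per DnaA-bearing replicon (the cluster center, a
#' putative chromosome). A replicon joins a cluster when it is not itself
#' DnaA-bearing, is strictly shorter than the center (equal length is
#' excluded), has |GC delta| within `gcDeltaMax` percentage points of the
#' center, and passes the candidate marker rule. A replicon may join
#' several clusters.
#'
#' @param pool A [RepliconSet-class] of pooled replicons.
#' @param profiles Marker profiles covering the pooled replicons.
#' @param gcPct Named numeric vector of GC contents in percent (computed
#'   from `pool` when `NULL`).
#' @param thresholds A [ChromidThresholds-class].
#' @return List of clusters, ordered by center id; each cluster is
#'   `list(center = <id>, members = <data.frame>)` with member columns
#'   `replicon_id`, `delta_gc`, `tetra_dist` (NA until the distance filter
#'   runs) and `passed`.
#' @export
findClusters <- function(pool, profiles, gcPct = NULL,
                         thresholds = chromidThresholds()) {
  stopifnot(is(pool, "RepliconSet"))
  if (is.null(gcPct)) gcPct <- 100 * gcContent(pool)
  ids <- repliconIds(pool)
  prof <- profiles[match(ids, profiles$replicon_id), , drop = FALSE]
  inPool <- !is.na(prof$replicon_id)
  lens <- repliconLengths(pool)
  centers <- ids[inPool & prof$n_dnaa > 0L]
  if (length(centers) == 0L) {
    warning("no DnaA-bearing replicon in pool; no clusters formed")
    return(list())
  }
  candOk <- inPool & prof$n_dnaa == 0L & .markerPass(prof, thresholds@markerRule)
  centers <- sort(centers)
  lapply(centers, function(ctr) {
    dGC <- abs(gcPct[ids] - gcPct[[ctr]])
    member <- candOk & lens < lens[[ctr]] & dGC <= thresholds@gcDeltaMax
    n <- sum(member)
    list(center = ctr,
         members = data.frame(
           replicon_id = ids[member],
           delta_gc = as.numeric(dGC[member]),
           tetra_dist = rep(NA_real_, n),
           passed = rep(NA, n),
           stringsAsFactors = FALSE))
  })
}

#' Tetranucleotide distance filter for one cluster
#'
#' Computes the tetranucleotide relative-abundance distance from every
#' cluster member to the center and marks members with
#' `distance < tetraDistMax` as passed. Failing members stay in the record
#' with `passed = FALSE` for audit but are excluded from CHROMID calls.
#'
#' @param cluster One cluster from [findClusters()].
#' @param signatures Named list of k=4 [CompositionSignature-class]
#'   objects covering the center and all members.
#' @param thresholds A [ChromidThresholds-class].
#' @return The cluster with `tetra_dist` and `passed` filled in.
#' @export
applyDistanceFilter <- function(cluster, signatures,
                                thresholds = chromidThresholds()) {
  need <- c(cluster$center, cluster$members$replicon_id)
  missing <- setdiff(need, names(signatures))
  if (length(missing))
    stop("missing tetranucleotide signature(s) for: ",
         paste(missing, collapse = ", "))
  ctrSig <- signatures[[cluster$center]]
  d <- vapply(cluster$members$replicon_id, function(id)
    signatureDistance(signatures[[id]], ctrSig, scale = thresholds@scale),
    numeric(1))
  cluster$members$tetra_dist <- as.numeric(d)
  cluster$members$passed <- as.numeric(d) < thresholds@tetraDistMax
  cluster
}

# Steps 1-3 of the pooled pipeline: GC, gene prediction, marker scan,
# retention, clustering, and the k=4 signatures of clustered replicons.
# Shared by runChromidFinder() and thresholdSweep().
.chromidFinderState <- function(pool, db, thresholds, backend = "naive",
                                eThreshold = 1e-5, minGenes = 1L,
                                minHits = 1L) {
  if (is.list(pool)) pool <- poolReplicons(pool)
  stopifnot(is(pool, "RepliconSet"), is(db, "MarkerDatabase"))
  ids <- repliconIds(pool)
  gcPct <- 100 * .gcOrNA(pool@sequences)

  genes <- predictGenes(pool, backend = backend)
  hits <- scanMarkers(genes, db, eThreshold = eThreshold)
  nGenes <- table(factor(genes$replicon_id, levels = ids))
  nHits <- table(factor(hits$replicon_id, levels = ids))
  retained <- ids[as.integer(nGenes) >= minGenes &
                  as.integer(nHits) >= minHits & !is.na(gcPct)]
  discardReason <- setNames(rep(NA_character_, length(ids)), ids)
  discardReason[is.na(gcPct)] <- "undefined GC (all-N sequence)"
  discardReason[as.integer(nGenes) < minGenes & is.na(discardReason)] <-
    sprintf("fewer than %d predicted gene(s)", minGenes)
  discardReason[as.integer(nHits) < minHits & is.na(discardReason) &
                !(ids %in% retained)] <-
    sprintf("fewer than %d marker hit(s)", minHits)

  profiles <- profileReplicons(hits[hits$replicon_id %in% retained, ,
                                    drop = FALSE], retained)
  clusters <- if (length(retained)) {
    withCallingHandlers(
      findClusters(pool[retained], profiles, gcPct[retained], thresholds),
      warning = function(w) invokeRestart("muffleWarning"))
  } else list()

  clustered <- unique(c(
    vapply(clusters, `[[`, "", "center"),
    unlist(lapply(clusters, function(cl) cl$members$replicon_id))))
  seqs <- repliconSequences(pool, clustered)
  signatures <- lapply(seqs, relativeAbundance, k = 4)

  list(pool = pool, gcPct = gcPct, genes = genes, hits = hits,
       retained = retained, discardReason = discardReason,
       profiles = profiles, clusters = clusters, signatures = signatures)
}

.finishChromidFinder <- function(state, thresholds) {
  pool <- state$pool
  clusters <- lapply(state$clusters, applyDistanceFilter,
                     signatures = state$signatures, thresholds = thresholds)
  calls <- .newCalls(pool, state$gcPct, state$profiles)

  centerIds <- vapply(clusters, `[[`, "", "center")
  calls$role[calls$replicon_id %in% centerIds] <- "CHROMOSOME"
  calls$evidence[calls$replicon_id %in% centerIds] <-
    "DnaA-bearing cluster center"

  # collect every (member, center) pass/fail across clusters
  memb <- do.call(rbind, lapply(clusters, function(cl) {
    if (nrow(cl$members) == 0L) return(NULL)
    cbind(cl$members, center = cl$center, stringsAsFactors = FALSE)
  }))
  if (!is.null(memb) && nrow(memb)) {
    for (id in unique(memb$replicon_id)) {
      i <- which(calls$replicon_id == id)
      rows <- memb[memb$replicon_id == id, , drop = FALSE]
      passed <- rows[rows$passed, , drop = FALSE]
      if (nrow(passed)) {
        # best supporting center: smallest distance, id breaks ties
        passed <- passed[order(passed$tetra_dist, passed$center), ,
                         drop = FALSE]
        calls$role[i] <- "CHROMID"
        calls$center_id[i] <- passed$center[1L]
        calls$delta_gc[i] <- passed$delta_gc[1L]
        calls$tetra_dist[i] <- passed$tetra_dist[1L]
        calls$evidence[i] <- sprintf(
          "in cluster(s) of %s; tetra dist %s < %.2f",
          paste(passed$center, collapse = ","),
          paste(sprintf("%.4f", passed$tetra_dist), collapse = ","),
          thresholds@tetraDistMax)
      } else {
        rows <- rows[order(rows$tetra_dist, rows$center), , drop = FALSE]
        calls$center_id[i] <- rows$center[1L]
        calls$delta_gc[i] <- rows$delta_gc[1L]
        calls$tetra_dist[i] <- rows$tetra_dist[1L]
        calls$evidence[i] <- sprintf(
          "tetra dist %.4f >= %.2f to nearest center %s",
          rows$tetra_dist[1L], thresholds@tetraDistMax, rows$center[1L])
      }
    }
  }

  unexplained <- calls$role == "OTHER" & calls$evidence == ""
  reason <- state$discardReason[calls$replicon_id]
  calls$evidence[unexplained] <- ifelse(
    !is.na(reason[unexplained]),
    paste("discarded:", reason[unexplained]),
    "retained but joined no cluster")
  new("ChromidClassification", mode = "mag", calls = calls,
      clusters = clusters, thresholds = thresholds)
}

#' Run the pooled (MAG) chromid-identification pipeline
#'
#' The four-step procedure for pools of independent assembled sequences:
#' (1) GC content, gene prediction and marker scanning, discarding
#' replicons with no predicted gene or no marker hit; (2)–(3) clustering
#' around DnaA-bearing centers with the strict-shorter and GC-delta rules
#' ([findClusters()]); (4) the tetranucleotide relative-abundance distance
#' filter against each center ([applyDistanceFilter()]). Cluster centers
#' are called CHROMOSOME, passing members CHROMID, everything else OTHER;
#' a DnaA-bearing sequence is never callable as CHROMID. The run is
#' deterministic given fixed inputs, database and thresholds, and every
#' discard is recorded in the evidence column.
#'
#' @param pool A [RepliconSet-class] (or list of them, pooled first).
#' @param db A [MarkerDatabase-class].
#' @param thresholds A [ChromidThresholds-class]; defaults to the relaxed
#'   marker rule, which tolerates the incomplete marker complements of
#'   MAG-derived sequences.
#' @param backend Gene-caller backend for [predictGenes()].
#' @param eThreshold Marker-scan E-value cutoff.
#' @param minGenes,minHits Step-1 retention rule: a replicon must have at
#'   least this many predicted genes and marker hits (defaults 1 and 1).
#' @return A [ChromidClassification-class] with `mode = "mag"`.
#' @examples
#' sim <- generateAssembly(generatorParams(seed = 7,
#'   chromosomeLength = 60000, chromidLength = 30000, plasmidLength = 15000))
#' res <- runChromidFinder(sim$assembly, toyMarkerDatabase())
#' roleCalls(res)[, c("replicon_id", "role")]
#' @export
runChromidFinder <- function(pool, db, thresholds = chromidThresholds(),
                             backend = c("naive", "prodigal"),
                             eThreshold = 1e-5, minGenes = 1L, minHits = 1L) {
  backend <- match.arg(backend)
  stopifnot(is(thresholds, "ChromidThresholds"))
  state <- .chromidFinderState(pool, db, thresholds, backend = backend,
                               eThreshold = eThreshold, minGenes = minGenes,
                               minHits = minHits)
  .finishChromidFinder(state, thresholds)
}
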