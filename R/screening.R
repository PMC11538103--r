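#' Screening configuration
#'
#' Thresholds operationalizing the three false-branch failure modes removed
#' after tracking: repeated tracking of the same vessel, pulsation-artifact
#' branches near large vessels, and noise-induced spurious connections.
#'
#' @param overlapThreshold Fraction of a branch's points within one voxel of
#'   another branch above which the pair counts as duplicated (default 0.7).
#' @param minLength Minimum branch length in mm (default 2.0).
#' @param minMaskSupport Minimum fraction of branch points inside the vessel
#'   mask (default 0.8).
#' @param artifactZone Dilation radius around the large-vessel mask in mm
#'   (default 1.0).
#' @param artifactMaxTortuosity Path-length / chord ratio above which a
#'   branch inside the zone is called artifactual (default 2.0).
#' @param voxelTolMM Point-proximity tolerance in mm used for overlap tests
#'   (defaults to the mask voxel size at call time when `NULL`).
#' @return A `screeningConfig` list.
#' @export
screeningConfig <- function(overlapThreshold = 0.7, minLength = 2.0,
                            minMaskSupport = 0.8, artifactZone = 1.0,
                            artifactMaxTortuosity = 2.0, voxelTolMM = NULL) {
  stopifnot(overlapThreshold > 0, overlapThreshold <= 1, minLength > 0,
            minMaskSupport > 0, minMaskSupport <= 1, artifactZone > 0,
            artifactMaxTortuosity > 0)
  structure(as.list(environment()), class = "screeningConfig")
}

## fraction of a's points within tol of some point of b
branchOverlapFraction <- function(a, b, tol) {
  mean(pairwiseMinDist(a@points, b@points) <= tol)
}

branchLength <- function(b) polylineLength(b@points)

branchTortuosity <- function(b) {
  chord <- sqrt(sum((b@points[nrow(b@points), ] - b@points[1, ])^2))
  if (chord < 1e-9) return(Inf)
  branchLength(b) / chord
}

branchMaskSupport <- function(b, mask) {
  mean(maskAtMM(mask, b@points))
}

## drop branches by index, re-parenting children of removed branches to the
## removed branch's parent (or orphaning them)
dropBranches <- function(branches, removeIds) {
  if (!length(removeIds)) return(branches)
  byId <- stats::setNames(branches, vapply(branches, function(b) b@id,
                                           integer(1)))
  keep <- branches[!vapply(branches, function(b) b@id %in% removeIds,
                           logical(1))]
  keptIds <- vapply(keep, function(b) b@id, integer(1))
  lapply(keep, function(b) {
    p <- b@parent
    while (!is.na(p) && p %in% removeIds) {
      pb <- byId[[as.character(p)]]
      p <- if (is.null(pb)) NA_integer_ else pb@parent
    }
    if (!is.na(p) && !(p %in% keptIds)) p <- NA_integer_
    if (!identical(p, b@parent)) {
      b@parent <- as.integer(p)
      if (is.na(p)) b@parentPoint <- NA_integer_
    }
    b
  })
}

## recompute branch orders from parent links (roots = 1)
recomputeOrders <- function(branches) {
  ids <- vapply(branches, function(b) b@id, integer(1))
  getOrder <- function(id, depth = 0L) {
    if (depth > length(branches)) return(1L)   # cycle guard
    b <- branches[[match(id, ids)]]
    if (is.na(b@parent) || !(b@parent %in% ids)) return(1L)
    getOrder(b@parent, depth + 1L) + 1L
  }
  lapply(branches, function(b) {
    b@order <- getOrder(b@id)
    b
  })
}

#' Remove duplicated branches from repeated tracking
#'
#' For any pair whose mutual overlap (fraction of points within one voxel of
#' the other branch) reaches the threshold, the longer branch is retained;
#' ties break deterministically toward the earlier branch id. A branch that
#' retraces another and then diverges keeps its novel tail, re-attached as a
#' child of the retained branch at the divergence point.
#'
#' @param branchList List of [BranchTrack-class].
#' @param config A [screeningConfig()].
#' @param voxelMM Voxel size in mm used as the proximity tolerance.
#' @return Screened branch list.
#' @export
removeDuplicates <- function(branchList, config = screeningConfig(),
                             voxelMM = 0.1) {
  tol <- config$voxelTolMM %||% voxelMM
  n <- length(branchList)
  if (n < 2) return(branchList)
  removed <- integer(0)
  newTails <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- branchList[[i]]; b <- branchList[[j]]
      if (a@id %in% removed || b@id %in% removed) next
      ovA <- branchOverlapFraction(a, b, tol)
      ovB <- branchOverlapFraction(b, a, tol)
      if (max(ovA, ovB) < config$overlapThreshold) next
      ## keep the longer branch; earlier id wins ties
      la <- branchLength(a); lb <- branchLength(b)
      if (lb > la + 1e-9) { keep <- b; drop <- a } else { keep <- a; drop <- b }
      removed <- c(removed, drop@id)
      ## novel tail of the dropped branch: trailing run of points farther
      ## than tol from the kept branch
      nearKeep <- pairwiseMinDist(drop@points, keep@points) <= tol
      lastNear <- max(which(nearKeep), 0)
      if (lastNear >= 1 && lastNear < nrow(drop@points) - 1) {
        tailIdx <- lastNear:nrow(drop@points)
        att <- which.min(pairwiseMinDist(
          drop@points[lastNear, , drop = FALSE], keep@points))
        newTails[[length(newTails) + 1]] <-
          BranchTrack(drop@points[tailIdx, , drop = FALSE],
                      drop@radii[tailIdx], parent = keep@id,
                      parentPoint = as.integer(att),
                      order = keep@order + 1L, id = drop@id,
                      provenance = paste0(drop@provenance, ":tail"))
      }
    }
  }
  out <- dropBranches(branchList, removed)
  c(out, newTails)
}

#' Remove pulsation-artifact branches near large vessels
#'
#' Branches lying at least half inside the artifact zone (the large-vessel
#' mask dilated by `artifactZone` mm) are removed when they are additionally
#' implausible: tortuosity above the cutoff or mask support below the
#' minimum. An empty large-vessel mask makes this the identity.
#'
#' @param branchList List of [BranchTrack-class].
#' @param largeMask Large-vessel [VesselMask-class] (or `NULL`).
#' @param mask Small-vessel [VesselMask-class] (for the support test).
#' @param config A [screeningConfig()].
#' @return Screened branch list.
#' @export
removeArtifactBranches <- function(branchList, largeMask, mask,
                                   config = screeningConfig()) {
  if (is.null(largeMask) || sum(imgData(largeMask)) == 0) return(branchList)
  largePts <- maskPointsMM(largeMask)
  removed <- integer(0)
  for (b in branchList) {
    inZone <- mean(pairwiseMinDist(b@points, largePts) <= config$artifactZone)
    if (inZone >= 0.5 &&
        (branchTortuosity(b) > config$artifactMaxTortuosity ||
         branchMaskSupport(b, mask) < config$minMaskSupport))
      removed <- c(removed, b@id)
  }
  dropBranches(branchList, removed)
}

#' Remove noise-induced spurious branches
#'
#' Branches shorter than the minimum length or with too few points inside
#' the vessel mask are removed; children of removed branches are re-parented
#' to the removed branch's parent, and dropped if they are orphaned and
#' themselves below the minimum length.
#'
#' @param branchList List of [BranchTrack-class].
#' @param mask Small-vessel [VesselMask-class].
#' @param config A [screeningConfig()].
#' @return Screened branch list.
#' @export
removeNoiseBranches <- function(branchList, mask,
                                config = screeningConfig()) {
  removed <- vapply(branchList, function(b) {
    branchLength(b) < config$minLength ||
      branchMaskSupport(b, mask) < config$minMaskSupport
  }, logical(1))
  out <- dropBranches(branchList,
                      vapply(branchList[removed], function(b) b@id,
                             integer(1)))
  ## orphaned-and-short after re-parenting
  again <- vapply(out, function(b) {
    is.na(b@parent) && branchLength(b) < config$minLength
  }, logical(1))
  dropBranches(out, vapply(out[again], function(b) b@id, integer(1)))
}

#' Screen traced branches
#'
#' Applies the three false-branch filters in order — duplicates, artifact
#' branches, noise branches — then recomputes branch orders on the surviving
#' tree. The operation is idempotent.
#'
#' @param branchList List of [BranchTrack-class].
#' @param mask Small-vessel [VesselMask-class].
#' @param largeMask Optional large-vessel [VesselMask-class].
#' @param config A [screeningConfig()].
#' @return Screened, re-ordered branch list.
#' @export
screenBranches <- function(branchList, mask, largeMask = NULL,
                           config = screeningConfig()) {
  voxelMM <- min(spacing(mask))
  out <- removeDuplicates(branchList, config, voxelMM)
  out <- removeArtifactBranches(out, largeMask, mask, config)
  out <- removeNoiseBranches(out, mask, config)
  recomputeOrders(out)
}
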