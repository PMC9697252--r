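## End-to-end glue: phantom generation -> reader consensus -> VOI
## extraction -> perspective stacks, streamed scan by scan so only the
## compact slice stacks (not the full volumes) are held in memory.

#' Generate a phantom benchmark as perspective-stack records
#'
#' Runs the full data-preparation pipeline on synthetic scans: generate
#' each scan with its simulated reader annotations, merge annotations into
#' consensus objects (single-linkage under the distance threshold),
#' eliminate cross-kind conflicts, filter by minimum approval, extract the
#' resolution-normalized VOI around each retained center and slice it into
#' the three perspective stacks. Scans are discarded as soon as their
#' records are built.
#'
#' @param nScans,objectsPerScan,separability,config,seed passed to the
#'   phantom generator, see \code{\link{generateDataset}}.
#' @param distanceThresholdMm consensus/conflict threshold in mm (default 5).
#' @param minApproval minimum reader approvals (default 1).
#' @param cubeMm,outRes,nSlices VOI geometry, see \code{\link{extractVoi}}
#'   and \code{\link{selectSlices}}.
#' @return List of records; each has \code{$objectId}, \code{$scanId},
#'   \code{$label}, \code{$approvalCount} and \code{$stacks} (named list
#'   of three \linkS4class{PerspectiveStack}).
#' @export
phantomStackDataset <- function(nScans, objectsPerScan = 4L,
                                separability = c("easy", "hard"),
                                config = phantomConfig(), seed = 1L,
                                distanceThresholdMm = 5, minApproval = 1L,
                                cubeMm = 30, outRes = 56L, nSlices = 6L) {
  separability <- match.arg(separability)
  set.seed(seed)
  base <- objectsPerScan %/% 2L
  extra <- objectsPerScan %% 2L
  records <- list()
  for (s in seq_len(nScans)) {
    nNod <- base + if (extra == 1L && s %% 2L == 1L) 1L else 0L
    scan <- generateScan(sprintf("scan%04d", s), nNod,
                         objectsPerScan - nNod, separability, config)
    ann <- do.call(rbind, lapply(scan@objects, function(ob)
      cbind(scan_id = scan@scanId, ob@readerAnnotations)))
    consensus <- scanConsensus(ann, distanceThresholdMm, minApproval)
    for (ci in seq_along(consensus)) {
      voi <- extractVoi(scan, consensus[[ci]], cubeMm, outRes)
      records[[length(records) + 1L]] <- list(
        objectId = sprintf("%s_obj%02d", scan@scanId, ci),
        scanId = scan@scanId,
        label = consensus[[ci]]@kind,
        approvalCount = consensus[[ci]]@approvalCount,
        stacks = voiToStacks(voi, nSlices, cubeMm))
    }
  }
  records
}

#' Manifest table of a stack-record dataset
#'
#' @param records as returned by \code{\link{phantomStackDataset}}.
#' @return data.frame with \code{object_id, scan_id, label,
#'   approval_count}.
#' @export
datasetManifest <- function(records) {
  data.frame(
    object_id = vapply(records, `[[`, character(1), "objectId"),
    scan_id = vapply(records, `[[`, character(1), "scanId"),
    label = vapply(records, `[[`, character(1), "label"),
    approval_count = vapply(records, function(r)
      as.integer(r$approvalCount), integer(1)))
}
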