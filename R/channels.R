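## Spatially uniform electrode selection via k-medoids and anatomical lobe
## grouping.

#' Select spatially uniform electrodes by k-medoids clustering
#'
#' Partitions the electrode cloud into k clusters and returns each
#' cluster's representative: the member with least mean Euclidean distance
#' to its co-members. The algorithm alternates between assigning every
#' point to its nearest medoid (ties broken toward the lower electrode
#' index) and recomputing each cluster's medoid, until the medoid set is a
#' fixed point or `maxIter` is reached. Because a single random
#' initialization can land in a poor local optimum, `nRestarts` seeded
#' restarts are run and the assignment with the smallest total
#' point-to-medoid distance is returned. The resulting medoids are
#' approximately homogeneously distributed across the cloud, whatever its
#' shape -- the property used to pick evenly spread EEG channels.
#'
#' @param layout an [ElectrodeLayout-class]
#' @param k number of clusters (1 <= k <= number of electrodes)
#' @param seed seed for the random initializations
#' @param nRestarts number of random restarts (default 10)
#' @param maxIter iteration cap per restart (default 300)
#' @return a [ClusterAssignment-class]
#' @export
kmedoidsSelect <- function(layout, k, seed = 1L, nRestarts = 10L,
                           maxIter = 300L) {
  stopifnot(is(layout, "ElectrodeLayout"))
  n <- length(layout@labels)
  if (k < 1L || k > n) stop("k must lie between 1 and ", n)
  D <- as.matrix(stats::dist(layout@coords))
  starts <- withSeed(seed, lapply(seq_len(nRestarts), function(r)
    sort(sample.int(n, k))))
  best <- NULL
  for (med in starts) {
    for (iter in seq_len(maxIter)) {
      # medoids kept sorted so which.min ties resolve to the lower index
      assign <- apply(D[, med, drop = FALSE], 1L, which.min)
      newMed <- vapply(seq_len(k), function(c_) {
        members <- which(assign == c_)
        if (!length(members)) return(med[c_])  # empty cluster keeps medoid
        members[which.min(rowMeans(D[members, members, drop = FALSE]))]
      }, integer(1))
      if (identical(sort(newMed), med)) break
      med <- sort(newMed)
    }
    assign <- apply(D[, med, drop = FALSE], 1L, which.min)
    cost <- sum(D[cbind(seq_len(n), med[assign])])
    if (is.null(best) || cost < best$cost)
      best <- list(med = med, assign = assign, cost = cost)
  }
  medoid <- rep(FALSE, n)
  medoid[best$med] <- TRUE
  new("ClusterAssignment", cluster = as.integer(best$assign),
      medoid = medoid, cost = best$cost, labels = layout@labels)
}

#' Selected electrode labels
#'
#' @param assignment a [ClusterAssignment-class]
#' @return the labels of the medoid (representative) electrodes
#' @export
selectedChannels <- function(assignment) {
  stopifnot(is(assignment, "ClusterAssignment"))
  assignment@labels[assignment@medoid]
}

#' Restrict a layout to one anatomical lobe
#'
#' @param layout an [ElectrodeLayout-class] with lobe tags
#' @param lobe one of "frontal", "parietal", "temporal", "occipital"
#' @return the sub-layout of electrodes tagged with that lobe
#' @export
restrictToLobe <- function(layout, lobe) {
  stopifnot(is(layout, "ElectrodeLayout"))
  lobes <- c("frontal", "parietal", "temporal", "occipital")
  if (!lobe %in% lobes)
    stop("unknown lobe '", lobe, "'; expected one of: ",
         paste(lobes, collapse = ", "))
  if (all(is.na(layout@lobe))) stop("layout carries no lobe tags")
  keep <- which(!is.na(layout@lobe) & layout@lobe == lobe)
  if (!length(keep)) stop("no electrodes tagged '", lobe, "'")
  ElectrodeLayout(layout@labels[keep],
                  layout@coords[keep, , drop = FALSE],
                  layout@lobe[keep])
}
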