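#' Electrode montages
#'
#' A montage holds channel labels, unit-sphere 3-D positions, and a table of
#' 10-10 name equivalences ("Pz", "Oz", "PO8", ...) resolving to channel
#' indices.  Positions are normalized to unit radius, as required by
#' spherical-spline interpolation.
#'
#' @param names character vector of unique channel labels.
#' @param positions3d numeric matrix `n_channels x 3`; rows are normalized to
#'   unit length.
#' @param equivalences named character vector mapping 10-10 labels to channel
#'   labels (may be empty).
#' @return an object of class `erp_montage` with elements `names`,
#'   `positions3d`, `equivalences` (named integer index vector).
#' @export
montage <- function(names, positions3d, equivalences = character()) {
  assert_that(!anyDuplicated(names), "montage_error",
              "montage channel names must be unique")
  positions3d <- as.matrix(positions3d)
  assert_that(nrow(positions3d) == length(names) && ncol(positions3d) == 3,
              "montage_error", "positions3d must be %d x 3", length(names))
  r <- sqrt(rowSums(positions3d^2))
  assert_that(all(r > 0), "montage_error", "zero-length electrode position")
  positions3d <- positions3d / r
  dimnames(positions3d) <- list(names, c("x", "y", "z"))
  eq <- integer(0)
  if (length(equivalences)) {
    idx <- match(equivalences, names)
    assert_that(!anyNA(idx), "montage_error",
                "equivalence target(s) not in montage: %s",
                paste(equivalences[is.na(idx)], collapse = ", "))
    eq <- stats::setNames(idx, names(equivalences))
  }
  structure(list(names = names, positions3d = positions3d,
                 equivalences = eq),
            class = "erp_montage")
}

#' @export
print.erp_montage <- function(x, ...) {
  cat(sprintf("<erp_montage> %d channels, %d named equivalences\n",
              length(x$names), length(x$equivalences)))
  invisible(x)
}

#' Bundled dense-array montage
#'
#' Loads the 129-channel HydroCel-style montage bundled with the package
#' (128 recording electrodes "E1".."E128" plus the Cz reference), together
#' with the published 10-10 equivalence table (Pz=E62, Oz=E75, PO8=E96, ...).
#'
#' @return an `erp_montage` with 129 channels.
#' @export
hydrocel_montage <- function() {
  pos <- utils::read.delim(system.file("extdata", "gsn_hydrocel_129.tsv",
                                       package = "erpsynth"))
  eqt <- utils::read.delim(system.file("extdata", "gsn129_1010_equiv.tsv",
                                       package = "erpsynth"))
  montage(pos$name, as.matrix(pos[, c("x", "y", "z")]),
          stats::setNames(eqt$channel, eqt$label))
}

# Canonical 10-10 scalp coordinates bundled for topography placement and for
# deriving equivalences on synthetic montages.
ten_ten_positions <- function() {
  p <- utils::read.delim(system.file("extdata", "ten_ten_positions.tsv",
                                     package = "erpsynth"))
  m <- as.matrix(p[, c("x", "y", "z")])
  rownames(m) <- p$label
  m / sqrt(rowSums(m^2))
}

#' Synthetic hemispheric montage
#'
#' Builds an evenly spread `n_channels` electrode layout on the upper portion
#' of the unit sphere (spherical Fibonacci lattice).  Used by the desk-scale
#' simulator profile where the full dense-array net is not needed.  10-10
#' equivalences are assigned by nearest canonical 10-10 position.
#'
#' @param n_channels number of electrodes.
#' @return an `erp_montage`.
#' @export
synthetic_montage <- function(n_channels) {
  assert_that(n_channels >= 2, "montage_error", "need at least 2 channels")
  i <- seq_len(n_channels) - 0.5
  # upper-ish cap: z in (-0.25, 1) covers scalp down to below the inion line
  z <- 1 - i / n_channels * 1.25
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  nm <- paste0("E", seq_len(n_channels))
  tt <- ten_ten_positions()
  eq <- vapply(rownames(tt), function(lab) {
    nm[which.min(colSums((t(pos) - tt[lab, ])^2))]
  }, character(1))
  montage(nm, pos, eq)
}

#' Resolve a 10-10 channel name to a montage index
#'
#' @param m an `erp_montage`.
#' @param name a 10-10 label present in the montage's equivalence table, or a
#'   raw channel label.
#' @return integer channel index usable to slice epoch data rows.
#' @export
channel_index <- function(m, name) {
  stopifnot(inherits(m, "erp_montage"))
  if (name %in% names(m$equivalences)) return(unname(m$equivalences[[name]]))
  hit <- match(name, m$names)
  if (!is.na(hit)) return(hit)
  known <- c(names(m$equivalences), m$names)
  sug <- known[which.min(utils::adist(name, known, ignore.case = TRUE))]
  stop_fmt("lookup_error",
           "unknown channel label '%s'; did you mean '%s'?", name, sug)
}
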