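#' Idealized B-form helix parameterization
#'
#' Parameterizes an idealized B-DNA duplex for scissile-phosphate
#' geometry. Phosphorus pseudo-atoms are placed on two antiparallel
#' strands by helical symmetry: residue `i` of strand 1 sits at
#' cylindrical coordinates `(p_radius, p_azimuth_offset + (i-1) * twist,
#' p_z_offset + (i-1) * rise)`; strand 2 is the image of strand 1 under
#' the duplex dyad (two-fold rotation about the x axis), i.e.
#' `(p_radius, -p_azimuth_offset + (i-1) * twist,
#' -p_z_offset + (i-1) * rise)`.
#'
#' The default twist and rise are the canonical B-form fiber values
#' (36 degrees, 3.38 Å per bp). The phosphate placement constants were
#' calibrated once (`system.file("scripts", "calibrate_helix.R", package
#' = "marinercleave")` reproduces them) so that a single parameter set
#' reproduces the three
#' scissile-phosphate distances of interest — 11.9 Å at stagger +3
#' (mariner, across the minor groove), 16.9 Å at stagger 0 (Tn10/Tn5,
#' through the middle of the helix) and 18.3 Å at stagger -4 (PiggyBac,
#' across the major groove) — within 0.3 Å, while keeping stagger +3 the
#' global minimum over opposite-strand phosphate pairs, as in real
#' B-DNA.
#'
#' @param twist Helical twist, degrees per bp, in `(0, 60]`.
#' @param rise Helical rise, Å per bp, `> 0`.
#' @param p_radius Phosphorus radial distance from the helix axis, Å.
#' @param p_azimuth_offset Angular placement of the strand-1 phosphorus
#'   relative to the base-pair dyad, degrees.
#' @param p_z_offset Axial offset of the phosphorus from its base-pair
#'   plane, Å (strand 2 gets the opposite sign).
#' @return An object of class `helix_model`.
#' @export
helix_model <- function(twist = 36, rise = 3.38,
                        p_radius = 9.5148,
                        p_azimuth_offset = 63.2298,
                        p_z_offset = -0.6071) {
  stopifnot(is.numeric(twist), twist > 0, twist <= 60,
            is.numeric(rise), rise > 0,
            is.numeric(p_radius), p_radius > 0,
            is.numeric(p_azimuth_offset), is.numeric(p_z_offset))
  structure(list(twist = twist, rise = rise, p_radius = p_radius,
                 p_azimuth_offset = p_azimuth_offset,
                 p_z_offset = p_z_offset, handedness = "right"),
            class = "helix_model")
}

#' Build the phosphate trace of an idealized duplex
#'
#' @param params A [helix_model()].
#' @param n_bp Number of base pairs (`>= 2`).
#' @return A data frame of class `phosphate_trace` with columns
#'   `strand` (`"A"`/`"B"`), `index` (residue, 1-based), `x`, `y`, `z`
#'   (Å). The helix parameters are carried in the `"helix"` attribute.
#' @examples
#' tr <- build_duplex(helix_model(), n_bp = 24)
#' head(tr)
#' @export
build_duplex <- function(params = helix_model(), n_bp) {
  stopifnot(inherits(params, "helix_model"))
  if (!is.numeric(n_bp) || n_bp < 2) {
    stop("n_bp must be at least 2", call. = FALSE)
  }
  n_bp <- as.integer(n_bp)
  i <- seq_len(n_bp) - 1L
  w <- params$twist * pi / 180
  az <- params$p_azimuth_offset * pi / 180
  r <- params$p_radius
  th1 <- az + w * i
  th2 <- -az + w * i
  out <- data.frame(
    strand = rep(c("A", "B"), each = n_bp),
    index = rep(seq_len(n_bp), 2L),
    x = c(r * cos(th1), r * cos(th2)),
    y = c(r * sin(th1), r * sin(th2)),
    z = c(params$p_z_offset + params$rise * i,
          -params$p_z_offset + params$rise * i)
  )
  attr(out, "helix") <- params
  class(out) <- c("phosphate_trace", "data.frame")
  out
}

.trace_strand <- function(trace, strand) {
  m <- as.matrix(trace[trace$strand == strand, c("x", "y", "z")])
  m[order(trace$index[trace$strand == strand]), , drop = FALSE]
}

#' Inter-strand phosphate distance at a given stagger
#'
#' Euclidean distance between a phosphate on strand A and the phosphate
#' on strand B offset by `stagger` base pairs. Sign convention: positive
#' staggers step toward the minor-groove side of the dyad — the
#' geometry of a 5'-recessed double-strand break leaving 5' overhangs,
#' as in mariner cleavage (stagger +3). Stagger 0 is the blunt,
#' directly-opposed pair (Tn10/Tn5); negative staggers step toward the
#' major-groove side (PiggyBac's 4-bp TTAA geometry is stagger -4). By
#' helical symmetry the distance is independent of the reference
#' position along the trace.
#'
#' @param trace A [build_duplex()] trace.
#' @param stagger Integer bp offset; the trace must be long enough to
#'   contain the offset pair away from its ends.
#' @param ref Optional reference residue index on strand A (defaults to
#'   the mid-trace position).
#' @return Distance in Å.
#' @examples
#' tr <- build_duplex(n_bp = 30)
#' interstrand_p_distance(tr, 3)    # mariner, ~11.9 across the minor groove
#' interstrand_p_distance(tr, 0)    # Tn10/5, ~16.9 through the helix
#' interstrand_p_distance(tr, -4)   # PiggyBac, ~18.3 across the major groove
#' @export
interstrand_p_distance <- function(trace, stagger, ref = NULL) {
  stopifnot(inherits(trace, "phosphate_trace"))
  stagger <- as.integer(stagger)
  n <- max(trace$index)
  if (is.null(ref)) ref <- (n + 1L) %/% 2L
  j <- ref + stagger
  if (ref < 1L || ref > n || j < 1L || j > n) {
    stop("stagger ", stagger, " falls outside the trace (n_bp = ", n,
         ", ref = ", ref, ")", call. = FALSE)
  }
  a <- .trace_strand(trace, "A")[ref, ]
  b <- .trace_strand(trace, "B")[j, ]
  sqrt(sum((a - b)^2))
}

#' Stagger minimizing the inter-strand phosphate distance
#'
#' Scans integer staggers and returns the one with the minimal
#' opposite-strand phosphate distance; with the default helix this is
#' +3, the mariner pair across the minor groove, the closest pair of
#' phosphates on opposite strands.
#'
#' @param trace A [build_duplex()] trace.
#' @param stagger_range Integer vector (or length-2 range) of staggers
#'   to scan, all of which must fit in the trace.
#' @return Named numeric vector `c(stagger, distance)`.
#' @examples
#' tr <- build_duplex(n_bp = 30)
#' min_distance_stagger(tr, -10:10)
#' @export
min_distance_stagger <- function(trace, stagger_range = -10:10) {
  stopifnot(inherits(trace, "phosphate_trace"))
  if (!length(stagger_range)) stop("empty stagger range", call. = FALSE)
  if (length(stagger_range) == 2L &&
      stagger_range[2] - stagger_range[1] > 1) {
    stagger_range <- seq(stagger_range[1], stagger_range[2])
  }
  d <- vapply(stagger_range, function(s) interstrand_p_distance(trace, s),
              numeric(1))
  i <- which.min(d)
  c(stagger = stagger_range[i], distance = d[i])
}

#' Scissile-phosphate staggers of reference transposon chemistries
#'
#' Signed staggers (see [interstrand_p_distance()] for the convention)
#' of the double-strand-break geometries discussed alongside mariner:
#' mariner's 3-bp 5'-overhang pair across the minor groove (+3), the
#' blunt Tn10/Tn5 hairpin pair through the helix (0), and PiggyBac's
#' 4-bp TTAA pair across the major groove (-4). The Tn10/5 and PiggyBac
#' values are mechanistic assignments (blunt hairpin chemistry; TTAA
#' overhang across the major groove), not printed staggers.
#'
#' @param which Optional subset of `c("mariner", "tn10_5", "piggybac")`.
#' @return Named integer vector of staggers.
#' @export
scissile_stagger <- function(which = c("mariner", "tn10_5", "piggybac")) {
  all <- c(mariner = 3L, tn10_5 = 0L, piggybac = -4L)
  which <- match.arg(which, several.ok = TRUE)
  all[which]
}

#' Descriptive groove side of an inter-strand pair
#'
#' Reports, from the azimuthal separation of the pair, whether a stagger
#' places the two phosphates across the minor groove, across the major
#' groove, or through the middle of the helix. Purely descriptive; no
#' computation consumes the label.
#'
#' @param params A [helix_model()].
#' @param stagger Integer bp offset.
#' @return One of `"minor_groove"`, `"major_groove"`, `"through_helix"`.
#' @export
groove_side <- function(params = helix_model(), stagger) {
  dphi <- 2 * params$p_azimuth_offset - params$twist * stagger
  dphi <- abs(((dphi + 180) %% 360) - 180)  # wrapped to [0, 180]
  if (dphi >= 120) "through_helix"
  else if (stagger >= 1) "minor_groove"
  else "major_groove"
}

#' Export a phosphate trace as a PDB file
#'
#' Writes one phosphorus pseudo-atom per residue, the two strands as
#' chains A and B, via [bio3d::write.pdb()]. Coordinates round-trip at
#' PDB precision (1e-3 Å).
#'
#' @param trace A [build_duplex()] trace.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
export_trace <- function(trace, file) {
  stopifnot(inherits(trace, "phosphate_trace"))
  n <- nrow(trace)
  xyz <- as.vector(t(as.matrix(trace[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = file,
    xyz = xyz,
    type = rep("ATOM", n),
    eleno = seq_len(n),
    elety = rep("P", n),
    resid = rep("DN", n),
    chain = trace$strand,
    resno = trace$index,
    elesy = rep("P", n)
  )
  invisible(file)
}

#' Read a phosphate trace back from a PDB file
#'
#' Inverse of [export_trace()].
#'
#' @param file PDB path written by [export_trace()].
#' @return A `phosphate_trace` data frame (without helix metadata).
#' @export
read_trace <- function(file) {
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  out <- data.frame(
    strand = at$chain,
    index = at$resno,
    x = at$x, y = at$y, z = at$z
  )
  out <- out[order(out$strand, out$index), ]
  rownames(out) <- NULL
  class(out) <- c("phosphate_trace", "data.frame")
  out
}
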