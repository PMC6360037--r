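#' Marker set and triplet definitions
#'
#' The pipeline works on a fixed set of 19 reflective markers placed on
#' standard anatomical landmarks (cervical spine, shoulders, elbows, wrists,
#' pelvis, greater trochanters, knees, heels and first metatarsal heads).
#' Angular features are planar angles measured at a vertex marker between
#' rays towards two other markers; 27 such triplets are defined, covering
#' both lower limbs, the trunk, the upper limbs and the pelvis.
#'
#' @format `gait_markers()` returns a character vector of the 19 marker
#'   identifiers in canonical order. `gait_triplets()` returns a 27 x 3
#'   character matrix with columns `p1`, `vertex`, `p3`: the angle is
#'   measured at `vertex` between the rays towards `p1` and `p3`.
#' @name marker_set
NULL

.GAIT_MARKERS <- c(
  "C7", "LA", "RA", "REP", "LEP", "RUL", "LUL",
  "RASIS", "LASIS", "RPSIS", "LPSIS",
  "RGT", "LGT", "RLE", "LLE", "RCA", "LCA", "RFM", "LFM"
)

# 27 triplets in canonical row order; middle column is the angle vertex.
.GAIT_TRIPLETS <- matrix(c(
  "LGT",   "LPSIS", "LLE",
  "LLE",   "LGT",   "LCA",
  "LCA",   "LLE",   "LFM",
  "LEP",   "LA",    "LUL",
  "LEP",   "C7",    "LUL",
  "LLE",   "LASIS", "LFM",
  "LA",    "C7",    "LEP",
  "RGT",   "RPSIS", "RLE",
  "RLE",   "RGT",   "RCA",
  "RCA",   "RLE",   "RFM",
  "REP",   "RA",    "RUL",
  "REP",   "C7",    "RUL",
  "RLE",   "RASIS", "RFM",
  "RA",    "C7",    "REP",
  "LPSIS", "LGT",   "RGT",
  "LASIS", "LGT",   "RGT",
  "LPSIS", "LLE",   "RLE",
  "C7",    "LA",    "RA",
  "C7",    "LEP",   "REP",
  "RPSIS", "LGT",   "RGT",
  "RASIS", "LGT",   "RGT",
  "RPSIS", "LLE",   "RLE",
  "C7",    "LUL",   "RUL",
  "LASIS", "C7",    "LPSIS",
  "RASIS", "C7",    "RPSIS",
  "LA",    "LASIS", "RASIS",
  "RA",    "LASIS", "RASIS"
), ncol = 3, byrow = TRUE, dimnames = list(NULL, c("p1", "vertex", "p3")))

.GAIT_PLANES <- c("sagittal", "frontal", "transverse")

#' @rdname marker_set
#' @export
gait_markers <- function() .GAIT_MARKERS

#' @rdname marker_set
#' @export
gait_triplets <- function() .GAIT_TRIPLETS

#' @rdname marker_set
#' @export
gait_planes <- function() .GAIT_PLANES

#' Names of the 81 angle features
#'
#' Plane-major ordering: all 27 triplet angles in the sagittal plane, then
#' frontal, then transverse; within a plane, triplets follow the canonical
#' row order of [gait_triplets()]. This ordering is frozen so that feature
#' indices are reproducible across runs.
#'
#' @return Character vector of length 81, e.g. `"sagittal.LPSIS.LGT_LLE"`
#'   (plane, vertex, then the two ray endpoints).
#' @export
angle_feature_names <- function() {
  tr <- .GAIT_TRIPLETS
  unlist(lapply(.GAIT_PLANES, function(pl) {
    paste0(pl, ".", tr[, "vertex"], ".", tr[, "p1"], "_", tr[, "p3"])
  }))
}
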