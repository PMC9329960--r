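#' BODY_25 keypoint layout
#'
#' Canonical keypoint names of the 25-keypoint BODY_25 human-skeleton layout
#' used by OpenPose, in model order (index 0 to 24).
#'
#' @format Character vector of length 25; element \code{i} is the name of
#'   keypoint index \code{i - 1}.
#' @export
BODY25 <- c(
  "Nose", "Neck", "RShoulder", "RElbow", "RWrist",
  "LShoulder", "LElbow", "LWrist", "MidHip", "RHip",
  "RKnee", "RAnkle", "LHip", "LKnee", "LAnkle",
  "REye", "LEye", "REar", "LEar", "LBigToe",
  "LSmallToe", "LHeel", "RBigToe", "RSmallToe", "RHeel"
)

#' Column index of a BODY_25 keypoint
#'
#' @param name Keypoint name (e.g. \code{"LAnkle"}); vectorized.
#' @return 1-based column index into the keypoint matrices of a
#'   \code{pose_sequence}.
#' @export
body25_index <- function(name) {
  idx <- match(name, BODY25)
  if (anyNA(idx)) {
    stop("unknown BODY_25 keypoint name(s): ",
         paste(name[is.na(idx)], collapse = ", "))
  }
  idx
}

# left/right keypoint pairs whose x-separation collapses during a turn;
# order: right member first, then left member
BODY25_PAIRS <- list(
  hips      = c("RHip", "LHip"),
  knees     = c("RKnee", "LKnee"),
  ankles    = c("RAnkle", "LAnkle"),
  bigtoes   = c("RBigToe", "LBigToe"),
  shoulders = c("RShoulder", "LShoulder"),
  elbows    = c("RElbow", "LElbow"),
  wrists    = c("RWrist", "LWrist"),
  ears      = c("REar", "LEar")
)
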