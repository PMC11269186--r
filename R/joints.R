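#' The 25 Kinect-v2 skeletal joint names
#'
#' The closed set of joint labels tracked by a Kinect v2 depth camera. All
#' recordings handled by this package carry exactly these 25 joints, in this
#' canonical order.
#'
#' @return A character vector of length 25.
#' @export
#' @examples
#' kinect_joints()
kinect_joints <- function() {
  c(
    "SpineBase", "SpineMid", "Neck", "Head",
    "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
    "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
    "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
    "HipRight", "KneeRight", "AnkleRight", "FootRight",
    "SpineShoulder", "HandTipLeft", "ThumbLeft",
    "HandTipRight", "ThumbRight"
  )
}

assert_joint <- function(joint) {
  bad <- setdiff(joint, kinect_joints())
  if (length(bad) > 0L) {
    abort(paste0(
      "Unknown joint label(s): ", paste(bad, collapse = ", "),
      ". Joints must be one of the 25 Kinect-v2 labels (see kinect_joints())."
    ))
  }
  invisible(joint)
}
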