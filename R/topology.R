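#' Body segment topology of the 11-IMU suit
#'
#' The eleven sensors are indexed 0 head, 1 breast, 2 LUArm, 3 LFArm,
#' 4 RUArm, 5 RFArm, 6 waist, 7 LThigh, 8 LShank, 9 RThigh, 10 RShank.
#' The waist is the root of the evaluation tree: the upper body hangs off
#' the breast (thoracic chain) and each limb chains through its proximal
#' segment.  Sensors on head, breast, waist, thighs and shanks share one
#' mounting frame (group `"O1"`); the arm sensors share another (`"O2"`),
#' each with its own constant quaternion into the animation frame.
#'
#' @param head_parent `"breast"` (neck chain, default) or `"waist"`.
#' @return a `body_topology` list with elements `segments` (names in IMU
#'   index order), `imu_index` (named 0..10), `parent` (named character,
#'   `NA` for the waist root) and `init_group` (named `"O1"`/`"O2"`).
#' @examples
#' topo <- body_topology()
#' topo$parent["LShank"]  # "LThigh"
#' @export
body_topology <- function(head_parent = c("breast", "waist")) {
  head_parent <- match.arg(head_parent)
  segments <- c("head", "breast", "LUArm", "LFArm", "RUArm", "RFArm",
                "waist", "LThigh", "LShank", "RThigh", "RShank")
  parent <- c(head = head_parent, breast = "waist",
              LUArm = "breast", LFArm = "LUArm",
              RUArm = "breast", RFArm = "RUArm",
              waist = NA_character_,
              LThigh = "waist", LShank = "LThigh",
              RThigh = "waist", RShank = "RThigh")
  group <- c(head = "O1", breast = "O1", LUArm = "O2", LFArm = "O2",
             RUArm = "O2", RFArm = "O2", waist = "O1", LThigh = "O1",
             LShank = "O1", RThigh = "O1", RShank = "O1")
  structure(list(segments = segments,
                 imu_index = stats::setNames(0:10, segments),
                 parent = parent[segments],
                 init_group = group[segments]),
            class = "body_topology")
}

#' @export
print.body_topology <- function(x, ...) {
  cat("Body topology: 11 IMU segments, root = waist\n")
  for (s in x$segments)
    cat(sprintf("  [%2d] %-7s parent: %s (%s)\n", x$imu_index[[s]], s,
                ifelse(is.na(x$parent[[s]]), "-", x$parent[[s]]),
                x$init_group[[s]]))
  invisible(x)
}

# column indices of segment i (IMU index 0..10) in an n x 44 quaternion
# block, ordered q0_w q0_x q0_y q0_z q1_w ...
seg_cols <- function(imu) 4L * imu + 1:4

segment_index <- function(topo, segment) {
  if (is.character(segment)) {
    if (!segment %in% topo$segments) stop("unknown segment: ", segment)
    unname(topo$imu_index[[segment]])
  } else {
    if (!segment %in% 0:10) stop("unknown segment index: ", segment)
    as.integer(segment)
  }
}
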