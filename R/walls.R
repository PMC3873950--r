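# Wall-artifact correction. Container-grown roots that reach a wall or the
# container bottom are deflected and then follow the face; for architectural
# analysis such axes are virtually extended in the direction the root was
# growing before it attained the edge, keeping every segment's length.

wall_faces <- function(container) {
  wx <- container[1] / 2; wy <- container[2] / 2; dz <- container[3]
  list(
    list(name = "x+", normal = c(1, 0, 0), offset = wx),
    list(name = "x-", normal = c(-1, 0, 0), offset = wx),
    list(name = "y+", normal = c(0, 1, 0), offset = wy),
    list(name = "y-", normal = c(0, -1, 0), offset = wy),
    list(name = "bottom", normal = c(0, 0, -1), offset = dz)
  )
}

#' Virtually extend wall-deflected roots
#'
#' Detects axes whose trajectory contacts a container face and subsequently
#' runs along it, and re-aims every post-contact segment along the last
#' pre-contact direction, preserving each segment's length. Sub-arborescences
#' borne by moved segments are translated with their bearing point; topology
#' is unchanged. Axes that never contact a face are returned bitwise
#' identical.
#'
#' Contact detection: a vertex within `contact_tol` of a face and at least
#' `min_follow` subsequent segment directions within `face_angle_tol` degrees
#' of that face's plane. An axis whose first vertex already lies on a face is
#' left unchanged with a warning.
#'
#' @param rs A [root_system()].
#' @param contact_tol Distance tolerance to a face, metres (default 2 mm).
#' @param face_angle_tol Max angle (degrees) between a post-contact segment
#'   direction and the face plane for the segment to count as wall-following.
#' @param min_follow Minimum number of consecutive wall-following segments
#'   after the contact vertex required to trigger the correction.
#' @param follow_tol Distance tolerance (m) within which the endpoints of a
#'   wall-following segment must lie on a face. Tighter than `contact_tol`:
#'   deflected segments run essentially on the face, whereas a vertex a
#'   couple of millimetres short of the wall is still free growth.
#' @return A corrected [root_system()]; corrected axis ids are recorded in
#'   `attr(, "corrected_axes")`.
#' @export
extend_wall_roots <- function(rs, contact_tol = 0.002, face_angle_tol = 15,
                              min_follow = 2, follow_tol = 1e-4) {
  faces <- wall_faces(rs$container)
  paths <- axis_paths(rs)
  seg <- rs$segments
  vectors <- stats::setNames(
    purrr::map(seq_len(nrow(seg)), ~ c(
      seg$tip_x[.x] - seg$base_x[.x],
      seg$tip_y[.x] - seg$base_y[.x],
      seg$tip_z[.x] - seg$base_z[.x]
    )),
    seg$segment_id
  )
  corrected <- character(0)
  sin_tol <- sin(face_angle_tol * pi / 180)

  for (p in paths) {
    nseg <- length(p$segment_ids)
    if (nseg < min_follow + 1) next
    dirs <- p$verts[-1, , drop = FALSE] - p$verts[-(nseg + 1), , drop = FALSE]
    dn <- sqrt(rowSums(dirs^2))
    udirs <- dirs / ifelse(dn > 0, dn, 1)
    hit <- NULL
    # a segment is wall-following when it lies on some container face
    # (both endpoints within tolerance) with a direction in that face's
    # plane; this also covers corner hits where the root slides onto a
    # second face
    on_face <- function(j) {
      for (f in faces) {
        d1 <- f$offset - sum(p$verts[j, ] * f$normal)
        d2 <- f$offset - sum(p$verts[j + 1, ] * f$normal)
        if (abs(d1) <= follow_tol && abs(d2) <= follow_tol &&
            abs(sum(udirs[j, ] * f$normal)) <= sin_tol) {
          return(TRUE)
        }
      }
      FALSE
    }
    # scan vertices for the first qualifying contact (enough segments must
    # remain after the contact vertex to witness wall-following)
    for (k in seq_len(nseg - min_follow + 1)) {
      vtx <- p$verts[k, ]
      for (f in faces) {
        dist <- f$offset - sum(vtx * f$normal)  # signed distance inside box
        if (abs(dist) <= contact_tol) {
          follow <- seq(k, k + min_follow - 1)
          if (all(vapply(follow, on_face, logical(1)))) {
            hit <- list(vertex = k, face = f)
            break
          }
        }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) next
    k <- hit$vertex
    if (k == 1) {
      rlang::warn(sprintf(
        "axis %s starts on container face %s; left unchanged",
        p$axis_id, hit$face$name
      ))
      next
    }
    # last pre-contact direction = direction of the segment arriving at k
    dir0 <- udirs[k - 1, ]
    for (j in seq(k, nseg)) {
      vectors[[p$segment_ids[j]]] <- dir0 * dn[j]
    }
    corrected <- c(corrected, p$axis_id)
  }

  if (length(corrected) == 0) {
    attr(rs, "corrected_axes") <- character(0)
    return(rs)
  }
  out <- rebuild_coordinates(rs, vectors)
  attr(out, "corrected_axes") <- corrected
  out
}
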