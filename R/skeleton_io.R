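#' Load a skeleton definition
#'
#' Two formats are supported: the package's native JSON dialect (see
#' [save_skeleton()] for the schema) and a restricted subset of the
#' OpenSim XML model format covering `Body`, `FreeJoint`, `BallJoint`,
#' `UniversalJoint` and `PinJoint` elements plus a `MarkerSet`. Muscles,
#' constraints and contact geometry in an OpenSim file are ignored with a
#' warning; any other joint class (notably `CustomJoint`) is rejected.
#'
#' @param path file path.
#' @param format `"native_json"` or `"osim_subset"`.
#' @return a [skeleton()].
#' @export
load_skeleton <- function(path, format = c("native_json", "osim_subset")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
         native_json = load_skeleton_json(path),
         osim_subset = load_skeleton_osim(path))
}

load_skeleton_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$format) || doc$format != "mocapfit-skeleton")
    stop("not a mocapfit skeleton JSON file (missing format tag)")
  segs <- lapply(doc$segments, function(s) {
    list(name = s$name, mass = s$mass, com = unlist(s$com),
         inertia = matrix(unlist(s$inertia), 3, 3, byrow = TRUE))
  })
  jts <- lapply(doc$joints, function(j) {
    pv <- j[["parent"]]
    if (is.list(pv) && !length(pv)) pv <- NULL # jsonlite writes NULL as {}
    list(name = j$name, type = j$type,
         parent = if (is.null(pv) || !length(pv)) NA else pv,
         child = j$child,
         parent_offset = unlist(j$parent_offset),
         child_offset = unlist(j$child_offset),
         parent_orient = unlist(j$parent_orient),
         child_orient = unlist(j$child_orient),
         axes = lapply(j$axes, unlist))
  })
  mks <- lapply(doc$markers, function(m) {
    list(label = m$label, segment = m$segment, offset = unlist(m$offset),
         anatomical = isTRUE(m$anatomical))
  })
  grav <- if (is.null(doc$gravity)) c(0, -9.81, 0) else unlist(doc$gravity)
  skeleton(segs, jts, mks, gravity = grav)
}

#' Write a skeleton to the native JSON format
#'
#' Schema (version 1): a JSON object with `format`, `version`, `gravity`,
#' `segments` (name/mass/com/inertia rows), `joints`
#' (name/type/parent/child/offsets/orientations/axes) and `markers`
#' (label/segment/offset/anatomical). Units: m, kg, rad.
#'
#' @param skel a [skeleton()].
#' @param path output path.
#' @param s optional scale vector baked into the written offsets; when
#'   provided, the saved model has unit scales with all offsets, COMs and
#'   inertias pre-scaled.
#' @param p optional 3 x M matrix of registered marker offsets to save in
#'   place of the nominal set.
#' @param masses optional per-segment masses replacing the model defaults.
#' @return `path`, invisibly.
#' @export
save_skeleton <- function(skel, path, s = NULL, p = NULL, masses = NULL) {
  ns <- n_segments(skel)
  if (is.null(p)) p <- skel$pbar
  if (is.null(masses)) masses <- skel$mass0
  poff <- skel$poff; coff <- skel$coff; com <- skel$com
  inertia <- skel$inertia0; pb <- p
  if (!is.null(s)) {
    for (i in seq_len(ns)) {
      si <- s[(3 * i - 2):(3 * i)]
      coff[, i] <- si * coff[, i]
      com[, i] <- si * com[, i]
      pr <- skel$parent[i]
      if (pr >= 0) {
        sp <- s[(3 * pr + 1):(3 * pr + 3)]
        poff[, i] <- sp * poff[, i]
      }
      I0 <- inertia[, , i]
      pmom <- c(-I0[1, 1] + I0[2, 2] + I0[3, 3],
                I0[1, 1] - I0[2, 2] + I0[3, 3],
                I0[1, 1] + I0[2, 2] - I0[3, 3]) / 2
      pmom <- pmom * si^2
      Is <- diag(c(pmom[2] + pmom[3], pmom[1] + pmom[3], pmom[1] + pmom[2]))
      Is[1, 2] <- Is[2, 1] <- si[1] * si[2] * I0[1, 2]
      Is[1, 3] <- Is[3, 1] <- si[1] * si[3] * I0[1, 3]
      Is[2, 3] <- Is[3, 2] <- si[2] * si[3] * I0[2, 3]
      inertia[, , i] <- Is * masses[i] / skel$mass0[i]
      mi <- skel$marker_seg == (i - 1L)
      pb[, mi] <- si * pb[, mi, drop = FALSE]
    }
  }
  doc <- list(
    format = "mocapfit-skeleton", version = 1L,
    gravity = skel$gravity,
    segments = lapply(seq_len(ns), function(i) list(
      name = skel$seg_names[i], mass = masses[i], com = com[, i],
      inertia = unname(apply(inertia[, , i], 1, function(r) r,
                             simplify = FALSE)))),
    joints = lapply(seq_len(ns), function(i) list(
      name = skel$joint_names[i],
      type = names(JOINT_TYPES)[skel$jtype[i] + 1L],
      parent = if (skel$parent[i] < 0) NULL else
        skel$seg_names[skel$parent[i] + 1L],
      child = skel$seg_names[i],
      parent_offset = poff[, i], child_offset = coff[, i],
      parent_orient = rot_to_euler_xyz(skel$porient[, , i]),
      child_orient = rot_to_euler_xyz(skel$corient[, , i]),
      axes = unname(apply(skel$axes[, , i], 2, function(a) a,
                          simplify = FALSE)))),
    markers = lapply(seq_along(skel$marker_labels), function(k) list(
      label = skel$marker_labels[k],
      segment = skel$seg_names[skel$marker_seg[k] + 1L],
      offset = pb[, k], anatomical = skel$anatomical[k]))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

rot_to_euler_xyz <- function(R) {
  # inverse of euler_xyz; assumes |R[1,3]| < 1 away from gimbal
  ry <- asin(max(-1, min(1, R[1, 3])))
  if (abs(abs(R[1, 3]) - 1) < 1e-12) {
    rx <- atan2(R[2, 1], R[2, 2]); rz <- 0
  } else {
    rx <- atan2(-R[2, 3], R[3, 3])
    rz <- atan2(-R[1, 2], R[1, 1])
  }
  c(rx, ry, rz)
}

# ---- restricted OpenSim reader -------------------------------------------

osim_vec <- function(node, name, default = c(0, 0, 0)) {
  ch <- xml2::xml_find_first(node, name)
  if (inherits(ch, "xml_missing")) return(default)
  as.numeric(strsplit(trimws(xml2::xml_text(ch)), "\\s+")[[1]])
}

osim_frame_name <- function(path) {
  # "/bodyset/femur_r" or "/ground" or an offset-frame name
  sub("^.*/", "", trimws(path))
}

load_skeleton_osim <- function(path) {
  doc <- xml2::read_xml(path)
  model <- xml2::xml_find_first(doc, ".//Model")
  if (inherits(model, "xml_missing")) stop("no <Model> element found")

  if (length(xml2::xml_find_all(model, ".//ForceSet//*")) > 0 ||
      length(xml2::xml_find_all(model, ".//ConstraintSet//*")) > 0)
    warning("muscles/forces/constraints in the OpenSim file are ignored")

  bodies <- xml2::xml_find_all(model, ".//BodySet/objects/Body")
  segs <- lapply(bodies, function(b) {
    iner <- osim_vec(b, "inertia", c(1e-3, 1e-3, 1e-3, 0, 0, 0))
    I <- diag(iner[1:3])
    if (length(iner) >= 6) {
      I[1, 2] <- I[2, 1] <- iner[4]
      I[1, 3] <- I[3, 1] <- iner[5]
      I[2, 3] <- I[3, 2] <- iner[6]
    }
    list(name = xml2::xml_attr(b, "name"),
         mass = as.numeric(xml2::xml_text(xml2::xml_find_first(b, "mass"))),
         com = osim_vec(b, "mass_center"), inertia = I)
  })
  seg_names <- vapply(segs, function(s) s$name, character(1))

  jset <- xml2::xml_find_all(model, ".//JointSet/objects/*")
  supported <- c(FreeJoint = "free6", BallJoint = "ball3",
                 UniversalJoint = "universal2", PinJoint = "revolute1")
  jts <- lapply(jset, function(j) {
    cls <- xml2::xml_name(j)
    if (!cls %in% names(supported))
      stop("unsupported joint type in OpenSim file: ", cls,
           " (only Free/Ball/Universal/Pin joints are read)")
    pf <- xml2::xml_text(xml2::xml_find_first(j, "socket_parent_frame"))
    cf <- xml2::xml_text(xml2::xml_find_first(j, "socket_child_frame"))
    frames <- xml2::xml_find_all(j, ".//PhysicalOffsetFrame")
    finfo <- list()
    for (f in frames) {
      finfo[[xml2::xml_attr(f, "name")]] <- list(
        parent = osim_frame_name(xml2::xml_text(
          xml2::xml_find_first(f, "socket_parent"))),
        translation = osim_vec(f, "translation"),
        orientation = osim_vec(f, "orientation"))
    }
    resolve <- function(ref) {
      nm <- osim_frame_name(ref)
      if (nm %in% names(finfo)) {
        fi <- finfo[[nm]]
        list(seg = fi$parent, off = fi$translation, orient = fi$orientation)
      } else {
        list(seg = nm, off = c(0, 0, 0), orient = c(0, 0, 0))
      }
    }
    pa <- resolve(pf); ch <- resolve(cf)
    axes <- switch(supported[[cls]],
                   revolute1 = list(c(0, 0, 1)),
                   universal2 = list(c(1, 0, 0), c(0, 1, 0)),
                   NULL)
    list(name = xml2::xml_attr(j, "name"), type = supported[[cls]],
         parent = if (pa$seg == "ground") NA else pa$seg,
         child = ch$seg,
         parent_offset = pa$off, parent_orient = pa$orient,
         child_offset = ch$off, child_orient = ch$orient,
         axes = axes)
  })

  mset <- xml2::xml_find_all(model, ".//MarkerSet/objects/Marker")
  mks <- lapply(mset, function(m) {
    seg <- osim_frame_name(xml2::xml_text(
      xml2::xml_find_first(m, "socket_parent_frame")))
    fixed <- xml2::xml_find_first(m, "fixed")
    list(label = xml2::xml_attr(m, "name"), segment = seg,
         offset = osim_vec(m, "location"),
         anatomical = !inherits(fixed, "xml_missing") &&
           trimws(xml2::xml_text(fixed)) == "true")
  })
  if (!length(mks)) stop("OpenSim file has no MarkerSet")
  keep <- vapply(mks, function(m) m$segment %in% seg_names, logical(1))
  if (!all(keep)) warning("dropping markers on unknown frames: ",
                          paste(vapply(mks[!keep], `[[`, "", "label"),
                                collapse = ", "))
  grav <- osim_vec(model, "gravity", c(0, -9.8065, 0))
  skeleton(segs, jts, mks[keep], gravity = grav)
}
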