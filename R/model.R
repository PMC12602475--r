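#' Tibiofemoral knee model
#'
#' Container for one subject's model: bone and cartilage surface meshes in
#' the femoral/tibial body frames, the anatomical landmark set, the 15
#' ligament elements and the contact parameters.
#'
#' @param femur_bone,femur_cartilage,tibia_bone,tibia_cartilage
#'   \code{\link{surface_mesh}}es expressed in their body frames (femoral
#'   frame for femoral meshes, tibial frame for tibial meshes).
#' @param landmarks a \code{\link{landmark_set}}.
#' @param ligaments named list of exactly the 15 \code{\link{ligament_spec}}s.
#' @param contact a \code{\link{contact_params}}.
#' @param side \code{"right"} or \code{"left"}.
#' @param initial optional list with \code{femur} and \code{tibia}
#'   \code{\link{rigid_state}}s giving the imaging/reference pose.
#' @param profiles optional list of flexion profiles (numeric vectors,
#'   degrees), one per passive-flexion cycle.
#' @param meta optional list of provenance fields (preset, seed, ...).
#' @return an object of class \code{knee_model}.
#' @export
knee_model <- function(femur_bone, femur_cartilage, tibia_bone,
                       tibia_cartilage, landmarks, ligaments,
                       contact = contact_params(), side = "right",
                       initial = NULL, profiles = NULL, meta = list()) {
  for (m in list(femur_bone, femur_cartilage, tibia_bone, tibia_cartilage))
    stopifnot(inherits(m, "surface_mesh"))
  stopifnot(inherits(landmarks, "landmark_set"),
            inherits(contact, "contact_params"))
  nm <- vapply(ligaments, function(l) l$name, character(1L))
  if (!setequal(nm, ligament_names()) || anyDuplicated(nm))
    stop("knee_model: ligaments must contain each of the 15 canonical ",
         "elements exactly once", call. = FALSE)
  names(ligaments) <- nm
  if (!identical(femur_cartilage$frame, "femur") ||
      !identical(tibia_cartilage$frame, "tibia"))
    stop("knee_model: cartilage meshes must be expressed in their body ",
         "frames ('femur'/'tibia')", call. = FALSE)
  structure(list(femur_bone = femur_bone,
                 femur_cartilage = femur_cartilage,
                 tibia_bone = tibia_bone,
                 tibia_cartilage = tibia_cartilage,
                 landmarks = landmarks,
                 ligaments = ligaments[ligament_names()],
                 contact = contact, side = side,
                 initial = initial, profiles = profiles, meta = meta,
                 cache = new.env(parent = emptyenv())),
            class = "knee_model")
}

#' @export
print.knee_model <- function(x, ...) {
  cat("<knee_model>", x$side, "knee\n")
  cat(sprintf("  femur: bone %d / cartilage %d vertices\n",
              nrow(x$femur_bone$vertices), nrow(x$femur_cartilage$vertices)))
  cat(sprintf("  tibia: bone %d / cartilage %d vertices\n",
              nrow(x$tibia_bone$vertices), nrow(x$tibia_cartilage$vertices)))
  init <- vapply(x$ligaments, function(l) !is.na(l$L0), logical(1L))
  cat(sprintf("  ligaments: %d elements (%s)\n", length(x$ligaments),
              if (all(init)) "initialised" else "slack lengths unset"))
  if (!is.null(x$profiles))
    cat(sprintf("  flexion profiles: %d cycle(s)\n", length(x$profiles)))
  invisible(x)
}

# merge two meshes sharing a frame into one (disconnected components)
mesh_merge <- function(a, b) {
  stopifnot(identical(a$frame, b$frame))
  surface_mesh(rbind(a$vertices, b$vertices),
               rbind(a$faces, b$faces + nrow(a$vertices)),
               frame = a$frame, open = a$open || b$open)
}
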