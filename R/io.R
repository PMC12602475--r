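# File-format glue: landmark/ligament JSON, parameter YAML, run
# configuration, the synthetic-fixture writer and the model loader.
# All file units are mm / N / degrees; the CSV dialect is fixed
# (comma, '.', UTF-8, one header line) so validation diffs stay exact.

#' Write / read a landmark JSON file
#'
#' Schema: \code{{"side": "right", "units": "mm", "points": {"Lepi":
#' [x,y,z], ...}}} with all ten canonical names required.
#'
#' @param landmarks a \code{\link{landmark_set}}.
#' @param path file path.
#' @return \code{path} / a \code{landmark_set}.
#' @export
write_landmarks_json <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  jsonlite::write_json(
    list(side = landmarks$side, units = "mm",
         points = lapply(landmarks$points, as.numeric)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$points))
    stop("read_landmarks_json: no 'points' field in ", path, call. = FALSE)
  if (!is.null(x$units) && !identical(x$units, "mm"))
    stop("read_landmarks_json: units must be mm, got '", x$units, "'",
         call. = FALSE)
  landmark_set(lapply(x$points, as.numeric), side = x$side %||% "right")
}

#' Write / read a ligament JSON file
#'
#' Schema: an array of \code{{"name": "aACL", "femoral_mm": [...],
#' "tibial_mm": [...]}} entries, one per canonical element.
#'
#' @param ligaments named list of \code{\link{ligament_spec}}s.
#' @param path file path.
#' @param params optional named list of per-element \code{K_Q, K_L, e}
#'   used when reading (e.g. from \code{\link{read_params_yaml}}).
#' @return \code{path} / named list of \code{ligament_spec}s.
#' @export
write_ligaments_json <- function(ligaments, path) {
  entries <- lapply(ligaments, function(l) {
    list(name = l$name, femoral_mm = as.numeric(l$femoral_mm),
         tibial_mm = as.numeric(l$tibial_mm),
         K_Q = l$K_Q, K_L = l$K_L, e = l$e)
  })
  jsonlite::write_json(unname(entries), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ligaments_json
#' @export
read_ligaments_json <- function(path, params = NULL) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(x, function(e) {
    if (is.null(e$name) || is.null(e$femoral_mm) || is.null(e$tibial_mm))
      stop("read_ligaments_json: each entry needs name, femoral_mm, ",
           "tibial_mm", call. = FALSE)
    pp <- params[[e$name]] %||% list()
    ligament_spec(e$name, unlist(e$femoral_mm), unlist(e$tibial_mm),
                  K_Q = pp$K_Q %||% e$K_Q %||% 25,
                  K_L = pp$K_L %||% e$K_L %||% 60,
                  e = pp$e %||% e$e %||% 1)
  })
  names(out) <- vapply(out, `[[`, character(1L), "name")
  out
}

#' Write / read the parameter YAML
#'
#' Sections: \code{ligaments} (per-name \code{K_Q, K_L, e}) and
#' \code{contact} (\code{k, p, delta_c, C, aggregation}).
#'
#' @param ligaments named list of \code{\link{ligament_spec}}s.
#' @param contact a \code{\link{contact_params}}.
#' @param path file path.
#' @return \code{path} / list with \code{ligaments} (named list of
#'   parameter lists) and \code{contact} (a \code{contact_params}).
#' @export
write_params_yaml <- function(ligaments, contact, path) {
  lig <- lapply(ligaments, function(l)
    list(K_Q = l$K_Q, K_L = l$K_L, e = l$e))
  yaml::write_yaml(list(
    ligaments = lig,
    contact = list(k = contact$k, p = contact$p,
                   delta_c = contact$delta_c, C = contact$C,
                   aggregation = contact$aggregation)), path)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  ct <- x$contact %||% list()
  list(ligaments = x$ligaments %||% list(),
       contact = contact_params(k = ct$k %||% 500, p = ct$p %||% 1.5,
                                delta_c = ct$delta_c %||% 0.01,
                                C = ct$C %||% 5,
                                aggregation = ct$aggregation %||% "area"))
}

#' Write a knee model to a fixture directory
#'
#' Emits the mesh files (bone and cartilage, both bodies), the landmark
#' and ligament JSON files, the parameter YAML and (when present) the
#' flexion-cycle CSV, in the layout \code{\link{load_model}} expects.
#'
#' @param model a \code{\link{knee_model}}.
#' @param dir output directory (created if missing).
#' @param mesh_format \code{"obj"}, \code{"stl"} or \code{"ply"}.
#' @return \code{dir}, invisibly.
#' @export
write_knee_fixture <- function(model, dir, mesh_format = "obj") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(nm) file.path(dir, paste0(nm, ".", mesh_format))
  write_mesh(model$femur_bone, fp("femur_bone"))
  write_mesh(model$femur_cartilage, fp("femur_cartilage"))
  write_mesh(model$tibia_bone, fp("tibia_bone"))
  write_mesh(model$tibia_cartilage, fp("tibia_cartilage"))
  write_landmarks_json(model$landmarks, file.path(dir, "landmarks.json"))
  write_ligaments_json(model$ligaments, file.path(dir, "ligaments.json"))
  write_params_yaml(model$ligaments, model$contact,
                    file.path(dir, "params.yaml"))
  if (!is.null(model$profiles)) {
    prof <- do.call(rbind, lapply(seq_along(model$profiles), function(cy)
      data.frame(cycle = cy,
                 sample = seq_along(model$profiles[[cy]]),
                 flexion_deg = model$profiles[[cy]])))
    utils::write.csv(prof, file.path(dir, "cycles.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Run configuration
#'
#' Paths plus solver and validation settings, loadable from a single
#' YAML file with sections \code{model}, \code{solver} and
#' \code{validate}.  Referenced files are checked for existence at load.
#'
#' @param path YAML file path.
#' @return an object of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) p <- file.path(base, p)
    if (!file.exists(p))
      stop("run_config: referenced file does not exist: ", p,
           call. = FALSE)
    p
  }
  mdl <- x$model %||% list()
  slv <- x$solver %||% list()
  val <- x$validate %||% list()
  cfg <- list(
    model = list(
      dir = if (!is.null(mdl$dir)) resolve(mdl$dir) else NULL,
      preset = mdl$preset, seed = mdl$seed %||% 1L,
      mesh_format = mdl$mesh_format %||% "obj"),
    solver = equilibrium_settings(
      tol = slv$tol %||% 1e-3,
      max_iter = slv$max_iter %||% 80,
      step_deg = slv$step_deg %||% 0.5,
      mode = slv$mode %||% "quasi-static"),
    validate = list(ranges = val$ranges %||% list(c(7, 90), c(7, 112))),
    seed = x$seed %||% 1L,
    out_dir = x$out_dir %||% ".",
    log_level = x$log_level %||% "info")
  class(cfg) <- "run_config"
  cfg
}

# short deterministic hash of a configuration (provenance headers)
config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Load a knee model from a fixture directory or configuration
#'
#' Reads the meshes, landmark and ligament JSON and parameter YAML
#' written by \code{\link{write_knee_fixture}} (or hand-assembled in the
#' same layout).  Meshes given in a global scanner frame are transformed
#' into the femoral/tibial body frames constructed from the landmarks,
#' so the body origins coincide with \code{Ofem}/\code{Otib}.
#'
#' @param config a \code{run_config}, or a path to a fixture directory.
#' @param frames_are_body if \code{TRUE} the mesh files are already in
#'   body frames (the fixture writer's convention); if \code{FALSE} they
#'   share the landmark (scanner) frame and are transformed.
#' @return a \code{\link{knee_model}}.
#' @export
load_model <- function(config, frames_are_body = TRUE) {
  if (inherits(config, "run_config")) {
    if (!is.null(config$model$preset))
      return(generate_synthetic_knee(config$model$preset,
                                     config$model$seed))
    dir <- config$model$dir
    fmt <- config$model$mesh_format
  } else {
    dir <- config
    fmt <- c("obj", "stl", "ply")[which(file.exists(file.path(
      dir, paste0("femur_cartilage.", c("obj", "stl", "ply")))))[1L]]
    if (is.na(fmt))
      stop("load_model: no femur_cartilage mesh found in ", dir,
           call. = FALSE)
  }
  need <- function(nm) {
    p <- file.path(dir, nm)
    if (!file.exists(p))
      stop("load_model: missing file: ", p, call. = FALSE)
    p
  }
  landmarks <- read_landmarks_json(need("landmarks.json"))
  params <- if (file.exists(file.path(dir, "params.yaml")))
    read_params_yaml(file.path(dir, "params.yaml"))
  else list(ligaments = list(), contact = contact_params())
  ligaments <- read_ligaments_json(need("ligaments.json"),
                                   params = params$ligaments)

  mesh <- function(nm, frame) {
    m <- read_mesh(need(paste0(nm, ".", fmt)), frame = frame, open = TRUE)
    m
  }
  fb <- mesh("femur_bone", "femur")
  fc <- mesh("femur_cartilage", "femur")
  tb <- mesh("tibia_bone", "tibia")
  tc <- mesh("tibia_cartilage", "tibia")

  if (!frames_are_body) {
    # scanner frame -> body frames defined by the landmarks
    ff <- build_femoral_frame(landmarks)
    tf <- build_tibial_frame(landmarks)
    to_body <- function(m, fr) {
      # x_body = R' (x_scanner - origin)
      R <- frame_matrix(fr)
      V <- sweep(m$vertices, 2L, fr$origin) %*% R
      surface_mesh(V, m$faces, frame = m$frame, open = m$open)
    }
    fb <- to_body(fb, ff); fc <- to_body(fc, ff)
    tb <- to_body(tb, tf); tc <- to_body(tc, tf)
    to_body_pt <- function(p, fr)
      as.numeric(crossprod(frame_matrix(fr), p - fr$origin))
    ligaments <- lapply(ligaments, function(l) {
      l$femoral_mm <- to_body_pt(l$femoral_mm, ff)
      l$tibial_mm <- to_body_pt(l$tibial_mm, tf)
      l
    })
  }

  profiles <- NULL
  cyc <- file.path(dir, "cycles.csv")
  if (file.exists(cyc)) {
    pc <- utils::read.csv(cyc, comment.char = "#")
    profiles <- lapply(split(pc, pc$cycle), function(d)
      d$flexion_deg[order(d$sample)])
    names(profiles) <- NULL
  }

  knee_model(fb, fc, tb, tc, landmarks, ligaments,
             contact = params$contact, side = landmarks$side,
             profiles = profiles,
             meta = list(source = dir))
}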