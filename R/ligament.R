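#' Ligament and capsule registry
#'
#' The fifteen tensile elements of the tibiofemoral model: double-bundle
#' cruciates (aACL/pACL, aPCL/pPCL), double-bundle deep and oblique medial
#' collaterals (dMCLa/dMCLp, oMCLa/oMCLp), the superficial MCL, lateral
#' collateral, anterolateral ligament, oblique and arcuate popliteal
#' ligaments, and the medial and lateral capsule elements.
#'
#' @return character vector of the 15 canonical element names.
#' @export
ligament_names <- function() {
  c("aACL", "pACL", "aPCL", "pPCL",
    "dMCLa", "dMCLp", "oMCLa", "oMCLp",
    "sMCL", "ALL", "LCL", "OPL", "APL", "mCAP", "lCAP")
}

#' Ligament element specification
#'
#' One straight-line tensile element: insertion points fixed in the femoral
#' and tibial body frames plus the constitutive parameters of the
#' quadratic-toe/linear force-elongation law.  The slack length \code{L0}
#' and transition strain \code{epsilon1} are set by
#' \code{\link{initialize_slack_lengths}}.
#'
#' @param name one of \code{\link{ligament_names}}.
#' @param femoral_mm insertion point in the femoral frame (mm).
#' @param tibial_mm insertion point in the tibial frame (mm).
#' @param K_Q toe-region quadratic stiffness (N/mm^2), > 0.
#' @param K_L linear-region stiffness (N/mm), > 0.
#' @param e expansion constant (dimensionless, 0 < e <= 1.2): the slack
#'   length is \code{e} times the element length at full extension.
#' @return an object of class \code{ligament_spec}.
#' @export
ligament_spec <- function(name, femoral_mm, tibial_mm,
                          K_Q = 25, K_L = 60, e = 1) {
  if (!name %in% ligament_names())
    stop("unknown ligament name '", name, "'", call. = FALSE)
  stopifnot(K_Q > 0, K_L > 0, e > 0, e <= 1.2)
  structure(list(name = name, femoral_mm = v3(femoral_mm),
                 tibial_mm = v3(tibial_mm),
                 K_Q = K_Q, K_L = K_L, e = e,
                 L0 = NA_real_, epsilon1 = NA_real_),
            class = "ligament_spec")
}

#' @export
print.ligament_spec <- function(x, ...) {
  cat(sprintf("<ligament_spec> %s: K_Q %.3g N/mm^2, K_L %.3g N/mm, e %.3g",
              x$name, x$K_Q, x$K_L, x$e))
  if (!is.na(x$L0))
    cat(sprintf(", L0 %.3f mm, eps1 %.5f", x$L0, x$epsilon1))
  cat("\n")
  invisible(x)
}

#' Engineering strain of a ligament
#'
#' \code{(L - L0) / L0}; negative values indicate a slack element.
#'
#' @param L instantaneous insertion-to-insertion length (mm).
#' @param L0 slack length (mm), > 0.
#' @return dimensionless strain.
#' @export
strain <- function(L, L0) {
  if (any(L0 <= 0)) stop("strain: L0 must be positive", call. = FALSE)
  (L - L0) / L0
}

#' Slack length from the expansion constant
#'
#' \code{L0 = e * Le}, where \code{Le} is the element length with the knee
#' at full extension.  \code{e < 1} pre-tensions the element at full
#' extension; \code{e > 1} leaves it slack there.
#'
#' @param e expansion constant, > 0.
#' @param Le full-extension length (mm), > 0.
#' @return slack length (mm).
#' @export
slack_length <- function(e, Le) {
  if (any(e <= 0) || any(Le <= 0))
    stop("slack_length: e and Le must be positive", call. = FALSE)
  e * Le
}

#' Toe-to-linear transition strain
#'
#' The strain \code{epsilon1} at which the quadratic toe region hands over
#' to the linear region such that the force law is continuous in value and
#' slope at strain \code{2 * epsilon1}:
#' \code{epsilon1 = K_L / (4 * K_Q * L0)}.
#'
#' @param K_Q quadratic stiffness (N/mm^2).
#' @param K_L linear stiffness (N/mm).
#' @param L0 slack length (mm).
#' @return dimensionless transition strain.
#' @export
transition_strain <- function(K_Q, K_L, L0) {
  stopifnot(K_Q > 0, K_L > 0, L0 > 0)
  K_L / (4 * K_Q * L0)
}

#' Ligament tension from the force-elongation law
#'
#' Zero when slack; quadratic \code{K_Q (L - L0)^2} in the toe region
#' (strain up to \code{2 epsilon1}); linear
#' \code{K_L (L - L0 (1 + epsilon1))} beyond.  With
#' \code{epsilon1 = K_L / (4 K_Q L0)} the two branches join with matching
#' value and slope.  \code{strict_literal = TRUE} switches to the
#' discontinuous variant that hands over already at strain \code{epsilon1}
#' (for comparison only).
#'
#' @param spec an initialised \code{\link{ligament_spec}} (with \code{L0}
#'   and \code{epsilon1} set), or a list with fields \code{K_Q, K_L, L0,
#'   epsilon1}.
#' @param L instantaneous length (mm); vectorised.
#' @param strict_literal use the transition at \code{epsilon1} instead of
#'   \code{2 epsilon1} (discontinuous force at the hand-over).
#' @return tension (N), >= 0, same length as \code{L}.
#' @export
ligament_tension <- function(spec, L, strict_literal = FALSE) {
  if (is.na(spec$L0) || is.na(spec$epsilon1))
    stop("ligament_tension: spec is not initialised (L0/epsilon1 unset); ",
         "run initialize_slack_lengths() first", call. = FALSE)
  eps <- strain(L, spec$L0)
  eps_t <- if (strict_literal) spec$epsilon1 else 2 * spec$epsilon1
  f <- numeric(length(L))
  toe <- eps >= 0 & eps <= eps_t
  lin <- eps > eps_t
  f[toe] <- spec$K_Q * (L[toe] - spec$L0)^2
  f[lin] <- spec$K_L * (L[lin] - spec$L0 * (1 + spec$epsilon1))
  pmax(f, 0)
}

# strain energy of the C1 law (N*mm); integral of ligament_tension over L
ligament_energy <- function(spec, L) {
  eps <- strain(L, spec$L0)
  eps_t <- 2 * spec$epsilon1
  e <- numeric(length(L))
  toe <- eps >= 0 & eps <= eps_t
  lin <- eps > eps_t
  e[toe] <- spec$K_Q * (L[toe] - spec$L0)^3 / 3
  if (any(lin)) {
    Lt <- spec$L0 * (1 + eps_t)
    e_toe_end <- spec$K_Q * (Lt - spec$L0)^3 / 3
    a <- spec$L0 * (1 + spec$epsilon1)
    e[lin] <- e_toe_end +
      spec$K_L / 2 * ((L[lin] - a)^2 - (Lt - a)^2)
  }
  e
}

#' Instantaneous state of a ligament element
#'
#' Length, strain, tension and line of action for a given femur/tibia pose.
#'
#' @param spec an initialised \code{\link{ligament_spec}}.
#' @param femur,tibia \code{\link{rigid_state}}s in the ground frame.
#' @return an object of class \code{ligament_state}: list with \code{L}
#'   (mm), \code{epsilon}, \code{tension} (N), \code{direction} (unit
#'   vector, tibial toward femoral insertion, ground frame), and the two
#'   insertion points in ground coordinates.
#' @export
ligament_state <- function(spec, femur, tibia) {
  fF <- as_rigid_state(femur)$frame
  fT <- as_rigid_state(tibia)$frame
  pf <- fF$origin + as.numeric(frame_matrix(fF) %*% spec$femoral_mm)
  pt <- fT$origin + as.numeric(frame_matrix(fT) %*% spec$tibial_mm)
  d <- pf - pt
  L <- vnorm(d)
  structure(list(name = spec$name, L = L,
                 epsilon = strain(L, spec$L0),
                 tension = ligament_tension(spec, L),
                 direction = d / L,
                 femoral_pt = pf, tibial_pt = pt),
            class = "ligament_state")
}

#' @export
print.ligament_state <- function(x, ...) {
  cat(sprintf("<ligament_state> %s: L %.3f mm, strain %.4f, tension %.3f N\n",
              x$name, x$L, x$epsilon, x$tension))
  invisible(x)
}
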