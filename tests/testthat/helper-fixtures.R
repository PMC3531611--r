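# shared fixtures, built in code

SEQ_E <- "DWSFYLLYYTEFT"

# cache the default class builds: they are deterministic and several test
# files measure them
zipper_cache <- new.env(parent = emptyenv())
default_zipper <- function(class_id) {
  key <- as.character(class_id)
  if (is.null(zipper_cache[[key]]))
    zipper_cache[[key]] <- build_class_zipper(SEQ_E, class_id)
  zipper_cache[[key]]
}

# noiseless logistic curve on a dense grid
logistic_curve <- function(tau = 10, k = 1, t_max = 30, dt = 0.25, A = 1) {
  t <- seq(0, t_max, by = dt)
  kinetic_curve(t, A * plogis(k * (t - tau)), "sim")
}

# apply a rigid motion to a fibril model, keeping its provenance attributes
rigid_move <- function(model, angles = c(0.3, -0.8, 1.2), tr = c(5, -3, 7)) {
  Rx <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
  Rz <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  Rm <- Rz(angles[3]) %*% Ry(angles[2]) %*% Rx(angles[1])
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(Rm)
  model$x <- xyz[, 1] + tr[1]
  model$y <- xyz[, 2] + tr[2]
  model$z <- xyz[, 3] + tr[3]
  attr(model, "rigid_R") <- Rm
  attr(model, "rigid_t") <- tr
  model
}

# strand E variants indexed once for the whole suite
VARIANTS <- strand_e_variants()
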