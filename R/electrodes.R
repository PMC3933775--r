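# Schematic 2-D layout of the 19-channel 10-20 montage, in head radii
# (x: left -> right, y: back -> front). Used for distance-based spatial
# noise correlation and for the built-in topography patterns.

electrode_positions_1020 <- function() {
  pos <- rbind(
    Fp1 = c(-0.31,  0.95), Fp2 = c( 0.31,  0.95),
    F7  = c(-0.81,  0.59), F3  = c(-0.42,  0.52), Fz = c(0,  0.50),
    F4  = c( 0.42,  0.52), F8  = c( 0.81,  0.59),
    T3  = c(-1.00,  0.00), C3  = c(-0.50,  0.00), Cz = c(0,  0.00),
    C4  = c( 0.50,  0.00), T4  = c( 1.00,  0.00),
    T5  = c(-0.81, -0.59), P3  = c(-0.42, -0.52), Pz = c(0, -0.50),
    P4  = c( 0.42, -0.52), T6  = c( 0.81, -0.59),
    O1  = c(-0.31, -0.95), O2  = c( 0.31, -0.95)
  )
  colnames(pos) <- c("x", "y")
  pos
}

#' Standard 10-20 channel names used by the simulator
#' @return Character vector of the 19 electrode labels.
#' @export
channels_1020 <- function() rownames(electrode_positions_1020())

# Channel correlation exp(-d / lambda) over the schematic electrode layout.
exp_distance_correlation <- function(channels = channels_1020(), lambda = 0.4) {
  pos <- electrode_positions_1020()
  if (!all(channels %in% rownames(pos))) {
    stop("exp-distance correlation is defined for 10-20 channel names",
         call. = FALSE)
  }
  pos <- pos[channels, , drop = FALSE]
  d <- as.matrix(dist(pos))
  exp(-d / lambda)
}

# Unit-peak Gaussian bump over the scalp centred on one electrode.
scalp_bump <- function(center, width = 0.45, channels = channels_1020()) {
  pos <- electrode_positions_1020()[channels, , drop = FALSE]
  d2 <- (pos[, "x"] - pos[center, "x"])^2 + (pos[, "y"] - pos[center, "y"])^2
  exp(-d2 / (2 * width^2))
}
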