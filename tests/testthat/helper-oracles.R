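# Independent brute-force oracle for surface distances: plain R double
# loop over boundary voxels extracted by erosion with array shifts.
boundary_points_oracle <- function(m) {
  v <- m$voxels > 0.5
  d <- dim(v)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  idx <- which(v & !core, arr.ind = TRUE) - 1L
  voxel_to_world(m, idx)
}

mbd_oracle <- function(a, b) {
  sa <- boundary_points_oracle(a)
  sb <- boundary_points_oracle(b)
  dir_mean <- function(p, q) {
    mean(vapply(seq_len(nrow(p)), function(i) {
      sqrt(min(colSums((t(q) - p[i, ])^2)))
    }, 0))
  }
  (dir_mean(sa, sb) + dir_mean(sb, sa)) / 2
}

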