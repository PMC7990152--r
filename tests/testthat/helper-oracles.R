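# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately share no code with the package internals.

# O(n^2) squared Euclidean distance to the nearest feature voxel
brute_edt_sq <- function(feature, spacing = c(1, 1, 1)) {
  d <- dim(feature)
  idx <- which(feature, arr.ind = TRUE)
  out <- array(Inf, d)
  if (nrow(idx) == 0) return(out)
  all_idx <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  for (r in seq_len(nrow(all_idx))) {
    p <- all_idx[r, ]
    dx <- (idx[, 1] - p[1]) * spacing[1]
    dy <- (idx[, 2] - p[2]) * spacing[2]
    dz <- (idx[, 3] - p[3]) * spacing[3]
    out[p[1], p[2], p[3]] <- min(dx^2 + dy^2 + dz^2)
  }
  out
}

# recursive-free flood-fill connected component labeling
brute_label <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  man <- rowSums(abs(offs))
  offs <- offs[man > 0 & man <= switch(as.character(connectivity),
                                       "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  labels <- array(0L, d)
  nxt <- 0L
  for (s in which(mask)) {
    if (labels[s] != 0L) next
    nxt <- nxt + 1L
    stack <- s
    labels[s] <- nxt
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      z <- (cur - 1) %/% (d[1] * d[2])
      rem <- (cur - 1) %% (d[1] * d[2])
      y <- rem %/% d[1]
      x <- rem %% d[1]
      for (o in seq_len(nrow(offs))) {
        nx <- x + offs[o, 1]; ny <- y + offs[o, 2]; nz <- z + offs[o, 3]
        if (nx < 0 || ny < 0 || nz < 0 ||
            nx >= d[1] || ny >= d[2] || nz >= d[3]) next
        ni <- nz * d[1] * d[2] + ny * d[1] + nx + 1
        if (mask[ni] && labels[ni] == 0L) {
          labels[ni] <- nxt
          stack <- c(stack, ni)
        }
      }
    }
  }
  labels
}

# digital ball intensity phantom on an n^3 grid
make_ball <- function(n, radius, inside = 450, outside = 0,
                      spacing = 0.16, center = (n + 1) / 2) {
  co <- expand.grid(1:n, 1:n, 1:n)
  r2 <- (co[, 1] - center)^2 + (co[, 2] - center)^2 + (co[, 3] - center)^2
  arr <- array(ifelse(r2 <= radius^2, inside, outside), c(n, n, n))
  v <- volume_image(arr, spacing)
  v$unit_state <- "normalized"
  v
}

ball_mask <- function(n, radius, spacing = 1, center = (n + 1) / 2) {
  co <- expand.grid(1:n, 1:n, 1:n)
  r2 <- (co[, 1] - center)^2 + (co[, 2] - center)^2 + (co[, 3] - center)^2
  binary_mask(array(r2 <= radius^2, c(n, n, n)), spacing)
}

# exposed boundary faces of a voxel mask (discrete surface area in faces)
face_count <- function(m) {
  d <- dim(m)
  sum(m[-d[1], , ] != m[-1, , ]) + sum(m[, -d[2], ] != m[, -1, ]) +
    sum(m[, , -d[3]] != m[, , -1]) +
    sum(m[c(1, d[1]), , ]) + sum(m[, c(1, d[2]), ]) + sum(m[, , c(1, d[3])])
}

# smooth random blob volume for registration tests: sum of Gaussians
make_blob_volume <- function(n = 40, k = 6, seed = 7, spacing = 0.25) {
  set.seed(seed)
  co <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  vals <- rep(0, nrow(co))
  for (i in 1:k) {
    cen <- runif(3, n * 0.3, n * 0.7)
    s <- runif(1, 2, 4)
    a <- runif(1, 300, 1000)
    dd <- (co[, 1] - cen[1])^2 + (co[, 2] - cen[2])^2 + (co[, 3] - cen[3])^2
    vals <- vals + a * exp(-dd / (2 * s^2))
  }
  volume_image(array(vals, c(n, n, n)), spacing)
}

# a small, fast phantom configuration for module-level tests (geometry
# only; its normalized intensities are not calibrated to the 300-600
# window)
small_spec <- function(...) {
  args <- list(field_of_view = c(10, 10, 10), spacing = 0.25,
               slab_thickness = 3, cortical_thickness = 0.75,
               graft_size = c(2, 5, 5), screw_radius = 0.5,
               screw_embed = 2, screw_protrusion = 0.25,
               blur_sigma = 0, noise_sigma = 0,
               misalignment = rigid_transform())
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

table2_volumes <- function() build_records(load_graft_volumes())
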