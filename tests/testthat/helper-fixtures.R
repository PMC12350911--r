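# Shared fixtures: a reduced-grid geometry (same tile layout and constants as
# the full device, quarter-resolution tiles) keeps simulations fast.

test_geometry <- function() buildGeometry(tilesAcross = 2L, tilesAlong = 6L,
                                          sensorsPerTileSide = 60L)

test_gait <- function(task = "W1")
  gaitParams(speed = 1.12, stepLengthCm = 50, stepWidthCm = 12, task = task)

test_feet <- function(archDepth = 0.7)
  footParams(soleLengthCm = 25, soleWidthCm = 9, archDepth = archDepth)

# Independent oracle: iterative flood-fill connected-components labeling.
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 8)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j]) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nbr))) {
        qi <- p[1] + nbr[k, 1]; qj <- p[2] + nbr[k, 2]
        if (qi < 1 || qi > nr || qj < 1 || qj > nc) next
        if (mask[qi, qj] && !lab[qi, qj]) {
          lab[qi, qj] <- cur
          stack[[length(stack) + 1L]] <- c(qi, qj)
        }
      }
    }
  }
  lab
}

# Independent oracle: binary dilation/erosion by explicit offset enumeration
# (iterating only over foreground pixels; out-of-border counts as background).
naive_morph <- function(mask, kern, op = c("dilate", "erode")) {
  op <- match.arg(op)
  r <- (nrow(kern) - 1) / 2
  offs <- which(kern > 0, arr.ind = TRUE) - (r + 1)
  nr <- nrow(mask); nc <- ncol(mask)
  if (op == "dilate") {
    out <- matrix(FALSE, nr, nc)
    for (p in which(mask)) {
      i <- (p - 1) %% nr + 1; j <- (p - 1) %/% nr + 1
      ii <- i + offs[, 1]; jj <- j + offs[, 2]
      ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
      out[cbind(ii[ok], jj[ok])] <- TRUE
    }
  } else {
    out <- matrix(FALSE, nr, nc)
    for (p in which(mask)) {
      i <- (p - 1) %% nr + 1; j <- (p - 1) %/% nr + 1
      ii <- i + offs[, 1]; jj <- j + offs[, 2]
      ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
      out[i, j] <- all(ok) && all(mask[cbind(ii, jj)])
    }
  }
  out
}

# random sparse test frame: a few rectangles and specks of quantized pressure
random_frame <- function(nr, nc, maxBlobs = 4) {
  fr <- matrix(0, nr, nc)
  for (b in seq_len(sample(0:maxBlobs, 1))) {
    h <- sample(1:12, 1); w <- sample(1:12, 1)
    i <- sample(seq_len(nr - h + 1), 1); j <- sample(seq_len(nc - w + 1), 1)
    fr[i:(i + h - 1), j:(j + w - 1)] <- sample(seq(0, 200, by = 10), h * w,
                                               replace = TRUE)
  }
  fr
}

# Independent oracle for detectFrameObjects on small frames: threshold,
# naive morphology, flood-fill labeling, min-size filter, transitive
# centroid merging by breadth-first search over the "within distance" graph.
naive_detect <- function(frame, geometry, params = detectionParams()) {
  mask <- frame >= geometry@activationKpa
  if (!any(mask)) return(list())
  if (params$dilateRadius > 0)
    mask <- naive_morph(mask, discKernel(params$dilateRadius), "dilate")
  if (params$erodeRadius > 0)
    mask <- naive_morph(mask, discKernel(params$erodeRadius), "erode")
  lab <- flood_fill_label(mask, params$connectivity)
  if (max(lab) == 0) return(list())
  comps <- lapply(seq_len(max(lab)), function(k) which(lab == k, arr.ind = TRUE))
  comps <- comps[vapply(comps, nrow, integer(1)) >= params$minPixels]
  if (!length(comps)) return(list())
  cent <- t(vapply(comps, colMeans, numeric(2)))
  n <- length(comps)
  adj <- as.matrix(stats::dist(cent)) <= params$mergeDistancePx
  grp <- rep(0L, n); g <- 0L
  for (i in seq_len(n)) {
    if (grp[i]) next
    g <- g + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (grp[v]) next
      grp[v] <- g
      queue <- c(queue, which(adj[v, ] & grp == 0L))
    }
  }
  lapply(seq_len(g), function(k) {
    px <- do.call(rbind, comps[grp == k])
    list(ymin = min(px[, 1]) - 1L, ymax = max(px[, 1]) - 1L,
         xmin = min(px[, 2]) - 1L, xmax = max(px[, 2]) - 1L,
         npx = nrow(px))
  })
}

# 3D IoU of two boxes given as named vectors/lists with StartFrame..Xmax.
iou3d <- function(a, b) {
  it <- min(a$EndFrame, b$EndFrame) - max(a$StartFrame, b$StartFrame) + 1
  iy <- min(a$Ymax, b$Ymax) - max(a$Ymin, b$Ymin) + 1
  ix <- min(a$Xmax, b$Xmax) - max(a$Xmin, b$Xmin) + 1
  if (it <= 0 || iy <= 0 || ix <= 0) return(0)
  vol <- function(z) (z$EndFrame - z$StartFrame + 1) *
    (z$Ymax - z$Ymin + 1) * (z$Xmax - z$Xmin + 1)
  inter <- it * iy * ix
  inter / (vol(a) + vol(b) - inter)
}

box_df <- function(steps)
  do.call(rbind, lapply(steps, function(s) as.data.frame(t(s@box))))
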