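# Pixel segmentation and particle extraction.
#
# Connectivity convention: 8-connected in-plane; volumetric mode extends
# this to 26-connectivity across slices. EBImage's labeller is
# 4-connected, so labelling is done here with vectorised neighbour
# matching and igraph components.

#' Maximum z-projection of one channel
#'
#' Per-pixel maximum over all optical slices.
#'
#' @param stack A [section_stack()]. @param channel Channel name.
#' @return A 2-D numeric matrix (y, x).
#' @export
max_project <- function(stack, channel) {
  arr <- stack_channel(stack, channel)
  nz <- dim(arr)[3]
  Reduce(pmax, lapply(seq_len(nz), function(k) arr[, , k]))
}

#' Label connected components (8-connectivity in-plane)
#'
#' @param mask Logical matrix (2-D) or logical array (3-D, y-x-z); 3-D
#'   masks are labelled with 26-connectivity.
#' @return Integer matrix/array of the same shape; 0 = background, labels
#'   are assigned in first-pixel (column-major) order.
#' @export
label_components <- function(mask) {
  dm <- dim(mask)
  labels <- array(0L, dm)
  idx <- which(mask)
  if (!length(idx)) return(labels)
  if (length(dm) == 2L) {
    nr <- dm[1]; nc <- dm[2]
    row <- ((idx - 1L) %% nr) + 1L
    col <- ((idx - 1L) %/% nr) + 1L
    offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
    edges <- integer(0)
    for (o in offs) {
      ok <- (row + o[1] >= 1L) & (row + o[1] <= nr) & (col + o[2] <= nc)
      nb <- idx + o[1] + o[2] * nr
      ok[ok] <- mask[nb[ok]]
      j <- match(nb[ok], idx)
      i <- seq_along(idx)[ok]
      edges <- c(edges, as.vector(rbind(i, j)))
    }
  } else if (length(dm) == 3L) {
    nr <- dm[1]; nc <- dm[2]; nz <- dm[3]
    rem <- (idx - 1L) %% (nr * nc)
    row <- (rem %% nr) + 1L
    col <- (rem %/% nr) + 1L
    sli <- ((idx - 1L) %/% (nr * nc)) + 1L
    offs <- expand.grid(dy = -1:1, dx = -1:1, dz = 0:1)
    offs <- offs[order(offs$dz, offs$dx, offs$dy), ]
    offs <- offs[(offs$dz > 0) | (offs$dx > 0) | (offs$dz == 0 & offs$dx == 0 & offs$dy > 0), ]
    edges <- integer(0)
    for (r in seq_len(nrow(offs))) {
      dy <- offs$dy[r]; dx <- offs$dx[r]; dz <- offs$dz[r]
      ok <- (row + dy >= 1L) & (row + dy <= nr) &
            (col + dx >= 1L) & (col + dx <= nc) &
            (sli + dz >= 1L) & (sli + dz <= nz)
      nb <- idx + dy + dx * nr + dz * nr * nc
      ok[ok] <- mask[nb[ok]]
      j <- match(nb[ok], idx)
      i <- seq_along(idx)[ok]
      edges <- c(edges, as.vector(rbind(i, j)))
    }
  } else stop("mask must be 2-D or 3-D")
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  labels[idx] <- match(memb, unique(memb))   # first-encounter order
  labels
}

#' Segment a channel image into a foreground mask
#'
#' Three methods stand in for a trained pixel classifier: a fixed
#' intensity threshold, Otsu's method (the deterministic default used by
#' the pipeline), and a trainable mode that fits a per-pixel random-forest
#' on intensity/texture features from a handful of foreground and
#' background scribbles (the manual training protocol: 5-10 marks per
#' class is typical).
#'
#' @param image 2-D numeric matrix (typically a max projection).
#' @param method A list: `list(type = "otsu")`,
#'   `list(type = "fixed", threshold = t)` (foreground is strictly above
#'   `t`), or `list(type = "trainable", positives = m, negatives = m)`
#'   where `positives`/`negatives` are n x 2 matrices of (row, col)
#'   scribble coordinates (1-based).
#' @return Logical matrix of the same shape.
#' @export
segment_pixels <- function(image, method = list(type = "otsu")) {
  stopifnot(is.matrix(image))
  type <- method$type %||% "otsu"
  if (type == "fixed") {
    if (is.null(method$threshold)) stop("fixed method needs a threshold")
    return(image > method$threshold)
  }
  if (type == "otsu") {
    return(image > otsu_threshold(image))
  }
  if (type == "trainable") {
    pos <- method$positives; neg <- method$negatives
    if (is.null(pos) || is.null(neg) || nrow(pos) < 1 || nrow(neg) < 1)
      stop("trainable mode needs at least one scribble per class")
    if (!requireNamespace("randomForest", quietly = TRUE))
      stop("trainable mode requires the randomForest package")
    feats <- pixel_features(image)
    tr_idx <- c(pos[, 1] + (pos[, 2] - 1) * nrow(image),
                neg[, 1] + (neg[, 2] - 1) * nrow(image))
    y <- factor(rep(c("fg", "bg"), c(nrow(pos), nrow(neg))))
    X <- feats[tr_idx, , drop = FALSE]
    fit <- randomForest::randomForest(X, y, ntree = 100)
    pr <- stats::predict(fit, feats, type = "prob")[, "fg"]
    return(matrix(pr > 0.5, nrow(image), ncol(image)))
  }
  stop("unknown segmentation method: ", type)
}

otsu_threshold <- function(image) {
  rng <- range(image)
  if (diff(rng) == 0) return(rng[1])   # constant image: nothing above threshold
  EBImage::otsu((image - rng[1]) / diff(rng), range = c(0, 1), levels = 2048) *
    diff(rng) + rng[1]
}

pixel_features <- function(image) {
  s1 <- EBImage::gblur(image, sigma = 1)
  s2 <- EBImage::gblur(image, sigma = 3)
  m2 <- EBImage::gblur(image^2, sigma = 2)
  m1 <- EBImage::gblur(image, sigma = 2)
  sdl <- sqrt(pmax(m2 - m1^2, 0))
  cbind(raw = as.vector(image), g1 = as.vector(s1), g3 = as.vector(s2),
        sd2 = as.vector(sdl))
}

#' Extract size-filtered particles from a foreground mask
#'
#' Connected components (8-connected in-plane; 26-connected for 3-D masks)
#' are kept only when their pixel count strictly exceeds `min_size_px`
#' (default 2, i.e. components of >= 3 pixels survive -- "greater than 2
#' pixels"). Centroids are in micrometres with the origin at the image
#' corner.
#'
#' @param mask Logical matrix (projected mode) or 3-D array (volumetric
#'   mode, y-x-z).
#' @param pixel_um Pixel edge length (um).
#' @param config A [pipeline_config()] (supplies `min_size_px`).
#' @param channel Channel name recorded on each particle.
#' @return A tibble with one row per retained particle: `id`, `channel`,
#'   `n_px` (pixel/voxel count), `area_px` and `area_um2` (footprint
#'   size; for 3-D particles the footprint is the full-projection pixel
#'   set), centroid `x_um`/`y_um`, `layer` (unset), and a `pixels`
#'   list-column of (y, x\[, z\]) 1-based indices.
#' @export
extract_particles <- function(mask, pixel_um, config = pipeline_config(),
                              channel = "NP") {
  labels <- label_components(mask)
  idx <- which(labels > 0L)
  empty <- tibble::tibble(id = integer(), channel = character(),
                          n_px = integer(), area_px = integer(),
                          area_um2 = numeric(), x_um = numeric(),
                          y_um = numeric(), layer = character(),
                          pixels = list())
  if (!length(idx)) return(empty)
  dm <- dim(mask)
  lab <- labels[idx]
  if (length(dm) == 2L) {
    coords <- cbind(y = ((idx - 1L) %% dm[1]) + 1L,
                    x = ((idx - 1L) %/% dm[1]) + 1L)
  } else {
    rem <- (idx - 1L) %% (dm[1] * dm[2])
    coords <- cbind(y = (rem %% dm[1]) + 1L,
                    x = (rem %/% dm[1]) + 1L,
                    z = ((idx - 1L) %/% (dm[1] * dm[2])) + 1L)
  }
  parts <- unname(lapply(split(seq_along(lab), lab), function(ii)
    coords[ii, , drop = FALSE]))
  n_px <- vapply(parts, nrow, 0L)
  keep <- n_px > config$min_size_px
  if (!any(keep)) return(empty)
  parts <- parts[keep]; n_px <- n_px[keep]
  foot <- vapply(parts, function(p) {
    if (ncol(p) == 2L) nrow(p)
    else nrow(unique(p[, c("y", "x"), drop = FALSE]))
  }, 0L)
  cx <- vapply(parts, function(p) (mean(p[, "x"]) - 0.5) * pixel_um, 0)
  cy <- vapply(parts, function(p) (mean(p[, "y"]) - 0.5) * pixel_um, 0)
  tibble::tibble(
    id = seq_along(parts), channel = channel,
    n_px = as.integer(n_px), area_px = as.integer(foot),
    area_um2 = foot * pixel_um^2,
    x_um = cx, y_um = cy,
    layer = NA_character_, pixels = unname(parts))
}
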