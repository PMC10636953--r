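# Compact two-scale convolutional encoder-decoder for heatmap regression,
# implemented directly on BLAS-backed matrix ops. Feature maps are stored as
# (npx x channels) matrices with pixel index r + (c - 1) * nrow; 3x3
# convolutions are nine shifted gathers followed by GEMMs, so forward and
# backward passes stay vectorized.
#
# Topology (F = n_filters):
#   slab(3) + coord(2) -> conv3x3(5 -> F) ReLU            @ full resolution
#   pool 2x -> conv3x3(F -> 2F) ReLU -> conv3x3(2F -> 2F) ReLU   @ half
#   1x1(2F -> F), nearest-upsample, + 1x1(F -> F) skip
#                + 1x1(coord 2 -> F), ReLU                       @ full
#   1x1(F + coord 2 -> 2) linear -> two heatmaps
# The full-resolution stage stays 1x1 beyond the first convolution so the
# dominant memory traffic (im2col + scatter at full resolution) happens once
# per pass; peak sharpness comes from the first-stage features, context from
# the pooled branch. Coordinate channels are injected at the input, at the
# fusion (where the ReLU lets them gate responses by position) and at the
# output, so the two otherwise identical wire points can be told apart as
# medial vs lateral.
#
# The two coordinate channels let the translation-equivariant network separate
# the medial from the lateral channel by in-plane position.

.geom_cache <- new.env(parent = emptyenv())

net_geometry <- function(nr, nc) {
  key <- paste(nr, nc, sep = "x")
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  npx <- nr * nc
  rows <- rep(seq_len(nr), nc)
  cols <- rep(seq_len(nc), each = nr)
  shift_idx <- function(dr, dc) {
    r <- rows + dr; c <- cols + dc
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    as.integer(ifelse(ok, r + (c - 1) * nr, 0L)) # 0 = out of bounds
  }
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  idx3 <- vapply(seq_len(9), function(k) shift_idx(offs$dr[k], offs$dc[k]),
                 integer(npx))
  nrp <- as.integer(ceiling(nr / 2)); ncp <- as.integer(ceiling(nc / 2))
  pg <- as.integer(ceiling(rows / 2) + (ceiling(cols / 2) - 1) * nrp)
  pn <- tabulate(pg, nbins = nrp * ncp)
  rows_p <- rep(seq_len(nrp), ncp); cols_p <- rep(seq_len(ncp), each = nrp)
  shift_idx_p <- function(dr, dc) {
    r <- rows_p + dr; c <- cols_p + dc
    ok <- r >= 1 & r <= nrp & c >= 1 & c <= ncp
    as.integer(ifelse(ok, r + (c - 1) * nrp, 0L))
  }
  idx3p <- vapply(seq_len(9), function(k) shift_idx_p(offs$dr[k], offs$dc[k]),
                  integer(nrp * ncp))
  coord <- cbind(
    if (nc > 1) (cols - 1) / (nc - 1) * 2 - 1 else rep(0, npx),
    if (nr > 1) (rows - 1) / (nr - 1) * 2 - 1 else rep(0, npx)
  )
  g <- list(nr = nr, nc = nc, npx = npx, idx3 = idx3,
            nrp = nrp, ncp = ncp, npxp = nrp * ncp, idx3p = idx3p,
            pool_g = pg, pool_n = pn, coord = coord)
  .geom_cache[[key]] <- g
  g
}

# batched geometry: B slices stacked along the pixel axis, out-of-bounds
# pixels of every block mapped to the shared zero row (B * npx + 1)
net_geometry_batch <- function(nr, nc, B) {
  if (B == 1L) return(net_geometry(nr, nc))
  key <- paste(nr, nc, B, sep = "x")
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  g1 <- net_geometry(nr, nc)
  tile_idx <- function(idx, npx, n_blocks) {
    oob <- idx == 0L
    out <- do.call(rbind, lapply(seq_len(n_blocks) - 1L, function(b) {
      o <- idx + b * npx
      o[oob] <- 0L
      o
    }))
    out
  }
  g <- list(
    nr = g1$nr, nc = g1$nc, npx = B * g1$npx,
    idx3 = tile_idx(g1$idx3, g1$npx, B),
    nrp = g1$nrp, ncp = g1$ncp, npxp = B * g1$npxp,
    idx3p = tile_idx(g1$idx3p, g1$npxp, B),
    pool_g = as.integer(rep(g1$pool_g, B) +
                          rep((seq_len(B) - 1L) * g1$npxp, each = g1$npx)),
    pool_n = rep(g1$pool_n, B),
    coord = g1$coord[rep(seq_len(g1$npx), B), , drop = FALSE]
  )
  .geom_cache[[key]] <- g
  g
}

# 3x3 convolution in im2col form: weights are a (9 * Cin) x Cout matrix, the
# gathered neighbourhood matrix feeds one wide GEMM (bandwidth-friendlier
# than nine skinny ones)
im2col <- function(X, idx) .cpp_im2col(X, idx)

conv3_fwd <- function(Xcol, layer) {
  Y <- Xcol %*% layer$W
  Y + rep(layer$b, each = nrow(Y))
}

# dX accumulation (col2im) is skipped when the input gradient is unused
conv3_bwd <- function(dY, Xcol, layer, idx, need_dx = TRUE) {
  out <- list(dW = crossprod(Xcol, dY), db = colSums(dY))
  if (need_dx) {
    cin <- ncol(Xcol) %/% 9L
    out$dX <- .cpp_col2im(dY %*% t(layer$W), idx, cin)
  }
  out
}

relu <- function(x) { x[x < 0] <- 0; x }

#' @keywords internal
net_init <- function(n_filters = 8L, n_in = 5L, seed = 0L) {
  F1 <- as.integer(n_filters)
  mk3 <- function(cin, cout) list(
    W = matrix(stats::rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
               9 * cin, cout),
    b = numeric(cout)
  )
  mk1 <- function(cin, cout, sd = sqrt(2 / cin)) list(
    W = matrix(stats::rnorm(cin * cout, 0, sd), cin, cout),
    b = numeric(cout)
  )
  # the head and the coordinate injections start at zero so the initial
  # prediction is the zero heatmap (the natural baseline for sparse targets)
  with_seed(seed, list(
    conv1 = mk3(n_in, F1),
    conv2 = mk3(F1, 2L * F1),
    conv3 = mk3(2L * F1, 2L * F1),
    proj_lo = mk1(2L * F1, F1),
    proj_hi = mk1(F1, F1),
    proj_xy = mk1(2L, F1, sd = 0),
    out = mk1(F1 + 2L, 2L, sd = 0)
  ))
}

# forward pass over one slab [nr, nc, 3], a batch [nr, nc, 3, B], or a
# pre-flattened (B*npx) x 3 matrix with attribute "geom" = c(nr, nc, B);
# train = TRUE keeps activations for the backward pass
net_forward <- function(params, slab, train = FALSE) {
  if (is.matrix(slab)) {
    gm <- attr(slab, "geom")
    d <- c(gm[1], gm[2], 3L); B <- gm[3]
    X <- slab
  } else {
    d <- dim(slab)
    B <- if (length(d) == 4L) d[4] else 1L
    X <- if (B == 1L) matrix(slab, d[1] * d[2], d[3]) else
      matrix(aperm(slab, c(1, 2, 4, 3)), d[1] * d[2] * B, d[3])
  }
  g <- net_geometry_batch(d[1], d[2], B)
  X <- cbind(X, g$coord)
  X1col <- im2col(X, g$idx3)
  a1 <- relu(conv3_fwd(X1col, params$conv1))
  xp <- rowsum(a1, g$pool_g) / g$pool_n
  x2col <- im2col(xp, g$idx3p)
  a2 <- relu(conv3_fwd(x2col, params$conv2))
  a3col <- im2col(a2, g$idx3p)
  a3 <- relu(conv3_fwd(a3col, params$conv3))
  lo <- a3 %*% params$proj_lo$W
  lo <- lo + rep(params$proj_lo$b, each = nrow(lo))
  hi <- a1 %*% params$proj_hi$W
  hi <- hi + rep(params$proj_hi$b, each = nrow(hi))
  xy <- g$coord %*% params$proj_xy$W
  xy <- xy + rep(params$proj_xy$b, each = nrow(xy))
  fuse <- relu(lo[g$pool_g, , drop = FALSE] + hi + xy)
  fuse_c <- cbind(fuse, g$coord)
  Y <- fuse_c %*% params$out$W
  Y <- Y + rep(params$out$b, each = nrow(Y))
  out <- if (B == 1L) array(Y, dim = c(d[1], d[2], 2L)) else
    aperm(array(Y, dim = c(d[1], d[2], B, 2L)), c(1, 2, 4, 3))
  res <- list(out = out, Y = Y)
  if (train) res <- c(res, list(X1col = X1col, a1 = a1, x2col = x2col,
                                a2 = a2, a3col = a3col, a3 = a3,
                                lo = lo, hi = hi, fuse = fuse,
                                fuse_c = fuse_c, g = g))
  res
}

net_backward <- function(params, act, dY) {
  g <- act$g
  grads <- list()
  grads$out <- list(W = crossprod(act$fuse_c, dY), b = colSums(dY))
  nf <- ncol(act$fuse)
  dfuse <- (dY %*% t(params$out$W))[, seq_len(nf), drop = FALSE]
  dfuse[act$fuse <= 0] <- 0
  # coordinate injection at the fusion
  grads$proj_xy <- list(W = crossprod(g$coord, dfuse), b = colSums(dfuse))
  # skip branch
  grads$proj_hi <- list(W = crossprod(act$a1, dfuse), b = colSums(dfuse))
  da1 <- dfuse %*% t(params$proj_hi$W)
  # low-res branch: upsample backward = sum over the pool groups
  dlo <- rowsum(dfuse, g$pool_g)
  grads$proj_lo <- list(W = crossprod(act$a3, dlo), b = colSums(dlo))
  da3 <- dlo %*% t(params$proj_lo$W)
  da3[act$a3 <= 0] <- 0
  b3 <- conv3_bwd(da3, act$a3col, params$conv3, g$idx3p)
  grads$conv3 <- list(W = b3$dW, b = b3$db)
  da2 <- b3$dX
  da2[act$a2 <= 0] <- 0
  b2 <- conv3_bwd(da2, act$x2col, params$conv2, g$idx3p)
  grads$conv2 <- list(W = b2$dW, b = b2$db)
  dxp <- b2$dX
  # pool backward: each full-res pixel receives its group's gradient / count
  da1 <- da1 + (dxp / g$pool_n)[g$pool_g, , drop = FALSE]
  da1[act$a1 <= 0] <- 0
  # input gradient is never used: dW/db only
  b1 <- conv3_bwd(da1, act$X1col, params$conv1, g$idx3, need_dx = FALSE)
  grads$conv1 <- list(W = b1$dW, b = b1$db)
  grads[names(params)] # map_params pairs by position: keep parameter order
}

# recursive elementwise combination over parameter structures
map_params <- function(f, ...) {
  args <- list(...)
  if (is.numeric(args[[1]])) return(do.call(f, args))
  out <- lapply(seq_along(args[[1]]), function(i)
    do.call(map_params, c(list(f), lapply(args, `[[`, i))))
  names(out) <- names(args[[1]])
  out
}

adam_init <- function(params) list(
  m = map_params(function(p) p * 0, params),
  v = map_params(function(p) p * 0, params),
  t = 0L
)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_params(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- map_params(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  params <- map_params(
    function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
    params, state$m, state$v
  )
  list(params = params, state = state)
}

#' Detector training configuration
#'
#' The optimizer is Adam minimizing mean squared error on the heatmaps, with
#' the parameter state achieving minimum validation loss retained. Defaults
#' are desk-scale (50 epochs); `learning_rate` defaults to the reference
#' protocol's 1e-4.
#'
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs (>= 1).
#' @param batch_size maximum slices per gradient step; slices of one case are
#'   stacked into a single batched pass (they share geometry).
#' @param n_filters base channel width of the network.
#' @param slice_policy `"all"` trains on every slice (zero targets on
#'   marker-free slices); `"marker"` trains only on annotated slices.
#' @param heatmap a [heatmap_spec()].
#' @param preprocess a [preprocess_config()].
#' @param seed RNG seed for weight init and slice shuffling.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 50L, batch_size = 16L,
                         n_filters = 8L, slice_policy = c("all", "marker"),
                         heatmap = heatmap_spec(), preprocess = preprocess_config(),
                         seed = 0L) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  list(learning_rate = learning_rate, epochs = as.integer(epochs),
       batch_size = as.integer(batch_size), n_filters = as.integer(n_filters),
       slice_policy = match.arg(slice_policy), heatmap = heatmap,
       preprocess = preprocess, seed = as.integer(seed))
}

# turn cases into gradient-step batches: chunks of up to batch_size slices of
# one case (slices of a case share geometry, so they stack into one batched
# forward pass). Targets are stored in the network's (B*npx) x 2 layout.
build_samples <- function(cases, cfg) {
  batches <- list()
  dropped <- 0L
  for (case in cases) {
    ct <- case$ct; ann <- case$annotations
    if (is.null(ct) || is.null(ann)) stop("each case needs ct and annotations")
    if (nrow(ann) == 0L) { dropped <- dropped + 1L; next }
    nv <- clip_normalize(ct, cfg$preprocess)
    d <- dim(nv)
    slices <- if (cfg$slice_policy == "all") seq_len(d[3]) else
      marker_slices(ann) + 1L
    for (chunk in split(slices, ceiling(seq_along(slices) / cfg$batch_size))) {
      B <- length(chunk)
      slabs <- array(0, dim = c(d[1], d[2], 3L, B))
      tgts <- array(0, dim = c(d[1], d[2], 2L, B))
      for (j in seq_len(B)) {
        slabs[, , , j] <- make_slab(nv, chunk[j])
        tgts[, , , j] <- make_heatmap_target(marker_pair(ann, chunk[j] - 1L),
                                             ct, cfg$heatmap)
      }
      Xmat <- if (B == 1L) matrix(slabs, d[1] * d[2], 3L) else
        matrix(aperm(slabs, c(1, 2, 4, 3)), d[1] * d[2] * B, 3L)
      attr(Xmat, "geom") <- c(d[1], d[2], B)
      batches[[length(batches) + 1L]] <- list(
        slab = Xmat,
        target = matrix(aperm(tgts, c(1, 2, 4, 3)), d[1] * d[2] * B, 2L),
        n_slices = B
      )
    }
  }
  if (dropped > 0L)
    warning(dropped, " case(s) without annotated slices excluded from training")
  batches
}

#' Train the lead-wire heatmap detector
#'
#' Stochastic gradient training (Adam, MSE heatmap loss) of the compact
#' two-scale network. The returned model carries the parameters of the epoch
#' with minimum validation loss, plus both loss curves.
#'
#' @param train_cases,val_cases lists of `phantom_case` objects (or lists with
#'   `ct` and `annotations`); both must be nonempty.
#' @param cfg a [train_config()].
#' @return A `detector_model` for [detect_markers()].
#' @export
train_detector <- function(train_cases, val_cases, cfg = train_config()) {
  if (length(train_cases) == 0L) stop("training set is empty")
  if (length(val_cases) == 0L) stop("validation set is empty")
  tr <- build_samples(train_cases, cfg)
  va <- build_samples(val_cases, cfg)
  if (length(tr) == 0L) stop("no usable training slices")
  params <- net_init(cfg$n_filters, n_in = 5L, seed = cfg$seed)
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  curve <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(tr))
      ep_loss <- 0; ep_n <- 0L
      for (i in ord) {
        s <- tr[[i]]
        fw <- net_forward(params, s$slab, train = TRUE)
        diffv <- fw$Y - s$target
        ep_loss <- ep_loss + mean(diffv^2) * s$n_slices
        ep_n <- ep_n + s$n_slices
        gr <- net_backward(params, fw, 2 * diffv / length(diffv))
        st <- adam_step(params, gr, opt, cfg$learning_rate)
        params <- st$params; opt <- st$state
      }
      vl_terms <- vapply(va, function(s) {
        fw <- net_forward(params, s$slab, train = FALSE)
        mean((fw$Y - s$target)^2) * s$n_slices
      }, numeric(1))
      vl <- sum(vl_terms) / sum(vapply(va, `[[`, numeric(1), "n_slices"))
      curve <- rbind(curve, data.frame(
        epoch = ep, train_loss = ep_loss / ep_n, val_loss = vl
      ))
      if (vl < best$loss) best <- list(loss = vl, params = params, epoch = ep)
    }
  })
  structure(
    list(params = best$params, best_epoch = best$epoch,
         val_loss = best$loss, curve = curve, cfg = cfg,
         pixel_spacing = train_cases[[1]]$ct$pixel_spacing),
    class = "detector_model"
  )
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf(
    "<detector_model> %d base filters, best epoch %d/%d (val MSE %.3g)\n",
    x$cfg$n_filters, x$best_epoch, x$cfg$epochs, x$val_loss
  ))
  invisible(x)
}

#' Save / load a trained detector
#'
#' The parameter state is written as a flat numeric vector alongside a JSON
#' sidecar describing shapes, geometry and training configuration, so model
#' files stay plain text.
#'
#' @param model a `detector_model`.
#' @param path file stem; `<path>.json` is written.
#' @export
write_detector <- function(model, path) {
  flat <- unlist(map_params(as.numeric, model$params))
  obj <- list(
    n_filters = model$cfg$n_filters,
    seed = model$cfg$seed,
    best_epoch = model$best_epoch,
    val_loss = model$val_loss,
    pixel_spacing = model$pixel_spacing,
    hu_window = model$cfg$preprocess$hu_window,
    sigma = model$cfg$heatmap$sigma,
    weights = flat
  )
  jsonlite::write_json(obj, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(path, ".json"))
}

#' @rdname write_detector
#' @export
read_detector <- function(path) {
  if (!grepl("\\.json$", path)) path <- paste0(path, ".json")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  template <- net_init(obj$n_filters, n_in = 5L, seed = 0L)
  flat <- obj$weights
  pos <- 0L
  params <- map_params(function(p) {
    v <- flat[pos + seq_along(p)]
    pos <<- pos + length(p)
    array(v, dim = dim(p) %||% length(p))
  }, template)
  cfg <- train_config(n_filters = obj$n_filters, seed = obj$seed,
                      heatmap = heatmap_spec(obj$sigma),
                      preprocess = preprocess_config(obj$hu_window))
  structure(
    list(params = params, best_epoch = obj$best_epoch, val_loss = obj$val_loss,
         curve = NULL, cfg = cfg, pixel_spacing = obj$pixel_spacing),
    class = "detector_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
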