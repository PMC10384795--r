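## Hierarchical point-set classifier ----------------------------------------
##
## An improved PointNet++-style network for filled/unfilled grain clouds:
## an additional set-abstraction (SA) layer in front of the standard chain,
## multi-scale grouping (MSG) at three ball radii, and a parallel branch that
## max-pools features of the normal channel into the global descriptor.
## The network, backpropagation and Adam optimizer are implemented in base R
## matrix algebra; every stochastic stage is seeded.

#' Network configuration
#'
#' Defaults mirror the classification protocol the package targets: 1024
#' input points with 6 channels (xyz + unit normals, unit-sphere
#' normalized), MSG radii 0.1/0.2/0.4 in normalized units, point counts
#' 1024 -> 512 -> 256 through the SA chain, groups padded from the 16 points
#' nearest each centroid, and two output classes.
#'
#' @param n_points input points per sample.
#' @param msg_radii three strictly increasing ball radii (normalized units).
#' @param sa_point_counts strictly decreasing centroid counts for the extra
#'   SA layer and the two MSG layers.
#' @param group_pad pool size used to pad undersized groups.
#' @param n_classes output classes.
#' @param normal_branch include the normal max-pooling branch.
#' @param extra_sa_layer include the additional first SA layer.
#' @param widths `"full"` or `"reduced"` preset for the shared MLP widths
#'   (reduced keeps the architecture but shrinks channels for CPU-scale
#'   experiments).
#' @return a `pointnet_config` list.
#' @export
pointnet_config <- function(n_points = 1024, msg_radii = c(0.1, 0.2, 0.4),
                            sa_point_counts = c(1024, 512, 256),
                            group_pad = 16, n_classes = 2,
                            normal_branch = TRUE, extra_sa_layer = TRUE,
                            widths = c("full", "reduced")) {
  widths <- match.arg(widths)
  if (any(diff(msg_radii) <= 0)) stop("msg_radii must be strictly increasing")
  if (any(diff(sa_point_counts) >= 0))
    stop("sa_point_counts must be strictly decreasing")
  if (any(sa_point_counts > n_points))
    stop("sa_point_counts cannot exceed n_points")
  w <- if (widths == "full") {
    list(sa0_mlp = c(32, 32), sa0_group = 16,
         msg1_mlps = rep(list(c(32, 64)), 3), msg1_groups = c(16, 32, 64),
         msg2_mlps = rep(list(c(64, 128)), 3), msg2_groups = c(16, 32, 64),
         global_mlp = c(128, 256), normal_mlp = c(16, 32), head_hidden = 128)
  } else {
    list(sa0_mlp = c(8, 8), sa0_group = 8,
         msg1_mlps = rep(list(c(8, 16)), 3), msg1_groups = c(8, 16, 32),
         msg2_mlps = rep(list(c(16, 32)), 3), msg2_groups = c(8, 16, 32),
         global_mlp = c(64), normal_mlp = c(8, 16), head_hidden = 32)
  }
  structure(c(list(n_points = as.integer(n_points), in_channels = 6L,
                   msg_radii = msg_radii,
                   msg2_radii = 2 * msg_radii,
                   sa_point_counts = as.integer(sa_point_counts),
                   group_pad = as.integer(group_pad),
                   n_classes = as.integer(n_classes),
                   normal_branch = normal_branch,
                   extra_sa_layer = extra_sa_layer,
                   widths = widths,
                   sa0_radius = msg_radii[1]),
              w),
            class = "pointnet_config")
}

#' Training configuration
#'
#' @param batch_size samples per optimizer step.
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param seed integer seed (initialization and shuffling).
#' @return a `pointnet_train_config` list.
#' @export
pointnet_train_config <- function(batch_size = 8, learning_rate = 1e-4,
                                  epochs = 60, seed = 1L) {
  if (batch_size < 1 || learning_rate <= 0 || epochs < 1)
    stop("batch_size, learning_rate and epochs must be positive")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "pointnet_train_config")
}

#' Farthest-point sampling
#'
#' Iteratively selects the point maximizing the minimum distance to the
#' already-selected set. The start point is the one farthest from the
#' centroid (ties broken lexicographically on coordinates), so the selection
#' depends only on the geometry, not the point order.
#'
#' @param xyz `n x 3` matrix.
#' @param m number of points to select (`<= n`).
#' @return integer vector of `m` selected indices, in selection order.
#' @export
farthest_point_sampling <- function(xyz, m) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (m > n) stop("cannot sample more points than available")
  pick_max <- function(d) {
    mx <- max(d)
    cand <- which(d >= mx - 1e-12)
    if (length(cand) == 1) return(cand)
    o <- do.call(order, as.data.frame(xyz[cand, , drop = FALSE]))
    cand[o[1]]
  }
  d0 <- rowSums(sweep(xyz, 2, colMeans(xyz))^2)
  sel <- integer(m)
  sel[1] <- pick_max(d0)
  if (m == 1) return(sel)
  dmin <- rowSums(sweep(xyz, 2, xyz[sel[1], ])^2)
  for (i in 2:m) {
    sel[i] <- pick_max(dmin)
    if (i < m)
      dmin <- pmin(dmin, rowSums(sweep(xyz, 2, xyz[sel[i], ])^2))
  }
  sel
}

# Squared distance matrix between rows of A (m x 3) and B (n x 3).
dist2_mat <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Sample and group points around centroids
#'
#' Centroids are chosen by [farthest_point_sampling()]; each centroid's group
#' is its ball-radius neighbourhood, truncated to the `group_size` nearest
#' members when too large and padded from the `pad_pool` nearest points
#' (cycled as needed) when too small, so every group has exactly
#' `group_size` members. Grouped coordinates are expressed relative to the
#' centroid.
#'
#' @param xyz point coordinates, `n x 3`.
#' @param features per-point features, `n x c` (optional).
#' @param n_centroids number of groups.
#' @param radius ball radius.
#' @param group_size members per group.
#' @param pad_pool nearest-point pool used for padding (default 16).
#' @return list with `centroid_idx`, `centroids` (`m x 3`), `groups`
#'   (`m x group_size` index matrix into `xyz` rows), `rel_xyz`
#'   (`(m*group_size) x 3`, group-major) and `grouped_features`.
#' @export
sample_and_group <- function(xyz, features = NULL, n_centroids, radius,
                             group_size, pad_pool = 16) {
  if (radius <= 0) stop("radius must be positive")
  xyz <- as.matrix(xyz)
  # selecting all points keeps them in input order (a trivial permutation);
  # downstream set functions are order-independent
  cidx <- if (n_centroids == nrow(xyz)) seq_len(nrow(xyz))
          else farthest_point_sampling(xyz, n_centroids)
  C <- xyz[cidx, , drop = FALSE]
  d2 <- dist2_mat(C, xyz)
  r2 <- radius^2
  groups <- matrix(0L, n_centroids, group_size)
  for (i in seq_len(n_centroids)) {
    o <- order(d2[i, ])
    inside <- o[d2[i, o] <= r2]
    if (length(inside) >= group_size) {
      groups[i, ] <- inside[seq_len(group_size)]
    } else {
      pool <- o[seq_len(min(pad_pool, ncol(d2)))]
      need <- group_size - length(inside)
      groups[i, ] <- c(inside, rep_len(pool, need))
    }
  }
  gi <- as.vector(t(groups))  # group-major rows
  rel <- xyz[gi, , drop = FALSE] -
    C[rep(seq_len(n_centroids), each = group_size), , drop = FALSE]
  list(centroid_idx = cidx, centroids = C, groups = groups, rel_xyz = rel,
       grouped_features = if (!is.null(features))
         as.matrix(features)[gi, , drop = FALSE])
}

## --- tiny autograd helpers -------------------------------------------------
##
## Shared point functions are linear -> batch norm -> ReLU stacks, the layer
## pattern of hierarchical point-set networks. Training normalizes with the
## statistics of the current mini-batch and maintains exponential running
## moments; evaluation freezes the running statistics, so inference is
## deterministic, independent of batch composition, and invariant to input
## point permutation. Weights use a small-gain initialization: under batch
## norm the function depends only on each weight vector's direction, so
## small gains let the fixed-size Adam steps reorient features quickly at
## short training budgets. The classification head is norm-free; its output
## layer starts at zero.

init_mlp <- function(sizes_in, widths, final_linear = FALSE, norm = TRUE) {
  layers <- vector("list", length(widths))
  d_in <- sizes_in
  for (i in seq_along(widths)) {
    W <- matrix(rnorm(d_in * widths[i], sd = 0.02), d_in, widths[i])
    layers[[i]] <- if (norm && !(final_linear && i == length(widths)))
      list(W = W, gamma = rep(1, widths[i]), beta = rep(0, widths[i]))
    else
      list(W = W, b = rep(0, widths[i]))
    d_in <- widths[i]
  }
  layers
}

bn_eps <- 1e-5
bn_momentum <- 0.1

# Fresh running statistics (mean 0, var 1) for every norm layer of an MLP.
init_mlp_stats <- function(layers) {
  lapply(layers, function(ly) {
    if (is.null(ly$gamma)) NULL
    else list(mean = rep(0, length(ly$gamma)), var = rep(1, length(ly$gamma)))
  })
}

# Forward through one shared MLP. `stats` holds per-layer running moments;
# in training mode the batch moments are used and the running ones updated
# (returned in `$stats`), in evaluation mode the running ones are frozen in.
mlp_forward <- function(layers, X, final_linear = FALSE, stats = NULL,
                        training = FALSE) {
  cache <- vector("list", length(layers))
  H <- X
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    Z <- H %*% ly$W
    n <- nrow(Z)
    if (is.null(ly$gamma)) {
      A <- Z + rep(ly$b, each = n)
      if (final_linear && i == length(layers)) {
        cache[[i]] <- list(input = H)
      } else {
        cache[[i]] <- list(input = H, pre = A)
        A <- pmax(A, 0)
      }
    } else if (training) {
      bn <- cpp_bn_forward(Z, ly$gamma, ly$beta, bn_eps)
      stats[[i]]$mean <- (1 - bn_momentum) * stats[[i]]$mean +
        bn_momentum * bn$mean
      stats[[i]]$var <- (1 - bn_momentum) * stats[[i]]$var +
        bn_momentum * bn$var
      cache[[i]] <- list(input = H, xhat = bn$xhat, sg = bn$sg, pre = bn$A)
      A <- pmax(bn$A, 0)
    } else {
      A <- cpp_bn_eval(Z, ly$gamma, ly$beta, stats[[i]]$mean,
                       stats[[i]]$var, bn_eps)
      cache[[i]] <- list(input = H, pre = A)
      A <- pmax(A, 0)
    }
    H <- A
  }
  list(out = H, cache = cache, stats = stats)
}

mlp_backward <- function(layers, cache, dOut, final_linear = FALSE) {
  grads <- vector("list", length(layers))
  dH <- dOut
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    cc <- cache[[i]]
    if (is.null(ly$gamma)) {
      if (!(final_linear && i == length(layers)))
        dH <- dH * (cc$pre > 0)
      grads[[i]] <- list(W = crossprod(cc$input, dH), b = colSums(dH))
      dH <- tcrossprod(dH, ly$W)
    } else {
      dH <- cpp_relu_mask(dH, cc$pre)
      bb <- cpp_bn_backward(dH, cc$xhat, cc$sg, ly$gamma)
      grads[[i]] <- list(W = crossprod(cc$input, bb$dZ),
                         gamma = bb$dgamma, beta = bb$dbeta)
      dH <- tcrossprod(bb$dZ, ly$W)
    }
  }
  list(grads = grads, dX = dH)
}

# Max over groups of g consecutive rows; returns (m x w) maxima and the
# winning replicate index per cell for gradient routing.
group_maxpool <- function(H, g) cpp_group_maxpool(H, as.integer(g))

group_maxpool_backward <- function(dOut, arg, g, n_rows) {
  cpp_maxpool_backward(dOut, arg, as.integer(g), as.integer(n_rows))
}

## --- model -----------------------------------------------------------------

#' Build a point-set classification model
#'
#' Initializes all shared MLP weights (He initialization, seeded); the final
#' classification layer starts at zero so early training follows the
#' class-mean feature direction.
#'
#' @param config a [pointnet_config()].
#' @param seed integer seed for the initialization.
#' @return object of class `pointnet_model`.
#' @export
build_pointnet <- function(config, seed = 1L) {
  with_seed(seed, {
    p <- list()
    feat_in <- config$in_channels
    if (config$extra_sa_layer) {
      p$sa0 <- init_mlp(3 + feat_in, config$sa0_mlp)
      f1 <- tail(config$sa0_mlp, 1)
    } else {
      f1 <- feat_in
    }
    p$msg1 <- lapply(config$msg1_mlps, function(wd) init_mlp(3 + f1, wd))
    f2 <- sum(vapply(config$msg1_mlps, function(wd) tail(wd, 1), 0))
    p$msg2 <- lapply(config$msg2_mlps, function(wd) init_mlp(3 + f2, wd))
    f3 <- sum(vapply(config$msg2_mlps, function(wd) tail(wd, 1), 0))
    p$global <- init_mlp(3 + f3, config$global_mlp)
    gdim <- tail(config$global_mlp, 1)
    if (config$normal_branch) {
      p$normal <- init_mlp(3, config$normal_mlp)
      gdim <- gdim + tail(config$normal_mlp, 1)
    }
    p$head <- init_mlp(gdim, c(config$head_hidden, config$n_classes),
                       final_linear = TRUE, norm = FALSE)
    # zero-init the output layer: logits start at 0
    k <- length(p$head)
    p$head[[k]]$W[] <- 0
    p$head[[k]]$b[] <- 0
    stats <- lapply(p, function(branch) {
      if (is.list(branch[[1]][[1]])) lapply(branch, init_mlp_stats)  # scales
      else init_mlp_stats(branch)
    })
    structure(list(config = config, params = p, stats = stats,
                   history = NULL, classes = NULL),
              class = "pointnet_model")
  })
}

#' Number of trainable parameters
#' @param model a `pointnet_model`.
#' @return integer parameter count.
#' @export
n_params <- function(model) length(unlist(model$params))

#' @export
print.pointnet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<pointnet_model> %s widths, %d input points, %d classes, %d parameters\n",
              cfg$widths, cfg$n_points, cfg$n_classes, n_params(x)))
  cat(sprintf("  SA chain: %s centroids; MSG radii %s\n",
              paste(cfg$sa_point_counts, collapse = " -> "),
              paste(cfg$msg_radii, collapse = "/")))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs, best test accuracy %.4f\n",
                nrow(x$history), max(x$history$test_accuracy)))
  invisible(x)
}

# Geometric grouping plan for one sample; depends only on coordinates.
build_plan <- function(xyz, config) {
  plan <- list()
  if (config$extra_sa_layer) {
    g0 <- sample_and_group(xyz, NULL, config$sa_point_counts[1],
                           config$sa0_radius, config$sa0_group,
                           config$group_pad)
    plan$sa0 <- g0
    P1 <- g0$centroids
  } else {
    P1 <- xyz
  }
  c1 <- farthest_point_sampling(P1, config$sa_point_counts[2])
  C1 <- P1[c1, , drop = FALSE]
  plan$msg1 <- list(centroid_idx = c1, centroids = C1,
                    scales = lapply(seq_along(config$msg_radii), function(s)
                      ball_groups(P1, C1, config$msg_radii[s],
                                  config$msg1_groups[s], config$group_pad)))
  c2 <- farthest_point_sampling(C1, config$sa_point_counts[3])
  C2 <- C1[c2, , drop = FALSE]
  plan$msg2 <- list(centroid_idx = c2, centroids = C2,
                    scales = lapply(seq_along(config$msg2_radii), function(s)
                      ball_groups(C1, C2, config$msg2_radii[s],
                                  config$msg2_groups[s], config$group_pad)))
  plan$P1 <- P1
  plan
}

# Ball-query groups for precomputed centroids (no internal FPS).
ball_groups <- function(xyz, C, radius, group_size, pad_pool) {
  m <- nrow(C)
  d2 <- dist2_mat(C, xyz)
  r2 <- radius^2
  groups <- matrix(0L, m, group_size)
  for (i in seq_len(m)) {
    o <- order(d2[i, ])
    inside <- o[d2[i, o] <= r2]
    if (length(inside) >= group_size) {
      groups[i, ] <- inside[seq_len(group_size)]
    } else {
      pool <- o[seq_len(min(pad_pool, ncol(d2)))]
      groups[i, ] <- c(inside, rep_len(pool, group_size - length(inside)))
    }
  }
  groups
}

# Forward a batch of samples. Samples are stacked row-wise (group plans get
# per-sample row offsets) so every shared MLP runs as one matrix product;
# max pooling over g consecutive rows then covers all groups of all samples
# at once. Returns the B x d descriptor matrix Z plus backprop caches.
forward_batch <- function(params, config, samples, plans, keep_cache = FALSE,
                          stats = NULL, training = FALSE) {
  B <- length(samples)
  n <- config$n_points
  X0 <- do.call(rbind, samples)  # (B n) x 6, sample-major blocks
  cache <- list()

  if (config$extra_sa_layer) {
    m0 <- config$sa_point_counts[1]
    g0 <- config$sa0_group
    off0 <- (seq_len(B) - 1L) * n
    gi <- unlist(lapply(seq_len(B), function(i)
      as.vector(t(plans[[i]]$sa0$groups)) + off0[i]), use.names = FALSE)
    P1 <- do.call(rbind, lapply(plans, function(p) p$sa0$centroids))
    rel <- cpp_group_rel(X0[, 1:3, drop = FALSE], gi, P1, g0)
    mf <- mlp_forward(params$sa0, cbind(rel, cpp_gather_rows(X0, gi)),
                      stats = stats$sa0, training = training)
    if (training) stats$sa0 <- mf$stats
    mp <- group_maxpool(mf$out, g0)
    F1 <- mp$out
    if (keep_cache) cache$sa0 <- list(mlp = mf$cache, arg = mp$arg, g = g0,
                                      n_rows = nrow(mf$out))
  } else {
    m0 <- n
    P1 <- X0[, 1:3, drop = FALSE]
    F1 <- X0
  }

  msg_forward <- function(stage_name, Pprev, Fprev, mlps, C, m_prev,
                          m_here, st) {
    off <- (seq_len(B) - 1L) * m_prev
    feats <- list()
    sc_cache <- list()
    for (s in seq_along(mlps)) {
      gsz <- ncol(plans[[1]][[stage_name]]$scales[[s]])
      gi <- unlist(lapply(seq_len(B), function(i)
        as.vector(t(plans[[i]][[stage_name]]$scales[[s]])) + off[i]),
        use.names = FALSE)
      rel <- cpp_group_rel(Pprev, gi, C, gsz)
      mf <- mlp_forward(mlps[[s]], cbind(rel, cpp_gather_rows(Fprev, gi)),
                        stats = st[[s]], training = training)
      if (training) st[[s]] <- mf$stats
      mp <- group_maxpool(mf$out, gsz)
      feats[[s]] <- mp$out
      sc_cache[[s]] <- list(mlp = mf$cache, arg = mp$arg, g = gsz,
                            n_rows = nrow(mf$out), gi = gi)
    }
    list(F = do.call(cbind, feats), cache = sc_cache, stats = st)
  }

  m1 <- config$sa_point_counts[2]
  m2 <- config$sa_point_counts[3]
  C1 <- do.call(rbind, lapply(plans, function(p) p$msg1$centroids))
  r1 <- msg_forward("msg1", P1, F1, params$msg1, C1, m0, m1, stats$msg1)
  if (training) stats$msg1 <- r1$stats
  F2 <- r1$F
  C2 <- do.call(rbind, lapply(plans, function(p) p$msg2$centroids))
  r2 <- msg_forward("msg2", C1, F2, params$msg2, C2, m1, m2, stats$msg2)
  if (training) stats$msg2 <- r2$stats
  F3 <- r2$F

  gf <- mlp_forward(params$global, cbind(C2, F3), stats = stats$global,
                    training = training)
  if (training) stats$global <- gf$stats
  gp <- group_maxpool(gf$out, m2)  # B x w
  Z <- gp$out
  if (config$normal_branch) {
    nf <- mlp_forward(params$normal, X0[, 4:6, drop = FALSE],
                      stats = stats$normal, training = training)
    if (training) stats$normal <- nf$stats
    np <- group_maxpool(nf$out, n)  # B x w
    Z <- cbind(Z, np$out)
    if (keep_cache) cache$normal <- list(mlp = nf$cache, arg = np$arg, g = n,
                                         n_rows = nrow(nf$out))
  }
  if (keep_cache) {
    cache$msg1 <- r1$cache
    cache$msg2 <- r2$cache
    cache$global <- list(mlp = gf$cache, arg = gp$arg, g = m2,
                         n_rows = nrow(gf$out))
    cache$dims <- list(B = B, nF1 = nrow(F1), wF1 = ncol(F1),
                       nF2 = nrow(F2), wF2 = ncol(F2))
  }
  list(Z = Z, cache = cache, stats = stats,
       sizes = c(input = n, msg1 = m1, msg2 = m2))
}

# Backward through the SA chain of a batch, given dZ (B x d).
backward_batch <- function(params, config, cache, dZ) {
  grads <- list()
  B <- cache$dims$B
  gdim <- tail(config$global_mlp, 1)
  dZg <- dZ[, seq_len(gdim), drop = FALSE]
  if (config$normal_branch) {
    cn <- cache$normal
    dH <- group_maxpool_backward(dZ[, -seq_len(gdim), drop = FALSE],
                                 cn$arg, cn$g, cn$n_rows)
    grads$normal <- mlp_backward(params$normal, cn$mlp, dH)$grads
  }
  cg <- cache$global
  dH <- group_maxpool_backward(dZg, cg$arg, cg$g, cg$n_rows)
  bg <- mlp_backward(params$global, cg$mlp, dH)
  grads$global <- bg$grads
  dF3 <- bg$dX[, -(1:3), drop = FALSE]

  msg_backward <- function(sc_cache, mlps, dF, n_prev, w_prev) {
    dFprev <- matrix(0, n_prev, w_prev)
    sgrads <- vector("list", length(sc_cache))
    col0 <- 0L
    for (s in seq_along(sc_cache)) {
      cs <- sc_cache[[s]]
      w <- ncol(cs$arg)
      dOut <- dF[, col0 + seq_len(w), drop = FALSE]
      col0 <- col0 + w
      dH <- group_maxpool_backward(dOut, cs$arg, cs$g, cs$n_rows)
      bs <- mlp_backward(mlps[[s]], cs$mlp, dH)
      sgrads[[s]] <- bs$grads
      dFprev <- dFprev + cpp_scatter_rows(bs$dX[, -(1:3), drop = FALSE],
                                          cs$gi, n_prev)
    }
    list(grads = sgrads, dFprev = dFprev)
  }

  b2 <- msg_backward(cache$msg2, params$msg2, dF3,
                     cache$dims$nF2, cache$dims$wF2)
  grads$msg2 <- b2$grads
  b1 <- msg_backward(cache$msg1, params$msg1, b2$dFprev,
                     cache$dims$nF1, cache$dims$wF1)
  grads$msg1 <- b1$grads

  if (config$extra_sa_layer) {
    c0 <- cache$sa0
    dH <- group_maxpool_backward(b1$dFprev, c0$arg, c0$g, c0$n_rows)
    grads$sa0 <- mlp_backward(params$sa0, c0$mlp, dH)$grads
  }
  grads
}

#' Forward pass of a point-set model
#'
#' @param model a `pointnet_model`.
#' @param sample an `n_points x 6` matrix (xyz + normals, normalized).
#' @return list with `logits` (length `n_classes`) and `sizes`, the point
#'   counts entering the network and surviving each MSG sampling stage.
#' @export
pointnet_forward <- function(model, sample) {
  sample <- as.matrix(sample)
  if (nrow(sample) != model$config$n_points || ncol(sample) != 6)
    stop("sample must be ", model$config$n_points, " x 6")
  plan <- build_plan(sample[, 1:3, drop = FALSE], model$config)
  fw <- forward_batch(model$params, model$config, list(sample), list(plan),
                      stats = model$stats)
  hd <- mlp_forward(model$params$head, fw$Z, final_linear = TRUE)
  list(logits = as.vector(hd$out), sizes = fw$sizes)
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

validate_dnn_dataset <- function(dataset, config) {
  if (length(dataset$train) == 0 || length(dataset$test) == 0)
    stop("empty train or test split")
  for (i in seq_along(dataset$samples)) {
    m <- dataset$samples[[i]]
    if (nrow(m) != config$n_points)
      stop("sample ", i, " has ", nrow(m), " points, expected ",
           config$n_points)
    if (ncol(m) != 6 || anyNA(m[, 4:6]))
      stop("sample ", i, " lacks a complete normal channel")
  }
  invisible(TRUE)
}

#' Train a point-set classifier
#'
#' Cross-entropy training with Adam on the train split of a prepared
#' dataset; after every epoch the test split is scored and the
#' best-accuracy weights are retained. Geometric grouping plans depend only
#' on the coordinates and are precomputed once per sample. Fully seeded:
#' identical seeds give identical histories.
#'
#' @param dataset result of [prepare_dataset()] (or
#'   [read_modelnet_dataset()]).
#' @param config a [pointnet_config()].
#' @param train_config a [pointnet_train_config()].
#' @param verbose print per-epoch progress.
#' @return a trained `pointnet_model` with `$history` (epoch, train_loss,
#'   test_accuracy) and best weights in `$params`.
#' @export
train_pointnet <- function(dataset, config = pointnet_config(),
                           train_config = pointnet_train_config(),
                           verbose = FALSE) {
  validate_dnn_dataset(dataset, config)
  y <- as.integer(dataset$labels)
  K <- config$n_classes
  if (max(y) > K) stop("more classes in data than n_classes")
  model <- build_pointnet(config, seed = train_config$seed)
  model$classes <- levels(dataset$labels)
  plans <- lapply(dataset$samples, function(s)
    build_plan(s[, 1:3, drop = FALSE], config))

  theta <- unlist(model$params)
  madam <- numeric(length(theta))
  vadam <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  lr <- train_config$learning_rate
  best_acc <- -1
  best_theta <- theta
  stats <- model$stats
  best_stats <- stats
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        test_accuracy = numeric(0))

  eval_split <- function(params, stats, idx) {
    correct <- 0L
    for (ch in split(idx, ceiling(seq_along(idx) / 16))) {
      fw <- forward_batch(params, config, dataset$samples[ch], plans[ch],
                          stats = stats)
      hd <- mlp_forward(params$head, fw$Z, final_linear = TRUE)
      correct <- correct +
        sum(max.col(hd$out, ties.method = "first") == y[ch])
    }
    correct / length(idx)
  }

  with_seed(train_config$seed + 1L, {
    for (epoch in seq_len(train_config$epochs)) {
      ord <- sample(dataset$train)
      batches <- split(ord, ceiling(seq_along(ord) / train_config$batch_size))
      ep_loss <- 0
      for (batch in batches) {
        params <- utils::relist(theta, model$params)
        B <- length(batch)
        fw <- forward_batch(params, config, dataset$samples[batch],
                            plans[batch], keep_cache = TRUE,
                            stats = stats, training = TRUE)
        stats <- fw$stats
        hd <- mlp_forward(params$head, fw$Z, final_linear = TRUE)
        P <- softmax_rows(hd$out)
        yb <- y[batch]
        loss <- -mean(log(pmax(P[cbind(seq_len(B), yb)], 1e-12)))
        ep_loss <- ep_loss + loss * B
        dL <- P
        dL[cbind(seq_len(B), yb)] <- dL[cbind(seq_len(B), yb)] - 1
        dL <- dL / B
        bh <- mlp_backward(params$head, hd$cache, dL, final_linear = TRUE)
        grads <- backward_batch(params, config, fw$cache, bh$dX)
        grads$head <- bh$grads
        # order the gradient tree like the parameter tree before flattening
        grads <- grads[names(model$params)]
        gvec <- unlist(grads)
        step <- step + 1L
        madam <- b1 * madam + (1 - b1) * gvec
        vadam <- b2 * vadam + (1 - b2) * gvec^2
        mhat <- madam / (1 - b1^step)
        vhat <- vadam / (1 - b2^step)
        theta <- theta - lr * mhat / (sqrt(vhat) + eps)
      }
      params <- utils::relist(theta, model$params)
      acc <- eval_split(params, stats, dataset$test)
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = ep_loss / length(ord),
                                  test_accuracy = acc))
      if (acc > best_acc) {
        best_acc <- acc
        best_theta <- theta
        best_stats <- stats
      }
      if (verbose)
        message(sprintf("epoch %d  loss %.4f  test acc %.4f",
                        epoch, ep_loss / length(ord), acc))
    }
  })
  model$params <- utils::relist(best_theta, model$params)
  model$stats <- best_stats
  model$history <- history
  model
}

#' Predict classes for samples
#'
#' @param model trained `pointnet_model`.
#' @param samples list of `n_points x 6` matrices.
#' @return list with `class` (factor), `logits` matrix and per-sample
#'   inference `times` (seconds).
#' @export
predict_pointnet <- function(model, samples) {
  K <- model$config$n_classes
  logits <- matrix(0, length(samples), K)
  times <- numeric(length(samples))
  for (i in seq_along(samples)) {
    t0 <- proc.time()[[3]]
    logits[i, ] <- pointnet_forward(model, samples[[i]])$logits
    times[i] <- proc.time()[[3]] - t0
  }
  cls <- factor(model$classes[max.col(logits, ties.method = "first")],
                levels = model$classes)
  list(class = cls, logits = logits, times = times)
}

#' Evaluate a trained model on a test split
#'
#' @param model trained `pointnet_model`.
#' @param dataset prepared dataset.
#' @param indices sample indices to score (default the test split).
#' @return a [classification_report()] with the confusion matrix in
#'   `$confusion` and predictions in `$predictions`.
#' @export
evaluate_pointnet <- function(model, dataset, indices = dataset$test) {
  truth <- dataset$labels[indices]
  if (any(table(truth) == 0))
    warning("a class is absent from the evaluated set; F1 refers to '",
            levels(truth)[1], "' only")
  pred <- predict_pointnet(model, dataset$samples[indices])
  rep <- classification_report(truth, pred$class, times = pred$times)
  rep$confusion <- table(truth = truth, predicted = pred$class)
  rep$predictions <- pred$class
  rep
}

#' Enhancement-variant ablation
#'
#' Trains one model per enhancement variant under identical seeds and
#' reports test accuracy and F1 per variant, mirroring an up-sampling /
#' normal-fusion ablation design.
#'
#' @param grains list of labeled grain clouds.
#' @param variants subset of `c("raw","up","normal","both")`.
#' @param config,train_config network and training configuration.
#' @param n_points,split_ratio,upsample_factor,search_radius dataset
#'   preparation parameters, see [prepare_dataset()].
#' @param data_seed seed of the dataset preparation (split shared across
#'   variants).
#' @param verbose print progress.
#' @return data.frame with one row per variant (`variant`, `accuracy`,
#'   `F1`, `misjudged`).
#' @export
run_ablation <- function(grains, variants = c("raw", "up", "normal", "both"),
                         config = pointnet_config(widths = "reduced"),
                         train_config = pointnet_train_config(epochs = 10),
                         n_points = config$n_points, split_ratio = 0.8,
                         upsample_factor = 2, search_radius = 0.8,
                         data_seed = 1L, verbose = FALSE) {
  known <- c("raw", "up", "normal", "both")
  rows <- list()
  for (v in variants) {
    if (!(v %in% known)) {
      warning("unknown variant '", v, "' skipped")
      next
    }
    ds <- prepare_dataset(grains, variant = v, n_points = n_points,
                          split_ratio = split_ratio,
                          upsample_factor = upsample_factor,
                          search_radius = search_radius, seed = data_seed)
    fit <- train_pointnet(ds, config, train_config, verbose = verbose)
    rep <- evaluate_pointnet(fit, ds)
    rows[[v]] <- data.frame(variant = v, accuracy = rep$accuracy,
                            F1 = rep$F1, misjudged = rep$FP + rep$FN)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
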